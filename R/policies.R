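#' Allocation policy specification
#'
#' The six studied bed-allocation policies combine an initial-allocation
#' mode with a consecutive-reallocation mode:
#'
#' | id | initial                    | consecutive        |
#' |----|----------------------------|--------------------|
#' | 0  | random                     | random replacement |
#' | 1  | random                     | ex-post triage     |
#' | 2  | ex-ante triage             | random replacement |
#' | 3  | ex-ante triage             | ex-post triage     |
#' | 4  | 90% random / 10% ex-ante   | random replacement |
#' | 5  | 90% random / 10% ex-ante   | ex-post triage     |
#'
#' Ex-ante triage fills empty beds with the patients of lowest perceived
#' death probability; ex-post triage lets currently treated patients
#' compete with the queue, so a treated patient can lose the bed to a
#' queued patient with better prognosis. Policy 4 mirrors a legal regime
#' that permits prognosis-based allocation of free beds but forbids
#' withdrawing allocated ones.
#'
#' @param policy_id Integer 0 to 5.
#' @return An object of class `"policy_spec"` with fields `policy_id`,
#'   `initial_mode` (`"random"`, `"exante"`, `"mixed"`),
#'   `mixed_random_fraction` (0.9) and `consecutive_mode`
#'   (`"random_replacement"`, `"expost"`).
#' @export
policy_spec <- function(policy_id) {
  stopifnot(is.numeric(policy_id), length(policy_id) == 1L,
            policy_id %in% 0:5)
  policy_id <- as.integer(policy_id)
  initial <- c("random", "random", "exante", "exante", "mixed", "mixed")
  consec <- c("random_replacement", "expost")[policy_id %% 2L + 1L]
  structure(list(policy_id = policy_id,
                 initial_mode = initial[policy_id + 1L],
                 mixed_random_fraction = 0.9,
                 consecutive_mode = consec),
            class = "policy_spec")
}

#' @export
print.policy_spec <- function(x, ...) {
  cat(sprintf("Policy %d: initial %s, consecutive %s\n",
              x$policy_id, x$initial_mode, x$consecutive_mode))
  invisible(x)
}

# sample k ids uniformly without replacement (safe for length-1 pools)
sample_ids <- function(x, k) x[sample.int(length(x), k)]

new_allocation <- function(treated, admitted, discharged, denied) {
  structure(list(treated = treated, admitted = admitted,
                 discharged = discharged, denied = denied),
            class = "allocation_result")
}

# Ranking key for triage: perceived probability with a random tie-break key
# drawn unconditionally from the current stream (so stream consumption does
# not depend on the data, and rankings are invariant to the scalar e).
triage_order <- function(p, e) {
  key <- stats::runif(length(p))
  order(perceived_probability(p, e), key)
}

#' Initial bed allocation
#'
#' Fills the `beds` intensive-care beds from the initial demand according
#' to the policy's initial mode: `random` picks patients uniformly (all of
#' them when demand equals capacity); `exante` picks the `beds` patients
#' with the lowest perceived death probability `e * p`; `mixed` fills
#' `floor(0.9 * beds)` beds uniformly at random and the remaining beds by
#' lowest perceived probability among the not-yet-admitted demanders.
#' Everyone not admitted is denied.
#'
#' @param spec A [policy_spec()].
#' @param demand Data frame of patients (as from [generate_patients()])
#'   requesting treatment.
#' @param beds Number of beds `B`.
#' @param e Misestimation factor for perceived probabilities.
#' @return An `allocation_result`: lists of patient ids `treated`
#'   (length `beds`), `admitted` (= treated here), `discharged` (empty)
#'   and `denied`.
#' @export
initial_allocation <- function(spec, demand, beds, e = 1) {
  stopifnot(inherits(spec, "policy_spec"), is.data.frame(demand),
            beds >= 1)
  n <- nrow(demand)
  if (n < beds)
    stop("infeasible demand: ", n, " patients for ", beds, " beds",
         call. = FALSE)
  ids <- demand$id
  treated <- switch(
    spec$initial_mode,
    random = if (n == beds) ids else sample_ids(ids, beds),
    exante = ids[triage_order(demand$p, e)[seq_len(beds)]],
    mixed = {
      n_rand <- floor(spec$mixed_random_fraction * beds)
      rand_ids <- sample_ids(ids, n_rand)
      rest <- demand[!ids %in% rand_ids, , drop = FALSE]
      tri_ids <- rest$id[triage_order(rest$p, e)[seq_len(beds - n_rand)]]
      c(rand_ids, tri_ids)
    })
  new_allocation(treated = treated, admitted = treated,
                 discharged = integer(0),
                 denied = setdiff(ids, treated))
}

#' Random consecutive replacement step
#'
#' `replace_count` bed-holders chosen uniformly without replacement free
#' their beds; `replace_count` queue members chosen uniformly without
#' replacement receive them. The remaining queue members are denied. With
#' the default configuration this is 6 patients, i.e. 10% of capacity, per
#' time point regardless of queue length.
#'
#' @param treated Data frame of currently treated patients.
#' @param queue Data frame of queued patients.
#' @param replace_count Number of beds turned over.
#' @return An `allocation_result`; `treated` keeps size `nrow(treated)`.
#' @export
step_random_replacement <- function(treated, queue, replace_count) {
  stopifnot(is.data.frame(treated), is.data.frame(queue),
            replace_count >= 0)
  if (replace_count > min(nrow(treated), nrow(queue)))
    stop("replace_count ", replace_count,
         " exceeds cohort or queue size", call. = FALSE)
  discharged <- if (replace_count == 0) integer(0) else
    sample_ids(treated$id, replace_count)
  admitted <- if (replace_count == 0) integer(0) else
    sample_ids(queue$id, replace_count)
  new_allocation(treated = c(setdiff(treated$id, discharged), admitted),
                 admitted = admitted, discharged = discharged,
                 denied = setdiff(queue$id, admitted))
}

#' Ex-post triage step
#'
#' Currently treated patients and the queue are pooled; the `beds` pool
#' members with the lowest perceived death probability `e * p` keep or
#' receive beds (ties broken uniformly at random). Displaced bed-holders
#' are discharged; queue members not admitted are denied.
#'
#' @inheritParams step_random_replacement
#' @param beds Number of beds `B` (= `nrow(treated)`).
#' @param e Misestimation factor.
#' @return An `allocation_result` with `treated` of size `beds`.
#' @export
step_expost_triage <- function(treated, queue, beds, e = 1) {
  stopifnot(is.data.frame(treated), is.data.frame(queue))
  if (nrow(treated) != beds)
    stop("ex-post step requires a full cohort of ", beds, " beds",
         call. = FALSE)
  pool_id <- c(treated$id, queue$id)
  pool_p <- c(treated$p, queue$p)
  keep <- pool_id[triage_order(pool_p, e)[seq_len(beds)]]
  new_allocation(treated = keep,
                 admitted = intersect(queue$id, keep),
                 discharged = setdiff(treated$id, keep),
                 denied = setdiff(queue$id, keep))
}
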