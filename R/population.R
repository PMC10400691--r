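#' Generate simulated patients
#'
#' Draws `count` patients from a [population_mix()]. Each patient is
#' independently comorbid with probability `share_comorbid`; a comorbid
#' patient is assigned the disability category with probability
#' `disability_share` (otherwise pre-existing) and then a concrete
#' condition within the category with probability proportional to the
#' prevalence weights (or the fixed `single_condition`). The true death
#' probability `p` is drawn from the condition's triangle (the baseline
#' triangle for patients without comorbidity) and the death indicator `y`
#' is a Bernoulli draw with success probability `p`, realised through one
#' uniform on `[0, 1]`.
#'
#' Draw-order contract: each patient consumes exactly five uniforms from
#' the current R random stream, in the fixed order (comorbidity, category,
#' condition, death probability, death indicator). Draws that a patient
#' does not need (e.g. the condition draw of a healthy patient) are still
#' consumed, so the generated sequence is identical whether patients are
#' generated in one batch or several, given the same stream state.
#'
#' `y` is fixed at generation and never re-drawn: a patient's survival
#' prospect does not change during treatment in this model.
#'
#' @param count Number of patients (>= 1).
#' @param mix A [population_mix()] object.
#' @param id_offset Integer added to the running patient ids (used by the
#'   engine to keep ids unique across the initial demand and later
#'   queues).
#' @return A data frame with one row per patient and columns `id`,
#'   `comorbid` (0/1), `condition` (label or `NA`), `p` (true death
#'   probability) and `y` (0/1 death indicator).
#' @examples
#' set.seed(1)
#' generate_patients(5, population_mix(share_comorbid = 0.5))
#' @export
generate_patients <- function(count, mix, id_offset = 0L) {
  stopifnot(is.numeric(count), length(count) == 1L, count >= 1)
  stopifnot(inherits(mix, "population_mix"))
  count <- as.integer(count)
  u <- matrix(stats::runif(5L * count), ncol = 5L, byrow = TRUE)
  comorbid <- u[, 1L] < mix$share_comorbid

  condition <- rep(NA_character_, count)
  if (any(comorbid)) {
    if (!is.null(mix$single_condition)) {
      condition[comorbid] <- mix$single_condition
    } else {
      disab <- u[, 2L] < mix$disability_share
      for (cat in c("disability", "pre-existing")) {
        sel <- comorbid & (disab == (cat == "disability"))
        if (!any(sel)) next
        w <- category_weights(mix$profiles, cat)
        cw <- cumsum(w) / sum(w)
        idx <- findInterval(u[sel, 3L], cw) + 1L
        condition[sel] <- names(w)[idx]
      }
    }
  }

  p <- qtriangular(u[, 4L], mix$baseline)
  for (k in unique(condition[!is.na(condition)])) {
    sel <- !is.na(condition) & condition == k
    p[sel] <- qtriangular(u[sel, 4L], mix$profiles[[k]]$triangle)
  }
  y <- as.integer(u[, 5L] < p)

  fast_df(id = id_offset + seq_len(count),
          comorbid = as.integer(comorbid),
          condition = condition,
          p = p, y = y)
}

# data.frame constructor without the validation overhead of data.frame();
# callers guarantee equal-length atomic columns
fast_df <- function(...) {
  cols <- list(...)
  structure(cols, class = "data.frame",
            row.names = .set_row_names(length(cols[[1L]])))
}

#' Perceived death probability
#'
#' The probability a clinician acts on when triaging: the true death
#' probability scaled by the misestimation factor `e` (`e = 1` is a
#' correct estimate; `e = 0.9` or `1.1` a systematic 10% under- or
#' over-estimate). The perceived probability is used exclusively for
#' ranking in allocation decisions; death indicators are always drawn from
#' the true probability.
#'
#' @param p True death probability (vectorised).
#' @param e Positive misestimation factor.
#' @return `e * p`.
#' @export
perceived_probability <- function(p, e) {
  stopifnot(is.numeric(e), length(e) == 1L, e > 0)
  stopifnot(all(p >= 0 & p <= 1))
  e * p
}

#' Draw death indicators
#'
#' Bernoulli draw via one uniform per patient: the indicator is 1 iff the
#' uniform falls below the death probability.
#'
#' @param p Death probabilities (vectorised).
#' @return Integer vector of 0/1 indicators, one per element of `p`.
#' @export
draw_death_flag <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  as.integer(stats::runif(length(p)) < p)
}
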