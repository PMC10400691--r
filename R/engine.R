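#' Experiment configuration
#'
#' Bundles every parameter of a simulation experiment. Defaults are the
#' study conditions of the mixed-population scenario: 10,000 replications,
#' 60 beds (the fully staffed surge capacity of a large German university
#' hospital), initial demand 70, queue length 10 at each of 3 consecutive
#' reallocation time points, comorbid share 0.7, correct probability
#' estimation (`e = 1`), all six policies.
#'
#' @param replications Number of Monte-Carlo replications `R`.
#' @param horizon Number of consecutive reallocation time points `T`
#'   (metrics are reported at `t = 0, ..., T`).
#' @param beds ICU capacity `B`.
#' @param initial_demand Demand `d` at initialisation, used by policies
#'   with an ex-ante or mixed initial allocation. Policies with purely
#'   random initial allocation generate exactly `B` patients unless
#'   `random_init_from_pool = TRUE`, in which case they sample `B` of `d`.
#' @param queue_length Queue length `w` generated at each time point.
#' @param comorbid_share Share `s` of comorbid patients; used to build the
#'   default mix when `mix` is not supplied.
#' @param misestimation Misestimation factor `e` applied to perceived
#'   probabilities in every triage decision.
#' @param policies Integer vector, subset of `0:5`.
#' @param mix A [population_mix()]; defaults to [default_mix()] with the
#'   given `comorbid_share`.
#' @param master_seed Integer master seed; every random draw in the
#'   experiment derives deterministically from it (see Details).
#' @param replace_count Beds turned over per random-replacement step;
#'   default `floor(0.1 * beds)`, i.e. 10% of capacity, independent of
#'   the queue length.
#' @param random_init_from_pool See `initial_demand`.
#'
#' @details Seed discipline: the master seed spawns named substreams per
#'   replication — one for the initial demand, one for the initial
#'   allocation, and one per time point for the queue and for the step's
#'   own randomness. Substream derivation does not involve the policy id
#'   or `e`, so policies sharing an initial mode see identical initial
#'   cohorts, and runs differing only in `e` see identical draws
#'   throughout.
#'
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(replications = 10000L, horizon = 3L,
                              beds = 60L, initial_demand = 70L,
                              queue_length = 10L, comorbid_share = 0.7,
                              misestimation = 1, policies = 0:5,
                              mix = NULL, master_seed = 1L,
                              replace_count = NULL,
                              random_init_from_pool = FALSE) {
  stopifnot(replications >= 1, horizon >= 0, beds >= 1,
            queue_length >= 0, misestimation > 0,
            all(policies %in% 0:5), length(policies) >= 1)
  if (is.null(mix)) mix <- default_mix(share_comorbid = comorbid_share)
  stopifnot(inherits(mix, "population_mix"))
  if (is.null(replace_count)) replace_count <- floor(0.1 * beds)
  if (any(policies >= 2) && initial_demand < beds)
    stop("initial_demand (", initial_demand, ") must be >= beds (", beds,
         ") for policies with ex-ante or mixed initial allocation",
         call. = FALSE)
  if (any(policies %in% c(0, 2, 4)) && horizon > 0 &&
      queue_length < replace_count)
    stop("queue_length (", queue_length, ") must be >= replace_count (",
         replace_count, ") for random-replacement policies", call. = FALSE)
  structure(list(replications = as.integer(replications),
                 horizon = as.integer(horizon),
                 beds = as.integer(beds),
                 initial_demand = as.integer(initial_demand),
                 queue_length = as.integer(queue_length),
                 comorbid_share = mix$share_comorbid,
                 misestimation = misestimation,
                 policies = as.integer(sort(unique(policies))),
                 mix = mix,
                 master_seed = as.integer(master_seed),
                 replace_count = as.integer(replace_count),
                 random_init_from_pool = isTRUE(random_init_from_pool)),
            class = "experiment_config")
}

# Deterministic substream seed: mixes the master seed with numeric and
# character labels into [0, 2^31 - 2]. All arithmetic stays below 2^53,
# so the result is exact in double precision and platform-independent.
mix_seed <- function(master, ...) {
  parts <- c(master,
             unlist(lapply(list(...), function(x) {
               if (is.character(x)) utf8ToInt(paste(x, collapse = ""))
               else as.numeric(x)
             })))
  h <- 0
  for (p in parts) h <- (h * 69069 + p + 1) %% 2147483647
  as.integer(h)
}

metric_names <- c("m_total", "m_healthy", "m_comorbid",
                  "treated_healthy", "treated_comorbid",
                  "admitted_healthy", "admitted_comorbid",
                  "discharged_healthy", "discharged_comorbid")

# One row of time-point metrics as a numeric vector; group membership and
# death indicators looked up in the id-indexed registry vectors. Group
# mortalities are NA when no patient of that group is currently treated.
tp_metrics_row <- function(treated_ids, alloc, reg_com, reg_y, beds) {
  com <- reg_com[treated_ids]
  y <- reg_y[treated_ids]
  nv <- sum(com); nh <- beds - nv
  adm <- reg_com[alloc$admitted]
  dis <- reg_com[alloc$discharged]
  c(m_total = sum(y) / beds,
    m_healthy = if (nh > 0) sum(y[com == 0L]) / nh else NA_real_,
    m_comorbid = if (nv > 0) sum(y[com == 1L]) / nv else NA_real_,
    treated_healthy = nh, treated_comorbid = nv,
    admitted_healthy = sum(adm == 0L), admitted_comorbid = sum(adm == 1L),
    discharged_healthy = sum(dis == 0L), discharged_comorbid = sum(dis == 1L))
}

# Core replication loop; returns a (horizon + 1) x 9 metric matrix.
# Patients are registered in id-indexed vectors (ids are consecutive
# across the initial demand and the per-time-point queues), so cohort
# bookkeeping is plain integer indexing.
replicate_core <- function(spec, config, rep_index, patient_source = NULL) {
  ms <- config$master_seed
  beds <- config$beds
  e <- config$misestimation
  gen <- function(n, offset, seed) {
    if (!is.null(patient_source)) return(patient_source(n, offset))
    set.seed(seed)
    generate_patients(n, config$mix, id_offset = offset)
  }
  n0 <- if (spec$initial_mode == "random" && !config$random_init_from_pool)
    beds else config$initial_demand
  n_all <- n0 + config$horizon * config$queue_length
  reg_com <- integer(n_all); reg_p <- numeric(n_all); reg_y <- integer(n_all)
  register <- function(df) {
    reg_com[df$id] <<- df$comorbid
    reg_p[df$id] <<- df$p
    reg_y[df$id] <<- df$y
  }
  demand <- gen(n0, 0L, mix_seed(ms, "demand", rep_index))
  register(demand)
  set.seed(mix_seed(ms, "init", rep_index))
  alloc <- initial_allocation(spec, demand, beds, e)
  treated <- alloc$treated
  out <- matrix(NA_real_, nrow = config$horizon + 1L,
                ncol = length(metric_names),
                dimnames = list(NULL, metric_names))
  out[1L, ] <- tp_metrics_row(treated, alloc, reg_com, reg_y, beds)
  offset <- n0
  for (t in seq_len(config$horizon)) {
    queue <- gen(config$queue_length, offset,
                 mix_seed(ms, "queue", rep_index, t))
    register(queue)
    offset <- offset + config$queue_length
    cohort <- fast_df(id = treated, p = reg_p[treated])
    set.seed(mix_seed(ms, "step", rep_index, t))
    alloc <- switch(spec$consecutive_mode,
                    random_replacement =
                      step_random_replacement(cohort, queue,
                                              config$replace_count),
                    expost = step_expost_triage(cohort, queue, beds, e))
    treated <- alloc$treated
    out[t + 1L, ] <- tp_metrics_row(treated, alloc, reg_com, reg_y, beds)
  }
  out
}

#' Run one replication of a policy
#'
#' Executes a single simulation replication: initial demand generation and
#' allocation at `t = 0`, then for each consecutive time point a fresh
#' queue of `queue_length` patients and the policy's reallocation step.
#' Death probabilities and indicators are fixed at generation and never
#' re-drawn; denied and discharged patients leave the system permanently.
#' The prospective mortality `m_t` is the fraction of the currently
#' treated cohort whose pre-drawn death indicator is 1.
#'
#' @param spec A [policy_spec()].
#' @param config An [experiment_config()].
#' @param rep_index Replication index (feeds the substream seeds).
#' @param patient_source Optional generator override: a
#'   `function(count, id_offset)` returning a patient data frame. Intended
#'   for deterministic test scenarios; when supplied, the demand and queue
#'   substreams are bypassed.
#' @return A data frame with one row per time point `0..horizon`: columns
#'   `time`, `m_total`, `m_healthy`, `m_comorbid` (group mortalities, `NA`
#'   when the group is absent from the cohort) and per-group
#'   treated/admitted/discharged counts.
#' @export
run_replication <- function(spec, config, rep_index = 1L,
                            patient_source = NULL) {
  stopifnot(inherits(spec, "policy_spec"),
            inherits(config, "experiment_config"))
  m <- replicate_core(spec, config, rep_index, patient_source)
  data.frame(time = 0:config$horizon, m, row.names = NULL)
}

#' Run a full simulation experiment
#'
#' Runs `replications` independent replications for every requested policy
#' and aggregates means and standard deviations of all metrics per policy
#' and time point. Replication-level records are retained for statistical
#' evaluation (see [compare_policies()]).
#'
#' @param config An [experiment_config()].
#' @param progress Print a progress line per policy.
#' @return An object of class `"triage_experiment"`: a list with the
#'   `config`, the replication-level data frame `replications` (columns
#'   `policy`, `rep`, `time`, metrics) and the aggregated `summary`
#'   (per policy and time point: `mean_*` and `sd_*` for every metric,
#'   plus `n_healthy_absent` / `n_comorbid_absent`, the number of
#'   replications in which that group was absent from the treated cohort
#'   and therefore contributed no group mortality value).
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  R <- config$replications
  tp <- config$horizon + 1L
  specs <- lapply(config$policies, policy_spec)
  nrow_total <- length(specs) * R * tp
  big <- matrix(NA_real_, nrow = nrow_total, ncol = length(metric_names))
  policy_col <- integer(nrow_total)
  rep_col <- integer(nrow_total)
  time_col <- integer(nrow_total)
  row <- 0L
  for (spec in specs) {
    if (progress)
      message("policy ", spec$policy_id, ": ", R, " replications")
    for (r in seq_len(R)) {
      idx <- row + seq_len(tp)
      big[idx, ] <- replicate_core(spec, config, r)
      policy_col[idx] <- spec$policy_id
      rep_col[idx] <- r
      time_col[idx] <- 0:(tp - 1L)
      row <- row + tp
    }
  }
  colnames(big) <- metric_names
  reps <- data.frame(policy = policy_col, rep = rep_col, time = time_col,
                     big, row.names = NULL)
  structure(list(config = config,
                 replications = reps,
                 summary = summarise_replications(reps)),
            class = "triage_experiment")
}

summarise_replications <- function(reps) {
  key <- interaction(reps$policy, reps$time, drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(reps)), key)
  rows <- lapply(groups, function(idx) {
    d <- reps[idx, , drop = FALSE]
    out <- data.frame(policy = d$policy[1L], time = d$time[1L],
                      n_reps = nrow(d))
    for (m in metric_names) {
      out[[paste0("mean_", m)]] <- mean(d[[m]], na.rm = TRUE)
      out[[paste0("sd_", m)]] <- stats::sd(d[[m]][!is.na(d[[m]])])
    }
    out$n_healthy_absent <- sum(is.na(d$m_healthy))
    out$n_comorbid_absent <- sum(is.na(d$m_comorbid))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$policy, out$time), , drop = FALSE]
}

#' @export
print.triage_experiment <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Triage simulation experiment: %d policies x %d ",
                     "replications, t = 0..%d\n"),
              length(cfg$policies), cfg$replications, cfg$horizon))
  cat(sprintf("B = %d beds, d = %d, w = %d, s = %.2f, e = %g, seed = %d\n",
              cfg$beds, cfg$initial_demand, cfg$queue_length,
              cfg$comorbid_share, cfg$misestimation, cfg$master_seed))
  cat("\nMean total mortality (%):\n")
  print(round(100 * mortality_matrix(x, "mean_m_total"), 1))
  invisible(x)
}

mortality_matrix <- function(experiment, col) {
  s <- experiment$summary
  pol <- sort(unique(s$policy)); tt <- sort(unique(s$time))
  m <- matrix(NA_real_, nrow = length(tt), ncol = length(pol),
              dimnames = list(paste0("t=", tt), paste0("policy", pol)))
  for (i in seq_len(nrow(s)))
    m[paste0("t=", s$time[i]), paste0("policy", s$policy[i])] <-
      s[[col]][i]
  m
}

#' Group-mortality table at one time point
#'
#' Mean mortality in percent, by policy (columns) for all patients, the
#' healthy group and the comorbid group (rows) at one time point — the
#' layout in which per-group results are usually reported.
#'
#' @param experiment A `triage_experiment`.
#' @param time Time point (default 1, the first reallocation).
#' @return A 3 x n-policies numeric matrix of percentages.
#' @export
mortality_table <- function(experiment, time = 1L) {
  stopifnot(inherits(experiment, "triage_experiment"))
  s <- experiment$summary[experiment$summary$time == time, , drop = FALSE]
  if (nrow(s) == 0L) stop("no results at time ", time, call. = FALSE)
  out <- rbind(all = s$mean_m_total,
               healthy = s$mean_m_healthy,
               comorbid = s$mean_m_comorbid) * 100
  colnames(out) <- paste0("policy", s$policy)
  out
}

#' Sensitivity grid over demand, queue length and misestimation
#'
#' Re-runs the experiment over the cross product of initial demands,
#' queue lengths and misestimation factors. Infeasible cells (demand below
#' capacity for ex-ante policies, queue shorter than the replacement
#' count) are skipped with a warning. Because substream seeds do not
#' depend on `e`, cells differing only in `e` reproduce identical
#' allocations and hence identical summaries.
#'
#' @param base An [experiment_config()] providing all other settings.
#' @param demands Integer vector of initial demands `d`.
#' @param queues Integer vector of queue lengths `w`.
#' @param misestimations Numeric vector of misestimation factors `e`.
#' @return A list of class `"sensitivity_grid"`; each element has the
#'   cell's `d`, `w`, `e` and the `triage_experiment`.
#' @export
sensitivity_grid <- function(base, demands = c(70L, 90L),
                             queues = c(10L, 20L, 30L, 60L),
                             misestimations = c(0.9, 1, 1.1)) {
  stopifnot(inherits(base, "experiment_config"))
  cells <- expand.grid(d = demands, w = queues, e = misestimations,
                       KEEP.OUT.ATTRS = FALSE)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cfg <- base
    cfg$initial_demand <- as.integer(cells$d[i])
    cfg$queue_length <- as.integer(cells$w[i])
    cfg$misestimation <- cells$e[i]
    feasible <- tryCatch({
      experiment_config(replications = cfg$replications,
                        horizon = cfg$horizon, beds = cfg$beds,
                        initial_demand = cfg$initial_demand,
                        queue_length = cfg$queue_length,
                        misestimation = cfg$misestimation,
                        policies = cfg$policies, mix = cfg$mix,
                        master_seed = cfg$master_seed,
                        replace_count = cfg$replace_count,
                        random_init_from_pool = cfg$random_init_from_pool)
    }, error = function(err) {
      warning("skipping infeasible cell d=", cells$d[i], " w=", cells$w[i],
              " e=", cells$e[i], ": ", conditionMessage(err), call. = FALSE)
      NULL
    })
    if (is.null(feasible)) next
    out[[length(out) + 1L]] <-
      list(d = cfg$initial_demand, w = cfg$queue_length,
           e = cfg$misestimation, experiment = run_experiment(feasible))
  }
  structure(out, class = "sensitivity_grid")
}
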