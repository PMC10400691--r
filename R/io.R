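#' Load an experiment configuration from a YAML file
#'
#' Reads a structured configuration file and returns a validated
#' [experiment_config()] with defaults filled in for everything the file
#' does not set. An empty file yields the full default configuration
#' (R = 10,000, T = 3, B = 60, d = 70, w = 10, s = 0.7, e = 1, all six
#' policies). Unknown keys are rejected with a field-level message.
#'
#' Recognised keys: `replications`, `horizon`, `beds`, `initial_demand`,
#' `queue_length`, `comorbid_share`, `disability_share`, `misestimation`,
#' `policies`, `master_seed`, `replace_count`, `random_init_from_pool`,
#' `single_condition`, `calibrate`, `calibration_target`, `baseline`
#' (triple `[min, max, mode]`) and `comorbidities` — a list of entries
#' with `name`, `category`, `relative_risk`, `prevalence_weight` and
#' optionally an explicit `triangle` triple, a `method`
#' (`translate` / `translate_widen`) and a `widen` amount.
#'
#' @param path Path to a YAML file.
#' @return An [experiment_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  known <- c("replications", "horizon", "beds", "initial_demand",
             "queue_length", "comorbid_share", "disability_share",
             "misestimation", "policies", "master_seed", "replace_count",
             "random_init_from_pool", "single_condition", "calibrate",
             "calibration_target", "baseline", "comorbidities")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  get <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]

  baseline <- if (is.null(raw$baseline)) baseline_triangle() else
    as_triangular(unlist(raw$baseline))
  profiles <- if (is.null(raw$comorbidities)) default_comorbidities() else
    lapply(raw$comorbidities, function(entry) {
      req <- c("name", "category", "relative_risk", "prevalence_weight")
      missing <- setdiff(req, names(entry))
      if (length(missing) > 0L)
        stop("comorbidity entry missing field(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      scaling <- if (!is.null(entry$triangle))
        risk_scaling(entry$relative_risk, method = "explicit",
                     explicit = as_triangular(unlist(entry$triangle)))
      else
        risk_scaling(entry$relative_risk,
                     method = if (is.null(entry$method)) "translate"
                              else entry$method,
                     widen = if (is.null(entry$widen)) 0 else entry$widen)
      comorbidity_profile(entry$name, entry$category, scaling,
                          entry$prevalence_weight, base = baseline)
    })

  mix <- population_mix(share_comorbid = get("comorbid_share", 0.7),
                        disability_share = get("disability_share", 0.10),
                        profiles = profiles,
                        single_condition = raw$single_condition,
                        baseline = baseline)
  if (isTRUE(get("calibrate", is.null(raw$comorbidities))))
    mix <- calibrate_prevalence_weights(mix,
                                        target = get("calibration_target",
                                                     0.438))

  experiment_config(replications = get("replications", 10000L),
                    horizon = get("horizon", 3L),
                    beds = get("beds", 60L),
                    initial_demand = get("initial_demand", 70L),
                    queue_length = get("queue_length", 10L),
                    misestimation = get("misestimation", 1),
                    policies = get("policies", 0:5),
                    mix = mix,
                    master_seed = get("master_seed", 1L),
                    replace_count = raw$replace_count,
                    random_init_from_pool = get("random_init_from_pool",
                                                FALSE))
}

config_as_list <- function(config) {
  mix <- config$mix
  list(replications = config$replications, horizon = config$horizon,
       beds = config$beds, initial_demand = config$initial_demand,
       queue_length = config$queue_length,
       comorbid_share = mix$share_comorbid,
       disability_share = mix$disability_share,
       misestimation = config$misestimation,
       policies = config$policies,
       master_seed = config$master_seed,
       replace_count = config$replace_count,
       random_init_from_pool = config$random_init_from_pool,
       single_condition = mix$single_condition,
       baseline = unlist(mix$baseline),
       comorbidities = lapply(unname(mix$profiles), function(p) {
         list(name = p$name, category = p$category,
              relative_risk = p$scaling$relative_risk,
              method = p$scaling$method,
              prevalence_weight = p$prevalence_weight,
              triangle = unlist(p$triangle),
              mean = triangular_mean(p$triangle))
       }))
}

#' Run manifest
#'
#' A JSON-serialisable record of everything needed to reproduce an
#' experiment bitwise: the fully resolved configuration (including the
#' derived comorbidity triangles and calibrated prevalence weights), the
#' package version, the master seed, the per-policy replication-1
#' substream seeds, and a timestamp.
#'
#' @param config An [experiment_config()].
#' @return A list of class `"run_manifest"`.
#' @export
run_manifest <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  ms <- config$master_seed
  sub <- list(demand = mix_seed(ms, "demand", 1L),
              init = mix_seed(ms, "init", 1L))
  for (t in seq_len(config$horizon)) {
    sub[[paste0("queue_t", t)]] <- mix_seed(ms, "queue", 1L, t)
    sub[[paste0("step_t", t)]] <- mix_seed(ms, "step", 1L, t)
  }
  structure(list(package = "icutriage",
                 version = as.character(utils::packageVersion("icutriage")),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 master_seed = ms,
                 substream_seeds_rep1 = sub,
                 config = config_as_list(config)),
            class = "run_manifest")
}

# Numeric columns rendered with 17 significant digits so that reading the
# CSV back reproduces every double bitwise.
write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA, sprintf("%.17g", out[[j]]))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
}

#' Write experiment results to a directory
#'
#' Writes the replication-level table (`replications.csv`, one row per
#' replication x policy x time point), the summary table
#' (`summary.csv`), a wide per-group mortality table per time point
#' (`mortality_by_group.csv`, percentages) and the JSON manifest
#' (`manifest.json`). CSVs are UTF-8 with a header row and dot decimal
#' separator; numeric values carry full precision so
#' [read_results()] round-trips them exactly.
#'
#' @param experiment A `triage_experiment`.
#' @param out_dir Output directory (created if needed).
#' @param manifest Optional [run_manifest()]; derived from the
#'   experiment's config when omitted.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(experiment, out_dir, manifest = NULL) {
  stopifnot(inherits(experiment, "triage_experiment"))
  if (is.null(manifest)) manifest <- run_manifest(experiment$config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(replications = file.path(out_dir, "replications.csv"),
             summary = file.path(out_dir, "summary.csv"),
             mortality = file.path(out_dir, "mortality_by_group.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  write_csv_exact(experiment$replications, paths["replications"])
  write_csv_exact(experiment$summary, paths["summary"])

  tabs <- lapply(sort(unique(experiment$summary$time)), function(t) {
    m <- mortality_table(experiment, t)
    data.frame(time = t, group = rownames(m), m, row.names = NULL)
  })
  write_csv_exact(do.call(rbind, tabs), paths["mortality"])

  jsonlite::write_json(unclass(manifest), paths["manifest"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read back results written by [write_results()]
#'
#' @param out_dir Directory previously passed to [write_results()].
#' @return A list with `replications`, `summary`, `mortality_by_group`
#'   (data frames) and `manifest` (list).
#' @export
read_results <- function(out_dir) {
  read1 <- function(name)
    utils::read.csv(file.path(out_dir, name), stringsAsFactors = FALSE)
  list(replications = read1("replications.csv"),
       summary = read1("summary.csv"),
       mortality_by_group = read1("mortality_by_group.csv"),
       manifest = jsonlite::read_json(file.path(out_dir, "manifest.json"),
                                      simplifyVector = TRUE))
}
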