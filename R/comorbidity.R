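#' Baseline death-probability distribution
#'
#' Triangular distribution of the probability of dying under intensive-care
#' treatment for patients without any of the modelled disabilities or
#' pre-existing conditions: minimum 0.04, maximum 0.41, mode 0.045, hence
#' mean 0.165. The values normalise published COVID-19 ICU survival
#' figures for otherwise healthy patients.
#'
#' @return A [triangular()] object with mean 0.165.
#' @export
baseline_triangle <- function() triangular(0.04, 0.41, 0.045)

#' Comorbidity profile
#'
#' One modelled disability or pre-existing condition: its relative death
#' risk, the triangular death-probability distribution derived from it, and
#' a prevalence weight used when a comorbid patient is assigned a concrete
#' condition.
#'
#' @param name Condition label.
#' @param category `"disability"` or `"pre-existing"`.
#' @param scaling A [risk_scaling()] object (or bare relative risk).
#' @param prevalence_weight Non-negative weight; weights are normalised
#'   within each category, so any common unit (cases, percent) works.
#' @param base Reference triangle the scaling is applied to.
#' @return An object of class `"comorbidity_profile"` with the derived
#'   `triangle` attached.
#' @export
comorbidity_profile <- function(name,
                                category = c("disability", "pre-existing"),
                                scaling, prevalence_weight,
                                base = baseline_triangle()) {
  category <- match.arg(category)
  if (is.numeric(scaling)) scaling <- risk_scaling(scaling)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(prevalence_weight), length(prevalence_weight) == 1L,
            prevalence_weight >= 0)
  structure(list(name = name, category = category, scaling = scaling,
                 prevalence_weight = prevalence_weight,
                 triangle = scale_by_relative_risk(base, scaling)),
            class = "comorbidity_profile")
}

#' Default comorbidity set
#'
#' The five modelled conditions with their literature-based relative death
#' risks: two disabilities (trisomy 21, OR 4.52; amyotrophic lateral
#' sclerosis, OR 3.0) and three pre-existing diseases (cardiovascular
#' disease, OR 4.85; hypertension, HR 2.12; type-2 diabetes, OR 2.03).
#' The hypertension triangle is the published explicit triple
#' (0.19, 0.63, 0.23); the other four are derived from the baseline
#' triangle by mean-preserving translation (see
#' [scale_by_relative_risk()]).
#'
#' Prevalence weights default to approximate German figures (people living
#' with the condition for the disabilities, adult prevalence in percent for
#' the diseases); only their within-category proportions matter. See
#' [calibrate_prevalence_weights()] for the calibration applied by
#' [default_mix()].
#'
#' @return Named list of [comorbidity_profile()] objects.
#' @export
default_comorbidities <- function() {
  profiles <- list(
    comorbidity_profile("trisomy21", "disability",
                        risk_scaling(4.52), prevalence_weight = 50000),
    comorbidity_profile("als", "disability",
                        risk_scaling(3.0), prevalence_weight = 9000),
    comorbidity_profile("cardiovascular", "pre-existing",
                        risk_scaling(4.85), prevalence_weight = 7),
    comorbidity_profile("hypertension", "pre-existing",
                        risk_scaling(2.12, method = "explicit",
                                     explicit = triangular(0.19, 0.63, 0.23)),
                        prevalence_weight = 30),
    comorbidity_profile("diabetes2", "pre-existing",
                        risk_scaling(2.03), prevalence_weight = 9)
  )
  names(profiles) <- vapply(profiles, `[[`, character(1), "name")
  profiles
}

#' Population mix
#'
#' Describes the simulated patient population: the comorbid share `s`, the
#' split of comorbid patients into the disability versus pre-existing
#' category, the set of comorbidity profiles, and optionally a single fixed
#' condition (for single-comorbidity simulations in which every comorbid
#' patient has the same condition).
#'
#' @param share_comorbid Fraction `s` of patients with a disability or
#'   pre-existing condition (default 0.7).
#' @param disability_share Probability that a comorbid patient's condition
#'   is a disability rather than a pre-existing disease (default 0.10).
#' @param profiles Named list of [comorbidity_profile()] objects.
#' @param single_condition Optional name of one profile; when set, every
#'   comorbid patient receives that condition.
#' @param baseline Triangle for patients without comorbidity.
#' @return An object of class `"population_mix"`.
#' @export
population_mix <- function(share_comorbid = 0.7, disability_share = 0.10,
                           profiles = default_comorbidities(),
                           single_condition = NULL,
                           baseline = baseline_triangle()) {
  stopifnot(share_comorbid >= 0, share_comorbid <= 1,
            disability_share >= 0, disability_share <= 1)
  baseline <- as_triangular(baseline)
  if (share_comorbid > 0 && length(profiles) == 0L)
    stop("share_comorbid > 0 requires at least one comorbidity profile",
         call. = FALSE)
  if (!all(vapply(profiles, inherits, logical(1), "comorbidity_profile")))
    stop("profiles must be comorbidity_profile objects", call. = FALSE)
  names(profiles) <- vapply(profiles, `[[`, character(1), "name")
  if (!is.null(single_condition)) {
    if (!single_condition %in% names(profiles))
      stop("single_condition '", single_condition,
           "' does not name a profile", call. = FALSE)
  } else if (share_comorbid > 0) {
    for (cat in c("disability", "pre-existing")) {
      p_needed <- if (cat == "disability") disability_share else 1 - disability_share
      if (p_needed > 0) {
        w <- category_weights(profiles, cat)
        if (length(w) == 0L || sum(w) <= 0)
          stop("category '", cat, "' has no positive prevalence weight",
               call. = FALSE)
      }
    }
  }
  structure(list(share_comorbid = share_comorbid,
                 disability_share = disability_share,
                 profiles = profiles,
                 single_condition = single_condition,
                 baseline = baseline),
            class = "population_mix")
}

category_weights <- function(profiles, category) {
  sel <- vapply(profiles, function(p) p$category == category, logical(1))
  w <- vapply(profiles[sel], `[[`, numeric(1), "prevalence_weight")
  names(w) <- names(profiles)[sel]
  w
}

#' Mean death probability of the comorbid group under a mix
#'
#' The mixture mean over conditions: within each category, prevalence
#' weights are normalised; categories are combined with the
#' disability/pre-existing split. Used as the calibration functional for
#' [calibrate_prevalence_weights()].
#'
#' @param mix A [population_mix()] object.
#' @return A probability.
#' @export
comorbid_mixture_mean <- function(mix) {
  stopifnot(inherits(mix, "population_mix"))
  if (!is.null(mix$single_condition))
    return(triangular_mean(mix$profiles[[mix$single_condition]]$triangle))
  means <- vapply(mix$profiles, function(p) triangular_mean(p$triangle),
                  numeric(1))
  out <- 0
  for (cat in c("disability", "pre-existing")) {
    p_cat <- if (cat == "disability") mix$disability_share else 1 - mix$disability_share
    if (p_cat == 0) next
    w <- category_weights(mix$profiles, cat)
    out <- out + p_cat * sum(w * means[names(w)]) / sum(w)
  }
  out
}

#' Calibrate prevalence weights to a target comorbid-group mean
#'
#' The per-condition prevalence weights of the mixed ("real") simulation
#' are the one input not fully determined by published values. This
#' routine anchors them: it applies an exponential tilt
#' `w_k -> w_k * exp(lambda * mean_k)` to every profile's weight, with a
#' single scalar `lambda` chosen (by root finding) so that the comorbid
#' mixture mean death probability equals `target`. The natural anchor is
#' the comorbid-group mortality observed under the fully random policy,
#' which is an unbiased estimate of the mixture mean (random allocation
#' does not select on prognosis).
#'
#' @param mix A [population_mix()] object supplying the starting weights.
#' @param target Target comorbid mixture mean (default 0.438, the
#'   comorbid-group mortality under the fully random benchmark policy).
#' @return A `population_mix` with tilted weights such that
#'   `comorbid_mixture_mean(mix)` equals `target` to root-finder precision.
#' @export
calibrate_prevalence_weights <- function(mix, target = 0.438) {
  stopifnot(inherits(mix, "population_mix"), target > 0, target < 1)
  means <- vapply(mix$profiles, function(p) triangular_mean(p$triangle),
                  numeric(1))
  tilted <- function(lambda) {
    m <- mix
    for (k in names(m$profiles))
      m$profiles[[k]]$prevalence_weight <-
        m$profiles[[k]]$prevalence_weight * exp(lambda * means[k])
    m
  }
  f <- function(lambda) comorbid_mixture_mean(tilted(lambda)) - target
  if (f(-60) * f(60) > 0)
    stop("target comorbid mean ", target,
         " is not attainable by tilting these profiles", call. = FALSE)
  lambda <- stats::uniroot(f, c(-60, 60), tol = 1e-12)$root
  tilted(lambda)
}

#' Default calibrated population mix
#'
#' The mixed-population ("real") scenario: comorbid share 0.7, disability
#' share 0.10, the five default comorbidities, with prevalence weights
#' calibrated once so that the comorbid mixture mean equals 0.438 (the
#' comorbid-group mortality under the fully random benchmark policy).
#'
#' @param share_comorbid Comorbid share `s` (default 0.7).
#' @param calibrate Logical; apply the weight calibration (default `TRUE`).
#' @return A [population_mix()] object.
#' @export
default_mix <- function(share_comorbid = 0.7, calibrate = TRUE) {
  mix <- population_mix(share_comorbid = share_comorbid)
  if (calibrate) mix <- calibrate_prevalence_weights(mix)
  mix
}
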