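# Shared fixtures: small deterministic objects used across test files.

base_tri <- triangular(0.04, 0.41, 0.045)
hyper_tri <- triangular(0.19, 0.63, 0.23)

# Riemann-sum oracle for the density overlap: independent of the
# piecewise-linear segment integration in overlap_fraction().
riemann_overlap <- function(p1, p2, n = 1e6) {
  lo <- min(p1$minimum, p2$minimum)
  hi <- max(p1$maximum, p2$maximum)
  x <- seq(lo, hi, length.out = n)
  sum(pmin(dtriangular(x, p1), dtriangular(x, p2))) * (x[2] - x[1])
}

# Random valid triangle on [0,1]
random_triangle <- function() {
  v <- sort(runif(3))
  triangular(v[1], v[3], v[2])
}

# Patient data frame with fixed values (bypasses all generation draws)
fixed_patients <- function(id, comorbid, p, y,
                           condition = rep(NA_character_, length(id))) {
  data.frame(id = id, comorbid = as.integer(comorbid),
             condition = condition, p = p, y = as.integer(y),
             stringsAsFactors = FALSE)
}

# A small fast experiment config for engine tests
small_config <- function(...) {
  experiment_config(replications = 50, master_seed = 7, ...)
}
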