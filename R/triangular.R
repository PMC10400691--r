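#' Triangular death-probability distribution
#'
#' Constructs a triangular distribution on `[0, 1]` given its minimum,
#' maximum and most likely value (mode), in that order. The triangular
#' distribution is the package's model for a patient's probability of dying
#' under intensive-care treatment: it is fully determined by three values a
#' clinician can state directly, and its mean has the closed form
#' `(minimum + maximum + mode) / 3`.
#'
#' @param minimum Lower end of the support, a probability.
#' @param maximum Upper end of the support, a probability.
#' @param mode Most likely value, must lie between `minimum` and `maximum`.
#' @return An object of class `"triangular"` with fields `minimum`,
#'   `maximum` and `mode`.
#' @examples
#' baseline <- triangular(0.04, 0.41, 0.045)
#' triangular_mean(baseline) # 0.165
#' @export
triangular <- function(minimum, maximum, mode) {
  stopifnot(is.numeric(minimum), is.numeric(maximum), is.numeric(mode),
            length(minimum) == 1L, length(maximum) == 1L, length(mode) == 1L)
  if (is.na(minimum) || is.na(maximum) || is.na(mode))
    stop("triangular parameters must not be NA", call. = FALSE)
  if (minimum < 0 || maximum > 1)
    stop("triangular support must lie within [0, 1], got [",
         minimum, ", ", maximum, "]", call. = FALSE)
  if (!(minimum <= mode && mode <= maximum))
    stop("triangular parameters must satisfy minimum <= mode <= maximum, got (",
         minimum, ", ", maximum, ", ", mode, ")", call. = FALSE)
  structure(list(minimum = minimum, maximum = maximum, mode = mode),
            class = "triangular")
}

#' @export
print.triangular <- function(x, ...) {
  cat(sprintf("Triangular(min = %g, max = %g, mode = %g), mean = %g\n",
              x$minimum, x$maximum, x$mode, triangular_mean(x)))
  invisible(x)
}

is_triangular <- function(x) inherits(x, "triangular")

as_triangular <- function(x) {
  if (is_triangular(x)) return(x)
  if (is.numeric(x) && length(x) == 3L) return(triangular(x[1], x[2], x[3]))
  stop("cannot interpret object as a triangular distribution", call. = FALSE)
}

#' Mean of a triangular distribution
#'
#' @param params A [triangular()] object (or a numeric triple in
#'   minimum/maximum/mode order).
#' @return `(minimum + maximum + mode) / 3`.
#' @export
triangular_mean <- function(params) {
  params <- as_triangular(params)
  (params$minimum + params$maximum + params$mode) / 3
}

#' Variance of a triangular distribution
#'
#' @inheritParams triangular_mean
#' @return `(a^2 + b^2 + c^2 - ab - ac - bc) / 18` for support `[a, b]`
#'   and mode `c`.
#' @export
triangular_var <- function(params) {
  params <- as_triangular(params)
  a <- params$minimum; b <- params$maximum; c <- params$mode
  (a^2 + b^2 + c^2 - a * b - a * c - b * c) / 18
}

#' Triangular density, distribution function, quantile function and sampling
#'
#' Standard distribution functions for the triangular law used throughout
#' the simulator. `rtriangular` draws by inverse-transform from the current
#' R random stream, so a single `set.seed()` call makes draws reproducible
#' and each variate consumes exactly one uniform.
#'
#' @param x,q Numeric vector of evaluation points.
#' @param p Numeric vector of probabilities.
#' @param n Number of draws.
#' @inheritParams triangular_mean
#' @return Numeric vector.
#' @export
dtriangular <- function(x, params) {
  params <- as_triangular(params)
  a <- params$minimum; b <- params$maximum; c <- params$mode
  out <- numeric(length(x))
  if (b == a) { # point mass: density not defined, return 0 off the atom
    return(out)
  }
  up <- x >= a & x <= c & c > a
  dn <- x > c & x <= b & b > c
  out[up] <- 2 * (x[up] - a) / ((b - a) * (c - a))
  out[dn] <- 2 * (b - x[dn]) / ((b - a) * (b - c))
  if (c == a) out[x == a] <- 2 / (b - a)
  out
}

#' @rdname dtriangular
#' @export
ptriangular <- function(q, params) {
  params <- as_triangular(params)
  a <- params$minimum; b <- params$maximum; c <- params$mode
  if (b == a) return(as.numeric(q >= a))
  out <- numeric(length(q))
  up <- q > a & q <= c
  dn <- q > c & q < b
  if (c > a) out[up] <- (q[up] - a)^2 / ((b - a) * (c - a))
  out[dn] <- 1 - (b - q[dn])^2 / ((b - a) * (b - c))
  out[q >= b] <- 1
  out
}

#' @rdname dtriangular
#' @export
qtriangular <- function(p, params) {
  params <- as_triangular(params)
  a <- params$minimum; b <- params$maximum; c <- params$mode
  stopifnot(all(p >= 0 & p <= 1))
  if (b == a) return(rep(a, length(p)))
  fc <- (c - a) / (b - a)
  out <- numeric(length(p))
  low <- p < fc
  out[low] <- a + sqrt(p[low] * (b - a) * (c - a))
  out[!low] <- b - sqrt((1 - p[!low]) * (b - a) * (b - c))
  out
}

#' @rdname dtriangular
#' @export
rtriangular <- function(n, params) {
  stopifnot(n >= 1)
  qtriangular(stats::runif(n), params)
}

# Linear segments (lo, hi, slope, intercept) of a triangular density.
density_segments <- function(params) {
  a <- params$minimum; b <- params$maximum; c <- params$mode
  segs <- list()
  if (c > a)
    segs[[length(segs) + 1L]] <-
      c(lo = a, hi = c, slope = 2 / ((b - a) * (c - a)),
        icpt = -2 * a / ((b - a) * (c - a)))
  if (b > c)
    segs[[length(segs) + 1L]] <-
      c(lo = c, hi = b, slope = -2 / ((b - a) * (b - c)),
        icpt = 2 * b / ((b - a) * (b - c)))
  segs
}

#' Density overlap fraction of two triangular distributions
#'
#' Computes the overlapping coefficient of two triangular densities: the
#' integral of their pointwise minimum. Because each density integrates to
#' one, the result is the fraction of shared area and lies in `[0, 1]`. The
#' integral is evaluated exactly by piecewise-linear segment integration:
#' the pointwise minimum of two piecewise-linear densities is itself
#' piecewise linear once every vertex and every crossing point of the two
#' densities is taken as a breakpoint, so a trapezoid per breakpoint
#' interval is exact (no quadrature error, no Monte-Carlo noise).
#'
#' @param p1,p2 [triangular()] objects.
#' @return The shared-area fraction in `[0, 1]`.
#' @examples
#' overlap_fraction(triangular(0.04, 0.41, 0.045), triangular(0.19, 0.63, 0.23))
#' @export
overlap_fraction <- function(p1, p2) {
  p1 <- as_triangular(p1); p2 <- as_triangular(p2)
  deg1 <- p1$maximum == p1$minimum
  deg2 <- p2$maximum == p2$minimum
  if (deg1 || deg2) {
    # point masses: full overlap only for identical atoms
    return(as.numeric(deg1 && deg2 && p1$minimum == p2$minimum))
  }
  lo <- max(p1$minimum, p2$minimum)
  hi <- min(p1$maximum, p2$maximum)
  if (hi <= lo) return(0)
  knots <- c(p1$minimum, p1$mode, p1$maximum,
             p2$minimum, p2$mode, p2$maximum)
  for (s1 in density_segments(p1)) {
    for (s2 in density_segments(p2)) {
      if (s1["slope"] != s2["slope"]) {
        x <- (s2["icpt"] - s1["icpt"]) / (s1["slope"] - s2["slope"])
        if (x >= s1["lo"] && x <= s1["hi"] && x >= s2["lo"] && x <= s2["hi"])
          knots <- c(knots, x)
      }
    }
  }
  knots <- sort(unique(pmin(pmax(knots, lo), hi)))
  f <- pmin(dtriangular(knots, p1), dtriangular(knots, p2))
  sum(diff(knots) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
}

#' Relative-risk scaling specification
#'
#' Describes how a comorbidity's relative death risk (an odds or hazard
#' ratio treated as a multiplicative risk ratio) is turned into a
#' death-probability distribution. Three methods are supported:
#' `"translate"` shifts every vertex of the reference triangle by
#' `mean * (relative_risk - 1)`, which scales the mean exactly while
#' preserving the shape; `"translate_widen"` additionally widens minimum
#' and maximum symmetrically by `widen`, which leaves the mean unchanged;
#' `"explicit"` ignores the reference shape and uses a user-supplied
#' triple.
#'
#' @param relative_risk Positive ratio applied to the reference mean.
#' @param method One of `"translate"`, `"translate_widen"`, `"explicit"`.
#' @param explicit A [triangular()] object; required for `method =
#'   "explicit"`.
#' @param widen Non-negative symmetric widening of the support, used by
#'   `"translate_widen"` (default 0).
#' @return An object of class `"risk_scaling"`.
#' @export
risk_scaling <- function(relative_risk,
                         method = c("translate", "translate_widen", "explicit"),
                         explicit = NULL, widen = 0) {
  method <- match.arg(method)
  stopifnot(is.numeric(relative_risk), length(relative_risk) == 1L)
  if (!(relative_risk > 0))
    stop("relative_risk must be positive", call. = FALSE)
  if (method == "explicit") {
    if (is.null(explicit))
      stop("method 'explicit' requires an explicit triangular triple",
           call. = FALSE)
    explicit <- as_triangular(explicit)
  }
  stopifnot(is.numeric(widen), length(widen) == 1L, widen >= 0)
  structure(list(relative_risk = relative_risk, method = method,
                 explicit = explicit, widen = widen),
            class = "risk_scaling")
}

#' Scale a triangular distribution by a relative death risk
#'
#' Derives a comorbidity-specific death-probability distribution from a
#' reference (baseline) triangle so that the derived mean equals
#' `relative_risk` times the reference mean. If translation pushes the
#' support outside `[0, 1]`, the offending endpoint is clamped and the
#' remaining vertices are adjusted equally so the target mean is preserved;
#' if no valid triangle with the target mean exists the call errors rather
#' than silently distorting the risk.
#'
#' @param base Reference [triangular()] distribution.
#' @param scaling A [risk_scaling()] object (or a bare positive number,
#'   interpreted as `risk_scaling(number, "translate")`).
#' @return A [triangular()] object whose mean is
#'   `relative_risk * triangular_mean(base)` (exactly, up to clamping
#'   feasibility), or the explicit triple for `method = "explicit"`.
#' @examples
#' base <- triangular(0.04, 0.41, 0.045)
#' scale_by_relative_risk(base, risk_scaling(2.12))
#' @export
scale_by_relative_risk <- function(base, scaling) {
  base <- as_triangular(base)
  if (is.numeric(scaling)) scaling <- risk_scaling(scaling)
  stopifnot(inherits(scaling, "risk_scaling"))
  if (scaling$method == "explicit") return(scaling$explicit)
  m0 <- triangular_mean(base)
  target <- scaling$relative_risk * m0
  if (target > 1)
    stop("infeasible scaling: target mean ", signif(target, 6),
         " exceeds 1", call. = FALSE)
  shift <- m0 * (scaling$relative_risk - 1)
  a <- base$minimum + shift
  b <- base$maximum + shift
  c <- base$mode + shift
  if (scaling$method == "translate_widen") {
    a <- a - scaling$widen
    b <- b + scaling$widen
  }
  # clamp support into [0,1], redistributing over the two free vertices to
  # keep the mean at target; an equal shift unless an order constraint
  # binds, in which case the remainder goes to the other vertex
  if (b > 1) {
    s <- 3 * target - 1
    d <- (s - a - c) / 2
    a <- a + d; c <- c + d; b <- 1
    if (a < 0) { a <- 0; c <- s }
    if (c > 1) { c <- 1; a <- s - 1 }
    if (a > c) { a <- s / 2; c <- s / 2 }
  }
  if (a < 0) {
    s <- 3 * target
    d <- (s - b - c) / 2
    b <- b + d; c <- c + d; a <- 0
    if (c < 0) { c <- 0; b <- s }
    if (b > 1) { b <- 1; c <- s - 1 }
    if (c > b) { b <- s / 2; c <- s / 2 }
  }
  if (!(a >= 0 && b <= 1 && a <= c && c <= b))
    stop("infeasible scaling: no valid triangle on [0,1] with mean ",
         signif(target, 6), " reachable by clamping", call. = FALSE)
  triangular(a, b, c)
}
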