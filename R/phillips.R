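## CMC detection from conductivity-vs-concentration titration curves.
##
## The Phillips criterion places the CMC where the third derivative of
## conductivity with respect to concentration vanishes, i.e. at the extremum
## of the second derivative. The second derivative is obtained by local
## polynomial (moving least-squares) fitting, which tolerates non-uniform
## concentration grids; the extremum is refined by parabolic interpolation.

#' Construct a conductivity titration curve
#'
#' @param concentration Strictly increasing surfactant concentrations (mM).
#' @param conductivity Specific conductivities (uS/cm), same length.
#' @param temperature Temperature in kelvin.
#' @param meta Optional free-form metadata (instrument, notes).
#' @return An object of class `conductivity_titration`.
#' @export
conductivity_titration <- function(concentration, conductivity,
                                   temperature = 298.15, meta = list()) {
  if (length(concentration) != length(conductivity)) {
    stop_schema("concentration and conductivity must have equal length")
  }
  if (length(concentration) < 8) {
    stop_schema("titration curve needs at least 8 points")
  }
  if (any(!is.finite(concentration)) || any(diff(concentration) <= 0)) {
    stop_schema("concentrations must be finite and strictly increasing")
  }
  if (any(!is.finite(conductivity))) {
    stop_schema("conductivities must be finite")
  }
  structure(
    list(concentration = as.numeric(concentration),
         conductivity = as.numeric(conductivity),
         temperature = temperature, meta = meta),
    class = "conductivity_titration"
  )
}

#' @export
print.conductivity_titration <- function(x, ...) {
  cat(sprintf(
    "Conductivity titration: %d points, %.3g-%.3g mM, %.2f K\n",
    length(x$concentration), min(x$concentration), max(x$concentration),
    x$temperature))
  invisible(x)
}

#' Smoothed second derivative of a titration curve
#'
#' Local-polynomial (moving least-squares) estimate of d2(kappa)/dC2: at each
#' interior point a polynomial of degree `degree` is fitted to the `window`
#' nearest points and differentiated twice analytically. Endpoints where the
#' window cannot be centred are excluded.
#'
#' @param curve A [conductivity_titration()] object.
#' @param window Odd window width in points; must satisfy
#'   `window >= degree + 2` and `window <= length(curve)`.
#' @param degree Polynomial degree (default cubic).
#' @return A data frame with columns `concentration` and `d2` (second
#'   derivative of conductivity, uS/cm per mM^2) at interior points.
#' @export
smooth_second_derivative <- function(curve, window = 7, degree = 3) {
  stopifnot(inherits(curve, "conductivity_titration"))
  n <- length(curve$concentration)
  if (window %% 2 != 1) stop_domain("`window` must be odd")
  if (window < degree + 2) stop_domain("`window` must be >= degree + 2")
  if (window > n) stop_domain("`window` exceeds the number of points")
  half <- (window - 1) %/% 2
  idx <- (half + 1):(n - half)
  x <- curve$concentration
  y <- curve$conductivity
  d2 <- vapply(idx, function(i) {
    j <- (i - half):(i + half)
    ## centred design keeps the Vandermonde well conditioned
    dx <- x[j] - x[i]
    X <- outer(dx, 0:degree, `^`)
    cf <- qr.coef(qr(X), y[j])
    2 * cf[3]
  }, numeric(1))
  data.frame(concentration = x[idx], d2 = d2)
}

.parabolic_vertex <- function(x3, y3) {
  ## vertex of the parabola through three points; returns c(x0, curvature a)
  X <- cbind(1, x3, x3^2)
  cf <- tryCatch(solve(X, y3), error = function(e) rep(NA_real_, 3))
  a <- cf[3]
  if (!is.finite(a) || a == 0) return(c(NA_real_, NA_real_))
  c(-cf[2] / (2 * a), a)
}

#' CMC by the Phillips breakpoint criterion
#'
#' Estimates the critical micelle concentration as the location of the
#' extremum of the smoothed second derivative of conductivity with respect
#' to concentration (equivalently the zero of the third derivative), refined
#' by parabolic interpolation around the discrete extremum.
#'
#' @param curve A [conductivity_titration()] object spanning the breakpoint.
#' @param window,degree Smoothing parameters, see
#'   [smooth_second_derivative()].
#' @param min_signal Dimensionless detection threshold: the peak of the
#'   second derivative, non-dimensionalized by the curve's concentration and
#'   conductivity ranges, must exceed this for a breakpoint to be declared.
#' @return An object of class `cmc_estimate` with fields `cmc` (mM),
#'   `uncertainty` (half-width, mM), `method = "phillips"` and `diagnostics`.
#' @examples
#' tt <- gen_conductivity(cmc = 4, pre_slope = 60, post_slope = 30,
#'                        c_range = c(1, 8), n = 40, noise = 0, seed = 1)
#' phillips_cmc(tt)
#' @export
phillips_cmc <- function(curve, window = 7, degree = 3, min_signal = 1e-6) {
  sd2 <- smooth_second_derivative(curve, window = window, degree = degree)
  x <- sd2$concentration
  d2 <- sd2$d2
  c_range <- diff(range(curve$concentration))
  k_range <- diff(range(curve$conductivity))
  if (k_range == 0) k_range <- max(abs(curve$conductivity), 1)
  ## deviation from the typical level, dimensionless
  dev <- d2 - stats::median(d2)
  signal <- max(abs(dev)) * c_range^2 / k_range
  if (!is.finite(signal) || signal < min_signal) {
    stop_domain("no breakpoint: the second derivative shows no extremum ",
                "(curve may be a single linear regime)")
  }
  m <- which.max(abs(dev))
  cmc <- x[m]
  step <- if (m == 1) x[2] - x[1]
          else if (m == length(x)) x[m] - x[m - 1]
          else (x[m + 1] - x[m - 1]) / 2
  uncertainty <- step / 2
  if (m > 1 && m < length(x)) {
    v <- .parabolic_vertex(x[(m - 1):(m + 1)], dev[(m - 1):(m + 1)])
    if (is.finite(v[1]) && v[1] >= x[m - 1] && v[1] <= x[m + 1]) {
      cmc <- v[1]
      ## half-width at half the peak height of the interpolating parabola
      w <- sqrt(abs(dev[m] / (2 * v[2])))
      if (is.finite(w) && w > 0) uncertainty <- min(w, step)
    }
  }
  structure(
    list(cmc = cmc, uncertainty = uncertainty, method = "phillips",
         diagnostics = list(window = window, degree = degree,
                            signal = signal, second_derivative = sd2),
         curve = curve),
    class = "cmc_estimate"
  )
}

#' CMC by two-segment linear regression
#'
#' Classical cross-check for conductometric CMC determination: every interior
#' split of the curve is scored by the total sum of squared errors of two
#' independent line fits, and the CMC is the intersection of the two lines at
#' the best split.
#'
#' @param curve A [conductivity_titration()] object with at least 10 points.
#' @param min_points Minimum points per segment.
#' @return An object of class `cmc_estimate` with `method = "segmented"`;
#'   `diagnostics` carries the pre- and post-CMC slopes, the split index and
#'   flags (`degenerate` for equal slopes, `extrapolated` when the
#'   intersection falls outside the measured range).
#' @export
segmented_cmc <- function(curve, min_points = 3) {
  stopifnot(inherits(curve, "conductivity_titration"))
  x <- curve$concentration
  y <- curve$conductivity
  n <- length(x)
  if (n < 10) stop_domain("segmented fit needs at least 10 points")
  splits <- min_points:(n - min_points)
  sse <- vapply(splits, function(k) {
    f1 <- stats::lm.fit(cbind(1, x[1:k]), y[1:k])
    f2 <- stats::lm.fit(cbind(1, x[(k + 1):n]), y[(k + 1):n])
    sum(f1$residuals^2) + sum(f2$residuals^2)
  }, numeric(1))
  k <- splits[which.min(sse)]
  f1 <- stats::lm.fit(cbind(1, x[1:k]), y[1:k])
  f2 <- stats::lm.fit(cbind(1, x[(k + 1):n]), y[(k + 1):n])
  a1 <- f1$coefficients[1]; m1 <- f1$coefficients[2]
  a2 <- f2$coefficients[1]; m2 <- f2$coefficients[2]
  degenerate <- !is.finite(m1) || !is.finite(m2) ||
    isTRUE(all.equal(m1, m2, tolerance = 1e-10))
  if (degenerate) {
    cmc <- x[k]
    extrapolated <- FALSE
    warning("segmented fit degenerate: segment slopes are equal; ",
            "returning the split concentration")
  } else {
    cmc <- (a2 - a1) / (m1 - m2)
    extrapolated <- cmc < min(x) || cmc > max(x)
    if (extrapolated) {
      warning("segmented-fit intersection lies outside the measured range")
    }
  }
  uncertainty <- (x[min(k + 1, n)] - x[max(k - 1, 1)]) / 2
  structure(
    list(cmc = unname(cmc), uncertainty = unname(uncertainty),
         method = "segmented",
         diagnostics = list(split_index = k, pre_slope = unname(m1),
                            post_slope = unname(m2), sse = min(sse),
                            degenerate = degenerate,
                            extrapolated = extrapolated),
         curve = curve),
    class = "cmc_estimate"
  )
}

#' Degree of counter-ion ionization from conductometric slopes
#'
#' The ratio of the post-CMC to the pre-CMC slope of a conductivity
#' titration estimates the fraction of counter-ions remaining dissociated
#' in the micellar regime (1 minus the degree of counter-ion binding).
#'
#' @param pre_slope Pre-CMC slope (uS/cm per mM), strictly positive.
#' @param post_slope Post-CMC slope (same units).
#' @return Ionization degree in `[0, 1]`; values outside are clipped with a
#'   warning.
#' @export
ionization_degree <- function(pre_slope, post_slope) {
  if (!is.numeric(pre_slope) || !is.finite(pre_slope) || pre_slope <= 0) {
    stop_domain("`pre_slope` must be finite and > 0")
  }
  r <- post_slope / pre_slope
  if (r < 0 || r > 1) {
    warning(sprintf("slope ratio %.3g outside [0, 1]; clipping", r))
    r <- min(max(r, 0), 1)
  }
  r
}

#' @export
print.cmc_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("CMC estimate (%s): %.*g mM  (+/- %.2g mM)\n",
              x$method, digits, x$cmc, x$uncertainty))
  if (x$method == "segmented") {
    cat(sprintf("  pre-CMC slope %.4g, post-CMC slope %.4g (uS/cm per mM)\n",
                x$diagnostics$pre_slope, x$diagnostics$post_slope))
    if (isTRUE(x$diagnostics$degenerate)) cat("  [degenerate: equal slopes]\n")
    if (isTRUE(x$diagnostics$extrapolated)) {
      cat("  [intersection outside measured range]\n")
    }
  }
  invisible(x)
}

#' @export
plot.cmc_estimate <- function(x, ...) {
  plot(x$curve$concentration, x$curve$conductivity,
       xlab = "concentration (mM)", ylab = "conductivity (uS/cm)",
       main = sprintf("CMC = %.3g mM (%s)", x$cmc, x$method), ...)
  graphics::abline(v = x$cmc, lty = 2)
  invisible(x)
}
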