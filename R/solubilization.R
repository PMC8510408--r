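## Molar solubilization ratio (MSR): moles of solubilizate incorporated per
## mole of micellized surfactant, estimated as the slope of solubilizate
## concentration against surfactant concentration strictly above the CMC.

#' Construct a solubilization series
#'
#' @param surfactant_conc Increasing surfactant concentrations (mM).
#' @param solubilizate_conc Dissolved solubilizate concentrations (mM).
#' @param cmc Critical micelle concentration of the surfactant (mM).
#' @param solubilizate Name of the solubilized compound.
#' @return An object of class `solubilization_series`.
#' @export
solubilization_series <- function(surfactant_conc, solubilizate_conc, cmc,
                                  solubilizate = "") {
  if (length(surfactant_conc) != length(solubilizate_conc)) {
    stop_schema("surfactant and solubilizate series must have equal length")
  }
  check_positive(cmc, "cmc")
  structure(
    list(surfactant_conc = as.numeric(surfactant_conc),
         solubilizate_conc = as.numeric(solubilizate_conc),
         cmc = cmc, solubilizate = solubilizate),
    class = "solubilization_series"
  )
}

#' Molar solubilization ratio from a solubility series
#'
#' Ordinary least-squares slope of solubilizate concentration against
#' surfactant concentration, restricted to points strictly above the CMC
#' (the micellar regime). The intercept is free, so a constant baseline
#' (aqueous) solubility does not bias the estimate.
#'
#' @param series A [solubilization_series()] object.
#' @return An object of class `msr_fit`: list with `msr` (dimensionless
#'   mol/mol), its standard error `se`, the number of points used `n_used`,
#'   and the underlying `lm` fit.
#' @examples
#' s <- solubilization_series(seq(2, 20, 2), 0.02 + 0.05 * pmax(seq(2, 20, 2) - 5, 0),
#'                            cmc = 5, solubilizate = "example")
#' compute_msr(s)
#' @export
compute_msr <- function(series) {
  stopifnot(inherits(series, "solubilization_series"))
  above <- series$surfactant_conc > series$cmc
  if (sum(above) < 3) {
    stop_domain("insufficient data: fewer than 3 points above the CMC")
  }
  df <- data.frame(C = series$surfactant_conc[above],
                   S = series$solubilizate_conc[above])
  fit <- stats::lm(S ~ C, data = df)
  slope <- unname(stats::coef(fit)["C"])
  ## slope SE computed directly; exact fits legitimately give se = 0
  n <- nrow(df)
  s2 <- sum(stats::residuals(fit)^2) / (n - 2)
  se <- sqrt(s2 / sum((df$C - mean(df$C))^2))
  structure(
    list(msr = slope, se = se,
         n_used = sum(above), cmc = series$cmc,
         solubilizate = series$solubilizate, fit = fit),
    class = "msr_fit"
  )
}

#' @export
print.msr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("MSR fit%s: %.*g (SE %.2g), %d points above CMC (%.3g mM)\n",
              if (nzchar(x$solubilizate)) paste0(" [", x$solubilizate, "]")
              else "",
              digits, x$msr, x$se, x$n_used, x$cmc))
  invisible(x)
}

#' @export
coef.msr_fit <- function(object, ...) c(msr = object$msr)

#' Pearson correlation with a two-sided t-test p-value
#'
#' Sample Pearson correlation between two numeric vectors, with the p-value
#' from the exact t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. Used to relate solubilizate descriptors such as
#' logKow and molecular volume.
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_domain("x and y must have equal length")
  if (length(x) < 3) stop_domain("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_domain("zero variance in x or y")
  }
  r <- stats::cor(x, y)
  n <- length(x)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}
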