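## Regular-solution theory (Rubingh) for binary mixed micelles.
##
## At the mixed CMC the monomer balance for each component reads
##   alpha   * C12 = x1     * f1 * C1,   f1 = exp(beta * (1 - x1)^2)
##   (1-alpha)* C12 = (1-x1) * f2 * C2,   f2 = exp(beta * x1^2)
## where x1 is the micellar mole fraction of component 1 and beta the
## dimensionless interaction parameter (negative = synergism, positive =
## antagonism). Eliminating beta gives the implicit equation solved by
## solve_micellar_composition(); eliminating x1 gives the forward model of
## predict_mixed_cmc().

#' Ideal (Clint) mixed CMC of a binary surfactant mixture
#'
#' Computes the critical micelle concentration predicted for an ideally
#' mixing binary system: `1/C12 = alpha/C1 + (1 - alpha)/C2`.
#'
#' @param alpha Bulk mole fraction of component 1, in `[0, 1]`.
#' @param c1,c2 Pure-component CMCs (mM), strictly positive.
#' @return Ideal mixed CMC in the same concentration unit as `c1`, `c2`.
#' @examples
#' clint_cmc(0.2, 13, 6)
#' @export
clint_cmc <- function(alpha, c1, c2) {
  check_fraction(alpha, "alpha", open = FALSE)
  check_positive(c1, "c1")
  check_positive(c2, "c2")
  1 / (alpha / c1 + (1 - alpha) / c2)
}

## Monomer-balance equation in log form. Roots in (0,1) are candidate
## micellar compositions for a given beta. Strictly increasing for beta < 2;
## up to three roots in the demixing regime beta > 2.
.balance_log <- function(x1, alpha, c1, c2, beta) {
  log(x1 / (1 - x1)) + log(c1 * (1 - alpha) / (c2 * alpha)) +
    beta * (1 - 2 * x1)
}

.mixed_cmc_at <- function(x1, alpha, c1, c2, beta) {
  f1 <- exp(beta * (1 - x1)^2)
  f2 <- exp(beta * x1^2)
  1 / (alpha / (f1 * c1) + (1 - alpha) / (f2 * c2))
}

## All roots of a scalar function on (lo, hi): sign-change scan on a dense
## grid, each bracket polished by uniroot.
.scan_roots <- function(fn, lo, hi, n_grid = 4000, tol = 1e-14) {
  xs <- seq(lo, hi, length.out = n_grid)
  fx <- vapply(xs, fn, numeric(1))
  ok <- is.finite(fx)
  xs <- xs[ok]
  fx <- fx[ok]
  if (length(xs) < 2) return(numeric(0))
  sgn <- sign(fx)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(flip, function(i) {
    stats::uniroot(fn, lower = xs[i], upper = xs[i + 1], tol = tol)$root
  }, numeric(1))
  exact <- xs[fx == 0]
  sort(unique(c(roots, exact)))
}

#' Predict the mixed CMC of a binary mixture under regular-solution theory
#'
#' Forward model: given the pure CMCs, bulk composition and interaction
#' parameter, solves the monomer balance for the micellar composition and
#' returns the mixed CMC. For strongly antagonistic systems (`beta > 2`) the
#' balance can admit several compositions; the canonical solution returned is
#' the root closest to the bulk composition, which keeps the model continuous
#' in `beta` and preserves the symmetry `x1 = 1/2` for identical components.
#'
#' @param alpha Bulk mole fraction of component 1, strictly in `(0, 1)`.
#' @param c1,c2 Pure-component CMCs (mM).
#' @param beta Dimensionless interaction parameter.
#' @return A list with elements `cmc_mix` (mM) and `x1` (micellar mole
#'   fraction of component 1).
#' @examples
#' predict_mixed_cmc(0.3, 10, 5, beta = -2)
#' @export
predict_mixed_cmc <- function(alpha, c1, c2, beta) {
  check_fraction(alpha, "alpha")
  check_positive(c1, "c1")
  check_positive(c2, "c2")
  stopifnot(is.finite(beta))
  eps <- 1e-12
  fn <- function(x) .balance_log(x, alpha, c1, c2, beta)
  roots <- .scan_roots(fn, eps, 1 - eps)
  if (length(roots) == 0) {
    ## the balance is -Inf at 0+ and +Inf at 1-; a root always exists but may
    ## sit beyond the scan endpoints for extreme inputs
    roots <- stats::uniroot(fn, lower = eps, upper = 1 - eps,
                            extendInt = "upX", tol = 1e-14)$root
  }
  ## polish with a few Newton steps (d/dx of the log balance is available
  ## in closed form) so downstream round trips hold to tight tolerance
  roots <- vapply(roots, function(x) {
    for (i in 1:6) {
      g <- fn(x)
      dg <- 1 / (x * (1 - x)) - 2 * beta
      step <- g / dg
      xn <- x - step
      ## accept only improving steps: near a degenerate (multiple) root the
      ## vanishing derivative would otherwise amplify round-off
      if (!is.finite(xn) || xn <= 0 || xn >= 1 || abs(fn(xn)) >= abs(g)) break
      x <- xn
      if (abs(step) < 1e-16) break
    }
    x
  }, numeric(1))
  x1 <- roots[which.min(abs(roots - alpha))]
  list(cmc_mix = .mixed_cmc_at(x1, alpha, c1, c2, beta), x1 = x1)
}

## Rubingh implicit equation: zero where the two single-component beta
## expressions agree.
.rubingh_F <- function(x1, alpha, cmc_mix, c1, c2) {
  x1^2 * log(alpha * cmc_mix / (x1 * c1)) -
    (1 - x1)^2 * log((1 - alpha) * cmc_mix / ((1 - x1) * c2))
}

.beta_from_x1 <- function(x1, alpha, cmc_mix, c1) {
  log(alpha * cmc_mix / (x1 * c1)) / (1 - x1)^2
}

#' Micellar composition of a binary mixed micelle (Rubingh solution)
#'
#' Solves the regular-solution-theory implicit equation for the micellar
#' mole fraction `x1` of component 1 from a measured mixed CMC and the two
#' pure-component CMCs. Every root of the implicit equation is an exactly
#' self-consistent regular-solution solution (the two single-component beta
#' expressions agree at any root), so when several roots exist they are
#' disambiguated by forward consistency: the accepted composition is the one
#' whose implied beta, pushed through [predict_mixed_cmc()], reproduces the
#' observed mixed CMC; remaining ties go to the smaller `|beta|`.
#'
#' @param alpha Bulk mole fraction of component 1 in `(0, 1)`.
#' @param cmc_mix Measured mixed CMC (mM).
#' @param c1,c2 Pure-component CMCs (mM).
#' @param tol Absolute tolerance on the implicit equation at the root.
#' @return Micellar mole fraction `x1`, strictly inside `(0, 1)`.
#' @export
solve_micellar_composition <- function(alpha, cmc_mix, c1, c2, tol = 1e-12) {
  check_fraction(alpha, "alpha")
  check_positive(cmc_mix, "cmc_mix")
  check_positive(c1, "c1")
  check_positive(c2, "c2")
  eps <- 1e-10
  fn <- function(x) .rubingh_F(x, alpha, cmc_mix, c1, c2)
  roots <- .scan_roots(fn, eps, 1 - eps)
  if (length(roots) == 0) {
    stop_domain(
      "no physical root: the Rubingh equation has no sign change on (0, 1); ",
      "the (alpha, mixed CMC, pure CMC) triple is mutually inconsistent"
    )
  }
  ## polish each root by Newton on F
  roots <- vapply(roots, function(x) {
    for (i in 1:8) {
      g <- fn(x)
      h <- 1e-7
      dg <- (fn(min(x + h, 1 - eps)) - fn(max(x - h, eps))) / (2 * h)
      if (!is.finite(dg) || dg == 0) break
      xn <- x - g / dg
      if (!is.finite(xn) || xn <= 0 || xn >= 1 || abs(fn(xn)) >= abs(g)) break
      if (abs(xn - x) < 1e-16) { x <- xn; break }
      x <- xn
    }
    x
  }, numeric(1))
  if (length(roots) > 1) {
    ## disambiguate by forward consistency: the admissible composition is the
    ## one whose implied beta reproduces the observation under the canonical
    ## forward model (both the mixed CMC and the composition itself)
    betas <- vapply(roots, .beta_from_x1, numeric(1), alpha = alpha,
                    cmc_mix = cmc_mix, c1 = c1)
    mism <- vapply(seq_along(roots), function(i) {
      fw <- predict_mixed_cmc(alpha, c1, c2, betas[i])
      abs(fw$cmc_mix - cmc_mix) / cmc_mix + abs(fw$x1 - roots[i])
    }, numeric(1))
    roots <- roots[order(mism, abs(betas))]
  }
  x1 <- roots[1]
  if (abs(fn(x1)) > max(tol, 1e-9)) {
    stop_domain("Rubingh solver failed to reach tolerance at the root")
  }
  x1
}

#' Interaction parameter of a binary mixed micelle
#'
#' Fits the regular-solution-theory interaction parameter `beta` to one
#' measured binary mixture: solves for the micellar composition, evaluates
#' `beta` from the component-1 balance, checks consistency against the
#' component-2 balance, and classifies the interaction as synergistic
#' (`beta < -tol_label`), antagonistic (`beta > tol_label`) or ideal.
#'
#' @param alpha Bulk mole fraction of component 1 in `(0, 1)`.
#' @param cmc_mix Measured mixed CMC (mM).
#' @param c1,c2 Pure-component CMCs (mM).
#' @param pair_label Optional label for the mixture (e.g. `"PU:PC"`).
#' @param tol_label Half-width of the band of `beta` values reported as
#'   ideal mixing; see [classify_interaction()].
#' @return An object of class `rst_fit`: a list with `beta`, `x1`, activity
#'   coefficients `f1`, `f2`, the solver `residual`, the interaction `label`,
#'   and the inputs.
#' @seealso [predict_mixed_cmc()] for the forward model,
#'   [classify_interaction()] for the labelling rule.
#' @examples
#' m <- predict_mixed_cmc(0.3, 10, 5, beta = -2)
#' compute_beta(0.3, m$cmc_mix, 10, 5)
#' @export
compute_beta <- function(alpha, cmc_mix, c1, c2, pair_label = NULL,
                         tol_label = 0.05) {
  x1 <- solve_micellar_composition(alpha, cmc_mix, c1, c2)
  eps_edge <- 1e-6
  if (x1 < eps_edge || x1 > 1 - eps_edge) {
    stop_domain(
      sprintf("ill-conditioned: micellar composition x1 = %.2e is too close ",
              x1),
      "to a pure component for beta to be identifiable"
    )
  }
  beta1 <- .beta_from_x1(x1, alpha, cmc_mix, c1)
  beta2 <- log((1 - alpha) * cmc_mix / ((1 - x1) * c2)) / x1^2
  residual <- abs(.rubingh_F(x1, alpha, cmc_mix, c1, c2))
  beta <- beta1
  structure(
    list(
      beta = beta,
      x1 = x1,
      f1 = exp(beta * (1 - x1)^2),
      f2 = exp(beta * x1^2),
      residual = residual,
      consistency = abs(beta1 - beta2),
      label = classify_interaction(beta, tol = tol_label),
      alpha = alpha, cmc_mix = cmc_mix, c1 = c1, c2 = c2,
      cmc_ideal = clint_cmc(alpha, c1, c2),
      pair_label = pair_label
    ),
    class = "rst_fit"
  )
}

#' Classify a mixed-micelle interaction from its beta parameter
#'
#' A positive interaction parameter marks antagonism (the mixed CMC exceeds
#' the ideal-mixing prediction), a negative one synergism (lower mixed CMC);
#' values within `tol` of zero are reported as ideal mixing.
#'
#' @param beta Interaction parameter (dimensionless).
#' @param tol Nonnegative half-width of the ideal band; default 0.05
#'   distinguishes genuine interaction from numerical noise.
#' @return One of `"synergistic"`, `"antagonistic"`, `"ideal"`.
#' @examples
#' classify_interaction(1.33)   # antagonistic
#' classify_interaction(-0.40)  # synergistic
#' @export
classify_interaction <- function(beta, tol = 0.05) {
  stopifnot(is.numeric(beta), length(beta) == 1, is.finite(beta), tol >= 0)
  if (beta > tol) "antagonistic" else if (beta < -tol) "synergistic" else "ideal"
}

#' @export
print.rst_fit <- function(x, digits = 4, ...) {
  cat("Regular-solution-theory fit (binary mixed micelle)\n")
  if (!is.null(x$pair_label)) cat("  pair:      ", x$pair_label, "\n")
  cat(sprintf("  alpha = %.3f   C1 = %.4g mM   C2 = %.4g mM\n",
              x$alpha, x$c1, x$c2))
  cat(sprintf("  mixed CMC (observed) = %.*g mM,  (ideal/Clint) = %.*g mM\n",
              digits, x$cmc_mix, digits, x$cmc_ideal))
  cat(sprintf("  beta = %.*g  [%s]\n", digits, x$beta, x$label))
  cat(sprintf("  x1 = %.*g   f1 = %.*g   f2 = %.*g\n",
              digits, x$x1, digits, x$f1, digits, x$f2))
  cat(sprintf("  residual = %.2e   beta consistency = %.2e\n",
              x$residual, x$consistency))
  invisible(x)
}

#' @export
coef.rst_fit <- function(object, ...) {
  c(beta = object$beta, x1 = object$x1)
}

#' Interaction parameters for a table of binary mixtures
#'
#' Vectorized front end to [compute_beta()] for a data frame of mixture
#' measurements, as read from a `mixtures.csv` file with columns
#' `pair_label`, `alpha`, `cmc_mix_mM`, `cmc1_mM`, `cmc2_mM`.
#'
#' @param mixtures Data frame with one row per measured mixture.
#' @param tol_label Ideal-mixing band passed to [classify_interaction()].
#' @return The input with columns `beta`, `x1`, `label`, `residual` appended.
#' @export
beta_table <- function(mixtures, tol_label = 0.05) {
  need <- c("alpha", "cmc_mix_mM", "cmc1_mM", "cmc2_mM")
  miss <- setdiff(need, names(mixtures))
  if (length(miss)) {
    stop_schema("mixtures table is missing column(s): ",
                paste(miss, collapse = ", "))
  }
  fits <- lapply(seq_len(nrow(mixtures)), function(i) {
    compute_beta(mixtures$alpha[i], mixtures$cmc_mix_mM[i],
                 mixtures$cmc1_mM[i], mixtures$cmc2_mM[i],
                 pair_label = if ("pair_label" %in% names(mixtures))
                   mixtures$pair_label[i] else NULL,
                 tol_label = tol_label)
  })
  mixtures$beta <- vapply(fits, `[[`, numeric(1), "beta")
  mixtures$x1 <- vapply(fits, `[[`, numeric(1), "x1")
  mixtures$label <- vapply(fits, `[[`, character(1), "label")
  mixtures$residual <- vapply(fits, `[[`, numeric(1), "residual")
  mixtures
}
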