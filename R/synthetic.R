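## Seeded synthetic-data generators. Every generator plants its ground truth
## in a `truth` attribute/field so each analysis stage has an end-to-end
## recovery test; identical seeds give identical output.
##
## Noise conventions: additive Gaussian for conductivity, meta-table
## responses and titration volumes; multiplicative lognormal for CMCs
## (strictly positive quantities).

#' Synthetic conductivity titration with a planted CMC
#'
#' Piecewise-linear conductivity with a slope change at the CMC (the
#' anionic-surfactant convention, pre-CMC slope > post-CMC slope), an
#' optional smooth sigmoidal transition of configurable width, and relative
#' Gaussian noise.
#'
#' @param cmc Planted breakpoint (mM), inside `c_range`.
#' @param pre_slope,post_slope Conductivity slopes (uS/cm per mM),
#'   `pre_slope > post_slope > 0`.
#' @param c_range Concentration span `c(lo, hi)` (mM).
#' @param n Number of titration points.
#' @param noise Relative noise: Gaussian sd as a fraction of each
#'   conductivity value (e.g. 0.005 for 0.5 percent).
#' @param seed Integer seed; fixed seed gives identical curves.
#' @param kappa0 Conductivity at zero concentration (uS/cm).
#' @param transition_width Width (mM) of the smooth transition around the
#'   CMC; 0 (default) gives an exact kink.
#' @param temperature Kelvin.
#' @return A [conductivity_titration()] whose `meta$truth` records the
#'   planted parameters.
#' @export
gen_conductivity <- function(cmc, pre_slope = 60, post_slope = 30,
                             c_range = c(cmc / 4, cmc * 2), n = 40,
                             noise = 0, seed = NULL, kappa0 = 10,
                             transition_width = 0, temperature = 298.15) {
  if (!(pre_slope > post_slope && post_slope > 0)) {
    stop_domain("require pre_slope > post_slope > 0")
  }
  if (cmc <= c_range[1] || cmc >= c_range[2]) {
    stop_domain("planted cmc must lie strictly inside c_range")
  }
  conc <- seq(c_range[1], c_range[2], length.out = n)
  kappa <- if (transition_width > 0) {
    ## integral of a logistic blend of the two slopes; slope crosses the
    ## midpoint exactly at the cmc
    w <- transition_width / 4
    kappa0 + pre_slope * conc +
      (post_slope - pre_slope) * w * log1p(exp((conc - cmc) / w))
  } else {
    kappa0 + ifelse(conc <= cmc, pre_slope * conc,
                    pre_slope * cmc + post_slope * (conc - cmc))
  }
  kappa <- with_seed(seed, kappa + stats::rnorm(n, sd = noise * abs(kappa)))
  conductivity_titration(
    conc, kappa, temperature = temperature,
    meta = list(truth = list(cmc = cmc, pre_slope = pre_slope,
                             post_slope = post_slope, noise = noise,
                             transition_width = transition_width,
                             seed = seed))
  )
}

#' Synthetic binary-mixture CMC records with a planted interaction parameter
#'
#' Mixed CMCs from the regular-solution forward model
#' [predict_mixed_cmc()], optionally perturbed by multiplicative lognormal
#' noise.
#'
#' @param c1,c2 Pure-component CMCs (mM).
#' @param beta Planted interaction parameter.
#' @param alphas Bulk mole fractions of component 1; the classic composition
#'   grid `c(0.2, 0.4, 0.6, 0.8)` by default.
#' @param noise Lognormal sdlog of the multiplicative noise on the mixed CMC.
#' @param seed Integer seed.
#' @param pair_label Category label for the pair (e.g. `"PU:PC"`).
#' @return Data frame with columns `pair_label`, `alpha`, `cmc_mix_mM`,
#'   `cmc1_mM`, `cmc2_mM`, `x1_true`; planted parameters in
#'   `attr(, "truth")`.
#' @export
gen_mixture_cmc_dataset <- function(c1, c2, beta,
                                    alphas = c(0.2, 0.4, 0.6, 0.8),
                                    noise = 0, seed = NULL,
                                    pair_label = "A:B") {
  check_fraction(alphas, "alphas")
  fw <- lapply(alphas, predict_mixed_cmc, c1 = c1, c2 = c2, beta = beta)
  cmc_mix <- vapply(fw, `[[`, numeric(1), "cmc_mix")
  cmc_mix <- with_seed(seed,
    cmc_mix * exp(stats::rnorm(length(alphas), sd = noise)))
  out <- data.frame(
    pair_label = pair_label, alpha = alphas, cmc_mix_mM = cmc_mix,
    cmc1_mM = c1, cmc2_mM = c2,
    x1_true = vapply(fw, `[[`, numeric(1), "x1"),
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- list(beta = beta, c1 = c1, c2 = c2, noise = noise,
                             seed = seed)
  out
}

#' Synthetic meta-analysis table with planted categorical and numeric effects
#'
#' Emulates a literature-collated table: a numeric response (CMC, beta,
#' aggregation number or MSR) built from a baseline, additive effects of
#' uniformly drawn categorical levels, linear effects of standard-normal
#' numeric covariates, and Gaussian noise.
#'
#' @param level_effects Named list: for each categorical column, a named
#'   numeric vector of per-level additive effects (names declare the levels).
#' @param numeric_effects Named numeric vector of slopes for numeric
#'   covariates (drawn N(0, 1)).
#' @param baseline Intercept of the response.
#' @param n Number of records (>= 10).
#' @param noise_sd Gaussian noise sd on the response.
#' @param seed Integer seed.
#' @return Data frame with one categorical column per entry of
#'   `level_effects`, one numeric column per entry of `numeric_effects`, and
#'   a `response` column; planted parameters in `attr(, "truth")`.
#' @export
gen_meta_table <- function(level_effects, numeric_effects = numeric(),
                           baseline = 0, n = 100, noise_sd = 0,
                           seed = NULL) {
  if (n < 10) stop_domain("`n` must be >= 10")
  with_seed(seed, {
    out <- data.frame(row.names = seq_len(n))
    response <- rep(baseline, n)
    for (col in names(level_effects)) {
      eff <- level_effects[[col]]
      lv <- names(eff)
      draw <- sample(lv, n, replace = TRUE)
      out[[col]] <- draw
      response <- response + unname(eff[draw])
    }
    for (col in names(numeric_effects)) {
      v <- stats::rnorm(n)
      out[[col]] <- v
      response <- response + numeric_effects[[col]] * v
    }
    out$response <- response + stats::rnorm(n, sd = noise_sd)
    attr(out, "truth") <- list(level_effects = level_effects,
                               numeric_effects = numeric_effects,
                               baseline = baseline, noise_sd = noise_sd,
                               seed = seed)
    out
  })
}

#' Synthetic pH-stat lipolysis runs with planted first-order kinetics
#'
#' Inverts the target release curve `FFA(t) = phi_max * (1 - exp(-k t))`
#' through the pH-stat stoichiometry of [ffa_percent()] to cumulative NaOH
#' volumes, adds Gaussian noise on the %FFA scale, and monotonizes. Protocol
#' defaults mirror a duodenal in-vitro digestion: 0.1 M NaOH, 0.075 g oil,
#' 310.15 K, triplicate runs.
#'
#' @param phi_max Plateau release (%).
#' @param k First-order rate constant (1/min), > 0.
#' @param t_grid Sampling times (min).
#' @param noise_sd Additive Gaussian noise on %FFA.
#' @param replicates Number of replicate runs (default 3).
#' @param seed Integer seed.
#' @param condition Condition label.
#' @param naoh_molarity,lipid_mass,lipid_molar_mass,ffa_per_tag Stoichiometry
#'   passed to [lipolysis_run()] / [ffa_percent()].
#' @return List of [lipolysis_run()] objects; planted parameters in
#'   `attr(, "truth")`.
#' @export
gen_lipolysis <- function(phi_max, k, t_grid = seq(1, 60, by = 1),
                          noise_sd = 0, replicates = 3, seed = NULL,
                          condition = "", naoh_molarity = 0.1,
                          lipid_mass = 0.075, lipid_molar_mass = 880,
                          ffa_per_tag = 2, temperature = 310.15) {
  if (phi_max < 0) stop_domain("`phi_max` must be >= 0")
  if (phi_max > 0 && k <= 0) stop_domain("`k` must be > 0")
  moles_tag <- lipid_mass / lipid_molar_mass
  pct_to_ml <- function(p) p / 100 * ffa_per_tag * moles_tag /
    naoh_molarity * 1000
  runs <- with_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      pct <- if (phi_max == 0) rep(0, length(t_grid))
             else phi_max * (1 - exp(-k * t_grid))
      pct <- pct + stats::rnorm(length(t_grid), sd = noise_sd)
      pct <- cummax(pmax(pct, 0))
      lipolysis_run(t_grid, pct_to_ml(pct), naoh_molarity = naoh_molarity,
                    lipid_mass = lipid_mass,
                    lipid_molar_mass = lipid_molar_mass,
                    condition = condition, temperature = temperature)
    })
  })
  attr(runs, "truth") <- list(phi_max = phi_max, k = k, noise_sd = noise_sd,
                              seed = seed)
  runs
}

#' Synthetic solubilization series with a planted MSR
#'
#' Flat baseline solubility below the CMC, linear micellar solubilization of
#' slope `msr` above it, plus additive Gaussian noise.
#'
#' @param cmc Surfactant CMC (mM).
#' @param msr Planted molar solubilization ratio (slope above the CMC).
#' @param baseline Aqueous solubility (mM) below the CMC.
#' @param c_grid Surfactant concentrations (mM); at least 3 above `cmc`.
#' @param noise Additive Gaussian sd on the solubilizate concentration.
#' @param seed Integer seed.
#' @param solubilizate Compound name.
#' @return A [solubilization_series()]; planted parameters in
#'   `attr(, "truth")`.
#' @export
gen_solubility_series <- function(cmc, msr, baseline = 0.02,
                                  c_grid = seq(cmc * 0.5, cmc * 4,
                                               length.out = 12),
                                  noise = 0, seed = NULL,
                                  solubilizate = "synthetic") {
  if (sum(c_grid > cmc) < 3) {
    stop_domain("`c_grid` must contain at least 3 points above the CMC")
  }
  s <- baseline + msr * pmax(c_grid - cmc, 0)
  s <- with_seed(seed, s + stats::rnorm(length(c_grid), sd = noise))
  out <- solubilization_series(c_grid, s, cmc = cmc,
                               solubilizate = solubilizate)
  out$truth <- list(msr = msr, baseline = baseline, noise = noise,
                    seed = seed)
  out
}
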