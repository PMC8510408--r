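# bilemix

Physicochemical analysis of bile-salt surfactant systems and their role in
fat digestion, for colloid and food scientists studying how bile-salt
conjugation (glycine/taurine vs free carboxyl) and backbone origin
(primary vs secondary) shape micellization, solubilization and lipolysis.

Bile salts occur in four categories — primary/secondary ×
conjugated/unconjugated (PC, PU, SC, SU) — and physiological mixtures shift
along the conjugation axis as gut bacteria deconjugate them. `bilemix`
provides the estimators needed to quantify what that shift does:

* **Mixed-micelle interactions.** Regular-solution (Rubingh) analysis of a
  binary mixture: the micellar composition `x1` solves
  `x1² ln(α C12 / (x1 C1)) = (1−x1)² ln((1−α) C12 / ((1−x1) C2))`, after
  which the interaction parameter is
  `β = ln(α C12 / (x1 C1)) / (1−x1)²` with activity coefficients
  `f1 = exp(β(1−x1)²)`, `f2 = exp(β x1²)`. Negative β = synergism (mixed
  CMC below the ideal Clint prediction `1/C12 = α/C1 + (1−α)/C2`),
  positive β = antagonism. A forward model predicts the mixed CMC from β.
* **CMC detection** from conductivity titrations by the Phillips criterion
  (extremum of the smoothed second derivative, i.e. the zero of the third
  derivative), with a two-segment regression cross-check and the
  counter-ion ionization degree from the slope ratio.
* **Molar solubilization ratio** (MSR): the least-squares slope of
  solubilizate vs surfactant concentration above the CMC, plus Pearson
  correlation of solubilizate descriptors.
* **Meta-regression**: one-hot category encoding (all levels kept; mixture
  records may tag two categories, e.g. `"PU:PC"`), NIPALS partial least
  squares on autoscaled data, VIP scores
  (`VIP_j = sqrt(p Σ_a SSY_a (w_ja/‖w_a‖)² / Σ_a SSY_a)`, so ΣVIP² = p),
  standardized coefficients, grouped summaries and one-tailed Welch t-tests.
* **pH-stat lipolysis**: conversion of cumulative NaOH titrant volume to
  percent free fatty acids released,
  `%FFA = 100 · V·c·M / (2·m)` (sn-1,3 lipase stoichiometry), first-order
  kinetic fits `Φ(t) = Φmax(1 − e^(−kt))`, and between-condition Welch
  comparisons.
* **Seeded synthetic-data generators** for every input class, with planted
  ground truth, so the entire pipeline is testable end to end.

## Worked example

Plant an interaction parameter β = −2 on a synthetic bile-salt pair
(pure CMCs 10 and 5 mM), add 2% lognormal noise to the mixed CMCs, and fit:

```r
library(bilemix)
mx <- gen_mixture_cmc_dataset(c1 = 10, c2 = 5, beta = -2,
                              noise = 0.02, seed = 42, pair_label = "PU:SC")
beta_table(mx)[, c("alpha", "cmc_mix_mM", "beta", "x1", "label")]
#>   alpha cmc_mix_mM   beta     x1       label
#> 1   0.2      4.231 -1.853 0.2440 synergistic
#> 2   0.4      4.016 -2.049 0.3660 synergistic
#> 3   0.6      4.386 -1.971 0.4638 synergistic
#> 4   0.8      5.269 -1.948 0.5873 synergistic
```

All four compositions recover β near the planted −2 (synergistic: the mixed
CMC sits below the ideal-mixing prediction), and `x1` is the fitted micellar
mole fraction of component 1 at each bulk composition.

Detect a CMC from a noisy synthetic conductivity titration with the
breakpoint planted at 4.16 mM:

```r
curve <- gen_conductivity(cmc = 4.16, pre_slope = 60, post_slope = 30,
                          c_range = c(1, 8.5), n = 40, noise = 0.002,
                          seed = 7)
phillips_cmc(curve)
#> CMC estimate (phillips): 4.126 mM  (+/- 0.19 mM)
```

Recover a planted category effect (SC lowering the response by 2 units)
from a synthetic meta-table by PLS/VIP:

```r
mt <- gen_meta_table(list(bs_type = c(PC = 0, PU = 0, SC = -2, SU = 0)),
                     baseline = 5, n = 100, noise_sd = 0.3, seed = 11)
X <- one_hot_encode(mt, list(bs_type = c("PC", "PU", "SC", "SU")))
vip_scores(fit_pls(X, mt$response, ncomp = 2))
#> Variable importance in projection (VIP > 1 = influential):
#>    variable   vip coefficient influential
#>  bs_type_SC 1.723      -0.703           *
#>  bs_type_PU 0.627       0.248
#>  bs_type_SU 0.595       0.243
#>  bs_type_PC 0.532       0.225
```

The planted SC effect tops the VIP ranking (> 1, flagged influential) with
a negative standardized coefficient; the other levels stay below 1.

Fit first-order release kinetics to a synthetic triplicate pH-stat run:

```r
runs <- gen_lipolysis(phi_max = 15, k = 0.08, noise_sd = 0.3, seed = 3,
                      condition = "NaTC 10 mM")
fit_first_order(ffa_percent(runs[[1]]))
#> First-order FFA fit [NaTC 10 mM]: phi_max = 15.39%, k = 0.07556 1/min
```

`run_pipeline()` chains these stages from a config (or YAML file), writing
one CSV per stage and a JSON manifest; see `?run_pipeline` and the methods
vignette (`vignettes/bile-salt-micellization.Rmd`) for the model details,
defaults and limitations.

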