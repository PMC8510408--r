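---
title: "Methods: bile-salt micellization, mixed-micelle interactions and lipolysis kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bile-salt micellization, mixed-micelle interactions and lipolysis kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilemix)
```

Bile salts (BS) are rigid, planar steroid surfactants. Their physiological
behaviour — emulsifying dietary fat, ferrying lipolysis products in mixed
micelles — depends strongly on whether the molecule carries a glycine or
taurine residue at C-24 ("conjugated") or a free carboxyl ("unconjugated"),
and on whether the steroid backbone is liver-made ("primary": cholate,
chenodeoxycholate) or produced by gut bacteria ("secondary": deoxycholate,
lithocholate). Crossing the two axes gives the four categories PC, PU, SC,
SU used throughout the package. `bilemix` implements the quantitative
toolchain for studying how conjugation state shapes micellization and fat
digestion: regular-solution analysis of binary mixed micelles, conductometric
CMC detection, molar solubilization ratios, PLS/VIP meta-regression over
categorical descriptors, and pH-stat lipolysis kinetics. Every stage has a
seeded synthetic-data generator with planted ground truth, so the full
pipeline is testable without any external data.

## Regular-solution theory for binary mixed micelles

For a binary mixture with bulk mole fraction $\alpha$ of component 1, pure
critical micelle concentrations $C_1$, $C_2$ and mixed CMC $C_{12}$, the
regular-solution (Rubingh) treatment postulates that at the mixed CMC the
monomer balances

$$\alpha\,C_{12} = x_1 f_1 C_1, \qquad
  (1-\alpha)\,C_{12} = (1-x_1) f_2 C_2$$

hold with activity coefficients
$f_1 = e^{\beta (1-x_1)^2}$, $f_2 = e^{\beta x_1^2}$, where $x_1$ is the
micellar mole fraction of component 1 and $\beta$ the dimensionless
interaction parameter. $\beta < 0$ marks synergism (mixed CMC below the
ideal prediction), $\beta > 0$ antagonism; $\beta = 0$ recovers ideal
(Clint) mixing, $1/C_{12} = \alpha/C_1 + (1-\alpha)/C_2$.

Eliminating $\beta$ gives the implicit equation solved by
`solve_micellar_composition()`:

$$F(x_1) = x_1^2 \ln\!\frac{\alpha C_{12}}{x_1 C_1}
         - (1-x_1)^2 \ln\!\frac{(1-\alpha) C_{12}}{(1-x_1) C_2} = 0 ,$$

after which $\beta = \ln(\alpha C_{12}/(x_1 C_1)) / (1-x_1)^2$
(`compute_beta()`). Eliminating $x_1$ instead gives the forward model
`predict_mixed_cmc()` used by the synthetic generator and by round-trip
tests.

### Numerical choices

* **Root finding.** Both solvers scan a 4000-point grid on
  $(10^{-12}, 1-10^{-12})$ (respectively $(10^{-10}, \cdot)$) for sign
  changes, polish each bracket with `uniroot` at tolerance $10^{-14}$, then
  apply guarded Newton steps (a step is accepted only if it reduces $|F|$,
  which prevents round-off blow-up near degenerate roots).
* **Multiple roots.** For $\beta > 2$ the monomer balance can admit up to
  three compositions (the regular-solution demixing regime). The canonical
  forward solution is the root *closest to the bulk composition* $\alpha$:
  this keeps $C_{12}(\beta)$ continuous and strictly increasing in $\beta$
  and preserves the symmetry $x_1 = 1/2$ for identical components. On the
  inverse side a subtlety arises: *every* root of $F$ is an exactly
  self-consistent regular-solution solution (at any root the two
  single-component $\beta$ expressions agree), each implying its own
  $\beta$. The solver therefore disambiguates by forward consistency — it
  accepts the root whose implied $\beta$, pushed back through the canonical
  forward model, reproduces the observed mixed CMC — with ties broken
  toward the smaller $|\beta|$. With this pairing the forward–inverse round
  trip recovers planted $\beta \in (-8, 8)$ to better than $10^{-6}$.
* **Degenerate case.** At exactly $\beta = 2$ the symmetric balance has a
  triple root at $x_1 = 1/2$; attainable accuracy there is about $10^{-6}$
  rather than the usual $10^{-9}$, which the tests acknowledge.
* **No physical root.** Some $(\alpha, C_{12}, C_1, C_2)$ triples are
  mutually inconsistent — e.g. one component's balance demands $f > 1$
  while the other demands $f < 1$ — and $F$ has no zero on $(0,1)$; the
  solver raises a `no physical root` error rather than returning a
  boundary value. Compositions within $10^{-6}$ of 0 or 1 are rejected as
  ill-conditioned for $\beta$.
* **Classification.** `classify_interaction()` labels $\beta$ synergistic
  / antagonistic outside a band of half-width `tol = 0.05` (configurable);
  the band separates genuine interaction from solver noise.

Pure-component CMCs for literature mixtures must be supplied by the user;
the package never guesses them, so published $\beta$ values are checked by
sign and label rather than reproduced numerically when the source's pure
CMCs are not available.

## Conductometric CMC detection (Phillips criterion)

A conductivity titration $\kappa(C)$ of an ionic surfactant is nearly
linear below and above the CMC, with a smaller slope above (counter-ion
binding). The Phillips criterion defines the CMC as the concentration where
$d^3\kappa/dC^3 = 0$, i.e. the extremum of $d^2\kappa/dC^2$. The package
realizes this as:

1. `smooth_second_derivative()`: a moving least-squares local polynomial
   (default window 7 points, degree 3) fitted around each interior point and
   differentiated analytically. The window is the smallest that resolves a
   cubic inflection on curves of 20+ points; both parameters are
   configurable. The local fit handles non-uniform concentration grids,
   which autotitrator exports often have.
2. `phillips_cmc()`: the extremum of the smoothed second derivative
   (deviation from its median level), refined by parabolic interpolation
   through the three points around the discrete extremum. The extremum
   location is numerically far stabler than a zero crossing of a thrice
   differentiated noisy signal. The reported uncertainty is the half-width
   at half peak height of the interpolating parabola, bounded by the local
   concentration step (half the step when the curvature-based width is
   undefined).
3. Breakpoint detection is scale-free: the peak second derivative is
   non-dimensionalized by the curve's concentration and conductivity ranges
   and compared with `min_signal` ($10^{-6}$ by default). A single linear
   regime therefore raises a `no breakpoint` error instead of reporting an
   arbitrary extremum, and the estimate is invariant under affine
   rescaling of the conductivity axis.

`segmented_cmc()` provides the classical cross-check: an exhaustive scan of
interior split points, two independent line fits, CMC at the intersection.
Equal slopes are flagged degenerate; an intersection outside the measured
range is flagged but still returned. The ratio of post- to pre-CMC slopes
(`ionization_degree()`) estimates the fraction of counter-ions remaining
dissociated in the micellar regime.

On noiseless planted curves the Phillips estimate is within 1% of truth;
across 100 replicates with 0.5% relative conductivity noise the mean
estimate stays within 2%, and the median error grows monotonically with the
noise level.

## Molar solubilization ratio

The MSR — moles of solubilizate incorporated per mole of micellized
surfactant — is the ordinary least-squares slope of solubilizate
concentration against surfactant concentration *strictly above* the CMC
(`compute_msr()`). Points exactly at the CMC are excluded: the micellar
regime is defined above the breakpoint. The intercept is left free, which
makes the estimate invariant to the baseline aqueous solubility; OLS (not
orthogonal regression) matches the practice of the solubilization
literature this kind of meta-analysis collates. At least 3 points above the
CMC are required. `pearson_r()` gives the correlation between solubilizate
descriptors (e.g. logK~ow~ and molecular volume, which are strongly
collinear for typical solubilizate panels) with the exact t-transform
p-value.

## Meta-regression: one-hot categories, NIPALS PLS, VIP

Literature-collated records mix categorical descriptors (the four BS
categories, possibly two tags per record for mixtures, written `"PU:PC"`)
with numeric ones (temperature, concentration, pH, salt, logK~ow~,
molecular volume). `one_hot_encode()` builds the design matrix with **all**
levels kept — no reference level is dropped, because PLS tolerates the
collinearity and an importance score is wanted for every category — and a
`"PU:PC"` cell sets both indicators.

`fit_pls()` is univariate-response NIPALS PLS on autoscaled data (every
column and the response centred and scaled to unit sd): per component,
weights $w_a \propto X^\top y$, scores $t_a = X w_a$, loadings
$p_a = X^\top t_a / t_a^\top t_a$, $q_a = y^\top t_a / t_a^\top t_a$, with
deflation of both $X$ and $y$. Standardized coefficients are
$B = W (P^\top W)^{-1} q$. Scores are mutually orthogonal; at full rank the
coefficients coincide with OLS on the standardized data (both are tested to
$10^{-8}$, and predictions are cross-checked against an independent PLS
implementation). Variable importance in projection is

$$\mathrm{VIP}_j = \sqrt{\;p\,\frac{\sum_a \mathrm{SSY}_a\,
  (w_{ja}/\lVert w_a\rVert)^2}{\sum_a \mathrm{SSY}_a}\;},
  \qquad \mathrm{SSY}_a = q_a^2\, t_a^\top t_a ,$$

so $\sum_j \mathrm{VIP}_j^2 = p$ identically and VIP > 1 conventionally
marks an influential predictor.

The default of **2 components** suits the small descriptor sets of this
kind of meta-analysis and keeps VIP stable; `select_ncomp()` offers
leave-one-out PRESS selection when wanted. Zero-variance columns and
constant responses are rejected; requesting more components than the design
rank truncates with a warning.

`welch_t_test()` implements the unequal-variance statistic with
Satterthwaite degrees of freedom and one- or two-tailed p-values. It is
implemented directly (rather than wrapping `stats::t.test`) so that two
identical samples return the conventional $t = 0$, one-tailed $p = 0.5$
instead of an error; on non-degenerate data it agrees with `stats::t.test`
to machine precision. Results carry a `significant` flag at the 0.05 level.

## pH-stat lipolysis

The extent of lipolysis is measured by continuous titration of released
free fatty acids (FFA) with NaOH at fixed pH. With titrant volume $V(t)$
(mL), molarity $c$ (mol/L), oil mass $m$ (g) and mean triacylglycerol molar
mass $M$ (g/mol),

$$\%\mathrm{FFA}(t) = 100\,\frac{V(t)\,c\,M}{\nu\, m},$$

where $\nu$ is the number of fatty acids released per triacylglycerol.
The default $\nu = 2$ reflects the sn-1,3 specificity of pancreatic lipase
(the sn-2 monoglyceride is not hydrolysed), the standard convention for
intestinal-phase pH-stat protocols; $\nu = 3$ is available for
fully-hydrolysed assumptions. Defaults $m = 0.075$ g (0.375 mL of a 20%
w/w oil-in-water emulsion), $M = 880$ g/mol (conventional for sunflower
oil) and $c = 0.1$ M make the stoichiometric endpoint 1.70455 mL of titrant
for 100% release. No back-titration correction is applied by default (the
raw titration is reported); an `ionized_fraction` multiplier is available.

`fit_first_order()` summarizes a release profile as
$\Phi(t) = \Phi_{\max}(1 - e^{-kt})$ by Levenberg–Marquardt least squares,
started from $\Phi_{\max} \approx \max \Phi$ and $k \approx$ initial
slope / $\Phi_{\max}$; an all-zero profile short-circuits to a flagged
degenerate result. `compare_conditions()` tests two replicate sets (pH-stat
experiments are typically run in triplicate) at a chosen time by the Welch
test, interpolating to a common time point with a warning when grids
differ.

## Synthetic data: what it emulates, and what it does not

Each generator plants known truth and records it in the returned object:

* `gen_conductivity()` — piecewise-linear conductivity with a slope break
  at the CMC; optional smooth sigmoidal transition of configurable width
  (real titrations are not perfectly kinked; default width 0 for exact
  tests); relative Gaussian noise. Typical bench settings: pre/post slopes
  60/30 µS/cm per mM, 40 points, 0–0.5% noise.
* `gen_mixture_cmc_dataset()` — mixed CMCs from the forward
  regular-solution model on the classic composition grid
  $\alpha \in \{0.2, 0.4, 0.6, 0.8\}$; multiplicative lognormal noise
  (CMCs are strictly positive).
* `gen_meta_table()` — additive categorical effects over uniformly drawn
  levels plus linear effects of standard-normal covariates and Gaussian
  noise. The canonical recovery scenario plants a single-category effect of
  −2.0 with noise sd 0.3 at $n = 100$, under which the planted level tops
  the VIP ranking with a negative coefficient in at least 19 of 20 seeds.
* `gen_lipolysis()` — inverts the first-order release curve through the
  titration stoichiometry, adds Gaussian noise on the %FFA scale, and
  monotonizes (cumulative titrant volume cannot decrease); triplicates by
  default.
* `gen_solubility_series()` — flat baseline below the CMC, slope `msr`
  above, additive Gaussian noise.

All generators take an integer `seed` and restore the caller's RNG state;
identical seeds give identical data. These simulations establish
*correctness of the estimators under their own model assumptions* — linear
conductivity regimes, exact first-order kinetics, additive/lognormal noise.
Real titrations show premicellar aggregation, drift and electrode lag; real
meta-tables have unbalanced categories, correlated covariates and
between-study heterogeneity; real lipolysis curves deviate from first-order
kinetics at late times. Passing tests therefore demonstrate algorithmic
correctness, not robustness to those effects.

## Worked example

```{r rst-example}
# plant beta = -2 on a PU:SC-like pair, then fit
mx <- gen_mixture_cmc_dataset(c1 = 10, c2 = 5, beta = -2,
                              noise = 0.02, seed = 42, pair_label = "PU:SC")
beta_table(mx)[, c("alpha", "cmc_mix_mM", "beta", "x1", "label")]
```

```{r cmc-example}
curve <- gen_conductivity(cmc = 4.16, pre_slope = 60, post_slope = 30,
                          c_range = c(1, 8.5), n = 40, noise = 0.002,
                          seed = 7)
phillips_cmc(curve)
segmented_cmc(curve)
```

```{r pls-example}
mt <- gen_meta_table(list(bs_type = c(PC = 0, PU = 0, SC = -2, SU = 0)),
                     baseline = 5, n = 100, noise_sd = 0.3, seed = 11)
X <- one_hot_encode(mt, list(bs_type = c("PC", "PU", "SC", "SU")))
summary(fit_pls(X, mt$response, ncomp = 2))
```

```{r lipolysis-example}
runs <- gen_lipolysis(phi_max = 15, k = 0.08, noise_sd = 0.3, seed = 3,
                      condition = "conjugated BS 10 mM")
fit_first_order(ffa_percent(runs[[1]]))
```

## Known limitations

* Binary mixtures only; no ternary systems, no temperature-dependent
  $\beta$, no counter-ion binding correction of the mixed-CMC analysis.
* The Phillips implementation assumes the titration spans the breakpoint
  with both regimes well represented; curves truncated near the CMC will
  fail detection or return boundary-flagged estimates.
* PLS component count and scaling follow the package's own conventions
  (autoscaling, NIPALS, default 2 components); numerical equality with
  other PLS software's VIP bar heights is not guaranteed — sign and rank
  behaviour is what the tests pin down.
* The %FFA conversion assumes a single mean triacylglycerol molar mass and
  complete titration of ionized FFA at the working pH; both are explicit,
  overridable parameters.
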