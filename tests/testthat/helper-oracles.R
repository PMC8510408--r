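# Independent oracles kept deliberately dumb: dense-grid minimization of the
# Rubingh implicit equation, and the printed small-intestine composition
# table used by the grouped-summary checks.

rubingh_F_oracle <- function(x1, alpha, cmc_mix, c1, c2) {
  x1^2 * log(alpha * cmc_mix / (x1 * c1)) -
    (1 - x1)^2 * log((1 - alpha) * cmc_mix / ((1 - x1) * c2))
}

# argmin |F| over an n-point grid; independent of the package's root finder
grid_x1_oracle <- function(alpha, cmc_mix, c1, c2, n = 1e6) {
  xs <- seq(1e-6, 1 - 1e-6, length.out = n)
  fx <- abs(rubingh_F_oracle(xs, alpha, cmc_mix, c1, c2))
  xs[which.min(fx)]
}

# Literature-collated bile-salt composition of the small intestine:
# percentage conjugated / unconjugated per gut segment, one row per source.
intestine_bs_composition <- function() {
  data.frame(
    segment = c(rep("duodenum", 3), rep("jejunum", 3), rep("ileum", 2)),
    conjugated = c(99.70, 94.20, 91.00, 100.00, 96.50, 84.00, 88.00, 75.00),
    unconjugated = c(0.30, 5.00, 9.00, 0.00, 3.50, 15.50, 11.79, 25.00)
  )
}
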