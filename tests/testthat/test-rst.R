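test_that("Clint ideal-mixing CMC matches direct arithmetic and boundaries", {
  expect_equal(clint_cmc(0.5, 4, 4), 4)
  expect_equal(clint_cmc(0.37, 4, 4), 4)      # equal components, any alpha
  expect_equal(clint_cmc(1, 13, 6), 13)       # boundary: pure component 1
  expect_equal(clint_cmc(0, 13, 6), 6)
  expect_equal(clint_cmc(0.2, 13, 6), 1 / (0.2 / 13 + 0.8 / 6),
               tolerance = 1e-12)
  expect_equal(clint_cmc(0.2, 13, 6), 6.7241, tolerance = 1e-4)
  expect_error(clint_cmc(0.2, -1, 6), "must be finite and > 0")
  expect_error(clint_cmc(1.2, 13, 6), "must lie in")
})

test_that("micellar composition solver: symmetry, ideal closed form, oracle", {
  # symmetric mixture
  expect_equal(solve_micellar_composition(0.5, 5, 5, 5), 0.5,
               tolerance = 1e-10)
  # ideal mixture: x1 = alpha * C12 / C1 in closed form
  c12 <- clint_cmc(0.2, 13, 6)
  x1 <- solve_micellar_composition(0.2, c12, 13, 6)
  expect_equal(x1, 0.2 * c12 / 13, tolerance = 1e-8)
  expect_equal(x1, 0.10345, tolerance = 1e-4)
  # grid-search oracle on random instances
  set.seed(101)
  for (i in 1:12) {
    a <- runif(1, 0.1, 0.9)
    c1 <- runif(1, 1, 15); c2 <- runif(1, 1, 15)
    b <- runif(1, -4, 1.5)
    fw <- predict_mixed_cmc(a, c1, c2, b)
    x_pkg <- solve_micellar_composition(a, fw$cmc_mix, c1, c2)
    x_orc <- grid_x1_oracle(a, fw$cmc_mix, c1, c2, n = 2e5)
    expect_lt(abs(x_pkg - x_orc), 2 / 2e5)
  }
})

test_that("inconsistent CMC triples raise a no-physical-root error", {
  # component 1 demands f1 > 1 while component 2 demands f2 < 1: no beta
  # can satisfy both balances
  expect_error(solve_micellar_composition(0.1, 20, 1, 30),
               "no physical root")
})

test_that("forward model: ideal reduction, symmetry, monotonicity in beta", {
  # beta = 0 reproduces Clint exactly, both directions
  for (a in c(0.2, 0.5, 0.8)) {
    expect_equal(predict_mixed_cmc(a, 10, 5, 0)$cmc_mix, clint_cmc(a, 10, 5),
                 tolerance = 1e-9)
  }
  # symmetric system: x1 = 1/2 for every beta (beta = 2 is a degenerate
  # triple root of the balance, hence the softer tolerance)
  for (b in c(-6, -2, 0, 2, 6)) {
    expect_equal(predict_mixed_cmc(0.5, 7, 7, b)$x1, 0.5, tolerance = 1e-6)
  }
  # mixed CMC increases monotonically with beta (dense sweep)
  betas <- seq(-6, 6, by = 0.25)
  cmcs <- vapply(betas, function(b) predict_mixed_cmc(0.3, 10, 5, b)$cmc_mix,
                 numeric(1))
  expect_true(all(diff(cmcs) > 0))
  expect_lt(predict_mixed_cmc(0.3, 10, 5, -2)$cmc_mix,
            predict_mixed_cmc(0.3, 10, 5, 0)$cmc_mix)
})

test_that("round trip recovers the planted interaction parameter", {
  set.seed(7)
  err <- replicate(200, {
    a <- runif(1, 0.05, 0.95)
    c1 <- runif(1, 0.5, 20); c2 <- runif(1, 0.5, 20)
    b <- runif(1, -8, 8)
    fw <- predict_mixed_cmc(a, c1, c2, b)
    abs(compute_beta(a, fw$cmc_mix, c1, c2)$beta - b)
  })
  expect_lt(max(err), 1e-6)
})

test_that("fitted solution satisfies the regular-solution identities", {
  set.seed(9)
  for (i in 1:25) {
    a <- runif(1, 0.1, 0.9)
    c1 <- runif(1, 1, 15); c2 <- runif(1, 1, 15)
    b <- runif(1, -5, 5)
    fw <- predict_mixed_cmc(a, c1, c2, b)
    fit <- compute_beta(a, fw$cmc_mix, c1, c2)
    expect_equal(fit$f1, exp(fit$beta * (1 - fit$x1)^2), tolerance = 1e-10)
    expect_equal(fit$f2, exp(fit$beta * fit$x1^2), tolerance = 1e-10)
    # the two single-component beta expressions agree at the root
    expect_lt(fit$consistency, 1e-6)
    expect_lt(fit$residual, 1e-9)
    expect_true(fit$x1 > 0 && fit$x1 < 1)
  }
})

test_that("ideal mixtures are labelled ideal with beta ~ 0", {
  fit <- compute_beta(0.3, clint_cmc(0.3, 12, 4), 12, 4)
  expect_lt(abs(fit$beta), 1e-6)
  expect_identical(fit$label, "ideal")
})

test_that("interaction classification follows the sign of beta", {
  expect_identical(classify_interaction(1.33), "antagonistic")
  expect_identical(classify_interaction(-0.40), "synergistic")
  expect_identical(classify_interaction(0), "ideal")
  expect_identical(classify_interaction(0.04), "ideal")   # inside band
  expect_identical(classify_interaction(0.04, tol = 0.01), "antagonistic")
  expect_error(classify_interaction(0.1, tol = -1))
})

test_that("beta_table vectorizes over a mixtures data frame", {
  mx <- gen_mixture_cmc_dataset(10, 5, beta = -1.5, seed = 3,
                                pair_label = "PU:SC")
  out <- beta_table(mx)
  expect_equal(nrow(out), 4)
  expect_equal(out$beta, rep(-1.5, 4), tolerance = 1e-7)
  expect_true(all(out$label == "synergistic"))
  expect_error(beta_table(mx[, -2]), "missing column")
})

test_that("rst_fit methods print and expose coefficients", {
  fit <- compute_beta(0.3, predict_mixed_cmc(0.3, 10, 5, -2)$cmc_mix, 10, 5)
  expect_output(print(fit), "synergistic")
  expect_named(coef(fit), c("beta", "x1"))
})
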