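test_that("local-polynomial second derivative reproduces polynomials", {
  x <- seq(1, 10, length.out = 25)
  # exact parabola: constant second derivative 2a
  cv <- conductivity_titration(x, 3 * x^2 + 2 * x + 1)
  d2 <- smooth_second_derivative(cv)
  expect_equal(d2$d2, rep(6, nrow(d2)), tolerance = 1e-8)
  # straight line: zero everywhere
  cv <- conductivity_titration(x, 5 + 4 * x)
  expect_equal(smooth_second_derivative(cv)$d2, rep(0, 19),
               tolerance = 1e-8)
  # endpoints excluded: window 7 drops 3 per side
  expect_equal(nrow(smooth_second_derivative(cv, window = 7)), 25 - 6)
  expect_error(smooth_second_derivative(cv, window = 6), "odd")
  expect_error(smooth_second_derivative(cv, window = 3, degree = 3),
               "degree")
  expect_error(smooth_second_derivative(cv, window = 27), "exceeds")
})

test_that("second-derivative extremum localizes a planted slope change", {
  tt <- gen_conductivity(cmc = 4, pre_slope = 60, post_slope = 30,
                         c_range = c(1, 8), n = 40, noise = 0)
  d2 <- smooth_second_derivative(tt)
  dev <- d2$d2 - median(d2$d2)
  loc <- d2$concentration[which.max(abs(dev))]
  window_span <- 7 * diff(tt$concentration[1:2])
  expect_lt(abs(loc - 4), window_span)
})

test_that("Phillips estimate recovers planted CMCs", {
  # noiseless: within 1 percent
  for (cmc in c(2.5, 4.16, 10)) {
    tt <- gen_conductivity(cmc = cmc, pre_slope = 60, post_slope = 30,
                           c_range = c(cmc / 3, cmc * 2), n = 40, noise = 0)
    est <- phillips_cmc(tt)
    expect_lt(abs(est$cmc - cmc) / cmc, 0.01)
    expect_gte(est$uncertainty, 0)
    expect_true(est$cmc >= min(tt$concentration) &&
                est$cmc <= max(tt$concentration))
  }
  # noisy: mean of 100 replicates within 2 percent
  est <- vapply(0:99, function(s) {
    phillips_cmc(gen_conductivity(10, 60, 30, c_range = c(2, 20), n = 40,
                                  noise = 0.005, seed = s))$cmc
  }, numeric(1))
  expect_lt(abs(mean(est) - 10) / 10, 0.02)
})

test_that("a single linear regime raises a no-breakpoint error", {
  x <- seq(1, 20, length.out = 30)
  expect_error(phillips_cmc(conductivity_titration(x, 5 + 3 * x)),
               "no breakpoint")
})

test_that("Phillips estimate is invariant under affine conductivity maps
           and equivariant under concentration rescaling", {
  tt <- gen_conductivity(cmc = 6, pre_slope = 55, post_slope = 28,
                         c_range = c(2, 12), n = 36, noise = 0.002, seed = 4)
  base <- phillips_cmc(tt)$cmc
  scaled <- conductivity_titration(tt$concentration,
                                   3.7 * tt$conductivity + 120)
  expect_equal(phillips_cmc(scaled)$cmc, base, tolerance = 1e-9)
  # mM -> M divides the estimate by 1000
  in_molar <- conductivity_titration(tt$concentration / 1000,
                                     tt$conductivity)
  expect_equal(phillips_cmc(in_molar)$cmc, base / 1000, tolerance = 1e-9)
})

test_that("estimation error grows with noise level", {
  mae <- vapply(c(0, 0.002, 0.01), function(nz) {
    errs <- vapply(1:40, function(s) {
      abs(phillips_cmc(gen_conductivity(8, 60, 30, c_range = c(2, 16),
                                        n = 40, noise = nz,
                                        seed = s))$cmc - 8)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(mae) > 0))
})

test_that("segmented two-line fit finds exact breakpoints and flags
           pathologies", {
  tt <- gen_conductivity(cmc = 4, pre_slope = 60, post_slope = 30,
                         c_range = c(1, 8), n = 30, noise = 0)
  sg <- segmented_cmc(tt)
  expect_equal(sg$cmc, 4, tolerance = 1e-9)
  expect_equal(sg$diagnostics$pre_slope, 60, tolerance = 1e-9)
  expect_equal(sg$diagnostics$post_slope, 30, tolerance = 1e-9)
  expect_false(sg$diagnostics$degenerate)
  # equal slopes: degenerate, flagged, estimate still returned
  x <- seq(1, 10, length.out = 20)
  expect_warning(sgd <- segmented_cmc(conductivity_titration(x, 2 + 5 * x)),
                 "degenerate")
  expect_true(sgd$diagnostics$degenerate)
  expect_true(is.finite(sgd$cmc))
})

test_that("Phillips and segmented estimates agree on noiseless curves", {
  for (cmc in c(3, 7, 12)) {
    tt <- gen_conductivity(cmc = cmc, pre_slope = 70, post_slope = 35,
                           c_range = c(cmc / 3, cmc * 2), n = 40, noise = 0)
    expect_lt(abs(segmented_cmc(tt)$cmc - phillips_cmc(tt)$cmc) / cmc, 0.03)
  }
})

test_that("ionization degree is the post/pre slope ratio, clipped to [0,1]", {
  expect_equal(ionization_degree(60, 30), 0.5)
  expect_equal(ionization_degree(50, 50), 1)
  expect_warning(r <- ionization_degree(50, 60), "clipping")
  expect_equal(r, 1)
  expect_error(ionization_degree(0, 30), "> 0")
  # planted slope ratio recovered through the segmented fit
  tt <- gen_conductivity(cmc = 5, pre_slope = 100, post_slope = 37,
                         c_range = c(1, 10), n = 40, noise = 0.001, seed = 2)
  sg <- segmented_cmc(tt)
  expect_equal(ionization_degree(sg$diagnostics$pre_slope,
                                 sg$diagnostics$post_slope),
               0.37, tolerance = 0.01)
})
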