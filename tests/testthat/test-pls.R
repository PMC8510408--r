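test_that("grouped summaries reproduce the intestinal composition ratios", {
  tab <- intestine_bs_composition()
  ile <- tab[tab$segment == "ileum", ]
  expect_equal(mean(ile$conjugated), 81.5)
  expect_equal(round(mean(ile$conjugated)), 82)
  expect_equal(round(mean(ile$unconjugated)), 18)
  duo <- tab[tab$segment == "duodenum", ]
  expect_equal(round(mean(duo$unconjugated)), 5)

  long <- rbind(
    data.frame(segment = tab$segment, form = "conjugated",
               pct = tab$conjugated),
    data.frame(segment = tab$segment, form = "unconjugated",
               pct = tab$unconjugated))
  gs <- group_summary(long[long$segment == "ileum", ], "pct", "form")
  expect_equal(gs$mean[gs$group == "conjugated"], 81.5)
  expect_equal(gs$n, c(2L, 2L))
  expect_equal(gs$sd[gs$group == "conjugated"], sd(c(88, 75)))
})

test_that("group_summary handles constants, singletons and bad schemas", {
  df <- data.frame(g = c("a", "a", "a", "b"), y = c(4, 4, 4, 9))
  gs <- group_summary(df, "y", "g")
  expect_equal(gs$mean, c(4, 9))
  expect_equal(gs$sd[1], 0)
  expect_true(is.na(gs$sd[2]))  # singleton: sd undefined
  expect_error(group_summary(df, "z", "g"), "not found")
  expect_error(group_summary(df[0, ], "y", "g"), "no records")
})

test_that("one-hot encoding keeps all levels and handles mixture tags", {
  df <- data.frame(bs_type = c("PC", "SU", "PU:PC"), temp = c(298, 310, 303))
  X <- one_hot_encode(df, list(bs_type = c("PC", "PU", "SC", "SU")),
                      numeric_cols = "temp")
  expect_equal(colnames(X), c("bs_type_PC", "bs_type_PU", "bs_type_SC",
                              "bs_type_SU", "temp"))
  expect_equal(unname(X[1, 1:4]), c(1, 0, 0, 0))
  expect_equal(unname(X[2, 1:4]), c(0, 0, 0, 1))
  # a mixture record sets both component indicators
  expect_equal(unname(X[3, 1:4]), c(1, 1, 0, 0))
  expect_equal(X[, "temp"], c(298, 310, 303))
  expect_error(one_hot_encode(df, list(bs_type = c("PC", "PU"))),
               "record 2.*'SU'")
  expect_error(one_hot_encode(df[0, ], list(bs_type = "PC")), "no records")
})

test_that("NIPALS PLS matches the OLS oracle at full rank", {
  set.seed(2)
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- drop(X %*% c(1, -0.5, 0, 2, 0.3)) + rnorm(40, sd = 0.2)
  fit <- fit_pls(X, y, ncomp = 5)
  ols <- qr.coef(qr(scale(X)), drop(scale(y)))
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-8)
})

test_that("PLS scores are orthogonal and predictions are affine-invariant", {
  set.seed(4)
  X <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, letters[1:4]))
  y <- X[, 1] - 2 * X[, 3] + rnorm(30, sd = 0.3)
  fit <- fit_pls(X, y, ncomp = 3)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  # rescaling input columns changes nothing after autoscaling
  X2 <- sweep(sweep(X, 2, c(10, 0.1, 5, 2), "*"), 2, c(1, -3, 0, 7), "+")
  fit2 <- fit_pls(X2, y, ncomp = 3)
  expect_equal(predict(fit2, X2), predict(fit, X), tolerance = 1e-8)
})

test_that("PLS rejects degenerate inputs and truncates at rank", {
  X <- matrix(c(1:10, rep(3, 10)), 10, 2,
              dimnames = list(NULL, c("ok", "const")))
  expect_error(fit_pls(X, rnorm(10)), "zero-variance")
  expect_error(fit_pls(X[, 1, drop = FALSE], rep(2, 10)), "zero variance")
  # rank-1 design cannot support 2 components
  expect_warning(fit <- fit_pls(matrix(rnorm(24), 12, 2,
                                       dimnames = list(NULL, c("a", "b"))) %*%
                                  matrix(c(1, 1, 2, 2), 2),
                                rnorm(12), ncomp = 2),
                 "rank exhausted")
  expect_equal(fit$ncomp, 1)
})

test_that("PLS predictions agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(6)
  X <- matrix(rnorm(150), 30, 5, dimnames = list(NULL, paste0("d", 1:5)))
  y <- drop(X %*% c(0.5, 0, -1, 0, 2)) + rnorm(30, sd = 0.4)
  mine <- fit_pls(X, y, ncomp = 2)
  ref <- mixOmics::pls(X, y, ncomp = 2, scale = TRUE, mode = "regression")
  ref_pred <- predict(ref, X)$predict[, 1, 2]
  expect_equal(unname(predict(mine, X)), unname(ref_pred),
               tolerance = 1e-10)
})

test_that("VIP identities hold: equal weights give VIP 1, sum VIP^2 = p", {
  # y equal to the sum of iid columns: weights equal across variables
  set.seed(10)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rowSums(scale(X))
  v <- vip_scores(fit_pls(X, y, ncomp = 1))
  expect_equal(v$vip, rep(1, 3), tolerance = 0.35)  # sampling wobble
  # the normalization is exact on every model
  for (s in 1:5) {
    set.seed(s)
    Xr <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("x", 1:4)))
    yr <- rnorm(30)
    vr <- vip_scores(fit_pls(Xr, yr, ncomp = 2))
    expect_equal(sum(vr$vip^2), 4, tolerance = 1e-9)
  }
})

test_that("a planted single-category effect is recovered by VIP rank and
           coefficient sign", {
  hits <- vapply(1:20, function(s) {
    mt <- gen_meta_table(
      list(bs_type = c(PC = 0, PU = 0, SC = -2, SU = 0)),
      baseline = 5, n = 100, noise_sd = 0.3, seed = s)
    X <- one_hot_encode(mt, list(bs_type = c("PC", "PU", "SC", "SU")))
    v <- vip_scores(fit_pls(X, mt$response, ncomp = 2))
    v$variable[1] == "bs_type_SC" && v$coefficient[1] < 0
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("exact planted signal puts all importance on one column", {
  set.seed(13)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- drop(scale(X[, 2]))
  fit <- fit_pls(X, y, ncomp = 1)
  v <- vip_scores(fit)
  expect_identical(v$variable[1], "x2")
  expect_equal(which.max(abs(fit$coefficients)), c(x2 = 2L))
})

test_that("Welch t-test matches stats::t.test and handles edge cases", {
  set.seed(5)
  a <- rnorm(10); b <- rnorm(12) + 1
  mine <- welch_t_test(a, b)
  ref <- t.test(a, b)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # one-tailed agreement
  mine_r <- welch_t_test(a, b, tail = "right")
  ref_r <- t.test(a, b, alternative = "greater")
  expect_equal(mine_r$p_value, ref_r$p.value, tolerance = 1e-12)
  # identical samples: t = 0, one-tailed p = 0.5
  w <- welch_t_test(c(1, 2, 3), c(1, 2, 3), tail = "right")
  expect_equal(w$t, 0)
  expect_equal(w$p_value, 0.5)
  # complete separation of constant samples
  w2 <- welch_t_test(c(5, 5, 5), c(1, 1, 1), tail = "right")
  expect_lt(w2$p_value, 1e-6)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("one-tailed Welch test has power on unequal-n category groups", {
  # true gap of one sd, n = 28 vs 16
  sig <- vapply(1:500, function(s) {
    set.seed(s)
    a <- rnorm(28, mean = 1)
    b <- rnorm(16, mean = 0)
    welch_t_test(a, b, tail = "right")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.8)
})

test_that("select_ncomp returns the argmin of leave-one-out PRESS", {
  set.seed(20)
  X <- matrix(rnorm(240), 60, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- drop(scale(X[, 1])) + rnorm(60, sd = 0.1)
  a <- select_ncomp(X, y, max_ncomp = 3)
  # recompute PRESS independently from the fit/predict primitives
  press <- vapply(1:3, function(k) {
    sum(vapply(1:60, function(i) {
      f <- fit_pls(X[-i, ], y[-i], ncomp = k)
      (predict(f, X[i, , drop = FALSE]) - y[i])^2
    }, numeric(1)))
  }, numeric(1))
  expect_equal(a, which.min(press))
})
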