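## Meta-analysis statistics: grouped summaries, one-hot design matrices,
## NIPALS partial least squares with VIP scores, and Welch t-tests.
##
## The PLS model is fitted on autoscaled data (every column of X and the
## response centred to mean 0 and scaled to unit standard deviation), which
## makes the regression coefficients directly comparable across predictors
## ("standardized coefficients") and is the convention the VIP score assumes.

#' Grouped mean, standard deviation and count
#'
#' @param data A data frame of records.
#' @param response Name of the numeric response column.
#' @param group Name of the grouping column.
#' @return Data frame with one row per group: `group`, `mean`, `sd`
#'   (sample standard deviation, `n - 1` denominator; `NA` for singleton
#'   groups) and `n`.
#' @examples
#' ileum <- data.frame(form = rep(c("conjugated", "unconjugated"), each = 2),
#'                     pct = c(88, 75, 11.79, 25))
#' group_summary(ileum, "pct", "form")
#' @export
group_summary <- function(data, response, group) {
  if (!response %in% names(data)) {
    stop_schema("response column `", response, "` not found")
  }
  if (!group %in% names(data)) {
    stop_schema("group column `", group, "` not found")
  }
  if (nrow(data) == 0) stop_schema("no records")
  g <- factor(data[[group]])
  y <- data[[response]]
  out <- data.frame(
    group = levels(g),
    mean = as.numeric(tapply(y, g, mean)),
    sd = as.numeric(tapply(y, g, function(v)
      if (length(v) < 2) NA_real_ else stats::sd(v))),
    n = as.integer(tapply(y, g, length)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' One-hot design matrix from categorical and numeric descriptors
#'
#' Expands each declared categorical column into one indicator column per
#' declared level; no reference level is dropped (PLS tolerates the
#' collinearity and an importance score is wanted for every level). A cell
#' may carry several levels separated by `:` — as for binary-mixture records
#' tagged with the category of each component — in which case every named
#' level's indicator is set. Declared numeric columns are appended unchanged.
#' Column order is deterministic: indicators in declared order, then numeric
#' columns in declared order.
#'
#' @param data Data frame of records.
#' @param levels Named list: for each categorical column, the character
#'   vector of admissible levels in the desired order.
#' @param numeric_cols Character vector of numeric descriptor columns.
#' @return Numeric matrix with informative column names.
#' @export
one_hot_encode <- function(data, levels, numeric_cols = character()) {
  if (nrow(data) == 0) stop_schema("no records to encode")
  blocks <- list()
  for (col in names(levels)) {
    if (!col %in% names(data)) {
      stop_schema("categorical column `", col, "` not found")
    }
    lv <- levels[[col]]
    vals <- strsplit(as.character(data[[col]]), ":", fixed = TRUE)
    for (i in seq_along(vals)) {
      unknown <- setdiff(vals[[i]], lv)
      if (length(unknown)) {
        stop_schema(sprintf(
          "record %d: level '%s' of `%s` is not among the declared levels",
          i, unknown[1], col))
      }
    }
    ind <- vapply(lv, function(l)
      as.numeric(vapply(vals, function(v) l %in% v, logical(1))),
      numeric(nrow(data)))
    ind <- matrix(ind, nrow = nrow(data),
                  dimnames = list(NULL, paste(col, lv, sep = "_")))
    blocks[[length(blocks) + 1]] <- ind
  }
  for (col in numeric_cols) {
    if (!col %in% names(data)) {
      stop_schema("numeric column `", col, "` not found")
    }
    v <- data[[col]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop_schema("numeric column `", col, "` contains non-finite values")
    }
    blocks[[length(blocks) + 1]] <- matrix(v, ncol = 1,
                                           dimnames = list(NULL, col))
  }
  if (length(blocks) == 0) stop_schema("no columns declared")
  do.call(cbind, blocks)
}

#' Partial least squares regression by NIPALS
#'
#' Univariate-response PLS1. Predictors and response are autoscaled; weight,
#' score and loading vectors are extracted one component at a time with
#' deflation of both `X` and `y`. If the design's rank is exhausted before
#' `ncomp` components, the model is truncated with a warning.
#'
#' @param X Numeric matrix (n x p) of predictors with column names.
#' @param y Numeric response of length n.
#' @param ncomp Number of latent components to extract.
#' @return Object of class `pls_fit` with autoscaling parameters
#'   (`x_means`, `x_scales`, `y_mean`, `y_scale`), NIPALS `weights` (p x A),
#'   `scores` (n x A), `x_loadings` (p x A), `y_loadings` (A), and
#'   `coefficients` — the p-vector of regression coefficients on the
#'   standardized scale.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
#' fit_pls(X, X[, 1] + rnorm(20, sd = 0.1), ncomp = 2)
#' @export
fit_pls <- function(X, y, ncomp = 2) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop_domain("need at least 3 observations")
  if (ncomp < 1) stop_domain("`ncomp` must be >= 1")
  if (length(y) != n) stop_domain("length(y) must equal nrow(X)")
  x_means <- colMeans(X)
  x_scales <- apply(X, 2, stats::sd)
  if (any(x_scales == 0)) {
    stop_schema("zero-variance column(s): ",
                paste(colnames(X)[x_scales == 0], collapse = ", "))
  }
  y_mean <- mean(y)
  y_scale <- stats::sd(y)
  if (y_scale == 0) stop_schema("response has zero variance")
  Xs <- sweep(sweep(X, 2, x_means), 2, x_scales, "/")
  ys <- (y - y_mean) / y_scale

  A <- min(ncomp, n - 1, p)
  W <- matrix(0, p, A); Tm <- matrix(0, n, A); P <- matrix(0, p, A)
  q <- numeric(A)
  Xd <- Xs; yd <- ys
  a_used <- 0
  for (a in seq_len(A)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_a <- Xd %*% w
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- crossprod(Xd, t_a) / tt
    q_a <- sum(yd * t_a) / tt
    W[, a] <- w; Tm[, a] <- t_a; P[, a] <- p_a; q[a] <- q_a
    Xd <- Xd - t_a %*% t(p_a)
    yd <- yd - q_a * t_a
    a_used <- a
  }
  if (a_used == 0) stop_domain("no extractable PLS component (X'y is zero)")
  if (a_used < ncomp) {
    warning(sprintf("rank exhausted: %d component(s) extracted, %d requested",
                    a_used, ncomp))
  }
  W <- W[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  ## standardized-scale regression vector: B = W (P'W)^{-1} q
  B <- W %*% solve(crossprod(P, W), q)
  structure(
    list(ncomp = a_used, x_means = x_means, x_scales = x_scales,
         y_mean = y_mean, y_scale = y_scale,
         weights = W, scores = Tm, x_loadings = P, y_loadings = q,
         coefficients = stats::setNames(drop(B), colnames(X)),
         var_names = colnames(X), n = n, p = p),
    class = "pls_fit"
  )
}

#' @export
print.pls_fit <- function(x, digits = 4, ...) {
  cat(sprintf("NIPALS PLS fit: %d observations, %d predictors, %d component(s)\n",
              x$n, x$p, x$ncomp))
  cat("Standardized coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.pls_fit <- function(object, scale = c("standardized", "original"), ...) {
  scale <- match.arg(scale)
  b <- object$coefficients
  if (scale == "standardized") return(b)
  b_orig <- b * object$y_scale / object$x_scales
  c(`(intercept)` = object$y_mean - sum(b_orig * object$x_means), b_orig)
}

#' @export
predict.pls_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$var_names, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$x_means), 2, object$x_scales, "/")
  drop(Xs %*% object$coefficients) * object$y_scale + object$y_mean
}

#' @export
summary.pls_fit <- function(object, ...) {
  v <- vip_scores(object)
  cat(sprintf("NIPALS PLS: %d component(s), n = %d, p = %d\n",
              object$ncomp, object$n, object$p))
  print(v)
  invisible(v)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a SSY_a * w_ja^2 / sum_a SSY_a)` with
#' `SSY_a = q_a^2 * t_a' t_a` the response variance captured by component `a`
#' (NIPALS weights are unit-norm). The squared VIPs average to 1, so VIP > 1
#' conventionally marks an influential predictor.
#'
#' @param model A [fit_pls()] model.
#' @return Object of class `vip_report`: data frame with one row per
#'   predictor and columns `variable`, `vip`, `coefficient` (standardized),
#'   sorted by declining VIP.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_fit"))
  W <- model$weights
  ssy <- model$y_loadings^2 * colSums(model$scores^2)
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  vip <- sqrt(model$p * drop(wn2 %*% ssy) / sum(ssy))
  out <- data.frame(variable = model$var_names, vip = vip,
                    coefficient = unname(model$coefficients),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$vip), ]
  rownames(out) <- NULL
  class(out) <- c("vip_report", "data.frame")
  out
}

#' @export
print.vip_report <- function(x, digits = 3, ...) {
  cat("Variable importance in projection (VIP > 1 = influential):\n")
  df <- data.frame(variable = x$variable,
                   vip = round(x$vip, digits),
                   coefficient = round(x$coefficient, digits),
                   influential = ifelse(x$vip > 1, "*", ""))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Welch two-sample t-test with selectable tail
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom. For
#' two identical (zero-variance, zero-difference) samples the statistic is 0
#' and the one-tailed p-value 0.5 by convention.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param tail `"two"`, `"right"` (H1: mean(a) > mean(b)) or `"left"`
#'   (H1: mean(a) < mean(b)).
#' @return List with `t`, `df`, `p_value`, `mean_diff` and a `significant`
#'   flag at the 0.05 level.
#' @export
welch_t_test <- function(a, b, tail = c("two", "right", "left")) {
  tail <- match.arg(tail)
  if (length(a) < 2 || length(b) < 2) {
    stop_domain("each sample needs at least 2 observations")
  }
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  d <- mean(a) - mean(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    tstat <- if (d == 0) 0 else sign(d) * Inf
    df <- na + nb - 2
  } else {
    tstat <- d / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  p <- switch(tail,
    two = if (is.infinite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df),
    right = if (is.infinite(tstat)) as.numeric(tstat < 0)
            else stats::pt(tstat, df, lower.tail = FALSE),
    left = if (is.infinite(tstat)) as.numeric(tstat > 0)
           else stats::pt(tstat, df)
  )
  list(t = tstat, df = df, p_value = p, mean_diff = d,
       significant = p < 0.05)
}

#' Choose the number of PLS components by leave-one-out PRESS
#'
#' @param X,y As in [fit_pls()].
#' @param max_ncomp Largest number of components to consider.
#' @return Integer: the component count minimizing the leave-one-out
#'   predictive residual sum of squares.
#' @export
select_ncomp <- function(X, y, max_ncomp = min(4, ncol(X))) {
  X <- as.matrix(X)
  n <- nrow(X)
  press <- vapply(seq_len(max_ncomp), function(a) {
    errs <- vapply(seq_len(n), function(i) {
      fit <- tryCatch(
        suppressWarnings(fit_pls(X[-i, , drop = FALSE], y[-i], ncomp = a)),
        error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      (predict(fit, X[i, , drop = FALSE]) - y[i])^2
    }, numeric(1))
    sum(errs, na.rm = TRUE)
  }, numeric(1))
  which.min(press)
}
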