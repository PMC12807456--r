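#' Z-score a table of numeric columns
#'
#' Centers each column to mean 0 and scales to unbiased sample Std 1.
#'
#' @param table data.frame or matrix of numeric columns.
#' @return data.frame of standardized columns.
#' @export
zscore <- function(table) {
  x <- as.data.frame(table)
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0 | is.na(sds)))
    stop("constant column(s): ",
         paste(names(x)[sds == 0 | is.na(sds)], collapse = ", "))
  as.data.frame(scale(x))
}

#' Ordinary least squares with CIs, AIC and VIF
#'
#' Multiple linear regression of an outcome on (typically z-scored)
#' features, reporting coefficients with t-based 95\% CIs, R-squared,
#' adjusted R-squared, Gaussian maximum-likelihood AIC (constants
#' included; parameter count = coefficients + intercept), and the
#' variance inflation factor of each predictor.
#'
#' @param X data.frame/matrix of predictors (n x p).
#' @param y Numeric outcome of length n.
#' @param conf_level CI level (default 0.95).
#' @return List of class `regression_report`: `coefficients` (data.frame:
#'   estimate, lower, upper, p), `r_squared`, `adj_r_squared`, `aic`,
#'   `vif`, `aic_floored` flag.
#' @export
fit_ols <- function(X, y, conf_level = 0.95) {
  X <- as.data.frame(X)
  n <- length(y); p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1")
  df <- data.frame(X, .y = y)
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) stop("singular design matrix")
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, 1],
                      lower = ci[, 1], upper = ci[, 2],
                      p = sm$coefficients[, 4], row.names = NULL)
  rss <- sum(stats::residuals(fit)^2)
  floored <- rss < 1e-12 * max(1, sum(y^2))
  sigma2 <- max(rss / n, 1e-300)
  aic <- n * (log(2 * pi * sigma2) + 1) + 2 * (p + 1)
  structure(list(coefficients = coefs, r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared, aic = aic,
                 aic_floored = floored, vif = vif_values(X), fit = fit),
            class = "regression_report")
}

# VIF_j = 1 / (1 - R^2 of predictor j on the others); Inf when exactly
# collinear
vif_values <- function(X) {
  X <- as.data.frame(X)
  p <- ncol(X)
  if (p < 2) return(stats::setNames(rep(1, p), names(X)))
  out <- numeric(p)
  for (j in seq_len(p)) {
    fit <- stats::lm(X[[j]] ~ ., data = X[-j])
    r2 <- summary(fit)$r.squared
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  stats::setNames(out, names(X))
}

#' Iterative VIF pruning
#'
#' Removes the single highest-VIF variable, recomputes, and repeats until
#' every remaining variable has VIF below `threshold`. Ties break to the
#' first variable in input order.
#'
#' @param X data.frame of predictors.
#' @param threshold VIF threshold (default 10).
#' @return List: `retained` (names), `trail` (data.frame of removed
#'   variable and its VIF per step), `vif` (final VIFs).
#' @export
vif_prune <- function(X, threshold = 10) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("need >= 2 variables")
  trail <- data.frame(removed = character(0), vif = numeric(0))
  repeat {
    v <- vif_values(X)
    if (all(v < threshold) || ncol(X) <= 1) break
    worst <- which.max(v)     # which.max takes the first on ties
    trail <- rbind(trail, data.frame(removed = names(X)[worst],
                                     vif = v[[worst]]))
    X <- X[-worst]
  }
  list(retained = names(X), trail = trail, vif = vif_values(X))
}

#' Spearman correlation network with bootstrap CIs and BH correction
#'
#' All pairwise Spearman correlations of the table's columns, percentile
#' bootstrap CIs over subjects, and Benjamini-Hochberg adjusted Q values
#' across all pairs jointly. Edges with Q below `q` are flagged. Ties are
#' handled by average ranks; pairs involving a constant column are
#' skipped with a reason.
#'
#' @param table data.frame of numeric columns (>= 3 rows).
#' @param n_boot Bootstrap resamples (default 10000; 0 skips CIs).
#' @param q Significance threshold on Q (default 0.05).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level CI level (default 0.95).
#' @return List: `edges` (data.frame: var1, var2, r, lower, upper, p, Q,
#'   significant), `skipped` (data.frame of skipped pairs and reasons).
#' @export
spearman_network <- function(table, n_boot = 10000, q = 0.05, seed = 0,
                             conf_level = 0.95) {
  x <- as.data.frame(table)
  n <- nrow(x); p <- ncol(x)
  if (n < 3) stop("need >= 3 subjects")
  sds <- vapply(x, stats::sd, numeric(1))
  const <- names(x)[sds == 0 | is.na(sds)]
  pairs <- utils::combn(names(x), 2)
  skipped <- data.frame(var1 = character(0), var2 = character(0),
                        reason = character(0))
  keep <- rep(TRUE, ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    if (any(pairs[, k] %in% const)) {
      keep[k] <- FALSE
      skipped <- rbind(skipped,
                       data.frame(var1 = pairs[1, k], var2 = pairs[2, k],
                                  reason = "constant column"))
    }
  }
  pairs <- pairs[, keep, drop = FALSE]
  m <- ncol(pairs)
  if (!m) return(list(edges = NULL, skipped = skipped))
  xm <- as.matrix(x)
  r_all <- stats::cor(xm, method = "spearman")
  r <- vapply(seq_len(m), function(k) r_all[pairs[1, k], pairs[2, k]],
              numeric(1))
  # asymptotic t test on the rank correlation
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pval[abs(r) >= 1] <- 0
  Q <- stats::p.adjust(pval, method = "BH")
  lower <- upper <- rep(NA_real_, m)
  if (n_boot > 0) {
    alpha <- (1 - conf_level) / 2
    boots <- with_seed(seed, {
      bs <- matrix(NA_real_, n_boot, m)
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        rm_ <- suppressWarnings(stats::cor(xm[idx, , drop = FALSE],
                                           method = "spearman"))
        bs[b, ] <- vapply(seq_len(m),
                          function(k) rm_[pairs[1, k], pairs[2, k]],
                          numeric(1))
      }
      bs
    })
    for (k in seq_len(m)) {
      qs <- stats::quantile(boots[, k], c(alpha, 1 - alpha), na.rm = TRUE,
                            names = FALSE)
      lower[k] <- qs[1]; upper[k] <- qs[2]
    }
  }
  edges <- data.frame(var1 = pairs[1, ], var2 = pairs[2, ], r = r,
                      lower = lower, upper = upper, p = pval, Q = Q,
                      significant = Q < q)
  list(edges = edges, skipped = skipped)
}

#' LASSO with leave-one-out cross-validation
#'
#' L1-penalized least squares with the (1/2n) residual scaling and an
#' unpenalized intercept, solved by glmnet over a log-spaced lambda grid.
#' The optimal lambda minimizes the leave-one-out cross-validated MSE;
#' coefficients are refit on the full data at the optimum.
#'
#' @param X Standardized predictor matrix/data.frame.
#' @param y Numeric outcome.
#' @param lambda_grid Decreasing positive grid; default 200 log-spaced
#'   points in [1e-3, 1e2].
#' @return List of class `lasso_report`: `lambda` (grid), `cv_mse`,
#'   `lambda_opt`, `path` (p x n_lambda coefficient matrix),
#'   `coefficients` and `nonzero` at the optimum.
#' @export
lasso_loocv <- function(X, y, lambda_grid = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need n >= 3")
  if (is.null(lambda_grid))
    lambda_grid <- exp(seq(log(1e2), log(1e-3), length.out = 200))
  if (!length(lambda_grid)) stop("empty lambda grid")
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  errs <- matrix(NA_real_, n, length(lambda_grid))
  for (i in seq_len(n)) {
    fit <- glmnet::glmnet(X[-i, , drop = FALSE], y[-i], family = "gaussian",
                          lambda = lambda_grid, standardize = FALSE)
    pred <- stats::predict(fit, newx = X[i, , drop = FALSE],
                           s = lambda_grid, exact = FALSE)
    errs[i, ] <- (as.numeric(pred) - y[i])^2
  }
  cv_mse <- colMeans(errs)
  opt <- which.min(cv_mse)
  full <- glmnet::glmnet(X, y, family = "gaussian", lambda = lambda_grid,
                         standardize = FALSE)
  path <- as.matrix(full$beta)
  beta_opt <- path[, opt]
  structure(list(lambda = lambda_grid, cv_mse = cv_mse,
                 lambda_opt = lambda_grid[opt],
                 intercept = full$a0[opt], path = path,
                 coefficients = beta_opt,
                 nonzero = names(beta_opt)[beta_opt != 0]),
            class = "lasso_report")
}

#' Partial least squares regression with VIP scores
#'
#' Univariate-response PLS (NIPALS), with the number of components chosen
#' by leave-one-out cross-validated MSE over 1..min(max_components, p,
#' n-1). VIP_j = sqrt(p * sum_a SS_a w_ja^2 / sum_a SS_a) with normalized
#' weight vectors w_a and per-component explained outcome variance SS_a.
#' VIP >= 1 marks a variable as contributing to the prediction.
#'
#' @param X Predictor matrix/data.frame (internally centered/scaled).
#' @param y Numeric outcome (nonzero variance).
#' @param max_components Upper bound on components (default 5).
#' @return List of class `pls_report`: `n_components`, `vip` (named),
#'   `cv_mse` per component count, `weights`, `ss`.
#' @export
pls_vip <- function(X, y, max_components = 5) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(y) == 0) stop("zero-variance outcome")
  amax <- min(max_components, p, n - 1)
  cv_mse <- numeric(amax)
  sse <- matrix(0, n, amax)
  for (i in seq_len(n)) {
    f <- pls1_fit(X[-i, , drop = FALSE], y[-i], amax)
    for (a in seq_len(amax)) {
      pred <- pls1_predict(f, X[i, , drop = FALSE], a)
      sse[i, a] <- (pred - y[i])^2
    }
  }
  cv_mse <- colMeans(sse)
  ncomp <- which.min(cv_mse)
  f <- pls1_fit(X, y, ncomp)
  ss <- f$q^2 * f$tt                     # outcome variance per component
  w2 <- f$W^2                            # weights are unit-norm columns
  vip <- sqrt(p * as.numeric(w2 %*% ss) / sum(ss))
  structure(list(n_components = ncomp, vip = stats::setNames(vip, colnames(X)),
                 cv_mse = cv_mse, weights = f$W, ss = ss),
            class = "pls_report")
}

# NIPALS PLS1 on centered/scaled data; returns what predict and VIP need
pls1_fit <- function(X, y, A) {
  xm <- colMeans(X); xs <- apply(X, 2, stats::sd)
  xs[xs == 0] <- 1
  ym <- mean(y)
  E <- sweep(sweep(X, 2, xm), 2, xs, "/")
  fres <- y - ym
  p <- ncol(X)
  W <- P <- matrix(0, p, A)
  q <- tt <- numeric(A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, fres))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1L; break }
    w <- w / nw
    t_ <- drop(E %*% w)
    tt_a <- sum(t_^2)
    p_ <- drop(crossprod(E, t_)) / tt_a
    q_ <- sum(fres * t_) / tt_a
    E <- E - tcrossprod(t_, p_)
    fres <- fres - q_ * t_
    W[, a] <- w; P[, a] <- p_; q[a] <- q_; tt[a] <- tt_a
  }
  list(W = W[, seq_len(A), drop = FALSE], P = P[, seq_len(A), drop = FALSE],
       q = q[seq_len(A)], tt = tt[seq_len(A)], xm = xm, xs = xs, ym = ym,
       A = A)
}

# score matrix (n x A) of new data under a fitted PLS1 model
pls1_scores <- function(fit, Xnew) {
  E <- sweep(sweep(as.matrix(Xnew), 2, fit$xm), 2, fit$xs, "/")
  T_ <- matrix(0, nrow(E), fit$A)
  for (k in seq_len(fit$A)) {
    T_[, k] <- drop(E %*% fit$W[, k])
    E <- E - tcrossprod(T_[, k], fit$P[, k])
  }
  T_
}

pls1_predict <- function(fit, Xnew, a) {
  a <- min(a, fit$A)
  if (a < 1) return(rep(fit$ym, nrow(Xnew)))
  E <- sweep(sweep(as.matrix(Xnew), 2, fit$xm), 2, fit$xs, "/")
  yhat <- rep(fit$ym, nrow(Xnew))
  for (k in seq_len(a)) {
    t_ <- drop(E %*% fit$W[, k])
    yhat <- yhat + fit$q[k] * t_
    E <- E - tcrossprod(t_, fit$P[, k])
  }
  yhat
}

#' Minimum sample size to detect a correlation
#'
#' Fisher z approximation, two-sided:
#' n = ceil(((z_{1-alpha/2} + z_{power}) / atanh(r))^2) + 3.
#'
#' @param r Expected correlation, 0 < |r| < 1.
#' @param alpha Type I error (default 0.05).
#' @param power Target power (default 0.8).
#' @return Minimum n (integer).
#' @export
power_sample_size <- function(r, alpha = 0.05, power = 0.8) {
  if (!(abs(r) > 0 && abs(r) < 1)) stop("need 0 < |r| < 1")
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  as.integer(ceiling(((za + zb) / atanh(abs(r)))^2) + 3)
}
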