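# Ledermann bound: largest k of an identified k-factor model for p
# variables, (p - k)^2 >= p + k
ledermann_bound <- function(p) {
  k <- 0L
  while (k + 1 <= p && (p - (k + 1))^2 >= p + (k + 1)) k <- k + 1L
  k
}

# Gaussian log-likelihood of a correlation matrix S under the factor
# model Sigma = Lambda Lambda' + Psi
fa_loglik <- function(S, Lambda, psi, n) {
  Sigma <- tcrossprod(Lambda) + diag(psi)
  p <- ncol(S)
  -n / 2 * (p * log(2 * pi) + determinant(Sigma)$modulus[1] +
              sum(diag(solve(Sigma, S))))
}

#' Select the number of factors by BIC and Velicer's MAP
#'
#' BIC: maximum-likelihood factor models for k = 1..k_max are fit and
#' scored by -2 logLik + params log n, with params = p(k + 1) -
#' k(k - 1)/2 and k_max the Ledermann bound capped at 8. MAP: Velicer's
#' minimum average partial on the correlation matrix, using squared
#' partial correlations after removing successive principal components.
#'
#' @param table data.frame of numeric columns (n > p, p >= 3).
#' @param k_max Optional cap on the number of factors examined.
#' @return List: `k_bic`, `k_map`, `bic` (per k), `map` (per k, index 1
#'   is 0 components), `no_common_factor` flag (MAP minimized at 0
#'   components).
#' @export
select_n_factors <- function(table, k_max = NULL) {
  x <- as.matrix(as.data.frame(table))
  n <- nrow(x); p <- ncol(x)
  if (p < 3) stop("need p >= 3")
  if (n <= p) stop("need n > p")
  R <- stats::cor(x)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) <= 1e-10)
    stop("correlation matrix not positive definite; smallest eigenvalue ",
         format(min(ev$values)))
  led <- ledermann_bound(p)
  if (is.null(k_max)) k_max <- min(led, 8L)
  k_max <- min(k_max, led)
  bic <- rep(Inf, k_max)
  for (k in seq_len(k_max)) {
    fit <- tryCatch(stats::factanal(covmat = R, factors = k, n.obs = n,
                                    rotation = "none"),
                    error = function(e) NULL)
    if (is.null(fit)) next
    L <- matrix(fit$loadings, p, k)
    ll <- fa_loglik(R, L, fit$uniquenesses, n)
    params <- p * (k + 1) - k * (k - 1) / 2
    bic[k] <- -2 * ll + params * log(n)
  }
  # Velicer MAP: average squared partial correlation after removing the
  # first m principal components, m = 0..p-2
  map <- rep(NA_real_, p - 1)
  off <- upper.tri(R)
  map[1] <- mean(R[off]^2)
  for (m in seq_len(p - 2)) {
    Lm <- ev$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(ev$values[seq_len(m)]), m)
    Rstar <- R - tcrossprod(Lm)
    d <- sqrt(diag(Rstar))
    if (any(d < 1e-10)) { map[m + 1] <- NA_real_; next }
    Pm <- Rstar / tcrossprod(d)
    map[m + 1] <- mean(Pm[off]^2)
  }
  k_map <- which.min(map) - 1L
  list(k_bic = which.min(bic), k_map = k_map, bic = bic, map = map,
       no_common_factor = k_map == 0L)
}

#' Maximum-likelihood exploratory factor analysis with varimax rotation
#'
#' ML extraction ([stats::factanal]), Kaiser-normalized varimax rotation,
#' regression (Thurstone) factor scores, per-factor variance-explained
#' proportions, and interpretation sets at |loading| >= `cut`.
#'
#' @param table data.frame of numeric columns.
#' @param k Number of factors (at most the Ledermann bound).
#' @param cut Interpretation threshold on |loading| (default 0.30).
#' @return List of class `factor_solution`: `loadings` (p x k),
#'   `uniquenesses`, `variance_explained` (proportion of total variance
#'   per factor), `scores` (n x k), `rotation`, `interpretation` (list of
#'   variable-name vectors), `heywood` flag.
#' @export
fit_efa <- function(table, k, cut = 0.30) {
  x <- as.data.frame(table)
  p <- ncol(x)
  if (k > ledermann_bound(p)) stop("k exceeds the Ledermann bound")
  fit <- stats::factanal(~ ., data = x, factors = k,
                         rotation = "varimax", scores = "regression",
                         lower = 0.005, nstart = 4)
  L <- matrix(fit$loadings, p, k,
              dimnames = list(names(x), paste0("F", seq_len(k))))
  heywood <- any(fit$uniquenesses <= 0.005 + 1e-8)
  if (heywood)
    warning("Heywood case: uniqueness at its lower bound for ",
            paste(names(x)[fit$uniquenesses <= 0.005 + 1e-8],
                  collapse = ", "))
  interp <- lapply(seq_len(k), function(j) names(x)[abs(L[, j]) >= cut])
  names(interp) <- colnames(L)
  structure(list(loadings = L, uniquenesses = fit$uniquenesses,
                 variance_explained = colSums(L^2) / p,
                 scores = fit$scores, rotation = "varimax",
                 interpretation = interp, heywood = heywood),
            class = "factor_solution")
}

#' Sampling adequacy: KMO and Bartlett's test of sphericity
#'
#' KMO = sum r^2 / (sum r^2 + sum q^2) over off-diagonal elements, with q
#' the anti-image partial correlations; Bartlett chi-squared =
#' -(n - 1 - (2p + 5)/6) log det R on p(p - 1)/2 degrees of freedom.
#'
#' @param table data.frame of numeric columns (p >= 3, n > p).
#' @return List: `kmo`, `bartlett_chisq`, `bartlett_df`, `bartlett_p`.
#' @export
adequacy <- function(table) {
  x <- as.matrix(as.data.frame(table))
  n <- nrow(x); p <- ncol(x)
  if (p < 3) stop("need p >= 3")
  if (n <= p) stop("need n > p")
  R <- stats::cor(x)
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("singular correlation matrix"))
  d <- 1 / sqrt(diag(Rinv))
  Qp <- -Rinv * tcrossprod(d)          # anti-image partial correlations
  off <- upper.tri(R)
  kmo <- sum(R[off]^2) / (sum(R[off]^2) + sum(Qp[off]^2))
  chisq <- -(n - 1 - (2 * p + 5) / 6) * determinant(R)$modulus[1]
  df <- p * (p - 1) / 2
  list(kmo = kmo, bartlett_chisq = as.numeric(chisq), bartlett_df = df,
       bartlett_p = stats::pchisq(as.numeric(chisq), df,
                                  lower.tail = FALSE))
}

#' Internal-consistency reliability of a factor's items
#'
#' Raw-score Cronbach's alpha = (k/(k-1)) (1 - sum var_i / var_total)
#' with a Feldt F-based 95\% CI, and corrected item-total correlations
#' (each item against the sum of the remaining items). Items may be
#' sign-flipped first (e.g. those with negative loadings) via `flip`.
#'
#' @param items data.frame of the factor's variables (>= 2 columns).
#' @param flip Optional character vector of columns to negate first.
#' @param conf_level CI level (default 0.95).
#' @return List of class `reliability_report`: `alpha`, `alpha_ci`,
#'   `item_total` (named, corrected).
#' @export
reliability <- function(items, flip = NULL, conf_level = 0.95) {
  x <- as.data.frame(items)
  k <- ncol(x); n <- nrow(x)
  if (k < 2) stop("need >= 2 items")
  if (!is.null(flip)) for (v in flip) x[[v]] <- -x[[v]]
  vars <- vapply(x, stats::var, numeric(1))
  if (any(vars == 0)) stop("zero-variance item: ",
                           paste(names(x)[vars == 0], collapse = ", "))
  total <- rowSums(x)
  vt <- stats::var(total)
  alpha <- k / (k - 1) * (1 - sum(vars) / vt)
  a2 <- (1 - conf_level) / 2
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  lo <- 1 - (1 - alpha) * stats::qf(1 - a2, df1, df2)
  hi <- 1 - (1 - alpha) * stats::qf(a2, df1, df2)
  it <- vapply(seq_len(k), function(j)
    stats::cor(x[[j]], rowSums(x[, -j, drop = FALSE])), numeric(1))
  structure(list(alpha = alpha, alpha_ci = c(lo, hi),
                 item_total = stats::setNames(it, names(x))),
            class = "reliability_report")
}

#' Association of factor scores with an outcome
#'
#' Per-factor Spearman correlation with percentile bootstrap CIs.
#'
#' @param scores n x k matrix of factor scores.
#' @param y Outcome aligned with the score rows.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @param conf_level CI level.
#' @return data.frame: factor, r, lower, upper; constant score columns
#'   are reported with `NA` and reason "constant".
#' @export
factor_score_assoc <- function(scores, y, n_boot = 10000, seed = 0,
                               conf_level = 0.95) {
  S <- as.matrix(scores)
  if (is.null(colnames(S))) colnames(S) <- paste0("F", seq_len(ncol(S)))
  stopifnot(nrow(S) == length(y))
  a2 <- (1 - conf_level) / 2
  out <- data.frame(factor = colnames(S),
                    r = NA_real_, lower = NA_real_, upper = NA_real_,
                    note = "")
  boots <- if (n_boot > 0) with_seed(seed, {
    matrix(sample.int(nrow(S), nrow(S) * n_boot, replace = TRUE),
           nrow(S), n_boot)
  })
  for (j in seq_len(ncol(S))) {
    if (stats::sd(S[, j]) == 0) { out$note[j] <- "constant"; next }
    out$r[j] <- stats::cor(S[, j], y, method = "spearman")
    if (n_boot == 0) next
    bs <- vapply(seq_len(n_boot), function(b) {
      i <- boots[, b]
      suppressWarnings(stats::cor(S[i, j], y[i], method = "spearman"))
    }, numeric(1))
    qs <- stats::quantile(bs, c(a2, 1 - a2), na.rm = TRUE, names = FALSE)
    out$lower[j] <- qs[1]; out$upper[j] <- qs[2]
  }
  out
}

#' Ward/silhouette clustering of variables
#'
#' Variables (columns) are clustered by Euclidean distance between their
#' z-scored observation profiles with Ward linkage. Variables listed in
#' `invert` are negated first so that every index increases with
#' abnormality. The number of clusters is chosen in `k_range` by maximum
#' mean silhouette width.
#'
#' @param table data.frame of numeric columns (>= 3).
#' @param invert Character vector of variables to negate.
#' @param k_range Candidate cluster counts (default 2:6).
#' @return List: `tree` (hclust), `k` (chosen), `membership` (named),
#'   `silhouette` (mean width per candidate k).
#' @export
hclust_variables <- function(table, invert = character(0), k_range = 2:6) {
  x <- zscore(table)
  for (v in invert) {
    if (!v %in% names(x)) stop("unknown variable in invert: ", v)
    x[[v]] <- -x[[v]]
  }
  p <- ncol(x)
  if (p < 3) stop("need >= 3 variables")
  k_range <- k_range[k_range < p]
  if (!length(k_range)) stop("fewer variables than the smallest k")
  d <- stats::dist(t(as.matrix(x)))
  tree <- stats::hclust(d, method = "ward.D2")
  sil <- vapply(k_range, function(k) {
    mem <- stats::cutree(tree, k)
    mean(cluster::silhouette(mem, d)[, "sil_width"])
  }, numeric(1))
  k <- k_range[which.max(sil)]
  list(tree = tree, k = k, membership = stats::cutree(tree, k),
       silhouette = stats::setNames(sil, k_range))
}

#' Tucker congruence between loading matrices, after alignment
#'
#' Aligns the columns of `B` to those of `A` by the sign/permutation that
#' maximizes mean absolute Tucker congruence, and returns the per-factor
#' congruences. Used to check factor-recovery against a known structure.
#'
#' @param A,B p x k loading matrices.
#' @return List: `congruence` (per aligned factor), `perm`, `signs`.
#' @export
tucker_congruence <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B), ncol(A) == ncol(B))
  k <- ncol(A)
  cg <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  M <- outer(seq_len(k), seq_len(k),
             Vectorize(function(i, j) cg(A[, i], B[, j])))
  perms <- all_perms(k)
  best <- NULL; best_val <- -Inf
  for (pp in perms) {
    val <- mean(abs(M[cbind(seq_len(k), pp)]))
    if (val > best_val) { best_val <- val; best <- pp }
  }
  signs <- sign(M[cbind(seq_len(k), best)])
  signs[signs == 0] <- 1
  list(congruence = abs(M[cbind(seq_len(k), best)]), perm = best,
       signs = signs)
}

all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (tail in all_perms(k - 1L)) {
      rest <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, rest[tail])
    }
  }
  out
}
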