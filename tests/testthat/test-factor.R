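test_that("BIC and MAP recover a known 3-factor structure", {
  g <- generate_index_table(n = 300, k_true = 3, seed = 31)
  sel <- select_n_factors(g$table)
  expect_equal(sel$k_bic, 3)
  expect_equal(sel$k_map, 3L)
  expect_false(sel$no_common_factor)
})

test_that("MAP flags independent noise as having no common factor", {
  set.seed(32)
  x <- as.data.frame(matrix(rnorm(200 * 6), 200, 6))
  sel <- select_n_factors(x)
  expect_true(sel$k_map <= 1)
  # a parallel second measurement of each variable (same factors, fresh
  # measurement error) keeps the same MAP dimensionality
  g <- generate_index_table(n = 400, k_true = 2, p_per_block = 3, seed = 33)
  sel1 <- select_n_factors(g$table)
  dup <- cbind(g$table,
               setNames(g$table + matrix(rnorm(400 * 6, 0, 0.5), 400, 6),
                        paste0("D", 1:6)))
  sel2 <- select_n_factors(dup)
  expect_equal(sel1$k_map, sel2$k_map)
})

test_that("varimax EFA recovers block loadings and preserves communality", {
  g <- generate_index_table(n = 500, k_true = 3, seed = 34)
  efa <- fit_efa(g$table, 3)
  tc <- tucker_congruence(g$Lambda, efa$loadings)
  expect_true(all(tc$congruence > 0.95))
  expect_true(all(rowSums(efa$loadings^2) <= 1 + 1e-6))
  expect_true(all(efa$variance_explained >= 0))
  # varimax preserves per-variable communality of the unrotated solution
  un <- stats::factanal(~ ., data = g$table, factors = 3, rotation = "none")
  L0 <- matrix(un$loadings, ncol = 3)
  expect_equal(unname(rowSums(efa$loadings^2)), unname(rowSums(L0^2)),
               tolerance = 1e-6)
  # interpretation sets at |loading| >= 0.30 recover the blocks
  blocks <- split(paste0("V", 1:12), rep(1:3, each = 4))
  got <- lapply(efa$interpretation, sort)
  expect_setequal(
    unname(vapply(got, paste, "", collapse = ",")),
    unname(vapply(blocks, function(b) paste(sort(b), collapse = ","), "")))
})

test_that("rotating an already-simple structure is a fixed point", {
  # a perfect block-loading matrix is its own varimax optimum
  g <- generate_index_table(n = 50, k_true = 3, p_per_block = 4,
                            loading = 0.85, seed = 35)
  v <- stats::varimax(g$Lambda, normalize = TRUE)
  expect_equal(abs(det(v$rotmat)), 1, tolerance = 1e-6)
  expect_equal(unclass(v$loadings), g$Lambda, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("adequacy statistics behave on null and structured data", {
  set.seed(36)
  noise <- as.data.frame(matrix(rnorm(50 * 5), 50, 5))
  ad <- adequacy(noise)
  expect_equal(ad$kmo, 0.5, tolerance = 0.2)
  one <- generate_index_table(n = 200, k_true = 1, p_per_block = 6,
                              seed = 37)
  ad1 <- adequacy(one$table)
  expect_gt(ad1$kmo, 0.7)
  expect_lt(ad1$bartlett_p, 1e-6)
  # hand evaluation on a fixed 3x3 correlation matrix
  R <- matrix(c(1, 0.5, 0.3, 0.5, 1, 0.4, 0.3, 0.4, 1), 3)
  n <- 40; p <- 3
  chisq_hand <- -(n - 1 - (2 * p + 5) / 6) * log(det(R))
  # build data with exactly this correlation matrix
  set.seed(38)
  x <- scale(matrix(rnorm(n * p), n, p))
  x <- x %*% solve(chol(cov(x))) %*% chol(R)
  ad2 <- adequacy(as.data.frame(x))
  expect_equal(ad2$bartlett_chisq, chisq_hand, tolerance = 1e-6)
  expect_equal(ad2$bartlett_df, 3)
})

test_that("Cronbach alpha matches closed forms and the covariance oracle", {
  set.seed(39)
  base <- rnorm(100)
  same <- data.frame(a = base, b = base, c = base)
  expect_equal(reliability(same)$alpha, 1)
  # two equal-variance items with correlation 0.5: Spearman-Brown 2r/(1+r)
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  xy <- MASS::mvrnorm(4000, c(0, 0), S, empirical = TRUE)
  r2 <- reliability(as.data.frame(xy))
  expect_equal(r2$alpha, 2 * 0.5 / 1.5, tolerance = 1e-10)
  expect_equal(unname(r2$item_total), c(0.5, 0.5), tolerance = 1e-10)
  expect_true(r2$alpha_ci[1] < r2$alpha && r2$alpha < r2$alpha_ci[2])
  # covariance-matrix oracle on random item sets
  for (s in 1:10) {
    set.seed(400 + s)
    k <- sample(3:6, 1)
    x <- as.data.frame(matrix(rnorm(60 * k), 60, k) +
                         rnorm(60) %o% runif(k, 0.5, 1.5))
    C <- cov(x)
    alpha_o <- (k / (k - 1)) * (1 - sum(diag(C)) / sum(C))
    expect_equal(reliability(x)$alpha, alpha_o, tolerance = 1e-10)
  }
  expect_error(reliability(data.frame(a = rnorm(10), b = rep(1, 10))),
               "zero-variance")
})

test_that("factor-score associations detect exact and null relations", {
  g <- generate_index_table(n = 200, k_true = 2, seed = 41)
  efa <- fit_efa(g$table, 2)
  y <- efa$scores[, 1]
  fa <- factor_score_assoc(efa$scores, y, n_boot = 200, seed = 1)
  expect_equal(fa$r[1], 1)
  set.seed(42)
  y_null <- rnorm(200)
  fa0 <- factor_score_assoc(efa$scores, y_null, n_boot = 200, seed = 1)
  expect_true(all(abs(fa0$r) < 0.2))
})

test_that("the cohort index panel organizes into mean/variance/AC factors", {
  spec <- cohort_spec(n_ngt = 30, n_igt = 60, n_t2dm = 110, seed = 77)
  out <- suppressWarnings(generate_cohort(spec, panel = TRUE))
  feats <- c("FBG", "HbA1c", "PG120", "CGM_Mean", "CGM_Std", "CONGA",
             "LI", "JINDEX", "HBGI", "GRADE", "MODD", "MAGE", "ADRR",
             "MVALUE", "MAG", "AC_Mean", "AC_Var")
  x <- zscore(out$cohort[, feats])
  sel <- select_n_factors(x)
  expect_gte(min(sel$k_bic, sel$k_map), 3)
  k <- min(sel$k_bic, sel$k_map, 5)
  efa <- NULL
  while (is.null(efa) && k >= 3) {
    efa <- tryCatch(suppressWarnings(fit_efa(x, k)),
                    error = function(e) NULL)
    if (is.null(efa)) k <- k - 1
  }
  sets <- efa$interpretation
  together <- function(vars)
    any(vapply(sets, function(s) all(vars %in% s), logical(1)))
  expect_true(together(c("FBG", "HbA1c", "PG120", "CGM_Mean", "HBGI",
                         "GRADE")))
  expect_true(together(c("CGM_Std", "MODD", "MAGE")))
  expect_true(together(c("AC_Mean", "AC_Var")))
  # the AC pair forms its own component: some factor holds them without
  # any conventional marker
  expect_true(any(vapply(sets, function(s)
    all(c("AC_Mean", "AC_Var") %in% s) &&
      !any(c("FBG", "HbA1c", "PG120", "CGM_Mean") %in% s), logical(1))))
})

test_that("variable clustering finds blocks; inversion is an involution", {
  g <- generate_index_table(n = 250, k_true = 3, p_per_block = 4,
                            loading = 0.9, seed = 43)
  hc <- hclust_variables(g$table)
  expect_equal(hc$k, 3)
  truth <- rep(1:3, each = 4)
  # co-membership agreement with the generating blocks
  co_t <- outer(truth, truth, "==")
  co_g <- outer(hc$membership, hc$membership, "==")
  expect_true(all(co_t == co_g))
  # duplicating variables preserves structure
  dup <- cbind(g$table, setNames(g$table, paste0("D", 1:12)))
  hc2 <- hclust_variables(dup)
  expect_equal(hc2$k, 3)
  # double inversion restores the original tree heights
  hc_inv2 <- hclust_variables(g$table, invert = character(0))
  hc_a <- hclust_variables(g$table, invert = "V1")
  hc_b_tab <- g$table; hc_b_tab$V1 <- -hc_b_tab$V1
  hc_b <- hclust_variables(hc_b_tab, invert = "V1")
  expect_equal(hc_b$tree$height, hc_inv2$tree$height)
  expect_false(isTRUE(all.equal(hc_a$tree$height, hc_inv2$tree$height)))
})
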