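make_const <- function(v = 100, n = 600, step = 5)
  glucose_trace("c", (seq_len(n) - 1) * step, rep(v, n), step)

test_that("ACF matches AR(1) theory and rejects degenerate traces", {
  set.seed(7)
  n <- 5000
  g <- 120 + as.numeric(stats::filter(rnorm(n), 0.8, "recursive"))
  tr <- glucose_trace("ar", (seq_len(n) - 1) * 5, g, 5)
  a <- trace_acf(tr, 5)
  expect_equal(a$r[1], 0.8, tolerance = 0.03)
  expect_error(trace_acf(make_const(), 30), "constant")
  expect_error(trace_acf(make_const(120, n = 10), 30), "too short")
})

test_that("AC metrics are affine-invariant and match the geometric-series oracle", {
  set.seed(8)
  g <- 120 + as.numeric(stats::filter(rnorm(20000), 0.9, "recursive"))
  tr <- glucose_trace("ar", (seq_along(g) - 1) * 5, g, 5)
  m <- ac_metrics(trace_acf(tr, 30))
  # oracle: mean/variance of the analytic AR(1) ACF 0.9^k
  th <- 0.9^(1:30)
  expect_equal(m[["AC_Mean"]], mean(th), tolerance = 0.05)
  expect_equal(m[["AC_Var"]], var(th), tolerance = 0.15)

  tr2 <- glucose_trace("aff", tr$times, 2 * tr$values + 30, 5)
  m2 <- ac_metrics(trace_acf(tr2, 30))
  expect_equal(m, m2, tolerance = 1e-12)

  r <- list(lags = 1:5, r = rep(0.4, 5))
  expect_equal(unname(ac_metrics(r)), c(0.4, 0))
})

test_that("CONGA matches direct enumeration and its invariances", {
  expect_equal(conga(make_const(), n_hours = 1), 0)
  g <- rep(c(5, 6), length.out = 11) * 18.016
  tr <- glucose_trace("alt", (0:10) * 60, g, 60)
  expect_equal(conga(tr, n_hours = 1), sd(rep(c(1, -1), 5)), tolerance = 1e-12)
  expect_equal(conga(tr, n_hours = 1), 1.054, tolerance = 1e-3)
  set.seed(1)
  tru <- random_trace(101, days = 1)
  expect_equal(conga(tru), {
    off <- glucose_trace("o", tru$times, tru$values + 50, 5); conga(off)
  }, tolerance = 1e-12)
  expect_error(conga(glucose_trace("s", c(0, 5), c(100, 101), 5)), "lag|span")
})

test_that("LI evaluates the stated hourly formula", {
  expect_equal(li(make_const(n = 48, step = 60)), 0)
  g <- c(5, 7, 5) * 18.016
  tr <- glucose_trace("li", c(0, 60, 120), g, 60)
  expect_equal(li(tr), 4)
  tr2 <- glucose_trace("li2", c(0, 60, 120), 100 + 2 * (g - 100), 60)
  expect_equal(li(tr2), 16)  # doubling excursions quadruples LI
})

test_that("J-index follows the mmol formula and is monotone in spread", {
  g <- c(80, 120)  # mean 100, sd ~28.3
  tr <- glucose_trace("j", c(0, 5), g, 5)
  expect_equal(jindex(tr),
               0.324 * ((mean(g) + sd(g)) / 18.016)^2, tolerance = 1e-12)
  # worked value: mean 100, Std 20
  expect_equal(0.324 * ((100 + 20) / 18.016)^2, 14.37, tolerance = 1e-3)
  tr_wide <- glucose_trace("jw", c(0, 5), c(60, 140), 5)
  expect_gt(jindex(tr_wide), jindex(tr))
})

test_that("risk indices split by the analytic root of the transform", {
  root <- exp(5.381^(1 / 1.084))  # f(g) = 0
  tr <- make_const(root)
  b <- bgri(tr)
  expect_equal(b$HBGI, 0, tolerance = 1e-9)
  expect_equal(b$LBGI, 0, tolerance = 1e-9)
  hi <- make_const(300)
  bh <- bgri(hi)
  expect_equal(bh$LBGI, 0)
  f300 <- 1.509 * (log(300)^1.084 - 5.381)
  expect_equal(bh$HBGI, 10 * f300^2)
  mx <- random_trace(55, days = 1)
  bm <- bgri(mx)
  f <- 1.509 * (log(mx$values)^1.084 - 5.381)
  expect_equal(bm$HBGI + bm$LBGI, mean(10 * f^2))
})

test_that("GRADE caps extreme scores and zeroes at its analytic root", {
  root_mmol <- 10^(10^(-0.16))
  tr <- make_const(root_mmol * 18.016)
  expect_equal(grade(tr), 0, tolerance = 1e-9)
  extreme <- make_const(700)
  raw <- 425 * (log10(log10(700 / 18.016)) + 0.16)^2
  expect_gt(raw, 50)
  expect_equal(grade(extreme), 50)
})

test_that("MODD pairs readings exactly 24 h apart", {
  n <- 288
  day1 <- 120 + 20 * sin((1:n) / 20)
  tr_same <- glucose_trace("m", (seq_len(2 * n) - 1) * 5, c(day1, day1), 5)
  expect_equal(modd(tr_same), 0)
  tr_off <- glucose_trace("m2", (seq_len(2 * n) - 1) * 5,
                          c(day1, day1 + 18.016), 5)
  expect_equal(modd(tr_off), 1.0, tolerance = 1e-12)
  day3 <- day1 + 36.032
  tr3 <- glucose_trace("m3", (seq_len(3 * n) - 1) * 5,
                       c(day1, day1 + 18.016, day3), 5)
  expect_equal(modd(tr3), 1.0, tolerance = 1e-12)  # both adjacent day-pairs
  expect_error(modd(glucose_trace("s", c(0, 5), c(100, 101), 5)), "24-h")
})

test_that("MAGE keeps only excursions exceeding one Std", {
  expect_equal(as.numeric(mage(make_const())), 0)
  tt <- (0:575) * 5
  sine <- 100 + 20 * sin(2 * pi * tt / 360)
  tr <- glucose_trace("sin", tt, sine, 5)
  expect_equal(as.numeric(mage(tr)), 40 / 18.016, tolerance = 0.01)
  # small noise barely moves it
  set.seed(9)
  noisy <- glucose_trace("ns", tt, sine + rnorm(length(tt), 0, 1), 5)
  expect_equal(as.numeric(mage(noisy)), as.numeric(mage(tr)),
               tolerance = 0.05 * as.numeric(mage(tr)) + 0.05)
})

test_that("ADRR averages per-day risk ranges and needs a complete day", {
  root <- exp(5.381^(1 / 1.084))
  tr <- make_const(root, n = 864)
  expect_equal(adrr(tr), 0, tolerance = 1e-9)
  # single spike on day 1 only
  g <- rep(root, 864); g[100] <- 300
  tr2 <- glucose_trace("sp", (0:863) * 5, g, 5)
  f300 <- 1.509 * (log(300)^1.084 - 5.381)
  expect_equal(adrr(tr2), 10 * f300^2 / 3, tolerance = 1e-9)
  expect_error(adrr(glucose_trace("s", (0:10) * 5, rep(100, 11), 5)),
               "complete day")
})

test_that("M-value matches hand evaluation and its range correction", {
  expect_equal(mvalue(make_const(120)), 0)
  expect_equal(mvalue(make_const(240)), abs(10 * log10(2))^3, tolerance = 1e-12)
  expect_equal(mvalue(make_const(240)), 27.27, tolerance = 0.01)
  g <- c(240, 240, 120)
  tr <- glucose_trace("w", c(0, 5, 10), g, 5)
  per <- mean(abs(10 * log10(g / 120))^3)
  expect_equal(mvalue(tr), per + 120 / 20)
})

test_that("MAG is total absolute change per hour, direction-free", {
  tr <- glucose_trace("r", c(0, 300), c(100, 100 + 5 * 18.016), 5)
  expect_equal(mag(tr), 1.0)
  expect_equal(mag(make_const()), 0)
  x <- random_trace(77, days = 1)
  rev_tr <- glucose_trace("rev", x$times, rev(x$values), 5)
  expect_equal(mag(x), mag(rev_tr), tolerance = 1e-12)
})

test_that("summary stats: TIR bounds inclusive, permutation-invariant", {
  s <- summary_stats(make_const())
  expect_equal(unname(s), c(100, 0, 100))
  tr <- glucose_trace("t", (0:3) * 5, c(65, 100, 185, 170), 5)
  expect_equal(summary_stats(tr)[["TIR"]], 50)
  tr_b <- glucose_trace("b", (0:3) * 5, c(70, 180, 100, 150), 5)
  expect_equal(summary_stats(tr_b)[["TIR"]], 100)
  set.seed(3)
  x <- random_trace(5, days = 1)
  sh <- glucose_trace("sh", x$times, sample(x$values), 5)
  expect_equal(summary_stats(x), summary_stats(sh))
})

test_that("index panel applies the sampling-dependent lag convention", {
  tr5 <- generate_trace("p5", 130, 8, 0.9, 50, days = 3, seed = 11)
  p5 <- index_panel(tr5)
  expect_length(p5, 15)
  expect_false(anyNA(p5))
  expect_equal(ac_lag_window(5), 30L)
  expect_equal(ac_lag_window(15), 10L)

  tr15 <- generate_trace("p15", 130, 8, 0.9, 50, days = 3,
                         sampling_interval = 15, seed = 11)
  p15 <- index_panel(tr15)
  expect_false(anyNA(p15))

  # 1-day trace: MODD and ADRR unavailable with reasons, others present
  tr1 <- generate_trace("p1", 130, 8, 0.9, 50, days = 1, seed = 12)
  p1 <- index_panel(tr1)
  expect_true(is.na(p1[["MODD"]]))
  expect_true(is.na(p1[["ADRR"]]))
  expect_false(anyNA(p1[setdiff(names(p1), c("MODD", "ADRR"))]))
  expect_true(all(c("MODD", "ADRR") %in% names(attr(p1, "reasons"))))
})

test_that("non-negative indices stay non-negative on random traces", {
  nn <- c("CGM_Std", "CONGA", "LI", "JINDEX", "HBGI", "GRADE", "MODD",
          "MAGE", "ADRR", "MVALUE", "MAG", "AC_Var")
  for (seed in 1:5) {
    p <- index_panel(random_trace(seed))
    expect_true(all(p[nn] >= 0), info = paste("seed", seed))
    expect_true(p[["AC_Mean"]] >= -1 && p[["AC_Mean"]] <= 1)
    expect_true(p[["TIR"]] >= 0 && p[["TIR"]] <= 100)
  }
})

test_that("15-min subsampled AC_Var tracks the 5-min value across a cohort", {
  acv5 <- acv15 <- numeric(50)
  for (i in 1:50) {
    tr <- generate_trace(paste0("c", i), 130, runif(1, 4, 12),
                         runif(1, 0.75, 0.97), runif(1, 20, 80),
                         days = 3, seed = 1000 + i)
    acv5[i] <- ac_metrics(trace_acf(tr, 30))[["AC_Var"]]
    idx <- seq(1, length(tr$values), by = 3)
    tr15 <- glucose_trace(tr$subject_id, tr$times[idx], tr$values[idx], 15)
    acv15[i] <- ac_metrics(trace_acf(tr15, 10))[["AC_Var"]]
  }
  expect_gt(cor(acv5, acv15, method = "spearman"), 0.9)
})
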