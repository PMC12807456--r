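#' Autocorrelation function of a uniform glucose trace
#'
#' Computes r_k = sum_t (G_t - Gbar)(G_{t+k} - Gbar) / sum_t (G_t - Gbar)^2
#' for k = 1..K (the standard biased-denominator estimator, as returned by
#' [stats::acf]).
#'
#' @param trace A uniform [glucose_trace] (see [resample_uniform]).
#' @param K Maximum lag, in sampling steps.
#' @return List with `lags` (1..K) and `r` (autocorrelations).
#' @export
trace_acf <- function(trace, K) {
  g <- trace$values
  if (anyNA(g)) stop("trace has missing values; resample first")
  if (length(g) <= K + 1) stop("trace too short for lag ", K)
  if (stats::var(g) == 0) stop("autocorrelation undefined: constant trace")
  r <- as.numeric(stats::acf(g, lag.max = K, plot = FALSE,
                             demean = TRUE)$acf)[-1]
  list(lags = seq_len(K), r = r)
}

#' Mean and variance of the autocorrelation function
#'
#' AC_Mean and AC_Var summarize the shape of the ACF over a fixed lag
#' window: lags 1-30 at 5-min sampling and 1-10 at 15-min sampling, both
#' spanning 150 min. AC_Var uses the unbiased sample variance.
#'
#' @param acf A list as returned by [trace_acf].
#' @return Named numeric vector `c(AC_Mean, AC_Var)`.
#' @export
ac_metrics <- function(acf) {
  r <- acf$r
  c(AC_Mean = mean(r), AC_Var = stats::var(r))
}

#' Lag window for the AC metrics given a sampling interval
#'
#' 150 min window: 30 lags at 5-min sampling, 10 lags at 15-min.
#' @param sampling_interval Minutes between readings.
#' @return Integer number of lags.
#' @export
ac_lag_window <- function(sampling_interval) {
  K <- as.integer(round(150 / sampling_interval))
  if (K < 1) stop("sampling interval too long for a 150-min lag window")
  K
}

#' Mean, standard deviation and time in range of a trace
#'
#' @param trace A [glucose_trace].
#' @return Named vector: `CGM_Mean` (mg/dL), `CGM_Std` (mg/dL, unbiased),
#'   `TIR` (% of readings in [70, 180] mg/dL, bounds inclusive).
#' @export
summary_stats <- function(trace) {
  g <- trace$values[!is.na(trace$values)]
  if (length(g) < 2) stop("need >= 2 readings")
  c(CGM_Mean = mean(g), CGM_Std = stats::sd(g),
    TIR = 100 * mean(g >= 70 & g <= 180))
}

#' Continuous overlapping net glycemic action (CONGA)
#'
#' Sample standard deviation of differences between readings `n_hours`
#' apart, in mmol/L.
#'
#' @param trace A uniform [glucose_trace].
#' @param n_hours Lag in hours (default 1).
#' @return CONGA in mmol/L.
#' @export
conga <- function(trace, n_hours = 1) {
  step <- trace$sampling_interval
  lag <- round(n_hours * 60 / step)
  if (abs(lag * step - n_hours * 60) > 1e-9)
    stop("n_hours is not a multiple of the sampling interval")
  g <- trace$values
  if (length(g) <= lag) stop("trace span does not exceed the CONGA lag")
  d <- mgdl_to_mmol(g[-seq_len(lag)] - g[seq_len(length(g) - lag)])
  if (length(d) < 2) stop("too few differences for CONGA")
  stats::sd(d)
}

#' Lability index (LI)
#'
#' Mean squared hourly glucose change: the trace is resampled to a 60-min
#' grid and LI = (1/(N-1)) * sum (Delta G_mmol)^2 / Delta t_hours over
#' consecutive hourly pairs, in (mmol/L)^2 / h.
#'
#' @param trace A [glucose_trace].
#' @return LI.
#' @export
li <- function(trace) {
  hourly <- resample_uniform(trace, step = 60, max_gap = 120)
  g <- mgdl_to_mmol(hourly$values)
  if (length(g) < 2) stop("fewer than 2 hourly points")
  dg <- diff(g)
  dt_h <- diff(hourly$times) / 60
  mean(dg^2 / dt_h)
}

#' J-index
#'
#' J = 0.324 * (mean + Std)^2 with glucose in mmol/L; a combined measure
#' of level and spread.
#'
#' @param trace A [glucose_trace].
#' @return J-index (unitless).
#' @export
jindex <- function(trace) {
  s <- summary_stats(trace)
  m <- mgdl_to_mmol(s[["CGM_Mean"]])
  sd_ <- mgdl_to_mmol(s[["CGM_Std"]])
  0.324 * (m + sd_)^2
}

#' Blood glucose risk indices (LBGI / HBGI)
#'
#' Symmetrizing risk transform f(g) = 1.509 * ((ln g)^1.084 - 5.381) with
#' g in mg/dL; per-reading low/high risks rl = 10 f^2 (f < 0),
#' rh = 10 f^2 (f > 0). LBGI and HBGI are the means of rl and rh.
#'
#' @param trace A [glucose_trace].
#' @return List with `LBGI`, `HBGI`, and per-reading `rl`, `rh`.
#' @export
bgri <- function(trace) {
  g <- trace$values[!is.na(trace$values)]
  if (any(g <= 1)) stop("glucose <= 1 mg/dL outside log domain")
  f <- 1.509 * (log(g)^1.084 - 5.381)
  rl <- ifelse(f < 0, 10 * f^2, 0)
  rh <- ifelse(f > 0, 10 * f^2, 0)
  list(LBGI = mean(rl), HBGI = mean(rh), rl = rl, rh = rh)
}

#' Glycemic risk assessment diabetes equation (GRADE)
#'
#' Per-reading score 425 * (log10(log10(g_mmol)) + 0.16)^2, capped at 50;
#' GRADE is the mean score.
#'
#' @param trace A [glucose_trace].
#' @return GRADE (unitless).
#' @export
grade <- function(trace) {
  gm <- mgdl_to_mmol(trace$values[!is.na(trace$values)])
  if (any(gm <= 1)) stop("glucose <= 1 mmol/L outside nested-log domain")
  sc <- 425 * (log10(log10(gm)) + 0.16)^2
  mean(pmin(sc, 50))
}

#' Mean of daily differences (MODD)
#'
#' Mean absolute difference between readings exactly 24 h apart
#' (tolerance: half the sampling interval), in mmol/L.
#'
#' @param trace A [glucose_trace].
#' @return MODD in mmol/L.
#' @export
modd <- function(trace) {
  keep <- !is.na(trace$values)
  tt <- trace$times[keep]; g <- trace$values[keep]
  tol <- trace$sampling_interval / 2
  diffs <- numeric(0)
  j <- 1L
  for (i in seq_along(tt)) {
    target <- tt[i] + 1440
    while (j <= length(tt) && tt[j] < target - tol) j <- j + 1L
    if (j > length(tt)) break
    if (abs(tt[j] - target) <= tol)
      diffs <- c(diffs, abs(g[j] - g[i]))
  }
  if (!length(diffs)) stop("no valid 24-h pairs for MODD")
  mean(mgdl_to_mmol(diffs))
}

#' Mean amplitude of glycemic excursions (MAGE)
#'
#' Service-style algorithm: (1) Std of the whole trace; (2) alternating
#' local extrema by three-point comparison after merging plateaus;
#' (3) iterative deletion of extrema whose adjacent amplitude is below
#' 1 Std, preserving alternation; (4) mean absolute amplitude of the
#' remaining consecutive-extremum excursions, direction-agnostic, in
#' mmol/L. When no excursion exceeds 1 Std, MAGE is 0 with attribute
#' `flag = "no qualifying excursion"`.
#'
#' @param trace A [glucose_trace].
#' @return MAGE in mmol/L.
#' @export
mage <- function(trace) {
  g <- trace$values[!is.na(trace$values)]
  if (length(g) < 3 || stats::sd(g) == 0) {
    out <- 0
    attr(out, "flag") <- "no qualifying excursion"
    return(out)
  }
  s <- stats::sd(g)
  e <- extrema_alternating(g)
  # prune smallest adjacent amplitudes below 1 Std
  repeat {
    if (length(e) < 2) break
    amp <- abs(diff(e))
    if (all(amp >= s)) break
    i <- which.min(amp)
    if (i == 1) {
      e <- e[-1]
    } else if (i == length(e) - 1) {
      e <- e[-length(e)]
    } else {
      e <- e[-c(i, i + 1)]
    }
    e <- merge_alternation(e)
  }
  if (length(e) < 2) {
    out <- 0
    attr(out, "flag") <- "no qualifying excursion"
    return(out)
  }
  mean(mgdl_to_mmol(abs(diff(e))))
}

# alternating local extrema by three-point comparison (series endpoints
# are not turning points), plateaus merged to a single point
extrema_alternating <- function(g) {
  v <- g[c(TRUE, diff(g) != 0)]   # collapse plateaus
  if (length(v) < 3) return(numeric(0))
  d <- sign(diff(v))
  turn <- c(FALSE, d[-1] != d[-length(d)], FALSE)
  merge_alternation(v[turn])
}

# enforce strict high/low alternation by keeping the more extreme of any
# same-direction neighbours
merge_alternation <- function(e) {
  repeat {
    if (length(e) < 3) return(e)
    d <- sign(diff(e))
    bad <- which(d[-1] == d[-length(d)])
    if (!length(bad)) return(e)
    e <- e[-(bad[1] + 1)]
  }
}

#' Average daily risk range (ADRR)
#'
#' Per complete day d, LR_d and HR_d are the maxima of the per-reading
#' low/high risks from [bgri]; ADRR is the mean over days of LR_d + HR_d.
#' A day counts as complete when it holds at least 20 h of readings.
#' Days are calendar days when the trace has a `start_time`, otherwise
#' consecutive 1440-min blocks from the first reading.
#'
#' @param trace A [glucose_trace].
#' @return ADRR (unitless).
#' @export
adrr <- function(trace) {
  keep <- !is.na(trace$values)
  tt <- trace$times[keep]
  risks <- bgri(trace)
  day <- day_index(trace, tt)
  per_day <- tapply(seq_along(tt), day, function(idx) {
    coverage <- length(idx) * trace$sampling_interval
    if (coverage < 20 * 60) return(NA_real_)
    max(risks$rl[idx]) + max(risks$rh[idx])
  })
  per_day <- per_day[!is.na(per_day)]
  if (!length(per_day)) stop("no complete day (>= 20 h of readings)")
  mean(per_day)
}

day_index <- function(trace, tt) {
  if (!is.null(trace$start_time)) {
    as.integer(as.Date(trace$start_time + tt * 60, tz = "UTC"))
  } else {
    floor(tt / 1440)
  }
}

#' Schlichtkrull M-value
#'
#' M = mean over readings of |10 * log10(g / 120)|^3 (g in mg/dL) plus the
#' range correction W/20, W = max - min in mg/dL.
#'
#' @param trace A [glucose_trace].
#' @return M-value (unitless).
#' @export
mvalue <- function(trace) {
  g <- trace$values[!is.na(trace$values)]
  if (any(g <= 0)) stop("non-positive glucose")
  if (length(g) < 2) stop("need >= 2 readings")
  mean(abs(10 * log10(g / 120))^3) + (max(g) - min(g)) / 20
}

#' Mean absolute glucose change (MAG)
#'
#' Sum of absolute consecutive glucose changes (mmol/L) divided by the
#' total elapsed time in hours.
#'
#' @param trace A [glucose_trace].
#' @return MAG in mmol/L/h.
#' @export
mag <- function(trace) {
  keep <- !is.na(trace$values)
  tt <- trace$times[keep]; g <- trace$values[keep]
  if (length(g) < 2) stop("need >= 2 readings")
  hours <- (tt[length(tt)] - tt[1]) / 60
  if (hours <= 0) stop("zero elapsed time")
  sum(abs(diff(mgdl_to_mmol(g)))) / hours
}

PANEL_NAMES <- c("CGM_Mean", "CGM_Std", "CONGA", "LI", "JINDEX", "HBGI",
                 "GRADE", "MODD", "MAGE", "ADRR", "MVALUE", "MAG",
                 "AC_Mean", "AC_Var", "TIR")

#' Compute the full CGM index panel for one trace
#'
#' The 14 CGM-derived indices (12 established glycemic-variability
#' indices plus AC_Mean and AC_Var) and time in range. The AC lag window
#' follows the sampling interval (30 lags at 5 min, 10 at 15 min). The
#' trace is resampled to its nominal grid first. Indices whose
#' preconditions fail (e.g. MODD on a 1-day trace) are reported `NA` with
#' the reason in attribute `"reasons"`.
#'
#' @param trace A [glucose_trace].
#' @param max_gap Interpolation limit in minutes passed to
#'   [resample_uniform].
#' @return Named numeric vector over `PANEL_NAMES` with attribute
#'   `"reasons"` (named character vector for failed indices).
#' @export
index_panel <- function(trace, max_gap = 30) {
  u <- resample_uniform(trace, max_gap = max_gap)
  out <- stats::setNames(rep(NA_real_, length(PANEL_NAMES)), PANEL_NAMES)
  reasons <- character(0)
  grab <- function(name, expr) {
    v <- tryCatch(expr, error = function(e) {
      reasons[[name]] <<- conditionMessage(e)
      NA_real_
    })
    out[[name]] <<- as.numeric(v)[1]
  }
  grab("CGM_Mean", summary_stats(u)[["CGM_Mean"]])
  grab("CGM_Std", summary_stats(u)[["CGM_Std"]])
  grab("TIR", summary_stats(u)[["TIR"]])
  grab("CONGA", conga(u))
  grab("LI", li(u))
  grab("JINDEX", jindex(u))
  grab("HBGI", bgri(u)$HBGI)
  grab("GRADE", grade(u))
  grab("MODD", modd(u))
  grab("MAGE", mage(u))
  span_days <- (diff(range(u$times)) + u$sampling_interval) / 1440
  grab("ADRR", if (span_days < 2) stop("trace covers < 2 days")
       else adrr(u))
  grab("MVALUE", mvalue(u))
  grab("MAG", mag(u))
  K <- ac_lag_window(u$sampling_interval)
  grab("AC_Mean", ac_metrics(trace_acf(u, K))[["AC_Mean"]])
  grab("AC_Var", ac_metrics(trace_acf(u, K))[["AC_Var"]])
  attr(out, "reasons") <- reasons
  out
}

#' Index panels for a list of traces
#'
#' @param traces List of [glucose_trace] objects.
#' @param ... Passed to [index_panel].
#' @return data.frame, one row per subject, columns `subject_id` then the
#'   panel names.
#' @export
index_panel_table <- function(traces, ...) {
  rows <- lapply(traces, function(tr) {
    p <- index_panel(tr, ...)
    cbind(data.frame(subject_id = tr$subject_id),
          as.data.frame(as.list(p)))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
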