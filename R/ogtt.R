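#' An OGTT record
#'
#' Plasma glucose (mg/dL) and immunoreactive insulin (IRI, uU/mL) sampled
#' at the canonical 75-g OGTT minutes 0/30/60/90/120. Missing samples are
#' `NA`; each index checks the samples it needs.
#'
#' @param glucose,insulin Named numeric vectors; names among
#'   `"0","30","60","90","120"`.
#' @return An object of class `ogtt_record`.
#' @export
ogtt_record <- function(glucose, insulin) {
  canon <- c("0", "30", "60", "90", "120")
  g <- stats::setNames(rep(NA_real_, 5), canon)
  i <- g
  if (!all(names(glucose) %in% canon) || !all(names(insulin) %in% canon))
    stop("times restricted to OGTT minutes 0/30/60/90/120")
  g[names(glucose)] <- as.numeric(glucose)
  i[names(insulin)] <- as.numeric(insulin)
  if (any(!is.na(g) & g <= 0) || any(!is.na(i) & i < 0))
    stop("non-positive glucose or negative insulin")
  structure(list(glucose = g, insulin = i), class = "ogtt_record")
}

#' Read OGTT records from CSV
#'
#' Expects columns `subject_id`, `t_min` (in 0/30/60/90/120), `glucose`
#' (mg/dL) and `insulin` (uU/mL); returns one [ogtt_record] per subject.
#'
#' @param path CSV file path.
#' @return Named list of [ogtt_record] objects.
#' @export
read_ogtt_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "t_min", "glucose", "insulin")
  if (!all(need %in% names(df)))
    stop("CSV must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$subject_id), function(sub) {
    tm <- as.character(sub$t_min)
    ogtt_record(stats::setNames(sub$glucose, tm),
                stats::setNames(sub$insulin, tm))
  })
  out
}

#' Insulinogenic index
#'
#' Early-phase insulin secretion: the ratio of the 0-to-30-min increment
#' of IRI to that of plasma glucose.
#'
#' @param rec An [ogtt_record].
#' @return I.I. = (IRI30 - IRI0) / (PG30 - PG0). A negative glucose
#'   increment (paradoxical response) returns the value with a warning.
#' @export
insulinogenic_index <- function(rec) {
  g <- rec$glucose; i <- rec$insulin
  if (anyNA(c(g[c("0", "30")], i[c("0", "30")])))
    stop("0- and 30-min glucose and insulin required")
  dpg <- g[["30"]] - g[["0"]]
  if (dpg == 0) stop("undefined increment ratio: PG30 = PG0")
  if (dpg < 0) warning("negative glucose increment: paradoxical response")
  (i[["30"]] - i[["0"]]) / dpg
}

#' Composite (Matsuda) insulin-sensitivity index
#'
#' 10000 / sqrt(FPG x FIRI x meanG x meanI) with the means taken over the
#' five OGTT samples, glucose in mg/dL and insulin in uU/mL.
#'
#' @param rec An [ogtt_record] with all five samples of both analytes.
#' @return Composite index.
#' @export
composite_index <- function(rec) {
  g <- rec$glucose; i <- rec$insulin
  if (anyNA(g) || anyNA(i)) stop("all five OGTT samples required")
  fac <- g[["0"]] * i[["0"]] * mean(g) * mean(i)
  if (fac <= 0) stop("non-positive factor in composite index")
  10000 / sqrt(fac)
}

#' Oral disposition index
#'
#' Product of the composite index and the ratio of the insulin to glucose
#' areas under the curve from 0 to 120 min. AUCs are trapezoidal over the
#' nodes 0/30/60/120 min; the 90-min sample is excluded by definition.
#'
#' @param rec An [ogtt_record].
#' @return Oral DI.
#' @export
oral_di <- function(rec) {
  nodes <- c("0", "30", "60", "120")
  g <- rec$glucose[nodes]; i <- rec$insulin[nodes]
  if (anyNA(g) || anyNA(i)) stop("0/30/60/120-min samples required")
  t <- c(0, 30, 60, 120)
  auc <- function(y) sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
  composite_index(rec) * auc(i) / auc(g)
}

#' Three-point OGTT glucose-curve characterization
#'
#' The 0/30/120-min glucose samples are linearly interpolated onto a
#' 1-min grid over [0, 120] and summarized by the time-average (trapezoid
#' mean of the curve), the sample Std of the grid values, and AC_Var of
#' the grid values at lags 1-20 (the data cover only 2 h). A flat curve
#' has Std 0 and undefined AC metrics, reported as `NA`.
#'
#' @param g0,g30,g120 Glucose (mg/dL) at 0, 30 and 120 min.
#' @param step Interpolation grid step in minutes (default 1).
#' @return Named vector `c(mean, sd, AC_Var)`.
#' @export
ogtt_pattern_metrics <- function(g0, g30, g120, step = 1) {
  stopifnot(g0 > 0, g30 > 0, g120 > 0)
  grid <- seq(0, 120, by = step)
  y <- stats::approx(c(0, 30, 120), c(g0, g30, g120), xout = grid)$y
  n <- length(y)
  tmean <- (sum(y) - (y[1] + y[n]) / 2) / (n - 1)   # trapezoid / T
  if (stats::var(y) == 0)
    return(c(mean = tmean, sd = 0, AC_Var = NA_real_))
  tr <- glucose_trace("ogtt", grid, y, sampling_interval = step)
  K <- as.integer(round(20 / step))
  c(mean = tmean, sd = stats::sd(y),
    AC_Var = ac_metrics(trace_acf(tr, K))[["AC_Var"]])
}
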