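#' Construct a glucose trace
#'
#' A `glucose_trace` holds one subject's CGM time series: times in minutes
#' from the subject's first reading, glucose in mg/dL, and the nominal
#' sampling interval of the device (5 or 15 min for the common sensors).
#'
#' @param subject_id Character scalar identifying the subject.
#' @param times Numeric vector, minutes since the first reading, strictly
#'   increasing.
#' @param values Numeric vector of glucose readings in mg/dL, positive,
#'   same length as `times`. `NA` marks a reading removed by QC or a gap
#'   introduced by resampling.
#' @param sampling_interval Nominal minutes between readings (> 0).
#' @param start_time Optional `POSIXct` timestamp of the first reading.
#'   When present, day-based indices (ADRR, MODD) use calendar days;
#'   otherwise consecutive 1440-min blocks from the first reading.
#'
#' @return An object of class `glucose_trace`.
#' @export
glucose_trace <- function(subject_id, times, values, sampling_interval,
                          start_time = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have the same length")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(values[!is.na(values)] <= 0))
    stop("glucose values must be positive (mg/dL)")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0)
    stop("sampling_interval must be > 0")
  structure(
    list(subject_id = subject_id, times = times, values = values,
         sampling_interval = as.numeric(sampling_interval),
         start_time = start_time),
    class = "glucose_trace")
}

#' @method print glucose_trace
#' @export
print.glucose_trace <- function(x, ...) {
  span <- diff(range(x$times))
  cat(sprintf("<glucose_trace> subject %s: %d readings over %.1f h (%g-min sampling)\n",
              x$subject_id, length(x$values), span / 60, x$sampling_interval))
  invisible(x)
}

#' @export
length.glucose_trace <- function(x) length(x$values)

#' Convert glucose units
#'
#' Multiplicative conversion between mg/dL and mmol/L using the molar-mass
#' convention 1 mmol/L = 18.016 mg/dL.
#'
#' @param values Numeric vector of glucose values.
#' @param from,to Unit labels, each one of `"mg/dL"` or `"mmol/L"`.
#' @return Converted numeric vector.
#' @export
to_unit <- function(values, from, to) {
  units <- c("mg/dL", "mmol/L")
  if (!(from %in% units) || !(to %in% units))
    stop("unknown unit label; use 'mg/dL' or 'mmol/L'")
  if (from == to) return(values)
  if (from == "mg/dL") values / MGDL_PER_MMOLL else values * MGDL_PER_MMOLL
}

MGDL_PER_MMOLL <- 18.016

mgdl_to_mmol <- function(g) g / MGDL_PER_MMOLL

#' Read CGM traces from CSV
#'
#' Expects columns `subject_id`, `glucose`, and either `timestamp`
#' (ISO 8601) or `t_min` (minutes). One trace is returned per subject,
#' with times rebased to minutes since that subject's first reading.
#' Subjects with non-monotone timestamps are rejected; non-positive
#' readings are dropped. Both are recorded in the attached QC report.
#'
#' @param path CSV file path.
#' @param unit Input glucose unit; `"mmol/L"` values are converted to the
#'   internal mg/dL.
#' @param sampling_interval Nominal sampling interval in minutes; when
#'   `NULL` it is inferred as the median time difference per subject.
#' @return A list of [glucose_trace] objects with attribute `"qc"`, a list
#'   of rejected subjects/readings and reasons (see [write_qc_report]).
#' @export
read_cgm_csv <- function(path, unit = "mg/dL", sampling_interval = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "glucose") %in% names(df)))
    stop("CSV must have columns subject_id and glucose")
  has_ts <- "timestamp" %in% names(df)
  if (!has_ts && !("t_min" %in% names(df)))
    stop("CSV must have a timestamp or t_min column")
  qc <- list(rejected_subjects = list(), rejected_readings = list())
  traces <- list()
  for (sid in unique(df$subject_id)) {
    sub <- df[df$subject_id == sid, , drop = FALSE]
    if (has_ts) {
      tt <- as.POSIXct(sub$timestamp, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
      t_min <- as.numeric(difftime(tt, tt[1], units = "mins"))
      start_time <- tt[1]
    } else {
      t_min <- as.numeric(sub$t_min)
      t_min <- t_min - t_min[1]
      start_time <- NULL
    }
    g <- to_unit(as.numeric(sub$glucose), from = unit, to = "mg/dL")
    bad <- which(!is.finite(g) | g <= 0)
    if (length(bad)) {
      qc$rejected_readings[[as.character(sid)]] <-
        list(rows = bad, reason = "non-positive or missing glucose")
      t_min <- t_min[-bad]; g <- g[-bad]
    }
    if (length(t_min) < 2 || any(diff(t_min) <= 0)) {
      reason <- if (length(t_min) < 2) "fewer than 2 usable readings"
                else "non-monotone or duplicated timestamps"
      qc$rejected_subjects[[as.character(sid)]] <- reason
      next
    }
    si <- if (is.null(sampling_interval)) stats::median(diff(t_min))
          else sampling_interval
    traces[[as.character(sid)]] <-
      glucose_trace(as.character(sid), t_min, g, si, start_time)
  }
  attr(traces, "qc") <- qc
  traces
}

#' Write CGM traces to CSV
#'
#' Emits `subject_id`, `t_min`, `glucose` (mg/dL); the inverse of
#' [read_cgm_csv] for traces without calendar timestamps.
#'
#' @param traces List of [glucose_trace] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(tr) {
    keep <- !is.na(tr$values)
    data.frame(subject_id = tr$subject_id, t_min = tr$times[keep],
               glucose = tr$values[keep])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write the QC report of a CSV import as JSON
#'
#' @param traces Result of [read_cgm_csv].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(traces, path) {
  jsonlite::write_json(attr(traces, "qc"), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Resample a trace onto a uniform grid
#'
#' Linear interpolation onto an even grid of `step` minutes. Gaps longer
#' than `max_gap` are not interpolated across; when gaps split the grid,
#' the longest fully covered contiguous block is returned. Most index
#' definitions (autocorrelation, CONGA, MODD, ...) assume an even grid,
#' so this is the canonical preprocessing step.
#'
#' @param trace A [glucose_trace].
#' @param step Grid step in minutes; defaults to the trace's nominal
#'   sampling interval.
#' @param max_gap Longest gap (minutes) interpolated across (default 30).
#' @return A uniform [glucose_trace] covering the longest usable block.
#' @export
resample_uniform <- function(trace, step = trace$sampling_interval,
                             max_gap = 30) {
  stopifnot(inherits(trace, "glucose_trace"))
  keep <- !is.na(trace$values)
  tt <- trace$times[keep]; gg <- trace$values[keep]
  if (length(tt) < 2) stop("trace unusable: fewer than 2 readings")
  grid <- seq(tt[1], tt[length(tt)], by = step)
  val <- stats::approx(tt, gg, xout = grid, method = "linear")$y
  # invalidate grid points that fall inside an observation gap > max_gap
  gaps <- which(diff(tt) > max_gap)
  for (i in gaps) {
    inside <- grid > tt[i] & grid < tt[i + 1]
    val[inside] <- NA_real_
  }
  ok <- !is.na(val)
  if (!any(ok)) stop("trace unusable: no grid point covered")
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blocks <- which(r$values)
  lens <- r$lengths[blocks]
  if (!length(blocks) || max(lens) < 2)
    stop("trace unusable: no contiguous block of >= 2 grid points")
  b <- blocks[which.max(lens)]
  idx <- starts[b]:ends[b]
  st <- trace$start_time
  if (!is.null(st)) st <- st + grid[idx[1]] * 60
  glucose_trace(trace$subject_id, grid[idx] - grid[idx[1]], val[idx],
                sampling_interval = step, start_time = st)
}
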