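# Core data containers for the pipeline. All timestamps are timezone-naive
# local time, represented internally as POSIXct in UTC so that arithmetic is
# never perturbed by DST rules.

.TZ <- "UTC"
.TIME_FMT <- "%Y-%m-%d %H:%M:%OS"

parse_time <- function(x) {
  out <- as.POSIXct(x, tz = .TZ, format = "%Y-%m-%d %H:%M:%OS")
  if (anyNA(out)) stop("unparseable timestamp: ", x[which(is.na(out))[1]])
  out
}

format_time <- function(t, digits = 3) {
  # %OS truncates; add half a unit so the printed value is rounded
  format(t + 0.5 * 10^-digits,
         format = paste0("%Y-%m-%d %H:%M:%OS", digits), tz = .TZ)
}

#' Raw triaxial acceleration stream
#'
#' A uniformly sampled triaxial acceleration recording from a hip-worn
#' accelerometer, in g units. Gaps are not representable: the stream claims
#' a start time and a constant rate, and the sample matrix covers the span
#' contiguously.
#'
#' @param start_time POSIXct (or parseable string), first sample instant.
#' @param rate_hz Sampling rate in samples/second (30 for device exports,
#'   10 after downsampling).
#' @param data Numeric matrix with one row per sample and columns x, y, z.
#' @param device_id Free-text device identifier.
#' @return An object of class `raw_stream`.
#' @export
raw_stream <- function(start_time, rate_hz, data, device_id = "") {
  if (is.character(start_time)) start_time <- parse_time(start_time)
  stopifnot(length(rate_hz) == 1, rate_hz > 0)
  data <- as.matrix(data)
  if (ncol(data) != 3) stop("raw stream requires exactly 3 axes")
  if (!all(is.finite(data))) stop("non-finite acceleration values")
  if (any(abs(data) >= 16)) stop("acceleration magnitude outside +/-16 g")
  colnames(data) <- c("x", "y", "z")
  structure(list(start_time = start_time, rate_hz = rate_hz,
                 data = data, device_id = device_id),
            class = "raw_stream")
}

#' @export
print.raw_stream <- function(x, ...) {
  cat(sprintf("<raw_stream> %d samples @ %g Hz from %s (%.1f min)\n",
              nrow(x$data), x$rate_hz, format_time(x$start_time),
              nrow(x$data) / x$rate_hz / 60))
  invisible(x)
}

#' 60-s epoch counts stream
#'
#' ActiGraph-style activity counts at fixed 60-s epochs. Only the vertical
#' axis is required; additional axes may be carried along.
#'
#' @param start_time First epoch start.
#' @param counts Non-negative integer vector, vertical-axis counts per epoch.
#' @param epoch_s Epoch length in seconds; must be 60.
#' @param extra Optional data.frame of additional count axes.
#' @return An object of class `counts_stream`.
#' @export
counts_stream <- function(start_time, counts, epoch_s = 60, extra = NULL) {
  if (is.character(start_time)) start_time <- parse_time(start_time)
  if (epoch_s != 60) stop("counts stream requires 60-s epochs, got ", epoch_s)
  counts <- as.numeric(counts)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  structure(list(start_time = start_time, epoch_s = 60,
                 counts = as.integer(counts), extra = extra),
            class = "counts_stream")
}

#' @export
print.counts_stream <- function(x, ...) {
  cat(sprintf("<counts_stream> %d one-minute epochs from %s\n",
              length(x$counts), format_time(x$start_time)))
  invisible(x)
}

#' Posture event list
#'
#' Ordered, contiguous posture intervals (sitting/lying vs upright) as
#' produced by a thigh-worn inclinometer's events export or by the
#' simulator. Device-grade lists obey the 10-s registration minimum.
#'
#' @param start_time POSIXct vector of interval starts.
#' @param duration_s Positive durations in seconds.
#' @param code Character vector, each "SIT" or "UPRIGHT".
#' @param provenance One of "device", "simulator", "simulator-exact".
#'   The 10-s minimum-duration invariant is enforced for "device" and
#'   "simulator" (registered) lists, not for exact simulator truth.
#' @param tol Contiguity tolerance in seconds.
#' @return An object of class `posture_events` (a data.frame).
#' @export
posture_events <- function(start_time, duration_s, code,
                           provenance = c("device", "simulator",
                                          "simulator-exact"),
                           tol = 0.01) {
  provenance <- match.arg(provenance)
  if (is.character(start_time)) start_time <- parse_time(start_time)
  n <- length(start_time)
  stopifnot(length(duration_s) == n, length(code) == n)
  if (!all(code %in% c("SIT", "UPRIGHT"))) stop("unknown posture code")
  if (any(duration_s <= 0)) stop("durations must be positive")
  if (n > 1) {
    expected <- start_time[-n] + duration_s[-n]
    gap <- as.numeric(start_time[-1]) - as.numeric(expected)
    if (any(gap > tol)) stop("non-contiguous events: gap of ",
                             signif(max(gap), 4), " s")
    if (any(gap < -tol)) stop("overlapping events")
  }
  if (provenance != "simulator-exact" && n > 1 &&
      any(duration_s[-1] < 10 - tol)) {
    stop("registered events must last >= 10 s")
  }
  out <- data.frame(start_time = start_time, duration_s = duration_s,
                    code = code, stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("posture_events", "data.frame")
  out
}

#' @export
print.posture_events <- function(x, ...) {
  cat(sprintf("<posture_events> %d events, %.1f min total (%s)\n",
              nrow(x), sum(x$duration_s) / 60, attr(x, "provenance")))
  invisible(x)
}

events_end <- function(events) {
  n <- nrow(events)
  events$start_time[n] + events$duration_s[n]
}

#' Fixed-width epoch label series
#'
#' Contiguous 10-s or 60-s epochs each labeled SIT, NONSIT or UNWORN, with
#' optional sitting probabilities (for model output). For model-derived
#' series the strict decision rule prob > 0.5 <=> SIT is enforced.
#'
#' @param start_time First epoch start.
#' @param epoch_s Epoch width in seconds, 10 or 60.
#' @param labels Character vector of SIT/NONSIT/UNWORN.
#' @param probs Optional sitting probabilities aligned with labels.
#' @param source One of "activpal", "model", "cpm".
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(start_time, epoch_s, labels, probs = NULL,
                         source = c("activpal", "model", "cpm")) {
  source <- match.arg(source)
  if (is.character(start_time)) start_time <- parse_time(start_time)
  if (!epoch_s %in% c(10, 60)) stop("epoch_s must be 10 or 60")
  if (!all(labels %in% c("SIT", "NONSIT", "UNWORN"))) stop("unknown label")
  if (!is.null(probs)) {
    if (length(probs) != length(labels)) stop("probs/labels length mismatch")
    if (any(probs < 0 | probs > 1, na.rm = TRUE)) stop("probs outside [0,1]")
    if (source == "model") {
      lab <- ifelse(probs > 0.5, "SIT", "NONSIT")
      chk <- labels != "UNWORN" & !is.na(probs)
      if (any(lab[chk] != labels[chk]))
        stop("labels inconsistent with prob > 0.5 rule")
    }
  }
  structure(list(start_time = start_time, epoch_s = epoch_s,
                 labels = labels, probs = probs, source = source),
            class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  tab <- table(factor(x$labels, c("SIT", "NONSIT", "UNWORN")))
  cat(sprintf("<epoch_series> %d x %d-s epochs from %s [%s] SIT=%d NONSIT=%d UNWORN=%d\n",
              length(x$labels), x$epoch_s, format_time(x$start_time),
              x$source, tab["SIT"], tab["NONSIT"], tab["UNWORN"]))
  invisible(x)
}

epoch_times <- function(series) {
  series$start_time + (seq_along(series$labels) - 1) * series$epoch_s
}

#' Wear-time mask
#'
#' Ordered, disjoint time intervals classified as worn.
#'
#' @param start,end POSIXct vectors (or parseable strings) of equal length.
#' @return An object of class `wear_mask` (a data.frame).
#' @export
wear_mask <- function(start, end) {
  if (is.character(start)) start <- parse_time(start)
  if (is.character(end)) end <- parse_time(end)
  stopifnot(length(start) == length(end))
  if (length(start)) {
    if (any(end <= start)) stop("mask intervals need start < end")
    o <- order(start)
    start <- start[o]; end <- end[o]
    if (length(start) > 1 && any(start[-1] < end[-length(end)]))
      stop("mask intervals overlap")
  }
  out <- data.frame(start = start, end = end)
  class(out) <- c("wear_mask", "data.frame")
  out
}

# Intersection of two masks (interval arithmetic).
intersect_masks <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(wear_mask(as.POSIXct(character(), tz = .TZ),
                                             as.POSIXct(character(), tz = .TZ)))
  starts <- c(); ends <- c()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start[i], b$start)
    e <- pmin(a$end[i], b$end)
    keep <- s < e
    starts <- c(starts, as.numeric(s[keep]))
    ends <- c(ends, as.numeric(e[keep]))
  }
  wear_mask(as.POSIXct(starts, origin = "1970-01-01", tz = .TZ),
            as.POSIXct(ends, origin = "1970-01-01", tz = .TZ))
}

# TRUE for each (start, start+width) epoch fully inside some mask interval.
epochs_in_mask <- function(times, width_s, mask) {
  if (!nrow(mask)) return(rep(FALSE, length(times)))
  t0 <- as.numeric(times); t1 <- t0 + width_s
  res <- rep(FALSE, length(times))
  for (i in seq_len(nrow(mask))) {
    res <- res | (t0 >= as.numeric(mask$start[i]) &
                  t1 <= as.numeric(mask$end[i]))
  }
  res
}
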