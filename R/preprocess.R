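# Conversion of raw streams and posture events into aligned 10-s epoch
# sequences: downsampling, windowing, ground-truth aggregation, wear masking.

#' Downsample a 30 Hz stream to 10 Hz by block means
#'
#' Each output sample is the mean of 3 consecutive input samples per axis.
#' Block means are deterministic and robust to sampling phase, unlike naive
#' decimation. A trailing remainder of 1-2 samples is dropped with a message.
#'
#' @param stream A [raw_stream()] at 30 Hz.
#' @return A [raw_stream()] at 10 Hz with the same start time.
#' @export
downsample_to_10hz <- function(stream) {
  if (stream$rate_hz != 30) stop("expected a 30 Hz stream, got ",
                                 stream$rate_hz, " Hz")
  n <- nrow(stream$data)
  keep <- (n %/% 3) * 3
  if (keep < n) message("dropping ", n - keep, " trailing sample(s) not ",
                        "filling a 3-sample block")
  if (keep == 0) stop("stream shorter than one 10 Hz sample")
  x <- stream$data[seq_len(keep), , drop = FALSE]
  # column-major fold: rows of each axis reshaped to 3 x (keep/3)
  out <- vapply(1:3, function(j) colMeans(matrix(x[, j], nrow = 3)),
                numeric(keep / 3))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)  # single 10 Hz sample
  raw_stream(stream$start_time, 10, out, device_id = stream$device_id)
}

#' Expand posture events to per-second labels
#'
#' One label per whole second over `span`; each second takes the label of
#' the event covering its start instant, so a second whose start coincides
#' with an event change takes the new event's label.
#'
#' @param events A [posture_events()] list.
#' @param span Length-2 POSIXct (start, end); must lie within the events'
#'   coverage. Defaults to the full coverage.
#' @return Character vector of SIT/UPRIGHT labels, one per second.
#' @export
events_to_second_labels <- function(events, span = NULL) {
  if (!nrow(events)) stop("empty event list")
  cov_start <- events$start_time[1]
  cov_end <- events_end(events)
  if (is.null(span)) span <- c(cov_start, cov_end)
  if (is.character(span)) span <- parse_time(span)
  s0 <- as.numeric(span[1]); s1 <- as.numeric(span[2])
  if (s0 < as.numeric(cov_start) - 1e-9 || s1 > as.numeric(cov_end) + 1e-9)
    stop("span outside event coverage")
  n_sec <- floor(s1 - s0 + 1e-9)
  if (n_sec <= 0) return(character(0))
  sec_starts <- s0 + seq_len(n_sec) - 1
  idx <- findInterval(sec_starts + 1e-9, as.numeric(events$start_time))
  idx[idx < 1] <- 1L
  events$code[idx]
}

#' Aggregate per-second labels to fixed epochs
#'
#' An epoch is labeled SIT when at least `sit_min_s` of its seconds are
#' sitting (>= 6 of 10 by default), otherwise NONSIT. A trailing partial
#' epoch is dropped with a message.
#'
#' @param second_labels Character vector of SIT/UPRIGHT (or NONSIT) seconds.
#' @param start_time Timestamp of the first second.
#' @param epoch_s Epoch width in seconds (default 10).
#' @param sit_min_s Minimum sitting seconds for a SIT epoch (default 6).
#' @param source Series provenance tag.
#' @return An [epoch_series()].
#' @export
aggregate_to_epochs <- function(second_labels, start_time, epoch_s = 10,
                                sit_min_s = 6, source = "activpal") {
  n <- length(second_labels)
  keep <- (n %/% epoch_s) * epoch_s
  if (keep < n) message("dropping ", n - keep,
                        " trailing second(s) not filling an epoch")
  if (keep == 0) stop("fewer seconds than one epoch")
  sit <- matrix(second_labels[seq_len(keep)] == "SIT", nrow = epoch_s)
  labels <- ifelse(colSums(sit) >= sit_min_s, "SIT", "NONSIT")
  epoch_series(start_time, epoch_s, labels, source = source)
}

#' Cut a 10 Hz stream into non-overlapping 10-s windows
#'
#' Returns the model's input substrate: an array of 100 x 3 windows, one per
#' 10-s epoch. A trailing partial window is dropped.
#'
#' @param stream A [raw_stream()] at 10 Hz.
#' @return An object of class `epoch_windows`: list with `array`
#'   (100 x 3 x k), `start_time`, `epoch_s = 10`.
#' @export
window_raw <- function(stream) {
  if (stream$rate_hz != 10) stop("expected a 10 Hz stream")
  n <- nrow(stream$data)
  k <- n %/% 100
  if (k == 0) stop("stream shorter than one 10-s window")
  if (k * 100 < n) message("dropping trailing partial window (",
                           n - k * 100, " samples)")
  a <- array(NA_real_, c(100, 3, k))
  for (j in 1:3) a[, j, ] <- stream$data[seq_len(k * 100), j]
  structure(list(array = a, start_time = stream$start_time, epoch_s = 10),
            class = "epoch_windows")
}

#' @export
print.epoch_windows <- function(x, ...) {
  cat(sprintf("<epoch_windows> %d windows of 10 s from %s\n",
              dim(x$array)[3], format_time(x$start_time)))
  invisible(x)
}

#' Align predicted and truth epoch series under wear masks
#'
#' Keeps only epochs whose full span lies inside the intersection of all
#' masks and inside both series' coverage, pairing labels by timestamp.
#'
#' @param pred,truth [epoch_series()] objects with equal `epoch_s`.
#' @param masks A list of [wear_mask()] objects (possibly empty).
#' @return List with `times`, `pred`, `truth` (index-aligned vectors).
#' @export
align_and_mask <- function(pred, truth, masks = list()) {
  if (pred$epoch_s != truth$epoch_s) stop("epoch widths differ")
  w <- pred$epoch_s
  tp <- as.numeric(epoch_times(pred))
  tt <- as.numeric(epoch_times(truth))
  common <- intersect(tp, tt)
  if (!length(common)) stop("no temporal overlap between series")
  common <- sort(common)
  keep <- rep(TRUE, length(common))
  ct <- as.POSIXct(common, origin = "1970-01-01", tz = .TZ)
  for (m in masks) keep <- keep & epochs_in_mask(ct, w, m)
  ip <- match(common, tp); it <- match(common, tt)
  list(times = ct[keep],
       pred = pred$labels[ip][keep],
       truth = truth$labels[it][keep],
       pred_probs = if (!is.null(pred$probs)) pred$probs[ip][keep] else NULL,
       epoch_s = w)
}
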