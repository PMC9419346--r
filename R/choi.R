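# Choi non-wear detection from 60-s vertical-axis counts.

#' Choi algorithm parameters
#'
#' The standard 2011 parameterization: a non-wear period is a run of at
#' least `min_window_min` zero-count minutes; a spike of up to
#' `spike_tolerance_min` consecutive nonzero minutes is absorbed into the
#' run only when flanked on both sides by at least `flank_window_min`
#' consecutive zero-count minutes (the "streamframe"). Absorbed spike
#' minutes count toward the run length.
#'
#' @param min_window_min Minimum non-wear window, minutes (default 90).
#' @param spike_tolerance_min Maximum absorbable spike, minutes (default 2).
#' @param flank_window_min Required zero flank around a spike, minutes
#'   (default 30).
#' @return An object of class `choi_params`.
#' @export
choi_params <- function(min_window_min = 90, spike_tolerance_min = 2,
                        flank_window_min = 30) {
  stopifnot(min_window_min > 0, spike_tolerance_min > 0,
            flank_window_min > 0,
            spike_tolerance_min < min_window_min)
  structure(list(min_window_min = min_window_min,
                 spike_tolerance_min = spike_tolerance_min,
                 flank_window_min = flank_window_min),
            class = "choi_params")
}

#' Detect accelerometer non-wear from 60-s counts (Choi)
#'
#' Classifies each minute as wear or non-wear by the Choi rule (see
#' [choi_params()]) and returns the wear complement as a [wear_mask()].
#'
#' @param counts A [counts_stream()].
#' @param params A [choi_params()] object.
#' @param use_magnitude Reserved for a vector-magnitude variant; the default
#'   (and the only validated channel) is the vertical axis.
#' @return A [wear_mask()] of wear intervals. The per-minute classification
#'   is attached as attribute `nonwear` (logical vector).
#' @export
detect_nonwear <- function(counts, params = choi_params(),
                           use_magnitude = FALSE) {
  c_vec <- counts$counts
  if (use_magnitude && !is.null(counts$extra)) {
    ex <- as.matrix(counts$extra[vapply(counts$extra, is.numeric, TRUE)])
    c_vec <- round(sqrt(rowSums(cbind(c_vec, ex)^2)))
  }
  n <- length(c_vec)
  nw <- choi_nonwear_minutes(c_vec, params)
  t0 <- counts$start_time
  if (!n) return(wear_mask(as.POSIXct(character(), tz = .TZ),
                           as.POSIXct(character(), tz = .TZ)))
  r <- rle(!nw)  # wear runs
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  wi <- which(r$values)
  mask <- wear_mask(t0 + (starts[wi] - 1) * 60, t0 + ends[wi] * 60)
  attr(mask, "nonwear") <- nw
  mask
}

# Per-minute Choi classification. Returns logical vector, TRUE = non-wear.
choi_nonwear_minutes <- function(c_vec, params) {
  n <- length(c_vec)
  if (!n) return(logical(0))
  zero <- c_vec == 0
  # absorbable spikes: maximal nonzero runs of length <= tolerance with
  # >= flank_window_min consecutive zeros immediately on both sides
  ok <- zero
  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  fl <- params$flank_window_min
  for (i in seq_along(r$values)) {
    if (r$values[i]) next                      # a zero run
    len <- r$lengths[i]
    if (len > params$spike_tolerance_min) next
    left_ok <- i > 1 && r$lengths[i - 1] >= fl
    right_ok <- i < length(r$values) && r$lengths[i + 1] >= fl
    if (left_ok && right_ok) ok[starts[i]:ends[i]] <- TRUE
  }
  nw <- logical(n)
  r2 <- rle(ok)
  e2 <- cumsum(r2$lengths)
  s2 <- e2 - r2$lengths + 1
  long <- which(r2$values & r2$lengths >= params$min_window_min)
  for (i in long) nw[s2[i]:e2[i]] <- TRUE
  # an absorbed spike at the edge of a qualifying run is only non-wear if
  # the run containing it (including the spike) still qualifies -- handled
  # above because spikes are interior by construction (zero flanks).
  nw
}
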