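# Sedentary bout segmentation and participant-season pattern variables.

#' Classify 60-s epochs as sedentary by the counts cut-point
#'
#' A minute is sedentary when its vertical-axis counts fall below the
#' cut-point (strictly: counts < 100 by default, so a minute at exactly
#' 100 cpm is NONSIT). The legacy convention classifies low-count minutes
#' as sedentary; see the methods vignette for the boundary discussion.
#'
#' @param counts A [counts_stream()].
#' @param threshold Cut-point in counts per minute (default 100).
#' @return An [epoch_series()] with `epoch_s = 60`, `source = "cpm"`.
#' @export
classify_cpm <- function(counts, threshold = 100) {
  labels <- ifelse(counts$counts < threshold, "SIT", "NONSIT")
  epoch_series(counts$start_time, 60, labels, source = "cpm")
}

#' Segment an epoch series into sedentary bouts
#'
#' Bouts are maximal runs of SIT epochs; the shortest possible bout is one
#' epoch. UNWORN epochs terminate a bout.
#'
#' @param series An [epoch_series()].
#' @return A data.frame of class `bout_list` with columns `start_time` and
#'   `duration_min`.
#' @export
segment_bouts <- function(series) {
  lab <- series$labels
  times <- epoch_times(series)
  r <- rle(lab == "SIT")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sit <- which(r$values)
  out <- data.frame(
    start_time = times[starts[sit]],
    duration_min = r$lengths[sit] * series$epoch_s / 60)
  class(out) <- c("bout_list", "data.frame")
  out
}

#' Count breaks in sedentary time (sit-to-stand transitions)
#'
#' A break is a SIT epoch immediately followed by a NONSIT epoch, with no
#' interruption tolerance. A bout ending at the series end or at an UNWORN
#' epoch is not a break.
#'
#' @param series An [epoch_series()].
#' @return Integer count.
#' @export
count_breaks <- function(series) {
  lab <- series$labels
  n <- length(lab)
  if (n < 2) return(0L)
  sum(lab[-n] == "SIT" & lab[-1] == "NONSIT")
}

#' Usual (duration-weighted median) bout duration
#'
#' The bout duration at which half of total sitting time is accumulated:
#' sort durations ascending and return the smallest duration whose
#' cumulative share of total sitting time reaches 50%.
#'
#' @param bouts A bout list from [segment_bouts()], or a numeric vector of
#'   durations in minutes.
#' @return Minutes.
#' @export
usual_bout_duration <- function(bouts) {
  d <- if (is.data.frame(bouts)) bouts$duration_min else as.numeric(bouts)
  if (!length(d)) stop("no bouts")
  d <- sort(d)
  cum <- cumsum(d)
  d[which(cum >= 0.5 * cum[length(d)])[1]]
}

#' Power-law exponent of the bout-duration distribution
#'
#' Continuous maximum-likelihood estimate
#' \eqn{\hat\alpha = 1 + n / \sum_i \ln(x_i / x_{min})}. Lower values
#' indicate proportionally more sitting time accumulated in long bouts.
#' `xmin` is the method's minimum observable bout (10 s for
#' inclinometer/model labels, 1 min for the counts cut-point).
#'
#' @param bouts Bout list or numeric durations in minutes.
#' @param xmin Minimum bout duration in minutes (default 10/60).
#' @return Unitless exponent (> 1).
#' @export
bout_alpha <- function(bouts, xmin = 10 / 60) {
  d <- if (is.data.frame(bouts)) bouts$duration_min else as.numeric(bouts)
  if (length(d) < 2) stop("alpha needs at least 2 bouts")
  if (any(d < xmin - 1e-12)) stop("durations below xmin")
  s <- sum(log(d / xmin))
  if (s <= 0) stop("alpha undefined: all durations equal xmin")
  1 + length(d) / s
}

#' Sample from a continuous power law
#'
#' Inverse-CDF sampling of the Pareto-type density
#' \eqn{p(x) \propto x^{-\alpha}} on \eqn{[x_{min}, x_{max}]}.
#'
#' @param n Number of draws.
#' @param alpha Exponent (> 1).
#' @param xmin Lower bound.
#' @param xmax Upper truncation bound (default `Inf` for the untruncated
#'   distribution).
#' @return Numeric vector of draws.
#' @export
rpowerlaw <- function(n, alpha, xmin, xmax = Inf) {
  stopifnot(alpha > 1, xmin > 0, xmax > xmin)
  u <- stats::runif(n)
  a1 <- 1 - alpha
  if (is.finite(xmax)) {
    # F(x) = (x^a1 - xmin^a1) / (xmax^a1 - xmin^a1)
    (u * (xmax^a1 - xmin^a1) + xmin^a1)^(1 / a1)
  } else {
    xmin * (1 - u)^(1 / a1)
  }
}

#' Summarize one calendar day of epoch labels
#'
#' @param series An [epoch_series()] restricted to one date.
#' @param mask A [wear_mask()] giving simultaneous wear for the day; wear
#'   minutes are the mask's total within the series' span.
#' @return A one-row data.frame of class `day_stats`: `date`, `wear_min`,
#'   `sed_min`, `breaks_n`, `min_in_bouts_ge30`, plus list-column `bouts`
#'   holding the day's bout durations (minutes) for pooling.
#' @export
summarize_day <- function(series, mask = NULL) {
  lab <- series$labels
  w <- series$epoch_s
  sed_min <- sum(lab == "SIT") * w / 60
  bouts <- segment_bouts(series)
  span0 <- as.numeric(series$start_time)
  span1 <- span0 + length(lab) * w
  wear_min <- if (is.null(mask)) {
    sum(lab != "UNWORN") * w / 60
  } else {
    s <- pmax(as.numeric(mask$start), span0)
    e <- pmin(as.numeric(mask$end), span1)
    sum(pmax(0, e - s)) / 60
  }
  out <- data.frame(
    date = as.Date(series$start_time, tz = .TZ),
    wear_min = wear_min,
    sed_min = sed_min,
    breaks_n = count_breaks(series),
    min_in_bouts_ge30 = sum(bouts$duration_min[bouts$duration_min >= 30]))
  out$bouts <- list(bouts$duration_min)
  class(out) <- c("day_stats", "data.frame")
  out
}

#' Summarize a participant-season from daily statistics
#'
#' Valid days require at least `valid_day_min` minutes of simultaneous
#' monitor wear; participant-seasons with fewer than `min_valid_days` valid
#' days are excluded. Per-day variables are averaged across valid days;
#' mean/usual bout duration and alpha are computed on the bout durations
#' pooled across valid days.
#'
#' @param day_stats A data.frame of [summarize_day()] rows.
#' @param participant,season Identifiers carried into the summary row.
#' @param valid_day_min Minimum daily wear minutes (default 480 = 8 h).
#' @param min_valid_days Minimum number of valid days (default 3).
#' @param xmin Minimum bout duration for the alpha fit, minutes.
#' @param source Label series provenance carried into the summary.
#' @return A one-row data.frame (class `participant_summary`), or `NULL`
#'   when the participant-season is excluded.
#' @export
summarize_participant_season <- function(day_stats, participant = "P1",
                                         season = 1L, valid_day_min = 480,
                                         min_valid_days = 3,
                                         xmin = 10 / 60,
                                         source = "activpal") {
  valid <- day_stats[day_stats$wear_min >= valid_day_min, , drop = FALSE]
  if (nrow(valid) < min_valid_days) return(NULL)
  pooled <- unlist(valid$bouts)
  alpha <- tryCatch(bout_alpha(pooled, xmin = xmin),
                    error = function(e) NA_real_)
  out <- data.frame(
    participant = participant,
    season = season,
    valid_days = nrow(valid),
    total_sed_min_day = mean(valid$sed_min),
    breaks_per_day = mean(valid$breaks_n),
    min_day_bouts_ge30 = mean(valid$min_in_bouts_ge30),
    mean_bout_min = mean(pooled),
    usual_bout_min = usual_bout_duration(pooled),
    alpha = alpha,
    source = source,
    stringsAsFactors = FALSE)
  class(out) <- c("participant_summary", "data.frame")
  out
}
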