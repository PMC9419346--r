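# Synthetic paired-device data: ground-truth posture events from an
# alternating renewal process, the inclinometer's 10-s registration rule,
# 30 Hz hip acceleration with posture-dependent gravity tilt, and 60-s
# counts integrated from the dynamic acceleration. Stands in for concurrent
# two-monitor recordings of free-living children so every pipeline stage is
# testable with known truth.

#' Simulation configuration
#'
#' Defaults emulate the descriptive scale reported for primary-school
#' children wearing a thigh inclinometer: ~62% of a ~12-h wear day spent
#' sitting, accumulated in power-law bouts with exponent ~1.40 (minimum
#' registrable bout 10 s). Upright bouts are lognormal; their mean is
#' derived from `p_sit_time` unless `upright_lognorm_mu` is given.
#'
#' @param n_participants Number of simulated participants.
#' @param days_per_participant Days per participant (default 5).
#' @param day_wear_hours Simultaneous wear per day, hours (default 12).
#' @param sit_alpha_true Power-law exponent of sitting bout durations
#'   (default 1.40).
#' @param sit_xmin_s Minimum sitting bout, seconds (default 10).
#' @param sit_xmax_s Upper truncation of sitting bouts, seconds (default
#'   3600; the exponent 1.40 has infinite mean untruncated).
#' @param upright_lognorm_mu,upright_lognorm_sigma Lognormal parameters of
#'   upright bout durations in seconds; `mu = NULL` derives it from
#'   `p_sit_time`.
#' @param p_sit_time Target long-run sitting fraction (default 0.62).
#' @param difficulty "easy" (classes separable by per-window dynamic
#'   variance alone) or "hard" (smaller tilt separation, intermittent
#'   movement, boundary jitter).
#' @param seed Master seed; per-(participant, day) streams are derived.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 2, days_per_participant = 5,
                       day_wear_hours = 12, sit_alpha_true = 1.40,
                       sit_xmin_s = 10, sit_xmax_s = 3600,
                       upright_lognorm_mu = NULL,
                       upright_lognorm_sigma = 0.8,
                       p_sit_time = 0.62,
                       difficulty = c("easy", "hard"), seed = 1L) {
  difficulty <- match.arg(difficulty)
  stopifnot(sit_alpha_true > 1, sit_xmin_s > 0, sit_xmax_s > sit_xmin_s,
            p_sit_time > 0, p_sit_time < 1, day_wear_hours >= 0,
            upright_lognorm_sigma > 0)
  e_sit <- .powerlaw_mean(sit_alpha_true, sit_xmin_s, sit_xmax_s)
  if (is.null(upright_lognorm_mu)) {
    e_up <- e_sit * (1 - p_sit_time) / p_sit_time
    upright_lognorm_mu <- log(e_up) - upright_lognorm_sigma^2 / 2
  }
  structure(list(n_participants = as.integer(n_participants),
                 days_per_participant = as.integer(days_per_participant),
                 day_wear_hours = day_wear_hours,
                 sit_alpha_true = sit_alpha_true,
                 sit_xmin_s = sit_xmin_s, sit_xmax_s = sit_xmax_s,
                 upright_lognorm_mu = upright_lognorm_mu,
                 upright_lognorm_sigma = upright_lognorm_sigma,
                 p_sit_time = p_sit_time, difficulty = difficulty,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# mean of the truncated continuous power law on [xmin, xmax]
.powerlaw_mean <- function(alpha, xmin, xmax) {
  a1 <- 1 - alpha
  if (abs(alpha - 2) < 1e-12) {
    (log(xmax) - log(xmin)) * a1 / (xmax^a1 - xmin^a1)
  } else {
    ((xmax^(2 - alpha) - xmin^(2 - alpha)) / (2 - alpha)) *
      a1 / (xmax^a1 - xmin^a1)
  }
}

# deterministic stream seed per (master seed, participant, day)
.derive_seed <- function(seed, participant, day) {
  as.integer((as.numeric(seed) * 100003 + participant * 10007 + day * 101) %%
               2147483629)
}

.sim_day_start <- function(day) {
  parse_time("2015-06-01 08:00:00") + (day - 1) * 86400
}

#' Simulate exact posture events for one participant-day
#'
#' Alternating SIT/UPRIGHT renewal process: sitting durations follow a
#' truncated continuous power law (inverse-CDF sampling), upright durations
#' a lognormal. The sequence is truncated to exactly `day_wear_hours`.
#' Deterministic given (seed, participant, day).
#'
#' @param cfg A [sim_config()].
#' @param participant Participant index (integer).
#' @param day Day index (integer).
#' @return A [posture_events()] list with provenance "simulator-exact".
#' @export
simulate_posture_events <- function(cfg, participant = 1L, day = 1L) {
  total <- cfg$day_wear_hours * 3600
  start <- .sim_day_start(day)
  if (total <= 0)
    return(posture_events(start[0], numeric(0), character(0),
                          provenance = "simulator-exact"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.derive_seed(cfg$seed, participant, day))
  sit_first <- stats::runif(1) < cfg$p_sit_time
  dur <- numeric(0); code <- character(0)
  acc <- 0
  sitting <- sit_first
  while (acc < total) {
    d <- if (sitting) {
      rpowerlaw(1, cfg$sit_alpha_true, cfg$sit_xmin_s, cfg$sit_xmax_s)
    } else {
      stats::rlnorm(1, cfg$upright_lognorm_mu, cfg$upright_lognorm_sigma)
    }
    # durations quantized to 1 ms: the events-file dialect carries
    # millisecond precision, and quantizing at the source keeps on-disk and
    # in-memory truth identical
    d <- round(min(d, total - acc), 3)
    if (d <= 0) {  # sub-millisecond day remainder: absorb into the last event
      if (length(dur)) dur[length(dur)] <- dur[length(dur)] + (total - acc)
      break
    }
    dur <- c(dur, d)
    code <- c(code, if (sitting) "SIT" else "UPRIGHT")
    acc <- acc + d
    sitting <- !sitting
  }
  starts <- start + c(0, cumsum(dur[-length(dur)]))
  posture_events(starts, dur, code, provenance = "simulator-exact")
}

#' Apply the inclinometer's minimum posture registration rule
#'
#' A new posture lasting less than `min_posture_s` fails to register: the
#' event is merged into the preceding registered posture. Adjacent
#' same-label events are then merged. The first event is kept even when
#' short (nothing precedes it). Idempotent.
#'
#' @param events A contiguous [posture_events()] list.
#' @param min_posture_s Registration threshold, seconds (default 10).
#' @return A [posture_events()] list with provenance "simulator".
#' @export
register_activpal <- function(events, min_posture_s = 10) {
  n <- nrow(events)
  if (!n) return(posture_events(events$start_time, numeric(0), character(0),
                                provenance = "simulator"))
  starts <- numeric(0); dur <- numeric(0); code <- character(0)
  for (i in seq_len(n)) {
    d <- events$duration_s[i]; cd <- events$code[i]
    if (!length(dur)) {
      starts <- as.numeric(events$start_time[i]); dur <- d; code <- cd
    } else if (d < min_posture_s || cd == code[length(code)]) {
      dur[length(dur)] <- dur[length(dur)] + d
    } else {
      starts <- c(starts, as.numeric(events$start_time[i]))
      dur <- c(dur, d); code <- c(code, cd)
    }
  }
  # merging may have produced new same-label adjacencies; resolved above
  # because a merged short event keeps the previous label.
  posture_events(as.POSIXct(starts, origin = "1970-01-01", tz = .TZ),
                 dur, code, provenance = "simulator")
}

.sim_signal_params <- function(difficulty) {
  if (difficulty == "easy") {
    list(theta_sit = 35 * pi / 180, theta_up = 5 * pi / 180,
         walk_amp_min = 0.20, walk_amp_max = 0.35, walk_p = 1,
         fidget_p = 0.02, fidget_amp = 0.08, jitter_s = 0)
  } else {
    list(theta_sit = 15 * pi / 180, theta_up = 8 * pi / 180,
         walk_amp_min = 0.08, walk_amp_max = 0.30, walk_p = 0.6,
         fidget_p = 0.08, fidget_amp = 0.15, jitter_s = 2)
  }
}

#' Synthesize a 30 Hz hip acceleration stream from posture events
#'
#' Piecewise signal: a gravity vector tilted by a sitting vs upright hip
#' angle, Gaussian sensor noise (SD 0.01 g), ~2 Hz stepping oscillation
#' during upright time and sparse 1-s fidget bursts during sitting. At
#' difficulty "easy" every upright second carries movement, so 10-s windows
#' are linearly separable from sitting by dynamic variance alone; "hard"
#' shrinks the tilt separation, makes movement intermittent and jitters the
#' signal change points around the label boundaries.
#'
#' @param events A contiguous [posture_events()] list.
#' @param cfg A [sim_config()] (difficulty and seed source).
#' @param seed Stream seed (default derived from `cfg$seed`).
#' @return A [raw_stream()] at 30 Hz.
#' @export
synthesize_raw <- function(events, cfg, seed = cfg$seed) {
  sp <- .sim_signal_params(cfg$difficulty)
  total <- sum(events$duration_s)
  n <- round(total * 30)
  if (n < 1) stop("events span shorter than one sample")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% 2147483629))
  tgrid <- (seq_len(n) - 1) / 30
  bounds <- cumsum(events$duration_s)
  if (sp$jitter_s > 0 && length(bounds) > 1) {
    jit <- stats::runif(length(bounds) - 1, -sp$jitter_s, sp$jitter_s)
    bounds[-length(bounds)] <- pmax(0, bounds[-length(bounds)] + jit)
    bounds <- cummax(bounds)
  }
  ev_idx <- findInterval(tgrid, c(0, bounds[-length(bounds)]))
  sit <- events$code[ev_idx] == "SIT"
  theta <- ifelse(sit, sp$theta_sit, sp$theta_up)

  # per-second movement envelope
  n_sec <- ceiling(total)
  sec_of <- floor(tgrid) + 1
  sec_sit <- sit[pmin((0:(n_sec - 1)) * 30 + 1, n)]
  walk_on <- stats::runif(n_sec) < sp$walk_p
  walk_amp <- stats::runif(n_sec, sp$walk_amp_min, sp$walk_amp_max)
  fid_on <- stats::runif(n_sec) < sp$fidget_p
  fid_amp <- stats::runif(n_sec, 0.3, 1) * sp$fidget_amp
  amp_sec <- ifelse(sec_sit, ifelse(fid_on, fid_amp, 0),
                    ifelse(walk_on, walk_amp, 0))
  amp <- amp_sec[sec_of]
  phase <- stats::runif(1, 0, 2 * pi)
  osc <- sin(2 * pi * 2 * tgrid + phase)
  x <- sin(theta) + 0.5 * amp * osc + stats::rnorm(n, 0, 0.01)
  y <- 0.3 * amp * sin(2 * pi * 2 * tgrid + phase + 1) +
    stats::rnorm(n, 0, 0.01)
  z <- cos(theta) + amp * osc + stats::rnorm(n, 0, 0.01)
  raw_stream(events$start_time[1], 30, cbind(x, y, z),
             device_id = "SIM00000001")
}

#' Integrate a 30 Hz stream into 60-s vertical-axis counts
#'
#' Counts emulate the hip monitor's per-minute activity metric: the dynamic
#' acceleration (deviation of the vector magnitude from 1 g) is deadbanded
#' so that still periods yield exactly zero-count minutes (making non-wear
#' detection exercisable), then summed per minute and scaled to counts.
#' Deterministic: no randomness beyond the stream itself.
#'
#' @param stream A [raw_stream()] at 30 Hz.
#' @param deadband Ignored dynamic amplitude in g (default 0.05).
#' @param scale Counts per g-sample of supra-deadband dynamics (default 3).
#' @return A [counts_stream()].
#' @export
synthesize_counts <- function(stream, deadband = 0.05, scale = 3) {
  n <- nrow(stream$data)
  spm <- stream$rate_hz * 60
  n_min <- n %/% spm
  if (n_min < 1) stop("stream shorter than one minute")
  vm <- sqrt(rowSums(stream$data^2))
  dyn <- pmax(0, abs(vm - 1) - deadband)
  per_min <- colSums(matrix(dyn[seq_len(n_min * spm)], nrow = spm))
  counts_stream(stream$start_time, as.integer(round(per_min * scale)))
}

#' Generate an on-disk study bundle with truth manifest
#'
#' Writes, per participant-day, an ActiGraph-style raw CSV, a 60-s counts
#' CSV and an activPAL-style events CSV (the registered events), plus
#' `events_exact_*.csv` ground truth and a JSON manifest holding the
#' configuration, file index, per-day statistics and the true
#' participant-season summaries (computed from the registered events through
#' the label-aggregation and bout machinery). Byte-identical on re-run.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created).
#' @param write_raw Write the (large) 30 Hz CSVs (default TRUE).
#' @param valid_day_min,min_valid_days Valid-day rules recorded in and used
#'   for the manifest summaries.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
make_study <- function(cfg, out_dir, write_raw = TRUE,
                       valid_day_min = 480, min_valid_days = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(); summaries <- list(); day_rows <- list()
  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("P%02d", p)
    stats_p <- NULL
    for (d in seq_len(cfg$days_per_participant)) {
      exact <- simulate_posture_events(cfg, p, d)
      reg <- register_activpal(exact)
      seed_pd <- .derive_seed(cfg$seed, p, d) + 7L
      raw <- synthesize_raw(reg, cfg, seed = seed_pd)
      counts <- synthesize_counts(raw)
      base <- sprintf("%s_day%d", pid, d)
      # manifest holds paths relative to the bundle directory so that two
      # bundles with the same configuration are byte-identical
      f <- list(events = paste0(base, "_events.csv"),
                events_exact = paste0(base, "_events_exact.csv"),
                counts = paste0(base, "_counts.csv"))
      write_activpal_events(reg, file.path(out_dir, f$events))
      write_activpal_events(exact, file.path(out_dir, f$events_exact))
      write_actigraph_counts(counts, file.path(out_dir, f$counts))
      if (write_raw) {
        f$raw <- paste0(base, "_raw.csv")
        write_actigraph_raw(raw, file.path(out_dir, f$raw))
      }
      files[[base]] <- f
      # truth labels and per-day statistics from registered events
      sec <- events_to_second_labels(reg)
      series <- aggregate_to_epochs(sec, reg$start_time[1])
      mask <- wear_mask(reg$start_time[1], events_end(reg))
      ds <- summarize_day(series, mask)
      ds$participant <- pid; ds$day <- d
      stats_p <- rbind(stats_p, ds)
    }
    day_rows[[pid]] <- stats_p
    s <- summarize_participant_season(stats_p, participant = pid, season = 1L,
                                      valid_day_min = valid_day_min,
                                      min_valid_days = min_valid_days,
                                      xmin = cfg$sit_xmin_s / 60,
                                      source = "activpal")
    if (!is.null(s)) summaries[[pid]] <- s
  }
  summary_df <- if (length(summaries)) do.call(rbind, summaries) else NULL
  manifest <- list(
    config = unclass(cfg),
    valid_day_min = valid_day_min, min_valid_days = min_valid_days,
    files = files,
    day_stats = lapply(day_rows, function(df) {
      df$bouts <- NULL; df$date <- as.character(df$date); df
    }),
    truth_summaries = if (!is.null(summary_df)) summary_df else list())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(summary_df))
    write_summary_csv(summary_df, file.path(out_dir, "truth_summaries.csv"))
  invisible(manifest)
}
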