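small_cfg <- function(...) sim_config(n_participants = 1,
                                      days_per_participant = 1,
                                      day_wear_hours = 0.5, seed = 11, ...)

test_that("posture event simulation is deterministic and spans the day", {
  cfg <- small_cfg()
  e1 <- simulate_posture_events(cfg, 1, 1)
  e2 <- simulate_posture_events(cfg, 1, 1)
  expect_identical(e1, e2)
  expect_equal(sum(e1$duration_s), 1800)
  expect_true(all(rle(e1$code)$lengths == 1))  # strictly alternating

  e3 <- simulate_posture_events(cfg, 2, 1)
  expect_false(identical(e1$duration_s, e3$duration_s))

  cfg0 <- sim_config(day_wear_hours = 0, seed = 1)
  expect_equal(nrow(simulate_posture_events(cfg0, 1, 1)), 0)
})

test_that("generated sitting bouts recover the configured power-law exponent", {
  cfg <- sim_config(n_participants = 1, days_per_participant = 1,
                    day_wear_hours = 600, seed = 13)
  ev <- simulate_posture_events(cfg, 1, 1)
  d <- ev$duration_s[ev$code == "SIT"]
  d <- d[-length(d)]  # last bout may be cut by the day end
  expect_gt(length(d), 5000)
  # independent estimator: MLE of the xmax-truncated power law (the
  # generator truncates bouts at sit_xmax_s) by direct likelihood search
  xmin <- cfg$sit_xmin_s; xmax <- cfg$sit_xmax_s
  ll <- function(a) {
    r <- (xmax / xmin)^(1 - a)
    length(d) * (log(a - 1) - log(1 - r) - (1 - a) * log(xmin)) -
      a * sum(log(d))
  }
  ahat <- stats::optimize(ll, c(1.01, 3), maximum = TRUE)$maximum
  expect_lt(abs(ahat - 1.40), 0.05)
})

test_that("sitting fraction of a large bundle is near the target", {
  cfg <- sim_config(n_participants = 4, days_per_participant = 5,
                    day_wear_hours = 12, seed = 3)
  sit <- 0; tot <- 0
  for (p in 1:4) for (d in 1:5) {
    ev <- simulate_posture_events(cfg, p, d)
    sit <- sit + sum(ev$duration_s[ev$code == "SIT"])
    tot <- tot + sum(ev$duration_s)
  }
  expect_lt(abs(sit / tot - cfg$p_sit_time), 0.03)
})

test_that("registration merges unregistrable postures into the previous one", {
  mk <- function(dur, code) posture_events(t0() + c(0, cumsum(dur[-length(dur)])),
                                           dur, code,
                                           provenance = "simulator-exact")
  r1 <- register_activpal(mk(c(60, 5, 60), c("SIT", "UPRIGHT", "SIT")))
  expect_equal(nrow(r1), 1)
  expect_equal(r1$duration_s, 125)
  expect_equal(r1$code, "SIT")

  r2 <- register_activpal(mk(c(60, 30), c("SIT", "UPRIGHT")))
  expect_equal(r2$duration_s, c(60, 30))

  r3 <- register_activpal(mk(9, "SIT"))
  expect_equal(r3$duration_s, 9)  # nothing precedes the first event

  # idempotence on random exact event lists
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    dur <- stats::runif(n, 2, 120)
    ev <- mk(dur, rep(c("SIT", "UPRIGHT"), length.out = n))
    reg <- register_activpal(ev)
    expect_identical(register_activpal(reg), reg)
    expect_true(all(reg$duration_s[-1] >= 10))
    expect_equal(sum(reg$duration_s), sum(dur))
  }
})

test_that("raw synthesis is deterministic with ~1 g resting magnitude", {
  cfg <- small_cfg()
  ev <- register_activpal(simulate_posture_events(cfg, 1, 1))
  s1 <- synthesize_raw(ev, cfg, seed = 5)
  s2 <- synthesize_raw(ev, cfg, seed = 5)
  expect_identical(s1$data, s2$data)
  expect_equal(s1$rate_hz, 30)
  expect_equal(nrow(s1$data), 1800 * 30)

  # still sitting: magnitude within 1.00 +/- 0.05 g
  still <- posture_events(t0(), 3600, "SIT", provenance = "simulator")
  raw <- synthesize_raw(still, sim_config(seed = 1), seed = 9)
  quiet_sec <- which(apply(matrix(sqrt(rowSums(raw$data^2)), nrow = 30), 2,
                           stats::sd) < 0.02)
  vm <- mean(sqrt(rowSums(raw$data[rep((quiet_sec - 1) * 30,
                                       each = 30) + 1:30, ]^2)))
  expect_lt(abs(vm - 1), 0.05)
})

test_that("easy-mode windows are variance-separable by posture", {
  cfg <- sim_config(seed = 2, difficulty = "easy")
  sit_hour <- posture_events(t0(), 3600, "SIT", provenance = "simulator")
  up_hour <- posture_events(t0(), 3600, "UPRIGHT", provenance = "simulator")
  v_sit <- window_variances(window_raw(downsample_to_10hz(
    synthesize_raw(sit_hour, cfg, seed = 21)))$array)
  v_up <- window_variances(window_raw(downsample_to_10hz(
    synthesize_raw(up_hour, cfg, seed = 22)))$array)
  expect_lt(max(v_sit), min(v_up))
})

test_that("counts integrate dynamic acceleration with a still deadband", {
  cfg <- sim_config(seed = 2)
  still <- posture_events(t0(), 3600, "SIT", provenance = "simulator")
  raw <- synthesize_raw(still, cfg, seed = 31)
  # suppress the fidgets by zeroing dynamics: still hour -> all-zero minutes
  raw_still <- raw_stream(raw$start_time, 30,
                          cbind(sin(35 * pi / 180) +
                                  stats::rnorm(nrow(raw$data), 0, 0.01),
                                stats::rnorm(nrow(raw$data), 0, 0.01),
                                cos(35 * pi / 180) +
                                  stats::rnorm(nrow(raw$data), 0, 0.01)))
  cs <- synthesize_counts(raw_still)
  expect_length(cs$counts, 60)
  expect_true(all(cs$counts == 0))

  # a walking hour exceeds the 100 cpm cut-point in every minute
  up <- posture_events(t0(), 3600, "UPRIGHT", provenance = "simulator")
  cs_up <- synthesize_counts(synthesize_raw(up, cfg, seed = 32))
  expect_true(all(cs_up$counts > 100))

  expect_identical(synthesize_counts(raw)$counts,
                   synthesize_counts(raw)$counts)
})

test_that("study bundles are complete, truthful and byte-reproducible", {
  cfg <- sim_config(n_participants = 2, days_per_participant = 3,
                    day_wear_hours = 0.2, seed = 17)
  d1 <- withr::local_tempdir()
  man <- make_study(cfg, d1, valid_day_min = 10, min_valid_days = 3)
  files <- list.files(d1)
  expect_length(grep("_raw.csv$", files), 6)
  expect_length(grep("_counts.csv$", files), 6)
  expect_length(grep("_events.csv$", files), 6)

  # manifest summaries equal recomputation from the written events files
  for (pid in c("P01", "P02")) {
    stats_p <- NULL
    for (d in 1:3) {
      ev <- read_activpal_events(
        file.path(d1, sprintf("%s_day%d_events.csv", pid, d)),
        provenance = "simulator")
      sec <- events_to_second_labels(ev)
      es <- aggregate_to_epochs(sec, ev$start_time[1])
      ds <- summarize_day(es, wear_mask(ev$start_time[1],
                                        sitstand:::events_end(ev)))
      stats_p <- rbind(stats_p, ds)
    }
    s <- summarize_participant_season(stats_p, participant = pid,
                                      valid_day_min = 10, min_valid_days = 3,
                                      xmin = cfg$sit_xmin_s / 60)
    ms <- man$truth_summaries[man$truth_summaries$participant == pid, ]
    for (v in c("total_sed_min_day", "breaks_per_day", "min_day_bouts_ge30",
                "mean_bout_min", "usual_bout_min", "alpha"))
      expect_equal(s[[v]], ms[[v]], tolerance = 1e-6, label = v)
  }

  d2 <- withr::local_tempdir()
  make_study(cfg, d2, valid_day_min = 10, min_valid_days = 3)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
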