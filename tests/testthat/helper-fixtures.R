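# Small programmatic fixtures shared across test files.

tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(conv_channels = c(4, 6), conv_kernel = 3, pool = 2,
         seq_len_epochs = 3, rnn_hidden = 6, dropout = 0.2, seed = 1),
    list(...))
  do.call(model_config, args)
}

# two variance-separable classes with a tilt offset, labels in runs
tiny_data <- function(n_epochs = 36, seed = 5, amp = 0.4) {
  set.seed(seed)
  lab <- rep(rep(c("SIT", "NONSIT"), length.out = 12),
             each = ceiling(n_epochs / 12))[1:n_epochs]
  arr <- array(0, c(100, 3, n_epochs))
  t <- (1:100) / 10
  for (i in seq_len(n_epochs)) {
    a <- if (lab[i] == "NONSIT") amp else 0
    th <- if (lab[i] == "NONSIT") 0.1 else 0.6
    arr[, , i] <- cbind(sin(th) + a * sin(4 * t) + stats::rnorm(100, 0, 0.01),
                        stats::rnorm(100, 0, 0.01),
                        cos(th) + a * cos(4 * t) + stats::rnorm(100, 0, 0.01))
  }
  list(windows = arr, labels = lab)
}

# in-memory participant data for learning experiments: simulate events,
# register, synthesize raw, window, and align labels
sim_participant_data <- function(cfg, participants, days = 1) {
  out <- list()
  for (p in participants) {
    windows <- NULL; labels <- character(0)
    for (d in seq_len(days)) {
      ev <- register_activpal(simulate_posture_events(cfg, p, d))
      raw <- synthesize_raw(ev, cfg,
                            seed = sitstand:::.derive_seed(cfg$seed, p, d) + 7L)
      w <- window_raw(downsample_to_10hz(raw))
      truth <- aggregate_to_epochs(events_to_second_labels(ev),
                                   ev$start_time[1])
      k <- min(dim(w$array)[3], length(truth$labels))
      arr <- w$array[, , seq_len(k), drop = FALSE]
      windows <- if (is.null(windows)) arr else {
        both <- array(0, c(100, 3, dim(windows)[3] + k))
        both[, , seq_len(dim(windows)[3])] <- windows
        both[, , dim(windows)[3] + seq_len(k)] <- arr
        both
      }
      labels <- c(labels, truth$labels[seq_len(k)])
    }
    out[[sprintf("P%02d", p)]] <- list(windows = windows, labels = labels,
                                       start_time = .sim_start(d = 1))
  }
  out
}

.sim_start <- function(d = 1) sitstand:::.sim_day_start(d)
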