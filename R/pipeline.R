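# End-to-end orchestration: load a study bundle, detect non-wear, build
# ground-truth epochs, train/apply the classifier, derive bout variables for
# every method, and evaluate agreement. The command-line wrapper in
# inst/cli/sitstand.R is a thin shell over these functions.

#' Load a simulated (or equivalently laid-out) study bundle
#'
#' Reads the manifest written by [make_study()] and, per participant-day,
#' the events, counts and (when present) raw acceleration files.
#'
#' @param study_dir Bundle directory containing `manifest.json`.
#' @param read_raw Read the 30 Hz raw CSVs (default TRUE).
#' @return List with `manifest` and `days` (one element per participant-day:
#'   participant, day, events, counts, raw).
#' @export
load_study <- function(study_dir, read_raw = TRUE) {
  manifest <- jsonlite::read_json(file.path(study_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  days <- lapply(names(manifest$files), function(base) {
    f <- lapply(manifest$files[[base]], function(p) file.path(study_dir, p))
    list(participant = sub("_day.*", "", base),
         day = as.integer(sub(".*_day", "", base)),
         events = read_activpal_events(f$events, provenance = "simulator"),
         counts = read_actigraph_counts(f$counts),
         raw = if (read_raw && !is.null(f$raw))
           read_actigraph_raw(f$raw, expected_rate = 30) else NULL)
  })
  names(days) <- names(manifest$files)
  list(manifest = manifest, days = days)
}

# ground-truth 10-s epochs and model input windows for one participant-day
.prepare_day <- function(day_rec) {
  reg <- day_rec$events
  sec <- events_to_second_labels(reg)
  truth <- aggregate_to_epochs(sec, reg$start_time[1])
  windows <- NULL
  if (!is.null(day_rec$raw)) {
    windows <- window_raw(downsample_to_10hz(day_rec$raw))
    k <- min(dim(windows$array)[3], length(truth$labels))
    windows$array <- windows$array[, , seq_len(k), drop = FALSE]
    truth$labels <- truth$labels[seq_len(k)]
  }
  list(truth = truth, windows = windows)
}

#' Run the full pipeline on a study bundle
#'
#' Trains the posture classifier on the training participants (checkpoint
#' selected on the selection participants), predicts 10-s epochs for the
#' test participants, derives sedentary summaries from model labels, true
#' labels and the counts cut-point, and evaluates epoch-, transition- and
#' participant-level agreement against truth.
#'
#' @param study_dir Bundle directory from [make_study()].
#' @param out_dir Output directory for predictions, summaries and the
#'   evaluation report.
#' @param split List with character vectors `train`, `selection`, `test`
#'   of participant ids (e.g. "P01").
#' @param mcfg,tcfg Model and training configurations.
#' @param tolerance_s Transition-pairing lag tolerance (default 60).
#' @param cpm_threshold Counts cut-point (default 100).
#' @param valid_day_min,min_valid_days Valid-day inclusion rules
#'   (defaults 480 min, 3 days).
#' @return List: model, epoch evaluation, transition evaluation, agreement
#'   reports (model and cpm vs truth), summaries.
#' @export
run_pipeline <- function(study_dir, out_dir, split,
                         mcfg = model_config(), tcfg = train_config(),
                         tolerance_s = 60, cpm_threshold = 100,
                         valid_day_min = 480, min_valid_days = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- load_study(study_dir)
  prep <- lapply(study$days, .prepare_day)

  by_participant <- function(ids) {
    out <- list()
    for (nm in names(study$days)) {
      p <- study$days[[nm]]$participant
      if (!p %in% ids) next
      if (is.null(prep[[nm]]$windows))
        stop("participant ", p, " has no raw stream for model input")
      if (is.null(out[[p]]))
        out[[p]] <- list(windows = prep[[nm]]$windows$array,
                         labels = prep[[nm]]$truth$labels)
      else {
        out[[p]]$windows <- .abind3(out[[p]]$windows,
                                    prep[[nm]]$windows$array)
        out[[p]]$labels <- c(out[[p]]$labels, prep[[nm]]$truth$labels)
      }
    }
    out
  }

  model_data <- by_participant(c(split$train, split$selection))
  model <- build_posture_model(mcfg)
  model <- train_posture_model(model, model_data, tcfg,
                               holdout = split$selection)
  save_model(model, file.path(out_dir, "model"))

  # per-test-participant-day predictions and evaluation inputs
  epoch_pairs <- list(); series_pairs <- list()
  day_stats <- list(model = list(), truth = list(), cpm = list())
  for (nm in names(study$days)) {
    rec <- study$days[[nm]]
    if (!rec$participant %in% split$test) next
    pd <- prep[[nm]]
    pred <- predict_posture(model, pd$windows)
    write_epoch_predictions(pred, file.path(out_dir, paste0(nm, "_pred.csv")))
    wearmask <- detect_nonwear(rec$counts)
    al <- align_and_mask(pred, pd$truth, list(wearmask))
    key <- rec$participant
    epoch_pairs[[key]]$pred <- c(epoch_pairs[[key]]$pred, al$pred)
    epoch_pairs[[key]]$truth <- c(epoch_pairs[[key]]$truth, al$truth)
    series_pairs[[nm]] <- list(pred = pred, truth = pd$truth)
    cpm <- classify_cpm(rec$counts, threshold = cpm_threshold)
    for (src in c("model", "truth", "cpm")) {
      series <- switch(src, model = pred, truth = pd$truth, cpm = cpm)
      ds <- summarize_day(series, wear_mask(rec$events$start_time[1],
                                            events_end(rec$events)))
      ds$participant <- rec$participant
      day_stats[[src]][[key]] <- rbind(day_stats[[src]][[key]], ds)
    }
  }
  if (!length(epoch_pairs)) stop("no test participants found")

  # transition evaluation pools each participant's days
  series_by_p <- list()
  for (nm in names(series_pairs)) {
    p <- study$days[[nm]]$participant
    series_by_p[[p]] <- c(series_by_p[[p]], list(series_pairs[[nm]]))
  }
  trans_input <- lapply(series_by_p, function(lst) {
    list(pred = lst[[1]]$pred, truth = lst[[1]]$truth, all = lst)
  })

  ep_eval <- evaluate_epochs(epoch_pairs)
  tr_eval <- .evaluate_transitions_pooled(series_by_p, tolerance_s)

  summarize_src <- function(src, xmin) {
    rows <- lapply(names(day_stats[[src]]), function(p)
      summarize_participant_season(day_stats[[src]][[p]], participant = p,
                                   season = 1L,
                                   valid_day_min = valid_day_min,
                                   min_valid_days = min_valid_days,
                                   xmin = xmin, source = src))
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  summaries <- list(model = summarize_src("model", 10 / 60),
                    truth = summarize_src("truth", 10 / 60),
                    cpm = summarize_src("cpm", 1))
  agree <- list()
  if (!is.null(summaries$model) && !is.null(summaries$truth) &&
      nrow(summaries$truth) >= 2) {
    agree$model <- agreement(summaries$model, summaries$truth)
    if (!is.null(summaries$cpm))
      agree$cpm <- agreement(summaries$cpm, summaries$truth)
  }
  for (src in names(summaries)) {
    if (!is.null(summaries[[src]]))
      write_summary_csv(summaries[[src]],
                        file.path(out_dir, paste0("summary_", src, ".csv")))
  }
  report <- list(
    epoch = ep_eval, transitions = tr_eval, agreement = agree,
    split = split, tolerance_s = tolerance_s)
  jsonlite::write_json(
    list(epoch_summary = ep_eval$summary,
         transition_summary = tr_eval$summary,
         agreement = lapply(agree, identity)),
    file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  c(report, list(model = model, summaries = summaries))
}

# per-participant transition metrics with days pooled
.evaluate_transitions_pooled <- function(series_by_p, tolerance_s) {
  per <- do.call(rbind, lapply(names(series_by_p), function(p) {
    pt <- c(); tt <- c(); m <- 0
    for (pair in series_by_p[[p]]) {
      tp <- transition_pairing(extract_transitions(pair$pred),
                               extract_transitions(pair$truth),
                               tolerance_s = tolerance_s)
      pt <- c(pt, tp$n_pred); tt <- c(tt, tp$n_true); m <- m + tp$n_matched
    }
    data.frame(id = p,
               sensitivity = if (sum(tt)) m / sum(tt) else NA_real_,
               ppv = if (sum(pt)) m / sum(pt) else NA_real_,
               n_true = sum(tt), n_pred = sum(pt), n_matched = m)
  }))
  num <- per[, c("sensitivity", "ppv")]
  list(per_season = per,
       summary = data.frame(
         metric = names(num),
         mean = vapply(num, function(v) mean(v, na.rm = TRUE), 0),
         sd = vapply(num, function(v) stats::sd(v, na.rm = TRUE), 0),
         n_defined = vapply(num, function(v) sum(!is.na(v)), 0L)),
       tolerance_s = tolerance_s)
}

.abind3 <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}
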