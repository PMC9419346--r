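# Agreement machinery: confusion metrics on paired epoch labels, lag-tolerant
# transition pairing, and participant-level agreement statistics.

#' Epoch-level confusion metrics
#'
#' SIT is the positive class. Balanced accuracy is the mean of sensitivity
#' and specificity; kappa is Cohen's kappa on the 2x2 table. Metrics whose
#' denominator is zero are reported as `NA`, never as 0.
#'
#' @param pred,truth Equal-length character vectors of SIT/NONSIT.
#' @return One-row data.frame: sensitivity, specificity, balanced_accuracy,
#'   ppv, npv, kappa.
#' @export
confusion_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (!length(pred)) stop("empty input")
  tp <- sum(pred == "SIT" & truth == "SIT")
  tn <- sum(pred == "NONSIT" & truth == "NONSIT")
  fp <- sum(pred == "SIT" & truth == "NONSIT")
  fn <- sum(pred == "NONSIT" & truth == "SIT")
  div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  n <- tp + tn + fp + fn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  data.frame(sensitivity = sens, specificity = spec,
             balanced_accuracy = (sens + spec) / 2,
             ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
             kappa = kappa)
}

#' Extract sit-to-stand transition times
#'
#' The timestamp of the first NONSIT epoch of every SIT-then-NONSIT
#' adjacency. Stand-to-sit changes and bouts truncated by UNWORN or by the
#' series end yield no transition.
#'
#' @param series An [epoch_series()].
#' @return POSIXct vector of transition times (possibly empty).
#' @export
extract_transitions <- function(series) {
  lab <- series$labels
  n <- length(lab)
  if (n < 2) return(series$start_time[0])
  idx <- which(lab[-n] == "SIT" & lab[-1] == "NONSIT") + 1
  epoch_times(series)[idx]
}

#' Pair predicted and true transitions within a lag tolerance
#'
#' One-to-one chronological matching: each true transition, in time order,
#' is matched to the earliest unmatched predicted transition within
#' `tolerance_s`. Because every pairing window has the same width, this
#' greedy order attains the maximum number of matched pairs, which makes the
#' pairing symmetric in pred/true (with sensitivity and PPV swapping) and
#' monotone in the tolerance. Sensitivity is matched / |true|; PPV is
#' matched / |pred|. Empty truth yields `NA` sensitivity; empty predictions
#' yield `NA` PPV.
#'
#' @param pred_times,true_times Sorted numeric or POSIXct transition times.
#' @param tolerance_s Lag tolerance in seconds (default 60).
#' @return List: sensitivity, ppv, n_matched, n_true, n_pred, pairs
#'   (two-column matrix of matched indices).
#' @export
transition_pairing <- function(pred_times, true_times, tolerance_s = 60) {
  p <- as.numeric(pred_times); tr <- as.numeric(true_times)
  if (is.unsorted(p) || is.unsorted(tr)) stop("transition times must be sorted")
  used <- rep(FALSE, length(p))
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(tr)) {
    cand <- which(!used & abs(p - tr[i]) <= tolerance_s)
    if (!length(cand)) next
    j <- cand[1]  # earliest unmatched prediction in the window
    used[j] <- TRUE
    pairs <- rbind(pairs, c(j, i))
  }
  m <- nrow(pairs)
  list(sensitivity = if (length(tr)) m / length(tr) else NA_real_,
       ppv = if (length(p)) m / length(p) else NA_real_,
       n_matched = m, n_true = length(tr), n_pred = length(p),
       pairs = pairs)
}

#' Lin's concordance correlation coefficient
#'
#' \eqn{2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)} with population
#' (1/n) moment estimators: the product of Pearson precision and a bias
#' penalty for deviation from the identity line.
#'
#' @param x,y Equal-length numeric vectors, n >= 2.
#' @return Unitless concordance in [-1, 1].
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) stop("need paired n >= 2")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) stop("degenerate: zero combined variance")
  2 * sxy / denom
}

#' Participant-level agreement statistics
#'
#' For each variable, computes bias (mean of method - truth) and its SD,
#' MAE, MAPE (% over pairs with truth > 0), Spearman correlation
#' (average-rank ties) and Lin's CCC across paired participant-seasons.
#'
#' @param pred_summaries,truth_summaries Data.frames with `participant`,
#'   `season` and the variable columns; paired on (participant, season).
#' @param variables Character vector of variable column names.
#' @return Data.frame of class `agreement_report`, one row per variable:
#'   variable, n, bias, bias_sd, mae, mape_pct, spearman_rho, ccc.
#' @export
agreement <- function(pred_summaries, truth_summaries,
                      variables = c("total_sed_min_day", "breaks_per_day",
                                    "min_day_bouts_ge30", "mean_bout_min",
                                    "usual_bout_min", "alpha")) {
  key <- function(df) paste(df$participant, df$season, sep = "\r")
  kp <- key(pred_summaries); kt <- key(truth_summaries)
  common <- intersect(kp, kt)
  if (length(common) < 2) stop("need at least 2 paired participant-seasons")
  p <- pred_summaries[match(common, kp), , drop = FALSE]
  t <- truth_summaries[match(common, kt), , drop = FALSE]
  rows <- lapply(variables, function(v) {
    x <- p[[v]]; y <- t[[v]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    d <- x - y
    pos <- y > 0
    data.frame(
      variable = v, n = length(d),
      bias = mean(d), bias_sd = stats::sd(d),
      mae = mean(abs(d)),
      mape_pct = if (any(pos)) mean(abs(d[pos]) / y[pos]) * 100 else NA_real_,
      spearman_rho = suppressWarnings(
        stats::cor(x, y, method = "spearman")),
      ccc = tryCatch(lin_ccc(y, x), error = function(e) NA_real_),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("agreement_report", "data.frame")
  out
}

#' Per-participant-season epoch evaluation
#'
#' Applies [confusion_metrics()] within each participant-season and appends
#' across-season mean and SD rows, mirroring how device-validation studies
#' report epoch-level agreement.
#'
#' @param pairs_by_season Named list; each element a list with `pred` and
#'   `truth` label vectors for one participant-season.
#' @return List with `per_season` (data.frame) and `summary` (mean/SD rows).
#' @export
evaluate_epochs <- function(pairs_by_season) {
  per <- do.call(rbind, lapply(names(pairs_by_season), function(nm) {
    x <- pairs_by_season[[nm]]
    cbind(id = nm, confusion_metrics(x$pred, x$truth))
  }))
  num <- per[, setdiff(names(per), "id")]
  list(per_season = per,
       summary = data.frame(
         metric = names(num),
         mean = vapply(num, function(v) mean(v, na.rm = TRUE), 0),
         sd = vapply(num, function(v) stats::sd(v, na.rm = TRUE), 0),
         n_defined = vapply(num, function(v) sum(!is.na(v)), 0L)))
}

#' Per-participant-season transition evaluation
#'
#' Extracts sit-to-stand transitions from paired label series and applies
#' [transition_pairing()] within each participant-season.
#'
#' @param series_by_season Named list; each element a list with `pred` and
#'   `truth` [epoch_series()] objects.
#' @param tolerance_s Lag tolerance in seconds (default 60).
#' @return List with `per_season` and `summary` as in [evaluate_epochs()].
#' @export
evaluate_transitions <- function(series_by_season, tolerance_s = 60) {
  per <- do.call(rbind, lapply(names(series_by_season), function(nm) {
    x <- series_by_season[[nm]]
    tp <- transition_pairing(extract_transitions(x$pred),
                             extract_transitions(x$truth),
                             tolerance_s = tolerance_s)
    data.frame(id = nm, sensitivity = tp$sensitivity, ppv = tp$ppv,
               n_true = tp$n_true, n_pred = tp$n_pred,
               n_matched = tp$n_matched)
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
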