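# The posture classifier: per-epoch convolutional features from 10-s raw
# windows, a bidirectional LSTM over epoch sequences, and a softmax sitting
# probability per epoch. CPU-trainable in minutes at the default sizes.

#' Model architecture configuration
#'
#' @param conv_channels Filter counts of the 1-D convolution stack
#'   (default `c(32, 64)`).
#' @param conv_kernel Kernel width in samples at 10 Hz (default 5).
#' @param pool Mean-pooling width after each convolution (default 2).
#' @param seq_len_epochs Number of consecutive 10-s epochs the LSTM sees per
#'   sequence (default 9; the center epoch receives the prediction).
#' @param rnn_hidden LSTM units per direction (default 64).
#' @param dropout Dropout fraction applied to CNN features and LSTM outputs
#'   during training (default 0.2).
#' @param seed Integer seed controlling parameter initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(conv_channels = c(32, 64), conv_kernel = 5,
                         pool = 2, seq_len_epochs = 9, rnn_hidden = 64,
                         dropout = 0.2, seed = 1L) {
  if (conv_kernel < 1) stop("conv_kernel must be positive")
  if (any(conv_channels < 1) || !length(conv_channels))
    stop("conv_channels must be positive")
  if (pool < 1) stop("pool must be positive")
  if (seq_len_epochs < 1) stop("seq_len_epochs must be >= 1")
  if (rnn_hidden < 1) stop("rnn_hidden must be positive")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  P <- 100L
  for (l in seq_along(conv_channels)) {
    P <- (P - conv_kernel + 1L) %/% pool
    if (P < 1) stop("conv stack consumes the whole 10-s window")
  }
  structure(list(conv_channels = as.integer(conv_channels),
                 conv_kernel = as.integer(conv_kernel),
                 pool = as.integer(pool),
                 seq_len_epochs = as.integer(seq_len_epochs),
                 rnn_hidden = as.integer(rnn_hidden),
                 dropout = dropout, seed = as.integer(seed)),
            class = "model_config")
}

#' Training configuration
#'
#' The checkpoint kept is the one maximizing the selection metric on the
#' holdout participants: the mean of epoch-level balanced accuracy and
#' transition-level balanced accuracy (equal weights).
#'
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Sequences per minibatch (default 16).
#' @param max_epochs Maximum training epochs (default 30).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param seed Integer seed controlling shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, batch_size = 16, max_epochs = 30,
                         patience = 5, seed = 1L) {
  stopifnot(lr > 0, batch_size >= 1, max_epochs >= 1, patience >= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Build an untrained posture model
#'
#' @param cfg A [model_config()].
#' @return An object of class `posture_model` with randomly initialized
#'   parameters (seeded by `cfg$seed`) and `fitted = FALSE`.
#' @export
build_posture_model <- function(cfg = model_config()) {
  if (!inherits(cfg, "model_config")) cfg <- do.call(model_config, cfg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  params <- init_params(cfg)
  structure(list(cfg = cfg, params = params,
                 norm = list(mean = c(0, 0, 0), sd = c(1, 1, 1)),
                 fitted = FALSE,
                 label_map = c(`0` = "NONSIT", `1` = "SIT"),
                 format_version = 1L),
            class = "posture_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' @export
print.posture_model <- function(x, ...) {
  cat(sprintf("<posture_model> conv [%s] k=%d | BiLSTM %d/dir | seq %d | %s (%d parameters)\n",
              paste(x$cfg$conv_channels, collapse = ","), x$cfg$conv_kernel,
              x$cfg$rnn_hidden, x$cfg$seq_len_epochs,
              if (x$fitted) "fitted" else "unfitted", n_params(x$params)))
  invisible(x)
}

# standardize a (N*100, 3) matrix with stored constants
.standardize <- function(Xm, norm) {
  sweep(sweep(Xm, 2, norm$mean, `-`), 2, norm$sd, `/`)
}

.as_windows_array <- function(windows) {
  if (inherits(windows, "epoch_windows")) windows$array else windows
}

# selection metric on one participant: mean of epoch balanced accuracy and
# transition balanced accuracy (transition = SIT->NONSIT adjacency indicator)
.selection_metric <- function(pred_labels, true_labels) {
  ba <- function(p, t) {
    se <- if (any(t)) mean(p[t]) else NA_real_
    sp <- if (any(!t)) mean(!p[!t]) else NA_real_
    mean(c(se, sp), na.rm = TRUE)
  }
  ep <- ba(pred_labels == "SIT", true_labels == "SIT")
  n <- length(true_labels)
  if (n < 2) return(ep)
  tt <- true_labels[-n] == "SIT" & true_labels[-1] == "NONSIT"
  pt <- pred_labels[-n] == "SIT" & pred_labels[-1] == "NONSIT"
  tr <- if (any(tt)) ba(pt, tt) else NA_real_
  mean(c(ep, tr), na.rm = TRUE)
}

#' Train the posture model
#'
#' Gradient-descent training (Adam) on softmax cross-entropy over sequences
#' of consecutive 10-s epochs, with early stopping on the holdout selection
#' metric (mean of epoch balanced accuracy and transition balanced
#' accuracy). Input windows are standardized per axis with training-set
#' mean/SD, stored with the model: raw g offsets encode the gravity
#' direction, so per-window normalization would destroy the posture signal.
#'
#' @param model An unfitted (or fitted) [build_posture_model()] object.
#' @param data Named list, one element per participant:
#'   `list(windows = <epoch_windows or 100 x 3 x k array>, labels =
#'   <character vector of SIT/NONSIT, one per window>)`.
#' @param tcfg A [train_config()].
#' @param holdout Character vector of participant names used only for
#'   checkpoint selection; must be non-empty and disjoint from training.
#' @return The fitted model, with a `history` data.frame attached
#'   (per-epoch loss and holdout metric).
#' @export
train_posture_model <- function(model, data, tcfg = train_config(),
                                holdout) {
  if (missing(holdout) || !length(holdout)) stop("empty holdout")
  if (!all(holdout %in% names(data))) stop("holdout participants not in data")
  train_ids <- setdiff(names(data), holdout)
  if (!length(train_ids)) stop("no training participants")
  cfg <- model$cfg
  T <- cfg$seq_len_epochs

  # assemble non-overlapping training sequences
  seq_X <- list(); seq_y <- list()
  for (id in train_ids) {
    arr <- .as_windows_array(data[[id]]$windows)
    lab <- data[[id]]$labels
    stopifnot(dim(arr)[3] == length(lab))
    ns <- length(lab) %/% T
    if (ns == 0) next
    for (s in seq_len(ns)) {
      idx <- ((s - 1) * T + 1):(s * T)
      seq_X[[length(seq_X) + 1]] <- arr[, , idx, drop = FALSE]
      seq_y[[length(seq_y) + 1]] <- lab[idx]
    }
  }
  if (!length(seq_X)) stop("no full training sequences")
  all_lab <- unlist(seq_y)
  if (length(unique(all_lab)) < 2)
    stop("single class in training labels")

  # normalization constants from all training windows
  big <- do.call(c, lapply(seq_X, as.vector))
  dim(big) <- c(100, 3, length(big) / 300)
  mu <- apply(big, 2, mean)
  sdv <- apply(big, 2, stats::sd)
  sdv[sdv < 1e-8] <- 1
  model$norm <- list(mean = mu, sd = sdv)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(tcfg$seed)
  params <- init_params(cfg)
  opt <- adam_init(params)

  nseq <- length(seq_X)
  B_full <- tcfg$batch_size
  best <- list(metric = -Inf, params = params, norm = model$norm)
  history <- data.frame()
  bad <- 0
  C_last <- cnn_out_channels(cfg)
  keep <- 1 - cfg$dropout

  for (ep in seq_len(tcfg$max_epochs)) {
    ord <- sample.int(nseq)
    tot_loss <- 0; nb <- 0
    for (b0 in seq(1, nseq, by = B_full)) {
      ids <- ord[b0:min(b0 + B_full - 1, nseq)]
      B <- length(ids)
      arr <- array(0, c(100, 3, B * T))
      y <- integer(B * T)
      for (j in seq_along(ids)) {
        arr[, , ((j - 1) * T + 1):(j * T)] <- seq_X[[ids[j]]]
        y[((j - 1) * T + 1):(j * T)] <-
          ifelse(seq_y[[ids[j]]] == "SIT", 2L, 1L)
      }
      Xm <- .standardize(windows_to_matrix(arr), model$norm)
      masks <- NULL
      if (cfg$dropout > 0) {
        masks <- list(
          F = matrix(stats::rbinom(B * T * C_last, 1, keep) / keep,
                     B * T, C_last),
          H = matrix(stats::rbinom(B * T * 2 * cfg$rnn_hidden, 1, keep) /
                       keep, B * T, 2 * cfg$rnn_hidden))
      }
      res <- nn_loss(params, cfg, Xm, y, B, T, want_grads = TRUE,
                     drop_masks = masks)
      st <- adam_step(params, res$grads, opt, tcfg$lr)
      params <- st$params; opt <- st$state
      tot_loss <- tot_loss + res$loss; nb <- nb + 1
    }
    # holdout selection metric
    model$params <- params
    model$fitted <- TRUE
    mets <- vapply(holdout, function(id) {
      pr <- predict_posture(model, data[[id]]$windows,
                            start_time = parse_time("2000-01-01 00:00:00"))
      .selection_metric(pr$labels, data[[id]]$labels)
    }, 0)
    metric <- mean(mets)
    history <- rbind(history, data.frame(epoch = ep, loss = tot_loss / nb,
                                         holdout_metric = metric))
    if (metric > best$metric + 1e-9) {
      best <- list(metric = metric, params = params, norm = model$norm)
      bad <- 0
    } else {
      bad <- bad + 1
      if (bad >= tcfg$patience) break
    }
  }
  model$params <- best$params
  model$norm <- best$norm
  model$fitted <- TRUE
  model$history <- history
  model$selection_metric <- best$metric
  model
}

#' Predict sitting probabilities for 10-s windows
#'
#' Each epoch is predicted exactly once, from the sequence in which it is
#' centered (stride 1); sequences extending past the ends of the recording
#' are padded by replicating the first/last window, and the padded outputs
#' are discarded. The label is SIT iff the sitting probability is strictly
#' greater than 0.5.
#'
#' @param model A fitted posture model.
#' @param windows An `epoch_windows` object or a 100 x 3 x k array.
#' @param start_time Timestamp of the first epoch (taken from
#'   `epoch_windows` when available).
#' @param chunk Maximum sequences evaluated per batch.
#' @return An [epoch_series()] with `source = "model"` and probabilities.
#' @export
predict_posture <- function(model, windows, start_time = NULL, chunk = 4096) {
  if (!model$fitted) stop("model is not fitted")
  if (inherits(windows, "epoch_windows") && is.null(start_time))
    start_time <- windows$start_time
  if (is.null(start_time)) start_time <- parse_time("2000-01-01 00:00:00")
  arr <- .as_windows_array(windows)
  N <- dim(arr)[3]
  cfg <- model$cfg
  T <- cfg$seq_len_epochs
  H <- cfg$rnn_hidden
  Xm <- .standardize(windows_to_matrix(arr), model$norm)
  feats <- cnn_forward(model$params, cfg, Xm, N)$F
  center <- (T + 1L) %/% 2L
  probs <- numeric(N)
  for (c0 in seq(1, N, by = chunk)) {
    idx <- c0:min(c0 + chunk - 1, N)
    B <- length(idx)
    # per-step feature rows with replicated-edge padding
    Fseq <- matrix(0, B * T, ncol(feats))
    for (t in seq_len(T)) {
      src <- pmin(pmax(idx - center + t, 1L), N)
      Fseq[(seq_len(B) - 1L) * T + t, ] <- feats[src, , drop = FALSE]
    }
    lf <- lstm_forward(list(Wx = model$params$lstmf_Wx,
                            Wh = model$params$lstmf_Wh,
                            b = model$params$lstmf_b), Fseq, B, T, H)
    lb <- lstm_forward(list(Wx = model$params$lstmb_Wx,
                            Wh = model$params$lstmb_Wh,
                            b = model$params$lstmb_b), Fseq, B, T, H,
                       reverse = TRUE)
    rows <- (seq_len(B) - 1L) * T + center
    Hc <- cbind(lf$H[rows, , drop = FALSE], lb$H[rows, , drop = FALSE])
    logits <- sweep(Hc %*% model$params$out_W, 2, model$params$out_b, `+`)
    mx <- pmax(logits[, 1], logits[, 2])
    ez <- exp(logits - mx)
    probs[idx] <- ez[, 2] / rowSums(ez)
  }
  epoch_series(start_time, 10, ifelse(probs > 0.5, "SIT", "NONSIT"),
               probs = probs, source = "model")
}

#' Save / load a model bundle
#'
#' The bundle is a directory holding the parameter file and a JSON sidecar
#' with the architecture, normalization constants and a format version.
#' Round trips preserve predictions bit-for-bit.
#'
#' @param model A posture model.
#' @param path Bundle directory (created if absent).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sidecar <- list(format_version = model$format_version,
                  cfg = unclass(model$cfg),
                  norm = model$norm, fitted = model$fitted,
                  label_map = as.list(model$label_map),
                  selection_metric = model$selection_metric)
  jsonlite::write_json(sidecar, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model$params, file.path(path, "params.rds"))
  if (!is.null(model$history))
    utils::write.csv(model$history, file.path(path, "history.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  sidecar <- jsonlite::read_json(file.path(path, "model.json"),
                                 simplifyVector = TRUE)
  if (is.null(sidecar$format_version) || sidecar$format_version != 1L)
    stop("model bundle format version mismatch")
  cfg <- do.call(model_config, sidecar$cfg[setdiff(names(sidecar$cfg),
                                                   character(0))])
  model <- structure(list(cfg = cfg,
                          params = readRDS(file.path(path, "params.rds")),
                          norm = sidecar$norm,
                          fitted = isTRUE(sidecar$fitted),
                          label_map = c(`0` = "NONSIT", `1` = "SIT"),
                          format_version = 1L,
                          selection_metric = sidecar$selection_metric),
                     class = "posture_model")
  hist_path <- file.path(path, "history.csv")
  if (file.exists(hist_path)) model$history <- utils::read.csv(hist_path)
  model
}

#' Select the best architecture from a candidate grid
#'
#' Trains each candidate configuration on the training participants and
#' evaluates the selection metric on the selection participants; returns the
#' argmax, breaking ties toward the model with fewer parameters.
#'
#' @param candidates List of [model_config()] objects.
#' @param data Participant data as in [train_posture_model()].
#' @param tcfg A [train_config()].
#' @param selection Character vector of selection-participant names.
#' @return List with `best_cfg`, `best_model` and a `report` data.frame.
#' @export
grid_select <- function(candidates, data, tcfg = train_config(), selection) {
  if (!length(candidates)) stop("no candidate configurations")
  report <- data.frame()
  models <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    m <- build_posture_model(candidates[[i]])
    m <- train_posture_model(m, data, tcfg, holdout = selection)
    models[[i]] <- m
    report <- rbind(report, data.frame(
      candidate = i, metric = m$selection_metric,
      n_params = n_params(m$params)))
  }
  best_metric <- max(report$metric)
  tied <- which(report$metric >= best_metric - 1e-12)
  winner <- tied[which.min(report$n_params[tied])]
  list(best_cfg = candidates[[winner]], best_model = models[[winner]],
       winner = winner, report = report)
}
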