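# Tiny architectures keep these tests fast (fixtures in helper-fixtures.R);
# the learning-quality experiment lives in test-acceptance.R.

test_that("configuration contracts are enforced", {
  expect_error(model_config(conv_kernel = 0), "conv_kernel")
  expect_error(model_config(dropout = 1), "dropout")
  expect_error(model_config(seq_len_epochs = 0), "seq_len")
  expect_error(model_config(conv_channels = c(8, 8), conv_kernel = 40,
                            pool = 4), "consumes")
  expect_s3_class(model_config(seq_len_epochs = 1), "model_config")
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config(conv_channels = c(3, 4), conv_kernel = 3, pool = 2,
                      seq_len_epochs = 3, rnn_hidden = 5, dropout = 0,
                      seed = 1)
  set.seed(42)
  params <- sitstand:::init_params(cfg)
  B <- 2; T <- 3; N <- B * T
  arr <- array(stats::rnorm(100 * 3 * N), c(100, 3, N))
  Xm <- sitstand:::windows_to_matrix(arr)
  y <- sample(1:2, N, replace = TRUE)
  res <- sitstand:::nn_loss(params, cfg, Xm, y, B, T, want_grads = TRUE)
  eps <- 1e-6
  set.seed(7)
  for (nm in names(params)) {
    p <- params[[nm]]
    for (j in sample(length(p), min(3, length(p)))) {
      up <- params; up[[nm]][j] <- up[[nm]][j] + eps
      dn <- params; dn[[nm]][j] <- dn[[nm]][j] - eps
      num <- (sitstand:::nn_loss(up, cfg, Xm, y, B, T)$loss -
                sitstand:::nn_loss(dn, cfg, Xm, y, B, T)$loss) / (2 * eps)
      expect_equal(res$grads[[nm]][j], num, tolerance = 1e-4,
                   label = paste("grad", nm, j))
    }
  }
})

test_that("the model emits one probability per epoch and refuses when unfit", {
  m <- build_posture_model(tiny_cfg())
  expect_false(m$fitted)
  d <- tiny_data(18)
  expect_error(predict_posture(m, d$windows), "not fitted")
  m$fitted <- TRUE  # parameters are random but shapes must hold
  pr <- predict_posture(m, d$windows)
  expect_length(pr$probs, 18)
  expect_true(all(pr$probs >= 0 & pr$probs <= 1))
  expect_identical(pr$labels, ifelse(pr$probs > 0.5, "SIT", "NONSIT"))

  # seq_len_epochs = 1 degenerates to a per-epoch classifier
  m1 <- build_posture_model(tiny_cfg(seq_len_epochs = 1))
  m1$fitted <- TRUE
  expect_length(predict_posture(m1, d$windows)$probs, 18)
})

test_that("a probability of exactly 0.5 is NONSIT (strict rule)", {
  expect_error(epoch_series(t0(), 10, "SIT", probs = 0.5, source = "model"),
               "inconsistent")
  es <- epoch_series(t0(), 10, "NONSIT", probs = 0.5, source = "model")
  expect_equal(es$labels, "NONSIT")
})

test_that("training learns separable classes, deterministically per seed", {
  d1 <- tiny_data(60, seed = 5)
  d2 <- tiny_data(60, seed = 6)
  d3 <- tiny_data(60, seed = 9)
  data <- list(A = d1, B = d2, C = d3)
  tc <- train_config(lr = 3e-3, max_epochs = 30, batch_size = 4, seed = 3)
  m <- train_posture_model(build_posture_model(tiny_cfg()), data, tc,
                           holdout = "C")
  expect_true(m$fitted)
  expect_equal(nrow(m$history), length(unique(m$history$epoch)))
  pr <- predict_posture(m, d3$windows)
  ba <- confusion_metrics(pr$labels, d3$labels)$balanced_accuracy
  expect_gt(ba, 0.9)

  m2 <- train_posture_model(build_posture_model(tiny_cfg()), data, tc,
                            holdout = "C")
  expect_identical(m$params, m2$params)
  expect_identical(m$history, m2$history)

  # repeated prediction is bitwise identical
  expect_identical(predict_posture(m, d3$windows)$probs, pr$probs)
  # chunked evaluation does not change per-epoch outputs
  expect_identical(predict_posture(m, d3$windows, chunk = 7)$probs, pr$probs)
})

test_that("degenerate training inputs are rejected", {
  d <- tiny_data(24)
  allsit <- list(windows = d$windows, labels = rep("SIT", 24))
  expect_error(train_posture_model(build_posture_model(tiny_cfg()),
                                   list(A = allsit, B = allsit),
                                   train_config(max_epochs = 1),
                                   holdout = "B"),
               "single class")
  expect_error(train_posture_model(build_posture_model(tiny_cfg()),
                                   list(A = d), train_config(),
                                   holdout = character(0)),
               "empty holdout")
})

test_that("model bundles round-trip predictions bit-for-bit", {
  d <- tiny_data(30)
  for (cfg in list(tiny_cfg(), tiny_cfg(rnn_hidden = 3, seed = 2),
                   tiny_cfg(conv_channels = c(5), seq_len_epochs = 1))) {
    m <- build_posture_model(cfg)
    m$fitted <- TRUE
    dir <- withr::local_tempdir()
    save_model(m, dir)
    m2 <- load_model(dir)
    expect_identical(predict_posture(m2, d$windows)$probs,
                     predict_posture(m, d$windows)$probs)
  }
  # version mismatch is flagged
  m <- build_posture_model(tiny_cfg()); m$fitted <- TRUE
  dir <- withr::local_tempdir()
  save_model(m, dir)
  sc <- jsonlite::read_json(file.path(dir, "model.json"))
  sc$format_version <- 99
  jsonlite::write_json(sc, file.path(dir, "model.json"), auto_unbox = TRUE)
  expect_error(load_model(dir), "version mismatch")
})

test_that("class probabilities always sum to one", {
  m <- build_posture_model(tiny_cfg()); m$fitted <- TRUE
  d <- tiny_data(12)
  pr <- predict_posture(m, d$windows)
  # predict_posture returns the sitting probability of a 2-class softmax;
  # verify normalization at the logit level
  cfg <- m$cfg
  arr <- d$windows
  Xm <- sitstand:::.standardize(sitstand:::windows_to_matrix(arr),
                                m$norm)
  y <- rep(1L, 12)
  res <- sitstand:::nn_loss(m$params, cfg, Xm, y, 4, 3)
  expect_equal(rowSums(res$probs), rep(1, 12))
})

test_that("grid selection prefers the smaller model on ties", {
  d <- list(A = tiny_data(36, seed = 5), B = tiny_data(36, seed = 6),
            C = tiny_data(36, seed = 7))
  tc <- train_config(lr = 3e-3, max_epochs = 10, batch_size = 4, seed = 3)
  small <- tiny_cfg()
  big <- tiny_cfg(conv_channels = c(4, 6, 6))
  gs <- grid_select(list(big, small), d, tc, selection = "C")
  expect_equal(nrow(gs$report), 2)
  if (abs(diff(gs$report$metric)) < 1e-12) {
    expect_equal(gs$winner, which.min(gs$report$n_params))
  } else {
    expect_equal(gs$winner, which.max(gs$report$metric))
  }
  one <- grid_select(list(small), d, tc, selection = "C")
  expect_equal(one$winner, 1)
})
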