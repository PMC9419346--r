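test_that("confusion metrics handle perfect, inverted and one-class input", {
  truth <- rep(c("SIT", "NONSIT"), 25)
  m <- confusion_metrics(truth, truth)
  expect_equal(unlist(m[c("sensitivity", "specificity", "balanced_accuracy",
                          "ppv", "npv", "kappa")]),
               c(sensitivity = 1, specificity = 1, balanced_accuracy = 1,
                 ppv = 1, npv = 1, kappa = 1))

  inv <- ifelse(truth == "SIT", "NONSIT", "SIT")
  mi <- confusion_metrics(inv, truth)
  expect_equal(mi$sensitivity, 0)
  expect_equal(mi$specificity, 0)
  expect_lte(mi$kappa, 0)

  # zero-denominator metrics are missing, not zero
  m1 <- confusion_metrics(rep("SIT", 4), rep("SIT", 4))
  expect_true(is.na(m1$specificity))
  expect_true(is.na(m1$npv))
  expect_equal(m1$sensitivity, 1)

  expect_error(confusion_metrics("SIT", c("SIT", "SIT")), "length mismatch")
})

test_that("balanced accuracy is exactly the mean of sensitivity and specificity", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(10:200, 1)
    truth <- sample(c("SIT", "NONSIT"), n, replace = TRUE)
    pred <- ifelse(stats::runif(n) < 0.8, truth,
                   ifelse(truth == "SIT", "NONSIT", "SIT"))
    m <- confusion_metrics(pred, truth)
    if (!is.na(m$balanced_accuracy))
      expect_identical(m$balanced_accuracy,
                       (m$sensitivity + m$specificity) / 2)
  }
})

test_that("sit-to-stand transitions are the first NONSIT epoch of each break", {
  es <- function(l) epoch_series(t0(), 10, l, source = "cpm")
  expect_equal(extract_transitions(es(c("SIT", "NONSIT"))), t0() + 10)
  expect_length(extract_transitions(es(c("NONSIT", "SIT"))), 0)
  tr <- extract_transitions(es(c("SIT", "SIT", "NONSIT", "NONSIT", "SIT",
                                 "NONSIT")))
  expect_equal(as.numeric(tr - t0(), units = "secs"), c(20, 50))
})

test_that("transition pairing follows the worked examples", {
  t_ <- as.numeric(t0())
  same <- transition_pairing(t_ + c(100, 400), t_ + c(100, 400))
  expect_equal(c(same$sensitivity, same$ppv), c(1, 1))

  one <- transition_pairing(t_ + 150, t_ + 100, tolerance_s = 60)
  expect_equal(c(one$sensitivity, one$ppv), c(1, 1))

  two <- transition_pairing(t_ + c(150, 170), t_ + 100, tolerance_s = 60)
  expect_equal(c(two$sensitivity, two$ppv), c(1, 0.5))

  out <- transition_pairing(t_ + 161.1, t_ + 100, tolerance_s = 60)
  expect_equal(c(out$sensitivity, out$ppv), c(0, 0))

  empty <- transition_pairing(numeric(0), t_ + 100)
  expect_equal(empty$sensitivity, 0)
  expect_true(is.na(empty$ppv))
  no_truth <- transition_pairing(t_ + 100, numeric(0))
  expect_true(is.na(no_truth$sensitivity))

  expect_error(transition_pairing(c(5, 1), c(1, 5)), "sorted")
})

test_that("pairing is symmetric under swapping pred/true", {
  set.seed(22)
  for (rep in 1:40) {
    a <- sort(stats::runif(sample(0:8, 1), 0, 3000))
    b <- sort(stats::runif(sample(0:8, 1), 0, 3000))
    f <- transition_pairing(a, b, tolerance_s = 120)
    r <- transition_pairing(b, a, tolerance_s = 120)
    expect_equal(f$n_matched, r$n_matched)
    expect_equal(f$sensitivity, r$ppv)
    expect_equal(f$ppv, r$sensitivity)
  }
})

test_that("sensitivity and ppv never decrease as the tolerance grows", {
  set.seed(23)
  for (rep in 1:40) {
    true <- sort(sample(seq(0, 7200, by = 10), sample(1:12, 1)))
    keep <- true[stats::runif(length(true)) < 0.8]
    pred <- sort(c(keep + sample(-90:90, length(keep), replace = TRUE),
                   sample(seq(0, 7200, by = 10), 2)))
    prev_s <- -1; prev_p <- -1
    for (tol in c(30, 60, 120, 300)) {
      tp <- transition_pairing(pred, true, tolerance_s = tol)
      expect_gte(tp$sensitivity, prev_s)
      expect_gte(tp$ppv, prev_p)
      prev_s <- tp$sensitivity; prev_p <- tp$ppv
    }
  }
})

test_that("Lin's CCC matches its closed forms", {
  x <- c(1, 2, 3, 4, 5, 8)
  expect_equal(lin_ccc(x, x), 1)
  # shift by c: 2 s^2 / (2 s^2 + c^2) with population variance
  s2 <- mean((x - mean(x))^2)
  for (c_ in c(0.5, 2, 10))
    expect_equal(lin_ccc(x, x + c_), 2 * s2 / (2 * s2 + c_^2))
  xz <- x - mean(x)
  expect_equal(lin_ccc(xz, -xz), -1)
  expect_error(lin_ccc(rep(1, 3), rep(1, 3)), "degenerate")
})

test_that("|CCC| never exceeds |Pearson correlation|", {
  set.seed(24)
  for (rep in 1:50) {
    x <- stats::rnorm(20)
    y <- 0.5 * x + stats::rnorm(20, sd = 0.7) + stats::runif(1, -1, 1)
    expect_lte(abs(lin_ccc(x, y)), abs(stats::cor(x, y)) + 1e-12)
  }
})

test_that("agreement statistics match direct recomputation", {
  mk <- function(vals, src) data.frame(
    participant = sprintf("P%02d", seq_along(vals)), season = 1L,
    total_sed_min_day = vals, source = src)
  truth <- mk(c(400, 450, 500, 390), "activpal")
  same <- agreement(mk(c(400, 450, 500, 390), "model"), truth,
                    variables = "total_sed_min_day")
  expect_equal(same$bias, 0)
  expect_equal(same$mae, 0)
  expect_equal(same$mape_pct, 0)
  expect_equal(same$spearman_rho, 1)
  expect_equal(same$ccc, 1)

  prop <- agreement(mk(c(400, 450, 500, 390) * 1.10, "model"), truth,
                    variables = "total_sed_min_day")
  expect_equal(prop$mape_pct, 10)

  set.seed(25)
  pv <- c(420, 430, 510, 380)
  rep_ <- agreement(mk(pv, "model"), truth, variables = "total_sed_min_day")
  d <- pv - c(400, 450, 500, 390)
  expect_equal(rep_$bias, mean(d))
  expect_equal(rep_$bias_sd, stats::sd(d))
  expect_equal(rep_$mae, mean(abs(d)))
  expect_equal(rep_$mape_pct, mean(abs(d) / c(400, 450, 500, 390)) * 100)
  expect_equal(rep_$spearman_rho,
               stats::cor(pv, c(400, 450, 500, 390), method = "spearman"))
  expect_equal(rep_$ccc, lin_ccc(c(400, 450, 500, 390), pv))
})

test_that("per-season reports aggregate with mean and SD across seasons", {
  pairs <- list(
    s1 = list(pred = c("SIT", "SIT", "NONSIT", "NONSIT"),
              truth = c("SIT", "NONSIT", "NONSIT", "NONSIT")),
    s2 = list(pred = c("SIT", "NONSIT", "SIT", "NONSIT"),
              truth = c("SIT", "NONSIT", "SIT", "NONSIT")))
  rep_ <- evaluate_epochs(pairs)
  expect_equal(nrow(rep_$per_season), 2)
  ba <- rep_$per_season$balanced_accuracy
  row <- rep_$summary[rep_$summary$metric == "balanced_accuracy", ]
  expect_equal(row$mean, mean(ba))
  expect_equal(row$sd, stats::sd(ba))
})
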