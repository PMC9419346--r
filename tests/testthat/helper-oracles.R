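# Independent brute-force reference implementations used to validate the
# package's algorithms. These deliberately use different mechanics (explicit
# per-minute loops, exhaustive enumeration) than the production code.

# Choi non-wear, minute-by-minute with explicit window checks.
oracle_choi <- function(counts, min_window = 90, tol = 2, flank = 30) {
  n <- length(counts)
  if (!n) return(logical(0))
  zero <- counts == 0
  absorbable <- logical(n)
  m <- 1
  while (m <= n) {
    if (!zero[m]) {
      a <- m
      while (m <= n && !zero[m]) m <- m + 1
      b <- m - 1
      if (b - a + 1 <= tol &&
          a - flank >= 1 && all(counts[(a - flank):(a - 1)] == 0) &&
          b + flank <= n && all(counts[(b + 1):(b + flank)] == 0)) {
        absorbable[a:b] <- TRUE
      }
    } else m <- m + 1
  }
  eff <- zero | absorbable
  nw <- logical(n)
  m <- 1
  while (m <= n) {
    if (eff[m]) {
      a <- m
      while (m <= n && eff[m]) m <- m + 1
      if (m - a >= min_window) nw[a:(m - 1)] <- TRUE
    } else m <- m + 1
  }
  nw
}

# run-length bout segmentation by explicit scan
oracle_bouts <- function(labels) {
  runs <- c(); cur <- 0
  for (l in labels) {
    if (l == "SIT") cur <- cur + 1
    else { if (cur > 0) runs <- c(runs, cur); cur <- 0 }
  }
  if (cur > 0) runs <- c(runs, cur)
  runs
}

oracle_breaks <- function(labels) {
  b <- 0L
  for (i in seq_len(length(labels) - 1))
    if (labels[i] == "SIT" && labels[i + 1] == "NONSIT") b <- b + 1L
  b
}

oracle_usual <- function(durations) {
  total <- sum(durations)
  for (x in sort(unique(durations)))
    if (sum(durations[durations <= x]) >= total / 2) return(x)
}

# exhaustive maximum-cardinality matching of true to predicted transitions
oracle_max_matching <- function(pred, true, tol) {
  best <- 0
  rec <- function(i, used, count) {
    if (count + (length(true) - i + 1) <= best) return()
    if (i > length(true)) { best <<- max(best, count); return() }
    rec(i + 1, used, count)  # leave true[i] unmatched
    for (j in seq_along(pred)) {
      if (!used[j] && abs(pred[j] - true[i]) <= tol) {
        used[j] <- TRUE
        rec(i + 1, used, count + 1)
        used[j] <- FALSE
      }
    }
  }
  rec(1, rep(FALSE, length(pred)), 0)
  best
}

# random valid SIT/NONSIT/UNWORN label sequence
random_labels <- function(n, p_unworn = 0.05) {
  sample(c("SIT", "NONSIT", "UNWORN"), n, replace = TRUE,
         prob = c(0.5, 0.45, p_unworn))
}

# mean per-axis variance of each 10-s window (the separability oracle)
window_variances <- function(arr) {
  apply(arr, 3, function(w) mean(apply(w, 2, stats::var)))
}

t0 <- function() sitstand:::parse_time("2015-06-01 08:00:00")
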