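# Independent reference implementations used as oracles. These are written
# as plain loops, deliberately different from the package's vectorised code.

# two-pass log-ratio SD: explicit ratio loop, then explicit two-pass variance
oracle_log_ratio_sd <- function(x) {
  logs <- c()
  for (i in seq_len(length(x) - 1)) {
    if (x[i] > 0 && x[i + 1] > 0) logs <- c(logs, log(x[i + 1]) - log(x[i]))
  }
  if (length(logs) < 2) return(NA_real_)
  m <- 0
  for (v in logs) m <- m + v / length(logs)
  ss <- 0
  for (v in logs) ss <- ss + (v - m)^2
  sqrt(ss / (length(logs) - 1))
}

# AUC by exhaustive pair counting with ties scored 1/2
oracle_auc_pairs <- function(cases, controls) {
  wins <- 0
  for (x in cases) {
    for (y in controls) {
      wins <- wins + if (x > y) 1 else if (x == y) 0.5 else 0
    }
  }
  wins / (length(cases) * length(controls))
}

# DeLong z and p from explicitly looped placement values
oracle_delong <- function(xa_cases, xa_controls, xb_cases, xb_controls) {
  m <- length(xa_cases)
  n <- length(xa_controls)
  psi <- function(x, y) if (x > y) 1 else if (x == y) 0.5 else 0
  v10 <- function(cases, controls, i) {
    s <- 0
    for (j in seq_len(n)) s <- s + psi(cases[i], controls[j])
    s / n
  }
  v01 <- function(cases, controls, j) {
    s <- 0
    for (i in seq_len(m)) s <- s + psi(cases[i], controls[j])
    s / m
  }
  va10 <- sapply(seq_len(m), function(i) v10(xa_cases, xa_controls, i))
  vb10 <- sapply(seq_len(m), function(i) v10(xb_cases, xb_controls, i))
  va01 <- sapply(seq_len(n), function(j) v01(xa_cases, xa_controls, j))
  vb01 <- sapply(seq_len(n), function(j) v01(xb_cases, xb_controls, j))
  ta <- mean(va10)
  tb <- mean(vb10)
  s10 <- matrix(0, 2, 2)
  for (i in seq_len(m)) {
    d <- c(va10[i] - ta, vb10[i] - tb)
    s10 <- s10 + outer(d, d) / (m - 1)
  }
  s01 <- matrix(0, 2, 2)
  for (j in seq_len(n)) {
    d <- c(va01[j] - ta, vb01[j] - tb)
    s01 <- s01 + outer(d, d) / (n - 1)
  }
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  z <- (ta - tb) / sqrt(v)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# exhaustive Youden scan over every candidate threshold (all midpoints and
# the score values themselves, both comparison directions at midpoints)
oracle_max_youden <- function(cases, controls) {
  cand <- sort(unique(c(cases, controls)))
  thr <- c(-Inf, cand, (cand[-1] + cand[-length(cand)]) / 2, Inf)
  best <- -Inf
  for (t in thr) {
    j <- mean(cases > t) + mean(controls <= t) - 1
    if (j > best) best <- j
  }
  best
}

# small deterministic typing session builder
make_session <- function(press, release, keys = NULL, subject = "S1",
                         visit = 1L) {
  n <- length(press)
  tibble::tibble(
    subject_id = subject, visit_index = as.integer(visit),
    key_id = keys %||% letters[(seq_len(n) - 1) %% 26 + 1],
    press_time = press, release_time = release
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
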