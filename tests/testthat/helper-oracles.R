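# Naive reference implementations: direct pattern histograms and O(N^2)
# double loops, written along an independent code path from the package
# (order()-based ranks, explicit loops, no Chebyshev shortcuts). Used to
# cross-check the estimators on short sequences.

oracle_pen <- function(x, n, normalize = TRUE) {
  ids <- character(0)
  for (i in seq_len(length(x) - n + 1)) {
    w <- x[i:(i + n - 1)]
    # stable sort twice: rank with ties broken by order of appearance
    ids <- c(ids, paste(order(order(w)), collapse = "_"))
  }
  p <- as.numeric(table(ids)) / length(ids)
  h <- -sum(p * log(p))
  if (normalize) h / log(factorial(n)) else h
}

oracle_mpen <- function(x, n, normalize = TRUE) {
  ids <- character(0)
  for (i in seq_len(length(x) - n + 1)) {
    w <- x[i:(i + n - 1)]
    dr <- vapply(w, function(v) 1L + sum(unique(w) < v), 1L)
    ids <- c(ids, paste(dr, collapse = "_"))
  }
  p <- as.numeric(table(ids)) / length(ids)
  h <- -sum(p * log(p))
  if (normalize) h / log(oracle_merged_count(n)) else h
}

# Ordered Bell numbers by the classical recurrence
# a(n) = sum_{k=1}^{n} choose(n, k) a(n - k), a(0) = 1 -- an independent
# route to the merged-rank pattern-universe size.
oracle_merged_count <- function(n) {
  a <- numeric(n + 1)
  a[1] <- 1
  for (m in seq_len(n)) {
    a[m + 1] <- sum(choose(m, seq_len(m)) * a[m + 1 - seq_len(m)])
  }
  a[n + 1]
}

oracle_sen <- function(x, m, r_frac) {
  r <- r_frac * sd(x)
  nt <- length(x) - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- 0
      for (k in 0:(m - 1)) dm <- max(dm, abs(x[i + k] - x[j + k]))
      if (dm <= r) {
        B <- B + 1
        dm1 <- max(dm, abs(x[i + m] - x[j + m]))
        if (dm1 <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

oracle_qsen <- function(x, m, r_frac) oracle_sen(x, m, r_frac) + log(2 * r_frac)

oracle_fen <- function(x, nexp, m, r_frac) {
  r <- r_frac * sd(x)
  nt <- length(x) - m
  phi_m <- 0; phi_m1 <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      vi <- x[i:(i + m - 1)]; vj <- x[j:(j + m - 1)]
      vi <- vi - mean(vi); vj <- vj - mean(vj)
      phi_m <- phi_m + exp(-max(abs(vi - vj))^nexp / r)
      wi <- x[i:(i + m)]; wj <- x[j:(j + m)]
      wi <- wi - mean(wi); wj <- wj - mean(wj)
      phi_m1 <- phi_m1 + exp(-max(abs(wi - wj))^nexp / r)
    }
  }
  -log(phi_m1 / phi_m)
}

# Distinct orbit values after merging values closer than tol.
count_distinct <- function(x, tol = 1e-6) {
  s <- sort(x)
  1L + sum(diff(s) > tol)
}

# Writes a single-column ASCII fixture and returns its path.
write_ascii_fixture <- function(values, trailing_blank = FALSE) {
  path <- tempfile(fileext = ".txt")
  lines <- format(values, trim = TRUE)
  if (trailing_blank) lines <- c(lines, "")
  writeLines(lines, path)
  path
}
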