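#' Ordinal patterns of a time series
#'
#' Encodes every window of `n` consecutive samples by the rank order of its
#' values (embedding delay fixed at 1 sample). Two tie rules are available:
#' `"order-of-appearance"` assigns tied samples distinct ranks in order of
#' appearance (the encoding behind permutation entropy), while
#' `"merged-rank"` gives tied samples one shared (dense) rank, enlarging the
#' pattern universe (the encoding behind modified permutation entropy).
#'
#' @param x Numeric vector, `length(x) >= n`.
#' @param n Pattern length (order), `n >= 2`.
#' @param tie_rule `"order-of-appearance"` or `"merged-rank"`.
#' @return Character vector of `length(x) - n + 1` pattern identifiers
#'   (dash-separated rank sequences).
#' @export
#' @examples
#' ordinal_patterns(c(4, 7, 9, 10, 6, 11, 3), 2)
#' ordinal_patterns(c(1, 1, 2), 3, tie_rule = "merged-rank")
ordinal_patterns <- function(x, n,
                             tie_rule = c("order-of-appearance",
                                          "merged-rank")) {
  tie_rule <- match.arg(tie_rule)
  if (!is.numeric(n) || length(n) != 1L || n < 2L) stop("`n` must be >= 2")
  if (length(x) < n) {
    stop("sequence shorter than the pattern length `n`")
  }
  nw <- length(x) - n + 1L
  enc <- if (tie_rule == "order-of-appearance") {
    function(v) rank(v, ties.method = "first")
  } else {
    function(v) match(v, sort(unique(v)))  # dense ranks, ties merged
  }
  vapply(seq_len(nw),
         function(i) paste(enc(x[i:(i + n - 1L)]), collapse = "-"),
         character(1))
}

#' Size of the merged-rank pattern universe
#'
#' Number of distinct tie-inclusive (dense-rank) patterns of length `n`,
#' found by exhaustive enumeration of rank assignments: every length-`n`
#' vector over `1..n` whose values form a contiguous set `1..k` is an
#' achievable dense ranking. (These counts are the ordered Bell numbers:
#' 3, 13, 75, 541, 4683 for n = 2..6.) Used as the normalisation
#' denominator for modified permutation entropy.
#'
#' @param n Pattern length, `2 <= n <= 7`.
#' @return Integer count.
#' @export
merged_pattern_count <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    stopifnot(n >= 1L, n <= 7L)
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    valid <- apply(grid, 1L, function(v) {
      u <- unique(v)
      length(u) == max(v) && min(v) == 1L
    })
    cache[[key]] <- sum(valid)
    cache[[key]]
  }
})

shannon <- function(freqs, log_base = "natural") {
  p <- freqs / sum(freqs)
  p <- p[p > 0]
  h <- -sum(p * log(p))
  if (log_base == "2") h / log(2) else h
}

logb_ <- function(v, log_base) if (log_base == "2") log2(v) else log(v)

#' Permutation entropy
#'
#' Shannon entropy of the empirical distribution of ordinal patterns of
#' order `n` (ties resolved by order of appearance). With
#' `normalize = TRUE` the value is divided by `log(n!)`, bounding it in
#' `[0, 1]`.
#'
#' @param x Numeric vector, `length(x) >= n + 1`. `n! < length(x)` is
#'   recommended for a well-populated pattern histogram.
#' @param n Pattern order (the study grid is 3-6).
#' @param normalize Divide by the log pattern-universe size?
#' @param log_base `"natural"` or `"2"`.
#' @return Entropy value.
#' @export
#' @examples
#' permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), n = 2, normalize = FALSE)
permutation_entropy <- function(x, n, normalize = TRUE,
                                log_base = c("natural", "2")) {
  log_base <- match.arg(log_base)
  if (length(x) < n + 1L) stop("sequence too short for order `n`")
  pat <- ordinal_patterns(x, n, "order-of-appearance")
  h <- shannon(table(pat), log_base)
  if (normalize) h / logb_(factorial(n), log_base) else h
}

#' Modified permutation entropy
#'
#' Shannon entropy of merged-rank (tie-inclusive) ordinal patterns: equal
#' samples share one rank, so ties form patterns of their own. With
#' `normalize = TRUE` the value is divided by the log of the full
#' tie-inclusive pattern count ([merged_pattern_count]); because continuous
#' noise never realises tie patterns, normalized values saturate near
#' `log(n!) / log(count)` (about 0.70 for `n = 3`) rather than 1.
#'
#' @inheritParams permutation_entropy
#' @param n Pattern order (the study grid is 3-5).
#' @return Entropy value.
#' @export
modified_permutation_entropy <- function(x, n, normalize = TRUE,
                                         log_base = c("natural", "2")) {
  log_base <- match.arg(log_base)
  if (length(x) < n + 1L) stop("sequence too short for order `n`")
  pat <- ordinal_patterns(x, n, "merged-rank")
  h <- shannon(table(pat), log_base)
  if (normalize) h / logb_(merged_pattern_count(n), log_base) else h
}

#' Sample entropy
#'
#' `-log(A / B)`, where `B` counts pairs of length-`m` templates whose
#' Chebyshev distance is within the tolerance and `A` the corresponding
#' length-`(m + 1)` pairs. Self-matches are excluded; the tolerance is
#' `r` times the standard deviation of `x` (so in windowed analysis each
#' window is scaled by its own SD). If either count is zero the ratio is
#' undefined and `NA` is returned (never a silent `Inf`).
#'
#' @param x Numeric vector, `length(x) > m + 1`.
#' @param m Embedding dimension (study grid 1-2).
#' @param r Tolerance as a fraction of `sd(x)` (study grid 0.1-0.25).
#' @return Entropy value (natural log), or `NA` when undefined.
#' @export
sample_entropy <- function(x, m, r) {
  stopifnot(m >= 1L, r > 0)
  if (length(x) <= m + 1L) stop("sequence too short for embedding `m`")
  s <- stats::sd(x)
  if (s == 0) return(0)  # constant series: all templates match at both lengths
  counts <- sampen_counts(as.numeric(x), as.integer(m), r * s)
  if (counts[["A"]] == 0 || counts[["B"]] == 0) return(NA_real_)
  -log(counts[["A"]] / counts[["B"]])
}

#' Quadratic sample entropy
#'
#' Sample entropy normalised by the volume of the matching region:
#' `QSEn(m, r, N) = SEn(m, r, N) + log(2 r)` (natural log, matching the
#' sample-entropy log). The additive term makes values comparable across
#' different tolerances, so `r` can range beyond the usual sample-entropy
#' grid (study grids 0.2-0.8 and 0.4-1).
#'
#' @inheritParams sample_entropy
#' @return Entropy value, or `NA` when the sample entropy is undefined.
#' @export
quadratic_sample_entropy <- function(x, m, r) {
  se <- sample_entropy(x, m, r)
  se + log(2 * r)
}

#' Fuzzy entropy
#'
#' Embedding entropy in which the hard Heaviside match of sample entropy is
#' replaced by the graded similarity `exp(-d^n / r)`, with `d` the
#' Chebyshev distance between templates. Templates are baseline-removed
#' (each embedded vector has its own mean subtracted) by default. The
#' result is `-log(phi_{m+1} / phi_m)` with `phi` the average pairwise
#' similarity, self-matches excluded.
#'
#' @inheritParams sample_entropy
#' @param n Similarity-shape exponent (study grid 1-3).
#' @param baseline Subtract each template's own mean before comparing?
#' @return Entropy value (natural log); all-identical templates give 0.
#' @export
fuzzy_entropy <- function(x, n, m, r, baseline = TRUE) {
  stopifnot(n >= 1L, m >= 1L, r > 0)
  if (length(x) <= m + 1L) stop("sequence too short for embedding `m`")
  s <- stats::sd(x)
  if (s == 0) return(0)
  phis <- fuzzy_phis(as.numeric(x), as.integer(m), r * s, n, baseline)
  -log(phis[["phi_m1"]] / phis[["phi_m"]])
}

#' Entropy estimator configurations
#'
#' Constructors for tagged estimator settings, used by [compute_entropy()],
#' [entropy_curve()] and [batch_entropy()]. Each carries the algorithm
#' family, its parameters, and a display label such as `"SEn(m=2,r=0.2)"`.
#'
#' @param n Pattern order (PEn/MPEn) or similarity exponent (FEn).
#' @param normalize Normalise PEn/MPEn by the log pattern-universe size?
#' @param log_base `"natural"` or `"2"` (PEn/MPEn only).
#' @param m Embedding dimension. @param r Tolerance (fraction of SD).
#' @param baseline Baseline-removal flag (FEn only).
#' @return An object of class `entropy_config`.
#' @name entropy_config
NULL

new_config <- function(family, params, label) {
  structure(list(family = family, params = params, label = label),
            class = "entropy_config")
}

#' @rdname entropy_config
#' @export
cfg_pen <- function(n = 3, normalize = TRUE, log_base = "natural") {
  new_config("PEn", list(n = n, normalize = normalize, log_base = log_base),
             sprintf("PEn(n=%d)", n))
}

#' @rdname entropy_config
#' @export
cfg_mpen <- function(n = 3, normalize = TRUE, log_base = "natural") {
  new_config("MPEn", list(n = n, normalize = normalize, log_base = log_base),
             sprintf("MPEn(n=%d)", n))
}

#' @rdname entropy_config
#' @export
cfg_sen <- function(m = 2, r = 0.2) {
  new_config("SEn", list(m = m, r = r), sprintf("SEn(m=%d,r=%g)", m, r))
}

#' @rdname entropy_config
#' @export
cfg_qsen <- function(m = 2, r = 0.6) {
  new_config("QSEn", list(m = m, r = r), sprintf("QSEn(m=%d,r=%g)", m, r))
}

#' @rdname entropy_config
#' @export
cfg_fen <- function(n = 1, m = 2, r = 0.2, baseline = TRUE) {
  new_config("FEn", list(n = n, m = m, r = r, baseline = baseline),
             sprintf("FEn(n=%d,m=%d,r=%g)", n, m, r))
}

#' @export
print.entropy_config <- function(x, ...) {
  cat("<entropy_config>", x$label, "\n")
  invisible(x)
}

#' Evaluate an estimator configuration on a series
#'
#' @param x Numeric vector (or [ent_signal]).
#' @param cfg An [entropy_config].
#' @return Entropy value (`NA` when undefined).
#' @export
compute_entropy <- function(x, cfg) {
  stopifnot(inherits(cfg, "entropy_config"))
  if (inherits(x, "ent_signal")) x <- x$samples
  p <- cfg$params
  switch(cfg$family,
    PEn  = permutation_entropy(x, p$n, p$normalize, p$log_base),
    MPEn = modified_permutation_entropy(x, p$n, p$normalize, p$log_base),
    SEn  = sample_entropy(x, p$m, p$r),
    QSEn = quadratic_sample_entropy(x, p$m, p$r),
    FEn  = fuzzy_entropy(x, p$n, p$m, p$r, p$baseline),
    stop("unknown entropy family: ", cfg$family)
  )
}

#' The study's default estimator parameter grids
#'
#' The 47 configurations evaluated in the EEG study: PEn with n = 3..6,
#' MPEn with n = 3..5, SEn with m = 1..2 crossed with r = 0.1, 0.15, 0.2,
#' 0.25, QSEn with m = 1..2 crossed with `qsen_r`, and FEn with
#' n = 1..3 crossed with the SEn grid. Two QSEn tolerance presets are
#' shipped (`0.2-0.8` and `0.4-1`), both used in the study at different
#' stages.
#'
#' @param qsen_r QSEn tolerance grid.
#' @return List of [entropy_config] objects (length 47 for the defaults).
#' @export
default_entropy_grids <- function(qsen_r = c(0.2, 0.4, 0.6, 0.8)) {
  cfgs <- list()
  for (n in 3:6) cfgs <- c(cfgs, list(cfg_pen(n)))
  for (n in 3:5) cfgs <- c(cfgs, list(cfg_mpen(n)))
  for (m in 1:2) for (r in c(0.1, 0.15, 0.2, 0.25)) {
    cfgs <- c(cfgs, list(cfg_sen(m, r)))
  }
  for (m in 1:2) for (r in qsen_r) cfgs <- c(cfgs, list(cfg_qsen(m, r)))
  for (n in 1:3) for (m in 1:2) for (r in c(0.1, 0.15, 0.2, 0.25)) {
    cfgs <- c(cfgs, list(cfg_fen(n, m, r)))
  }
  cfgs
}
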