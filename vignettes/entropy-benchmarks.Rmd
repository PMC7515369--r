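---
title: "Entropy estimators, synthetic benchmarks, and the EEG study pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy estimators, synthetic benchmarks, and the EEG study pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`entrobench` implements five entropy estimators used to quantify the
complexity of biomedical time series, a suite of ten synthetic benchmark
signals engineered to probe what each estimator responds to, a
sliding-window engine that turns signals into entropy-versus-time curves,
and the downstream study pipeline for EEG group comparisons (band-pass
preprocessing, nonparametric tests, k-NN classification over entropy
features). This vignette explains the models, the parameters that matter,
the numerical choices, and the limits of what the synthetic validation can
show.

# The five estimators

## Permutation entropy (PEn)

Each window of `n` consecutive samples is encoded by the permutation that
sorts it; PEn is the Shannon entropy of the empirical distribution of these
ordinal patterns, normalised by `log(n!)` so that values lie in [0, 1].
Ties are resolved by order of appearance. The embedding delay is fixed at
one sample throughout the package: none of the analyses here vary it, and a
fixed delay keeps the pattern distributions comparable across estimators.
The supported study grid is `n` = 3–6; `n` must stay well below `log(N)!`
territory so the pattern histogram is populated (`permutation_entropy()`
enforces only the hard length requirement and leaves grid discipline to the
caller).

## Modified permutation entropy (MPEn)

MPEn gives tied samples a single shared (dense) rank, so ties form
patterns of their own. The pattern universe is therefore larger: its size
is the ordered Bell number of `n` (13 for `n` = 3, 75 for `n` = 4, 541 for
`n` = 5, 4683 for `n` = 6). The package computes these by exhaustive
enumeration of achievable dense rankings (`merged_pattern_count()`) rather
than trusting any published constant, and the test suite cross-checks the
enumeration against the classical ordered-Bell recurrence. A practical
consequence: continuous-valued noise never realises tie patterns, so only
`n!` of the patterns ever occur and normalized MPEn saturates near
`log(n!) / log(universe)` — about 0.70 for `n` = 3 — rather than 1. The
study grid is `n` = 3–5.

## Sample entropy (SEn)

SEn is `-log(A/B)`, where `B` counts pairs of length-`m` templates whose
Chebyshev distance is at most `r` and `A` the matching length-`(m+1)`
pairs. Conventions follow Richman–Moorman: `N - m` templates (so every
length-`m` template has an extension), self-matches excluded. The
tolerance `r` is a *fraction of the standard deviation of the exact series
passed in* — in windowed analysis each window is rescaled by its own SD,
treating every window as an independent series. Whether a whole-signal SD
would be preferable cannot be decided from first principles; per-window SD
is the package default because windowed analysis otherwise leaks
information across regime boundaries that the curves are meant to detect.
When `A` or `B` is zero the ratio is undefined and the estimator returns
`NA` (never a silent `Inf`); curves flag such windows and report their
count. Study grid: `m` = 1–2, `r` = 0.1–0.25.

## Quadratic sample entropy (QSEn)

`QSEn(m, r, N) = SEn(m, r, N) + log(2r)`: normalising the match count by
the volume of the matching region converts the conditional probability to
a density, which makes values comparable across tolerances and lets `r`
range more freely. The additive term uses the same natural log as SEn.
Two tolerance presets are shipped (0.2–0.8 and 0.4–1), both used in the
study at different stages; `default_entropy_grids(qsen_r = ...)` selects
between them.

## Fuzzy entropy (FEn)

FEn replaces the hard Heaviside match with the graded similarity
`exp(-d^n / r)`, where `d` is the Chebyshev distance between
baseline-removed templates (each embedded vector minus its own mean; the
removal is toggleable for cross-checks). The exponent `n` (1–3) shapes
the similarity kernel. One property worth flagging: because the formula
divides `d^n` by `r` — not by `r^n` — FEn is affine-invariant only for
`n` = 1. For `n` = 2 or 3 the estimator is deliberately scale-sensitive;
the SD-relative tolerance softens but does not remove this. The package
implements the formula as published and documents the asymmetry instead of
"fixing" it.

All estimators default to natural logarithms; PEn and MPEn also accept
base 2. The log base of QSEn's correction term always follows SEn's.

# The synthetic benchmark suite

All ten signals are sampled at 256 Hz for 40 s (10 240 samples), matching
standard EEG acquisition, with regime changes at t = 10/20/30 s where the
signal is stepped. `benchmark_suite(seed)` expands one master seed into
independent per-generator streams, so the suite is bit-reproducible while
generators stay independently usable.

1. **Constant-amplitude chirp** — frequency sweeps linearly 0.5→5 Hz;
   probes pure frequency sensitivity.
2. **Modulated chirp** — the same chirp under a 0.05-Hz cosine envelope
   (amplitude 0.25, offset 0.75); probes amplitude-modulation sensitivity.
3. **Harmonic stack** — segments with 1, 2, 5, 7 components, frequencies
   log-spaced 0.4–100 Hz per segment, amplitudes log-spaced 0.5–0.005 so
   the highest frequency is weakest (a 1/f-like spectrum, the shape EEG
   rhythms approximate). The source description gives only the endpoint
   amplitudes; log spacing per segment is this package's reading, chosen
   for the 1/f analogy, and the spacing helper is exposed for inspection.
4. **Quasi-periodic + noise** — 0.61-Hz and 1-Hz sinusoids under a slow
   modulator, with white Gaussian noise of SD 0/0.1/0.3/0.5 per segment.
   "Noise magnitude" is interpreted as standard deviation.
5. **WGN, stepped power** — four independent Gaussian segments with
   variances 0.1/0.3/0.5/0.7. "Power" is interpreted as variance.
6. **WGN, stepped bandwidth** — one realisation, segments low-pass
   filtered at 30/60/100 Hz (Hamming FIR, order 425), last segment
   unfiltered.
7. **MIX process** — per sample, a Bernoulli(p) switch selects uniform
   noise on (-3, 3) or the period-12 sequence `2 sin(2 pi k / 12)`; `p`
   sweeps 0.9→0.1 (randomness → determinism). The construction is
   `(1 - z) x + z y`; the package follows the standard MIX definition with
   the uniform term present.
8. **AR(1) sweep** — `x_k = p_k x_{k-1} + e_k` with unit-variance Gaussian
   innovations (the innovation scale is immaterial to SD-relative and
   rank-based estimators), coefficient swept +0.9→-0.9 per sample across
   the retained record after a 100-sample burn-in at the initial
   coefficient.
9. **Logistic map** — `x_k = mu x_{k-1} (1 - x_{k-1})` from `x0 = 0.3`,
   20 s at `mu = 3.55` (a period-8 orbit) then 20 s at `mu = 3.8`
   (chaotic). The 100-iterate burn-in is applied independently per
   segment so each regime sits on its attractor from its first retained
   sample.
10. **Lorenz system** — the x-coordinate under (sigma, beta, rho) =
    (10, 8/3, 28) (chaotic) then (10, 8/3, 99.96) (a torus knot), each
    half standardised to unit SD. Integration is fixed-step RK4 with
    `dt = 1/256` s, initial state (1, 1, 1), and a 10-s discarded
    transient per parameter set — all configurable; fixed-step keeps the
    output exactly reproducible and uniformly sampled.

**Surrogate EEG classes.** `gen_surrogate_classes()` produces labelled
AR(1)-based segments whose classes differ in regularity (optionally with
an added sinusoid). They exist so the full study pipeline — feature
table, group tests, classification — runs end to end without external
data. They emulate controllable regularity differences only: no 1/f
spectral shape, no nonstationarity, no artefacts, no inter-subject
variability. A pipeline that separates them demonstrates the machinery
and the direction of the constructed effect (more regular → lower SEn),
not clinical performance on real EEG.

# Windowed analysis

Entropy curves use 10-s windows with 90% overlap (a 1-s hop), timestamped
at the *window end*, so a 40-s signal yields 31 values at t = 10, 11, …,
40 s. Windows straddling a regime boundary mix two regimes; curves keep
them (they are part of the observable), but the step-change statistic
`transition_contrast()` excludes them and compares clean-regime means
only. Undefined windows (SEn/QSEn with zero matches) are kept as flagged
`NA`s and messaged, never silently dropped or imputed.

# The EEG study pipeline

`load_ascii_segment()` reads the single-column ASCII format of the public
epilepsy EEG releases (one value per line; 173.61 Hz / 23.6-s segments in
the surface-and-intracranial study, 512 Hz / 20-s segments in the
focal/non-focal study). `bandpass_fir()` applies the study's order-425
Hamming FIR band-pass (0.5–40 Hz, suppressing DC and 50-Hz mains).
Filtering is zero-phase (forward–backward) so filtered samples stay
time-aligned; since a forward–backward pass of a long FIR leaves visible
edge transients, the input is extended by a mirrored margin of one filter
length at each end and trimmed after filtering. The filtered segment is
then used whole — whole-segment entropies feed the tests — matching the
study design; no trimming beyond the mirrored margin is applied.

Group comparisons are a pure function of the declared design: paired
two-group data get a Wilcoxon signed-rank test (eyes-open/eyes-closed
segments pair by index as repeated measurements), independent two-group
data a Mann–Whitney U test, three or more independent groups a
Kruskal–Wallis test, with pairwise Mann–Whitney post-hocs. P-values are
two-sided, exact where the underlying routines provide exactness, reported
raw (the study reports uncorrected tests) with an optional Holm flag, and
judged at alpha = 0.01.

Classification is k-NN with k = 3 under stratified 10-fold
cross-validation. Features are z-scored with statistics fitted on the
training folds only — k-NN over mixed-scale entropy features is otherwise
dominated by whichever feature happens to have the widest range — and the
flag is toggleable for faithfulness experiments. Voting ties are broken
by the single nearest neighbour, making predictions deterministic given
the folds; with the seed fixing the folds, reports are byte-identical
across runs. Both the mean of the 10 fold accuracies and the pooled
prediction accuracy are reported. The combination search enumerates
feature sets of size 1–5 under the family-exclusion rule (no set contains
two settings of the same algorithm), ranking by mean accuracy with ties
broken by smaller set then lexicographic order.

# Numerical choices and edge cases

- Embedding-entropy pair counting runs in compiled code; the naive
  R double-loop references live in the test suite and agree to 1e-10.
- Constant series: SEn and FEn return 0 (all templates match); PEn
  returns 0 (a single pattern); these are valid values, not errors.
- SD uses the sample (n-1) convention everywhere.
- `sample_entropy` returns `NA` for zero match counts; `batch_entropy`
  propagates `NA` into the feature table and `knn_cross_validate` drops
  incomplete rows with a logged count.
- Degenerate paired tests (all differences zero) return a tagged
  degenerate result with `NA` p-value instead of failing.
- Problem sizes used in the shipped analyses: 10 240-sample signals, 31
  windows per curve, 50 segments per surrogate class, and a size-2
  combination search over the 47-configuration grid — small enough to
  re-run interactively while large enough for stable rank statistics.

# Known limitations

- The harmonic-stack amplitude spacing and the MIX printed construction
  involve interpretation (documented above); alternative readings are a
  parameter change away.
- Rank-based estimators saturate on any vestigial high-frequency
  component regardless of its amplitude (visible in the harmonic stack,
  where PEn jumps to its ceiling once a weak 100-Hz component enters
  while SEn shows the graded increase).
- FEn with exponent > 1 is scale-sensitive by construction (see above).
- The surrogate classes validate machinery, not clinical claims; real-EEG
  accuracies require the original datasets, which are not shipped or
  fetched.
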