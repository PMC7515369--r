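#' Synthetic benchmark signal generators
#'
#' Ten generators produce the benchmark suite used to characterise the
#' entropy estimators: chirps (constant and modulated amplitude), a growing
#' harmonic stack, a quasi-periodic signal with stepped noise, white
#' Gaussian noise with stepped power and stepped bandwidth, a MIX process,
#' an AR(1) coefficient sweep, a logistic map, and a Lorenz system. All
#' default to 256 Hz sampling and 40 s duration (10 240 samples), with four
#' 10-s regimes where the signal structure steps.
#'
#' Stochastic generators take a `seed`; with a fixed seed the output is
#' bit-reproducible and the caller's RNG state is left untouched.
#'
#' @name generators
NULL

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Deterministic sub-stream seeds: one master seed expands to independent
# per-generator seeds (kept < 2^31 and exact in doubles).
derive_seed <- function(master, index) {
  as.integer(((master %% 46337) * 46337 + index * 101) %% 2147483647)
}

#' Linear chirp, constant or modulated amplitude
#'
#' Pure sinusoid whose instantaneous frequency sweeps linearly from `f0` to
#' `f1` over the full duration. With `modulated = TRUE` the unit envelope is
#' replaced by `0.75 + 0.25 * cos(2 * pi * 0.05 * t)`.
#'
#' @param f0,f1 Start and end frequencies in Hz; `0 < f0 < f1 < fs / 2`.
#' @param modulated Apply the 0.05-Hz cosine amplitude modulation?
#' @param fs Sampling rate (Hz). @param duration Length (s).
#' @return An [ent_signal].
#' @export
gen_chirp <- function(f0 = 0.5, f1 = 5, modulated = FALSE,
                      fs = 256, duration = 40) {
  if (!(0 < f0 && f0 < f1)) stop("need 0 < f0 < f1")
  if (f1 >= fs / 2) stop("f1 must be below the Nyquist frequency fs/2")
  t <- time_axis(fs, duration)
  phase <- 2 * pi * (f0 * t + (f1 - f0) / (2 * duration) * t^2)
  env <- if (modulated) 0.75 + 0.25 * cos(2 * pi * 0.05 * t) else 1
  ent_signal(env * sin(phase), fs,
             label = if (modulated) "modulated amplitude chirp"
                     else "constant amplitude chirp")
}

log_spaced <- function(from, to, n) {
  if (n == 1L) from else exp(seq(log(from), log(to), length.out = n))
}

#' Stacked harmonics with stepped component count
#'
#' Four consecutive segments containing 1, 2, 5 and 7 sinusoidal components.
#' Within each segment the component frequencies are log-spaced between
#' `f_base` and `f_top` and the amplitudes log-spaced from `a_base` down to
#' `a_top`, so the highest-frequency component has the smallest amplitude
#' (a 1/f-like profile).
#'
#' @param counts Harmonic counts per segment.
#' @param f_base,f_top Frequency range (Hz) spanned by each segment's
#'   components. @param a_base,a_top Corresponding amplitude range.
#' @inheritParams gen_chirp
#' @return An [ent_signal] with four regime segments.
#' @export
gen_harmonic_stack <- function(counts = c(1, 2, 5, 7),
                               f_base = 0.4, f_top = 100,
                               a_base = 0.5, a_top = 0.005,
                               fs = 256, duration = 40) {
  if (f_top >= fs / 2) stop("highest harmonic must be below fs/2")
  seg_dur <- duration / length(counts)
  ts <- time_axis(fs, seg_dur)
  x <- unlist(lapply(counts, function(k) {
    fr <- log_spaced(f_base, f_top, k)
    am <- log_spaced(a_base, a_top, k)
    colSums(am * sin(2 * pi * fr %o% ts))
  }))
  ent_signal(x, fs, label = "increasing number of harmonics",
             segments = four_segments(duration,
                                      sprintf("%d harmonics", counts)))
}

#' Quasi-periodic signal with stepped additive noise
#'
#' Sum of 0.61-Hz and 1-Hz sinusoids under a slow cosine modulator
#' (0.05 Hz, amplitude 0.1, offset 1), with white Gaussian noise of
#' standard deviation 0, 0.1, 0.3 and 0.5 added to the four segments.
#'
#' @param noise_sd Noise standard deviation per segment.
#' @param seed Integer seed for the noise.
#' @inheritParams gen_chirp
#' @return An [ent_signal] with four regime segments.
#' @export
gen_quasiperiodic_noise <- function(noise_sd = c(0, 0.1, 0.3, 0.5),
                                    fs = 256, duration = 40, seed = NULL) {
  t <- time_axis(fs, duration)
  base <- (1 + 0.1 * cos(2 * pi * 0.05 * t)) *
    (sin(2 * pi * 0.61 * t) + sin(2 * pi * 1 * t))
  seg_len <- length(t) / length(noise_sd)
  noise <- with_seed_if(seed,
    unlist(lapply(noise_sd, function(s) rnorm(seg_len, 0, s))))
  ent_signal(base + noise, fs, label = "quasi-periodic with stepped noise",
             segments = four_segments(duration,
                                      sprintf("noise SD %.2g", noise_sd)))
}

#' Quasi-periodic base signal without noise
#'
#' The noiseless carrier-plus-modulator used by
#' [gen_quasiperiodic_noise()]; exposed so residual noise can be isolated.
#' @inheritParams gen_chirp
#' @return Numeric vector of samples.
#' @export
quasiperiodic_base <- function(fs = 256, duration = 40) {
  t <- time_axis(fs, duration)
  (1 + 0.1 * cos(2 * pi * 0.05 * t)) *
    (sin(2 * pi * 0.61 * t) + sin(2 * pi * 1 * t))
}

#' White Gaussian noise with stepped power
#'
#' Four independent zero-mean Gaussian segments with variances (powers)
#' 0.1, 0.3, 0.5 and 0.7.
#'
#' @param powers Variance per segment.
#' @inheritParams gen_quasiperiodic_noise
#' @return An [ent_signal] with four regime segments.
#' @export
gen_wgn_power_steps <- function(powers = c(0.1, 0.3, 0.5, 0.7),
                                fs = 256, duration = 40, seed = NULL) {
  seg_len <- round(fs * duration) / length(powers)
  x <- with_seed_if(seed,
    unlist(lapply(powers, function(p) rnorm(seg_len, 0, sqrt(p)))))
  ent_signal(x, fs, label = "WGN of increasing power",
             segments = four_segments(duration,
                                      sprintf("variance %.2g", powers)))
}

#' White Gaussian noise with stepped bandwidth
#'
#' One white-noise realisation; the first three segments are low-pass
#' filtered at `cutoffs` Hz with a Hamming-window FIR filter of the given
#' order (applied forward-backward), and the final segment is left
#' unfiltered.
#'
#' @param cutoffs Low-pass cut-off frequencies (Hz) for segments 1-3.
#' @param order FIR filter order.
#' @inheritParams gen_quasiperiodic_noise
#' @return An [ent_signal] with four regime segments.
#' @export
gen_wgn_bandwidth_steps <- function(cutoffs = c(30, 60, 100), order = 425,
                                    fs = 256, duration = 40, seed = NULL) {
  if (any(cutoffs >= fs / 2)) stop("cut-off frequencies must be below fs/2")
  n <- round(fs * duration)
  raw <- with_seed_if(seed, rnorm(n))
  seg_len <- n / (length(cutoffs) + 1L)
  segs <- split(raw, rep(seq_len(length(cutoffs) + 1L), each = seg_len))
  filtered <- lapply(seq_along(cutoffs), function(i) {
    fir_apply(signal::fir1(order, cutoffs[i] / (fs / 2), type = "low"),
              segs[[i]])
  })
  x <- c(unlist(filtered), segs[[length(segs)]])
  ent_signal(x, fs, label = "WGN of increasing bandwidth",
             segments = four_segments(duration,
                                      c(sprintf("low-pass %g Hz", cutoffs),
                                        "unfiltered")))
}

#' MIX process with swept mixing probability
#'
#' Per sample `k`, a Bernoulli variable `z_k` with probability `p_k` selects
#' between the period-12 deterministic sequence `x_k = 2 sin(2 pi k / 12)`
#' (`z = 0`) and a Uniform(-3, 3) draw (`z = 1`):
#' `MIX_k = (1 - z_k) x_k + z_k y_k`. `p` is swept linearly from `p_start`
#' to `p_end`, so the default models a transition from randomness
#' (p = 0.9) to deterministic periodicity (p = 0.1).
#'
#' @param p_start,p_end Mixing probabilities in `[0, 1]` at the first and
#'   last sample.
#' @inheritParams gen_quasiperiodic_noise
#' @return An [ent_signal].
#' @export
gen_mix <- function(p_start = 0.9, p_end = 0.1,
                    fs = 256, duration = 40, seed = NULL) {
  stopifnot(p_start >= 0, p_start <= 1, p_end >= 0, p_end <= 1)
  n <- round(fs * duration)
  k <- seq_len(n)
  xdet <- 2 * sin(2 * pi * k / 12)
  p <- seq(p_start, p_end, length.out = n)
  x <- with_seed_if(seed, {
    y <- runif(n, -3, 3)
    z <- rbinom(n, 1, p)
    (1 - z) * xdet + z * y
  })
  ent_signal(x, fs, label = "MIX process")
}

#' Deterministic component of the MIX process
#' @param n Number of samples.
#' @return `2 * sin(2 * pi * k / 12)` for `k = 1..n`.
#' @export
mix_deterministic <- function(n) 2 * sin(2 * pi * seq_len(n) / 12)

#' AR(1) process with swept coefficient
#'
#' First-order autoregressive process `x_k = p_k x_{k-1} + e_k` with
#' unit-variance Gaussian innovations. The coefficient is swept linearly
#' from `p_start` to `p_end` across the retained record, modelling the
#' transfer of coloured-noise energy from low to high frequencies. The
#' first `burn_in` samples (generated at `p_start`) are discarded.
#'
#' @param p_start,p_end AR coefficients, each with `|p| < 1`.
#' @param burn_in Samples discarded before the retained record.
#' @inheritParams gen_quasiperiodic_noise
#' @return An [ent_signal].
#' @export
gen_ar1_sweep <- function(p_start = 0.9, p_end = -0.9, burn_in = 100,
                          fs = 256, duration = 40, seed = NULL) {
  if (max(abs(c(p_start, p_end))) >= 1) {
    stop("|p| must stay below 1 (stationarity)")
  }
  n <- round(fs * duration)
  p <- seq(p_start, p_end, length.out = n)
  x <- with_seed_if(seed, {
    e <- rnorm(burn_in + n)
    prev <- 0
    for (i in seq_len(burn_in)) prev <- p_start * prev + e[i]
    out <- numeric(n)
    for (i in seq_len(n)) {
      prev <- p[i] * prev + e[burn_in + i]
      out[i] <- prev
    }
    out
  })
  ent_signal(x, fs, label = "AR(1) coefficient sweep")
}

# Iterate the logistic map x_k = mu * x_{k-1} * (1 - x_{k-1}).
logistic_orbit <- function(mu, x0, n, burn_in = 0) {
  if (mu <= 0 || mu > 4) stop("mu must lie in (0, 4]")
  if (x0 <= 0 || x0 >= 1) stop("x0 must lie in (0, 1)")
  x <- x0
  for (i in seq_len(burn_in)) x <- mu * x * (1 - x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- mu * x * (1 - x)
    out[i] <- x
  }
  if (any(out <= 0 | out >= 1)) stop("logistic iterate escaped (0, 1)")
  out
}

#' Logistic map with stepped control parameter
#'
#' Iterates `x_k = mu * x_{k-1} * (1 - x_{k-1})`. The default produces a
#' 20-s period-8 regime (`mu = 3.55`) followed by a 20-s chaotic regime
#' (`mu = 3.8`). Each segment starts from `x0` and discards `burn_in`
#' iterates so that every regime is on its attractor.
#'
#' @param mu_segments Control parameter per (equal-length) segment.
#' @param x0 Starting point in (0, 1). @param burn_in Iterates discarded at
#'   the start of each segment.
#' @inheritParams gen_chirp
#' @return An [ent_signal] with one regime segment per `mu`.
#' @export
gen_logistic <- function(mu_segments = c(3.55, 3.8), x0 = 0.3,
                         burn_in = 100, fs = 256, duration = 40) {
  seg_len <- round(fs * duration) / length(mu_segments)
  x <- unlist(lapply(mu_segments,
                     function(mu) logistic_orbit(mu, x0, seg_len, burn_in)))
  ent_signal(x, fs, label = "logistic map",
             segments = four_segments(duration,
                                      sprintf("mu = %.3g", mu_segments)))
}

#' Lorenz system x-coordinate with stepped parameters
#'
#' Integrates the Lorenz equations `dx = sigma (y - x)`,
#' `dy = x (rho - z) - y`, `dz = x y - beta z` with fixed-step RK4 at step
#' `dt`, one trajectory per parameter set, each preceded by a discarded
#' transient. The default pairs the chaotic set (sigma 10, beta 8/3,
#' rho 28) with the torus-knot set (rho 99.96), 20 s each, and
#' standardises each part to unit standard deviation.
#'
#' @param param_sets List of named vectors with `sigma`, `beta`, `rho`.
#' @param dt Integration and sampling step (s). @param transient Discarded
#'   lead-in per parameter set (s). @param init Initial state.
#' @inheritParams gen_chirp
#' @return An [ent_signal] with one regime segment per parameter set.
#' @export
gen_lorenz <- function(param_sets = list(c(sigma = 10, beta = 8 / 3, rho = 28),
                                         c(sigma = 10, beta = 8 / 3,
                                           rho = 99.96)),
                       dt = 1 / 256, transient = 10,
                       fs = 256, duration = 40, init = c(1, 1, 1)) {
  seg_dur <- duration / length(param_sets)
  seg_len <- round(fs * seg_dur)
  deriv <- function(t, s, p) {
    list(c(p[["sigma"]] * (s[2] - s[1]),
           s[1] * (p[["rho"]] - s[3]) - s[2],
           s[1] * s[2] - p[["beta"]] * s[3]))
  }
  x <- unlist(lapply(param_sets, function(p) {
    tt <- seq(0, transient + seg_dur, by = dt)
    out <- deSolve::rk4(c(x = init[1], y = init[2], z = init[3]),
                        tt, deriv, p)
    xi <- out[, "x"]
    if (any(!is.finite(xi))) {
      stop("Lorenz integration blew up; reduce dt or check parameters")
    }
    xi <- xi[tt > transient][seq_len(seg_len)]
    xi / stats::sd(xi)
  }))
  ent_signal(x, fs, label = "Lorenz system",
             segments = four_segments(duration,
                                      vapply(param_sets, function(p)
                                        sprintf("rho = %.4g", p[["rho"]]),
                                        "")))
}

#' Generate the full ten-signal benchmark suite
#'
#' All ten benchmark signals with their default settings, 256 Hz and 40 s
#' each. Stochastic generators receive independent sub-seeds derived from
#' `seed`.
#'
#' @param seed Master integer seed.
#' @inheritParams gen_chirp
#' @return Named list of ten [ent_signal] objects, in the canonical order
#'   (chirp, modulated chirp, harmonics, quasi-periodic + noise, WGN power,
#'   WGN bandwidth, MIX, AR(1), logistic, Lorenz).
#' @export
benchmark_suite <- function(seed, fs = 256, duration = 40) {
  list(
    chirp          = gen_chirp(fs = fs, duration = duration),
    chirp_mod      = gen_chirp(modulated = TRUE, fs = fs, duration = duration),
    harmonics      = gen_harmonic_stack(fs = fs, duration = duration),
    quasiperiodic  = gen_quasiperiodic_noise(fs = fs, duration = duration,
                                             seed = derive_seed(seed, 4)),
    wgn_power      = gen_wgn_power_steps(fs = fs, duration = duration,
                                         seed = derive_seed(seed, 5)),
    wgn_bandwidth  = gen_wgn_bandwidth_steps(fs = fs, duration = duration,
                                             seed = derive_seed(seed, 6)),
    mix            = gen_mix(fs = fs, duration = duration,
                             seed = derive_seed(seed, 7)),
    ar1_sweep      = gen_ar1_sweep(fs = fs, duration = duration,
                                   seed = derive_seed(seed, 8)),
    logistic       = gen_logistic(fs = fs, duration = duration),
    lorenz         = gen_lorenz(fs = fs, duration = duration)
  )
}

#' Surrogate EEG-like class data
#'
#' Labelled AR(1)-based signals whose classes differ in regularity, standing
#' in for EEG segment groups so the study pipeline (group tests and
#' classification) can be exercised offline. Each class spec is a list with
#' an AR coefficient `ar` and optionally `sine_hz` / `sine_amp` for an
#' added sinusoid, plus a `label`.
#'
#' @param n_per_class Segments per class.
#' @param class_specs Named list of class specs (>= 2 classes).
#' @param fs Sampling rate (Hz). @param duration Segment length (s).
#' @param seed Integer seed; fully determines the output.
#' @return List with `signals` (list of [ent_signal]) and `labels`
#'   (factor, one level per class).
#' @export
gen_surrogate_classes <- function(n_per_class = 50,
                                  class_specs = list(
                                    regular   = list(ar = 0.9),
                                    irregular = list(ar = 0.2)),
                                  fs = 256, duration = 10, seed = 1) {
  if (length(class_specs) < 2L) stop("need at least 2 classes")
  key <- vapply(class_specs, function(s)
    paste(s$ar, s$sine_hz %||% 0, s$sine_amp %||% 0), "")
  if (anyDuplicated(key)) {
    warning("some class specs share identical parameters; ",
            "classes will be indistinguishable")
  }
  if (is.null(names(class_specs))) {
    names(class_specs) <- paste0("class", seq_along(class_specs))
  }
  n <- round(fs * duration)
  t <- time_axis(fs, duration)
  signals <- list()
  labels <- character(0)
  for (ci in seq_along(class_specs)) {
    spec <- class_specs[[ci]]
    for (j in seq_len(n_per_class)) {
      sseed <- derive_seed(seed, ci * 1000L + j)
      x <- with_seed_if(sseed, {
        e <- rnorm(100 + n)
        prev <- 0
        for (i in seq_len(100 + n)) {
          prev <- spec$ar * prev + e[i]
          e[i] <- prev
        }
        e[(100 + 1):(100 + n)]
      })
      if (!is.null(spec$sine_hz)) {
        x <- x + (spec$sine_amp %||% 1) * sin(2 * pi * spec$sine_hz * t)
      }
      signals[[length(signals) + 1L]] <-
        ent_signal(x, fs, label = sprintf("%s #%d", names(class_specs)[ci], j),
                   metadata = list(class = names(class_specs)[ci]))
      labels <- c(labels, names(class_specs)[ci])
    }
  }
  list(signals = signals, labels = factor(labels, levels = names(class_specs)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
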