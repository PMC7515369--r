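test_that("default generators return 10 240 samples at 256 Hz with 10-s regime boundaries", {
  suite <- benchmark_suite(11)
  expect_length(suite, 10)
  for (s in suite) {
    expect_equal(length(s$samples), 10240)
    expect_equal(s$fs, 256)
  }
  four_seg <- Filter(function(s) !is.null(s$segments) &&
                       nrow(s$segments) == 4, suite)
  for (s in four_seg) expect_equal(s$segments$start, c(0, 10, 20, 30))
})

test_that("stochastic generators are bit-reproducible and leave the RNG alone", {
  for (gen in list(function(s) gen_quasiperiodic_noise(seed = s),
                   function(s) gen_wgn_power_steps(seed = s),
                   function(s) gen_wgn_bandwidth_steps(seed = s),
                   function(s) gen_mix(seed = s),
                   function(s) gen_ar1_sweep(seed = s))) {
    expect_identical(gen(5)$samples, gen(5)$samples)
  }
  set.seed(99); before <- runif(1)
  set.seed(99); gen_mix(seed = 1); after <- runif(1)
  expect_identical(before, after)
})

test_that("chirp sweeps 0.5 to 5 Hz with the stated envelope", {
  expect_error(gen_chirp(f0 = 5, f1 = 0.5), "f0 < f1")
  expect_error(gen_chirp(f0 = 1, f1 = 200), "Nyquist")

  s <- gen_chirp()
  zc <- function(x) sum(diff(sign(x)) != 0)
  fs <- s$fs
  # zero-crossing rate ~ 2f: ~2 crossings in the first 2 s, ~20 in the last
  expect_lte(zc(s$samples[1:(2 * fs)]), 4)
  expect_gte(zc(s$samples[(38 * fs + 1):(40 * fs)]), 16)

  m <- gen_chirp(modulated = TRUE)
  t <- seq(0, by = 1 / fs, length.out = length(m$samples))
  env <- 0.75 + 0.25 * cos(2 * pi * 0.05 * t)
  expect_equal(env[1], 1.0)
  expect_equal(env[10 * fs + 1], 0.5)
  expect_true(all(abs(m$samples) <= env + 1e-12))
  # unmodulated: per-cycle peak amplitude stays constant
  pk <- vapply(seq(0, 35, by = 5), function(t0)
    max(abs(s$samples[(t0 * fs + 1):((t0 + 5) * fs)])), 1)
  expect_true(all(abs(pk - 1) < 0.01))
})

test_that("harmonic stack has the stated per-segment spectral structure", {
  s <- gen_harmonic_stack()
  band_power <- function(x, f_lo, f_hi, fs = 256) {
    sp <- Mod(fft(x))^2
    fr <- (seq_along(x) - 1) / length(x) * fs
    sum(sp[fr >= f_lo & fr <= f_hi & fr < fs / 2])
  }
  # segment 1: a single component at the 0.4-Hz base frequency
  s1 <- segment_samples(s, 1)
  expect_gt(band_power(s1, 0.2, 0.6) / band_power(s1, 0, 128), 0.99)
  # segment 4: 7 distinct components, each well above the spectral floor
  s4 <- segment_samples(s, 4)
  f7 <- entrobench:::log_spaced(0.4, 100, 7)
  floor_pw <- band_power(s4, 110, 125)  # component-free band
  for (f in f7) {
    expect_gt(band_power(s4, f - 0.25, f + 0.25), 10 * floor_pw)
  }
  # log-spacing with n = 2 returns the endpoints
  expect_equal(entrobench:::log_spaced(0.4, 100, 2), c(0.4, 100))
})

test_that("quasi-periodic noise steps have the stated magnitudes", {
  s <- gen_quasiperiodic_noise(seed = 21)
  base <- quasiperiodic_base()
  resid <- s$samples - base
  seg <- function(i) resid[((i - 1) * 2560 + 1):(i * 2560)]
  expect_equal(seg(1), rep(0, 2560))
  # SD of segment 3 noise ~ 0.3 within 3 standard errors
  expect_equal(sd(seg(3)), 0.3, tolerance = 3 * 0.3 / sqrt(2 * 2559) / 0.3)
})

test_that("WGN power steps are white with the stated variances", {
  s <- gen_wgn_power_steps(seed = 31)
  seg <- function(i) s$samples[((i - 1) * 2560 + 1):(i * 2560)]
  expect_equal(var(seg(1)), 0.1, tolerance = 3 * sqrt(2 / 2559))
  for (i in 1:4) {
    x <- seg(i)
    expect_lt(abs(mean(x)), 4 * sd(x) / sqrt(2560))
    rho1 <- cor(x[-1], x[-length(x)])
    expect_lt(abs(rho1), 4 / sqrt(2560))
  }
})

test_that("WGN bandwidth steps are filtered as stated", {
  expect_error(gen_wgn_bandwidth_steps(cutoffs = c(30, 60, 130)), "fs/2")
  s <- gen_wgn_bandwidth_steps(seed = 41)
  seg <- function(i) s$samples[((i - 1) * 2560 + 1):(i * 2560)]
  frac_above <- function(x, f0, fs = 256) {
    sp <- Mod(fft(x))^2
    fr <- (seq_along(x) - 1) / length(x) * fs
    half <- fr > 0 & fr < fs / 2
    sum(sp[half & fr > f0]) / sum(sp[half])
  }
  # 30-Hz low-passed segment keeps under 1% of power above 35 Hz
  expect_lt(frac_above(seg(1), 35), 0.01)
  # unfiltered segment: roughly flat spectrum, far more power above 35 Hz
  expect_gt(frac_above(seg(4), 35), 0.5)
  # segment 4 equals the raw realisation's last 10 s
  raw <- withr::with_seed(41, rnorm(10240))
  expect_identical(seg(4), raw[7681:10240])
})

test_that("MIX process interpolates between the sinusoid and uniform noise", {
  pure_det <- gen_mix(0, 0, seed = 3)
  expect_equal(pure_det$samples, mix_deterministic(10240))
  expect_equal(pure_det$samples[1:24], pure_det$samples[13:36])  # period 12

  pure_rand <- gen_mix(1, 1, seed = 3)
  ks <- suppressWarnings(ks.test(pure_rand$samples, "punif", -3, 3))
  expect_gt(ks$p.value, 0.01)

  s <- gen_mix(seed = 3)  # p sweeps 0.9 -> 0.1
  det <- mix_deterministic(10240)
  # deterministic fraction tracks 1 - p: ~0.1 early, ~0.9 late
  first <- mean(s$samples[1:1024] == det[1:1024])
  last <- mean(s$samples[9217:10240] == det[9217:10240])
  expect_lt(first, 0.25)
  expect_gt(last, 0.75)
  expect_gt(last, first + 0.5)
})

test_that("AR(1) sweep has the stated autocorrelation structure", {
  expect_error(gen_ar1_sweep(1.1, 0.5), "below 1")
  rho1 <- function(x) cor(x[-1], x[-length(x)])
  expect_lt(abs(rho1(gen_ar1_sweep(0, 0, seed = 51)$samples)), 0.05)
  expect_equal(rho1(gen_ar1_sweep(0.9, 0.9, seed = 52)$samples), 0.9,
               tolerance = 0.05 / 0.9)
  s <- gen_ar1_sweep(seed = 53)
  expect_gt(rho1(s$samples[1:1280]), 0)
  expect_lt(rho1(s$samples[8961:10240]), 0)
})

test_that("logistic map periods match a brute-force orbit enumeration", {
  expect_error(gen_logistic(mu_segments = 5), "\\(0, 4]")
  expect_error(gen_logistic(x0 = 1.5), "\\(0, 1\\)")
  s <- gen_logistic()
  expect_true(all(s$samples > 0 & s$samples < 1))

  for (case in list(c(2.0, 1), c(3.2, 2), c(3.5, 4), c(3.55, 8))) {
    orbit <- entrobench:::logistic_orbit(case[1], 0.3, 10000, burn_in = 100)
    expect_equal(count_distinct(orbit), case[2])
  }
  # mu = 2: fixed point at 1 - 1/mu = 0.5
  orbit <- entrobench:::logistic_orbit(2.0, 0.3, 100, burn_in = 100)
  expect_equal(orbit, rep(0.5, 100), tolerance = 1e-12)
})

test_that("Lorenz halves are unit-SD and deterministic", {
  s <- gen_lorenz()
  expect_equal(sd(s$samples[1:5120]), 1, tolerance = 1e-6)
  expect_equal(sd(s$samples[5121:10240]), 1, tolerance = 1e-6)
  dup <- gen_lorenz(param_sets = list(c(sigma = 10, beta = 8 / 3, rho = 28),
                                      c(sigma = 10, beta = 8 / 3, rho = 28)))
  expect_equal(dup$samples[1:5120], dup$samples[5121:10240])
  # chaotic half: autocorrelation decays instead of staying periodic
  ac <- acf(s$samples[1:5120], lag.max = 1500, plot = FALSE)$acf
  expect_lt(max(abs(ac[1000:1500])), 0.9)
})

test_that("surrogate classes differ in entropy and are reproducible", {
  sur <- gen_surrogate_classes(
    n_per_class = 20,
    class_specs = list(reg = list(ar = 0.9), irr = list(ar = 0.0)),
    duration = 4, seed = 7)
  expect_length(sur$signals, 40)
  feats <- batch_entropy(sur$signals, list(cfg_sen(2, 0.2)))
  tst <- compare_groups(split(feats[[1]], sur$labels), "independent-2")
  expect_lt(tst$p_value, 0.01)

  sur2 <- gen_surrogate_classes(
    n_per_class = 20,
    class_specs = list(reg = list(ar = 0.9), irr = list(ar = 0.0)),
    duration = 4, seed = 7)
  expect_identical(sur$signals[[1]]$samples, sur2$signals[[1]]$samples)

  expect_warning(
    dup <- gen_surrogate_classes(
      n_per_class = 10,
      class_specs = list(a = list(ar = 0.5), b = list(ar = 0.5)),
      duration = 2, seed = 8),
    "indistinguishable")
  f2 <- batch_entropy(dup$signals, list(cfg_pen(3)))
  cv <- knn_cross_validate(f2, dup$labels, folds = 5, seed = 1)
  expect_gt(cv$mean_accuracy, 0.2)
  expect_lt(cv$mean_accuracy, 0.8)
})
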