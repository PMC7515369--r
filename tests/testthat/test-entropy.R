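test_that("ordinal patterns encode ranks under both tie rules", {
  expect_error(ordinal_patterns(c(1, 2), 3), "shorter")
  expect_equal(ordinal_patterns(c(1, 2, 3), 3), "1-2-3")
  expect_equal(ordinal_patterns(c(1, 2, 3), 3, "merged-rank"), "1-2-3")

  # ties merge into one rank only under the merged-rank rule
  expect_equal(ordinal_patterns(c(1, 1, 2), 3, "merged-rank"), "1-1-2")
  expect_equal(ordinal_patterns(c(1, 1, 2), 3, "order-of-appearance"),
               "1-2-3")

  pats <- ordinal_patterns(c(4, 7, 9, 10, 6, 11, 3), 2)
  expect_equal(sum(pats == "1-2"), 4)
  expect_equal(sum(pats == "2-1"), 2)
})

test_that("merged-rank pattern universe matches the ordered Bell recurrence", {
  for (n in 2:6) {
    expect_equal(merged_pattern_count(n), oracle_merged_count(n))
  }
  expect_equal(merged_pattern_count(3), 13)
})

test_that("permutation entropies reproduce hand-enumerated examples", {
  ramp <- 1:50
  expect_equal(permutation_entropy(ramp, 3), 0)
  expect_equal(permutation_entropy(ramp, 5), 0)
  expect_equal(modified_permutation_entropy(rep(2, 30), 3), 0)

  h <- -(4 / 6) * log(4 / 6) - (2 / 6) * log(2 / 6)
  expect_equal(permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), 2,
                                   normalize = FALSE), h)
  # x = (1, 2, 2, 3), n = 2: two ascending windows and one tie window
  expect_equal(modified_permutation_entropy(c(1, 2, 2, 3), 2,
                                            normalize = FALSE), h)

  # base-2 logs rescale by log(2)
  expect_equal(permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), 2,
                                   normalize = FALSE, log_base = "2"),
               h / log(2))
})

test_that("long white noise saturates PEn near 1 and MPEn near log(n!)/log(universe)", {
  w <- withr::with_seed(1, rnorm(2560))
  expect_equal(permutation_entropy(w, 3), 1, tolerance = 0.02)
  # continuous noise never realises tie patterns: 6 of 13 patterns used
  expect_equal(modified_permutation_entropy(w, 3), log(6) / log(13),
               tolerance = 0.02)
  expect_gt(permutation_entropy(w, 3), modified_permutation_entropy(w, 3))
})

test_that("embedding entropies handle degenerate and closed-form cases", {
  expect_equal(sample_entropy(rep(3, 40), 2, 0.2), 0)
  expect_equal(fuzzy_entropy(rep(3, 40), 1, 2, 0.2), 0)
  # tolerance far above all distances: every pair matches at both lengths
  x <- withr::with_seed(2, rnorm(60))
  expect_equal(sample_entropy(x, 1, 100), 0)
  # undefined ratio reported as NA, not Inf
  expect_true(is.na(sample_entropy(sin(1:40), 2, 1e-6)))
  expect_error(sample_entropy(c(1, 2), 2, 0.2), "short")
  # a single template pair at distance d with d^n = r has similarity 1/e
  expect_equal(exp(-(0.2)^1 / 0.2), exp(-1))
})

test_that("five estimators match naive reference implementations to 1e-10", {
  withr::with_seed(10, {
    for (rep in 1:6) {
      x <- switch(1 + rep %% 3,
                  rnorm(sample(50:200, 1)),
                  round(rnorm(sample(50:200, 1)), 1),  # forces ties
                  cumsum(rnorm(sample(50:200, 1))))
      for (n in c(3, 4)) {
        expect_equal(permutation_entropy(x, n), oracle_pen(x, n),
                     tolerance = 1e-10)
        expect_equal(modified_permutation_entropy(x, n), oracle_mpen(x, n),
                     tolerance = 1e-10)
      }
      for (m in 1:2) {
        expect_equal(sample_entropy(x, m, 0.2), oracle_sen(x, m, 0.2),
                     tolerance = 1e-10)
        expect_equal(fuzzy_entropy(x, 2, m, 0.2), oracle_fen(x, 2, m, 0.2),
                     tolerance = 1e-10)
      }
      expect_equal(quadratic_sample_entropy(x, 2, 0.4),
                   oracle_qsen(x, 2, 0.4), tolerance = 1e-10)
    }
  })
  # the worked pair-counting example sequences
  x <- rep(c(1, 2, 3, 2), 10)
  expect_equal(sample_entropy(x, 1, 0.25), oracle_sen(x, 1, 0.25),
               tolerance = 1e-12)
  xj <- x + withr::with_seed(3, rnorm(40, 0, 0.01))
  expect_equal(fuzzy_entropy(xj, 1, 1, 0.2), oracle_fen(xj, 1, 1, 0.2),
               tolerance = 1e-12)
})

test_that("rank invariance, affine invariance and bounds hold", {
  withr::with_seed(20, {
    for (rep in 1:5) {
      x <- rnorm(150)
      # strictly increasing transform leaves rank-based entropies unchanged
      y <- exp(2 * x) + 5
      expect_equal(permutation_entropy(x, 4), permutation_entropy(y, 4))
      expect_equal(modified_permutation_entropy(x, 4),
                   modified_permutation_entropy(y, 4))
      # affine maps leave SD-relative embedding entropies unchanged
      # (FEn only for exponent n = 1: the similarity exp(-d^n / r) does not
      # raise r to n, so higher exponents are deliberately scale-sensitive)
      z <- 3.7 * x - 11
      expect_equal(sample_entropy(x, 2, 0.2), sample_entropy(z, 2, 0.2),
                   tolerance = 1e-12)
      expect_equal(fuzzy_entropy(x, 1, 2, 0.2), fuzzy_entropy(z, 1, 2, 0.2),
                   tolerance = 1e-10)
      # bounds
      expect_gte(permutation_entropy(x, 3), 0)
      expect_lte(permutation_entropy(x, 3), 1)
      expect_lte(permutation_entropy(x, 3, normalize = FALSE), log(6))
      expect_lte(modified_permutation_entropy(x, 3, normalize = FALSE),
                 log(13))
      expect_gte(fuzzy_entropy(x, 1, 2, 0.2), -1e-12)
    }
  })
})

test_that("QSEn differs from SEn by exactly log(2r) across the grids", {
  withr::with_seed(30, {
    x <- rnorm(300)
    for (m in 1:2) {
      for (r in c(0.2, 0.4, 0.6, 0.8, 1)) {
        expect_equal(quadratic_sample_entropy(x, m, r) - sample_entropy(x, m, r),
                     log(2 * r), tolerance = 1e-14)
      }
    }
    # r = 0.5 makes the additive term vanish
    expect_identical(quadratic_sample_entropy(x, 1, 0.5),
                     sample_entropy(x, 1, 0.5) + log(1))
  })
})

test_that("the default study grids contain 47 configurations", {
  grids <- default_entropy_grids()
  expect_length(grids, 47)
  fams <- table(vapply(grids, `[[`, "", "family"))
  expect_equal(fams[["PEn"]], 4)
  expect_equal(fams[["MPEn"]], 3)
  expect_equal(fams[["SEn"]], 8)
  expect_equal(fams[["QSEn"]], 8)
  expect_equal(fams[["FEn"]], 24)
  # the alternative QSEn tolerance preset is accepted
  alt <- default_entropy_grids(qsen_r = c(0.4, 0.6, 0.8, 1))
  expect_length(alt, 47)
})
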