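test_that("signal splitting partitions grids and streams, discarding leftovers", {
  # grid mode: rows are used directly
  hm <- heightmap(matrix(seq_len(50), 10, 5, byrow = TRUE))
  ss <- split_signals(hm)
  expect_identical(dim(ss$signals), c(10L, 5L))
  expect_identical(ss$signals[3, ], hm$z[3, ])
  # stream mode with remainder
  ss2 <- split_signals(as.numeric(1:103), points_per_signal = 10)
  expect_identical(dim(ss2$signals), c(10L, 10L))
  expect_identical(ss2$signals[10, 10], 100)  # points 101:103 discarded
  expect_error(split_signals(as.numeric(1:15), points_per_signal = 10),
               "fewer than 2")
})

test_that("detrending removes affine form exactly and keeps spikes", {
  expect_equal(detrend_signal(rep(4.2, 20), 5), rep(0, 20))
  # linear ramp: symmetric shrinking window keeps the average affine
  for (w in c(3, 7, 15))
    expect_equal(detrend_signal(0.7 * (1:30) - 3, w), rep(0, 30))
  expect_equal(detrend_signal(c(0, 0, 9, 0, 0), 3), c(0, -3, 6, -3, 0))
  expect_error(detrend_signal(rnorm(10), 4), "odd")
})

test_that("normalized cross-correlation honours its algebraic identities", {
  withr::with_seed(21, {
    s <- rnorm(50)
    r <- rnorm(50)
  })
  expect_identical(xcorr_at_lag(s, s, 0), 1)
  expect_equal(xcorr_at_lag(s, -s, 0), -1)
  expect_equal(xcorr_at_lag(c(1, 0, 1, 0), c(0, 1, 0, 1), 0), 0)
  # symmetry and scale invariance
  for (lag in c(-7, -1, 0, 3, 12)) {
    expect_equal(xcorr_at_lag(s, r, lag), xcorr_at_lag(r, s, -lag))
    expect_equal(xcorr_at_lag(2.5 * s, 0.3 * r, lag),
                 xcorr_at_lag(s, r, lag))
  }
  expect_error(xcorr_at_lag(s, rep(0, 50), 0), "all-zero")
  expect_error(xcorr_at_lag(s, r, 49), "3 overlapping")
})

test_that("cross-correlation matches the double-loop oracle everywhere", {
  withr::with_seed(22, {
    for (rep in 1:25) {
      p <- sample(8:60, 1)
      s1 <- rnorm(p)
      s2 <- rnorm(p)
      lag <- sample(seq(-(p - 4), p - 4), 1)
      expect_equal(xcorr_at_lag(s1, s2, lag), oracle_xcorr(s1, s2, lag),
                   tolerance = 1e-12)
    }
  })
})

test_that("the lag search equals the brute-force oracle on random pairs", {
  withr::with_seed(23, {
    for (rep in 1:50) {
      p <- 40
      s1 <- rnorm(p)
      s2 <- rnorm(p)
      got <- best_lag(s1, s2, max_lag = 10)
      want <- oracle_best_lag(s1, s2, max_lag = 10)
      expect_identical(got$lag, want$lag)
      expect_equal(got$coef, want$coef, tolerance = 1e-12)
    }
  })
})

test_that("a delayed copy is found at the undoing lag with coefficient 1", {
  withr::with_seed(24, base <- rnorm(140))
  p <- 100
  s1 <- base[11:(10 + p)]
  for (k in c(1, 4, 9)) {
    s2 <- base[(11 - k):(10 + p - k)]  # features delayed by k samples
    got <- best_lag(s1, s2, max_lag = 10)
    expect_identical(got$lag, as.integer(k))
    expect_equal(got$coef, 1, tolerance = 1e-12)
  }
  expect_identical(best_lag(s1, s1, 10), list(coef = 1, lag = 0L))
})

test_that("sequential alignment recovers constructed shifts", {
  withr::with_seed(25, base <- rnorm(240))
  hm <- shifted_rows_mark(base, shifts = c(0L, 2L, -1L), P = 200)
  ss <- split_signals(hm)
  ss$detrended <- TRUE  # rows are already zero-mean noise windows
  ar <- align_signals(ss, max_lag = 5)
  # the recovered lags undo the applied shifts
  expect_identical(ar$alignment$step_lags, c(-2L, 1L))
  expect_equal(ar$alignment$x_max, 1, tolerance = 1e-12)
  expect_equal(ar$alignment$l_xmax, 1.5)
  expect_length(ar$alignment$step_coeffs, 2L)
  # aligned rows agree on their common support
  core <- 4:197
  expect_equal(ar$signals$signals[2, core], ar$signals$signals[1, core])
  expect_equal(ar$signals$signals[3, core], ar$signals$signals[1, core])
})

test_that("identical signals align with X_max 1 and no lags", {
  withr::with_seed(26, s <- rnorm(120))
  ss <- striamark:::new_signal_set(rbind(s, s, s, s), dx = 3,
                                   detrended = TRUE)
  ar <- align_signals(ss, max_lag = 10)
  expect_equal(ar$alignment$x_max, 1, tolerance = 1e-12)
  expect_identical(ar$alignment$l_xmax, 0)
  expect_length(ar$alignment$step_coeffs, 3L)
})

test_that("alignment refuses non-detrended input", {
  ss <- split_signals(heightmap(matrix(rnorm(100), 5, 20)))
  expect_error(align_signals(ss, 5), "detrended")
})

test_that("signature averaging cancels, trims and records coverage", {
  withr::with_seed(27, a <- rnorm(60))
  # two opposite signals cancel
  ss <- striamark:::new_signal_set(rbind(a, -a), dx = 3, detrended = TRUE)
  sig <- build_signature(ss)
  expect_true(all(abs(sig$values) < 1e-15))
  # identical aligned signals reproduce the signal on the kept span
  ss2 <- striamark:::new_signal_set(rbind(a, a, a), dx = 3,
                                    detrended = TRUE)
  sig2 <- build_signature(ss2)
  expect_identical(sig2$values, a)
  expect_true(all(sig2$coverage == 3L))
})

test_that("signature sample variance shrinks like sigma^2 / S", {
  sigma <- 1.5
  S <- 40L
  P <- 400L
  vars <- vapply(1:20, function(seed) {
    m <- withr::with_seed(100 + seed,
                          matrix(rnorm(S * P, 0, sigma), S, P))
    ss <- striamark:::new_signal_set(m, dx = 3, detrended = TRUE)
    var(build_signature(ss)$values)
  }, 0)
  want <- sigma^2 / S
  se <- sd(vars) / sqrt(length(vars))
  expect_lt(abs(mean(vars) - want), 3 * se + 1e-12)
})

test_that("the full pipeline is deterministic and ignores global tilt", {
  knife <- generate_knife(P = 300, seed = 31)
  hm <- generate_mark(knife, material_presets()[["medium-fidelity"]],
                      S = 24, seed = 32)
  a <- mark_signature(hm, window = 31, max_lag = 20)
  b <- mark_signature(hm, window = 31, max_lag = 20)
  expect_identical(a$signature$values, b$signature$values)
  expect_identical(a$alignment$step_lags, b$alignment$step_lags)
  # adding a constant and a column-wise tilt to every row changes nothing
  tilted <- hm
  tilt <- 0.4 * seq_len(ncol(hm$z)) + 11
  tilted$z <- sweep(hm$z, 2L, tilt, `+`)
  c_ <- mark_signature(tilted, window = 31, max_lag = 20)
  expect_lt(max(abs(c_$signature$values - a$signature$values)), 1e-9)
  expect_identical(c_$alignment$step_lags, a$alignment$step_lags)
})

test_that("a jitter-free noiseless mark scores X_max 1 and L_Xmax 0", {
  knife <- generate_knife(P = 300, seed = 33)
  clean <- material_model("clean")
  hm <- generate_mark(knife, clean, S = 12, seed = 34)
  res <- mark_signature(hm, window = 31, max_lag = 20)
  expect_equal(res$alignment$x_max, 1, tolerance = 1e-9)
  expect_identical(res$alignment$l_xmax, 0)
})

test_that("correlation magnitude never exceeds 1 under fuzzing", {
  withr::with_seed(35, {
    for (rep in 1:200) {
      p <- sample(5:80, 1)
      s1 <- rnorm(p) * 10^sample(-3:3, 1)
      s2 <- rnorm(p) * 10^sample(-3:3, 1)
      lag <- sample(seq(-(p - 4), p - 4), 1)
      expect_lte(abs(xcorr_at_lag(s1, s2, lag)), 1 + 1e-12)
    }
  })
})

test_that("signature files round-trip values, coverage and metrics", {
  knife <- generate_knife(P = 260, seed = 36)
  hm <- generate_mark(knife, material_presets()[["high-fidelity"]],
                      S = 10, seed = 37)
  res <- mark_signature(hm, window = 31, max_lag = 20)
  path <- withr::local_tempfile(fileext = ".txt")
  write_signature(res$signature, path, alignment = res$alignment)
  back <- read_signature(path)
  expect_identical(back$values, res$signature$values)
  expect_identical(back$coverage, as.integer(res$signature$coverage))
  expect_identical(attr(back, "x_max"), res$alignment$x_max)
})
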