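small_signature <- function(values, dx = 3, mark_id = NULL) {
  sig <- structure(list(values = values, coverage = rep(1L, length(values)),
                        dx = dx, span = c(1L, length(values))),
                   class = "stria_signature")
  if (!is.null(mark_id)) attr(sig, "mark_id") <- mark_id
  sig
}

test_that("a signature compared with itself scores exactly 1 at lag 0", {
  withr::with_seed(41, sig <- small_signature(rnorm(200)))
  cr <- compare_signatures(sig, sig, max_lag = 20)
  expect_equal(cr$x_c, 1, tolerance = 1e-12)
  expect_identical(cr$lag, 0L)
})

test_that("comparison is symmetric in the score with a negated lag", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      a <- small_signature(rnorm(150))
      b <- small_signature(rnorm(150))
      f <- compare_signatures(a, b, max_lag = 15)
      g <- compare_signatures(b, a, max_lag = 15)
      expect_equal(f$x_c, g$x_c, tolerance = 1e-12)
      expect_identical(f$lag, -g$lag)
    }
  })
})

test_that("incompatible spacing and too-short signatures are refused", {
  a <- small_signature(rnorm(100), dx = 3)
  b <- small_signature(rnorm(100), dx = 4)
  expect_error(compare_signatures(a, b, 10), "spacing")
  short <- small_signature(rnorm(30), dx = 3)
  expect_error(compare_signatures(short, small_signature(rnorm(30)), 25),
               "below 10 samples")
})

test_that("white-noise signature pairs score near the permutation null", {
  # 100 seeded pairs of signatures from marks whose rows are dominated by
  # iid noise; their mean best-lag score is compared with a permutation
  # oracle for the null expectation of the maximum over the lag window.
  P <- 300L
  max_lag <- 20L
  noisy <- material_model("noise-dominated", noise_sd = 1)
  sig_of <- function(seed) {
    knife <- generate_knife(P = P, amplitude_sd = 1e-6, seed = seed)
    hm <- generate_mark(knife, noisy, S = 16, seed = seed + 5000L)
    ms <- mark_signature(hm, window = 31, max_lag = max_lag)
    ms$signature
  }
  xcs <- vapply(1:100, function(i) {
    a <- sig_of(2L * i)
    b <- sig_of(2L * i + 1L)
    compare_signatures(a, b, max_lag = max_lag)$x_c
  }, 0)
  # permutation oracle: destroy any structure by permuting one signature
  null_max <- withr::with_seed(43, {
    a <- sig_of(9001L)
    b <- sig_of(9003L)
    p <- min(length(a$values), length(b$values))
    vapply(1:100, function(i) {
      best_lag(a$values[1:p], sample(b$values[1:p]),
               max_lag = max_lag)$coef
    }, 0)
  })
  se <- sqrt(sd(xcs)^2 / length(xcs) + sd(null_max)^2 / length(null_max))
  expect_lt(abs(mean(xcs) - mean(null_max)), 3 * se + 0.02)
  expect_lt(mean(xcs), 0.5)  # unrelated marks never look like matches
})

test_that("zero-noise marks from one knife give a perfect known match", {
  knife <- generate_knife(P = 400, seed = 44)
  clean <- material_model("clean")
  sa <- mark_signature(generate_mark(knife, clean, S = 10, seed = 1),
                       window = 31, max_lag = 20)$signature
  sb <- mark_signature(generate_mark(knife, clean, S = 10, seed = 2),
                       window = 31, max_lag = 20)$signature
  cr <- compare_signatures(sa, sb, max_lag = 20, label = "KM")
  expect_equal(cr$x_c, 1, tolerance = 1e-9)
  expect_identical(cr$label, "KM")
})

test_that("pair construction yields one KM and one KNM per knife by default", {
  withr::with_seed(45, {
    sigs <- lapply(1:20, function(i)
      small_signature(rnorm(120), mark_id = paste0("m", i)))
  })
  knife <- rep(sprintf("K%02d", 1:10), each = 2)
  mark <- rep(c("A", "B"), 10)
  res <- km_knm_matrix(sigs, knife, mark, material = "test", max_lag = 10)
  expect_identical(sum(res$label == "KM"), 10L)
  expect_identical(sum(res$label == "KNM"), 10L)
  knm <- res[res$label == "KNM", ]
  expect_true(all(knm$knife_a != knm$knife_b))
  expect_true(all(knm$mark_a == "A") && all(knm$mark_b == "B"))
  # two knives: 2 KM + 2 KNM
  res2 <- km_knm_matrix(sigs[1:4], knife[1:4], mark[1:4], max_lag = 10)
  expect_identical(table(res2$label)[["KM"]], 2L)
  expect_identical(table(res2$label)[["KNM"]], 2L)
  # all-knm scheme: 2 * 2 * choose(10, 2) cross-knife pairs
  res3 <- km_knm_matrix(sigs, knife, mark, pairing = "all-knm",
                        max_lag = 10)
  expect_identical(sum(res3$label == "KNM"), 180L)
  expect_identical(sum(res3$label == "KM"), 10L)
  expect_error(km_knm_matrix(sigs[1:3], c("K1", "K1", "K2"),
                             c("A", "B", "A"), max_lag = 10),
               "K2")
})

test_that("material summaries separate fully distinct KM/KNM groups", {
  res <- data.frame(label = rep(c("KM", "KNM"), each = 10),
                    x_c = c(rep(1, 10), rep(0, 10)))
  s <- summarize_material(res, material = "ideal")
  expect_identical(unname(s$xc_km_stats["mean"]), 1)
  expect_identical(unname(s$xc_knm_stats["mean"]), 0)
  # the fully tied scores force the normal approximation; the exact
  # no-ties case (p = 2/choose(20, 10)) is covered by the U-test contract
  expect_lt(s$separation_p, 1e-4)
})

test_that("identical KM and KNM score samples are not separable", {
  withr::with_seed(46, v <- rnorm(8))
  res <- data.frame(label = rep(c("KM", "KNM"), each = 8), x_c = c(v, v))
  s <- summarize_material(res, material = "null")
  expect_gt(s$separation_p, 0.99)
})

test_that("pairwise material tables are symmetric with unit diagonal", {
  withr::with_seed(47, {
    vals <- list(a = rnorm(10), b = rnorm(10) + 3, c = rnorm(10))
  })
  p <- compare_materials(vals)
  expect_identical(p, t(p))
  expect_identical(unname(diag(p)), rep(1, 3))
  expect_lt(p["a", "b"], 0.05)
  # identical raw values: p = 1
  same <- list(x = vals$a, y = vals$a)
  expect_gt(compare_materials(same)["x", "y"], 0.99)
  expect_error(compare_materials(list(a = 1, b = vals$b)), "degenerate")
})

test_that("high- and low-fidelity presets separate on X_max", {
  presets <- material_presets()
  xm <- function(preset, seed) {
    knife <- generate_knife(P = 300, seed = seed)
    hm <- generate_mark(knife, presets[[preset]], S = 24, seed = seed + 50)
    mark_signature(hm, window = 31, max_lag = 25)$alignment$x_max
  }
  hi <- vapply(1:10, function(i) xm("high-fidelity", 100L + i), 0)
  lo <- vapply(1:10, function(i) xm("low-fidelity", 200L + i), 0)
  p <- compare_materials(list(hi = hi, lo = lo))["hi", "lo"]
  expect_lt(p, 0.05)
  expect_gt(mean(hi), mean(lo))
})
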