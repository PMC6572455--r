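test_that("a noiseless single-break curve is recovered exactly", {
  # y rises at 2 counts/m to the 275 m midpoint, then falls at 1
  cv <- gen_frequency_curve(275, c(2, -1), 0, n_bins = 12, bin_width = 50)
  fit <- fit_piecewise(cv, 1)
  expect_equal(fit$breakpoints, 275)
  expect_equal(fit$rss, 0, tolerance = 1e-8)
  expect_equal(fit$slopes, c(2, -1), tolerance = 1e-8)
})

test_that("k = 0 equals the closed-form OLS line", {
  set.seed(3)
  cv <- build_distance_curve(runif(200, 0, 600), 50)
  fit <- fit_piecewise(cv, 0)
  x <- curve_midpoints(cv)
  y <- as.numeric(cv$counts)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slopes, slope)
  expect_equal(fit$intercept, mean(y) - slope * mean(x))
})

test_that("grid search equals the exhaustive enumeration oracle", {
  set.seed(21)
  for (rep in 1:5) {
    counts <- pmax(0, round(rnorm(12, 30, 12)))
    counts[12] <- max(counts[12], 1L)
    cv <- build_distance_curve(rep((1:12 - 0.5) * 50, counts), 50)
    for (k in 1:2) {
      got <- fit_piecewise(cv, k)
      want <- oracle_piecewise(cv, k)
      expect_equal(got$rss, want$rss, tolerance = 1e-8)
      expect_equal(got$breakpoints, want$bps)
    }
  }
})

test_that("RSS never increases with k and refits are deterministic", {
  set.seed(8)
  cv <- gen_frequency_curve(c(300, 1500), c(0.3, -0.08, 0.04), 5,
                            n_bins = 40, noise_sd = 4, seed = 8)
  rss <- sapply(0:3, function(k) fit_piecewise(cv, k)$rss)
  expect_true(all(diff(rss) <= 1e-9))
  f1 <- fit_piecewise(cv, 2)
  f2 <- fit_piecewise(cv, 2)
  expect_identical(f1[c("breakpoints", "rss", "slopes")],
                   f2[c("breakpoints", "rss", "slopes")])
  s1 <- select_joinpoints(cv, k_max = 2, n_perm = 199, seed = 99)
  s2 <- select_joinpoints(cv, k_max = 2, n_perm = 199, seed = 99)
  expect_identical(s1[c("k", "breakpoints", "rss")],
                   s2[c("k", "breakpoints", "rss")])
  expect_identical(s1$significance, s2$significance)
})

test_that("infeasible requests signal rather than fit", {
  cv <- build_distance_curve(c(10, 60, 110, 160), 50)  # 4 bins
  expect_error(fit_piecewise(cv, 1), "infeasible")
})

test_that("BIC selects one break for a noiseless triangle", {
  cv <- gen_frequency_curve(325, c(2, -1), 0, n_bins = 14)
  fit <- select_joinpoints(cv, k_max = 2, method = "bic")
  expect_equal(fit$k, 1)
  expect_equal(fit$breakpoints, 325)
})

test_that("a degenerate flat curve returns k = 0 with a note", {
  cv <- build_distance_curve(rep(seq(25, 475, by = 50), each = 3), 50)
  fit <- select_joinpoints(cv, k_max = 2, n_perm = 199, seed = 4)
  expect_equal(fit$k, 0)
  expect_match(fit$note, "degenerate")
})

test_that("a noiseless rise-fall-rise curve selects k = 2 with signs (+,-,+)", {
  cv <- gen_frequency_curve(c(325, 1475), c(0.4, -0.12, 0.08), 10,
                            n_bins = 40, noise_sd = 0)
  for (method in c("permutation", "bic")) {
    fit <- select_joinpoints(cv, k_max = 2, method = method,
                             n_perm = 199, seed = 17)
    expect_equal(fit$k, 2)
    expect_equal(fit$breakpoints, c(325, 1475))
    expect_equal(sign(fit$slopes), c(1, -1, 1))
    expect_true(all(fit$significance$significant))
  }
})

test_that("permutation selection requires a seed and enough permutations", {
  cv <- gen_frequency_curve(325, c(2, -1), 0, n_bins = 14)
  expect_error(select_joinpoints(cv, method = "permutation", n_perm = 199),
               "seed")
  expect_error(select_joinpoints(cv, method = "permutation", n_perm = 50,
                                 seed = 1), "99")
})

test_that("slope-change tests flag real changes and pass over null ones", {
  # noiseless large change: zero residual variance -> significant
  cv <- gen_frequency_curve(325, c(2, -1), 0, n_bins = 14)
  fit <- fit_piecewise(cv, 1)
  for (method in c("t", "permutation")) {
    sig <- slope_change_significance(fit, cv, method = method, seed = 2)
    expect_true(sig$significant)
  }
  # collinear segments: slope change 0 -> never significant
  cv0 <- gen_frequency_curve(numeric(0), 1, 5, n_bins = 14)
  f0 <- fit_piecewise(cv0, 1)  # forced break on a straight line
  expect_equal(f0$slope_changes, 0, tolerance = 1e-10)
  sig0 <- slope_change_significance(f0, cv0, method = "t")
  expect_false(sig0$significant)
})

test_that("slope-change rejection rate grows with the effect size", {
  set.seed(60)
  reject_rate <- sapply(c(0.01, 0.04), function(drop) {
    hits <- 0
    for (i in 1:40) {
      cv <- gen_frequency_curve(975, c(0.04, 0.04 - drop), 20,
                                n_bins = 40, noise_sd = 4,
                                seed = 6000 + i + round(drop * 1e4))
      fit <- fit_piecewise(cv, 1)
      sig <- slope_change_significance(fit, cv, method = "t")
      hits <- hits + sig$significant[1]
    }
    hits / 40
  })
  expect_gt(reject_rate[1], 0.05)   # moderate change: detectably above alpha
  expect_gte(reject_rate[2], reject_rate[1])  # power grows with effect size
  expect_gt(reject_rate[2], 0.8)
})

test_that("breakpoints converge to truth as noise vanishes", {
  true_bp <- c(325, 1475)
  for (sd in c(4, 1, 0)) {
    err <- replicate(10, {
      seed <- sample.int(1e6, 1)
      cv <- gen_frequency_curve(true_bp, c(0.4, -0.12, 0.08), 10,
                                n_bins = 40, noise_sd = sd, seed = seed)
      max(abs(fit_piecewise(cv, 2)$breakpoints - true_bp))
    })
    if (sd == 0) expect_true(all(err == 0)) else
      expect_lt(median(err), 50 + 1e-9)
  }
})
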