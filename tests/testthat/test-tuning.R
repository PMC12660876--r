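linear_curve <- function(slope = 2, intercept = 0.1, n = 201) {
  grid <- seq(0, 1, length.out = n)
  list(grid = grid, values = slope * grid + intercept, domain = c(0, 1))
}

gaussian_curve <- function(mu = 0.5, sigma = 0.04, n = 201,
                           domain = c(0, 1)) {
  grid <- seq(domain[1], domain[2], length.out = n)
  list(grid = grid, values = exp(-(grid - mu)^2 / (2 * sigma^2)),
       domain = domain)
}

test_that("tuning curves are weighted sums of the basis functions", {
  b <- make_basis("gaussian", K = 10, domain = c(0, 1), width = 0.04)
  expect_equal(tuning_curve(rep(0, 10), b)$values, rep(0, 201))
  one_hot <- replace(rep(0, 10), 3, 1)
  tc <- tuning_curve(one_hot, b)
  expect_equal(tc$values, drop(eval_basis(b, tc$grid)[, 3]),
               tolerance = 1e-12)
  set.seed(1)
  w <- runif(10, -0.5, 0.5)
  tc2 <- tuning_curve(w, b)
  at_centers <- sapply(b$centers, function(mu)
    sum(w * eval_basis(b, mu)[1, ]))
  idx <- sapply(b$centers, function(mu) which.min(abs(tc2$grid - mu)))
  expect_equal(tc2$values[idx],
               drop(eval_basis(b, tc2$grid[idx]) %*% w),
               tolerance = 1e-12)
  expect_equal(drop(eval_basis(b, b$centers) %*% w), at_centers,
               tolerance = 1e-12)
  expect_error(tuning_curve(w[1:5], b), "K")
})

test_that("a linear monotone curve has m = 1, n = 0, nu = 0, no peaks", {
  ch <- characterize_curve(linear_curve())
  expect_equal(ch$argmax_x, 1)
  expect_false(ch$non_extreme)
  expect_equal(ch$nonmono, 0, tolerance = 1e-12)
  expect_equal(ch$mono, 1, tolerance = 1e-12)
  expect_equal(ch$nonlin, 0, tolerance = 1e-12)
  expect_equal(ch$n_peaks, 0L)
})

test_that("a symmetric central bump has n = 1, one peak, non-extreme argmax", {
  ch <- characterize_curve(gaussian_curve())
  expect_equal(ch$argmax_x, 0.5, tolerance = 1e-9)
  expect_true(ch$non_extreme)
  expect_equal(ch$nonmono, 1, tolerance = 1e-12)
  expect_equal(ch$n_peaks, 1L)
  # nu against an independent least-squares fit
  cv <- gaussian_curve()
  ind <- summary(lm(cv$values ~ cv$grid))$r.squared
  expect_equal(ch$nonlin, 1 - ind, tolerance = 1e-10)
})

test_that("two equal bumps give two peaks and the argmax tie resolves left", {
  grid <- seq(0, 1, length.out = 201)
  v <- exp(-(grid - 0.25)^2 / (2 * 0.04^2)) +
    exp(-(grid - 0.75)^2 / (2 * 0.04^2))
  ch <- characterize_curve(list(grid = grid, values = v,
                                domain = c(0, 1)))
  expect_equal(ch$n_peaks, 2L)
  expect_equal(ch$nonmono, 1, tolerance = 1e-9)
  expect_equal(ch$argmax_x, 0.25, tolerance = 1e-9)
})

test_that("constant curves are degenerate with zero indices by convention", {
  ch <- characterize_curve(list(grid = seq(0, 1, length.out = 11),
                                values = rep(2, 11), domain = c(0, 1)))
  expect_true(ch$degenerate)
  expect_equal(ch$nonmono, 0)
  expect_equal(ch$nonlin, 0)
  expect_equal(ch$n_peaks, 0L)
})

test_that("nu is affine-invariant and n is shift-invariant", {
  set.seed(2)
  b <- make_basis("gaussian", K = 10, domain = c(0, 1), width = 0.04)
  for (i in 1:10) {
    w <- runif(10, -0.5, 0.5)
    tc <- tuning_curve(w, b)
    ch <- characterize_curve(tc)
    tc2 <- tc
    tc2$values <- 3.7 * tc$values - 1.2
    ch2 <- characterize_curve(tc2)
    expect_equal(ch2$nonlin, ch$nonlin, tolerance = 1e-9)
    tc3 <- tc
    tc3$values <- tc$values + 5
    expect_equal(characterize_curve(tc3)$nonmono, ch$nonmono,
                 tolerance = 1e-9)
    expect_true(ch$nonmono >= 0 && ch$nonmono <= 1)
    expect_true(ch$nonlin >= 0 && ch$nonlin <= 1)
  }
})

test_that("peak counting agrees with the exhaustive prominence oracle", {
  set.seed(3)
  b <- make_basis("gaussian", K = 10, domain = c(0, 1), width = 0.04)
  grid <- seq(0, 1, length.out = 201)
  F <- eval_basis(b, grid)
  for (i in 1:1000) {
    v <- drop(F %*% runif(10, -0.5, 0.5))
    expect_identical(count_peaks(v), oracle_count_peaks(v))
  }
  # also on rougher non-smooth curves
  for (i in 1:200) {
    v <- cumsum(rnorm(60))
    expect_identical(count_peaks(v), oracle_count_peaks(v))
  }
})

test_that("empirical-null p-values and BH selection behave as specified", {
  null_r2 <- seq(0, 0.99, length.out = 100)
  sel <- select_units(c(1.5, 0.5), null_r2, alpha = 0.05)
  expect_equal(sel$p[1], 1 / 101, tolerance = 1e-12)
  expect_true(1 %in% sel$selected)
  # BH step-up by hand: {0.001, 0.02, 0.04, 0.2} at q = 0.05 -> first two
  adj <- fdr_bh(c(0.001, 0.02, 0.04, 0.2), q = 0.05)
  expect_identical(adj$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(select_units(1, numeric(0)), "empty")
  # all-noise selection stays near the FDR level
  set.seed(4)
  frac <- mean(replicate(50, {
    r2 <- sample(null_r2, 20, replace = TRUE) + runif(20, 0, 0.01)
    length(select_units(r2, null_r2)$selected) > 0
  }))
  expect_lt(frac, 0.3)
})

test_that("split-half weights correlate perfectly on identical noiseless halves", {
  cfg <- task_config(n_stimuli = 80L, n_sessions = 4L)
  spec <- encoding_spec("versatile", "probability")
  sim <- simulate_experiment(cfg, spec, n_voxels = 5, noise_ratio = 0,
                             seed = 8)
  # use the same two sessions in both halves: identical data
  Xp <- preprocess_sessions(lapply(sim$designs, `[[`, "X"), tr = 2)
  Yp <- preprocess_sessions(sim$Y, tr = 2)
  mask <- sim$designs[[1]]$interest_mask
  r_same <- split_half_reliability(Xp, Yp, mask,
                                   halves = list(c(1, 2), c(1, 2)))
  expect_equal(r_same, 1, tolerance = 1e-9)
  # noiseless disjoint halves still recover the common code
  r_disjoint <- split_half_reliability(Xp, Yp, mask)
  expect_gt(r_disjoint, 0.95)
  # pure-noise voxels decorrelate the halves
  set.seed(9)
  Yn <- preprocess_sessions(noise_sessions(sim$seqs, 5), tr = 2)
  r_noise <- split_half_reliability(Xp, Yn, mask)
  expect_lt(abs(r_noise), 0.5)
  expect_error(split_half_reliability(Xp, Yp, mask,
                                      halves = list(1, c(2, 5))),
               "halves")
})

test_that("FDR selection on independent noise does not manufacture reliability", {
  cfg <- task_config(n_stimuli = 100L, n_sessions = 4L)
  set.seed(12)
  seqs <- lapply(1:4, function(s) generate_sequence(cfg, seed = NULL))
  spec <- encoding_spec("versatile", "probability")
  designs <- lapply(seq_along(seqs), function(s)
    build_design(seqs[[s]],
                 run_ideal_observer(seqs[[s]]$values, observer_config()),
                 spec))
  Xp <- preprocess_sessions(lapply(designs, `[[`, "X"), tr = 2)
  mask <- designs[[1]]$interest_mask
  # selection driven by one noise dataset, reliability measured on an
  # independent one: the selected units must stay at chance
  Y_sel <- preprocess_sessions(noise_sessions(seqs, 40), tr = 2)
  r2_sel <- colMeans(probencode:::cv_core(Xp, mask, Y_sel, list(),
                                          1)$r2)
  top <- order(r2_sel, decreasing = TRUE)[1:10]
  Y_ind <- preprocess_sessions(noise_sessions(seqs, 40), tr = 2)
  r <- split_half_reliability(Xp, Y_ind, mask, units = top)
  expect_lt(abs(r), 0.4)
})

test_that("the ridge-penalty grid search returns a candidate with the best simulated score", {
  cfg <- task_config(n_stimuli = 60L, n_sessions = 2L)
  seqs <- lapply(1:2, function(s) generate_sequence(cfg, seed = 40 + s))
  out <- suppressWarnings(
    tune_ridge_lambda(seqs, encoding_spec("versatile", "probability"),
                      lambdas = c(1, 1e6), n_voxels = 3L, n_null = 6L,
                      seed = 2))
  expect_true(out$best %in% c(1, 1e6))
  expect_equal(out$scores$mean_z_r2[out$scores$lambda == out$best],
               max(out$scores$mean_z_r2))
})

test_that("group characterization separates bump-coded from linear-coded cohorts", {
  b <- make_basis("gaussian", K = 10, domain = c(0, 1), width = 0.04)
  set.seed(5)
  bump_tabs <- lapply(1:4, function(p) {
    W <- sapply(1:12, function(v) {
      w <- runif(10, -0.05, 0.05)
      w[sample(2:9, 1)] <- 1
      if (runif(1) < 0.3) w[sample(2:9, 1)] <- 0.9
      w
    })
    characterize_units(W, b)
  })
  lin_tabs <- lapply(1:4, function(p) {
    W <- sapply(1:12, function(v) seq(0.1, 1, length.out = 10) *
                  sample(c(-1, 1), 1) + rnorm(10, sd = 0.02))
    characterize_units(W, b)
  })
  g <- group_characterization(bump_tabs, lin_tabs)
  expect_true(all(g$per_participant$prop_non_extreme >= 0 &
                    g$per_participant$prop_non_extreme <= 1))
  tt <- g$tests
  expect_gt(tt$t[tt$measure == "mean_nonmono"], 0)
  expect_gt(tt$t[tt$measure == "mean_nonlin"], 0)
  expect_gt(tt$t[tt$measure == "prop_non_extreme"], 0)
  # identical groups give t = 0
  g0 <- group_characterization(bump_tabs, bump_tabs)
  expect_equal(g0$tests$t, rep(0, 4), tolerance = 1e-12)
  expect_error(group_characterization(bump_tabs[1], lin_tabs), "2")
})
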