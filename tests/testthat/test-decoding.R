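bin_coded_experiment <- function(n_voxels = 30L, noise_ratio = 0,
                                 seed = 5, n_stimuli = 420L,
                                 estimate = "probability") {
  spec5 <- encoding_spec("versatile", estimate, K = 5)
  set.seed(seed)
  W <- matrix(runif(5 * n_voxels, -0.05, 0.05), 5, n_voxels)
  for (v in seq_len(n_voxels)) W[sample(5, 1), v] <- 1
  simulate_experiment(task_config(n_stimuli = n_stimuli), spec5,
                      n_voxels = n_voxels, noise_ratio = noise_ratio,
                      seed = seed, weights = W)
}

test_that("n_top above the available units clamps with a warning", {
  sim <- bin_coded_experiment(n_voxels = 8L, n_stimuli = 100L)
  expect_warning(
    bp <- estimate_bin_patterns(sim$seqs, sim$Y, n_top = 100,
                                n_null = 0, reports = sim$reports),
    "using all")
  expect_length(bp$folds[[1]]$selected, 8L)
})

test_that("unit selection depends on training sessions only", {
  sim <- bin_coded_experiment(n_voxels = 15L, noise_ratio = 9,
                              n_stimuli = 150L, seed = 6)
  bp1 <- estimate_bin_patterns(sim$seqs, sim$Y, n_top = 5, n_null = 15,
                               seed = 2, reports = sim$reports)
  Y2 <- sim$Y
  set.seed(99)
  Y2[[1]] <- matrix(rnorm(length(Y2[[1]])), nrow(Y2[[1]]))
  bp2 <- estimate_bin_patterns(sim$seqs, Y2, n_top = 5, n_null = 15,
                               seed = 2, reports = sim$reports)
  # fold 1 leaves session 1 out: its selection must not change when the
  # test-session data are replaced
  expect_identical(bp1$folds[[1]]$selected, bp2$folds[[1]]$selected)
})

test_that("noiseless bin-coded voxels give near-perfect patterns and accuracy 1", {
  sim <- bin_coded_experiment()
  bp <- suppressWarnings(
    estimate_bin_patterns(sim$seqs, sim$Y, n_null = 0,
                          reports = sim$reports))
  f <- bp$folds[[1]]
  for (j in 1:5) {
    expect_gt(cor(f$train[, j], f$test[, j]), 0.99)
  }
  dec <- decode_bins(bp)
  expect_equal(dec$accuracy, 1)
})

test_that("RDM cells follow the correlation-distance arithmetic", {
  train <- cbind(c(1, 2, 3), c(3, 1, 2))
  test <- cbind(c(1, 2, 3), c(-1, -2, -3))
  D <- compute_rdm(train = train, test = test)
  expect_equal(D[1, 1], 0, tolerance = 1e-12)      # identical patterns
  expect_equal(D[2, 1], 2, tolerance = 1e-12)      # anti-correlated
  expect_equal(D[1, 2], 1 - cor(c(1, 2, 3), c(3, 1, 2)),
               tolerance = 1e-12)
  expect_true(all(D >= 0 & D <= 2))
  # zero-variance pattern flags the affected cells
  Dz <- compute_rdm(train = cbind(c(1, 1, 1), c(1, 2, 3)),
                    test = test)
  expect_true(all(is.na(Dz[, 1])))
  expect_true(all(attr(Dz, "flagged")[, 1]))
  expect_error(compute_rdm(train = matrix(1, 1, 2),
                           test = matrix(1, 1, 2)), "2 units")
})

test_that("decoding accuracy is invariant to unit-wise affine pattern rescaling", {
  sim <- bin_coded_experiment(noise_ratio = 2, seed = 7,
                              n_stimuli = 200L)
  bp <- suppressWarnings(
    estimate_bin_patterns(sim$seqs, sim$Y, n_null = 0,
                          reports = sim$reports))
  dec1 <- suppressWarnings(decode_bins(bp))
  bp2 <- bp
  bp2$folds <- lapply(bp$folds, function(f) {
    f$train <- 2.5 * f$train + 7
    f$test <- 0.3 * f$test - 1
    f
  })
  dec2 <- suppressWarnings(decode_bins(bp2))
  expect_equal(dec1$accuracy, dec2$accuracy, tolerance = 1e-12)
})

test_that("bins covering under 5% of the test stimuli are excluded", {
  b5 <- make_basis("gaussian", K = 5, domain = c(0, 1))
  # estimates concentrated mid-range: extreme bins see almost no stimuli
  x <- runif(200, 0.4, 0.6)
  valid <- probencode:::bin_validity(x, b5)
  expect_false(valid[1])
  expect_false(valid[5])
  expect_true(valid[3])
})

test_that("RDM regression recovers constructed geometries exactly", {
  n <- 5
  jk_id <- outer(1:n, 1:n, function(j, k) as.numeric(j != k))
  jk_gr <- abs(outer(1:n, 1:n, "-"))
  zs <- function(m) (m - mean(m)) / sd(m)
  D <- 1 + 0.3 * zs(jk_id) + 0.7 * zs(jk_gr)
  fit <- regress_rdm(D)
  expect_equal(fit$coef_identity, 0.3, tolerance = 1e-10)
  expect_equal(fit$coef_graded, 0.7, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$winner, "graded")
  # pure identity structure
  fit_id <- regress_rdm(0.5 + jk_id)
  expect_equal(fit_id$coef_graded, 0, tolerance = 1e-10)
  expect_equal(fit_id$winner, "identity")
  # quadratic graded variant
  fitq <- regress_rdm(1 + zs(jk_gr^2), graded = "quadratic")
  expect_equal(fitq$winner, "graded")
  expect_error(regress_rdm(matrix(1, 1, 1)), "valid")
})

test_that("fold-averaged RDMs ignore invalid rows per fold", {
  f1 <- list(rdm = matrix(1, 2, 2), valid = c(TRUE, FALSE))
  f2 <- list(rdm = matrix(3, 2, 2), valid = c(TRUE, TRUE))
  dec <- list(folds = list(f1, f2), n_bins = 2L)
  avg <- average_rdm(dec)
  expect_equal(avg[1, 1], 2)  # both folds contribute
  expect_equal(avg[2, 1], 3)  # only fold 2's row 2 is valid
  expect_true(all(attr(avg, "valid_rows")))
})

test_that("group decoding stats flag signal regions and test graded fractions", {
  set.seed(11)
  n_p <- 8
  acc <- cbind(rnorm(n_p, 0.45, 0.05),  # strong region
               rnorm(n_p, 0.2, 0.05),   # chance region
               rnorm(n_p, 0.2, 0.05))
  winners <- matrix(sample(c("graded", "identity"), n_p * 3,
                           replace = TRUE), n_p, 3)
  winners[1, ] <- c("identity", "graded", "graded")
  g <- group_decoding_stats(acc, winners)
  expect_true(g$regions$significant[1])
  expect_equal(nrow(g$regions), 3L)
  expect_equal(g$graded_fraction[1], 2 / 3)
  # all accuracies exactly at chance give t = 0
  acc0 <- matrix(0.2, 4, 1) + c(-0.02, -0.01, 0.01, 0.02)
  g0 <- group_decoding_stats(acc0, winners = NULL)
  expect_equal(g0$regions$t[1], 0, tolerance = 1e-9)
  expect_error(group_decoding_stats(acc[1, , drop = FALSE]), "2")
})
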