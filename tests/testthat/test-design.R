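make_toy_session <- function(n = 40L, seed = 11) {
  cfg <- small_task(n)
  sq <- generate_sequence(cfg, seed = seed)
  tr <- run_ideal_observer(sq, observer_config())
  list(cfg = cfg, sq = sq, tr = tr)
}

test_that("a single unit impulse reproduces the HRF sampled at the TR grid", {
  hrf <- hrf_spec()
  times <- seq(0, 40, by = 2)
  H <- event_operator(times, onsets = 5, hrf)
  expect_equal(drop(H), hrf_at(times - 5, hrf), tolerance = 1e-12)
  # all-zero modulator gives a zero column
  expect_equal(drop(H %*% 0), rep(0, length(times)))
})

test_that("interest columns equal the direct sum of shifted, scaled HRF copies", {
  hrf <- hrf_spec()
  toy <- make_toy_session(3L)
  sq <- toy$sq
  spec <- encoding_spec("versatile", "probability")
  d <- build_design(sq, toy$tr, spec, hrf)
  F <- eval_basis(spec$basis, toy$tr$estimates$p_hat)
  for (i in c(1, 5, 10)) {
    manual <- rowSums(sapply(1:3, function(j)
      F[j, i] * hrf_at(d$scan_times - sq$onsets[j], hrf)))
    expect_equal(unname(d$X[, i]), manual, tolerance = 1e-12)
  }
  expect_equal(sum(d$interest_mask), 10L)
})

test_that("linear-class design has one interest column holding the estimate", {
  toy <- make_toy_session()
  d <- build_design(toy$sq, toy$tr, encoding_spec("linear", "probability"))
  expect_equal(sum(d$interest_mask), 1L)
  expect_true(all(c("const", "surprise", "entropy") %in% d$labels))
})

test_that("entropy is dropped from no-interest when it is the estimate of interest", {
  toy <- make_toy_session()
  d <- build_design(toy$sq, toy$tr, encoding_spec("linear", "entropy"))
  expect_false("entropy" %in% d$labels)
  expect_true("surprise" %in% d$labels)
})

test_that("confidence values outside the domain are clamped with a warning", {
  toy <- make_toy_session(60L, seed = 4)
  spec <- encoding_spec("versatile", "confidence",
                        domain = c(1.5, 1.6), width = 0.05)
  expect_warning(d <- build_design(toy$sq, toy$tr, spec), "clamped")
  expect_gt(d$n_clamped, 0)
})

test_that("posterior-expectation modulators are grid quadratures of the basis", {
  toy <- make_toy_session()
  obs <- observer_config()
  spec <- encoding_spec("posterior_expectation", "probability")
  tr <- toy$tr
  M <- probencode:::posterior_expectation_modulators(tr, spec)
  # independent quadrature at a few trials
  Fg <- eval_basis(spec$basis, obs$grid)
  for (t in c(1, 10, 25)) {
    manual <- colSums(tr$prior_pred[t, ] * Fg)
    expect_equal(unname(M[t, ]), unname(manual), tolerance = 1e-10)
  }
  # delta posterior picks out f_i at the atom
  trd <- tr
  trd$prior_pred[1, ] <- 0
  trd$prior_pred[1, 37] <- 1
  Md <- probencode:::posterior_expectation_modulators(trd, spec)
  expect_equal(unname(Md[1, ]),
               unname(eval_basis(spec$basis, obs$grid[37])[1, ]),
               tolerance = 1e-12)
  # uniform posterior gives the grid mean of each basis function
  tru <- tr
  tru$prior_pred[2, ] <- 1 / length(obs$grid)
  Mu <- probencode:::posterior_expectation_modulators(tru, spec)
  expect_equal(unname(Mu[2, ]), unname(colMeans(Fg)), tolerance = 1e-12)
})

test_that("preprocessing zeroes constants and within-session linear trends", {
  n <- 120
  sessions <- list(matrix(c(rep(3.7, n), 5 + 0.01 * seq_len(n)), n, 2))
  out <- preprocess_sessions(sessions, tr = 2)
  expect_lt(max(abs(out[[1]])), 1e-8)
  expect_error(preprocess_sessions(list(matrix(1, 1, 1))), "2 scans")
})

test_that("the high-pass stage attenuates slow sinusoids as its projection predicts", {
  n <- 256
  tr <- 2
  t_sec <- (seq_len(n) - 1) * tr
  slow <- sin(2 * pi * t_sec / 256)
  # independent prediction: residual of OLS projection on the same
  # drift model (intercept + trend + DCT up to the cutoff)
  k_max <- floor(2 * n * tr / 128)
  B <- cbind(1, seq_len(n) - 1)
  for (k in seq_len(k_max)) {
    B <- cbind(B, cos(pi * (2 * (seq_len(n) - 1) + 1) * k / (2 * n)))
  }
  expected <- residuals(lm(slow ~ B - 1))
  got <- probencode:::session_filter_matrix(n, tr) %*% slow
  expect_equal(drop(got), unname(expected), tolerance = 1e-8)
  atten <- sqrt(sum(got^2) / sum(slow^2))
  expect_lt(atten, 0.3)  # 1/256 Hz lies below the 1/128 Hz cutoff
  # a fast sinusoid passes through nearly unchanged
  fast <- sin(2 * pi * t_sec / 20)
  kept <- probencode:::session_filter_matrix(n, tr) %*% fast
  expect_gt(sqrt(sum(kept^2) / sum(fast^2)), 0.95)
})

test_that("after preprocessing every column is session-demeaned and data/regressors share the pipeline", {
  toy1 <- make_toy_session(50L, seed = 21)
  toy2 <- make_toy_session(50L, seed = 22)
  ds <- lapply(list(toy1, toy2), function(x)
    build_design(x$sq, x$tr, encoding_spec("versatile", "probability")))
  Xp <- preprocess_sessions(lapply(ds, `[[`, "X"), tr = 2)
  for (m in Xp) expect_lt(max(abs(colMeans(m))), 1e-10)
  # z-scoring is across the concatenation: pooled variance ~ 1 for
  # non-degenerate columns
  pooled <- apply(do.call(rbind, Xp), 2, sd)
  expect_true(all(abs(pooled[pooled > 0] - 1) < 0.1))
})

test_that("session permutation permutes preprocessing output accordingly", {
  set.seed(8)
  sessions <- lapply(c(30, 40, 35), function(n) matrix(rnorm(n * 3), n, 3))
  out <- preprocess_sessions(sessions, tr = 2)
  out_perm <- preprocess_sessions(sessions[c(3, 1, 2)], tr = 2)
  expect_equal(out_perm, out[c(3, 1, 2)], tolerance = 1e-12)
})
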