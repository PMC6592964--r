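test_that("standardization matrix basics", {
  # identity lead field + AR: pinv of the centering projector is itself
  R <- standardization_matrix(diag(5), ur_weights("AR", n_channels = 5))
  expect_equal(R, t_ar(5), tolerance = 1e-12)
  # R_r depends on the prior reference ...
  K <- random_leadfield(8, 120, seed = 21)
  fam <- ur_family(8, K)
  R_rr <- standardization_matrix(K, fam$RR)
  R_ar <- standardization_matrix(K, fam$AR)
  expect_gt(max(abs(R_rr - R_ar)), 1e-3)
  expect_error(standardization_matrix(matrix(1, 8, 12), fam$RR),
               "full-row-rank")
})

test_that("REST is a UR: the composed route equals the unipolar route for
           every prior reference", {
  cases <- list(random_leadfield(8, 120, seed = 31),
                random_leadfield(16, 300, seed = 32),
                spherical_K(500)$gain)
  for (K in cases) {
    n <- nrow(K)
    T_uni <- rest_operator(K, "unipolar")
    for (f in ur_family(n, K)) {
      T_comp <- rest_operator(K, "composed", f)
      expect_lt(max(abs(T_comp - T_uni)), 1e-9)
    }
    # ... and T_REST is itself a UR with all three family properties
    f_rest <- rest_weights(K)
    op <- ur_operator(f_rest)
    expect_lt(max(abs(op$matrix - T_uni)), 1e-12)
    expect_identical(rank_deficiency(op), 1L)
    expect_lt(centering_deviation(op), 1e-10)
    expect_lt(max(abs(T_uni %*% rep(1, n))), 1e-12)
  }
  # identity lead field: REST collapses to the average reference
  expect_equal(rest_operator(diag(6)), t_ar(6), tolerance = 1e-12)
  expect_equal(rest_operator(diag(6), "composed",
                             ur_weights("RR", n_channels = 6, anchors = 2)),
               t_ar(6), tolerance = 1e-12)
})

test_that("REST reconstruction on noise-free data leaves a rank-one residual", {
  K <- spherical_K(300)
  sim <- simulate_recording(K, 40,
                            reference = ur_weights("RR", n_channels = 19,
                                                   anchors = 5),
                            seed = 41)
  est <- rest_estimate(sim$v, K)
  offset <- as.numeric(crossprod(rest_weights(K)$w, sim$phi$data))
  resid <- est$data - sim$phi$data
  expect_lt(max(abs(sweep(resid, 2, -offset))), 1e-8)
  # constant-channel data maps to zero; the estimate is a fixed point
  expect_lt(max(abs(suppressWarnings(
    rest_estimate(matrix(3, 19, 2), K))$data)), 1e-10)
  again <- apply_reference(est, ur_operator(rest_weights(K)))
  expect_lt(max(abs(again$data - est$data)), 1e-10)
})

test_that("rREST: lambda = 0 is classical REST, large lambda shrinks to zero", {
  K <- spherical_K(300)
  fam <- ur_family(19, K$gain)
  sim <- simulate_recording(K, 25, reference = fam$AR, seed = 43)
  rest <- rest_estimate(sim$v, K)$data
  for (f in fam) {
    v <- apply_reference(sim$phi, ur_operator(f))
    out <- rrest_operator(K, ur_operator(f)$matrix, 0) %*% v$data
    expect_lt(max(abs(out - rest_estimate(v, K)$data)), 1e-8)
  }
  scale <- sum(K$gain^2) / 19
  big <- rrest_operator(K, ur_operator(fam$AR)$matrix, 1e12 * scale)
  expect_lt(norm(big, "F"), 1e-8)
  expect_error(rrest_operator(K, ur_operator(fam$AR)$matrix, -1), ">= 0")
})

test_that("rREST coincides with the Bayesian MAP estimator under the
           IID-source prior", {
  K <- random_leadfield(12, 150, seed = 44)
  fam <- ur_family(12, K)
  set.seed(45)
  x <- matrix(rnorm(12 * 10), 12, 10)
  for (f in fam) {
    To <- ur_operator(f)$matrix
    xr <- To %*% x
    for (lam in c(0, 0.05, 1)) {
      a <- rrest_operator(K, To, lam) %*% xr
      b <- map_estimate(xr, To, "iid_sources", alpha2 = 1, sigma2 = lam,
                        K = K)
      expect_lt(max(abs(a - b)), 1e-8)
    }
  }
})

test_that("GCV selects no regularization on clean data and strictly positive
           regularization on noisy data", {
  K <- spherical_K(300)
  fAR <- ur_weights("AR", n_channels = 19)
  clean <- simulate_recording(K, 50, reference = fAR, seed = 7)
  sel0 <- select_lambda_gcv(clean$v, K)
  expect_equal(nrow(sel0$curve), 40L)
  scale <- max(sel0$curve$lambda) / 1e2
  # clean data: lambda* stays in the flat basin near zero ...
  expect_lt(sel0$lambda, 0.05 * scale)
  est0 <- rrest_operator(K, ur_operator(fAR)$matrix, sel0$lambda) %*%
    clean$v$data
  expect_lt(rel_err(est0, rest_estimate(clean$v, K)$data), 0.1)
  # ... noisy data at 0 dB pushes it well inside the grid
  s2 <- mean(rowSums(K$gain^2))
  noisy <- simulate_recording(K, 50, reference = fAR, sigma2 = s2, seed = 7)
  expect_lt(abs(noisy$snr_db), 3)
  seln <- select_lambda_gcv(noisy$v, K)
  expect_gt(seln$lambda, min(seln$curve$lambda))
  expect_gt(seln$lambda, 100 * sel0$lambda)
  expect_error(select_lambda_gcv(noisy$v, K, grid = numeric(0)), "empty")
  expect_error(select_lambda_gcv(noisy$v, K, grid = c(0, 1)),
               "strictly positive")
})

test_that("GCV-tuned rREST beats unregularized REST on noisy recordings", {
  K <- spherical_K(300)
  fAR <- ur_weights("AR", n_channels = 19)
  To <- ur_operator(fAR)$matrix
  s2 <- mean(rowSums(K$gain^2))           # SNR ~ 0 dB
  R0 <- rrest_operator(K, To, 0)
  wins <- 0L
  n_trials <- 100L
  for (t in seq_len(n_trials)) {
    sim <- simulate_recording(K, 50, reference = fAR, sigma2 = s2,
                              seed = 100L + t)
    sel <- select_lambda_gcv(sim$v, K)
    e0 <- rel_err(R0 %*% sim$v$data, sim$phi$data)
    e1 <- rel_err(rrest_operator(K, To, sel$lambda) %*% sim$v$data,
                  sim$phi$data)
    wins <- wins + (e1 <= e0)
  }
  expect_gte(wins, 0.8 * n_trials)
})
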