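test_that("model reduction drops the right row and keeps full row rank", {
  m <- montage_1020()
  fRR <- ur_weights("RR", montage = m, anchors = "Cz")
  rm_rr <- reduce_model(ur_operator(fRR))
  expect_identical(rm_rr$dropped_index, match("Cz", m$labels))
  expect_lt(max(abs(rm_rr$t_r)), 1e-15)          # the physical-reference row is zero
  expect_equal(mat_rank(rm_rr$T_minus), 18L)
  fLM <- ur_weights("LM", n_channels = 19, anchors = c(2, 7))
  expect_identical(reduce_model(ur_operator(fLM))$dropped_index, 2L)
  opAR <- ur_operator(ur_weights("AR", n_channels = 3))
  rm_ar <- reduce_model(opAR, drop = 2)
  expect_equal(dim(rm_ar$T_minus), c(2L, 3L))
  expect_equal(mat_rank(rm_ar$T_minus), 2L)
  expect_identical(reduce_model(opAR)$dropped_index, 3L)
  # dropping a non-reference row of an RR operator keeps its zero row and
  # cannot give full row rank: the guard must fire
  op_rr19 <- ur_operator(fRR)
  expect_error(reduce_model(op_rr19, drop = 1), "full-row-rank")
  # stacking the dropped row back reproduces the operator
  Tm <- matrix(0, 3, 3)
  Tm[-2, ] <- rm_ar$T_minus
  Tm[2, ] <- rm_ar$t_r
  expect_equal(Tm, opAR$matrix)
})

test_that("constrained BLUE: both routes agree, the zero-sum constraint
           holds, and the noise-free limit is the average reference", {
  for (n in c(3L, 19L, 32L)) {
    K <- random_leadfield(n, 3L * n, seed = n + 7L)
    set.seed(n)
    phi <- K %*% matrix(rnorm(3L * n * 6L), 3L * n, 6L)
    for (f in ur_family(n, K)) {
      op <- ur_operator(f)
      v <- eeg_data(op$matrix %*% phi, reference = f)
      rm <- reduce_model(op, v)
      est_simpl <- blue_ar(rm)
      est_full <- blue_ar(rm, method = "full")
      expect_lt(max(abs(est_simpl - est_full)), 1e-9)
      expect_lt(max(abs(colSums(est_simpl))), 1e-9)
      expect_lt(max(abs(est_simpl - t_ar(n) %*% phi)), 1e-9)
    }
  }
})

test_that("the closed-form inverse of P = T-' (T- T-')^-1 T- + 11' is exact", {
  for (n in c(5L, 19L)) {
    K <- random_leadfield(n, 2L * n, seed = n + 50L)
    for (f in ur_family(n, K)) {
      Tm <- reduce_model(ur_operator(f))$T_minus
      P <- t(Tm) %*% solve(Tm %*% t(Tm)) %*% Tm + matrix(1, n, n)
      Pinv_closed <- diag(n) - (n - 1) * matrix(1, n, n) / n^2
      expect_lt(max(abs(P %*% Pinv_closed - diag(n))), 1e-10)
    }
  }
})

test_that("MLE REST: direct and SVD routes agree; lambda = 0 equals the
           classical REST estimate; large lambda shrinks", {
  K <- spherical_K(300)
  fam <- ur_family(19, K$gain, anchors_rr = 10L)
  sim <- simulate_recording(K, 20, reference = fam$RR, seed = 51)
  rest_ref <- rest_estimate(sim$v, K)$data
  for (f in fam) {
    op <- ur_operator(f)
    v <- apply_reference(sim$phi, op)
    rm <- reduce_model(op, v)
    e_dir <- mle_rest(rm, K, 0)
    e_svd <- mle_rest(rm, K, 0, method = "svd")
    expect_lt(max(abs(e_dir - e_svd)), 1e-9)
    expect_lt(max(abs(e_dir - rest_estimate(v, K)$data)), 1e-8)
    e_dir1 <- mle_rest(rm, K, 0.02)
    e_svd1 <- mle_rest(rm, K, 0.02, method = "svd")
    expect_lt(max(abs(e_dir1 - e_svd1)), 1e-9)
  }
  opAR <- ur_operator(fam$AR)
  v <- apply_reference(sim$phi, opAR)
  rm <- reduce_model(opAR, v)
  scale <- sum(K$gain^2) / 19
  expect_lt(max(abs(mle_rest(rm, K, 1e10 * scale))),
            1e-6 * max(abs(mle_rest(rm, K, 0))))
  # estimate does not depend on which admissible row was dropped
  rm_b <- reduce_model(opAR, v, drop = 4)
  expect_lt(max(abs(mle_rest(rm_b, K, 0) - mle_rest(rm, K, 0))), 1e-9)
  expect_lt(max(abs(blue_ar(rm_b) - blue_ar(rm))), 1e-9)
})

test_that("Bayesian MAP limits: IID potentials recover AR, IID sources
           recover REST, for every embedded UR", {
  K <- spherical_K(300)
  fam <- ur_family(19, K$gain, anchors_rr = 3L)
  sim <- simulate_recording(K, 15, reference = fam$AR, seed = 61)
  for (f in fam) {
    op <- ur_operator(f)
    x <- apply_reference(sim$phi, op)
    est_ar <- map_estimate(x, op, "iid_potentials", sigma2 = 0)
    expect_lt(max(abs(est_ar - t_ar(19) %*% x$data)), 1e-8)
    est_rest <- map_estimate(x, op, "iid_sources", sigma2 = 0, K = K)
    expect_lt(max(abs(est_rest - rest_estimate(x, K)$data)), 1e-8)
  }
  expect_lt(max(abs(map_estimate(matrix(0, 19, 3), ur_operator(fam$AR),
                                 "iid_potentials"))), 1e-15)
  expect_error(map_estimate(sim$v, ur_operator(fam$AR), "iid_sources"),
               "lead field")
  expect_error(map_estimate(sim$v, ur_operator(fam$AR), alpha2 = 0), "> 0")
})
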