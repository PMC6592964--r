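test_that("weight vectors of the family match their defining forms", {
  expect_equal(ur_weights("RR", n_channels = 4, anchors = 3)$w,
               c(0, 0, 1, 0))
  expect_equal(ur_weights("LM", n_channels = 4, anchors = c(2, 4))$w,
               c(0, 0.5, 0, 0.5))
  expect_equal(ur_weights("AR", n_channels = 4)$w, rep(0.25, 4))
  m <- montage_1020(mastoids = TRUE)
  f <- ur_weights("RR", montage = m, anchors = "Cz")
  expect_equal(which(f$w == 1), match("Cz", m$labels))
  # LM auto-detection is case-insensitive over the known mastoid pairs
  lm <- ur_weights("LM", montage = m)
  expect_equal(sort(lm$anchors), sort(match(c("A1", "A2"), m$labels)))
  expect_equal(sum(lm$w == 0.5), 2L)
  expect_error(ur_weights("RR", montage = m, anchors = "Nope"),
               "not in montage")
  expect_error(ur_weights("LM", montage = montage_1020()), "no mastoid pair")
  expect_error(ur_weights("custom", weights = c(0.4, 0.4)), "sum to 1")
})

test_that("every family member's weights sum to one", {
  K <- random_leadfield(8, 100, seed = 2)
  fam <- ur_family(8, K)
  for (f in fam) expect_lt(abs(sum(f$w) - 1), 1e-12)
  Ks <- spherical_K(300)
  expect_lt(abs(sum(rest_weights(Ks)$w) - 1), 1e-12)
})

test_that("REST weights: identity lead field gives AR, and the weights are
           scale invariant", {
  f <- rest_weights(diag(6))
  expect_equal(f$w, rep(1 / 6, 6))
  K <- random_leadfield(8, 100, seed = 2)
  expect_equal(rest_weights(K)$w, rest_weights(37.5 * K)$w, tolerance = 1e-10)
  expect_error(rest_weights(matrix(1, 4, 10)), "full-row-rank")
})

test_that("operators have the rank-one structure I - 1 f'", {
  op <- ur_operator(c(0.5, 0.5))
  expect_equal(op$matrix, rbind(c(0.5, -0.5), c(-0.5, 0.5)))
  op2 <- ur_operator(ur_weights("RR", n_channels = 3, anchors = 1))
  expect_equal(op2$matrix,
               rbind(c(0, 0, 0), c(-1, 1, 0), c(-1, 0, 1)))
  expect_error(ur_operator(c(0.7, 0.2)), "sum to 1")
  K <- random_leadfield(7, 50, seed = 4)
  for (f in ur_family(7, K)) {
    Tm <- ur_operator(f)$matrix
    expect_lt(max(abs(Tm - (diag(7) - outer(rep(1, 7), f$w)))), 1e-12)
    expect_lt(max(abs(Tm %*% rep(1, 7))), 1e-12)          # T 1 = 0
    expect_lt(max(abs(Tm %*% Tm - Tm)), 1e-12)            # idempotent
  }
})

test_that("re-referencing acts on data as expected", {
  opAR <- ur_operator(ur_weights("AR", n_channels = 3))
  d <- eeg_data(matrix(c(1, 2, 3), 3, 1), reference = "infinity")
  out <- apply_reference(d, opAR)
  expect_equal(unname(out$data), matrix(c(-1, 0, 1), 3, 1))
  expect_identical(out$reference$kind, "AR")
  # constant-in-channels data is annihilated by any UR
  dc <- eeg_data(matrix(5, 3, 4), reference = "infinity")
  expect_lt(max(abs(apply_reference(dc, opAR)$data)), 1e-12)
  # idempotence
  twice <- apply_reference(apply_reference(d, opAR), opAR)
  expect_equal(twice$data, out$data, tolerance = 1e-14)
  expect_warning(apply_reference(eeg_data(matrix(1:6, 3)), opAR), "unknown")
  expect_error(apply_reference(matrix(1, 4, 2), opAR), "channels")
})

test_that("no-memory: a new UR annihilates any previous UR", {
  K <- random_leadfield(19, 150, seed = 6)
  ops <- lapply(ur_family(19, K), ur_operator)
  for (a in names(ops)) {
    for (b in names(ops)) {
      expect_lt(no_memory_deviation(ops[[a]], ops[[b]]), 1e-12)
    }
  }
  # operational restatement on data: re-referencing twice equals once
  d <- eeg_data(matrix(rnorm(19 * 7), 19), reference = "infinity")
  for (a in names(ops)) {
    for (b in names(ops)) {
      once <- apply_reference(d, ops[[a]])
      chained <- apply_reference(apply_reference(d, ops[[b]]), ops[[a]])
      expect_lt(max(abs(chained$data - once$data)), 1e-12)
    }
  }
})

test_that("every UR operator is rank deficient by exactly one", {
  for (n in c(2L, 5L, 19L, 32L, 64L)) {
    K <- random_leadfield(n, 2L * n, seed = n)
    for (f in ur_family(n, K)) {
      expect_identical(rank_deficiency(ur_operator(f)), 1L)
    }
  }
})

test_that("projector centering: T+ T = T_AR for the whole family", {
  for (n in c(5L, 19L, 32L)) {
    K <- random_leadfield(n, 2L * n, seed = n + 100L)
    for (f in ur_family(n, K)) {
      expect_lt(centering_deviation(ur_operator(f)), 1e-10)
    }
  }
  # independent oracle for one case
  Tm <- ur_operator(ur_weights("LM", n_channels = 19,
                               anchors = c(1, 3)))$matrix
  expect_lt(max(abs(MASS::ginv(Tm) %*% Tm - t_ar(19))), 1e-10)
})

test_that("only the average reference operator is symmetric", {
  K <- random_leadfield(9, 40, seed = 12)
  for (f in ur_family(9, K)) {
    Tm <- ur_operator(f)$matrix
    sym <- max(abs(Tm - t(Tm))) < 1e-12
    expect_identical(sym, f$kind == "AR")
  }
})
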