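# AO density-matrix response solver: transforms, projections, solver
# contract and invariants.

test_that("Lowdin transform honors its covariant/contravariant round trip", {
  S <- crossprod(sym_matrix(5)) + diag(5)  # positive definite
  M <- sym_matrix(5, seed = 7)
  expect_equal(lowdin_transform(M, diag(5), "covariant"), M)
  expect_lt(max(abs(lowdin_transform(S, S, "covariant") - diag(5))), 1e-12)
  tr <- lowdin_transform(M, S, "covariant")
  expect_lt(max(abs(lowdin_transform(tr, S, "inverse") - M)), 1e-11)
  half <- vcdpt:::mat_sqrt_pair(S)$half
  expect_lt(max(abs(half %*% half - S)), 1e-12)
  expect_error(lowdin_transform(M, -S, "covariant"), "positive definite")
})

test_that("redundant-space projector annihilates occ-occ blocks and is
           idempotent", {
  scf <- fix_scf("h2o")
  D <- scf$D0; S <- scf$S0
  expect_lt(max(abs(project_redundant(D, D, S))), 1e-10)
  A <- sym_matrix(nrow(D), seed = 3)
  P1 <- project_redundant(A, D, S)
  expect_lt(max(abs(project_redundant(P1, D, S) - P1)), 1e-10)
  # 2x2 orthonormal hand case
  D2 <- diag(c(1, 0)); S2 <- diag(2)
  A2 <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(project_redundant(A2, D2, S2),
               matrix(c(0, 2, 3, 0), 2, 2))
})

test_that("occupied-occupied block resolves the differentiated idempotency
           condition", {
  scf <- fix_scf("h2o")
  D <- scf$D0; S <- scf$S0
  n <- nrow(D)
  expect_equal(occ_occ_block(D, matrix(0, n, n)), matrix(0, n, n))
  ch <- fix_channels("h2o", "nvpt")[[2]]
  r <- fix_responses("h2o", "nvpt")[[2]]
  d <- r$d1; s1 <- ch$s
  expect_lt(max(abs(d %*% S %*% D + D %*% s1 %*% D + D %*% S %*% d - d)),
            1e-10)
})

test_that("zero perturbation yields exactly zero response", {
  scf <- fix_scf("h2")
  n <- nrow(scf$D0)
  pr <- list(flavor = "real", h = matrix(0, n, n), s = matrix(0, n, n),
             coupling = TRUE, label = "null")
  r <- solve_response(pr, scf)
  expect_equal(r$d1, matrix(0, n, n))
  expect_equal(r$n_iter, 0L)
})

test_that("solver preserves the hermiticity class of each flavor and meets
           the residual threshold", {
  for (set in c("ndpt", "nvpt", "mfpt")) {
    rs <- fix_responses("h2o", set)
    for (r in rs) {
      expect_lte(r$residual_norm, 5e-12)
      if (r$flavor == "real") expect_symmetric(r$d1, 1e-10)
      else expect_antisymmetric(r$d1, 1e-10)
    }
  }
})

test_that("electron number is conserved to first order in every channel", {
  scf <- fix_scf("h2o")
  S <- scf$S0; D <- scf$D0
  for (set in c("ndpt", "nvpt", "mfpt")) {
    ch <- fix_channels("h2o", set)
    rs <- fix_responses("h2o", set)
    for (k in seq_along(rs)) {
      expect_lt(abs(sum(rs[[k]]$d1 * S) + sum(D * ch[[k]]$s)), 5e-11)
    }
  }
})

test_that("an electric-field-like channel (zero overlap derivative) has a
           vanishing occ-occ block and matches the Sternheimer solver", {
  scf <- fix_scf("h2o")
  ints <- scf$ints
  n <- ints$n
  pr <- list(flavor = "real", h = ints$Dip[[3]], s = matrix(0, n, n),
             coupling = TRUE, label = "efield-z")
  r_ao <- solve_response(pr, scf)
  expect_lt(max(abs(r_ao$d1_oo)), 1e-14)
  r_mo <- solve_sternheimer(pr, scf)
  expect_lt(max(abs(r_ao$d1 - r_mo$d1)), 1e-8)
})
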