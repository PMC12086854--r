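# MO Sternheimer solver: the independent validation path.

test_that("density-response assembly has the right hermiticity class and
           reduces to zero for zero coefficients", {
  scf <- fix_scf("h2o")
  C0 <- scf$C0[, seq_len(scf$n_occ), drop = FALSE]
  zero <- matrix(0, nrow(C0), ncol(C0))
  expect_equal(assemble_density_response(C0, zero, "real"),
               matrix(0, nrow(C0), nrow(C0)))
  set.seed(5)
  C1 <- matrix(rnorm(length(C0)), nrow(C0))
  expect_symmetric(assemble_density_response(C0, C1, "real"), 1e-12)
  expect_antisymmetric(assemble_density_response(C0, C1, "imag"), 1e-12)
})

test_that("zero right-hand side gives zero perturbed coefficients", {
  scf <- fix_scf("h2")
  n <- nrow(scf$D0)
  pr <- list(flavor = "imag", h = matrix(0, n, n), s = matrix(0, n, n),
             coupling = TRUE, label = "null")
  r <- solve_sternheimer(pr, scf)
  expect_equal(max(abs(r$C1occ)), 0)
  expect_equal(max(abs(r$d1)), 0)
})

test_that("MO and AO solvers agree channel by channel on every theory", {
  for (set in c("ndpt", "nvpt", "mfpt")) {
    ao <- fix_responses("h2o", set, "ao")
    mo <- fix_responses("h2o", set, "mo")
    dev <- max(mapply(function(a, b) max(abs(a$d1 - b$d1)), ao, mo))
    expect_lt(dev, 1e-8)
  }
})

test_that("recovered coefficient response reproduces the Sternheimer
           solver's one-sided product", {
  scf <- fix_scf("h2o")
  C0 <- scf$C0[, seq_len(scf$n_occ), drop = FALSE]
  for (set in c("ndpt", "nvpt")) {
    ch <- fix_channels("h2o", set)[[3]]
    r <- solve_sternheimer(ch, scf)
    U_direct <- tcrossprod(r$C1occ, C0)
    U_rec <- recover_u(scf, r$d1, ch$s)
    expect_lt(max(abs(U_direct - U_rec)), 1e-9)
  }
})

test_that("near-degenerate occupied-virtual gaps are refused", {
  # an artificial state with a tiny gap
  scf <- fix_scf("h2")
  scf2 <- scf
  scf2$eps[2] <- scf2$eps[1] + 1e-8
  n <- nrow(scf$D0)
  pr <- list(flavor = "real", h = diag(n), s = matrix(0, n, n),
             coupling = FALSE, label = "x")
  expect_error(solve_sternheimer(pr, scf2), "near-degenerate")
})
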