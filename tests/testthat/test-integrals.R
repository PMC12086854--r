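# Core and first-order integrals against independent oracles: closed
# forms, Gauss-Hermite quadrature, geometric finite differences and
# complex-phase finite differences.

test_that("overlap of two s primitives matches 3-D quadrature", {
  bs <- read_basis(text = c("H S", " 1.0 1.0"))
  mol <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.0)),
                  unit = "bohr")
  basis <- build_ao_basis(mol, bs)
  ints <- compute_core_integrals(mol, basis)
  q12 <- Re(quad_matrix_element(basis$prim, 1, 2))
  expect_equal(ints$S0[1, 2], q12, tolerance = 1e-8)
  # closed form for unit-normalized s pair: exp(-mu R^2), mu = ab/(a+b)
  expect_equal(ints$S0[1, 2], exp(-0.5), tolerance = 1e-12)
  expect_equal(diag(ints$S0), c(1, 1), tolerance = 1e-12)
})

test_that("p-function overlap and kinetic elements match quadrature", {
  bs <- read_basis(text = c("H S", " 0.9 1.0", "H P", " 1.3 1.0"))
  mol <- molecule(c("H", "H"), rbind(c(0.1, -0.2, 0.0), c(0.4, 0.5, 1.1)),
                  unit = "bohr")
  basis <- build_ao_basis(mol, bs)
  ints <- compute_core_integrals(mol, basis)
  for (j in c(2, 4)) { # a p_x and a p_z function
    expect_equal(ints$S0[1, j],
                 Re(quad_matrix_element(basis$prim, 1, j)),
                 tolerance = 1e-8)
  }
})

test_that("ERI tensor has the full 8-fold permutational symmetry", {
  ints <- fix_scf("h2o")$ints
  e <- ints$eri
  expect_lt(max(abs(e - aperm(e, c(2, 1, 3, 4)))), 1e-12)
  expect_lt(max(abs(e - aperm(e, c(1, 2, 4, 3)))), 1e-12)
  expect_lt(max(abs(e - aperm(e, c(3, 4, 1, 2)))), 1e-12)
})

test_that("s-pair Coulomb repulsion matches the two-Gaussian closed form", {
  a <- 1.3; b <- 0.8; R <- 1.7
  bs <- read_basis(text = c("H S", sprintf(" %.10f 1.0", a)))
  bs2 <- read_basis(text = c("H S", sprintf(" %.10f 1.0", b)))
  bs$H <- c(bs$H, bs2$H)
  mol <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, R)), unit = "bohr")
  basis <- build_ao_basis(mol, bs)
  eri <- array(vcdpt:::cpp_eri(basis$prim), rep(basis$n, 4))
  # (11|33): interaction of the two normalized s-squared charge clouds
  # (Gaussians with exponents 2a and 2b): erf(sqrt(2ab/(a+b)) R) / R
  mu <- sqrt(2 * a * b / (a + b))
  closed <- (2 * pnorm(sqrt(2) * mu * R) - 1) / R
  expect_equal(eri[1, 1, 4, 4], closed, tolerance = 1e-12)
})

test_that("del matrices are antisymmetric with zero diagonal", {
  ints <- fix_scf("h2o")$ints
  for (d in 1:3) {
    expect_antisymmetric(ints$Nabla[[d]], 1e-10)
    expect_equal(diag(ints$Nabla[[d]]), rep(0, ints$n))
  }
  for (a in 1:3) expect_antisymmetric(ints$AngMom[[a]], 1e-10)
  for (a in 1:3) expect_symmetric(ints$Dip[[a]], 1e-10)
})

test_that("displacement derivatives of S, h and ERI match geometric FD", {
  mol <- fix_mol("h2o")
  bset <- fix_bset()
  ints <- fix_scf("h2o")$ints
  fd <- fd_core_derivatives(mol, bset, 2, 1, eri = TRUE)
  nd <- nuclear_derivative_integrals(ints, 2, 1)
  expect_lt(max(abs(nd$S1 - fd$S1)), 1e-7)
  expect_lt(max(abs(nd$h1 - (fd$T1 + fd$V1))), 1e-7)
  D <- sym_matrix(ints$n)
  n <- ints$n
  M <- matrix(fd$ERI1, n * n, n * n)
  K <- matrix(aperm(fd$ERI1, c(1, 4, 2, 3)), n * n, n * n)
  g1fd <- matrix(2 * (M %*% as.vector(t(D))) - K %*% as.vector(D), n, n)
  expect_lt(max(abs(nd$G1(D) - g1fd)), 1e-6)
})

test_that("displacement derivatives satisfy translational invariance", {
  ints <- fix_scf("h2o")$ints
  for (beta in 1:3) {
    acc_s <- 0; acc_h <- 0
    for (lam in 1:3) {
      nd <- nuclear_derivative_integrals(ints, lam, beta)
      acc_s <- acc_s + nd$S1
      acc_h <- acc_h + nd$h1
    }
    expect_lt(max(abs(acc_s)), 1e-12)
    # the summed h derivative is not zero (the operator moves too), but the
    # overlap derivative is pure basis motion and must cancel exactly
  }
})

test_that("two-center antisymmetry holds for an s-only diatomic", {
  scf <- fix_scf("h2")
  ints <- scf$ints
  d1 <- nuclear_derivative_integrals(ints, 1, 3)
  d2 <- nuclear_derivative_integrals(ints, 2, 3)
  expect_lt(max(abs(d1$S1 + d2$S1)), 1e-12)
})

test_that("velocity-gauge overlap derivative matches the complex-phase
           quadrature oracle and is antisymmetric", {
  scf <- fix_scf("h2")
  v <- vao_first_order(scf$ints, 1, 3)
  expect_antisymmetric(v$S1, 1e-14)
  fd <- fd_vao_overlap(scf$basis, 1, 3)
  expect_lt(max(abs(v$S1 - fd)), 1e-7)
})

test_that("single-center s-only system has zero velocity-gauge overlap
           derivative by parity", {
  bs <- read_basis(text = c("He S", " 1.5 1.0", "He S", " 0.4 1.0"))
  mol <- molecule("He", matrix(0, 1, 3), unit = "bohr")
  basis <- build_ao_basis(mol, bs)
  ints <- compute_core_integrals(mol, basis)
  v <- vao_first_order(ints, 1, 2)
  expect_lt(max(abs(v$S1)), 1e-14)
})

test_that("GIAO overlap derivative matches the London-phase quadrature
           oracle, depends only on center differences, and vanishes for a
           single center", {
  scf <- fix_scf("h2")
  g <- giao_first_order(scf$ints)
  fd <- fd_giao_overlap(scf$basis, 1)
  expect_lt(max(abs(g[[1]]$S1 - fd)), 1e-7)
  # magnetic-origin independence
  ints2 <- compute_core_integrals(scf$mol, scf$basis,
                                  gauge_config(o_mag = c(10, 0, 0)))
  g2 <- giao_first_order(ints2)
  for (a in 1:3) expect_lt(max(abs(g[[a]]$S1 - g2[[a]]$S1)), 1e-14)
  # single center: R_mu - R_nu = 0 everywhere
  bs <- read_basis(text = c("He S", " 1.5 1.0", "He P", " 0.7 1.0"))
  mol <- molecule("He", matrix(1, 1, 3), unit = "bohr")
  ints1c <- compute_core_integrals(mol, build_ao_basis(mol, bs))
  g1c <- giao_first_order(ints1c)
  for (a in 1:3) expect_lt(max(abs(g1c[[a]]$S1)), 1e-14)
})

test_that("moment-weighted core-Hamiltonian blocks match the
           exponential-tilt finite-difference oracle", {
  mol <- fix_mol("h2o")
  scf <- fix_scf("h2o")
  ints <- scf$ints
  for (g in c(1, 3)) {
    tilt <- tilt_moment_fd(scf$basis, g, type = "T") +
      tilt_moment_fd(scf$basis, g, type = "V", mol = mol)
    ana <- vcdpt:::ints_mom_bra(ints, g, "T") +
      vcdpt:::ints_mom_bra(ints, g, "V")
    expect_lt(max(abs(tilt - ana)), 1e-6)
  }
})
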