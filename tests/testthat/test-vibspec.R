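# Harmonic analysis and spectrum synthesis.

test_that("H2 has exactly one vibrational mode and five projected rigid
           modes", {
  vib <- fix_vib("h2")
  expect_equal(vib$n_rigid, 5L)
  expect_equal(sum(!vib$is_rigid), 1L)
  expect_equal(vib$n_imaginary, 0L)
  # the projected rigid modes are numerically zero on the 15 cm-1 scale
  # that separates them from genuine vibrations
  expect_lt(max(abs(vib$freq_cm1[vib$is_rigid])), 1e-2)
  # a light homonuclear diatomic stretches in the thousands of cm-1
  expect_gt(vib$freq_cm1[!vib$is_rigid], 3000)
})

test_that("the optimized water minimum has no imaginary modes while the
           planar hydrogen peroxide stationary point is a torsional
           saddle, both with clean projected zeros", {
  vw <- fix_vib("h2o")
  expect_equal(vw$n_imaginary, 0L)
  expect_equal(vw$n_rigid, 6L)
  expect_lt(max(abs(vw$freq_cm1[vw$is_rigid])), 1)
  vp <- fix_vib("h2o2_planar")
  expect_equal(vp$n_imaginary, 1L)   # the achiral saddle: soft torsion
  expect_lt(vp$freq_cm1[!vp$is_rigid][1], 0)
  expect_lt(max(abs(vp$freq_cm1[vp$is_rigid])), 1)
})

test_that("frequencies are invariant under rigid rotation of the input
           geometry", {
  mol <- fix_mol("h2o")
  th <- 0.3; ph <- 1.1
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3, 3)
  mol2 <- mol
  mol2$xyz <- mol$xyz %*% t(Rx %*% Rz)
  vib2 <- numeric_hessian(mol2, fix_bset())
  f1 <- fix_vib("h2o")$freq_cm1
  # agreement is limited by the O(step^2) truncation of the three-point
  # differences, which is orientation dependent
  expect_lt(max(abs(sort(f1[!fix_vib("h2o")$is_rigid]) -
                    sort(vib2$freq_cm1[!vib2$is_rigid]))), 0.25)
})

test_that("invalid steps and SCF failures are reported", {
  expect_error(numeric_hessian(fix_mol("h2"), fix_bset(), step = 0),
               "positive")
})

test_that("Lorentzian broadening has the closed-form peak height and
           unit-area normalization", {
  tab <- data.frame(wavenumber_cm1 = 1500, R_au = 1)
  w <- 12
  sp <- broaden(tab, "R_au", w = w)
  expect_equal(sp$fn(1500), 2 / (pi * w), tolerance = 1e-12)
  total <- integrate(sp$fn, -Inf, Inf, rel.tol = 1e-9,
                     subdivisions = 2000L)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("opposite equal strengths at the same frequency cancel exactly
           and spectra integrate to the summed strengths", {
  tab <- data.frame(wavenumber_cm1 = c(900, 900), R_au = c(0.7, -0.7))
  sp <- broaden(tab, "R_au")
  expect_equal(max(abs(sp$intensity)), 0)
  tab2 <- data.frame(wavenumber_cm1 = c(800, 1450, 3100),
                     D_au = c(0.2, 1.1, 0.5))
  sp2 <- broaden(tab2, "D_au", w = 12)
  total <- integrate(sp2$fn, -Inf, Inf, rel.tol = 1e-9,
                     subdivisions = 4000L)$value
  expect_equal(total, sum(tab2$D_au), tolerance = 1e-6)
  # the frequency shift moves peaks without changing the integral
  sp3 <- broaden(tab2, "D_au", w = 12, shift = 55)
  expect_equal(which.max(sp3$fn(seq(800, 900, 0.5))),
               which.max(sp2$fn(seq(800, 900, 0.5))) + 110L)
})

test_that("broadening rejects nonpositive widths and unsorted grids", {
  tab <- data.frame(wavenumber_cm1 = 1000, R_au = 1)
  expect_error(broaden(tab, "R_au", w = 0), "positive")
  expect_error(broaden(tab, "R_au", grid = c(2, 1, 3)), "increasing")
})
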