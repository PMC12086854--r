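test_that("XYZ reading converts units and round-trips coordinates", {
  tmp <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "water, angstrom",
               "O 0.000000 0.000000 0.000000",
               "H 0.000000 0.000000 0.957200",
               "H 0.926627 0.000000 -0.239987"), tmp)
  mol <- read_xyz(tmp, unit = "angstrom")
  # O-H distance 0.9572 A in bohr, CODATA conversion
  expect_equal(sqrt(sum((mol$xyz[2, ] - mol$xyz[1, ])^2)), 1.80885,
               tolerance = 1e-4 / 1.80885)
  out <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(mol, out, unit = "bohr")
  mol2 <- read_xyz(out, unit = "bohr")
  expect_lt(max(abs(mol$xyz - mol2$xyz)), 1e-10)
  expect_identical(mol$symbols, mol2$symbols)
})

test_that("single-atom bohr file is read verbatim", {
  tmp <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "", "H 0 0 0"), tmp)
  expect_error(read_xyz(tmp, unit = "bohr"), NA)
  mol <- molecule("He", matrix(0, 1, 3), unit = "bohr")
  expect_equal(mol$xyz, matrix(0, 1, 3))
})

test_that("malformed XYZ input fails with a line-aware parse error", {
  tmp <- withr::local_tempfile(fileext = ".xyz")
  writeLines(character(0), tmp)
  expect_error(read_xyz(tmp), "parse error")
  writeLines(c("2", "cmt", "H 0 0 0", "H 0 zero 0"), tmp)
  expect_error(read_xyz(tmp), "line 4")
  writeLines(c("1", "cmt", "Xx 0 0 0"), tmp)
  expect_error(read_xyz(tmp), "unknown element")
})

test_that("open-shell electron counts are representable but refused by
           the restricted mean field", {
  mol <- molecule(c("O", "H"), matrix(c(0, 0, 0, 0, 0, 1.8), 2, 3,
                                      byrow = TRUE), unit = "bohr")
  expect_equal(mol$n_electrons, 9L)
  expect_error(run_scf(mol, build_ao_basis(mol, builtin_basis("sto-3g"))),
               "closed-shell")
})

test_that("basis reader splits SP shells and rejects bad labels", {
  bs <- read_basis(text = c("O S", " 1.0 1.0", "O SP",
                            " 2.0 0.5 0.3", " 0.5 0.5 0.7"))
  expect_length(bs$O, 3)
  expect_equal(vapply(bs$O, `[[`, integer(1), "l"), c(0L, 0L, 1L))
  expect_error(read_basis(text = c("O Q", " 1.0 1.0")), "unknown shell label")
  expect_error(read_basis(text = c("O S", " -1.0 1.0")), "exponent")
})

test_that("a D shell expands to 6 Cartesian components", {
  bs <- read_basis(text = c("O D", " 0.8 1.0"))
  mol <- molecule("O", matrix(0, 1, 3), charge = -2L, unit = "bohr")
  basis <- build_ao_basis(mol, bs)
  expect_equal(basis$n, 6L)
  expect_equal(unique(basis$ao_l), 2L)
})

test_that("every contracted Cartesian AO has unit self-overlap", {
  for (bn in c("sto-3g", "6-31g", "6-31gss")) {
    mol <- fix_mol("hof")
    basis <- build_ao_basis(mol, builtin_basis(bn))
    S <- vcdpt:::cpp_int1e(basis$prim, basis$prim, 0L, numeric(0),
                   matrix(0, 0, 3), 0L)
    expect_lt(max(abs(diag(S) - 1)), 1e-12)
  }
})

test_that("nuclear dipole obeys symmetry and origin-shift linearity", {
  h2 <- molecule(c("H", "H"), rbind(c(0, 0, -0.7), c(0, 0, 0.7)),
                 unit = "bohr")
  expect_equal(nuclear_dipole(h2), c(0, 0, 0))
  hof <- fix_mol("hof")
  d <- c(0.3, -1.2, 2.0)
  q <- sum(hof$Z)
  expect_equal(nuclear_dipole(hof, origin = d),
               nuclear_dipole(hof) - q * d, tolerance = 1e-12)
})
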