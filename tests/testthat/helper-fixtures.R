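# Shared, lazily computed fixtures.  Everything is generated in code from
# the built-in fixture geometries and basis sets; results are cached for
# the duration of the test session since several test files (and the
# acceptance checks) interrogate the same converged states.

.fixcache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixcache[[key]])) .fixcache[[key]] <- force(expr)
  .fixcache[[key]]
}

fix_mol <- function(name) fixture_molecule(name)

fix_bset <- function(name = "sto-3g") cached(paste0("bset:", name),
                                             builtin_basis(name))

fix_scf <- function(name, basis = "sto-3g", o_mag = c(0, 0, 0)) {
  key <- paste("scf", name, basis, paste(o_mag, collapse = ","))
  cached(key, {
    mol <- fix_mol(name)
    b <- build_ao_basis(mol, fix_bset(basis))
    run_scf(mol, b, gauge = gauge_config(o_mag = o_mag))
  })
}

fix_responses <- function(name, set = c("ndpt", "nvpt", "mfpt"),
                          solver = "ao", basis = "sto-3g",
                          o_mag = c(0, 0, 0)) {
  set <- match.arg(set)
  key <- paste("resp", name, set, solver, basis, paste(o_mag, collapse = ","))
  cached(key, {
    scf <- fix_scf(name, basis, o_mag = o_mag)
    ch <- switch(set,
      ndpt = build_ndpt_channels(scf),
      nvpt = build_nvpt_channels(scf,
               fix_responses(name, "ndpt", "ao", basis, o_mag)),
      mfpt = build_mfpt_channels(scf))
    solve_channel_set(scf, ch, solver)
  })
}

fix_channels <- function(name, set = c("ndpt", "nvpt", "mfpt"),
                         basis = "sto-3g") {
  set <- match.arg(set)
  key <- paste("chan", name, set, basis)
  cached(key, {
    scf <- fix_scf(name, basis)
    switch(set,
      ndpt = build_ndpt_channels(scf),
      nvpt = build_nvpt_channels(scf, fix_responses(name, "ndpt", "ao", basis)),
      mfpt = build_mfpt_channels(scf))
  })
}

fix_vib <- function(name, basis = "sto-3g") {
  key <- paste("vib", name, basis)
  cached(key, numeric_hessian(fix_mol(name), fix_bset(basis)))
}

fix_strengths <- function(name, theory = c("nvpt", "mfpt"), solver = "ao") {
  theory <- match.arg(theory)
  key <- paste("str", name, theory, solver)
  cached(key, {
    scf <- fix_scf(name)
    ndpt <- fix_responses(name, "ndpt", solver)
    if (theory == "nvpt") {
      nv <- fix_responses(name, "nvpt", solver)
      strengths(apt_velocity(scf, nv), aat_nvpt(scf, nv), fix_vib(name))
    } else {
      mf <- fix_responses(name, "mfpt", solver)
      strengths(apt_length(scf, ndpt), aat_mfpt(scf, mf, ndpt),
                fix_vib(name))
    }
  })
}

# a deterministic symmetric test matrix
sym_matrix <- function(n, seed = 42) {
  set.seed(seed)
  M <- matrix(rnorm(n * n), n)
  (M + t(M)) / 2
}

expect_antisymmetric <- function(M, tol = 1e-12) {
  expect_lt(max(abs(M + t(M))), tol)
}
expect_symmetric <- function(M, tol = 1e-12) {
  expect_lt(max(abs(M - t(M))), tol)
}

fix_fd_apt <- function(name = "h2o") {
  cached(paste("fdapt", name), fd_apt(fix_mol(name), fix_bset()))
}
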