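# Orchestration: configuration, fixtures, full spectra pipeline and the
# run-time diagnostics (oracle) report.  A thin command-line wrapper over
# these functions ships in inst/cli/vcdpt.R.

# Fixture geometries (bohr), optimized at the package's own mean field with
# the built-in minimal basis so that harmonic analyses are clean minima.
# h2o2_M is generated from h2o2_P by exact mirror inversion (x -> -x) and
# h2o2_planar is the achiral trans saddle.
.fixture_geoms <- function() {
  list(
    # h2, h2o, hof, h2o2_planar: stationary geometries of the package's own
    # mean field with the built-in minimal basis (quasi-Newton refinement,
    # max force < 3e-7 a.u.), frozen here for reproducibility.
    h2 = list(symbols = c("H", "H"),
              xyz = rbind(c(0, 0, -0.67295968), c(0, 0, 0.67295968))),
    h2o = list(symbols = c("O", "H", "H"),
               xyz = rbind(c(0, 0, 0.19039478),
                           c(1.43256483, 0, -1.01109739),
                           c(-1.43256483, 0, -1.01109739))),
    hof = list(symbols = c("O", "H", "F"),
               xyz = rbind(c(0.03169943, -0.03032557, 0),
                           c(-0.36693952, 1.82824068, 0),
                           c(2.59174009, 0.00198490, 0))),
    # chiral skewed reference structure (dihedral 112 deg, C2 symmetry
    # about x): at this mean field the torsional minimum is trans-planar,
    # so this geometry is a chirality test structure, not a minimum
    h2o2_P = list(symbols = c("O", "O", "H", "H"),
                  xyz = rbind(c(0, 0, 1.3245), c(0, 0, -1.3245),
                              c(1.040351, 1.542383, 1.645856),
                              c(1.040351, -1.542383, -1.645856))),
    # achiral trans-planar stationary structure
    h2o2_planar = list(symbols = c("O", "O", "H", "H"),
                       xyz = rbind(c(-0.09435667, 1.32126495, 0),
                                   c(0.09435666, -1.32126495, 0),
                                   c(1.73839958, 1.77494010, 0),
                                   c(-1.73839959, -1.77494010, 0)))
  )
}

#' Built-in fixture molecule
#'
#' @param name one of "h2", "h2o", "hof", "h2o2_P", "h2o2_M", "h2o2_planar"
#' @return a [molecule()] (coordinates in bohr)
#' @export
fixture_molecule <- function(name) {
  geoms <- .fixture_geoms()
  if (name == "h2o2_M") {
    g <- geoms$h2o2_P
    g$xyz[, 1] <- -g$xyz[, 1]
  } else {
    g <- geoms[[name]]
    if (is.null(g))
      stop("unknown fixture '", name, "'; choices: ",
           paste(c(names(geoms), "h2o2_M"), collapse = ", "))
  }
  molecule(g$symbols, g$xyz, unit = "bohr")
}

#' Write fixture input files
#'
#' Writes `<name>.xyz` (bohr) and a copy of the built-in minimal basis into
#' `dir`.
#'
#' @param name fixture name (see [fixture_molecule()])
#' @param dir output directory
#' @return invisibly, the paths written
#' @export
make_fixture <- function(name, dir = ".") {
  mol <- fixture_molecule(name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  xyz <- file.path(dir, paste0(name, ".xyz"))
  write_xyz(mol, xyz, unit = "bohr", comment = paste("fixture", name, "(bohr)"))
  bas <- file.path(dir, "minimal.nwbas")
  file.copy(builtin_basis_path("sto-3g"), bas, overwrite = TRUE)
  invisible(c(xyz = xyz, basis = bas))
}

#' Default run configuration
#'
#' @param ... overrides merged into the defaults
#' @return config list
#' @export
default_config <- function(...) {
  cfg <- list(
    xyz = NULL, unit = "angstrom", charge = 0L,
    basis = "sto-3g",
    theory = "nvpt", solver = "both",
    o_sp = c(0, 0, 0), o_mag = c(0, 0, 0),
    response = list(tol = 5e-12, uncoupled_imaginary = FALSE),
    scf = list(conv_tol = 1e-10, max_iter = 200L),
    hessian = list(enabled = TRUE, step = 1e-2),
    spectrum = list(w = 12, shift = 0),
    out_dir = NULL)
  utils::modifyList(cfg, list(...))
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file
#' @return config list (defaults filled in)
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(default_config, yaml::read_yaml(path))
}

.load_bset <- function(basis) {
  if (inherits(basis, "basis_set")) return(basis)
  if (basis %in% c("sto-3g", "6-31g", "6-31gss")) return(builtin_basis(basis))
  read_basis(basis)
}

.solve_theory <- function(scf, theory, solver, tol, uncoupled) {
  ndpt_ch <- build_ndpt_channels(scf)
  ndpt <- solve_channel_set(scf, ndpt_ch, solver, tol)
  res <- list(ndpt = ndpt)
  if (theory == "nvpt") {
    nvpt_ch <- build_nvpt_channels(scf, ndpt, uncoupled = uncoupled)
    res$nvpt <- solve_channel_set(scf, nvpt_ch, solver, tol)
  } else if (theory == "mfpt") {
    mfpt_ch <- build_mfpt_channels(scf, uncoupled = uncoupled)
    res$mfpt <- solve_channel_set(scf, mfpt_ch, solver, tol)
  }
  res
}

.tensors_for <- function(scf, theory, responses) {
  if (theory == "ndpt") {
    list(apt = apt_length(scf, responses$ndpt), aat = NULL)
  } else if (theory == "nvpt") {
    list(apt = apt_velocity(scf, responses$nvpt),
         aat = aat_nvpt(scf, responses$nvpt))
  } else {
    list(apt = apt_length(scf, responses$ndpt),
         aat = aat_mfpt(scf, responses$mfpt, responses$ndpt))
  }
}

#' Run the full spectra pipeline
#'
#' SCF, response channels for the requested theory (displacement responses
#' are always solved since both the velocity and the magnetic-field routes
#' depend on them), property tensors, harmonic analysis, strengths and
#' broadened spectra.  With `solver = "both"` every channel is solved by
#' the AO density-matrix solver and the MO Sternheimer solver and a
#' comparison report with maximum absolute deviations is produced.
#'
#' @param config a configuration list (see [default_config()]); `xyz` may
#'   also be a [molecule()]
#' @return artifact bundle (list); written to `config$out_dir` when set
#' @export
run_pipeline <- function(config) {
  cfg <- do.call(default_config, config[!vapply(config, is.null, logical(1))])
  theory <- match.arg(cfg$theory, c("ndpt", "nvpt", "mfpt"))
  solver <- match.arg(cfg$solver, c("ao", "mo", "both"))
  mol <- if (inherits(cfg$xyz, "molecule")) cfg$xyz
         else read_xyz(cfg$xyz, unit = cfg$unit, charge = cfg$charge)
  bset <- .load_bset(cfg$basis)
  basis <- build_ao_basis(mol, bset)
  gauge <- gauge_config(cfg$o_sp, cfg$o_mag)
  scf <- run_scf(mol, basis, gauge = gauge,
                 conv_tol = cfg$scf$conv_tol, max_iter = cfg$scf$max_iter)
  tol <- cfg$response$tol
  unc <- isTRUE(cfg$response$uncoupled_imaginary)
  solvers <- if (solver == "both") c("ao", "mo") else solver
  runs <- lapply(solvers, function(sv)
    .solve_theory(scf, theory, sv, tol, unc))
  names(runs) <- solvers
  tens <- lapply(runs, function(r) .tensors_for(scf, theory, r))

  out <- list(config = cfg, scf = scf, responses = runs, tensors = tens)
  if (isTRUE(cfg$hessian$enabled)) {
    vib <- numeric_hessian(mol, bset, step = cfg$hessian$step)
    out$vib <- vib
    out$strengths <- lapply(tens, function(tt)
      strengths(tt$apt, tt$aat, vib))
    first <- out$strengths[[1]]
    out$spectra <- list(
      ir = broaden(first, "D_au", w = cfg$spectrum$w, shift = cfg$spectrum$shift))
    if (!is.null(tens[[1]]$aat))
      out$spectra$vcd <- broaden(first, "R_au", w = cfg$spectrum$w,
                                 shift = cfg$spectrum$shift)
  }
  if (solver == "both") {
    cmp <- list()
    for (set in names(runs$ao)) {
      dev <- max(mapply(function(a, b) max(abs(a$d1 - b$d1)),
                        runs$ao[[set]], runs$mo[[set]]))
      cmp[[paste0("max_dD1_", set)]] <- dev
    }
    cmp$max_dAPT <- max(abs(tens$ao$apt$total - tens$mo$apt$total))
    if (!is.null(tens$ao$aat))
      cmp$max_dAAT <- max(abs(tens$ao$aat$total - tens$mo$aat$total))
    if (!is.null(out$strengths))
      cmp$max_dR <- max(abs(out$strengths$ao$R_au - out$strengths$mo$R_au))
    out$comparison <- cmp
  }
  if (!is.null(cfg$out_dir)) .write_bundle(out, cfg$out_dir)
  out
}

.write_bundle <- function(out, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  j <- function(x, f) jsonlite::write_json(
    x, file.path(dir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  j(list(E_total = out$scf$E_total, n_iter = out$scf$n_iter,
         n_occ = out$scf$n_occ), "scf_summary.json")
  for (sv in names(out$responses)) {
    log <- do.call(rbind, lapply(unlist(out$responses[[sv]], recursive = FALSE),
      function(r) data.frame(label = r$label, solver = r$solver,
                             residual = r$residual_norm, n_iter = r$n_iter)))
    utils::write.csv(log, file.path(dir, paste0("channels_", sv, ".csv")),
                     row.names = FALSE)
  }
  sv1 <- names(out$tensors)[1]
  tt <- out$tensors[[sv1]]
  apt_df <- do.call(rbind, lapply(seq_len(dim(tt$apt$total)[1]), function(l)
    data.frame(atom = l,
               alpha = rep(c("x", "y", "z"), each = 3),
               beta = rep(c("x", "y", "z"), 3),
               value = as.vector(t(tt$apt$total[l, , ])))))
  utils::write.csv(apt_df, file.path(dir, "apt.csv"), row.names = FALSE)
  if (!is.null(tt$aat)) {
    aat_df <- apt_df
    aat_df$value <- unlist(lapply(seq_len(dim(tt$aat$total)[1]), function(l)
      as.vector(t(tt$aat$total[l, , ]))))
    utils::write.csv(aat_df, file.path(dir, "aat.csv"), row.names = FALSE)
  }
  if (!is.null(out$strengths))
    utils::write.csv(out$strengths[[sv1]], file.path(dir, "strengths.csv"),
                     row.names = FALSE)
  if (!is.null(out$spectra)) {
    for (nm in names(out$spectra)) {
      sp <- out$spectra[[nm]]
      utils::write.csv(data.frame(wavenumber_cm1 = sp$grid,
                                  intensity = sp$intensity),
                       file.path(dir, paste0("spectrum_", nm, ".csv")),
                       row.names = FALSE)
      j(list(kind = nm, w = sp$w, shift = sp$shift,
             total_strength = sp$total_strength),
        paste0("spectrum_", nm, ".json"))
    }
  }
  if (!is.null(out$comparison)) j(out$comparison, "comparison.json")
  invisible(dir)
}

#' Run the diagnostics (oracle) suite
#'
#' Executes the package's independent validation checks on small fixtures
#' and reports one machine-readable entry per check: finite-difference
#' versus analytic perturbed integrals, quadrature complex-phase overlap
#' derivatives, cross-solver response agreement, polar-tensor sum rules,
#' finite-difference dipole derivatives, magnetic-gauge-origin shifts, and
#' a deliberately corrupted negative control.
#'
#' @param out_json optional path for the JSON report
#' @return data.frame with columns check, value, tol, pass
#' @export
run_oracles <- function(out_json = NULL) {
  bset <- builtin_basis("sto-3g")
  entries <- list()
  add <- function(check, value, tol, pass = value <= tol)
    entries[[length(entries) + 1]] <<- data.frame(
      check = check, value = value, tol = tol, pass = pass)

  # geometric finite differences on the water fixture
  mol <- fixture_molecule("h2o")
  basis <- build_ao_basis(mol, bset)
  ints <- compute_core_integrals(mol, basis)
  fd <- fd_core_derivatives(mol, bset, 1, 3, eri = TRUE)
  nd <- nuclear_derivative_integrals(ints, 1, 3)
  add("fd_overlap_deriv", max(abs(nd$S1 - fd$S1)), 1e-7)
  add("fd_hcore_deriv", max(abs(nd$h1 - (fd$T1 + fd$V1))), 1e-7)
  D0r <- diag(ints$n) * 0.1 + 0.01
  g1_fd <- {
    De <- fd$ERI1
    n <- ints$n
    M <- matrix(De, n * n, n * n)
    K <- matrix(aperm(De, c(1, 4, 2, 3)), n * n, n * n)
    matrix(2 * (M %*% as.vector(t(D0r))) - K %*% as.vector(D0r), n, n)
  }
  add("fd_eri_deriv_contraction", max(abs(nd$G1(D0r) - g1_fd)), 1e-6)
  # exponential-tilt oracle for moment-weighted one-electron matrices
  tilt <- tilt_moment_fd(basis, 1, origin = c(0, 0, 0), type = "T") +
          tilt_moment_fd(basis, 1, origin = c(0, 0, 0), type = "V", mol = mol)
  ana <- ints_mom_bra(ints, 1, "T") + ints_mom_bra(ints, 1, "V")
  add("tilt_moment_hcore", max(abs(tilt - ana)), 1e-6)

  # complex-phase quadrature oracles on H2
  mh <- fixture_molecule("h2")
  bh <- build_ao_basis(mh, bset)
  ih <- compute_core_integrals(mh, bh)
  v <- vao_first_order(ih, 1, 3)
  add("quad_vao_overlap", max(abs(v$S1 - fd_vao_overlap(bh, 1, 3))), 1e-7)
  g <- giao_first_order(ih)
  add("quad_giao_overlap", max(abs(g[[2]]$S1 - fd_giao_overlap(bh, 2))), 1e-7)

  # cross-solver and sum rules on water
  scf <- run_scf(mol, basis, ints = ints)
  ndpt_ch <- build_ndpt_channels(scf)
  ndpt_ao <- solve_channel_set(scf, ndpt_ch, "ao")
  ndpt_mo <- solve_channel_set(scf, ndpt_ch, "mo")
  add("cross_solver_ndpt_d1",
      max(mapply(function(a, b) max(abs(a$d1 - b$d1)), ndpt_ao, ndpt_mo)),
      1e-8)
  nvpt_ch <- build_nvpt_channels(scf, ndpt_ao)
  nvpt_ao <- solve_channel_set(scf, nvpt_ch, "ao")
  apt_l <- apt_length(scf, ndpt_ao)
  apt_v <- apt_velocity(scf, nvpt_ao)
  # neutral molecule: total polar tensors sum to the zero matrix
  add("apt_length_sum_rule",
      max(abs(apply(apt_l$total, c(2, 3), sum))), 1e-8)
  add("apt_velocity_sum_rule",
      max(abs(apply(apt_v$total, c(2, 3), sum))), 1e-6)
  add("fd_dipole_apt", max(abs(apt_l$total - fd_apt(mol, bset))), 1e-6)

  # magnetic gauge-origin invariance
  ints2 <- compute_core_integrals(mol, basis,
                                  gauge_config(o_mag = c(10, 0, 0)))
  g2 <- giao_first_order(ints2)
  gh2o <- giao_first_order(ints)
  add("omag_shift_S1B",
      max(vapply(1:3, function(a)
        max(abs(gh2o[[a]]$S1 - g2[[a]]$S1)), numeric(1))),
      1e-12)
  add("omag_shift_H1B",
      max(vapply(1:3, function(a)
        max(abs(gh2o[[a]]$h1e + gh2o[[a]]$G1(scf$D0) -
                g2[[a]]$h1e - g2[[a]]$G1(scf$D0))), numeric(1))),
      1e-10)

  # negative control: corrupt the perturbed-overlap sign and verify the
  # differentiated idempotency condition breaks
  ch <- nvpt_ch[[1]]
  r_ok <- nvpt_ao[[1]]
  D <- scf$D0; S <- scf$S0
  resid <- function(d, s) max(abs(d %*% S %*% D + D %*% s %*% D +
                                  D %*% S %*% d - d))
  add("idempotency_derivative", resid(r_ok$d1, ch$s), 5e-10)
  add("negative_control_corrupted_S1", resid(r_ok$d1, -ch$s), 1e-6,
      pass = resid(r_ok$d1, -ch$s) > 1e-6)

  rep_ <- do.call(rbind, entries)
  if (!is.null(out_json))
    jsonlite::write_json(rep_, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  rep_
}
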