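# Channel builders: turn first-order integrals into response problems.
#
# Channel counts follow the structure of the three theories: a nuclear
# displacement or velocity perturbs every atom along every Cartesian
# direction (3N channels each), while a magnetic field has only the three
# field directions.  Displacement channels are real and symmetric and must
# be solved with the full self-consistent Coulomb + exchange response
# coupling; velocity and field channels are imaginary (antisymmetric real
# factors), whose response coupling at a Hartree-Fock mean field reduces
# exactly to the exchange term, since the Coulomb contraction of an
# antisymmetric density factor vanishes identically.  A configuration
# switch drops that exchange term to emulate the uncoupled equations of
# pure density functionals.

.dirs <- c("x", "y", "z")

#' Build the nuclear-displacement (NDPT) response channels
#'
#' One real-symmetric coupled channel per atom and Cartesian direction,
#' with H1 = dh/dR + G1(D0) from the derivative two-electron integrals and
#' the perturbed overlap S1 = dS/dR.
#'
#' @param scf a converged `scf_state`
#' @return list of 3N channel problems (atom-major, x,y,z order)
#' @export
build_ndpt_channels <- function(scf) {
  ints <- scf$ints
  nat <- nrow(scf$mol$xyz)
  out <- list()
  for (lam in seq_len(nat)) {
    for (beta in 1:3) {
      nd <- nuclear_derivative_integrals(ints, lam, beta)
      out[[length(out) + 1]] <- list(
        flavor = "real", h = nd$h1 + nd$G1(scf$D0), s = nd$S1,
        coupling = TRUE, lambda = lam, beta = beta,
        label = sprintf("R[%d,%s]", lam, .dirs[beta]))
    }
  }
  out
}

#' Recover the coefficient-response product U = C1 C0^T from AO data
#'
#' The full first-order density factor d and perturbed-overlap factor s
#' determine the one-sided product U = C1 C0^T (occupied sum) without any
#' reference to MO coefficients:
#'   U = (1 - D S) (d + D s D) S D - (1/2) D s D,
#' using the standard normalization gauge in which the redundant
#' occupied-occupied rotation is zero.  This is what lets the velocity
#' channels and the magnetic-field tensors consume displacement responses
#' computed purely in the AO basis.
#'
#' @param scf `scf_state`
#' @param d density-response real factor
#' @param s perturbed-overlap real factor
#' @return matrix factor of U (real part for real channels, times-i factor
#'   for imaginary ones)
#' @export
recover_u <- function(scf, d, s) {
  D <- scf$D0; S <- scf$S0
  n <- nrow(D)
  DsD <- D %*% s %*% D
  (diag(n) - D %*% S) %*% (d + DsD) %*% S %*% D - 0.5 * DsD
}

#' Build the nuclear-velocity (NVPT) response channels
#'
#' The perturbation right-hand side combines (i) the velocity-gauge phase
#' derivative of the unperturbed Hamiltonian matrix (one- and two-electron
#' parts), (ii) the electron-momentum coupling -i Rdot . del restricted to
#' basis functions of the perturbed atom, and (iii) the cross term carrying
#' the nuclear-displacement coefficient response, supplied as the effective
#' matrix -S U^R S.  All factors are antisymmetric-real (imaginary
#' Hermitian matrices).
#'
#' @param scf `scf_state`
#' @param ndpt_responses list of solved displacement channels, atom-major
#'   (as returned by [solve_channel_set()] on [build_ndpt_channels()])
#' @param uncoupled drop the exchange response coupling (emulates the
#'   uncoupled equations of pure density functionals)
#' @return list of 3N channel problems
#' @export
build_nvpt_channels <- function(scf, ndpt_responses, uncoupled = FALSE) {
  ints <- scf$ints
  nat <- nrow(scf$mol$xyz)
  if (length(ndpt_responses) != 3 * nat)
    stop("need all ", 3 * nat, " displacement responses, got ",
         length(ndpt_responses))
  n <- ints$n
  mask_atom <- ints$basis$ao_atom
  S <- scf$S0
  out <- list()
  for (lam in seq_len(nat)) {
    for (beta in 1:3) {
      k <- (lam - 1) * 3 + beta
      rr <- ndpt_responses[[k]]
      if (is.null(rr) || is.null(rr$d1))
        stop("missing displacement response for channel R[", lam, ",",
             .dirs[beta], "]")
      v <- vao_first_order(ints, lam, beta)
      mcol <- matrix(as.numeric(mask_atom == lam), n, n, byrow = TRUE)
      h_nab <- ints$Nabla[[beta]] * mcol
      UR <- recover_u(scf, rr$d1, rr$s1)
      h_cross <- -S %*% UR %*% S
      h <- v$h_phase + v$G1(scf$D0) + h_nab + h_cross
      out[[length(out) + 1]] <- list(
        flavor = "imag", h = h, s = v$S1,
        coupling = !uncoupled, lambda = lam, beta = beta,
        label = sprintf("V[%d,%s]", lam, .dirs[beta]))
    }
  }
  out
}

#' Build the magnetic-field (MFPT) response channels
#'
#' Exactly three imaginary channels, one per field direction, built from
#' the gauge-including atomic orbital first-order integrals.  Every matrix
#' is independent of the magnetic gauge origin by construction.
#'
#' @param scf `scf_state`
#' @param uncoupled drop the exchange response coupling
#' @return list of 3 channel problems
#' @export
build_mfpt_channels <- function(scf, uncoupled = FALSE) {
  g <- giao_first_order(scf$ints)
  lapply(1:3, function(a) {
    list(flavor = "imag", h = g[[a]]$h1e + g[[a]]$G1(scf$D0), s = g[[a]]$S1,
         coupling = !uncoupled, alpha = a,
         label = sprintf("B[%s]", .dirs[a]))
  })
}

#' Solve a set of response channels
#'
#' @param scf `scf_state`
#' @param channels list of channel problems from one of the builders
#' @param solver "ao" (density-matrix CG) or "mo" (Sternheimer)
#' @param tol residual threshold
#' @param verbose print per-channel convergence
#' @return list of `density_response` objects in channel order
#' @export
solve_channel_set <- function(scf, channels, solver = c("ao", "mo"),
                              tol = 5e-12, verbose = FALSE) {
  solver <- match.arg(solver)
  lapply(channels, function(ch) {
    r <- if (solver == "ao") solve_response(ch, scf, tol = tol)
         else solve_sternheimer(ch, scf, tol = tol)
    if (verbose)
      message(sprintf("  %-10s %s solver: residual %.2e (%d iter)",
                      ch$label, solver, r$residual_norm, r$n_iter))
    r
  })
}
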