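# Restricted Hartree-Fock ground state.
#
# Spinless density convention: D = sum_occ C C^T with occupation f_j = 1 per
# spatial orbital, so the idempotency condition reads D S D = D literally and
# tr(D S) equals the number of occupied orbitals.  The factor of two for the
# two electrons per orbital is applied inside the Coulomb build and in every
# expectation value.

#' Build the Fock matrix for a given density factor
#'
#' F = h + 2 J(D) - K(D) in the spinless convention (D = sum_occ C C^T).
#'
#' @param ints an `integral_set`
#' @param D density matrix (spinless convention)
#' @return Fock matrix
#' @export
build_fock <- function(ints, D) {
  ints$h + 2 * coulomb_J(ints, D) - exchange_K(ints, D)
}

nuclear_repulsion <- function(mol) {
  xyz <- mol$xyz; Z <- mol$Z
  e <- 0
  nat <- nrow(xyz)
  if (nat < 2) return(0)
  for (i in 1:(nat - 1)) for (j in (i + 1):nat)
    e <- e + Z[i] * Z[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  e
}

#' Run the self-consistent field
#'
#' Restricted Hartree-Fock with a core-Hamiltonian initial guess and DIIS
#' acceleration on the commutator residual F D S - S D F.
#'
#' @param mol a [molecule()]
#' @param basis an `ao_basis`
#' @param ints optional precomputed `integral_set` (built if missing)
#' @param gauge gauge configuration forwarded to the integral build
#' @param conv_tol convergence threshold on the max-abs commutator residual
#' @param max_iter maximum number of SCF iterations
#' @param diis_depth number of stored DIIS error vectors
#' @param verbose print per-iteration energy and residual
#' @return object of class `scf_state`: `C0` (MO coefficients), `eps`
#'   (orbital energies), `n_occ`, `D0`, `H0` (converged Fock), `E_total`,
#'   `E_electronic`, `ints`, and the iteration log
#' @export
run_scf <- function(mol, basis, ints = NULL, gauge = gauge_config(),
                    conv_tol = 1e-10, max_iter = 200L, diis_depth = 8L,
                    verbose = FALSE) {
  if (is.null(ints)) ints <- compute_core_integrals(mol, basis, gauge)
  n <- ints$n
  n_occ <- mol$n_electrons / 2
  if (n_occ != round(n_occ))
    stop("odd electron count (", mol$n_electrons,
         "): only closed-shell molecules are supported")
  if (n_occ > n) stop("basis too small: ", n, " AOs for ", n_occ, " occupied orbitals")
  S <- ints$S0
  Sinvh <- mat_invsqrt(S)
  Enn <- nuclear_repulsion(mol)

  solve_roothaan <- function(F) {
    Ft <- Sinvh %*% F %*% Sinvh
    Ft <- (Ft + t(Ft)) / 2
    eg <- eigen(Ft, symmetric = TRUE)
    ord <- order(eg$values)             # ascending orbital energies
    C <- Sinvh %*% eg$vectors[, ord, drop = FALSE]
    # polish C^T S C = 1 to machine precision (the response solvers lean
    # on exact orthonormality when recovering coefficient products)
    M <- crossprod(C, S %*% C)
    C <- C %*% backsolve(chol((M + t(M)) / 2), diag(n))
    list(C = C, eps = eg$values[ord])
  }
  rh <- solve_roothaan(ints$h)
  C <- rh$C
  D <- tcrossprod(C[, seq_len(n_occ), drop = FALSE])

  errs <- list(); focks <- list()
  log <- data.frame(iter = integer(0), energy = numeric(0), resid = numeric(0))
  E_old <- Inf
  for (it in seq_len(max_iter)) {
    F <- build_fock(ints, D)
    E_el <- sum(D * (ints$h + F))  # tr(D h) + tr(D F); matrices symmetric
    E <- E_el + Enn
    R <- F %*% D %*% S - S %*% D %*% F
    resid <- max(abs(R))
    log <- rbind(log, data.frame(iter = it, energy = E, resid = resid))
    if (verbose)
      message(sprintf("SCF %3d  E = %.12f  |FDS-SDF| = %.3e", it, E, resid))
    if (resid <= conv_tol && abs(E - E_old) <= 1e-10) {
      # polish cycles: pure diagonalize/rebuild passes until coefficients,
      # density and Fock matrix are mutually consistent near machine
      # precision (the response solvers rely on D0 = C_occ C_occ^T and on
      # H0 being the Fock matrix of exactly that density)
      for (pol in 1:12) {
        rh <- solve_roothaan(F)
        Dn <- tcrossprod(rh$C[, seq_len(n_occ), drop = FALSE])
        drift <- max(abs(Dn - D))
        D <- Dn
        F <- build_fock(ints, D)
        if (drift < 1e-13) break
      }
      E_el <- sum(D * (ints$h + F))
      E <- E_el + Enn
      st <- structure(list(C0 = rh$C, eps = rh$eps, n_occ = n_occ,
                           f = rep(1, n_occ), D0 = D, H0 = F,
                           E_total = E, E_electronic = E_el, E_nn = Enn,
                           S0 = S, ints = ints, mol = mol, basis = ints$basis,
                           gauge = ints$gauge, n_iter = it, log = log),
                      class = "scf_state")
      return(st)
    }
    E_old <- E
    # DIIS on the Lowdin-orthogonalized residual
    errs[[length(errs) + 1]] <- as.vector(Sinvh %*% R %*% Sinvh)
    focks[[length(focks) + 1]] <- F
    if (length(errs) > diis_depth) { errs <- errs[-1]; focks <- focks[-1] }
    m <- length(errs)
    Fuse <- F
    if (m >= 2) {
      B <- matrix(0, m + 1, m + 1)
      for (i in 1:m) for (j in 1:m) B[i, j] <- sum(errs[[i]] * errs[[j]])
      B[m + 1, 1:m] <- B[1:m, m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
      if (!is.null(cf)) {
        Fuse <- matrix(0, n, n)
        for (i in 1:m) Fuse <- Fuse + cf[i] * focks[[i]]
      }
    }
    rh <- solve_roothaan(Fuse)
    C <- rh$C
    D <- tcrossprod(C[, seq_len(n_occ), drop = FALSE])
  }
  stop("SCF failed to converge after ", max_iter,
       " iterations; last residuals: ",
       paste(format(tail(log$resid, 5), digits = 3), collapse = ", "))
}

#' @export
print.scf_state <- function(x, ...) {
  cat(sprintf("scf_state: E_total = %.10f Eh (%d iterations, %d occupied)\n",
              x$E_total, x$n_iter, x$n_occ))
  invisible(x)
}

#' Electric dipole moment of the converged state
#'
#' Electronic part -2 tr(D0 Dip) plus the nuclear point-charge part, both
#' about the reference origin (default the spatial gauge origin used in the
#' integral build is *not* re-applied: `origin` shifts the operator).
#'
#' @param scf an `scf_state`
#' @param origin reference origin (bohr)
#' @return 3-vector, a.u.
#' @export
scf_dipole <- function(scf, origin = c(0, 0, 0)) {
  ints <- scf$ints
  el <- -2 * vapply(1:3, function(a)
    sum(scf$D0 * (ints$Mom[[a]] - origin[a] * ints$S0)), numeric(1))
  el + nuclear_dipole(scf$mol, origin)
}
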