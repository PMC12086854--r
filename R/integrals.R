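# Core and first-order integral assembly.
#
# Every derived integral (moments, angular momentum, center derivatives,
# velocity-gauge and GIAO first-order matrices) is built from the analytic
# engine through exact operator identities:
#   (r_g - A_g) chi        -> the l-raised function
#   d chi / d A_g          -> 2*alpha*raised - l*lowered
# so no numerical differentiation enters the production path.  Matrices that
# multiply the imaginary unit are stored as their real factor throughout
# ("times i" convention); Hermitian imaginary matrices therefore appear as
# real antisymmetric factors.

.eps3 <- local({
  e <- array(0, c(3, 3, 3))
  e[1, 2, 3] <- e[2, 3, 1] <- e[3, 1, 2] <- 1
  e[3, 2, 1] <- e[1, 3, 2] <- e[2, 1, 3] <- -1
  e
})

# primitive table for a bra/ket spec string
.tab_for <- function(ints, spec) {
  b <- ints$basis
  if (spec == "orig") return(b$prim)
  p <- strsplit(spec, ":")[[1]]
  kind <- p[1]; args <- as.integer(strsplit(p[2], "")[[1]])
  if (kind == "r") return(ao_raise(b, args[1]))
  if (kind == "rr") return(ao_raise(b, args[2], prim = ao_raise(b, args[1])))
  if (kind == "d") return(ao_center_deriv(b, args[1]))
  stop("unknown basis spec: ", spec)
}

# memoized rectangular one-electron block between derived bases.
# type: "S", "T", "V" (all nuclei), "Vat" (single nucleus `at`), "nab" (dir)
ints_block <- function(ints, bra, ket = "orig", type = "S", dir = 0L, at = 0L) {
  key <- paste(bra, ket, type, dir, at, sep = "|")
  cache <- ints$cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  tb <- .tab_for(ints, bra); tk <- .tab_for(ints, ket)
  m <- ints$mol
  val <- switch(type,
    S = cpp_int1e(tb, tk, 0L, numeric(0), matrix(0, 0, 3), 0L),
    T = cpp_int1e(tb, tk, 1L, numeric(0), matrix(0, 0, 3), 0L),
    V = cpp_int1e(tb, tk, 2L, m$Z, m$xyz, 0L),
    Vat = cpp_int1e(tb, tk, 2L, m$Z[at], m$xyz[at, , drop = FALSE], 0L),
    nab = cpp_int1e(tb, tk, 3L, numeric(0), matrix(0, 0, 3),
                    as.integer(dir) - 1L),
    stop("unknown block type ", type))
  cache[[key]] <- val
  val
}

# absolute first moment of an operator on the bra side:
# <r_g chi_mu | Op | chi_nu> = <raised_g mu|Op|nu> + A_mu,g <mu|Op|nu>
ints_mom_bra <- function(ints, g, type = "S", dir = 0L) {
  M1 <- ints_block(ints, paste0("r:", g), "orig", type, dir)
  M0 <- ints_block(ints, "orig", "orig", type, dir)
  M1 + ints$basis$centers[, g] * M0
}

# absolute second moment with a ket derivative:
# <r_g1 r_g2 mu | d_dir | nu>
ints_mom2_nabla <- function(ints, g1, g2, dir) {
  A <- ints$basis$centers
  rr <- ints_block(ints, paste0("rr:", min(g1, g2), max(g1, g2)),
                   "orig", "nab", dir)
  r1 <- ints_block(ints, paste0("r:", g1), "orig", "nab", dir)
  r2 <- ints_block(ints, paste0("r:", g2), "orig", "nab", dir)
  n0 <- ints_block(ints, "orig", "orig", "nab", dir)
  rr + A[, g2] * r1 + A[, g1] * r2 + (A[, g1] * A[, g2]) * n0
}

#' Compute the core integral set
#'
#' Overlap, kinetic, nuclear attraction, two-electron repulsion, dipole
#' (about the spatial gauge origin), del and angular-momentum (about the
#' magnetic gauge origin) matrices over the AO basis.  Two-electron
#' integrals are kept as a dense rank-4 array; first-order blocks needed by
#' the perturbation builders are computed lazily and memoized.
#'
#' @param mol a [molecule()]
#' @param basis an `ao_basis` from [build_ao_basis()]
#' @param gauge a [gauge_config()]
#' @return object of class `integral_set`
#' @export
compute_core_integrals <- function(mol, basis, gauge = gauge_config()) {
  ints <- new.env(parent = emptyenv())
  ints$mol <- mol; ints$basis <- basis; ints$gauge <- gauge
  ints$n <- basis$n
  ints$cache <- new.env(parent = emptyenv())
  class(ints) <- "integral_set"
  n <- basis$n

  ints$S0 <- ints_block(ints, "orig", "orig", "S")
  ev <- eigen(ints$S0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-9)
    stop("AO basis is (near-)linearly dependent: smallest overlap eigenvalue ",
         format(min(ev)), "; use a less redundant basis")
  ints$T <- ints_block(ints, "orig", "orig", "T")
  ints$Vne <- ints_block(ints, "orig", "orig", "V")
  ints$h <- ints$T + ints$Vne
  ints$eri <- array(cpp_eri(basis$prim), rep(n, 4))

  # absolute moment matrices <mu|r_g|nu> (symmetrized: analytic identity)
  ints$Mom <- lapply(1:3, function(g) {
    M <- ints_mom_bra(ints, g, "S")
    (M + t(M)) / 2
  })
  # dipole about the spatial gauge origin
  ints$Dip <- lapply(1:3, function(g) ints$Mom[[g]] - gauge$o_sp[g] * ints$S0)
  ints$Nabla <- lapply(1:3, function(d) ints_block(ints, "orig", "orig", "nab", dir = d))
  # <mu | r_g d_d | nu> (absolute moment times ket derivative)
  momnab <- lapply(1:3, function(g)
    lapply(1:3, function(d) ints_mom_bra(ints, g, "nab", dir = d)))
  angmom_about <- function(orig) {
    lapply(1:3, function(a) {
      M <- matrix(0, n, n)
      for (g in 1:3) for (d in 1:3) {
        e <- .eps3[a, g, d]
        if (e != 0) M <- M + e * (momnab[[g]][[d]] - orig[g] * ints$Nabla[[d]])
      }
      M
    })
  }
  ints$AngMom <- angmom_about(gauge$o_mag)
  ints$AngMomAbs <- angmom_about(c(0, 0, 0))
  ints
}

#' @export
print.integral_set <- function(x, ...) {
  cat(sprintf("integral_set: %d AOs over %d atoms\n", x$n, nrow(x$mol$xyz)))
  invisible(x)
}

# reshaped ERI matrices for J/K builds, memoized
.eri_mats <- function(ints) {
  if (is.null(ints$cache$.emat)) {
    n <- ints$n
    ints$cache$.emat <- matrix(ints$eri, n * n, n * n)
    ints$cache$.kmat <- matrix(aperm(ints$eri, c(1, 4, 2, 3)), n * n, n * n)
  }
  list(emat = ints$cache$.emat, kmat = ints$cache$.kmat)
}

#' Coulomb and exchange builds
#'
#' `coulomb_J` returns J(D) with J_mn = sum_rs (mn|rs) D_sr; `exchange_K`
#' returns K(D) with K_mn = sum_rs (ms|rn) D_sr.  Both accept an arbitrary
#' real matrix argument (symmetric for real channels, antisymmetric factors
#' for imaginary ones; the Coulomb contraction of an antisymmetric factor
#' vanishes identically).
#'
#' @param ints an `integral_set`
#' @param D density-like matrix
#' @return matrix
#' @export
coulomb_J <- function(ints, D) {
  m <- .eri_mats(ints)
  matrix(m$emat %*% as.vector(t(D)), ints$n, ints$n)
}

#' @rdname coulomb_J
#' @export
exchange_K <- function(ints, D) {
  m <- .eri_mats(ints)
  matrix(m$kmat %*% as.vector(D), ints$n, ints$n)
}

# two-electron response Fock factor for a density-response factor `d`:
# full (Coulomb + exchange) for real channels, exchange-only for imaginary
# factors (their Coulomb part is identically zero and is skipped).
gresp <- function(ints, d, flavor) {
  if (flavor == "real") 2 * coulomb_J(ints, d) - exchange_K(ints, d)
  else -exchange_K(ints, d)
}

# ---------------------------------------------------------------------------
# R channel: nuclear displacement derivatives of all base integrals

# mixed ERI block over center-derivative functions for direction b,
# array [e, nu, rho, sigma] = (dchi_e nu | rho sigma); memoized
.eri_deriv_block <- function(ints, b) {
  key <- paste0(".erid", b)
  if (is.null(ints$cache[[key]])) {
    n <- ints$n
    tb <- ao_center_deriv(ints$basis, b)
    ints$cache[[key]] <- array(cpp_eri_mixed(tb, ints$basis$prim), rep(n, 4))
  }
  ints$cache[[key]]
}

# absolute-moment ERI block for direction g:
# array [e, nu, rho, sigma] = ((r_g e) nu | rho sigma); memoized
.eri_mom_block <- function(ints, g) {
  key <- paste0(".erim", g)
  if (is.null(ints$cache[[key]])) {
    n <- ints$n
    tb <- ao_raise(ints$basis, g)
    E <- array(cpp_eri_mixed(tb, ints$basis$prim), rep(n, 4))
    # first index varies fastest in column-major order, so per-first-index
    # center weights recycle exactly
    ints$cache[[key]] <- E + ints$eri * ints$basis$centers[, g]
  }
  ints$cache[[key]]
}

#' First-order integrals for a nuclear-displacement channel
#'
#' Analytic derivatives of overlap, one-electron Hamiltonian and the
#' two-electron integrals with respect to the position of atom `lambda`
#' along Cartesian direction `beta` (1 = x, 2 = y, 3 = z).  The operator
#' derivative of the nuclear attraction is included.  All matrices are real
#' symmetric.
#'
#' @param ints an `integral_set`
#' @param lambda atom index
#' @param beta Cartesian direction (1..3)
#' @return list with `S1`, `h1` (= dT + dVne), and `G1` (function of a
#'   density matrix returning the derivative-ERI mean-field contraction)
#' @export
nuclear_derivative_integrals <- function(ints, lambda, beta) {
  stopifnot(lambda >= 1, lambda <= nrow(ints$mol$xyz), beta %in% 1:3)
  n <- ints$n
  m <- as.numeric(ints$basis$ao_atom == lambda)
  Sd <- ints_block(ints, paste0("d:", beta), "orig", "S")
  Td <- ints_block(ints, paste0("d:", beta), "orig", "T")
  Vd <- ints_block(ints, paste0("d:", beta), "orig", "V")
  Vl <- ints_block(ints, paste0("d:", beta), "orig", "Vat", at = lambda)
  S1 <- m * Sd + t(m * Sd)
  T1 <- m * Td + t(m * Td)
  V1 <- m * Vd + t(m * Vd) - Vl - t(Vl)
  Ed <- .eri_deriv_block(ints, beta)
  G1 <- function(D) .g1_deriv(ints, Ed, m, D)
  list(channel = "R", lambda = lambda, beta = beta,
       S1 = S1, h1 = T1 + V1, G1 = G1)
}

# mean-field contraction of derivative ERIs:
# G1(D)_mn = sum_sr D_sr [2 dERI(m,n,r,s) - dERI(m,s,r,n)] with
# dERI(a,b,c,d) = m_a Ed[a,b,c,d] + m_b Ed[b,a,c,d]
#              + m_c Ed[c,d,a,b] + m_d Ed[d,c,a,b]
.g1_deriv <- function(ints, Ed, m, D) {
  n <- ints$n
  ME <- matrix(Ed, n * n, n * n)
  A1 <- matrix(ME %*% as.vector(t(D)), n, n)           # sum Ed[m,n,r,s] D_sr
  t3 <- matrix(crossprod(ME, as.vector(m * t(D))), n, n)
  t4 <- matrix(crossprod(ME, as.vector(m * D)), n, n)
  Jp <- 2 * (m * A1 + t(m * A1) + t3 + t4)
  M1 <- matrix(aperm(Ed, c(1, 4, 2, 3)), n * n, n * n)  # Ed[m,s,r,n]
  k1 <- matrix(M1 %*% as.vector(D), n, n)
  M2 <- matrix(aperm(Ed, c(1, 3, 2, 4)), n * n, n * n)  # Ed[e,m,c,n] rows (e,c)
  k2 <- matrix(crossprod(M2, as.vector(m * D)), n, n)
  M3 <- matrix(aperm(Ed, c(1, 4, 3, 2)), n * n, n * n)  # Ed[e,n,m,d] rows (e,d)
  k3 <- matrix(crossprod(M3, as.vector(m * t(D))), n, n)
  q <- matrix(M2 %*% as.vector(t(D)), n, n)             # q[nu,mu]
  Kp <- m * k1 + k2 + k3 + t(m * q)
  Jp - Kp
}

# ---------------------------------------------------------------------------
# V channel: velocity-gauge (VAO) first-order integrals

#' First-order integrals for a nuclear-velocity channel
#'
#' Velocity-gauge atomic orbitals attach the phase
#' exp(i Rdot_lambda . (r - O_sp)) to every basis function riding on atom
#' `lambda`.  The returned matrices are the real factors of the (purely
#' imaginary, Hermitian) first-order overlap and of the one- and
#' two-electron pieces of the gauge-phase derivative of the unperturbed
#' Hamiltonian matrix.  The del ("electron momentum") coupling term and the
#' displacement-response cross term are added by the channel builder, which
#' owns the dependency on the displacement-perturbation solutions.
#'
#' @inheritParams nuclear_derivative_integrals
#' @return list with antisymmetric real factors `S1` and `h_phase`
#'   (one-electron), plus `G1` (function of D: phase-derivative ERI
#'   contraction factor)
#' @export
vao_first_order <- function(ints, lambda, beta) {
  n <- ints$n
  m <- as.numeric(ints$basis$ao_atom == lambda)
  W <- matrix(m, n, n, byrow = TRUE) - matrix(m, n, n)  # m_nu - m_mu
  S1 <- ints$Dip[[beta]] * W
  # one-electron phase term: -maskrow <(r_b - Osp) mu|T+V|nu> + maskcol (transpose)
  Q <- ints_mom_bra(ints, beta, "T") + ints_mom_bra(ints, beta, "V") -
    ints$gauge$o_sp[beta] * (ints$T + ints$Vne)
  h_phase <- -(m * Q) + t(Q) * matrix(m, n, n, byrow = TRUE)
  # first-order phase ERIs: f = A + aperm(A, 34<->12), A = EmO * (m_nu - m_mu)
  EmO <- .eri_mom_block(ints, beta) - ints$gauge$o_sp[beta] * ints$eri
  A <- EmO * as.vector(W)
  f <- A + aperm(A, c(3, 4, 1, 2))
  G1 <- function(D) .g1_fourindex(ints, f, D)
  list(channel = "V", lambda = lambda, beta = beta,
       S1 = S1, h_phase = h_phase, G1 = G1)
}

# mean-field contraction of a general first-order ERI array f:
# G1(D)_mn = sum_sr D_sr [2 f(m,n,r,s) - f(m,s,r,n)]
.g1_fourindex <- function(ints, f, D) {
  n <- ints$n
  Fm <- matrix(f, n * n, n * n)
  Km <- matrix(aperm(f, c(1, 4, 2, 3)), n * n, n * n)
  matrix(2 * (Fm %*% as.vector(t(D))) - Km %*% as.vector(D), n, n)
}

# ---------------------------------------------------------------------------
# B channel: GIAO first-order integrals

#' First-order integrals for the magnetic-field channels
#'
#' Gauge-including atomic orbitals attach the London phase
#' exp(-(i/2c) (B x (R_mu - O_mag)) . r) to each basis function.  The
#' first-order overlap depends only on center differences and is free of
#' the magnetic gauge origin; the one-electron Hamiltonian derivative
#' combines the angular-momentum operator term with moment-weighted kinetic
#' and nuclear-attraction matrices, and the two-electron part contracts the
#' phase-differentiated repulsion integrals with a density matrix.  All
#' returned matrices are real antisymmetric factors of imaginary Hermitian
#' matrices.
#'
#' @param ints an `integral_set`
#' @return list of 3 channels (alpha = field direction 1..3), each with
#'   `S1`, `h1e` and `G1`
#' @export
giao_first_order <- function(ints) {
  n <- ints$n
  C <- ints$basis$centers
  cinv <- 1 / (2 * phys_constants$c_au)
  QTV <- lapply(1:3, function(d)
    ints_mom_bra(ints, d, "T") + ints_mom_bra(ints, d, "V"))
  lapply(1:3, function(a) {
    # overlap factor: -(1/2c) eps_agd (C_nu - C_mu)_g <mu|r_d|nu>
    S1 <- matrix(0, n, n)
    H1 <- matrix(0, n, n)
    Bt <- array(0, rep(n, 4))
    for (g in 1:3) for (d in 1:3) {
      e <- .eps3[a, g, d]
      if (e == 0) next
      Wg <- matrix(C[, g], n, n, byrow = TRUE) - matrix(C[, g], n, n)
      S1 <- S1 - cinv * e * Wg * ints$Mom[[d]]
      # bra/ket phase term of the one-electron Hamiltonian derivative
      Om <- ints$gauge$o_mag[g]
      H1 <- H1 + cinv * e *
        ((C[, g] - Om) * QTV[[d]] -
           t((C[, g] - Om) * QTV[[d]]))
      Bt <- Bt + e * (.eri_mom_block(ints, d) * as.vector(Wg))
    }
    # operator term -(1/2c) <mu|((r - O_mag) x del)_a|nu>
    H1 <- H1 - cinv * ints$AngMom[[a]]
    fB <- -cinv * (Bt + aperm(Bt, c(3, 4, 1, 2)))
    G1 <- function(D) .g1_fourindex(ints, fB, D)
    list(channel = "B", alpha = a, S1 = S1, h1e = H1, G1 = G1)
  })
}
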