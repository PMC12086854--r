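# Atomic polar tensors (length and velocity forms), atomic axial tensors
# (velocity and magnetic-field routes), and per-mode rotational and dipole
# strengths.
#
# Index convention for all per-atom tensors T[lambda, alpha, beta]:
# alpha = dipole (electric or magnetic) direction, beta = nuclear
# displacement/velocity direction.  Electronic and nuclear parts are kept
# separately.  tr(A B) for real matrices is sum(A * t(B)).

.tr2 <- function(A, B) sum(A * t(B))

.new_tensors <- function(nat, theory, form, solver = NA_character_) {
  z <- array(0, c(nat, 3, 3))
  list(elec = z, nuc = z, total = z, theory = theory, form = form,
       solver = solver)
}

#' Length-form atomic polar tensors from displacement responses
#'
#' Electronic part: dipole-operator contraction of the first-order density
#' plus the basis-derivative (Pulay) term; nuclear part Z_lambda *
#' delta_alpha,beta.
#'
#' @param scf `scf_state`
#' @param ndpt_responses solved displacement channels (atom-major)
#' @param origin reference origin for the length-form dipole operator (bohr)
#' @return tensor list with `elec`, `nuc`, `total` arrays [atom, alpha, beta]
#' @export
apt_length <- function(scf, ndpt_responses, origin = c(0, 0, 0)) {
  ints <- scf$ints
  nat <- nrow(scf$mol$xyz)
  n <- ints$n
  out <- .new_tensors(nat, "ndpt", "length")
  DipO <- lapply(1:3, function(a) ints$Mom[[a]] - origin[a] * ints$S0)
  Cc <- ints$basis$centers
  for (lam in seq_len(nat)) {
    m <- as.numeric(ints$basis$ao_atom == lam)
    for (beta in 1:3) {
      rr <- ndpt_responses[[(lam - 1) * 3 + beta]]
      Sd <- ints_block(ints, paste0("d:", beta), "orig", "S")
      for (a in 1:3) {
        Md <- ints_block(ints, paste0("d:", beta), paste0("r:", a), "S") +
          t(Cc[, a] * t(Sd)) - origin[a] * Sd
        dDip <- m * Md + t(m * Md)
        out$elec[lam, a, beta] <-
          -2 * (sum(rr$d1 * DipO[[a]]) + sum(scf$D0 * dDip))
      }
      out$nuc[lam, , beta] <- 0
    }
    out$nuc[lam, , ] <- scf$mol$Z[lam] * diag(3)
  }
  out$total <- out$elec + out$nuc
  out
}

#' Velocity-form atomic polar tensors from velocity responses
#'
#' The electronic part contracts the first-order density with the velocity
#' form of the electric dipole operator (i * del) and adds the
#' velocity-gauge phase derivative of the operator matrix itself.
#'
#' @param scf `scf_state`
#' @param nvpt_responses solved velocity channels (atom-major)
#' @return tensor list as in [apt_length()]
#' @export
apt_velocity <- function(scf, nvpt_responses) {
  ints <- scf$ints
  nat <- nrow(scf$mol$xyz)
  n <- ints$n
  osp <- scf$gauge$o_sp
  out <- .new_tensors(nat, "nvpt", "velocity")
  for (lam in seq_len(nat)) {
    m <- as.numeric(ints$basis$ao_atom == lam)
    mcol <- matrix(m, n, n, byrow = TRUE)
    for (beta in 1:3) {
      rr <- nvpt_responses[[(lam - 1) * 3 + beta]]
      for (a in 1:3) {
        W <- ints_mom_bra(ints, beta, "nab", a) - osp[beta] * ints$Nabla[[a]]
        PH <- m * W - mcol * ((a == beta) * ints$S0 + W)
        out$elec[lam, a, beta] <-
          2 * (sum(scf$D0 * PH) + sum(rr$d1 * ints$Nabla[[a]]))
      }
    }
    out$nuc[lam, , ] <- scf$mol$Z[lam] * diag(3)
  }
  out$total <- out$elec + out$nuc
  out
}

# Nuclear part of the axial tensor: (Z/4c) eps_{a g b} (R - O_mag)_g.
# Referencing the same magnetic origin as the electronic part makes the
# rotational strengths exactly origin invariant: under a shift d of O_mag
# every axial tensor transforms as dM = -(1/4c) d x P with its paired
# polar tensor P, and the triple product in R_i cancels.
.aat_nuclear <- function(mol, o_mag = c(0, 0, 0)) {
  nat <- nrow(mol$xyz)
  z <- array(0, c(nat, 3, 3))
  c_au <- phys_constants$c_au
  for (lam in seq_len(nat)) for (a in 1:3) for (b in 1:3) {
    acc <- 0
    for (g in 1:3)
      acc <- acc + .eps3[a, g, b] * (mol$xyz[lam, g] - o_mag[g])
    z[lam, a, b] <- mol$Z[lam] / (4 * c_au) * acc
  }
  z
}

#' Atomic axial tensors from the nuclear-velocity route
#'
#' Electronic part: derivative of the (velocity-representation) magnetic
#' dipole expectation with respect to nuclear velocity, combining the
#' angular-momentum contraction of the first-order density with the
#' velocity-gauge phase derivative of the operator matrix.  Nuclear part
#' (Z/4c) eps_{alpha gamma beta} (R - O_mag)_gamma, referenced to the same
#' magnetic origin as the electronic part so that rotational strengths are
#' exactly origin invariant.
#'
#' @param scf `scf_state`
#' @param nvpt_responses solved velocity channels (atom-major)
#' @return tensor list
#' @export
aat_nvpt <- function(scf, nvpt_responses) {
  ints <- scf$ints
  nat <- nrow(scf$mol$xyz)
  n <- ints$n
  osp <- scf$gauge$o_sp; om <- scf$gauge$o_mag
  cinv <- 1 / (2 * phys_constants$c_au)
  out <- .new_tensors(nat, "nvpt", "velocity")
  Mn <- lapply(1:3, function(g) lapply(1:3, function(d)
    ints_mom_bra(ints, g, "nab", d)))
  for (lam in seq_len(nat)) {
    m <- as.numeric(ints$basis$ao_atom == lam)
    mcol <- matrix(m, n, n, byrow = TRUE)
    for (beta in 1:3) {
      rr <- nvpt_responses[[(lam - 1) * 3 + beta]]
      for (a in 1:3) {
        G1a <- matrix(0, n, n)
        for (g in 1:3) for (d in 1:3) {
          e <- .eps3[a, g, d]
          if (e == 0) next
          G1a <- G1a + e * (ints_mom2_nabla(ints, beta, g, d)
                            - om[g] * Mn[[beta]][[d]]
                            - osp[beta] * Mn[[g]][[d]]
                            + osp[beta] * om[g] * ints$Nabla[[d]])
        }
        Extra <- matrix(0, n, n)
        for (g in 1:3) {
          e <- .eps3[a, g, beta]
          if (e != 0) Extra <- Extra + e * (ints$Mom[[g]] - om[g] * ints$S0)
        }
        G2a <- G1a + Extra
        PHm <- cinv * (m * G1a - mcol * G2a)
        # half-convention axial tensor (nuclear part (Z/4c) eps R): the
        # expectation-value derivative carries 2 electrons per orbital and
        # a factor 1/2 from the strength-formula normalization
        out$elec[lam, a, beta] <-
          sum(scf$D0 * PHm) + cinv * sum(rr$d1 * ints$AngMom[[a]])
      }
    }
  }
  out$nuc <- .aat_nuclear(scf$mol, scf$gauge$o_mag)
  out$total <- out$elec + out$nuc
  out
}

#' Atomic axial tensors from the magnetic-field route
#'
#' Electronic part: overlap of the nuclear-displacement derivative of the
#' occupied orbitals with their magnetic-field derivative, both including
#' the basis-function (GIAO phase / center motion) contributions, written
#' entirely in terms of AO-level response factors through [recover_u()].
#' The first-order GIAO integrals entering the responses are independent of
#' the magnetic gauge origin; the assembled tensors reference the common
#' origin and transform under origin shifts with the exact covariance law
#' dM = -(1/4c) d x P (paired with the length-form polar tensor), leaving
#' every rotational strength invariant.
#'
#' @param scf `scf_state`
#' @param mfpt_responses 3 solved field channels
#' @param ndpt_responses 3N solved displacement channels
#' @return tensor list
#' @export
aat_mfpt <- function(scf, mfpt_responses, ndpt_responses) {
  ints <- scf$ints
  nat <- nrow(scf$mol$xyz)
  n <- ints$n
  S <- scf$S0; D <- scf$D0
  om <- scf$gauge$o_mag
  Cc <- ints$basis$centers
  cinv <- 1 / (2 * phys_constants$c_au)
  out <- .new_tensors(nat, "mfpt", "length")
  UB <- lapply(1:3, function(a)
    recover_u(scf, mfpt_responses[[a]]$d1, mfpt_responses[[a]]$s1))
  # Phi_a[mu,nu] = eps_{a g d} (C_nu,g - Om_g) <mu|r_d|nu>
  Phi <- lapply(1:3, function(a) {
    M <- matrix(0, n, n)
    for (g in 1:3) for (d in 1:3) {
      e <- .eps3[a, g, d]
      if (e != 0) M <- M + e * t((Cc[, g] - om[g]) * t(ints$Mom[[d]]))
    }
    M
  })
  for (lam in seq_len(nat)) {
    m <- as.numeric(ints$basis$ao_atom == lam)
    for (beta in 1:3) {
      rr <- ndpt_responses[[(lam - 1) * 3 + beta]]
      UR <- recover_u(scf, rr$d1, rr$s1)
      Sd <- ints_block(ints, paste0("d:", beta), "orig", "S")
      for (a in 1:3) {
        ta <- .tr2(S %*% t(UR) %*% S %*% UB[[a]] %*% S, D)
        tb <- .tr2(S %*% t(UR) %*% (-cinv * Phi[[a]]), D)
        tc <- .tr2(m * Sd, t(UB[[a]]))
        Psi <- matrix(0, n, n)
        for (g in 1:3) for (d in 1:3) {
          e <- .eps3[a, g, d]
          if (e == 0) next
          Mdr <- ints_block(ints, paste0("d:", beta), paste0("r:", d), "S") +
            t(Cc[, d] * t(Sd))
          Psi <- Psi + e * t((Cc[, g] - om[g]) * t(Mdr))
        }
        td <- -cinv * sum((m * Psi) * D)
        out$elec[lam, a, beta] <- 2 * (ta + tb + tc + td)
      }
    }
  }
  out$nuc <- .aat_nuclear(scf$mol, scf$gauge$o_mag)
  out$total <- out$elec + out$nuc
  out
}

#' Rotational and dipole strengths per normal mode
#'
#' Contracts the polar and axial tensors over the mass-weighted normal-mode
#' transformation: for mode i with Cartesian displacement matrix S_i,
#'   dmu_a  = sum_{lambda beta} P^lambda_{a beta} S_i^{lambda beta}
#'   dm_a   = sum_{lambda beta} M^lambda_{a beta} S_i^{lambda beta}
#'   D_i    = (1 / 2 omega_i) |dmu|^2
#'   R_i    = dmu . dm
#' in atomic units (harmonic transition moments of the fundamental).
#' Rigid-body (near-zero) modes are excluded.
#'
#' @param apt polar tensor list (from [apt_length()] or [apt_velocity()])
#' @param aat axial tensor list or NULL (then R_i is reported as NA)
#' @param vib a `vibrational_model` from [numeric_hessian()]
#' @return data.frame: mode, wavenumber_cm1, D_au, D_1e40esu2cm2, R_au,
#'   R_1e44esu2cm2
#' @export
strengths <- function(apt, aat, vib) {
  nat <- dim(apt$total)[1]
  if (3 * nat != nrow(vib$modes_cart) || 3 * nat != nrow(vib$hessian))
    stop("atom count mismatch between tensors and vibrational model")
  sel <- which(!vib$is_rigid)
  res <- data.frame()
  for (i in sel) {
    Si <- matrix(vib$modes_cart[, i], nrow = nat, byrow = TRUE) # [lambda, beta]
    dmu <- vapply(1:3, function(a) sum(apt$total[, a, ] * Si), numeric(1))
    w <- vib$freq_au[i]
    D_au <- sum(dmu^2) / (2 * w)
    if (!is.null(aat)) {
      dm <- vapply(1:3, function(a) sum(aat$total[, a, ] * Si), numeric(1))
      R_au <- sum(dmu * dm)
    } else R_au <- NA_real_
    res <- rbind(res, data.frame(
      mode = i, wavenumber_cm1 = vib$freq_cm1[i],
      D_au = D_au,
      D_1e40esu2cm2 = D_au * phys_constants$dipole_strength_au_to_1e40esu2cm2,
      R_au = R_au,
      R_1e44esu2cm2 = R_au * phys_constants$rot_strength_au_to_1e44esu2cm2))
  }
  rownames(res) <- NULL
  res
}
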