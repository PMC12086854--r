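# Seminumerical harmonic analysis and spectrum synthesis.
#
# The Hessian is built from symmetric second differences of the converged
# SCF energy (default increment 1e-2 bohr), mass-weighted, and cleaned by
# Eckart projection of the rigid translations and rotations before
# diagonalization.  Coordinates are flattened atom-major: (atom1 x,y,z,
# atom2 x,y,z, ...).

.energy_at <- function(mol, bset, flat_xyz, conv_tol = 1e-10) {
  m <- mol
  m$xyz <- matrix(flat_xyz, ncol = 3, byrow = TRUE)
  basis <- build_ao_basis(m, bset)
  st <- run_scf(m, basis, conv_tol = conv_tol)
  st$E_total
}

#' Seminumerical Hessian and normal-mode analysis
#'
#' Three-point (symmetric) differences of the SCF energy with respect to
#' Cartesian displacements, default increment 1e-2 bohr.  Frequencies are
#' obtained after Eckart projection of the 3 translational and 3 (2 for
#' linear molecules) rotational directions from the mass-weighted Hessian.
#'
#' @param mol a [molecule()] at (or near) a stationary geometry
#' @param bset element basis (a `basis_set`)
#' @param step finite-difference increment (bohr)
#' @param verbose print progress
#' @return object of class `vibrational_model`: `hessian` (3N x 3N, a.u.),
#'   `freq_au`, `freq_cm1` (negative values flag imaginary modes),
#'   `modes_cart` (columns: Cartesian displacement per normal coordinate,
#'   i.e. mass-weighted eigenvector over sqrt(mass)), `is_rigid`,
#'   `n_imaginary`, `E0`
#' @export
numeric_hessian <- function(mol, bset, step = 1e-2, verbose = FALSE) {
  if (step <= 0) stop("finite-difference step must be positive")
  x0 <- as.vector(t(mol$xyz))
  nc <- length(x0)
  Efun <- function(x) {
    tryCatch(.energy_at(mol, bset, x),
             error = function(e)
               stop("SCF failed at displaced geometry (",
                    conditionMessage(e), ")"))
  }
  E0 <- Efun(x0)
  Ep <- numeric(nc); Em <- numeric(nc)
  for (k in seq_len(nc)) {
    xp <- x0; xp[k] <- xp[k] + step; Ep[k] <- Efun(xp)
    xm <- x0; xm[k] <- xm[k] - step; Em[k] <- Efun(xm)
    if (verbose) message("hessian: diagonal ", k, "/", nc)
  }
  H <- matrix(0, nc, nc)
  diag(H) <- (Ep + Em - 2 * E0) / step^2
  for (k in seq_len(nc - 1)) {
    for (l in (k + 1):nc) {
      xs <- x0
      f <- function(dk, dl) {
        x <- x0; x[k] <- x[k] + dk * step; x[l] <- x[l] + dl * step
        Efun(x)
      }
      H[k, l] <- H[l, k] <-
        (f(1, 1) - f(1, -1) - f(-1, 1) + f(-1, -1)) / (4 * step^2)
    }
    if (verbose) message("hessian: row ", k, "/", nc)
  }
  vibrational_model(H, mol, E0 = E0)
}

#' Normal-mode analysis of a Cartesian Hessian
#'
#' @param H Cartesian Hessian (3N x 3N, a.u., atom-major coordinate order)
#' @param mol the molecule (for masses and the Eckart frame)
#' @param E0 optional reference energy
#' @param rigid_cm1 modes with |frequency| below this (cm-1) count as rigid
#' @return a `vibrational_model`
#' @export
vibrational_model <- function(H, mol, E0 = NA_real_, rigid_cm1 = 15) {
  H <- (H + t(H)) / 2
  nat <- nrow(mol$xyz)
  nc <- 3 * nat
  mass_au <- rep(mol$mass * phys_constants$amu_to_me, each = 3)
  Hmw <- H / sqrt(outer(mass_au, mass_au))
  # Eckart vectors in mass-weighted coordinates
  com <- colSums(mol$xyz * mol$mass) / sum(mol$mass)
  shifted <- sweep(mol$xyz, 2, com)
  V <- matrix(0, nc, 6)
  for (k in 1:3) V[seq(k, nc, by = 3), k] <- sqrt(mass_au[seq(k, nc, by = 3)])
  ax <- diag(3)
  for (k in 1:3) {
    rv <- t(vapply(seq_len(nat), function(ia)
      crossprod_vec(ax[k, ], shifted[ia, ]), numeric(3)))
    V[, 3 + k] <- sqrt(mass_au) * as.vector(t(rv))
  }
  qr_ <- qr(V)
  rank <- qr_$rank                      # 5 for linear molecules, else 6
  Vo <- qr.Q(qr_)[, seq_len(rank), drop = FALSE]
  P <- diag(nc) - tcrossprod(Vo)
  Hp <- P %*% Hmw %*% P
  Hp <- (Hp + t(Hp)) / 2
  eg <- eigen(Hp, symmetric = TRUE)
  lam <- eg$values
  ord <- order(lam)
  lam <- lam[ord]; vec <- eg$vectors[, ord, drop = FALSE]
  freq_au <- sign(lam) * sqrt(abs(lam))
  freq_cm1 <- freq_au * phys_constants$hartree_to_cm1
  is_rigid <- seq_along(lam) %in% order(abs(lam))[seq_len(rank)]
  if (any(abs(freq_cm1[is_rigid]) > rigid_cm1))
    warning("projected rigid modes are not numerically zero: max |freq| = ",
            format(max(abs(freq_cm1[is_rigid])), digits = 3), " cm-1")
  modes_cart <- vec / sqrt(mass_au)
  # sort vibrational modes by frequency, rigid modes first
  structure(list(hessian = H, freq_au = freq_au, freq_cm1 = freq_cm1,
                 modes_cart = modes_cart, is_rigid = is_rigid,
                 n_imaginary = sum(!is_rigid & lam < 0),
                 n_rigid = rank, E0 = E0, mol = mol),
            class = "vibrational_model")
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.vibrational_model <- function(x, ...) {
  vib <- x$freq_cm1[!x$is_rigid]
  cat(sprintf("vibrational_model: %d vibrational modes (%d imaginary)\n",
              length(vib), x$n_imaginary))
  cat("  frequencies (cm-1): ",
      paste(sprintf("%.1f", vib), collapse = ", "), "\n")
  invisible(x)
}

#' Lorentzian-broadened spectrum
#'
#' Each mode contributes a unit-area Lorentzian of full width at half
#' maximum `w` centered at its (optionally shifted) frequency, scaled by
#' its strength:
#'   L(omega) = sum_i s_i (w / 2 pi) / ((omega - omega_i - shift)^2 + (w/2)^2).
#' The peak height of an isolated unit-strength mode is 2 / (pi w).
#'
#' @param table a strength table from [strengths()]
#' @param value column to broaden ("R_au" for VCD, "D_au" for IR, or any
#'   numeric column)
#' @param w full width at half maximum (cm-1)
#' @param grid wavenumber grid; default covers all modes with a 10 w margin
#' @param shift rigid frequency shift (cm-1) applied to all mode positions
#' @return object of class `spectrum`: `grid`, `intensity`, `w`, `shift`,
#'   and `fn`, the continuous profile function
#' @export
broaden <- function(table, value = "R_au", w = 12, grid = NULL, shift = 0) {
  if (w <= 0) stop("broadening width must be positive")
  if (!is.null(grid) && any(diff(grid) <= 0))
    stop("grid must be strictly increasing")
  s <- table[[value]]
  om <- table$wavenumber_cm1 + shift
  if (is.null(grid))
    grid <- seq(min(om) - 10 * w, max(om) + 10 * w, length.out = 2000L)
  fn <- function(x) {
    out <- numeric(length(x))
    for (i in seq_along(om))
      out <- out + s[i] * (w / (2 * pi)) / ((x - om[i])^2 + (w / 2)^2)
    out
  }
  structure(list(grid = grid, intensity = fn(grid), w = w, shift = shift,
                 fn = fn, total_strength = sum(s)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum: %d grid points, w = %.1f cm-1, shift = %.1f cm-1\n",
              length(x$grid), x$w, x$shift))
  invisible(x)
}

#' Quasi-Newton geometry optimization on the SCF energy
#'
#' BFGS minimization with finite-difference gradients; convergence is
#' checked against max-force 3e-5 and rms-force 1.5e-5 a.u.
#'
#' @param mol starting [molecule()]
#' @param bset element basis
#' @param maxit iteration cap
#' @return list with the optimized `molecule`, final `energy`, `max_force`,
#'   `rms_force`, `converged`
#' @export
optimize_geometry <- function(mol, bset, maxit = 200L) {
  x0 <- as.vector(t(mol$xyz))
  fn <- function(x) .energy_at(mol, bset, x)
  opt <- stats::optim(x0, fn, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = maxit,
                                     ndeps = rep(1e-4, length(x0))))
  x <- opt$par
  h <- 1e-4
  g <- vapply(seq_along(x), function(k) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(1))
  m <- mol; m$xyz <- matrix(x, ncol = 3, byrow = TRUE)
  list(molecule = m, energy = opt$value,
       max_force = max(abs(g)), rms_force = sqrt(mean(g^2)),
       converged = max(abs(g)) <= 3e-5 && sqrt(mean(g^2)) <= 1.5e-5)
}
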