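# Independent numerical oracles.
#
# These deliberately avoid the Hermite-recursion production path: matrix
# elements are evaluated by tensor-product Gauss-Hermite quadrature of the
# explicit integrand (exact for the polynomial-times-Gaussian part, and
# converged to machine precision for the entire phase factors used by the
# velocity-gauge and magnetic-gauge checks), and perturbed integrals are
# checked against central finite differences of zeroth-order quantities.
# They back both the test suite and the run-time diagnostics report.

#' Gauss-Hermite nodes and weights
#'
#' Golub-Welsch construction from the Jacobi matrix of the Hermite
#' polynomials: integrates f(x) exp(-x^2) over the real line.
#'
#' @param n number of nodes
#' @return list with `nodes` and `weights`
#' @export
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  eg <- eigen(J, symmetric = TRUE)
  list(nodes = eg$values, weights = sqrt(pi) * eg$vectors[1, ]^2)
}

# quadrature of  integral f(r) * chiA(r) * chiB(r) dr  for two primitive
# rows of a flat primitive table; f takes (x, y, z) vectors and may return
# complex values
.quad_prim_pair <- function(pa, pb, f, nq) {
  a <- pa[["alpha"]]; b <- pb[["alpha"]]
  A <- unname(pa[c("Ax", "Ay", "Az")]); B <- unname(pb[c("Ax", "Ay", "Az")])
  p <- a + b
  P <- (a * A + b * B) / p
  K <- exp(-a * b / p * sum((A - B)^2))
  gh <- gauss_hermite(nq)
  x <- P[1] + gh$nodes / sqrt(p)
  y <- P[2] + gh$nodes / sqrt(p)
  z <- P[3] + gh$nodes / sqrt(p)
  w <- gh$weights / sqrt(p)
  g <- expand.grid(i = seq_len(nq), j = seq_len(nq), k = seq_len(nq))
  xs <- x[g$i]; ys <- y[g$j]; zs <- z[g$k]
  ws <- w[g$i] * w[g$j] * w[g$k]
  poly <- (xs - A[1])^pa[["lx"]] * (ys - A[2])^pa[["ly"]] *
          (zs - A[3])^pa[["lz"]] * (xs - B[1])^pb[["lx"]] *
          (ys - B[2])^pb[["ly"]] * (zs - B[3])^pb[["lz"]]
  val <- sum(ws * poly * f(xs, ys, zs))
  pa[["coef"]] * pb[["coef"]] * K * val
}

#' Quadrature evaluation of a one-electron matrix element
#'
#' @param prim flat primitive table (as in an `ao_basis`)
#' @param i,j contracted function indices
#' @param f integrand weight function f(x, y, z) (default 1: plain overlap);
#'   may return complex values
#' @param nq Gauss-Hermite nodes per dimension
#' @return the matrix element (possibly complex)
#' @export
quad_matrix_element <- function(prim, i, j, f = function(x, y, z) 1,
                                nq = 24) {
  ri <- which(prim[, "fidx"] == i)
  rj <- which(prim[, "fidx"] == j)
  acc <- 0
  for (a in ri) for (b in rj)
    acc <- acc + .quad_prim_pair(prim[a, ], prim[b, ], f, nq)
  acc
}

# ---------------------------------------------------------------------------
# finite-difference oracles

#' Finite-difference derivative of core matrices with respect to an atom
#' position
#'
#' Rebuilds the AO basis and analytic core integrals at geometries displaced
#' by +/- step along R_beta of atom `lambda` and returns central
#' differences of S, T, Vne and (optionally) the full ERI tensor.
#'
#' @param mol molecule
#' @param bset element basis
#' @param lambda atom index
#' @param beta direction 1..3
#' @param step displacement (bohr)
#' @param eri include the ERI-tensor derivative
#' @return list with `S1`, `T1`, `V1`, and optionally `ERI1`
#' @export
fd_core_derivatives <- function(mol, bset, lambda, beta, step = 1e-5,
                                eri = FALSE) {
  val <- function(sgn) {
    m <- mol
    m$xyz[lambda, beta] <- m$xyz[lambda, beta] + sgn * step
    basis <- build_ao_basis(m, bset)
    ints <- compute_core_integrals(m, basis)
    list(S = ints$S0, T = ints$T, V = ints$Vne,
         E = if (eri) ints$eri else NULL)
  }
  p <- val(1); m_ <- val(-1)
  out <- list(S1 = (p$S - m_$S) / (2 * step),
              T1 = (p$T - m_$T) / (2 * step),
              V1 = (p$V - m_$V) / (2 * step))
  if (eri) out$ERI1 <- (p$E - m_$E) / (2 * step)
  out
}

#' Complex-phase finite-difference oracle for the velocity-gauge overlap
#'
#' Attaches the explicit phase exp(i rdot (r_beta - O_beta)) to the basis
#' functions of atom `lambda` and differentiates the quadrature-evaluated
#' overlap numerically at rdot = step.  Returns the real factor of the
#' (imaginary) derivative, comparable to the `S1` of [vao_first_order()].
#'
#' @param basis `ao_basis`
#' @param lambda atom index
#' @param beta direction
#' @param o_sp spatial gauge origin
#' @param step phase amplitude used for the finite difference
#' @param nq quadrature nodes per dimension
#' @return n x n real matrix
#' @export
fd_vao_overlap <- function(basis, lambda, beta, o_sp = c(0, 0, 0),
                           step = 1e-5, nq = 24) {
  n <- basis$n
  out <- matrix(0, n, n)
  on_lam <- basis$ao_atom == lambda
  coord <- function(x, y, z) switch(beta, x, y, z) - o_sp[beta]
  for (i in seq_len(n)) for (j in seq_len(n)) {
    si <- if (on_lam[i]) -1 else 0   # bra conjugate
    sj <- if (on_lam[j]) 1 else 0
    if (si == 0 && sj == 0) next
    f <- function(x, y, z) exp(1i * step * (si + sj) * coord(x, y, z))
    val <- quad_matrix_element(basis$prim, i, j, f, nq)
    out[i, j] <- Im(val) / step
  }
  out
}

#' Complex-phase finite-difference oracle for the GIAO overlap
#'
#' Attaches the London phase exp(-(i/2c) (B x (R_mu - O_mag)) . r) to every
#' basis function for a field B = step * e_alpha and differentiates the
#' quadrature overlap numerically.  Returns the real factor comparable to
#' the `S1` of [giao_first_order()].
#'
#' @param basis `ao_basis`
#' @param alpha field direction 1..3
#' @param o_mag magnetic gauge origin
#' @param step field amplitude
#' @param nq quadrature nodes per dimension
#' @return n x n real matrix
#' @export
fd_giao_overlap <- function(basis, alpha, o_mag = c(0, 0, 0), step = 1e-6,
                            nq = 24) {
  n <- basis$n
  cinv <- 1 / (2 * phys_constants$c_au)
  out <- matrix(0, n, n)
  B <- c(0, 0, 0); B[alpha] <- step
  for (i in seq_len(n)) for (j in seq_len(n)) {
    vi <- crossprod_vec(B, basis$centers[i, ] - o_mag)
    vj <- crossprod_vec(B, basis$centers[j, ] - o_mag)
    dv <- cinv * (vj - vi)   # bra phase conjugated
    f <- function(x, y, z) exp(-1i * (dv[1] * x + dv[2] * y + dv[3] * z))
    val <- quad_matrix_element(basis$prim, i, j, f, nq)
    out[i, j] <- Im(val) / step
  }
  out
}

#' Exponential-tilt finite-difference oracle for moment-weighted matrices
#'
#' Multiplying a Gaussian by exp(h (r_g - O_g)) is exactly another
#' polynomial Gaussian: the exponent completes the square into a shifted
#' center A' = A + h/(2 alpha) and the Cartesian polynomial re-expands
#' binomially about A'.  Differentiating engine-evaluated matrix elements
#' of the tilted bra at h = 0 therefore yields <(r_g - O_g) mu | Op | nu>
#' through plain base integrals at shifted centers -- a route entirely
#' independent of the angular-momentum-raising identity used in
#' production.
#'
#' @param basis `ao_basis`
#' @param g moment direction 1..3
#' @param origin moment origin
#' @param type operator: "S", "T" or "V"
#' @param mol molecule (required for type "V")
#' @param step tilt amplitude
#' @return n x n matrix approximating <(r_g - O_g) mu|Op|nu>
#' @export
tilt_moment_fd <- function(basis, g, origin = c(0, 0, 0), type = "S",
                           mol = NULL, step = 1e-5) {
  tilt_table <- function(h) {
    rows <- list()
    for (r in seq_len(nrow(basis$prim))) {
      p <- basis$prim[r, ]
      a <- p[["alpha"]]; l <- p[[2 + g]]
      shift <- h / (2 * a)
      scale <- exp(h * (p[[5 + g]] - origin[g]) + h^2 / (4 * a))
      for (k in 0:l) {
        q <- p
        q[["coef"]] <- p[["coef"]] * scale * choose(l, k) * shift^(l - k)
        q[[2 + g]] <- k
        q[[5 + g]] <- p[[5 + g]] + shift
        rows[[length(rows) + 1]] <- q
      }
    }
    do.call(rbind, rows)
  }
  mval <- function(h) {
    tb <- tilt_table(h)
    switch(type,
      S = cpp_int1e(tb, basis$prim, 0L, numeric(0), matrix(0, 0, 3), 0L),
      T = cpp_int1e(tb, basis$prim, 1L, numeric(0), matrix(0, 0, 3), 0L),
      V = cpp_int1e(tb, basis$prim, 2L, mol$Z, mol$xyz, 0L),
      stop("unsupported type"))
  }
  (mval(step) - mval(-step)) / (2 * step)
}

#' Finite-difference dipole derivative (atomic polar tensor oracle)
#'
#' Central differences of the converged SCF dipole moment with respect to
#' nuclear displacements; the reference oracle for the length-form polar
#' tensors.
#'
#' @param mol molecule
#' @param bset element basis
#' @param step displacement (bohr), default 1e-3
#' @param origin dipole reference origin
#' @return array [atom, alpha, beta]
#' @export
fd_apt <- function(mol, bset, step = 1e-3, origin = c(0, 0, 0)) {
  nat <- nrow(mol$xyz)
  out <- array(0, c(nat, 3, 3))
  dip <- function(xyz) {
    m <- mol; m$xyz <- xyz
    basis <- build_ao_basis(m, bset)
    st <- run_scf(m, basis)
    scf_dipole(st, origin)
  }
  for (lam in seq_len(nat)) for (beta in 1:3) {
    xp <- mol$xyz; xp[lam, beta] <- xp[lam, beta] + step
    xm <- mol$xyz; xm[lam, beta] <- xm[lam, beta] - step
    out[lam, , beta] <- (dip(xp) - dip(xm)) / (2 * step)
  }
  out
}
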