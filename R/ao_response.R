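# AO-basis density-matrix linear response.
#
# The perturbed density is parametrized through an anti-Hermitian generator
# X acting on the reference density,
#   D(x) = D0 + [D0, X]_S + ...,   [D0, X]_S = D0 S X - X S D0,
# which preserves idempotency and trace to first order for any X.  The
# occupied-occupied block of the response is fixed algebraically by the
# differentiated idempotency condition, D1_oo = -D0 S1 D0, and the
# occupied-virtual part solves the linearized stationarity condition
#   d/dx (F D S - S D F) = 0.
# Working in the symmetrically orthogonalized (Lowdin) basis and splitting
# F1 = H1 + G(D1), the unknown x obeys the linear equation
#   -P_ov([F,Dx] + [G(Dx),D])  =  P_ov([B,D] + [F,doo] + F D s - s D F),
# with Dx = [D, x], B = H1 + G(doo), P_ov the occupied-virtual projection.
# The left-hand operator is symmetric positive definite on that subspace
# (it is the singlet orbital Hessian: A+B-type coupling for real
# perturbations, A-B-type for imaginary ones), so a preconditioned
# conjugate-gradient iteration applies.  All algebra is real: imaginary
# Hermitian matrices are represented by their antisymmetric real factors.

mat_sqrt_pair <- function(S) {
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(eg$values) <= 0) stop("matrix is not positive definite")
  half <- eg$vectors %*% (sqrt(eg$values) * t(eg$vectors))
  invh <- eg$vectors %*% ((1 / sqrt(eg$values)) * t(eg$vectors))
  list(half = half, invhalf = invh)
}

mat_invsqrt <- function(S) mat_sqrt_pair(S)$invhalf

#' Lowdin (symmetric-orthogonalization) transform
#'
#' Covariant quantities (Fock, Hamiltonian and overlap-like matrices)
#' transform as S^{-1/2} M S^{-1/2}; contravariant (density-like) ones as
#' S^{1/2} M S^{1/2}.  `"inverse"` undoes the covariant transform (which is
#' exactly the contravariant congruence), so
#' `lowdin_transform(lowdin_transform(M, S, "covariant"), S, "inverse")`
#' returns `M`.
#'
#' @param M matrix to transform
#' @param S0 positive-definite overlap matrix
#' @param direction one of "covariant", "contravariant", "inverse"
#' @return transformed matrix
#' @export
lowdin_transform <- function(M, S0,
                             direction = c("covariant", "contravariant",
                                           "inverse")) {
  direction <- match.arg(direction)
  p <- mat_sqrt_pair(S0)
  X <- if (direction == "covariant") p$invhalf else p$half
  X %*% M %*% X
}

#' Project out the redundant (occ-occ and virt-virt) components
#'
#' Applies the occupied/virtual projectors built from D0 S0 to a
#' density-like matrix, keeping only the occupied-virtual and
#' virtual-occupied components that parametrize a genuine density change.
#' The operation is idempotent.
#'
#' @param A density-like matrix
#' @param D0 reference density (spinless convention)
#' @param S0 overlap
#' @return projected matrix
#' @export
project_redundant <- function(A, D0, S0) {
  P <- D0 %*% S0           # occupied projector (density-like action)
  Q <- diag(nrow(A)) - P
  P %*% A %*% t(Q) + Q %*% A %*% t(P)
}

#' Occupied-occupied block of the density response
#'
#' Resolves the derivative of the idempotency condition D S D = D in the
#' occupied space: D1_oo = -D0 S1 D0 (real factors for both perturbation
#' flavors).  Vanishes when the perturbed overlap is zero.
#'
#' @param D0 reference density
#' @param S1 perturbed overlap (real factor)
#' @return matrix
#' @export
occ_occ_block <- function(D0, S1) {
  -D0 %*% S1 %*% D0
}

# Lowdin-basis quantities shared by all channels of one SCF state; memoized
.response_ctx <- function(scf) {
  if (!is.null(scf$ints$cache$.rctx)) return(scf$ints$cache$.rctx)
  S <- scf$S0
  p <- mat_sqrt_pair(S)
  Dt <- p$half %*% scf$D0 %*% p$half
  Ft <- p$invhalf %*% scf$H0 %*% p$invhalf
  Dt <- (Dt + t(Dt)) / 2; Ft <- (Ft + t(Ft)) / 2
  ctx <- list(half = p$half, invhalf = p$invhalf, Dt = Dt, Ft = Ft,
              Qt = diag(nrow(S)) - Dt, fdiag = diag(Ft))
  scf$ints$cache$.rctx <- ctx
  ctx
}

#' Solve one AO-basis response channel
#'
#' @param problem list describing the channel: `flavor` ("real" or "imag"),
#'   `h` (real factor of the perturbation Hamiltonian H1 = h1 + G1(D0)),
#'   `s` (real factor of the perturbed overlap, may be zero), `coupling`
#'   (logical: include the self-consistent G(D1) term), `label`
#' @param scf a converged `scf_state`
#' @param tol residual threshold on the projected working equation
#' @param max_iter maximum CG iterations
#' @return object of class `density_response` with `d1` (AO-basis real
#'   factor of D1), `d1_oo`, `x1` (Lowdin-basis generator), `residual_norm`,
#'   `n_iter`, `flavor`, `s1`, `label`, and the residual history
#' @export
solve_response <- function(problem, scf, tol = 5e-12, max_iter = 2000L) {
  ctx <- .response_ctx(scf)
  ints <- scf$ints
  flavor <- problem$flavor
  n <- nrow(ctx$Dt)
  D <- ctx$Dt; Q <- ctx$Qt; F <- ctx$Ft
  Xh <- ctx$half; Xi <- ctx$invhalf
  sgn <- if (flavor == "real") 1 else -1   # transpose sign of the class

  st <- if (is.null(problem$s)) matrix(0, n, n) else Xi %*% problem$s %*% Xi
  ht <- Xi %*% problem$h %*% Xi
  # occ-occ response factor (Lowdin basis)
  doo <- -D %*% st %*% D
  # extract the physically determined ov/vo content of h; for a matrix
  # already in the proper hermiticity class this only removes the irrelevant
  # oo and vv blocks
  hov <- Q %*% ht %*% D
  ht_eff <- hov + sgn * t(hov)
  Goo <- if (is.null(problem$coupling) || problem$coupling) {
    Xi %*% gresp(ints, Xi %*% doo %*% Xi, flavor) %*% Xi
  } else matrix(0, n, n)
  B <- ht_eff + Goo

  pov <- function(A) D %*% A %*% Q + Q %*% A %*% D
  rhs <- pov(B %*% D - D %*% B + F %*% doo - doo %*% F +
             F %*% D %*% st - st %*% D %*% F)
  couple <- isTRUE(problem$coupling)
  Aop <- function(x) {
    Dx <- D %*% x - x %*% D
    M <- F %*% Dx - Dx %*% F
    if (couple) {
      G <- Xi %*% gresp(ints, Xi %*% Dx %*% Xi, flavor) %*% Xi
      M <- M + G %*% D - D %*% G
    }
    -pov(M)
  }
  # Jacobi preconditioner from Lowdin-diagonal level differences
  fd <- ctx$fdiag
  denom <- abs(outer(fd, fd, "-")) + 0.25
  prec <- function(r) r / denom

  x <- matrix(0, n, n)
  r <- rhs
  hist <- max(abs(r))
  if (hist <= tol) {
    z <- NULL
  } else {
    z <- prec(r); p <- z
    rz <- sum(r * z)
    best <- hist; since_best <- 0L
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter)
        stop("response CG exceeded ", max_iter, " iterations for channel ",
             problem$label, "; residual history tail: ",
             paste(format(tail(hist, 5), digits = 3), collapse = ", "))
      Ap <- Aop(p)
      alpha <- rz / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      res <- max(abs(r))
      hist <- c(hist, res)
      if (res <= tol) break
      if (res < best - 1e-30 && res < best) { best <- res; since_best <- 0L }
      else since_best <- since_best + 1L
      if (since_best >= 25L)
        stop("response CG stagnated (no residual decrease over 25 iterations) ",
             "for channel ", problem$label, "; residual history tail: ",
             paste(format(tail(hist, 6), digits = 3), collapse = ", "))
      z <- prec(r)
      rz_new <- sum(r * z)
      p <- z + (rz_new / rz) * p
      rz <- rz_new
    }
  }
  Dx <- D %*% x - x %*% D
  d1t <- Dx + doo
  d1 <- Xi %*% d1t %*% Xi
  d1 <- (d1 + sgn * t(d1)) / 2
  structure(list(d1 = d1, d1_oo = Xi %*% doo %*% Xi, x1 = x,
                 residual_norm = max(abs(r)), n_iter = length(hist) - 1L,
                 flavor = flavor, s1 = problem$s, label = problem$label,
                 history = hist, solver = "ao"),
            class = "density_response")
}

#' @export
print.density_response <- function(x, ...) {
  cat(sprintf("density_response [%s, %s solver]: residual %.2e after %d iterations\n",
              x$label, x$solver, x$residual_norm, x$n_iter))
  invisible(x)
}
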