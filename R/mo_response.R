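# Molecular-orbital Sternheimer solver: the independent validation path.
#
# Every channel is reduced to per-occupied-orbital linear equations in the
# virtual-projected space.  In the canonical MO basis the projected operator
# (F - eps_j S) is diagonal with elements (eps_a - eps_j), so the projected
# equation is solved exactly orbital by orbital; the self-consistent
# two-electron coupling is handled by an outer damped iteration.  The
# occupied-occupied response never solves an equation: differentiating the
# MO orthonormality condition C^T S C = 1 fixes it as u_oo = -S1^MO/2
# (symmetric part for real channels, antisymmetric factor for imaginary
# ones, i.e. literally -S1^MO/2 in the stored-factor convention).

#' Assemble a density-response factor from perturbed MO coefficients
#'
#' D1 = sum_occ (C1 C0^T + C0 C1^T) for real channels; for imaginary
#' channels C1 = i c and the real factor is c C0^T - C0 c^T.
#'
#' @param C0occ unperturbed occupied coefficients (n x n_occ)
#' @param C1occ perturbed occupied coefficients (real factor, n x n_occ)
#' @param flavor "real" or "imag"
#' @return density-response real factor (symmetric or antisymmetric)
#' @export
assemble_density_response <- function(C0occ, C1occ, flavor = c("real", "imag")) {
  flavor <- match.arg(flavor)
  M <- tcrossprod(C1occ, C0occ)
  if (flavor == "real") M + t(M) else M - t(M)
}

#' Solve one response channel with the MO Sternheimer approach
#'
#' @inheritParams solve_response
#' @param tol convergence threshold; the outer self-consistency loop stops
#'   when the density response changes by less than 10 * tol
#' @param damping mixing factor for the coupled outer iteration
#' @param max_outer maximum outer iterations
#' @return a `density_response` (same structure as the AO solver, plus
#'   `C1occ`, the perturbed occupied coefficient factor)
#' @export
solve_sternheimer <- function(problem, scf, tol = 5e-12, damping = 0.5,
                              max_outer = 300L) {
  flavor <- problem$flavor
  n <- nrow(scf$S0); no <- scf$n_occ
  C <- scf$C0; eps <- scf$eps
  occ <- seq_len(no); virt <- setdiff(seq_len(n), occ)
  if (length(virt)) {
    gap <- min(outer(eps[virt], eps[occ], "-"))
    if (gap < 1e-6) {
      i <- which(outer(eps[virt], eps[occ], "-") == gap, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "near-degenerate occupied-virtual pair (occ %d, virt %d, gap %.2e)",
        occ[i[2]], virt[i[1]], gap))
    }
  }
  s <- if (is.null(problem$s)) matrix(0, n, n) else problem$s
  sMO <- crossprod(C, s %*% C)          # S1 in the MO basis (factor)
  u_oo <- -0.5 * sMO[occ, occ, drop = FALSE]
  Cocc <- C[, occ, drop = FALSE]
  Cvirt <- C[, virt, drop = FALSE]
  # occ-occ part of C1 is fixed once; iterate on the occ-virt part
  C1_oo <- Cocc %*% u_oo
  d_oo <- assemble_density_response(Cocc, C1_oo, flavor)
  couple <- isTRUE(problem$coupling)
  ints <- scf$ints
  U_vo <- matrix(0, length(virt), no)
  gapm <- outer(eps[virt], eps[occ], "-")
  solve_diag <- function(h_eff) {
    hMO <- crossprod(Cvirt, h_eff %*% Cocc)     # (a,j) block
    -(hMO - sweep(sMO[virt, occ, drop = FALSE], 2, eps[occ], "*")) / gapm
  }
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_outer)
      stop("Sternheimer outer loop failed to converge for channel ",
           problem$label)
    d_cur <- d_oo + assemble_density_response(Cocc, Cvirt %*% U_vo, flavor)
    h_eff <- problem$h
    if (couple) h_eff <- h_eff + gresp(ints, d_cur, flavor)
    U_new <- solve_diag(h_eff)
    delta <- max(abs(U_new - U_vo))
    if (!couple || delta <= tol) { U_vo <- U_new; break }
    U_vo <- U_vo + damping * (U_new - U_vo)
  }
  C1occ <- C1_oo + Cvirt %*% U_vo
  d1 <- d_oo + assemble_density_response(Cocc, Cvirt %*% U_vo, flavor)
  # residual of the projected Sternheimer equation, for the record
  h_eff <- problem$h
  if (couple) h_eff <- h_eff + gresp(ints, d1, flavor)
  hMO <- crossprod(Cvirt, h_eff %*% Cocc)
  res <- max(abs(hMO - sweep(sMO[virt, occ, drop = FALSE], 2, eps[occ], "*") +
                   outer(eps[virt], eps[occ], "-") * U_vo))
  structure(list(d1 = d1, d1_oo = d_oo, C1occ = C1occ, U_vo = U_vo,
                 residual_norm = res, n_iter = it, flavor = flavor,
                 s1 = problem$s, label = problem$label, solver = "mo"),
            class = "density_response")
}
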