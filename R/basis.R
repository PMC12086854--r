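# AO basis construction: expand shells into contracted Cartesian Gaussians
# and build the flat primitive tables consumed by the C++ integral engine.

# Cartesian component exponents for angular momentum l, canonical order
# (lx descending, then ly descending): p -> x,y,z; d -> xx,xy,xz,yy,yz,zz.
cart_components <- function(l) {
  out <- list()
  for (lx in l:0) for (ly in (l - lx):0)
    out[[length(out) + 1]] <- c(lx, ly, l - lx - ly)
  do.call(rbind, out)
}

odd_fact2 <- function(n) { # (2n-1)!! with n >= 0
  if (n <= 0) return(1)
  prod(seq(1, 2 * n - 1, by = 2))
}

# primitive normalization for a Cartesian Gaussian x^i y^j z^k exp(-a r^2)
prim_norm <- function(alpha, lx, ly, lz) {
  l <- lx + ly + lz
  (2 * alpha / pi)^0.75 * (4 * alpha)^(l / 2) /
    sqrt(odd_fact2(lx) * odd_fact2(ly) * odd_fact2(lz))
}

#' Build the atomic-orbital basis for a molecule
#'
#' Expands every shell of the element basis into its Cartesian components
#' (6d/10f convention) and renormalizes each contracted function to unit
#' self-overlap.  The result carries the flat primitive table used by the
#' integral engine plus per-AO metadata (atom index, center, angular
#' momentum).
#'
#' @param mol a [molecule()]
#' @param bset a `basis_set` from [read_basis()]
#' @return object of class `ao_basis` with fields `prim` (primitive matrix),
#'   `n` (number of AOs), `ao_atom`, `ao_l`, `centers` (n x 3)
#' @export
build_ao_basis <- function(mol, bset) {
  rows <- list()
  ao_atom <- integer(0); ao_l <- integer(0)
  centers <- list()
  fidx <- 0L
  for (ia in seq_along(mol$symbols)) {
    el <- mol$symbols[ia]
    sh <- bset[[el]]
    if (is.null(sh))
      stop("basis set has no entry for element ", el)
    A <- mol$xyz[ia, ]
    for (s in sh) {
      comps <- cart_components(s$l)
      for (ic in seq_len(nrow(comps))) {
        fidx <- fidx + 1L
        lv <- comps[ic, ]
        nrm <- vapply(s$exps, prim_norm, numeric(1), lv[1], lv[2], lv[3])
        rows[[length(rows) + 1]] <- cbind(
          coef = s$coefs * nrm, alpha = s$exps,
          lx = lv[1], ly = lv[2], lz = lv[3],
          Ax = A[1], Ay = A[2], Az = A[3], fidx = fidx)
        ao_atom <- c(ao_atom, ia)
        ao_l <- c(ao_l, s$l)
        centers[[length(centers) + 1]] <- A
      }
    }
  }
  prim <- do.call(rbind, rows)
  basis <- structure(list(prim = prim, n = fidx, ao_atom = ao_atom,
                          ao_l = ao_l, centers = do.call(rbind, centers)),
                     class = "ao_basis")
  # renormalize contracted functions to unit self-overlap
  S <- cpp_int1e(basis$prim, basis$prim, 0L, numeric(0),
                 matrix(0, 0, 3), 0L)
  scale <- 1 / sqrt(diag(S))
  basis$prim[, "coef"] <- basis$prim[, "coef"] * scale[basis$prim[, "fidx"]]
  basis
}

#' @export
print.ao_basis <- function(x, ...) {
  cat(sprintf("ao_basis: %d contracted Cartesian AOs, %d primitives\n",
              x$n, nrow(x$prim)))
  invisible(x)
}

# --- extended (derived) primitive tables -----------------------------------
# These represent exact operator images of the AOs, used to assemble moment
# and derivative integrals from the core engine.  They are not renormalized.

# l-raised functions: row-wise (r_g - A_g) * chi_mu  (about each AO's center)
ao_raise <- function(basis, g, prim = basis$prim) {
  p <- prim
  p[, 2 + g] <- p[, 2 + g] + 1
  p
}

# center-derivative functions d chi_mu / d A_g = 2a * raised - l * lowered
ao_center_deriv <- function(basis, g) {
  p <- basis$prim
  up <- p
  up[, "coef"] <- 2 * up[, "alpha"] * up[, "coef"]
  up[, 2 + g] <- up[, 2 + g] + 1
  has_l <- p[, 2 + g] > 0
  down <- p[has_l, , drop = FALSE]
  if (nrow(down)) {
    down[, "coef"] <- -down[, 2 + g] * down[, "coef"]
    down[, 2 + g] <- down[, 2 + g] - 1
  }
  rbind(up, down)
}

# absolute-moment matrix  <r_g chi_mu | Op | chi_nu> given the matrix of Op
# over the raised functions and over the plain AOs:
#   <(r_g) mu|Op|nu> = <(r_g - A_g) mu|Op|nu> + A_g <mu|Op|nu>
moment_bra <- function(basis, g, M_raised, M_plain) {
  M_raised + basis$centers[, g] * M_plain
}
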