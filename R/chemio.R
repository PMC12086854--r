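#' Construct a molecule
#'
#' Positions are stored internally in bohr.  The electron count must be even:
#' only closed-shell species are supported by the restricted mean field.
#'
#' @param symbols character vector of element symbols
#' @param xyz numeric N x 3 matrix of positions
#' @param charge total molecular charge (integer)
#' @param unit unit of `xyz`: "bohr" or "angstrom"
#' @param masses optional amu masses overriding the built-in
#'   isotope-averaged table
#' @return an object of class `molecule` with fields `symbols`, `Z`,
#'   `mass` (amu), `xyz` (bohr), `charge`, `n_electrons`
#' @export
molecule <- function(symbols, xyz, charge = 0L, unit = c("bohr", "angstrom"),
                     masses = NULL) {
  unit <- match.arg(unit)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(nrow(xyz) == length(symbols))
  if (unit == "angstrom") xyz <- xyz * phys_constants$bohr_per_angstrom
  info <- lapply(symbols, element_info)
  Z <- vapply(info, `[[`, numeric(1), "Z")
  mass <- vapply(info, `[[`, numeric(1), "mass")
  if (!is.null(masses)) {
    stopifnot(length(masses) == length(symbols), all(masses > 0))
    mass <- as.numeric(masses)
  }
  n_el <- sum(Z) - charge
  # odd electron counts are representable (file I/O, geometry tooling) but
  # the restricted mean field refuses them at run_scf()
  structure(list(symbols = as.character(symbols), Z = Z, mass = mass,
                 xyz = xyz, charge = as.integer(charge),
                 n_electrons = as.integer(n_el)),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d atoms, charge %d, %d electrons\n",
              nrow(x$xyz), x$charge, x$n_electrons))
  for (i in seq_along(x$symbols))
    cat(sprintf("  %-2s %12.8f %12.8f %12.8f (bohr)\n",
                x$symbols[i], x$xyz[i, 1], x$xyz[i, 2], x$xyz[i, 3]))
  invisible(x)
}

#' Read a molecule from an XYZ file
#'
#' Standard two-header-line XYZ dialect: first line the atom count, second a
#' free comment, then one `symbol x y z` line per atom.
#'
#' @param path file path
#' @param unit unit of the coordinates in the file (default angstrom)
#' @param charge total charge
#' @return a [molecule()]
#' @export
read_xyz <- function(path, unit = c("angstrom", "bohr"), charge = 0L) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) <= 2]
  if (length(lines) < 1) stop("XYZ parse error: empty file ", path)
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat)) stop("XYZ parse error at line 1: expected atom count")
  if (length(lines) < nat + 2)
    stop("XYZ parse error: expected ", nat, " atom lines, found ",
         max(0, length(lines) - 2))
  sym <- character(nat)
  xyz <- matrix(0, nat, 3)
  for (i in seq_len(nat)) {
    ln <- i + 2
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4)
      stop("XYZ parse error at line ", ln, ": expected 'symbol x y z'")
    co <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(co))
      stop("XYZ parse error at line ", ln, ": non-numeric coordinate")
    sym[i] <- tok[1]
    xyz[i, ] <- co
  }
  molecule(sym, xyz, charge = charge, unit = unit)
}

#' Write a molecule to an XYZ file
#'
#' @param mol a [molecule()]
#' @param path output path
#' @param unit unit for the written coordinates
#' @param comment comment line
#' @export
write_xyz <- function(mol, path, unit = c("angstrom", "bohr"),
                      comment = "written by vcdpt") {
  unit <- match.arg(unit)
  xyz <- mol$xyz
  if (unit == "angstrom") xyz <- xyz * phys_constants$angstrom_per_bohr
  lines <- c(as.character(nrow(xyz)), comment,
             sprintf("%-2s %20.12f %20.12f %20.12f",
                     mol$symbols, xyz[, 1], xyz[, 2], xyz[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Gauge-origin configuration
#'
#' Spatial (velocity-gauge) and magnetic gauge origins, both in bohr.  The
#' default is the common-origin choice (0,0,0) for both.
#'
#' @param o_sp spatial gauge origin (3-vector, bohr)
#' @param o_mag magnetic gauge origin (3-vector, bohr)
#' @return list with `o_sp`, `o_mag`
#' @export
gauge_config <- function(o_sp = c(0, 0, 0), o_mag = c(0, 0, 0)) {
  o_sp <- as.numeric(o_sp); o_mag <- as.numeric(o_mag)
  stopifnot(length(o_sp) == 3, length(o_mag) == 3,
            all(is.finite(o_sp)), all(is.finite(o_mag)))
  list(o_sp = o_sp, o_mag = o_mag)
}

#' Nuclear contribution to the electric dipole moment
#'
#' @param mol a [molecule()]
#' @param origin reference origin (bohr)
#' @return 3-vector, atomic units: sum over atoms of Z * (R - origin)
#' @export
nuclear_dipole <- function(mol, origin = c(0, 0, 0)) {
  colSums(mol$Z * sweep(mol$xyz, 2, origin))
}

# ---------------------------------------------------------------------------
# NWChem-style basis text

#' Read a Gaussian basis set in NWChem text format
#'
#' Element header lines of the form `"O  S"` (shell labels S, P, D, F, SP)
#' followed by rows of one exponent and one (or, for SP, two) contraction
#' coefficients.  SP blocks are split into an S and a P shell.  Contraction
#' coefficients are later renormalized so every contracted Cartesian
#' function has unit self-overlap.
#'
#' @param path file path, or a character vector of lines via `text =`
#' @param text optional character vector holding the file content
#' @return object of class `basis_set`: named list (by element) of shells,
#'   each a list with `l` and numeric `exps`, `coefs`
#' @export
read_basis <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("basis file not found: ", path)
    text <- readLines(path, warn = FALSE)
  }
  lmap <- c(S = 0L, P = 1L, D = 2L, F = 3L, G = 4L)
  shells <- list()
  cur <- NULL # list(elem, label, rows)
  flush <- function(cur, shells) {
    if (is.null(cur)) return(shells)
    if (length(cur$rows) == 0)
      stop("basis parse error: shell ", cur$label, " for ", cur$elem,
           " has no primitives")
    rows <- do.call(rbind, cur$rows)
    if (any(rows[, 1] <= 0))
      stop("basis parse error: non-positive exponent in ", cur$elem,
           " ", cur$label, " shell")
    add <- function(shells, elem, l, exps, coefs) {
      shells[[elem]] <- c(shells[[elem]],
                          list(list(l = l, exps = exps, coefs = coefs)))
      shells
    }
    if (cur$label == "SP") {
      if (ncol(rows) < 3)
        stop("basis parse error: SP shell needs two coefficient columns")
      shells <- add(shells, cur$elem, 0L, rows[, 1], rows[, 2])
      shells <- add(shells, cur$elem, 1L, rows[, 1], rows[, 3])
    } else {
      l <- lmap[[cur$label]]
      shells <- add(shells, cur$elem, l, rows[, 1], rows[, 2])
    }
    shells
  }
  for (raw in text) {
    ln <- trimws(sub("#.*$", "", raw))
    if (!nzchar(ln)) next
    up <- toupper(ln)
    if (up %in% c("END") || startsWith(up, "BASIS")) next
    tok <- strsplit(ln, "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(tok))
    if (anyNA(num)) {
      # header line: element + shell label
      if (length(tok) != 2)
        stop("basis parse error: bad header line '", ln, "'")
      lab <- toupper(tok[2])
      if (!(lab %in% c(names(lmap), "SP")))
        stop("basis parse error: unknown shell label '", tok[2], "'")
      shells <- flush(cur, shells)
      cur <- list(elem = tok[1], label = lab, rows = list())
    } else {
      if (is.null(cur)) stop("basis parse error: data row before any header")
      cur$rows <- c(cur$rows, list(num))
    }
  }
  shells <- flush(cur, shells)
  structure(shells, class = "basis_set")
}

#' Path to a built-in basis set file
#'
#' Three ladder levels are shipped for H, O and F: a minimal ("sto-3g"), a
#' split-valence ("6-31g") and a polarized ("6-31gss") set, all in NWChem
#' text format under `inst/extdata`.
#'
#' @param name one of "sto-3g", "6-31g", "6-31gss"
#' @return file path
#' @export
builtin_basis_path <- function(name = c("sto-3g", "6-31g", "6-31gss")) {
  name <- match.arg(name)
  p <- system.file("extdata", paste0(name, ".nwbas"), package = "vcdpt")
  if (!nzchar(p)) stop("built-in basis not found: ", name)
  p
}

#' Load a built-in basis set
#'
#' @inheritParams builtin_basis_path
#' @return a `basis_set`
#' @export
builtin_basis <- function(name = c("sto-3g", "6-31g", "6-31gss")) {
  read_basis(builtin_basis_path(match.arg(name)))
}
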