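#' Crystal structure container
#'
#' Bundles the unit cell, wavelength, symmetry operations, atom sites and
#' the element scattering-coefficient table. Atom sites live in a data
#' frame with one row per atom: `label`, `element`, fractional `x`, `y`,
#' `z`, `occ`, `aniso` flag, `uiso` and the six `u11 ... u12` components
#' (SHELX order U11 U22 U33 U23 U13 U12), plus an optional
#' `riding_parent` label for constrained hydrogens.
#'
#' @param cell Six lattice parameters (a, b, c A; alpha, beta, gamma deg).
#' @param atoms Atom-site data frame (see Details); missing ADP columns
#'   are filled with defaults (isotropic, U = 0.03 A^2).
#' @param symmetry_ops List of 3x4 matrices (rotation | translation) in
#'   fractional coordinates; the identity is added if absent.
#' @param wavelength Radiation wavelength in Angstrom.
#' @param sfac Optional named list of `gaussian_coefficients`; defaults to
#'   the packaged table entries for the elements present.
#' @return A `crystal_structure` object.
#' @export
crystal_structure <- function(cell, atoms, symmetry_ops = list(),
                              wavelength = 0.71073, sfac = NULL) {
  atoms <- normalize_atoms(atoms)
  ops <- normalize_symm_ops(symmetry_ops)
  if (is.null(sfac)) {
    sfac <- lapply(unique(toupper(atoms$element)), sfac_coefficients)
    names(sfac) <- unique(toupper(atoms$element))
  }
  st <- structure(list(cell = as.numeric(cell), wavelength = wavelength,
                       symmetry_ops = ops, atoms = atoms, sfac = sfac,
                       extra_cards = character(0)),
                  class = "crystal_structure")
  validate_structure(st)
  st
}

normalize_atoms <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("label", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms need columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(atoms$label))
    stop("duplicate atom labels: ",
         paste(unique(atoms$label[duplicated(atoms$label)]), collapse = ", "))
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$uiso)) atoms$uiso <- 0.03
  if (is.null(atoms$aniso)) atoms$aniso <- FALSE
  for (u in c("u11", "u22", "u33", "u23", "u13", "u12"))
    if (is.null(atoms[[u]])) atoms[[u]] <- NA_real_
  if (is.null(atoms$riding_parent)) atoms$riding_parent <- NA_character_
  rownames(atoms) <- NULL
  atoms
}

normalize_symm_ops <- function(ops) {
  ident <- cbind(diag(3), c(0, 0, 0))
  ops <- lapply(ops, function(m) {
    m <- as.matrix(m)
    stopifnot(nrow(m) == 3, ncol(m) == 4)
    m
  })
  has_ident <- any(vapply(ops, function(m) all(abs(m - ident) < 1e-9), logical(1)))
  if (!has_ident) ops <- c(list(ident), ops)
  ops
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat("crystal_structure:", nrow(x$atoms), "atoms,",
      length(x$symmetry_ops), "symmetry op(s)\n")
  cat("  cell:", paste(format(x$cell, digits = 6), collapse = " "), "\n")
  invisible(x)
}

validate_structure <- function(st) {
  cell_metrics(st$cell)  # checks lengths/angles
  a <- st$atoms
  if (any(a$occ <= 0 | a$occ > 1))
    stop("occupancies must lie in (0, 1]")
  for (el in unique(toupper(a$element)))
    if (is.null(st$sfac[[el]]))
      stop("element '", el, "' has no scattering-factor entry")
  for (i in seq_len(nrow(a))) {
    if (a$aniso[i]) {
      U <- u_matrix(a[i, ])
      if (any(eigen(U, symmetric = TRUE, only.values = TRUE)$values <= 0))
        stop("U_ij of atom ", a$label[i], " is not positive-definite")
    } else if (!is.finite(a$uiso[i]) || a$uiso[i] <= 0) {
      stop("U_iso of atom ", a$label[i], " must be positive")
    }
  }
  invisible(st)
}

u_matrix <- function(atom_row) {
  with(atom_row, matrix(c(u11, u12, u13,
                          u12, u22, u23,
                          u13, u23, u33), 3, 3))
}

#' Isotropic-equivalent displacement parameter
#'
#' U_eq is one third of the trace of the orthogonalized U tensor; for an
#' isotropic atom it is U_iso itself.
#'
#' @param structure A `crystal_structure`.
#' @param label Atom label (vector allowed).
#' @return U_eq in A^2.
#' @export
u_eq <- function(structure, label) {
  m <- cell_metrics(structure$cell)
  vapply(label, function(lb) {
    i <- match(lb, structure$atoms$label)
    if (is.na(i)) stop("unknown atom label '", lb, "'")
    row <- structure$atoms[i, ]
    if (!row$aniso) return(row$uiso)
    Ustar <- u_matrix(row) * outer(m$astar, m$astar)
    Ucart <- m$ortho %*% Ustar %*% t(m$ortho)
    sum(diag(Ucart)) / 3
  }, numeric(1))
}

atom_index <- function(structure, label) {
  i <- match(label, structure$atoms$label)
  if (anyNA(i))
    stop("unknown atom label(s): ", paste(label[is.na(i)], collapse = ", "))
  i
}
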