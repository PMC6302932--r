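#' Unit-cell metric utilities
#'
#' Internal helpers turning the six lattice parameters (a, b, c in
#' Angstrom; alpha, beta, gamma in degrees) into the direct metric tensor,
#' the fractional-to-Cartesian orthogonalization matrix (a along x,
#' b in the xy plane) and the reciprocal metric.
#'
#' @param cell Numeric length-6: a, b, c, alpha, beta, gamma.
#' @return List with `G` (direct metric), `Gstar` (reciprocal metric),
#'   `ortho` (3x3 fractional -> Cartesian), `frac` (its inverse),
#'   `volume` (A^3), `astar` (reciprocal axis lengths).
#' @keywords internal
cell_metrics <- function(cell) {
  stopifnot(length(cell) == 6)
  if (any(cell[1:3] <= 0)) stop("cell lengths must be positive")
  if (any(cell[4:6] <= 0) || any(cell[4:6] >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  ca <- cos(al); cb <- cos(be); cg <- cos(ga); sg <- sin(ga)
  G <- matrix(c(a * a, a * b * cg, a * c * cb,
                a * b * cg, b * b, b * c * ca,
                a * c * cb, b * c * ca, c * c), 3, 3)
  vol2 <- det(G)
  if (vol2 <= 0) stop("singular cell metric")
  V <- sqrt(vol2)
  ortho <- matrix(c(a, 0, 0,
                    b * cg, b * sg, 0,
                    c * cb, c * (ca - cb * cg) / sg, V / (a * b * sg)),
                  3, 3)
  Gstar <- solve(G)
  list(G = G, Gstar = Gstar, ortho = ortho, frac = solve(ortho),
       volume = V, astar = sqrt(diag(Gstar)))
}

#' sin(theta)/lambda for Miller indices
#'
#' @param hkl Integer matrix with one h k l row per reflection.
#' @param cell Six lattice parameters.
#' @return s = sin(theta)/lambda in 1/Angstrom (equals 1/(2d)).
#' @export
s_of_hkl <- function(hkl, cell) {
  hkl <- as_hkl_matrix(hkl)
  m <- cell_metrics(cell)
  0.5 * sqrt(rowSums((hkl %*% m$Gstar) * hkl))
}

as_hkl_matrix <- function(hkl) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3, byrow = TRUE)
  storage.mode(hkl) <- "double"
  hkl
}

frac_to_cart <- function(xyz, metrics) {
  xyz <- if (is.null(dim(xyz))) matrix(xyz, ncol = 3) else xyz
  xyz %*% t(metrics$ortho)
}

cart_to_frac <- function(xyz, metrics) {
  xyz <- if (is.null(dim(xyz))) matrix(xyz, ncol = 3) else xyz
  xyz %*% t(metrics$frac)
}
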