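#' BEDE bond-density instruction
#'
#' Places a Gaussian of amplitude +A (spread B1) on the bond at distance
#' `r` from `atom1` toward `atom2`, and a compensating Gaussian of
#' amplitude -A (spread B2) at `atom1`, so no net charge is added. Four
#' free parameters per bond per atom: r, A, B1, B2.
#'
#' @param atom1,atom2 Atom labels defining the bond direction.
#' @param r Distance of the bond lobe from atom1 (Angstrom), > 0.
#' @param A Amplitude in electrons.
#' @param B1,B2 Dimensionless spread multipliers (> 0) of the +A and -A
#'   lobes; both couple to atom1's displacement parameter.
#' @return A `bede_instruction` object.
#' @export
bede <- function(atom1, atom2, r, A, B1, B2) {
  if (r <= 0) stop("BEDE r must be positive")
  if (B1 <= 0 || B2 <= 0) stop("BEDE spreads B1, B2 must be positive")
  structure(list(kind = "BEDE", atom1 = atom1, atom2 = atom2,
                 r = r, A = A, B1 = B1, B2 = B2),
            class = c("bede_instruction", "bodd_instruction"))
}

#' LONE lone-pair instruction
#'
#' Places lone-pair lobes of amplitude +A around `atom` according to the
#' geometry code `m`, and a compensating Gaussian at the atom whose
#' amplitude is minus the summed added density, keeping the electron count
#' balanced (e.g. -2A for m = 2; -6A for the twelve half-occupied lobes of
#' m = 12).
#'
#' Geometry codes: m = 1 one lobe opposite three bonds; m = 2 two lobes
#' (two bonds, angle between the lobes supplied); m = 3 three staggered
#' lobes on one bond; m = 6 two lobes perpendicular to the plane of two
#' bonds (pi density); m = 7 like 6 for terminal atoms, the plane being
#' fixed by a second-shell bond; m = 9 like 7 but in-plane; m = 12 twelve
#' half-occupied lobes on a cone (disordered methyl analogue); m = 15 one
#' lobe completing a 4-5 coordinate polyhedron.
#'
#' @param m Geometry code, one of 1, 2, 3, 6, 7, 9, 12, 15.
#' @param atom Host atom label.
#' @param A Amplitude per lobe (electrons).
#' @param B1,B2 Spread multipliers of added / subtracted lobes.
#' @param r Lobe distance from the atom (Angstrom).
#' @param angle Lobe opening angle in degrees; required exactly for
#'   m in {2, 3, 7, 9}.
#' @return A `lone_instruction` object.
#' @export
lone <- function(m, atom, A, B1, B2, r, angle = NULL) {
  if (!m %in% c(1, 2, 3, 6, 7, 9, 12, 15))
    stop("unsupported LONE geometry code m = ", m)
  needs_angle <- m %in% c(2, 3, 7, 9)
  if (needs_angle && is.null(angle))
    stop("LONE m = ", m, " requires an angle")
  if (!needs_angle && !is.null(angle))
    stop("LONE m = ", m, " takes no angle")
  if (r <= 0) stop("LONE r must be positive")
  if (B1 <= 0 || B2 <= 0) stop("LONE spreads B1, B2 must be positive")
  structure(list(kind = "LONE", m = m, atom = atom, A = A,
                 B1 = B1, B2 = B2, r = r,
                 angle = if (needs_angle) angle else NULL),
            class = c("lone_instruction", "bodd_instruction"))
}

#' @export
format.bodd_instruction <- function(x, ...) {
  if (x$kind == "BEDE") {
    sprintf("BEDE %s %s %.6g %.6g %.6g %.6g",
            x$atom1, x$atom2, x$r, x$A, x$B1, x$B2)
  } else {
    base <- sprintf("LONE %d %s %.6g %.6g %.6g %.6g",
                    x$m, x$atom, x$A, x$B1, x$B2, x$r)
    if (!is.null(x$angle)) paste(base, sprintf("%.6g", x$angle)) else base
  }
}

#' @export
print.bodd_instruction <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Refinement configuration
#'
#' @param osf Overall scale factor (> 0); the model intensity is
#'   osf^2 |F|^2.
#' @param k_A,k_B1,k_B2 Global asphericity scale factors multiplying all
#'   A, B1 and B2 card values (the only refinable asphericity quantities;
#'   individual card parameters stay fixed).
#' @param weight_a,weight_b SHELX weighting-scheme coefficients:
#'   w = 1 / (sigma^2(Fo^2) + (aP)^2 + bP).
#' @param elongation Riding X-H bond elongation factor; 1.14 is the
#'   recommended deformation-density default, 1.0 the plain IAM value.
#' @param max_cycles,convergence_tol Least-squares iteration controls
#'   (convergence when max shift/esd < convergence_tol).
#' @param b_coupling "multiplicative" (default) couples lobe spreads as
#'   exponent B * 8 pi^2 U_eq; "additive" uses (B + 8 pi^2 U_eq).
#' @return A `refinement_config` object.
#' @export
refinement_config <- function(osf = 1, k_A = 1, k_B1 = 1, k_B2 = 1,
                              weight_a = 0, weight_b = 0,
                              elongation = 1.14, max_cycles = 50,
                              convergence_tol = 0.01,
                              b_coupling = c("multiplicative", "additive")) {
  if (osf <= 0) stop("osf must be positive")
  if (any(c(k_A, k_B1, k_B2) < 0)) stop("k_A, k_B1, k_B2 must be >= 0")
  structure(list(osf = osf, k_A = k_A, k_B1 = k_B1, k_B2 = k_B2,
                 weight_a = weight_a, weight_b = weight_b,
                 elongation = elongation, max_cycles = max_cycles,
                 convergence_tol = convergence_tol,
                 b_coupling = match.arg(b_coupling)),
            class = "refinement_config")
}
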