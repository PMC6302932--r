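#' IAM atomic form factor
#'
#' Four-Gaussian analytic form factor
#' f(s) = sum_i a_i exp(-b_i s^2) + c with s = sin(theta)/lambda.
#' At s = 0 it equals the electron count Z (to tabulation accuracy).
#'
#' @param coeffs A `gaussian_coefficients` object (see
#'   [sfac_coefficients()]).
#' @param s sin(theta)/lambda values (1/Angstrom), >= 0.
#' @return Form-factor values (electrons).
#' @export
iam_form_factor <- function(coeffs, s) {
  if (any(s < 0)) stop("s = sin(theta)/lambda must be non-negative")
  s2 <- s * s
  out <- rep(coeffs$c, length(s))
  for (i in 1:4) out <- out + coeffs$a[i] * exp(-coeffs$b[i] * s2)
  out
}

#' Placed deformation Gaussian
#'
#' One expanded lobe of a BEDE or LONE card: a Gaussian of signed
#' amplitude riding a host atom, whose spread multiplier B couples to the
#' host's displacement parameter.
#'
#' @param center Fractional coordinates (length 3).
#' @param amplitude Signed electrons (occupancy-weighted for
#'   half-occupied lobes).
#' @param spread Dimensionless B multiplier, > 0.
#' @param host_atom Label of the atom supplying the displacement coupling.
#' @param sign Which global spread scale applies: +1 selects k_B1
#'   (added density), -1 selects k_B2 (subtracted density).
#' @param origin Text tag naming the producing instruction.
#' @return A `placed_gaussian` object.
#' @export
placed_gaussian <- function(center, amplitude, spread, host_atom,
                            sign = if (amplitude >= 0) 1 else -1,
                            origin = "") {
  if (spread <= 0) stop("spread must be positive")
  if (!is.finite(amplitude)) stop("amplitude must be finite")
  structure(list(center = as.numeric(center), amplitude = amplitude,
                 spread = spread, host_atom = host_atom,
                 sign = sign, origin = origin),
            class = "placed_gaussian")
}

#' Reciprocal-space value of a deformation lobe
#'
#' The lobe scatters as amplitude * exp(-beta s^2) where, in the default
#' multiplicative coupling, beta = spread * 8 pi^2 U_eq(host): the card's
#' B value scales the host atom's isotropic Debye-Waller exponent. The
#' additive alternative beta = spread + 8 pi^2 U_eq is selectable via
#' `coupling`.
#'
#' @param g A [placed_gaussian()].
#' @param s sin(theta)/lambda values.
#' @param host_U_eq Host atom U_eq in A^2, > 0.
#' @param coupling "multiplicative" (default) or "additive".
#' @return Form-factor contribution (electrons).
#' @export
deformation_form_factor <- function(g, s, host_U_eq,
                                    coupling = c("multiplicative", "additive")) {
  coupling <- match.arg(coupling)
  if (!is.finite(host_U_eq) || host_U_eq <= 0)
    stop("non-positive U_eq for host atom '", g$host_atom, "'")
  beta <- lobe_exponent(g$spread, host_U_eq, coupling)
  g$amplitude * exp(-beta * s * s)
}

lobe_exponent <- function(spread, u_eq, coupling) {
  if (coupling == "additive") spread + 8 * pi^2 * u_eq
  else spread * 8 * pi^2 * u_eq
}

#' Debye-Waller factor
#'
#' Isotropic: exp(-8 pi^2 U_iso s^2). Anisotropic:
#' exp(-2 pi^2 sum_ij U_ij h_i h_j a*_i a*_j).
#'
#' @param adp Either a single positive U_iso (A^2) or six components
#'   U11 U22 U33 U23 U13 U12 (A^2).
#' @param hkl Miller-index matrix (one row per reflection).
#' @param cell Six lattice parameters.
#' @return Attenuation factors in (0, 1] for physical ADPs.
#' @export
debye_waller <- function(adp, hkl, cell) {
  hkl <- as_hkl_matrix(hkl)
  m <- cell_metrics(cell)
  s <- 0.5 * sqrt(rowSums((hkl %*% m$Gstar) * hkl))
  if (length(adp) == 1) {
    if (adp < 0) stop("U_iso must be non-negative")
    return(exp(-8 * pi^2 * adp * s^2))
  }
  stopifnot(length(adp) == 6)
  U <- matrix(c(adp[1], adp[6], adp[5],
                adp[6], adp[2], adp[4],
                adp[5], adp[4], adp[3]), 3, 3)
  ev <- eigen(U, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-12)) stop("U_ij matrix is not positive-definite")
  Ustar <- U * outer(m$astar, m$astar)
  exp(-2 * pi^2 * rowSums((hkl %*% Ustar) * hkl))
}

# per-atom Debye-Waller over an hkl matrix (vectorized over reflections)
atom_dw <- function(atom_row, hkl, metrics) {
  if (atom_row$aniso) {
    U <- u_matrix(atom_row)
    Ustar <- U * outer(metrics$astar, metrics$astar)
    exp(-2 * pi^2 * rowSums((hkl %*% Ustar) * hkl))
  } else {
    s2 <- 0.25 * rowSums((hkl %*% metrics$Gstar) * hkl)
    exp(-8 * pi^2 * atom_row$uiso * s2)
  }
}

#' Complex structure factors of an IAM + deformation model
#'
#' F(h) = osf * sum_sym [ sum_atoms occ f_IAM(s) T(h) e^{2 pi i h.x}
#'        + sum_lobes k_A amp exp(-k_B beta(s)) e^{2 pi i h.x_lobe} ]
#' where T is the (an)isotropic Debye-Waller factor, beta the lobe's
#' displacement-coupled exponent, and k_B is the global B1 scale for
#' positive-amplitude lobes and the B2 scale for negative ones. With an
#' empty lobe list (or k_A = 0) the result is the pure IAM value,
#' bit-for-bit.
#'
#' @param structure A [crystal_structure()].
#' @param placed List of [placed_gaussian()] lobes (usually from
#'   [expand_instructions()]).
#' @param config A [refinement_config()]; supplies osf and the three
#'   global asphericity scales.
#' @param hkl Miller-index matrix.
#' @return Complex vector, one F per hkl row.
#' @export
structure_factor <- function(structure, placed = list(),
                             config = refinement_config(), hkl) {
  hkl <- as_hkl_matrix(hkl)
  m <- cell_metrics(structure$cell)
  if (abs(det(m$G)) < 1e-12) stop("singular cell metric")
  Ftot <- iam_sf_part(structure, hkl, m)
  if (length(placed) > 0 && config$k_A != 0)
    Ftot <- Ftot + deformation_sf_part(structure, placed, config, hkl, m)
  config$osf * Ftot
}

# unscaled IAM sum over atoms and symmetry operations
iam_sf_part <- function(structure, hkl, m = cell_metrics(structure$cell)) {
  a <- structure$atoms
  s <- 0.5 * sqrt(rowSums((hkl %*% m$Gstar) * hkl))
  nref <- nrow(hkl)
  Ftot <- complex(real = numeric(nref), imaginary = numeric(nref))
  fels <- lapply(unique(toupper(a$element)), function(el)
    iam_form_factor(structure$sfac[[el]], s))
  names(fels) <- unique(toupper(a$element))
  for (op in structure$symmetry_ops) {
    # symmetry copy j: T_j(h) = exp(-2 pi^2 (hR) U* (hR)^T), phase h.(Rx+t)
    hR <- hkl %*% op[, 1:3]
    phase_t <- exp(2i * pi * as.vector(hkl %*% op[, 4]))
    for (i in seq_len(nrow(a))) {
      dw <- atom_dw(a[i, ], hR, m)
      ph <- exp(2i * pi * as.vector(hR %*% c(a$x[i], a$y[i], a$z[i])))
      Ftot <- Ftot + a$occ[i] * fels[[toupper(a$element[i])]] * dw * ph * phase_t
    }
  }
  Ftot
}

# unscaled deformation-lobe sum (k_A and the spread scales applied)
deformation_sf_part <- function(structure, placed, config, hkl,
                                m = cell_metrics(structure$cell)) {
  s2 <- 0.25 * rowSums((hkl %*% m$Gstar) * hkl)
  nref <- nrow(hkl)
  Ftot <- complex(real = numeric(nref), imaginary = numeric(nref))
  hosts <- unique(vapply(placed, `[[`, character(1), "host_atom"))
  ueq_cache <- u_eq(structure, hosts)
  names(ueq_cache) <- hosts
  for (op in structure$symmetry_ops) {
    hR <- hkl %*% op[, 1:3]
    phase_t <- exp(2i * pi * as.vector(hkl %*% op[, 4]))
    for (g in placed) {
      ueq <- ueq_cache[[g$host_atom]]
      if (!is.finite(ueq) || ueq <= 0)
        stop("lobe hosted on atom '", g$host_atom, "' lacks a positive ADP")
      kB <- if (g$sign >= 0) config$k_B1 else config$k_B2
      beta <- lobe_exponent(kB * g$spread, ueq, config$b_coupling)
      ph <- exp(2i * pi * as.vector(hR %*% g$center))
      Ftot <- Ftot + config$k_A * g$amplitude * exp(-beta * s2) * ph * phase_t
    }
  }
  Ftot
}
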