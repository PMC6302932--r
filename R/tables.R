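#' Tabulated four-Gaussian scattering-factor coefficients
#'
#' Cromer-Mann coefficients (International Tables for Crystallography,
#' Vol. C, Table 6.1.1.4) for the elements the toolkit's fixtures and
#' typical light-atom structures need: f(s) = sum(a_i exp(-b_i s^2)) + c
#' with s = sin(theta)/lambda in 1/Angstrom.
#'
#' @param element Element symbol, e.g. "C".
#' @return A `gaussian_coefficients` object: list with `a` (4 amplitudes),
#'   `b` (4 exponents, A^2), `c` (constant) and `z` (electron count).
#' @export
sfac_coefficients <- function(element) {
  tab <- .sfac_table()
  key <- toupper(element)
  if (!key %in% names(tab))
    stop("no tabulated scattering coefficients for element '", element, "'")
  tab[[key]]
}

.sfac_table <- function() {
  g <- function(a, b, c, z) {
    structure(list(a = a, b = b, c = c, z = z),
              class = "gaussian_coefficients")
  }
  list(
    H  = g(c(0.489918, 0.262003, 0.196767, 0.049879),
           c(20.6593, 7.74039, 49.5519, 2.20159), 0.001305, 1),
    C  = g(c(2.31000, 1.02000, 1.58860, 0.865000),
           c(20.8439, 10.2075, 0.568700, 51.6512), 0.215600, 6),
    N  = g(c(12.2126, 3.13220, 2.01250, 1.16630),
           c(0.005700, 9.89330, 28.9975, 0.582600), -11.529, 7),
    O  = g(c(3.04850, 2.28680, 1.54630, 0.867000),
           c(13.2771, 5.70110, 0.323900, 32.9089), 0.250800, 8),
    F  = g(c(3.53920, 2.64120, 1.51700, 1.02430),
           c(10.2825, 4.29440, 0.261500, 26.1476), 0.277600, 9),
    P  = g(c(6.43450, 4.17910, 1.78000, 1.49080),
           c(1.90670, 27.1570, 0.526000, 68.1645), 1.11490, 15),
    S  = g(c(6.90530, 5.20340, 1.43790, 1.58630),
           c(1.46790, 22.2151, 0.253600, 56.1720), 0.866900, 16),
    CL = g(c(11.4604, 7.19640, 6.25560, 1.64550),
           c(0.010400, 1.16620, 18.5194, 47.7784), -9.5574, 17),
    FE = g(c(11.7695, 7.35730, 3.52220, 2.30450),
           c(4.76110, 0.307200, 15.3535, 76.8805), 1.03690, 26)
  )
}

#' Covalent radii used by the bonding criterion
#'
#' Single-bond covalent radii (Cordero et al. 2008 values, Angstrom) for
#' the supported elements.
#'
#' @param element Element symbol or vector of symbols.
#' @return Numeric radii in Angstrom.
#' @export
covalent_radius <- function(element) {
  r <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
         P = 1.07, S = 1.05, CL = 1.02, FE = 1.32)
  key <- toupper(element)
  out <- unname(r[key])
  if (anyNA(out))
    stop("no covalent radius for element(s): ",
         paste(unique(element[is.na(out)]), collapse = ", "))
  out
}

.element_z <- function(element) {
  vapply(element, function(e) sfac_coefficients(e)$z, numeric(1))
}
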