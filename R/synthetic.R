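#' Built-in synthetic fixtures
#'
#' Small P1 toy structures with chemically sensible geometry, plausible
#' isotropic ADPs and a truth instruction set exercising BEDE plus at
#' least one LONE geometry code. They stand in for experimental data in
#' every test and example; all randomness (a small coordinate/ADP jitter
#' emulating refinement scatter) is controlled by `seed`, so the same
#' (name, seed) pair regenerates the fixture bit-identically.
#'
#' Catalog: `ethane_p1` (8 atoms, 7 bonds, BEDE only), `carbonyl_p1`
#' (formaldehyde, in-plane LONE m = 9 on O), `water_p1` (LONE m = 2),
#' `methylamine_p1` (LONE m = 1 on N), `mixed_metal_p1` (Fe kept
#' IAM-only next to aspherical O ligands, LONE m = 3).
#'
#' @param name Fixture name (see catalog above).
#' @param seed Integer seed for the jitter.
#' @return A `fixture`: list(name, structure, instructions, config,
#'   noise).
#' @export
make_fixture <- function(name, seed = 1) {
  builders <- list(
    ethane_p1 = fixture_ethane,
    carbonyl_p1 = fixture_carbonyl,
    water_p1 = fixture_water,
    methylamine_p1 = fixture_methylamine,
    mixed_metal_p1 = fixture_mixed_metal)
  if (!name %in% names(builders))
    stop("unknown fixture '", name, "'; catalog: ",
         paste(names(builders), collapse = ", "))
  fx <- builders[[name]]()
  set.seed(seed)
  a <- fx$atoms
  m <- cell_metrics(fx$cell)
  jit <- matrix(stats::rnorm(3 * nrow(a), 0, 0.004), ncol = 3) %*% t(m$frac)
  a$x <- a$x + jit[, 1]; a$y <- a$y + jit[, 2]; a$z <- a$z + jit[, 3]
  a$uiso <- a$uiso * (1 + stats::runif(nrow(a), -0.05, 0.05))
  st <- crystal_structure(fx$cell, a)
  structure(list(name = name, structure = st,
                 instructions = fx$instructions,
                 config = fx$config, noise = 0.02),
            class = "fixture")
}

.polar_dir <- function(theta_deg, phi_deg, axis = c(0, 0, 1)) {
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  # direction at polar angle theta from `axis`, azimuth phi about it
  a <- unit_vec(axis)
  p1 <- if (abs(a[1]) < 0.9) unit_vec(c(1, 0, 0) - a[1] * a) else
    unit_vec(c(0, 1, 0) - a[2] * a)
  p2 <- cross3(a, p1)
  cos(th) * a + sin(th) * (cos(ph) * p1 + sin(ph) * p2)
}

.atoms_from_cart <- function(cart, labels, elements, uiso, cell) {
  m <- cell_metrics(cell)
  fr <- cart %*% t(m$frac)
  data.frame(label = labels, element = elements,
             x = fr[, 1], y = fr[, 2], z = fr[, 3],
             occ = 1, uiso = uiso, aniso = FALSE,
             stringsAsFactors = FALSE)
}

fixture_ethane <- function() {
  cell <- c(7.0, 7.5, 8.0, 90, 90, 90)
  ctr <- c(3.5, 3.75, 4.0)
  cc <- 1.54; ch <- 1.09
  c1 <- ctr + c(0, 0, -cc / 2); c2 <- ctr + c(0, 0, cc / 2)
  # H-C1-C2 = H-C2-C1 = 109.5 deg, staggered conformation
  hs <- rbind(
    t(vapply(c(0, 120, 240), function(p) c1 + ch * .polar_dir(109.5, p), numeric(3))),
    t(vapply(c(60, 180, 300), function(p) c2 + ch * .polar_dir(180 - 109.5, p), numeric(3))))
  cart <- rbind(c1, c2, hs)
  atoms <- .atoms_from_cart(cart,
                            c("C1", "C2", paste0("H", 1:6)),
                            c("C", "C", rep("H", 6)),
                            c(0.022, 0.022, rep(0.04, 6)), cell)
  instr <- c(list(bede("C1", "C2", 0.52, 0.18, 1.0, 1.4),
                  bede("C2", "C1", 0.52, 0.18, 1.0, 1.4)),
             lapply(1:3, function(i) bede("C1", paste0("H", i), 0.37, 0.12, 1.1, 1.5)),
             lapply(4:6, function(i) bede("C2", paste0("H", i), 0.37, 0.12, 1.1, 1.5)))
  list(cell = cell, atoms = atoms, instructions = instr,
       config = refinement_config(osf = 1.2))
}

fixture_carbonyl <- function() {
  cell <- c(6.0, 6.5, 7.0, 90, 90, 90)
  c1 <- c(2.6, 3.25, 3.5)
  o1 <- c1 + c(1.21, 0, 0)
  h1 <- c1 + 1.09 * c(cos(122 * pi / 180), sin(122 * pi / 180), 0)
  h2 <- c1 + 1.09 * c(cos(122 * pi / 180), -sin(122 * pi / 180), 0)
  atoms <- .atoms_from_cart(rbind(c1, o1, h1, h2),
                            c("C1", "O1", "H1", "H2"),
                            c("C", "O", "H", "H"),
                            c(0.020, 0.025, 0.04, 0.04), cell)
  instr <- list(bede("C1", "O1", 0.45, 0.22, 0.9, 1.3),
                bede("O1", "C1", 0.40, 0.16, 0.9, 1.3),
                bede("C1", "H1", 0.37, 0.12, 1.1, 1.5),
                bede("C1", "H2", 0.37, 0.12, 1.1, 1.5),
                lone(9, "O1", 0.14, 1.0, 1.3, 0.35, 120))
  list(cell = cell, atoms = atoms, instructions = instr,
       config = refinement_config(osf = 1.1))
}

fixture_water <- function() {
  cell <- c(6.0, 6.0, 6.5, 90, 90, 90)
  o1 <- c(3.0, 3.0, 3.25)
  ang <- 104.5 * pi / 180
  h1 <- o1 + 0.958 * c(sin(ang / 2), cos(ang / 2), 0)
  h2 <- o1 + 0.958 * c(-sin(ang / 2), cos(ang / 2), 0)
  atoms <- .atoms_from_cart(rbind(o1, h1, h2), c("O1", "H1", "H2"),
                            c("O", "H", "H"), c(0.025, 0.045, 0.045), cell)
  instr <- list(bede("O1", "H1", 0.33, 0.12, 1.0, 1.4),
                bede("O1", "H2", 0.33, 0.12, 1.0, 1.4),
                lone(2, "O1", 0.15, 1.0, 1.3, 0.35, 109.5))
  list(cell = cell, atoms = atoms, instructions = instr,
       config = refinement_config(osf = 1.0))
}

fixture_methylamine <- function() {
  cell <- c(7.5, 7.0, 8.0, 90, 90, 90)
  c1 <- c(3.0, 3.5, 4.0)
  n1 <- c1 + c(1.47, 0, 0)
  ch <- 1.09; nh <- 1.01
  # H-C-N = 109.5 (polar from C->N = +x); H-N-C = 110 (polar from N->C = -x)
  hc <- t(vapply(c(0, 120, 240), function(p)
    c1 + ch * .polar_dir(109.5, p, axis = c(1, 0, 0)), numeric(3)))
  hn <- t(vapply(c(60, 300), function(p)
    n1 + nh * .polar_dir(180 - 110, p, axis = c(1, 0, 0)), numeric(3)))
  atoms <- .atoms_from_cart(rbind(c1, n1, hc, hn),
                            c("C1", "N1", "H1", "H2", "H3", "H4", "H5"),
                            c("C", "N", rep("H", 5)),
                            c(0.022, 0.024, rep(0.042, 5)), cell)
  instr <- c(list(bede("C1", "N1", 0.50, 0.20, 1.0, 1.3),
                  bede("N1", "C1", 0.45, 0.16, 1.0, 1.3)),
             lapply(1:3, function(i) bede("C1", paste0("H", i), 0.37, 0.12, 1.1, 1.5)),
             lapply(4:5, function(i) bede("N1", paste0("H", i), 0.34, 0.13, 1.1, 1.5)),
             list(lone(1, "N1", 0.18, 1.0, 1.3, 0.38)))
  list(cell = cell, atoms = atoms, instructions = instr,
       config = refinement_config(osf = 1.15))
}

fixture_mixed_metal <- function() {
  cell <- c(8.0, 7.5, 7.0, 90, 90, 90)
  fe <- c(4.0, 3.75, 3.5)
  o1 <- fe + c(2.0, 0, 0)
  o2 <- fe + c(-2.0, 0, 0)
  atoms <- .atoms_from_cart(rbind(fe, o1, o2), c("FE1", "O1", "O2"),
                            c("FE", "O", "O"), c(0.015, 0.03, 0.03), cell)
  instr <- list(bede("O1", "FE1", 0.55, 0.12, 1.0, 1.3),
                bede("O2", "FE1", 0.55, 0.12, 1.0, 1.3),
                lone(3, "O1", 0.12, 1.0, 1.3, 0.36, 109.5))
  list(cell = cell, atoms = atoms, instructions = instr,
       config = refinement_config(osf = 1.0))
}

#' Enumerate unique reflections to a resolution limit
#'
#' One hemisphere of the full sphere s <= 1/(2 d_min), excluding (0 0 0)
#' (Friedel mates carry no extra information without anomalous
#' scattering).
#'
#' @param cell Six lattice parameters.
#' @param d_min Resolution limit in Angstrom.
#' @return Integer hkl matrix.
#' @export
hkl_to_resolution <- function(cell, d_min) {
  smax <- 1 / (2 * d_min)
  hmax <- ceiling(2 * smax * cell[1:3])
  g <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                             l = -hmax[3]:hmax[3]))
  s <- s_of_hkl(g, cell)
  keep <- s > 0 & s <= smax
  g <- g[keep, , drop = FALSE]
  hemi <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g[hemi, , drop = FALSE]
}

#' Simulate reflection data from a fixture's truth model
#'
#' All unique hkl to `d_min` are generated; Fo^2 is the truth intensity
#' (osf included) with multiplicative Gaussian noise of the stated
#' fraction, and sigma is set consistently with that noise model (with a
#' small floor so sigma stays positive for noise-free data).
#'
#' @param fixture A [make_fixture()] result.
#' @param d_min Resolution limit in Angstrom (> 0.3; finer is refused as
#'   a size guard).
#' @param noise_fraction Relative Gaussian noise on Fo^2.
#' @param seed RNG seed.
#' @return A `reflection_set` data frame.
#' @export
simulate_reflections <- function(fixture, d_min = 0.8, noise_fraction = 0.02,
                                 seed = 1) {
  if (d_min <= 0) stop("d_min must be positive")
  if (d_min < 0.3) stop("d_min finer than 0.3 A refused (size guard)")
  st <- fixture$structure
  hkl <- hkl_to_resolution(st$cell, d_min)
  placed <- expand_instructions(fixture$instructions, st)
  f <- structure_factor(st, placed, fixture$config, hkl)
  fo2_true <- Mod(f)^2
  set.seed(seed)
  eps <- if (noise_fraction > 0)
    stats::rnorm(length(fo2_true), 0, noise_fraction) else 0
  fo2 <- fo2_true * (1 + eps)
  floor_ <- 1e-4 * max(fo2_true)
  sigma <- pmax(noise_fraction * fo2_true, floor_)
  df <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                   fo2 = fo2, sigma = sigma,
                   s = s_of_hkl(hkl, st$cell))
  class(df) <- c("reflection_set", "data.frame")
  df
}

#' Brute-force grid density and numerical structure factors
#'
#' Independent oracle for the analytic structure-factor path: the model
#' electron density (IAM Gaussians convolved with their isotropic
#' Debye-Waller smearing, each term evaluated analytically in real space,
#' plus all deformation lobes) is sampled on a fractional grid and
#' Fourier-transformed numerically by FFT. Restricted to P1 structures
#' with orthogonal cells and isotropic ADPs - the fixture world - so the
#' separable Gaussian accumulation stays exact and fast.
#'
#' @param structure P1 [crystal_structure()] (orthogonal cell, isotropic
#'   ADPs).
#' @param instructions BEDE/LONE cards (may be empty).
#' @param spacing Grid spacing in Angstrom (<= 0.15).
#' @param config A [refinement_config()]; osf multiplies the numerical F
#'   like the analytic path.
#' @return List: `grid` (a [density_grid()]), `sf` (complex FFT array),
#'   `dims`, `osf`. Use [oracle_structure_factors()] to pull out F(hkl).
#' @export
grid_density_oracle <- function(structure, instructions = list(),
                                spacing = 0.1,
                                config = refinement_config()) {
  if (length(structure$symmetry_ops) != 1)
    stop("grid oracle is restricted to P1 structures")
  if (any(abs(structure$cell[4:6] - 90) > 1e-9))
    stop("grid oracle is restricted to orthogonal cells")
  if (spacing > 0.15) stop("oracle grid spacing must be <= 0.15 A")
  a <- structure$atoms
  if (any(a$aniso)) stop("grid oracle is restricted to isotropic ADPs")
  dims <- grid_dims(structure$cell, spacing)
  gaussians <- list()
  for (i in seq_len(nrow(a))) {
    cf <- structure$sfac[[toupper(a$element[i])]]
    dwb <- 8 * pi^2 * a$uiso[i]
    ctr <- c(a$x[i], a$y[i], a$z[i])
    for (t in 1:4)
      gaussians <- c(gaussians, list(list(center = ctr,
                                          amp = a$occ[i] * cf$a[t],
                                          beta = cf$b[t] + dwb)))
    if (cf$c != 0)
      gaussians <- c(gaussians, list(list(center = ctr,
                                          amp = a$occ[i] * cf$c,
                                          beta = dwb)))
  }
  placed <- expand_instructions(instructions, structure)
  if (length(placed) > 0 && config$k_A != 0) {
    hosts <- unique(vapply(placed, `[[`, character(1), "host_atom"))
    ueq <- u_eq(structure, hosts); names(ueq) <- hosts
    for (g in placed) {
      kB <- if (g$sign >= 0) config$k_B1 else config$k_B2
      beta <- lobe_exponent(kB * g$spread, ueq[[g$host_atom]],
                            config$b_coupling)
      gaussians <- c(gaussians, list(list(center = g$center,
                                          amp = config$k_A * g$amplitude,
                                          beta = beta)))
    }
  }
  rho <- accumulate_gaussians(array(0, dims), gaussians, structure$cell)
  grid <- density_grid(rho, structure$cell, spacing)
  V <- cell_metrics(structure$cell)$volume
  sf <- stats::fft(rho, inverse = TRUE) * V / prod(dims)
  list(grid = grid, sf = sf, dims = dims, osf = config$osf)
}

#' Extract numerical structure factors from the grid oracle
#'
#' @param oracle A [grid_density_oracle()] result.
#' @param hkl Miller-index matrix.
#' @return Complex F values (osf applied).
#' @export
oracle_structure_factors <- function(oracle, hkl) {
  hkl <- as_hkl_matrix(hkl)
  dims <- oracle$dims
  if (any(abs(hkl) >= matrix(dims / 2, nrow(hkl), 3, byrow = TRUE)))
    stop("hkl beyond the oracle grid's Nyquist limit")
  idx <- ((hkl %% matrix(dims, nrow(hkl), 3, byrow = TRUE)) +
            matrix(dims, nrow(hkl), 3, byrow = TRUE)) %%
    matrix(dims, nrow(hkl), 3, byrow = TRUE) + 1
  oracle$osf * vapply(seq_len(nrow(hkl)), function(i)
    oracle$sf[idx[i, 1], idx[i, 2], idx[i, 3]], complex(1))
}

#' Archetype database derived from the fixture world
#'
#' Builds one archetype record per instruction-bearing atom of the named
#' fixtures: the atom's two-shell environment graph keyed by its inner
#' hash, and instruction templates carrying the fixture's reference
#' parameter values (BEDE templates generalized per neighbor element).
#' Records with duplicate inner hashes keep the first occurrence.
#'
#' @param names Fixture names to harvest (default: the full catalog).
#' @param seed Fixture seed; must match the structures the database will
#'   be matched against exactly, since hashes quantize real geometry.
#' @param quantization Color quantization passed to [archetype_record()].
#' @return List of [archetype_record()]s.
#' @export
fixture_archetype_database <- function(names = c("ethane_p1", "carbonyl_p1",
                                                 "water_p1", "methylamine_p1",
                                                 "mixed_metal_p1"),
                                       seed = 1, quantization = 0.01) {
  records <- list()
  seen <- character(0)
  for (nm in names) {
    fx <- make_fixture(nm, seed)
    st <- fx$structure
    conn <- build_connectivity(st)
    hosts <- unique(vapply(fx$instructions, function(cd)
      if (cd$kind == "BEDE") cd$atom1 else cd$atom, character(1)))
    for (host in hosts) {
      tmpl <- character(0)
      for (cd in fx$instructions) {
        if (cd$kind == "BEDE" && cd$atom1 == host) {
          el2 <- toupper(st$atoms$element[atom_index(st, cd$atom2)])
          t <- sprintf("BEDE * @%s %.6g %.6g %.6g %.6g",
                       el2, cd$r, cd$A, cd$B1, cd$B2)
          if (!t %in% tmpl) tmpl <- c(tmpl, t)
        } else if (cd$kind == "LONE" && cd$atom == host) {
          t <- sprintf("LONE %d * %.6g %.6g %.6g %.6g", cd$m, cd$A,
                       cd$B1, cd$B2, cd$r)
          if (!is.null(cd$angle)) t <- paste(t, sprintf("%.6g", cd$angle))
          tmpl <- c(tmpl, t)
        }
      }
      g <- build_environment_graph(host, conn, st)
      el <- toupper(st$atoms$element[atom_index(st, host)])
      rec <- archetype_record(sprintf("%s.%s.%s", tolower(el), nm, host),
                              g, tmpl, el, quantization)
      if (!rec$inner_hash %in% seen) {
        records <- c(records, list(rec))
        seen <- c(seen, rec$inner_hash)
      }
    }
  }
  records
}
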