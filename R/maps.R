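#' Real-space density grid
#'
#' 3-D scalar field over the unit cell (e/A^3) with cell metadata.
#'
#' @param values Numeric 3-D array (fractional axes a, b, c).
#' @param cell Six lattice parameters.
#' @param spacing Approximate voxel spacing in Angstrom.
#' @return A `density_grid` with `rho_min`/`rho_max` recomputed from the
#'   values.
#' @export
density_grid <- function(values, cell, spacing) {
  structure(list(values = values, cell = as.numeric(cell),
                 spacing = spacing, dim = dim(values),
                 rho_min = min(values), rho_max = max(values)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid %d x %d x %d, rho in [%.4f, %.4f] e/A^3\n",
              x$dim[1], x$dim[2], x$dim[3], x$rho_min, x$rho_max))
  invisible(x)
}

grid_dims <- function(cell, spacing) {
  pmax(4L, as.integer(ceiling(cell[1:3] / spacing)))
}

# fractional coordinates of all voxels, as a list of axis vectors
grid_axes <- function(dims) lapply(dims, function(n) (seq_len(n) - 1) / n)

#' Difference Fourier map
#'
#' FFT synthesis with coefficients (|Fo| - |Fc|) exp(i phi_c): the
#' residual density left after subtracting the model. Observed
#' amplitudes are brought to the absolute scale by the overall scale
#' factor. Friedel mates are filled automatically.
#'
#' @param structure Model [crystal_structure()].
#' @param instructions BEDE/LONE cards of the model.
#' @param reflections Reflection set (fo2, sigma).
#' @param config [refinement_config()] (osf, k scales).
#' @param grid_spacing Voxel spacing in Angstrom, default 0.1; must not
#'   exceed half the data resolution (aliasing guard).
#' @return A [density_grid()] in e/A^3.
#' @export
difference_map <- function(structure, instructions, reflections,
                           config = refinement_config(), grid_spacing = 0.1) {
  refl <- attach_resolution(reflections, structure$cell)
  d_min <- 1 / (2 * max(refl$s))
  if (grid_spacing > d_min / 2)
    stop("grid spacing ", grid_spacing, " A exceeds resolution/2 = ",
         signif(d_min / 2, 3), " A: aliasing")
  hkl <- as.matrix(refl[, c("h", "k", "l")])
  placed <- expand_instructions(instructions, structure)
  fc <- structure_factor(structure, placed, config, hkl) / config$osf
  fo <- sqrt(pmax(refl$fo2, 0)) / config$osf
  coef <- (fo - Mod(fc)) * exp(1i * Arg(fc))
  fourier_synthesis(coef, hkl, structure$cell, grid_spacing)
}

# rho(x) = (1/V) sum_h F_h exp(-2 pi i h.x), Friedel mates added
fourier_synthesis <- function(coef, hkl, cell, grid_spacing) {
  dims <- grid_dims(cell, grid_spacing)
  if (any(2 * apply(abs(hkl), 2, max) + 1 > dims))
    dims <- pmax(dims, as.integer(2 * apply(abs(hkl), 2, max) + 2))
  G <- array(complex(real = 0, imaginary = 0), dims)
  put <- function(h, v) {
    idx <- ((h %% dims) + dims) %% dims + 1
    G[idx[1], idx[2], idx[3]] <<- G[idx[1], idx[2], idx[3]] + v
  }
  for (i in seq_len(nrow(hkl))) {
    h <- hkl[i, ]
    put(h, coef[i])
    if (any(h != 0)) put(-h, Conj(coef[i]))
  }
  V <- cell_metrics(cell)$volume
  rho <- Re(stats::fft(G)) / V
  density_grid(rho, cell, grid_spacing)
}

#' Deformation density map
#'
#' Direct real-space sum of every placed deformation Gaussian (no Fourier
#' truncation): the density the BODD cards add to the IAM. Each lobe of
#' reciprocal form A exp(-beta s^2) contributes
#' A (4 pi / beta)^(3/2) exp(-4 pi^2 |r - r0|^2 / beta). Its cell
#' integral is A, so any complete card set integrates to zero.
#'
#' @param structure Model [crystal_structure()].
#' @param instructions BEDE/LONE cards.
#' @param grid_spacing Voxel spacing in Angstrom.
#' @param config [refinement_config()] supplying the k scales and spread
#'   coupling.
#' @return A [density_grid()] in e/A^3.
#' @export
deformation_map <- function(structure, instructions, grid_spacing = 0.1,
                            config = refinement_config()) {
  placed <- expand_instructions(instructions, structure)
  dims <- grid_dims(structure$cell, grid_spacing)
  rho <- array(0, dims)
  if (length(placed) == 0)
    return(density_grid(rho, structure$cell, grid_spacing))
  hosts <- unique(vapply(placed, `[[`, character(1), "host_atom"))
  ueq <- u_eq(structure, hosts); names(ueq) <- hosts
  gaussians <- lapply(placed, function(g) {
    kB <- if (g$sign >= 0) config$k_B1 else config$k_B2
    beta <- lobe_exponent(kB * g$spread, ueq[[g$host_atom]], config$b_coupling)
    list(center = g$center, amp = config$k_A * g$amplitude, beta = beta)
  })
  density_grid(accumulate_gaussians(rho, gaussians, structure$cell),
               structure$cell, grid_spacing)
}

# Adds real-space Gaussians (amp, beta in the A exp(-beta s^2) sense) to a
# fractional grid, summing periodic images. Separable fast path for
# orthogonal cells, generic vectorized fallback otherwise.
accumulate_gaussians <- function(rho, gaussians, cell) {
  dims <- dim(rho)
  m <- cell_metrics(cell)
  ortho_cell <- all(abs(cell[4:6] - 90) < 1e-9)
  axes <- grid_axes(dims)
  if (ortho_cell) {
    for (g in gaussians) {
      p <- 4 * pi^2 / g$beta
      pref <- g$amp * (4 * pi / g$beta)^1.5
      gs <- lapply(1:3, function(k) {
        dx <- (axes[[k]] - g$center[k])
        dx <- cell[k] * (dx - round(dx))  # principal image, Angstrom
        v <- exp(-p * dx^2)
        for (im in c(-2, -1, 1, 2)) v <- v + exp(-p * (dx + im * cell[k])^2)
        v
      })
      rho <- rho + pref * (gs[[1]] %o% gs[[2]] %o% gs[[3]])
    }
    return(rho)
  }
  fr <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  for (g in gaussians) {
    p <- 4 * pi^2 / g$beta
    pref <- g$amp * (4 * pi / g$beta)^1.5
    acc <- numeric(nrow(fr))
    d0 <- sweep(fr, 2, g$center)
    d0 <- d0 - round(d0)
    for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
      dc <- cbind(d0[, 1] + sx, d0[, 2] + sy, d0[, 3] + sz) %*% t(m$ortho)
      acc <- acc + exp(-p * rowSums(dc^2))
    }
    rho <- rho + array(pref * acc, dims)
  }
  rho
}

#' Write a density grid as a CCP4/MRC map file
#'
#' Minimal mode-2 (float32) writer covering the whole unit cell.
#'
#' @param grid A [density_grid()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ccp4_map <- function(grid, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- grid$dim
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                 # NC NR NS
  wi(2)                 # MODE float32
  wi(c(0, 0, 0))        # start
  wi(d)                 # intervals
  wf(grid$cell)         # cell
  wi(c(1, 2, 3))        # axis order
  wf(c(grid$rho_min, grid$rho_max, mean(grid$values)))
  wi(1)                 # ISPG P1
  wi(0)                 # NSYMBT
  wi(rep(0, 25))        # extra
  wf(c(0, 0, 0))        # origin
  writeChar("MAP ", con, 4, eos = NULL)
  wi(16708)             # machine stamp (little endian)
  wf(stats::sd(grid$values))
  wi(0)                 # NLABL
  writeBin(raw(800), con)
  wf(as.vector(grid$values))
  invisible(path)
}

#' Write a density grid as a plain-text dump
#'
#' Header lines (dims, cell, spacing) then one value per line in Fortran
#' (first-axis-fastest) order.
#'
#' @param grid A [density_grid()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_grid_text <- function(grid, path) {
  hdr <- c(paste("# dims", paste(grid$dim, collapse = " ")),
           paste("# cell", paste(format(grid$cell, digits = 8), collapse = " ")),
           paste("# spacing", grid$spacing))
  writeLines(c(hdr, format(as.vector(grid$values), digits = 8)), path)
  invisible(path)
}
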