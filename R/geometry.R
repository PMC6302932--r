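#' Covalent-radius connectivity
#'
#' Two atoms are bonded when their nearest-image distance is below the sum
#' of their covalent radii plus a tolerance. Distances are evaluated over
#' all symmetry operations and the 27 neighboring cells so bonds across
#' the cell boundary are found.
#'
#' @param structure A [crystal_structure()].
#' @param tolerance Additive bond-length tolerance in Angstrom.
#' @param radii Optional named vector overriding [covalent_radius()].
#' @return A `connectivity` object: `bonds` data frame (a, b, length) and
#'   `neighbors`, a named list of neighbor labels per atom.
#' @export
build_connectivity <- function(structure, tolerance = 0.4, radii = NULL) {
  a <- structure$atoms
  m <- cell_metrics(structure$cell)
  n <- nrow(a)
  rad <- if (is.null(radii)) covalent_radius(a$element) else
    unname(radii[toupper(a$element)])
  xyz <- as.matrix(a[, c("x", "y", "z")])
  bonds <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    d <- min_image_distance(xyz[i, ], xyz[j, ], structure$symmetry_ops, m)
    if (d < rad[i] + rad[j] + tolerance && d > 0.1)
      bonds <- c(bonds, list(data.frame(a = a$label[i], b = a$label[j],
                                        length = d,
                                        stringsAsFactors = FALSE)))
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(a = character(0), b = character(0), length = numeric(0))
  nb <- stats::setNames(vector("list", n), a$label)
  for (k in seq_len(nrow(bonds))) {
    nb[[bonds$a[k]]] <- c(nb[[bonds$a[k]]], bonds$b[k])
    nb[[bonds$b[k]]] <- c(nb[[bonds$b[k]]], bonds$a[k])
  }
  nb <- lapply(nb, function(v) if (is.null(v)) character(0) else sort(v))
  structure(list(bonds = bonds, neighbors = nb), class = "connectivity")
}

min_image_distance <- function(f1, f2, ops, metrics) {
  best <- Inf
  for (op in ops) {
    f2o <- as.vector(op[, 1:3] %*% f2 + op[, 4])
    d0 <- f1 - f2o
    d0 <- d0 - round(d0)  # principal image
    for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
      dv <- d0 + c(sx, sy, sz)
      d <- sqrt(sum((metrics$ortho %*% dv)^2))
      if (d < best) best <- d
    }
  }
  best
}

bond_length <- function(connectivity, a, b) {
  bd <- connectivity$bonds
  hit <- (bd$a == a & bd$b == b) | (bd$a == b & bd$b == a)
  if (!any(hit)) stop("atoms ", a, " and ", b, " are not bonded")
  bd$length[which(hit)[1]]
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) stop("degenerate geometry: zero-length direction vector")
  v / n
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.lone_counts <- c(`1` = 1, `2` = 2, `3` = 3, `6` = 2, `7` = 2,
                  `9` = 2, `12` = 12, `15` = 1)
.lone_needed <- c(`1` = 3, `2` = 2, `3` = 1, `6` = 2, `7` = 1,
                  `9` = 1, `12` = 1, `15` = 4)

#' Lone-pair lobe directions for a geometry code
#'
#' Returns the unit vectors (Cartesian) along which the added lobes of a
#' LONE instruction point, following the hydrogen-placement analogy:
#' m = 1 one lobe opposite the sum of three bond vectors; m = 2 two lobes
#' in the plane spanned by the bond bisector and the bond-plane normal,
#' opened by `angle`; m = 3 three lobes staggered against the second
#' shell on a cone around the single bond; m = 6 two lobes perpendicular
#' to the plane of two bonds; m = 7 two lobes symmetric about the
#' anti-bond direction, out of the plane fixed by a second-shell bond,
#' opened by `angle` (angle 180 gives the pure plane normals); m = 9 as 7
#' but in-plane; m = 12 twelve lobes on a tetrahedral-complement cone with
#' successive azimuths 30 degrees apart (two 60-degree-staggered
#' half-sets); m = 15 one lobe completing a 4-5 coordinate polyhedron.
#'
#' @param m Geometry code.
#' @param root_xyz Cartesian position of the host atom.
#' @param neighbor_xyz Matrix of Cartesian neighbor positions (one row
#'   each).
#' @param angle Opening angle in degrees (m in 2, 3, 7, 9 only).
#' @param second_shell Cartesian position of a second-shell atom (bonded
#'   to the first neighbor), required for m = 3, 7, 9 and used to fix the
#'   cone azimuth for m = 12.
#' @param label Host atom label, used in error messages.
#' @return Matrix of unit row vectors.
#' @export
lone_directions <- function(m, root_xyz, neighbor_xyz, angle = NULL,
                            second_shell = NULL, label = "?") {
  key <- as.character(m)
  if (!key %in% names(.lone_counts))
    stop("unsupported LONE geometry code m = ", m)
  nb <- if (is.null(dim(neighbor_xyz))) matrix(neighbor_xyz, ncol = 3)
        else as.matrix(neighbor_xyz)
  nn <- nrow(nb)
  need <- .lone_needed[[key]]
  ok <- if (m == 15) nn %in% 4:5 else nn == need
  if (!ok)
    stop("atom ", label, ": LONE m = ", m, " needs ",
         if (m == 15) "4-5" else need, " neighbor(s), found ", nn)
  u <- t(apply(nb, 1, function(p) unit_vec(p - root_xyz)))
  rad <- function(deg) deg * pi / 180

  bare <- function(m_) { dimnames(m_) <- NULL; m_ }
  if (m == 1 || m == 15) {
    v <- -colSums(u)
    return(bare(matrix(unit_vec(v), 1)))
  }
  if (m == 2) {
    nrm <- cross3(u[1, ], u[2, ])
    if (sqrt(sum(nrm^2)) < 1e-8)
      stop("atom ", label, ": collinear neighbors, bond plane undefined")
    nrm <- unit_vec(nrm)
    d <- -unit_vec(u[1, ] + u[2, ])
    h <- rad(angle) / 2
    return(bare(rbind(cos(h) * d + sin(h) * nrm,
                      cos(h) * d - sin(h) * nrm)))
  }
  if (m == 6) {
    nrm <- cross3(u[1, ], u[2, ])
    if (sqrt(sum(nrm^2)) < 1e-8)
      stop("atom ", label, ": collinear bonds, plane normal undefined")
    nrm <- unit_vec(nrm)
    return(bare(rbind(nrm, -nrm)))
  }
  if (m %in% c(3, 12)) {
    axis <- -u[1, ]
    p1 <- cone_reference(axis, root_xyz, nb[1, ], second_shell, label)
    p2 <- cross3(axis, p1)
    if (m == 3) {
      alpha <- pi - rad(angle)       # polar angle from the anti-bond axis
      phis <- rad(c(60, 180, 300))   # staggered against the reference
    } else {
      alpha <- pi - acos(-1 / 3)     # tetrahedral complement, 70.53 deg
      phis <- rad(seq(0, 330, by = 30))
    }
    vs <- t(vapply(phis, function(p)
      cos(alpha) * axis + sin(alpha) * (cos(p) * p1 + sin(p) * p2),
      numeric(3)))
    return(bare(vs))
  }
  if (m %in% c(7, 9)) {
    if (is.null(second_shell))
      stop("atom ", label, ": LONE m = ", m, " needs a second-shell atom")
    axis <- -u[1, ]
    w <- unit_vec(second_shell - nb[1, ])
    nrm <- cross3(u[1, ], w)
    if (sqrt(sum(nrm^2)) < 1e-8)
      stop("atom ", label, ": second-shell bond collinear, plane undefined")
    nrm <- unit_vec(nrm)
    h <- rad(angle) / 2
    ref <- if (m == 7) nrm else unit_vec(cross3(nrm, axis))
    return(bare(rbind(cos(h) * axis + sin(h) * ref,
                      cos(h) * axis - sin(h) * ref)))
  }
  stop("unreachable")
}

cone_reference <- function(axis, root_xyz, nb_xyz, second_shell, label) {
  ref <- if (!is.null(second_shell)) second_shell - nb_xyz else NULL
  if (is.null(ref) || sqrt(sum(cross3(axis, ref)^2)) < 1e-8) {
    # deterministic perpendicular when no usable second shell exists
    ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  }
  unit_vec(ref - sum(ref * axis) * axis)
}

#' Expand a BEDE or LONE card into placed Gaussians
#'
#' BEDE yields two lobes: +A (spread B1) on the bond at distance r from
#' atom1 toward atom2, and -A (spread B2) at atom1. LONE yields its
#' geometry-code lobes of amplitude +A (occupancy 1/2 for m = 12) at
#' distance r along each [lone_directions()] vector plus one compensating
#' lobe at the atom of amplitude minus the occupancy-weighted sum, so the
#' net added electron count of every card is exactly zero.
#'
#' @param instr A [bede()] or [lone()] card.
#' @param structure A [crystal_structure()].
#' @param connectivity A [build_connectivity()] table (needed for LONE).
#' @return List of [placed_gaussian()] lobes.
#' @export
expand_instruction <- function(instr, structure, connectivity = NULL) {
  m <- cell_metrics(structure$cell)
  a <- structure$atoms
  cart <- function(lb) {
    i <- atom_index(structure, lb)
    as.vector(m$ortho %*% c(a$x[i], a$y[i], a$z[i]))
  }
  frac <- function(p) as.vector(m$frac %*% p)
  tag <- format(instr)

  if (instr$kind == "BEDE") {
    p1 <- cart(instr$atom1); p2 <- cart(instr$atom2)
    u <- unit_vec(p2 - p1)
    return(list(
      placed_gaussian(frac(p1 + instr$r * u), instr$A, instr$B1,
                      instr$atom1, sign = 1, origin = tag),
      placed_gaussian(frac(p1), -instr$A, instr$B2,
                      instr$atom1, sign = -1, origin = tag)))
  }
  if (is.null(connectivity))
    stop("LONE expansion requires a connectivity table")
  root <- instr$atom
  nbl <- connectivity$neighbors[[root]]
  if (is.null(nbl) || length(nbl) == 0)
    stop("atom ", root, " has no bonded neighbors; cannot place lone pairs")
  nbl <- order_neighbors(nbl, structure)
  rx <- cart(root)
  nxyz <- t(vapply(nbl, cart, numeric(3)))
  second <- NULL
  if (instr$m %in% c(3, 7, 9, 12)) {
    nb2 <- setdiff(connectivity$neighbors[[nbl[1]]], root)
    if (length(nb2) > 0) second <- cart(order_neighbors(nb2, structure)[1])
    else if (instr$m %in% c(7, 9))
      stop("atom ", root, ": LONE m = ", instr$m,
           " needs a bond on the neighboring atom to fix the plane")
  }
  dirs <- lone_directions(instr$m, rx, nxyz, instr$angle, second, root)
  occ <- if (instr$m == 12) 0.5 else 1
  lobes <- lapply(seq_len(nrow(dirs)), function(k)
    placed_gaussian(frac(rx + instr$r * dirs[k, ]), occ * instr$A,
                    instr$B1, root, sign = 1, origin = tag))
  # compensating amplitude written as minus the running sum of the added
  # lobes (-2A for m = 2, -6A for m = 12, ...) so the card's net electron
  # count is zero to the last bit
  comp <- placed_gaussian(frac(rx),
                          -sum(vapply(lobes, `[[`, numeric(1), "amplitude")),
                          instr$B2, root, sign = -1, origin = tag)
  c(lobes, list(comp))
}

order_neighbors <- function(labels, structure) {
  el <- toupper(structure$atoms$element[atom_index(structure, labels)])
  labels[order(el == "H", labels)]  # non-H first, then alphabetical
}

#' Expand a list of instructions
#'
#' @param instructions List of BEDE/LONE cards.
#' @param structure A [crystal_structure()].
#' @param connectivity Optional [build_connectivity()] result; built on
#'   demand when any LONE card is present.
#' @return Flat list of [placed_gaussian()] lobes.
#' @export
expand_instructions <- function(instructions, structure, connectivity = NULL) {
  if (length(instructions) == 0) return(list())
  if (is.null(connectivity) &&
      any(vapply(instructions, function(x) x$kind == "LONE", logical(1))))
    connectivity <- build_connectivity(structure)
  unlist(lapply(instructions, expand_instruction,
                structure = structure, connectivity = connectivity),
         recursive = FALSE)
}
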