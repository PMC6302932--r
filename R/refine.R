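#' SHELX-convention reflection weights
#'
#' w = 1 / (sigma^2(Fo^2) + (a P)^2 + b P) with
#' P = (max(Fo^2, 0) + 2 Fc^2) / 3.
#'
#' @param fo2,sigma Observed intensities and their esds.
#' @param fc2 Calculated intensities (on the observed scale).
#' @param a,b Weighting coefficients; a = b = 0 gives pure statistical
#'   weights 1/sigma^2.
#' @return Weight vector.
#' @export
compute_weights <- function(fo2, sigma, fc2, a = 0, b = 0) {
  if (any(sigma <= 0)) stop("sigma values must be positive")
  P <- (pmax(fo2, 0) + 2 * fc2) / 3
  1 / (sigma^2 + (a * P)^2 + b * P)
}

.ideal_xh <- c(C = 0.98, N = 0.91, O = 0.98, S = 1.2)

#' Constrain riding hydrogens
#'
#' Every atom whose `riding_parent` is set is repositioned at
#' parent + elongation * (ideal X-H length) along the current
#' parent-to-H direction. The deformation-density default elongation is
#' 1.14; 1.0 reproduces plain IAM riding.
#'
#' @param structure A [crystal_structure()].
#' @param connectivity Unused placeholder kept for API symmetry; the
#'   riding direction comes from the current geometry.
#' @param elongation Multiplier on the ideal X-H distance.
#' @return The structure with riding atoms repositioned.
#' @export
ride_hydrogens <- function(structure, connectivity = NULL, elongation = 1.14) {
  a <- structure$atoms
  m <- cell_metrics(structure$cell)
  riders <- which(!is.na(a$riding_parent))
  for (i in riders) {
    parent <- a$riding_parent[i]
    j <- match(parent, a$label)
    if (is.na(j)) stop("riding atom ", a$label[i], " has unknown parent ", parent)
    if (!is.na(a$riding_parent[j]))
      stop("riding atom ", a$label[i], " has a riding parent itself")
    ideal <- .ideal_xh[toupper(a$element[j])]
    if (is.na(ideal)) ideal <- 1.0
    pj <- as.vector(m$ortho %*% c(a$x[j], a$y[j], a$z[j]))
    pi_ <- as.vector(m$ortho %*% c(a$x[i], a$y[i], a$z[i]))
    u <- unit_vec(pi_ - pj)
    newp <- as.vector(m$frac %*% (pj + elongation * ideal * u))
    a$x[i] <- newp[1]; a$y[i] <- newp[2]; a$z[i] <- newp[3]
  }
  structure$atoms <- a
  structure
}

# ---- parameter packing ------------------------------------------------

pack_parameters <- function(structure, config, refine_k, refine_adp = TRUE) {
  a <- structure$atoms
  p <- numeric(0); names_ <- character(0)
  riding <- !is.na(a$riding_parent)
  for (i in seq_len(nrow(a))) {
    if (riding[i]) next
    p <- c(p, a$x[i], a$y[i], a$z[i])
    names_ <- c(names_, paste0(a$label[i], ".", c("x", "y", "z")))
    if (refine_adp) {
      if (a$aniso[i]) {
        p <- c(p, a$u11[i], a$u22[i], a$u33[i], a$u23[i], a$u13[i], a$u12[i])
        names_ <- c(names_, paste0(a$label[i], ".",
                                   c("u11", "u22", "u33", "u23", "u13", "u12")))
      } else {
        p <- c(p, a$uiso[i])
        names_ <- c(names_, paste0(a$label[i], ".uiso"))
      }
    }
  }
  p <- c(p, config$osf)
  names_ <- c(names_, "osf")
  if (refine_k) {
    p <- c(p, config$k_A, config$k_B1, config$k_B2)
    names_ <- c(names_, c("k_A", "k_B1", "k_B2"))
  }
  names(p) <- names_
  p
}

unpack_parameters <- function(p, structure, config, refine_k,
                              refine_adp = TRUE, riding_offsets = NULL) {
  a <- structure$atoms
  riding <- !is.na(a$riding_parent)
  idx <- 1
  for (i in seq_len(nrow(a))) {
    if (riding[i]) next
    a$x[i] <- p[idx]; a$y[i] <- p[idx + 1]; a$z[i] <- p[idx + 2]
    idx <- idx + 3
    if (refine_adp) {
      if (a$aniso[i]) {
        a[i, c("u11", "u22", "u33", "u23", "u13", "u12")] <- as.list(p[idx:(idx + 5)])
        idx <- idx + 6
      } else {
        a$uiso[i] <- p[idx]; idx <- idx + 1
      }
    }
  }
  config$osf <- p[idx]; idx <- idx + 1
  if (refine_k) {
    config$k_A <- max(0, p[idx])
    config$k_B1 <- max(1e-6, p[idx + 1])
    config$k_B2 <- max(1e-6, p[idx + 2])
  }
  structure$atoms <- a
  if (!is.null(riding_offsets)) {
    m <- cell_metrics(structure$cell)
    for (h in names(riding_offsets)) {
      i <- match(h, a$label)
      j <- match(a$riding_parent[i], a$label)
      pj <- as.vector(m$ortho %*% c(a$x[j], a$y[j], a$z[j]))
      newp <- as.vector(m$frac %*% (pj + riding_offsets[[h]]))
      structure$atoms$x[i] <- newp[1]
      structure$atoms$y[i] <- newp[2]
      structure$atoms$z[i] <- newp[3]
    }
  }
  list(structure = structure, config = config)
}

riding_offsets_of <- function(structure) {
  a <- structure$atoms
  riders <- a$label[!is.na(a$riding_parent)]
  if (length(riders) == 0) return(NULL)
  m <- cell_metrics(structure$cell)
  offs <- lapply(riders, function(h) {
    i <- match(h, a$label); j <- match(a$riding_parent[i], a$label)
    as.vector(m$ortho %*% (c(a$x[i], a$y[i], a$z[i]) -
                           c(a$x[j], a$y[j], a$z[j])))
  })
  names(offs) <- riders
  offs
}

#' Weighted least-squares refinement against intensities
#'
#' Minimizes sum w (Fo^2 - |Fc|^2)^2 (Fc carries the overall scale) by
#' damped Gauss-Newton (Levenberg-Marquardt) steps with a forward-
#' difference Jacobian. Refined quantities: fractional coordinates and
#' ADPs of non-riding atoms, the overall scale factor, and optionally the
#' three global asphericity scales k_A, k_B1, k_B2. Individual card
#' parameters (r, A, B1, B2) never refine: database values are fixed
#' additions to the IAM. With `refine_k = FALSE` and k_A = 0 the
#' trajectory is bit-identical to a pure-IAM refinement.
#'
#' @param structure Starting [crystal_structure()].
#' @param instructions BEDE/LONE cards (empty list for IAM mode).
#' @param reflections A `reflection_set`.
#' @param config A [refinement_config()].
#' @param free_mask Optional logical: reflections excluded from the
#'   working set (cross-validation holdout).
#' @param refine_k Refine the three global asphericity scales.
#' @param refine_adp Refine displacement parameters.
#' @param ride Apply riding-hydrogen constraints (elongation from
#'   `config`).
#' @param verbose Print a cycle table.
#' @return A `refinement_result`: refined structure/config, convergence
#'   flag, cycles, R1, wR2, GooF, parameter shifts and esds.
#' @export
refine_structure <- function(structure, instructions, reflections, config,
                             free_mask = NULL, refine_k = length(instructions) > 0,
                             refine_adp = TRUE, ride = FALSE, verbose = FALSE) {
  work <- if (is.null(free_mask)) rep(TRUE, nrow(reflections)) else !free_mask
  refl <- reflections[work, , drop = FALSE]
  hkl <- as.matrix(refl[, c("h", "k", "l")])
  conn <- if (length(instructions) > 0 || any(!is.na(structure$atoms$riding_parent)))
    build_connectivity(structure) else NULL
  if (ride) structure <- ride_hydrogens(structure, conn, config$elongation)
  offs <- riding_offsets_of(structure)

  p <- pack_parameters(structure, config, refine_k, refine_adp)
  np <- length(p)
  # Floating-origin restraint: in P1 the intensities are invariant under a
  # global translation, so the mean fractional coordinate along each axis
  # is pinned to its starting value after every accepted step.
  pin_origin <- length(structure$symmetry_ops) == 1
  axis_idx <- lapply(c("x", "y", "z"), function(ax)
    which(grepl(paste0("\\.", ax, "$"), names(p))))
  p_start_means <- vapply(axis_idx, function(ix)
    if (length(ix)) mean(p[ix]) else 0, numeric(1))
  pin <- function(pv) {
    if (!pin_origin) return(pv)
    for (k in 1:3) {
      ix <- axis_idx[[k]]
      if (length(ix)) pv[ix] <- pv[ix] - (mean(pv[ix]) - p_start_means[k])
    }
    pv
  }
  if (nrow(refl) <= np)
    stop("data-to-parameter ratio must exceed 1 (", nrow(refl),
         " reflections, ", np, " parameters)")

  fc2_of <- function(pv) {
    up <- unpack_parameters(pv, structure, config, refine_k, refine_adp, offs)
    placed <- expand_instructions(instructions, up$structure, conn)
    Mod(structure_factor(up$structure, placed, up$config, hkl))^2
  }

  cost_of <- function(fc2, w) sum(w * (refl$fo2 - fc2)^2)

  fc2 <- fc2_of(p)
  w <- compute_weights(refl$fo2, refl$sigma, fc2, config$weight_a, config$weight_b)
  cost <- cost_of(fc2, w)
  lambda <- 1e-3
  converged <- FALSE
  stop_reason <- "max_cycles"
  cycle <- 0
  shifts <- rep(0, np)
  esd <- rep(NA_real_, np)

  while (cycle < config$max_cycles) {
    cycle <- cycle + 1
    # forward-difference Jacobian of fc2 wrt parameters
    J <- matrix(0, nrow(refl), np)
    for (j in seq_len(np)) {
      h <- 1e-6 * max(1, abs(p[j]))
      pj <- p; pj[j] <- pj[j] + h
      J[, j] <- (fc2_of(pj) - fc2) / h
    }
    r <- refl$fo2 - fc2
    sw <- sqrt(w)
    A <- crossprod(J * sw)
    g <- crossprod(J, w * r)
    if (pin_origin) {
      # floating-origin restraint: |F|^2 is exactly invariant under a
      # uniform translation, so J has three null directions; restrain the
      # mean shift per axis to zero to keep A invertible (the pin() step
      # keeps the restraint residual at exactly zero, so g is untouched)
      wo <- mean(diag(A)) + 1e-12
      for (k in 1:3) {
        ix <- axis_idx[[k]]
        if (length(ix)) {
          v <- rep(0, np); v[ix] <- 1 / length(ix)
          A <- A + wo * outer(v, v)
        }
      }
    }
    accepted <- FALSE
    solve_ok <- FALSE
    for (try in 1:10) {
      # Marquardt damping with a scaled identity floor so that an exactly
      # flat direction (e.g. a spread scale whose lobes vanished) cannot
      # make the damped matrix numerically singular
      M <- A + lambda * diag(diag(A) + 1e-6 * mean(diag(A)) + 1e-300, np)
      step <- tryCatch(solve(M, g), error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      solve_ok <- TRUE
      p_new <- pin(p + as.vector(step))
      fc2_new <- fc2_of(p_new)
      w_new <- compute_weights(refl$fo2, refl$sigma, fc2_new,
                               config$weight_a, config$weight_b)
      cost_new <- cost_of(fc2_new, w_new)
      if (cost_new <= cost) {
        shifts <- p_new - p
        p <- p_new; fc2 <- fc2_new; w <- w_new
        improvement <- (cost - cost_new) / max(cost, 1e-300)
        cost <- cost_new
        lambda <- max(lambda / 3, 1e-12)
        accepted <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    dof <- max(nrow(refl) - np, 1)
    goof2 <- cost / dof
    # pseudo-inverse: soft directions (e.g. weakly determined spread
    # scales) get a large but finite esd instead of a singular solve
    dA <- tryCatch({
      sv <- svd(A)
      dinv <- ifelse(sv$d > max(sv$d) * 1e-12, 1 / sv$d, 0)
      rowSums(sv$v * sweep(sv$u, 2, dinv, `*`))
    }, error = function(e) rep(NA_real_, np))
    esd <- sqrt(pmax(dA, 0) * goof2)
    if (verbose) {
      rf <- r_factors(refl$fo2, refl$sigma, fc2, w, n_params = np)
      message(sprintf("cycle %2d  R1 = %.4f  wR2 = %.4f  max shift/esd = %.4f",
                      cycle, rf["R1"], rf["wR2"],
                      max(abs(shifts / esd), na.rm = TRUE)))
    }
    if (!accepted) {
      # a computable step that cannot reduce the cost at any damping means
      # the minimum is reached; an unsolvable normal matrix does not
      converged <- solve_ok
      stop_reason <- if (solve_ok) "stalled" else "singular"
      break
    }
    ratio <- abs(shifts) / pmax(esd, 1e-12)
    if (all(is.finite(ratio)) && max(ratio) < config$convergence_tol) {
      converged <- TRUE; stop_reason <- "shift_criterion"; break
    }
    if (improvement < 1e-12) {
      converged <- TRUE; stop_reason <- "no_improvement"; break
    }
  }

  up <- unpack_parameters(p, structure, config, refine_k, refine_adp, offs)
  rf <- r_factors(refl$fo2, refl$sigma, fc2, w, n_params = np)
  structure(list(structure = up$structure, config = up$config,
                 converged = converged, stop_reason = stop_reason,
                 cycles = cycle,
                 r1 = unname(rf["R1"]), wr2 = unname(rf["wR2"]),
                 goof = unname(rf["GooF"]),
                 shifts = stats::setNames(shifts, names(p)),
                 esd = stats::setNames(esd, names(p)),
                 n_params = np, n_reflections = nrow(refl)),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement_result: %s after %d cycle(s)\n",
              if (x$converged) "converged" else "NOT converged", x$cycles))
  cat(sprintf("  R1 = %.4f  wR2 = %.4f  GooF = %.3f  (%d refl, %d params)\n",
              x$r1, x$wr2, x$goof, x$n_reflections, x$n_params))
  invisible(x)
}

#' Fit archetype card parameters against reference intensities
#'
#' Toy-scale stand-in for the metaheuristic database generation: per-card
#' r, A, B1, B2 are fitted to reference reflections (computed from a
#' target density, e.g. the grid oracle of a truth model) by a seeded
#' differential-evolution-style bounded global search followed by a local
#' polish. Structure and configuration stay fixed; only card parameters
#' move.
#'
#' @param reference_reflections Reflection set with fo2/sigma from the
#'   target density.
#' @param instruction_skeletons Cards providing atoms/m-codes/angles;
#'   their r, A, B1, B2 serve as initial centers.
#' @param structure The (fixed) model structure.
#' @param config Fixed [refinement_config()].
#' @param seed RNG seed (reproducible search).
#' @param pop,generations Search-budget controls.
#' @return List: `instructions` (fitted cards), `objective`, `converged`
#'   flag (FALSE when the budget expired without improving on the start).
#' @export
fit_archetype <- function(reference_reflections, instruction_skeletons,
                          structure, config = refinement_config(),
                          seed = 1, pop = 24, generations = 60) {
  conn <- build_connectivity(structure)
  hkl <- as.matrix(reference_reflections[, c("h", "k", "l")])
  w <- 1 / reference_reflections$sigma^2
  ncard <- length(instruction_skeletons)
  lower <- rep(c(0.15, -1.0, 0.15, 0.15), ncard)
  upper <- rep(c(1.20, 1.0, 5.00, 5.00), ncard)

  apply_params <- function(v) {
    lapply(seq_len(ncard), function(i) {
      cd <- instruction_skeletons[[i]]
      q <- v[(4 * i - 3):(4 * i)]
      cd$r <- q[1]; cd$A <- q[2]; cd$B1 <- q[3]; cd$B2 <- q[4]
      cd
    })
  }
  # the structure is fixed during card fitting: cache its IAM part
  m <- cell_metrics(structure$cell)
  f_base <- iam_sf_part(structure, hkl, m)
  objective <- function(v) {
    cards <- apply_params(v)
    placed <- expand_instructions(cards, structure, conn)
    f <- config$osf * (f_base +
                         deformation_sf_part(structure, placed, config, hkl, m))
    sum(w * (reference_reflections$fo2 - Mod(f)^2)^2)
  }

  set.seed(seed)
  d <- 4 * ncard
  X <- matrix(stats::runif(pop * d, lower, upper), pop, d, byrow = TRUE)
  x0 <- unlist(lapply(instruction_skeletons, function(cd)
    c(cd$r, cd$A, cd$B1, cd$B2)))
  X[1, ] <- pmin(pmax(x0, lower), upper)
  fx <- apply(X, 1, objective)
  f_start <- fx[1]
  for (gen in seq_len(generations)) {
    for (i in seq_len(pop)) {
      idx <- sample(setdiff(seq_len(pop), i), 3)
      trial <- X[idx[1], ] + 0.7 * (X[idx[2], ] - X[idx[3], ])
      cr <- stats::runif(d) < 0.9
      cr[sample(d, 1)] <- TRUE
      trial <- ifelse(cr, trial, X[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      ft <- objective(trial)
      if (ft <= fx[i]) { X[i, ] <- trial; fx[i] <- ft }
    }
  }
  # local polish from the best few population members
  vbest <- X[which.min(fx), ]
  obest <- min(fx)
  for (i in order(fx)[1:min(2, pop)]) {
    pol <- stats::optim(X[i, ], objective, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 150, factr = 1e4))
    if (pol$value < obest) { obest <- pol$value; vbest <- pol$par }
  }
  list(instructions = apply_params(vbest), objective = obest,
       converged = obest < f_start)
}
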