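test_that("weighting scheme follows the stated formula", {
  expect_equal(compute_weights(c(100, 50), c(5, 4), c(90, 60)),
               1 / c(25, 16))
  # negative Fo2 clamps to zero inside P
  w <- compute_weights(-10, 2, 30, a = 0.1, b = 0.2)
  P <- (0 + 2 * 30) / 3
  expect_equal(w, 1 / (4 + (0.1 * P)^2 + 0.2 * P))
  # single-line hand evaluation: a=0.05, b=0.3, Fo2=100, sigma=5, Fc2=100
  expect_equal(compute_weights(100, 5, 100, 0.05, 0.3),
               1 / (25 + 25 + 30))
  expect_error(compute_weights(10, 0, 10), "positive")
})

test_that("riding hydrogens sit at elongation x ideal distance and follow", {
  fx <- make_fixture("water_p1", 1)
  st <- fx$structure
  st$atoms$riding_parent[2:3] <- "O1"
  m <- boddr:::cell_metrics(st$cell)
  dist_oh <- function(s, h) {
    a <- s$atoms
    i <- match(h, a$label); j <- match("O1", a$label)
    sqrt(sum((m$ortho %*% (unlist(a[i, c("x", "y", "z")]) -
                             unlist(a[j, c("x", "y", "z")])))^2))
  }
  r1 <- ride_hydrogens(st, elongation = 1.0)
  expect_equal(dist_oh(r1, "H1"), 0.98, tolerance = 1e-9)
  r2 <- ride_hydrogens(st, elongation = 1.14)
  expect_equal(dist_oh(r2, "H1"), 1.1172, tolerance = 1e-9)
  expect_equal(dist_oh(r2, "H2"), 1.1172, tolerance = 1e-9)
  # direction is preserved, only the length changes
  u_old <- unlist(st$atoms[2, c("x", "y", "z")]) -
    unlist(st$atoms[1, c("x", "y", "z")])
  u_new <- unlist(r2$atoms[2, c("x", "y", "z")]) -
    unlist(r2$atoms[1, c("x", "y", "z")])
  expect_equal(unname(u_new / sqrt(sum(u_new^2))),
               unname(u_old / sqrt(sum(u_old^2))), tolerance = 1e-9)
})

test_that("riding H follows its parent rigidly through refinement moves", {
  fx <- make_fixture("water_p1", 1)
  st <- ride_hydrogens(within_atoms(fx$structure, riding_parent = c(NA, "O1", "O1")),
                       elongation = 1.14)
  offs <- boddr:::riding_offsets_of(st)
  p <- boddr:::pack_parameters(st, fx$config, FALSE)
  p[grep("O1.x", names(p))] <- p[grep("O1.x", names(p))] + 0.02
  up <- boddr:::unpack_parameters(p, st, fx$config, FALSE,
                                  riding_offsets = offs)
  moved <- up$structure$atoms
  expect_equal(moved$x[2] - st$atoms$x[2], 0.02, tolerance = 1e-12)
  expect_equal(moved$x[3] - st$atoms$x[3], 0.02, tolerance = 1e-12)
})

test_that("riding constraint errors on a chained parent", {
  fx <- make_fixture("water_p1", 1)
  st <- within_atoms(fx$structure, riding_parent = c("H1", "O1", NA))
  expect_error(ride_hydrogens(st), "riding parent itself")
})

test_that("noise-free data from the start model is a fixed point", {
  fx <- make_fixture("water_p1", 1)
  refl <- simulate_reflections(fx, 0.9, 0, 1)
  res <- refine_structure(fx$structure, fx$instructions, refl, fx$config,
                          refine_k = TRUE)
  expect_true(res$converged)
  expect_lt(res$r1, 1e-10)
  expect_lt(max(abs(res$structure$atoms$x - fx$structure$atoms$x)), 1e-8)
})

test_that("perturbed start recovers positions, ADPs and scales exactly", {
  fx <- make_fixture("carbonyl_p1", 1)
  refl <- simulate_reflections(fx, 0.8, 0, 1)
  st <- fx$structure
  set.seed(7)
  for (ax in c("x", "y")) {
    d <- rnorm(nrow(st$atoms), 0, 0.01)
    st$atoms[[ax]] <- st$atoms[[ax]] + (d - mean(d))  # origin-neutral shake
  }
  st$atoms$uiso <- st$atoms$uiso * 1.1
  cfg <- fx$config; cfg$osf <- 1.0
  res <- refine_structure(st, fx$instructions, refl, cfg, refine_k = TRUE)
  expect_true(res$converged)
  for (ax in c("x", "y", "z"))
    expect_lt(max(abs(res$structure$atoms[[ax]] -
                        fx$structure$atoms[[ax]])), 1e-4)
  expect_lt(max(abs(res$structure$atoms$uiso /
                      fx$structure$atoms$uiso - 1)), 0.01)
  expect_lt(abs(res$config$osf / fx$config$osf - 1), 0.01)
  expect_lt(abs(res$config$k_A - 1), 0.01)
})

test_that("anisotropic ADP components are refinable and recovered", {
  cell <- c(6, 6.5, 7, 90, 90, 90)
  at <- data.frame(label = c("S1", "O1"), element = c("S", "O"),
                   x = c(0.3, 0.55), y = c(0.4, 0.4), z = c(0.5, 0.5),
                   occ = 1, uiso = NA_real_, aniso = TRUE,
                   u11 = c(0.020, 0.030), u22 = c(0.025, 0.022),
                   u33 = c(0.030, 0.026), u23 = c(0.002, -0.001),
                   u13 = c(-0.003, 0.002), u12 = c(0.004, 0.003),
                   stringsAsFactors = FALSE)
  st <- crystal_structure(cell, at)
  hkl <- hkl_to_resolution(cell, 0.8)
  cfg <- refinement_config(osf = 1.1)
  f <- structure_factor(st, list(), cfg, hkl)
  refl <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                     fo2 = Mod(f)^2, sigma = 1e-4 * max(Mod(f)^2))
  start <- st
  start$atoms$u11 <- start$atoms$u11 * 1.15
  start$atoms$u23 <- start$atoms$u23 + 0.002
  cfg0 <- refinement_config(osf = 1.0)
  res <- refine_structure(start, list(), refl, cfg0, refine_k = FALSE)
  expect_true(res$converged)
  for (u in c("u11", "u22", "u33", "u23", "u13", "u12"))
    expect_lt(max(abs(res$structure$atoms[[u]] - st$atoms[[u]])), 3e-4)
  expect_lt(abs(res$config$osf - 1.1), 0.01)
})

test_that("freeing the asphericity scales on BODD-truth data lowers R1", {
  fx <- make_fixture("water_p1", 1)
  refl <- simulate_reflections(fx, 0.8, 0.02, 4)
  cfg <- refinement_config(osf = 1.0)
  frozen <- refine_structure(fx$structure, fx$instructions, refl,
                             within_cfg(cfg, k_A = 0), refine_k = FALSE)
  free <- refine_structure(fx$structure, fx$instructions, refl, cfg,
                           refine_k = TRUE)
  expect_lt(free$r1, frozen$r1)
})

test_that("refinement refuses an under-determined problem", {
  fx <- make_fixture("water_p1", 1)
  refl <- simulate_reflections(fx, 0.9, 0, 1)[1:5, ]
  expect_error(refine_structure(fx$structure, list(), refl, fx$config),
               "data-to-parameter")
})

test_that("archetype fitter recovers card parameters from a target density", {
  fx <- make_fixture("water_p1", 1)
  truth <- list(bede("O1", "H1", 0.33, 0.12, 1.0, 1.4),
                bede("O1", "H2", 0.33, 0.12, 1.0, 1.4))
  hkl <- hkl_to_resolution(fx$structure$cell, 0.9)
  cfg <- refinement_config()
  placed <- expand_instructions(truth, fx$structure)
  f <- structure_factor(fx$structure, placed, cfg, hkl)
  ref <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    fo2 = Mod(f)^2, sigma = 1e-3 * max(Mod(f)^2))
  skel <- list(bede("O1", "H1", 0.5, 0.3, 1.5, 1.0),
               bede("O1", "H2", 0.5, 0.3, 1.5, 1.0))
  fit <- fit_archetype(ref, skel, fx$structure, cfg, seed = 1,
                       pop = 20, generations = 40)
  expect_true(fit$converged)
  got <- fit$instructions[[1]]
  expect_lt(abs(got$A - 0.12) / 0.12, 0.05)
  expect_lt(abs(got$r - 0.33), 0.02)
  # independent seed: objective agrees within 1%
  fit2 <- fit_archetype(ref, skel, fx$structure, cfg, seed = 2,
                        pop = 20, generations = 40)
  o1 <- max(fit$objective, 1e-12); o2 <- max(fit2$objective, 1e-12)
  norm <- sum(ref$fo2^2 / ref$sigma^2)
  expect_lt(abs(o1 - o2) / norm, 0.01)
})

test_that("zero-deformation target fits amplitudes near zero", {
  fx <- make_fixture("water_p1", 1)
  hkl <- hkl_to_resolution(fx$structure$cell, 1.0)
  cfg <- refinement_config()
  f <- structure_factor(fx$structure, list(), cfg, hkl)
  ref <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    fo2 = Mod(f)^2, sigma = 1e-3 * max(Mod(f)^2))
  skel <- list(bede("O1", "H1", 0.4, 0.2, 1.2, 1.2))
  fit <- fit_archetype(ref, skel, fx$structure, cfg, seed = 3,
                       pop = 16, generations = 30)
  expect_lt(abs(fit$instructions[[1]]$A), 0.02)
})
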