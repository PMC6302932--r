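test_that("covalent-radius connectivity finds and rejects bonds", {
  expect_equal(nrow(build_connectivity(two_carbons(1.54))$bonds), 1)
  expect_equal(nrow(build_connectivity(two_carbons(3.0))$bonds), 0)
  fx <- make_fixture("ethane_p1", 1)
  conn <- build_connectivity(fx$structure)
  expect_equal(nrow(conn$bonds), 7)
  expect_length(conn$neighbors[["C1"]], 4)
  expect_length(conn$neighbors[["C2"]], 4)
  # symmetric neighbor lists
  for (k in seq_len(nrow(conn$bonds)))
    expect_true(conn$bonds$a[k] %in% conn$neighbors[[conn$bonds$b[k]]])
})

test_that("bonds across the cell boundary are detected", {
  st <- crystal_structure(c(8, 8, 9, 90, 90, 90), data.frame(
    label = c("C1", "C2"), element = "C",
    x = 0.5, y = 0.5, z = c(0.02, 0.93), occ = 1, uiso = 0.025,
    stringsAsFactors = FALSE))
  # direct distance 8.2 A, image distance 0.81 A... use a realistic gap
  st$atoms$z <- c(0.05, 1 - 0.12)  # 0.05*9 + 0.12*9 = 1.53 A apart via image
  conn <- build_connectivity(st)
  expect_equal(nrow(conn$bonds), 1)
  expect_equal(conn$bonds$length, 1.53, tolerance = 1e-9)
})

test_that("lone directions have stated counts and unit length for all m", {
  root <- c(0, 0, 0)
  nb3 <- rbind(c(1.5, 0, 0), c(-0.7, 1.3, 0), c(-0.7, -1.3, 0))
  # seesaw (SF4-like): two axial, two equatorial bonds leaving one site
  nb4 <- rbind(c(1.5, 0, 0), c(-1.5, 0, 0), c(0, 1.4, -0.5), c(0, -1.4, -0.5))
  cases <- list(
    list(m = 1, nb = nb3, ang = NULL, n = 1),
    list(m = 2, nb = nb3[1:2, ], ang = 109.5, n = 2),
    list(m = 3, nb = nb3[1, , drop = FALSE], ang = 109.5, n = 3),
    list(m = 6, nb = nb3[1:2, ], ang = NULL, n = 2),
    list(m = 7, nb = nb3[1, , drop = FALSE], ang = 180, n = 2),
    list(m = 9, nb = nb3[1, , drop = FALSE], ang = 120, n = 2),
    list(m = 12, nb = nb3[1, , drop = FALSE], ang = NULL, n = 12),
    list(m = 15, nb = nb4, ang = NULL, n = 1))
  for (cs in cases) {
    d <- lone_directions(cs$m, root, cs$nb, cs$ang,
                         second_shell = c(2.2, 1.1, 0))
    expect_equal(nrow(d), cs$n, info = paste("m =", cs$m))
    expect_lt(max(abs(sqrt(rowSums(d^2)) - 1)), 1e-12)
  }
})

test_that("m = 1 under C3v symmetry is antiparallel to the bond sum", {
  nb <- t(vapply(c(0, 120, 240), function(p) {
    ph <- p * pi / 180; th <- 109.5 * pi / 180
    1.5 * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  }, numeric(3)))
  d <- lone_directions(1, c(0, 0, 0), nb)
  expect_equal(as.vector(d), c(0, 0, -sign(cos(109.5 * pi / 180))),
               tolerance = 1e-10)
})

test_that("m = 6 lobes are the antiparallel plane normals", {
  d <- lone_directions(6, c(0, 0, 0), rbind(c(1.4, 0, 0), c(-0.5, 1.2, 0)))
  expect_equal(abs(d[, 3]), c(1, 1), tolerance = 1e-12)
  expect_equal(d[1, ], -d[2, ], tolerance = 1e-12)
})

test_that("m = 12 cone: 30-degree azimuth grid, 60-degree half-sets", {
  d <- lone_directions(12, c(0, 0, 0), matrix(c(0, 0, -1.4), 1),
                       second_shell = c(1.0, 0.3, -2.1))
  az <- sort((atan2(d[, 2], d[, 1]) * 180 / pi) %% 360)
  expect_equal(diff(az), rep(30, 11), tolerance = 1e-9)
  half1 <- az[seq(1, 12, by = 2)]; half2 <- az[seq(2, 12, by = 2)]
  expect_equal(diff(half1), rep(60, 5), tolerance = 1e-9)
  expect_equal((half2 - half1) %% 360, rep(30, 6), tolerance = 1e-9)
  # all on the tetrahedral-complement cone about +z (anti-bond axis)
  expect_equal(unique(round(acos(d[, 3]) * 180 / pi, 6)),
               round(180 - 109.4712206, 6), tolerance = 1e-5)
})

test_that("geometry errors name the atom and the code", {
  expect_error(lone_directions(2, c(0, 0, 0),
                               matrix(c(1.5, 0, 0), 1), 109.5, label = "O7"),
               "O7.*m = 2")
  expect_error(lone_directions(2, c(0, 0, 0),
                               rbind(c(1.5, 0, 0), c(-1.5, 0, 0)), 109.5,
                               label = "O7"),
               "collinear")
  expect_error(lone_directions(5, c(0, 0, 0), matrix(c(1, 0, 0), 1)),
               "m = 5")
})

test_that("BEDE expansion: two lobes, +A on the bond, -A at atom1", {
  fx <- make_fixture("carbonyl_p1", 1)
  st <- fx$structure
  card <- bede("C1", "O1", 0.45, 0.22, 0.9, 1.3)
  lobes <- expand_instruction(card, st)
  expect_length(lobes, 2)
  expect_equal(vapply(lobes, `[[`, numeric(1), "amplitude"), c(0.22, -0.22))
  m <- boddr:::cell_metrics(st$cell)
  i1 <- match("C1", st$atoms$label); i2 <- match("O1", st$atoms$label)
  p1 <- as.vector(m$ortho %*% unlist(st$atoms[i1, c("x", "y", "z")]))
  p2 <- as.vector(m$ortho %*% unlist(st$atoms[i2, c("x", "y", "z")]))
  lb <- as.vector(m$ortho %*% lobes[[1]]$center)
  expect_equal(sqrt(sum((lb - p1)^2)), 0.45, tolerance = 1e-9)
  # lobe lies on the bond axis
  expect_lt(sqrt(sum(boddr:::cross3(lb - p1, p2 - p1)^2)) /
              sqrt(sum((p2 - p1)^2)), 1e-9)
  expect_equal(vapply(lobes, `[[`, numeric(1), "spread"), c(0.9, 1.3))
  expect_identical(lobes[[2]]$host_atom, "C1")
})

test_that("LONE expansions carry the stated lobe counts and balances", {
  fx <- make_fixture("water_p1", 1)
  conn <- build_connectivity(fx$structure)
  l2 <- expand_instruction(lone(2, "O1", 0.3, 1, 1, 0.4, 109.5),
                           fx$structure, conn)
  expect_length(l2, 3)
  expect_equal(l2[[3]]$amplitude, -2 * 0.3)

  fe <- make_fixture("mixed_metal_p1", 1)
  connf <- build_connectivity(fe$structure)
  l12 <- expand_instruction(lone(12, "O1", 0.2, 1, 1, 0.4),
                            fe$structure, connf)
  expect_length(l12, 13)
  amps <- vapply(l12, `[[`, numeric(1), "amplitude")
  expect_equal(amps[1:12], rep(0.1, 12))        # half occupancy
  expect_equal(amps[13], -6 * 0.2)
  expect_equal(sum(amps), 0)
})

test_that("signed amplitude x occupancy sums to zero for all fixtures", {
  for (nm in c("ethane_p1", "carbonyl_p1", "water_p1", "methylamine_p1",
               "mixed_metal_p1")) {
    fx <- make_fixture(nm, 5)
    conn <- build_connectivity(fx$structure)
    for (cd in fx$instructions) {
      lobes <- expand_instruction(cd, fx$structure, conn)
      expect_identical(sum(vapply(lobes, `[[`, numeric(1), "amplitude")), 0)
    }
  }
})

test_that("LONE on an atom without the needed environment errors", {
  fx <- make_fixture("water_p1", 1)
  conn <- build_connectivity(fx$structure)
  expect_error(expand_instruction(lone(1, "O1", 0.1, 1, 1, 0.4),
                                  fx$structure, conn), "m = 1")
  expect_error(expand_instruction(lone(7, "O1", 0.1, 1, 1, 0.4, 180),
                                  fx$structure, conn), "O1")
})
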