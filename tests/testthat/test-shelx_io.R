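test_that("minimal P1 file parses to one atom and no cards", {
  p <- read_ins(minimal_ins_lines())
  expect_s3_class(p$structure, "crystal_structure")
  expect_equal(nrow(p$structure$atoms), 1)
  expect_identical(p$structure$atoms$element, "C")
  expect_equal(p$structure$atoms$occ, 1)
  expect_equal(p$structure$atoms$uiso, 0.03)
  expect_length(p$instructions, 0)
  expect_equal(p$config$osf, 1.0)
})

test_that("missing CELL is a fatal parse error", {
  lines <- setdiff(minimal_ins_lines(), minimal_ins_lines()[2])
  expect_error(read_ins(lines), "CELL")
})

test_that("BEDE and LONE cards parse with documented token order", {
  lines <- append(minimal_ins_lines(),
                  c("O1 2 0.5 0.5 0.5 11.0 0.03",
                    "C2 1 0.35 0.35 0.35 11.0 0.03",
                    "BEDE C1 C2 0.5 0.2 1.1 0.9",
                    "LONE 2 O1 0.3 1.0 1.0 0.4 109.5"),
                  after = 6)
  lines[4] <- "SFAC C O"
  p <- read_ins(lines)
  b <- p$instructions[[1]]
  expect_identical(b$kind, "BEDE")
  expect_identical(c(b$atom1, b$atom2), c("C1", "C2"))
  expect_equal(c(b$r, b$A, b$B1, b$B2), c(0.5, 0.2, 1.1, 0.9))
  l <- p$instructions[[2]]
  expect_identical(l$kind, "LONE")
  expect_equal(l$m, 2)
  expect_identical(l$atom, "O1")
  expect_equal(c(l$A, l$B1, l$B2, l$r, l$angle), c(0.3, 1.0, 1.0, 0.4, 109.5))
})

test_that("card validation errors carry the offending detail", {
  bad_atom <- append(minimal_ins_lines(),
                     "BEDE C1 C9 0.5 0.2 1.1 0.9", after = 6)
  expect_error(read_ins(bad_atom), "C9")
  # angle supplied for a code that takes none
  bad_angle <- append(minimal_ins_lines(),
                      "LONE 1 C1 0.3 1.0 1.0 0.4 109.5", after = 6)
  expect_error(read_ins(bad_angle), "angle")
  expect_error(lone(6, "O1", 0.1, 1, 1, 0.4, angle = 90), "no angle")
  expect_error(lone(2, "O1", 0.1, 1, 1, 0.4), "requires an angle")
})

test_that("unknown benign keywords are preserved through a round trip", {
  lines <- append(minimal_ins_lines(), "CONF", after = 6)
  p <- read_ins(lines)
  out <- write_res(p$structure, p$instructions, p$config)
  expect_true(any(out == "CONF"))
  expect_warning(read_ins(append(minimal_ins_lines(), "EXTI 0.01", after = 6)),
                 "ignored")
})

test_that("external instruction files are included via + syntax", {
  dir <- withr::local_tempdir()
  writeLines(c("BEDE C1 O1 0.45 0.22 0.9 1.3",
               "LONE 9 O1 0.14 1.0 1.3 0.35 120"),
             file.path(dir, "cards.bodd"))
  fx <- make_fixture("carbonyl_p1", 1)
  res <- write_res(fx$structure, list(), fx$config)
  ins <- append(res, "+cards.bodd", after = length(res) - 2)
  writeLines(ins, file.path(dir, "model.ins"))
  p <- read_ins(file.path(dir, "model.ins"))
  expect_length(p$instructions, 2)
  expect_identical(p$instructions[[2]]$kind, "LONE")
})

test_that("write_res/read_ins round-trips every fixture", {
  for (nm in c("ethane_p1", "carbonyl_p1", "water_p1",
               "methylamine_p1", "mixed_metal_p1")) {
    fx <- make_fixture(nm, 3)
    p <- read_ins(write_res(fx$structure, fx$instructions, fx$config))
    expect_equal(p$structure$cell, fx$structure$cell, tolerance = 1e-6)
    expect_identical(p$structure$atoms$label, fx$structure$atoms$label)
    for (col in c("x", "y", "z", "occ", "uiso"))
      expect_equal(p$structure$atoms[[col]], fx$structure$atoms[[col]],
                   tolerance = 1e-5)
    expect_cards_equal(p$instructions, fx$instructions)
    expect_equal(p$config$osf, fx$config$osf, tolerance = 1e-6)
  }
})

test_that("config fields including k scales survive serialization", {
  fx <- make_fixture("water_p1", 1)
  cfg <- refinement_config(osf = 1.3, k_A = 0.8, k_B1 = 1.2, k_B2 = 0.7,
                           weight_a = 0.04, weight_b = 0.2, elongation = 1.14)
  p <- read_ins(write_res(fx$structure, fx$instructions, cfg))
  expect_equal(p$config$k_A, 0.8, tolerance = 1e-6)
  expect_equal(p$config$k_B1, 1.2, tolerance = 1e-6)
  expect_equal(p$config$k_B2, 0.7, tolerance = 1e-6)
  expect_equal(p$config$weight_a, 0.04, tolerance = 1e-6)
  expect_equal(p$config$elongation, 1.14, tolerance = 1e-6)
})

test_that("riding-parent marks and anisotropic ADPs round-trip", {
  st <- one_atom_structure()
  at <- rbind(st$atoms,
              data.frame(label = "H1", element = "H", x = 0.33, y = 0.42,
                         z = 0.52, occ = 1, uiso = 0.04, aniso = FALSE,
                         u11 = NA, u22 = NA, u33 = NA, u23 = NA, u13 = NA,
                         u12 = NA, riding_parent = "C1"))
  at$aniso[1] <- TRUE
  at[1, c("u11", "u22", "u33", "u23", "u13", "u12")] <-
    c(0.02, 0.025, 0.03, 0.001, -0.002, 0.003)
  at$uiso[1] <- NA
  st2 <- crystal_structure(st$cell, at, sfac = list(C = sfac_coefficients("C"),
                                                    H = sfac_coefficients("H")))
  st2$sfac_order <- c("C", "H")
  p <- read_ins(write_res(st2, list(), refinement_config()))
  expect_true(p$structure$atoms$aniso[1])
  expect_equal(p$structure$atoms$u13[1], -0.002, tolerance = 1e-6)
  expect_identical(p$structure$atoms$riding_parent[2], "C1")
})

test_that("random valid cards survive format -> parse (fuzz)", {
  set.seed(42)
  for (i in 1:25) {
    card <- if (i %% 2) random_bede_card() else random_lone_card()
    tok <- strsplit(format(card), "\\s+")[[1]]
    re <- if (card$kind == "BEDE") {
      v <- as.numeric(tok[4:7]); bede(tok[2], tok[3], v[1], v[2], v[3], v[4])
    } else {
      v <- as.numeric(tok[4:length(tok)])
      lone(as.integer(tok[2]), tok[3], v[1], v[2], v[3], v[4],
           if (length(v) >= 5) v[5] else NULL)
    }
    expect_cards_equal(list(card), list(re), tol = 1e-4)
  }
})

test_that("read_hkl parses, merges and guards", {
  lines <- c("   1   0   0  100.00    5.00",
             "   0   1   0   50.00    4.00",
             "   0   0   1   25.00    3.00",
             "   0   0   0    0.00    0.00")
  r <- read_hkl(lines, cell = c(6, 6, 6, 90, 90, 90))
  expect_equal(nrow(r), 3)           # terminator not stored
  expect_equal(r$s[r$h == 1], 1 / 12, tolerance = 1e-12)

  dup <- c("   1   0   0  100.00    5.00",
           "   1   0   0  110.00    5.00")
  m <- read_hkl(dup)
  expect_equal(nrow(m), 1)
  expect_equal(m$fo2, 105)           # equal sigma -> plain mean

  expect_warning(bad <- read_hkl(c("   1   0   0  100.00    5.00",
                                   "   2   0   0   10.00   -1.00")),
                 "sigma")
  expect_equal(nrow(bad), 1)
  expect_error(read_hkl("   1   0   x  100.00    5.00"), "line 1")
})

test_that("hkl files round-trip through write_hkl", {
  fx <- make_fixture("water_p1", 1)
  refl <- simulate_reflections(fx, 1.0, 0.02, 1)
  path <- withr::local_tempfile(fileext = ".hkl")
  write_hkl(refl, path)
  back <- read_hkl(path, fx$structure$cell)
  expect_equal(nrow(back), nrow(refl))
  expect_equal(back$fo2, refl$fo2, tolerance = 5e-2)
})
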