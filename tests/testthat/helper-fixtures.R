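# Shared helpers for the test suite. Everything is generated in code;
# no binary fixtures exist anywhere in the repository.

minimal_ins_lines <- function() {
  c("TITL minimal P1 carbon",
    "CELL 0.71073 6.0 6.5 7.0 90 90 90",
    "LATT -1",
    "SFAC C",
    "UNIT 1",
    "FVAR 1.0",
    "C1 1 0.25 0.25 0.25 11.0 0.03",
    "HKLF 4",
    "END")
}

# one-atom orthorhombic P1 structure, isotropic
one_atom_structure <- function(element = "C", uiso = 0.025,
                               cell = c(6, 6.5, 7, 90, 90, 90)) {
  crystal_structure(cell, data.frame(
    label = paste0(element, "1"), element = element,
    x = 0.3, y = 0.4, z = 0.5, occ = 1, uiso = uiso,
    stringsAsFactors = FALSE))
}

# two carbons at a given separation (Angstrom) along z
two_carbons <- function(d, cell = c(8, 8, 9, 90, 90, 90)) {
  crystal_structure(cell, data.frame(
    label = c("C1", "C2"), element = "C",
    x = 0.5, y = 0.5, z = c(0.5 - d / (2 * cell[3]), 0.5 + d / (2 * cell[3])),
    occ = 1, uiso = 0.025, stringsAsFactors = FALSE))
}

random_bede_card <- function() {
  bede(paste0("C", sample(9, 1)), paste0("N", sample(9, 1)),
       r = round(stats::runif(1, 0.2, 1.1), 4),
       A = round(stats::runif(1, -0.5, 0.5), 4),
       B1 = round(stats::runif(1, 0.2, 3), 4),
       B2 = round(stats::runif(1, 0.2, 3), 4))
}

random_lone_card <- function() {
  m <- sample(c(1, 2, 3, 6, 7, 9, 12, 15), 1)
  ang <- if (m %in% c(2, 3, 7, 9)) round(stats::runif(1, 90, 150), 2) else NULL
  lone(m, paste0("O", sample(9, 1)),
       A = round(stats::runif(1, 0.01, 0.5), 4),
       B1 = round(stats::runif(1, 0.2, 3), 4),
       B2 = round(stats::runif(1, 0.2, 3), 4),
       r = round(stats::runif(1, 0.2, 0.8), 4), angle = ang)
}

expect_cards_equal <- function(a, b, tol = 1e-6) {
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$kind, b[[i]]$kind)
    for (f in setdiff(names(a[[i]]), "kind")) {
      if (is.numeric(a[[i]][[f]]))
        expect_equal(a[[i]][[f]], b[[i]][[f]], tolerance = tol)
      else expect_identical(a[[i]][[f]], b[[i]][[f]])
    }
  }
}

within_atoms <- function(structure, ...) {
  mods <- list(...)
  for (nm in names(mods)) structure$atoms[[nm]] <- mods[[nm]]
  structure
}

within_cfg <- function(config, ...) {
  mods <- list(...)
  for (nm in names(mods)) config[[nm]] <- mods[[nm]]
  config
}
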