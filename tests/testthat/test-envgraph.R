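test_that("environment graph colors follow the level scheme", {
  fx <- make_fixture("ethane_p1", 1)
  conn <- build_connectivity(fx$structure)
  g <- build_environment_graph("C1", conn, fx$structure)
  nd <- g$nodes
  root <- nd[nd$level == 0, ]
  expect_equal(nrow(root), 1)
  expect_equal(root$r, 0)
  bl <- conn$bonds$length[conn$bonds$a == "C1" | conn$bonds$b == "C1"]
  expect_equal(root$g, sum(bl), tolerance = 1e-12)   # ~4 bond lengths
  expect_equal(root$g, 4 * 1.1, tolerance = 0.5)
  expect_true(all(nd$b == nd$level))
  expect_true(all(nd$a == 1))
  expect_true(all(nd$g[nd$level == 2] == 0))
  # every level-k node is adjacent to some level-(k-1) node
  for (i in which(nd$level > 0)) {
    nb <- c(g$edges$to[g$edges$from == nd$label[i]],
            g$edges$from[g$edges$to == nd$label[i]])
    expect_true(any(nd$level[match(nb, nd$label)] == nd$level[i] - 1))
  }
})

test_that("methylamine N1 graph has the hand-counted shape", {
  fx <- make_fixture("methylamine_p1", 1)
  conn <- build_connectivity(fx$structure)
  g <- build_environment_graph("N1", conn, fx$structure)
  expect_equal(sum(g$nodes$level == 0), 1)
  expect_equal(sum(g$nodes$level == 1), 3)   # C1, H4, H5
  expect_equal(sum(g$nodes$level == 2), 3)   # H1, H2, H3 via C1
  expect_equal(nrow(g$edges), 6)             # 3 root bonds + 3 C-H bonds
})

test_that("isolated atom yields a single flagged node with color (0,0,0,1)", {
  st <- crystal_structure(c(9, 9, 9, 90, 90, 90), data.frame(
    label = "C1", element = "C", x = 0.5, y = 0.5, z = 0.5,
    occ = 1, uiso = 0.03, stringsAsFactors = FALSE))
  conn <- build_connectivity(st)
  g <- build_environment_graph("C1", conn, st)
  expect_true(g$isolated)
  expect_equal(nrow(g$nodes), 1)
  expect_equal(unlist(g$nodes[1, c("r", "g", "b", "a")]),
               c(r = 0, g = 0, b = 0, a = 1))
})

test_that("graph hash is invariant under node relabeling (100 trials)", {
  fx <- make_fixture("methylamine_p1", 1)
  conn <- build_connectivity(fx$structure)
  g <- build_environment_graph("N1", conn, fx$structure)
  h0 <- graph_hash(g)
  set.seed(99)
  for (i in 1:100) {
    perm <- sample(nrow(g$nodes))
    g2 <- g
    g2$nodes <- g$nodes[perm, ]
    new_names <- paste0("X", seq_len(nrow(g$nodes)))
    names(new_names) <- g$nodes$label[perm]
    g2$nodes$label <- new_names[g2$nodes$label]
    g2$edges$from <- unname(new_names[g$edges$from])
    g2$edges$to <- unname(new_names[g$edges$to])
    if (i %% 2 == 0) g2$edges <- g2$edges[sample(nrow(g2$edges)), ]
    expect_identical(graph_hash(g2), h0)
  }
})

test_that("hash respects quantization buckets and structural change", {
  fx <- make_fixture("carbonyl_p1", 1)
  conn <- build_connectivity(fx$structure)
  g <- build_environment_graph("C1", conn, fx$structure)
  h0 <- graph_hash(g, quantization = 0.01)
  g_eps <- g
  # nudge one level-1 color by much less than a bucket
  i <- which(g_eps$nodes$level == 1)[1]
  base <- round(g_eps$nodes$r[i] / 0.01) * 0.01   # bucket center
  g_eps$nodes$r[i] <- base + 0.001
  g_ref <- g; g_ref$nodes$r[i] <- base
  expect_identical(graph_hash(g_eps, 0.01), graph_hash(g_ref, 0.01))
  # removing a level-2 node changes the digest
  g_cut <- g
  drop <- g_cut$nodes$label[g_cut$nodes$level == 2][1]
  g_cut$nodes <- g_cut$nodes[g_cut$nodes$label != drop, ]
  g_cut$edges <- g_cut$edges[g_cut$edges$from != drop & g_cut$edges$to != drop, ]
  expect_false(identical(graph_hash(g_cut), h0))
})

test_that("archetype database round-trips through its text format", {
  db <- fixture_archetype_database(c("water_p1", "carbonyl_p1"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_archetype_db(db, path)
  back <- read_archetype_db(path)
  expect_length(back, length(db))
  for (i in seq_along(db)) {
    expect_identical(back[[i]]$inner_hash, db[[i]]$inner_hash)
    expect_identical(back[[i]]$invariom_name, db[[i]]$invariom_name)
    expect_identical(back[[i]]$templates, db[[i]]$templates)
    expect_identical(back[[i]]$serialized_graph, db[[i]]$serialized_graph)
    expect_identical(back[[i]]$color_summary, db[[i]]$color_summary)
  }
})

test_that("the shipped database file matches a fresh regeneration", {
  shipped <- read_archetype_db(system.file("extdata", "bodd_archetypes.txt",
                                           package = "boddr"))
  fresh <- fixture_archetype_database()
  expect_identical(vapply(shipped, `[[`, character(1), "inner_hash"),
                   vapply(fresh, `[[`, character(1), "inner_hash"))
})

test_that("assignment: exact matches, fallbacks, and IAM-only heavies", {
  db <- fixture_archetype_database()
  fx <- make_fixture("carbonyl_p1", 1)
  res <- assign_instructions(fx$structure, db)
  rep_ <- res$report
  expect_true(all(rep_$status[rep_$atom %in% c("C1", "O1")] == "assigned"))
  # same card set as the truth instructions (order-insensitive)
  expect_setequal(vapply(res$instructions, format, character(1)),
                  vapply(fx$instructions, format, character(1)))

  # deliberately absent archetype: drop the carbonyl records, keep others
  db_miss <- Filter(function(r) !grepl("carbonyl", r$invariom_name), db)
  res2 <- assign_instructions(fx$structure, db_miss)
  o_row <- res2$report[res2$report$atom == "O1", ]
  expect_identical(o_row$status, "fallback")
  expect_false(is.na(o_row$record))
  expect_lt(o_row$score, 1)

  # heavy atom without records scatters as plain IAM, no error
  fxm <- make_fixture("mixed_metal_p1", 1)
  resm <- assign_instructions(fxm$structure, db)
  expect_identical(resm$report$status[resm$report$atom == "FE1"], "iam")
})

test_that("an empty database is rejected", {
  fx <- make_fixture("water_p1", 1)
  expect_error(assign_instructions(fx$structure, list()), "empty")
})
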