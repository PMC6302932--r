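#' Two-shell environment graph of an atom
#'
#' Builds the colored graph keying the asphericity-parameter database.
#' Node colors are (r, g, b, a) tuples: level 0 (the typed atom) has
#' r = 0, g = sum of bond lengths to its bonding partners, b = 0, a = 1;
#' level 1 nodes carry r = distance to the root, g = their own bond-length
#' sum, b = 1, a = 1; level 2 nodes carry r = distance to the root, g = 0,
#' b = 2 and a = 1 (the constant alpha sits behind one helper so the
#' convention can be revised in a single place). The graph is truncated
#' after the second shell.
#'
#' @param root_atom Label of the typed atom.
#' @param connectivity A [build_connectivity()] result.
#' @param structure A [crystal_structure()].
#' @return An `environment_graph`: `nodes` data frame (label, level, r, g,
#'   b, a), `edges` data frame (from, to), `root`, `isolated` flag.
#' @export
build_environment_graph <- function(root_atom, connectivity, structure) {
  nb <- connectivity$neighbors
  if (is.null(nb[[root_atom]]))
    stop("unknown atom label '", root_atom, "'")
  m <- cell_metrics(structure$cell)
  a <- structure$atoms
  fx <- function(lb) {
    i <- atom_index(structure, lb)
    c(a$x[i], a$y[i], a$z[i])
  }
  dist_root <- function(lb)
    min_image_distance(fx(root_atom), fx(lb), structure$symmetry_ops, m)
  bondsum <- function(lb) {
    ns <- nb[[lb]]
    if (length(ns) == 0) return(0)
    sum(vapply(ns, function(x) bond_length(connectivity, lb, x), numeric(1)))
  }
  l1 <- nb[[root_atom]]
  l2 <- setdiff(unique(unlist(nb[l1])), c(root_atom, l1))
  labels <- c(root_atom, l1, l2)
  levels <- c(0L, rep(1L, length(l1)), rep(2L, length(l2)))
  nodes <- data.frame(label = labels, level = levels,
                      r = 0, g = 0, b = as.numeric(levels),
                      a = level2_alpha(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(nodes))) {
    lv <- nodes$level[i]; lb <- nodes$label[i]
    if (lv == 0) {
      nodes$g[i] <- bondsum(lb)
    } else if (lv == 1) {
      nodes$r[i] <- dist_root(lb)
      nodes$g[i] <- bondsum(lb)
    } else {
      nodes$r[i] <- dist_root(lb)
    }
  }
  bd <- connectivity$bonds
  keep <- bd$a %in% labels & bd$b %in% labels
  edges <- bd[keep, c("a", "b")]
  names(edges) <- c("from", "to")
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, root = root_atom,
                 isolated = length(l1) == 0),
            class = "environment_graph")
}

# Table-4 level-2 alpha: unreadable in the source table; fixed at 1 here.
level2_alpha <- function() 1

#' Canonical digest of an environment graph
#'
#' Colors are quantized to `quantization` Angstrom, node identities are
#' canonicalized by iterative neighborhood color refinement
#' (Weisfeiler-Lehman style, lexicographic tie-breaking), and the sorted
#' canonical serialization of node colors and edge color pairs is digested
#' with two independent 31-bit polynomial rolling hashes. The digest is a
#' function of the isomorphism class of the quantized colored graph:
#' relabeling or reordering nodes cannot change it.
#'
#' @param graph An [build_environment_graph()] result.
#' @param quantization Color resolution in Angstrom (default 0.01).
#' @return Hex digest string.
#' @export
graph_hash <- function(graph, quantization = 0.01) {
  ser <- canonical_serialization(graph, quantization)
  poly_digest(ser)
}

canonical_serialization <- function(graph, quantization = 0.01) {
  nd <- graph$nodes
  q <- function(x) as.character(round(x / quantization))
  lab <- sprintf("(%d|%s|%s|%s|%s)", nd$level, q(nd$r), q(nd$g),
                 as.character(nd$b), as.character(nd$a))
  n <- nrow(nd)
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(graph$edges) > 0) {
    fi <- match(graph$edges$from, nd$label)
    ti <- match(graph$edges$to, nd$label)
    for (k in seq_along(fi)) {
      adj[[fi[k]]] <- c(adj[[fi[k]]], ti[k])
      adj[[ti[k]]] <- c(adj[[ti[k]]], fi[k])
    }
  }
  for (iter in seq_len(max(1, n))) {
    newlab <- vapply(seq_len(n), function(i)
      paste0(lab[i], "{", paste(sort(lab[adj[[i]]]), collapse = ","), "}"),
      character(1))
    if (length(unique(newlab)) == length(unique(lab)) && iter > 1) break
    lab <- newlab
  }
  edge_ser <- if (nrow(graph$edges) > 0) {
    fi <- match(graph$edges$from, nd$label)
    ti <- match(graph$edges$to, nd$label)
    pairs <- vapply(seq_along(fi), function(k)
      paste(sort(c(lab[fi[k]], lab[ti[k]])), collapse = "~"), character(1))
    paste(sort(pairs), collapse = ";")
  } else ""
  paste0("V[", paste(sort(lab), collapse = ";"), "]E[", edge_ser, "]")
}

poly_digest <- function(txt) {
  bytes <- utf8ToInt(txt)
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 131 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

#' Archetype record
#'
#' One row of the environmental archetype table: the serialized
#' environment graph, its inner hash, an invariom-style name, the root
#' element, and the instruction templates to instantiate on a matching
#' atom. Template cards use `*` for the root atom; a BEDE template's
#' second field `@El` expands to every bonded neighbor of element `El`
#' (`@*` to every neighbor).
#'
#' @param invariom_name Text name of the atom type.
#' @param graph The [build_environment_graph()] of the reference atom.
#' @param templates Character vector of template card lines.
#' @param root_element Element symbol of the typed atom.
#' @param quantization Hash quantization passed to [graph_hash()].
#' @return An `archetype_record`.
#' @export
archetype_record <- function(invariom_name, graph, templates, root_element,
                             quantization = 0.01) {
  structure(list(invariom_name = invariom_name,
                 serialized_graph = canonical_serialization(graph, quantization),
                 inner_hash = graph_hash(graph, quantization),
                 root_element = toupper(root_element),
                 templates = templates,
                 quantization = quantization,
                 color_summary = graph_color_summary(graph, quantization)),
            class = "archetype_record")
}

graph_color_summary <- function(graph, quantization = 0.01) {
  nd <- graph$nodes
  lapply(0:2, function(lv) {
    sel <- nd$level == lv
    sort(sprintf("%d:%d", round(nd$r[sel] / quantization),
                 round(nd$g[sel] / quantization)))
  })
}

#' Write an archetype database file
#'
#' Line-oriented plain-text table: each record is a block
#' `RECORD name hash element`, one `GRAPH` line holding the canonical
#' serialization, `TEMPLATE` lines with the card skeletons, then `END`.
#'
#' @param records List of [archetype_record()]s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_archetype_db <- function(records, path) {
  lines <- c("# boddr archetype database v1")
  for (r in records) {
    lines <- c(lines,
               sprintf("RECORD %s %s %s %g", r$invariom_name, r$inner_hash,
                       r$root_element, r$quantization),
               paste("GRAPH", r$serialized_graph),
               paste("COLORS", jsonlite::toJSON(r$color_summary)),
               paste("TEMPLATE", r$templates),
               "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an archetype database file
#'
#' @param path File written by [write_archetype_db()].
#' @return List of `archetype_record`s.
#' @export
read_archetype_db <- function(path) {
  lines <- readLines(path, warn = FALSE)
  records <- list()
  cur <- NULL
  for (ln in lines) {
    t <- trimws(ln)
    if (!nzchar(t) || startsWith(t, "#")) next
    tok <- strsplit(t, "\\s+")[[1]]
    if (tok[1] == "RECORD") {
      cur <- list(invariom_name = tok[2], inner_hash = tok[3],
                  root_element = tok[4],
                  quantization = if (length(tok) >= 5) as.numeric(tok[5]) else 0.01,
                  templates = character(0))
    } else if (tok[1] == "GRAPH") {
      cur$serialized_graph <- sub("^GRAPH\\s+", "", t)
    } else if (tok[1] == "COLORS") {
      cur$color_summary <- lapply(
        jsonlite::fromJSON(sub("^COLORS\\s+", "", t), simplifyVector = FALSE),
        function(x) sort(as.character(unlist(x))))
    } else if (tok[1] == "TEMPLATE") {
      cur$templates <- c(cur$templates, sub("^TEMPLATE\\s+", "", t))
    } else if (tok[1] == "END") {
      records <- c(records, list(structure(cur, class = "archetype_record")))
      cur <- NULL
    }
  }
  records
}

#' Automatic instruction assignment from an archetype database
#'
#' For every atom the two-shell environment graph is built and hashed. An
#' exact inner-hash match instantiates the matching record's templates
#' with the actual neighbor labels. When no exact match exists, the
#' nearest record of the same element by a level-wise color-overlap score
#' is used and the atom flagged `fallback`. Elements with no record at
#' all scatter as pure IAM and are flagged `iam` (the model permits
#' mixing aspherical and conventional scattering factors, e.g. for heavy
#' atoms).
#'
#' @param structure A [crystal_structure()].
#' @param database List of [archetype_record()]s.
#' @param connectivity Optional precomputed [build_connectivity()].
#' @return List with `instructions` (cards) and `report` (data frame:
#'   atom, status, record, score).
#' @export
assign_instructions <- function(structure, database, connectivity = NULL) {
  if (length(database) == 0) stop("archetype database is empty")
  if (is.null(connectivity)) connectivity <- build_connectivity(structure)
  atoms <- structure$atoms
  cards <- list()
  rep_rows <- list()
  for (i in seq_len(nrow(atoms))) {
    lb <- atoms$label[i]
    el <- toupper(atoms$element[i])
    g <- build_environment_graph(lb, connectivity, structure)
    cand <- Filter(function(r) r$root_element == el, database)
    status <- "iam"; name <- NA_character_; score <- NA_real_
    chosen <- NULL
    if (length(cand) > 0) {
      hashes <- vapply(cand, `[[`, character(1), "inner_hash")
      qz <- cand[[1]]$quantization
      hit <- which(hashes == graph_hash(g, qz))
      if (length(hit) > 0) {
        chosen <- cand[[hit[1]]]
        status <- "assigned"; score <- 1
      } else {
        scores <- vapply(cand, function(r)
          graph_similarity(graph_color_summary(g, r$quantization),
                           r$color_summary), numeric(1))
        chosen <- cand[[which.max(scores)]]
        status <- "fallback"; score <- max(scores)
      }
      name <- chosen$invariom_name
      cards <- c(cards, instantiate_templates(chosen$templates, lb,
                                              structure, connectivity))
    }
    rep_rows <- c(rep_rows, list(data.frame(atom = lb, status = status,
                                            record = name, score = score,
                                            stringsAsFactors = FALSE)))
  }
  list(instructions = cards, report = do.call(rbind, rep_rows))
}

# level-wise fraction of matching quantized (r, g) colors
graph_similarity <- function(sum_a, sum_b) {
  tot <- 0; match_n <- 0
  for (lv in 1:3) {
    a <- sum_a[[lv]]; b <- sum_b[[lv]]
    tot <- tot + max(length(a), length(b))
    common <- 0
    bb <- b
    for (x in a) {
      j <- match(x, bb)
      if (!is.na(j)) { common <- common + 1; bb <- bb[-j] }
    }
    match_n <- match_n + common
  }
  if (tot == 0) return(1)
  match_n / tot
}

instantiate_templates <- function(templates, root_label, structure,
                                  connectivity) {
  out <- list()
  nbs <- connectivity$neighbors[[root_label]]
  for (tp in templates) {
    tok <- strsplit(trimws(tp), "\\s+")[[1]]
    kw <- toupper(tok[1])
    if (kw == "BEDE") {
      sel <- tok[3]
      targets <- if (sel == "@*") nbs else if (startsWith(sel, "@")) {
        want <- toupper(sub("^@", "", sel))
        nbs[toupper(structure$atoms$element[atom_index(structure, nbs)]) == want]
      } else sel
      v <- as.numeric(tok[4:7])
      for (tg in targets)
        out <- c(out, list(bede(root_label, tg, v[1], v[2], v[3], v[4])))
    } else if (kw == "LONE") {
      m <- as.integer(tok[2])
      v <- as.numeric(tok[4:length(tok)])
      ang <- if (length(v) >= 5) v[5] else NULL
      out <- c(out, list(lone(m, root_label, v[1], v[2], v[3], v[4], ang)))
    } else stop("unknown template card: ", tp)
  }
  out
}
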