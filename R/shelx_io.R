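#' Read a SHELX INS/RES file
#'
#' Parses CELL, ZERR, LATT, SYMM, SFAC (element or full nine-coefficient
#' form), UNIT, FVAR, WGHT, atom records and BEDE/LONE deformation cards.
#' Cards may live inline or in an external file pulled in with the SHELX
#' `+filename` include syntax (one card per line, whitespace-delimited,
#' same token order as inline cards). Two small dialect cards carry the
#' toolkit's extra configuration: `KSCL k_A k_B1 k_B2` (global asphericity
#' scales) and `ELON factor` (riding-H elongation); `RIDE h_label parent`
#' marks a riding hydrogen. Unknown benign keywords are preserved verbatim
#' so that a read/write cycle round-trips them.
#'
#' @param src Path to an INS file, or a character vector of lines.
#' @return List with `structure` (a [crystal_structure()]),
#'   `instructions` (list of [bede()]/[lone()] cards) and
#'   `config` (a [refinement_config()]).
#' @export
read_ins <- function(src) {
  if (length(src) == 1 && !grepl("\n", src) && file.exists(src)) {
    lines <- readLines(src, warn = FALSE)
    base <- dirname(src)
  } else {
    lines <- unlist(strsplit(paste(src, collapse = "\n"), "\n"))
    base <- "."
  }
  lines <- resolve_includes(lines, base)
  lines <- join_continuations(lines)

  cell <- NULL; wavelength <- NA_real_
  latt <- -1L; symm <- list()
  sfac_labels <- character(0); sfac <- list()
  atoms <- list(); cards <- list(); extra <- character(0)
  riding <- list()
  osf <- 1; wa <- 0; wb <- 0
  ks <- c(1, 1, 1); elong <- 1.14
  ignored_kw <- c("TWIN", "BASF", "EXTI", "SWAT", "DISP")

  for (ln in lines) {
    raw <- trimws(ln)
    if (!nzchar(raw)) next
    tok <- strsplit(raw, "\\s+")[[1]]
    kw <- toupper(tok[1])
    if (kw %in% c("END", "HKLF")) break
    if (kw == "TITL" || kw == "REM" || kw == "ZERR" || kw == "UNIT") {
      extra <- c(extra, raw); next
    }
    if (kw %in% ignored_kw) {
      warning("keyword ", kw, " parsed and ignored")
      extra <- c(extra, raw); next
    }
    if (kw == "CELL") {
      v <- as.numeric(tok[-1])
      wavelength <- v[1]; cell <- v[2:7]; next
    }
    if (kw == "LATT") { latt <- as.integer(tok[2]); next }
    if (kw == "SYMM") {
      symm <- c(symm, list(parse_symm(sub("^\\S+\\s+", "", raw)))); next
    }
    if (kw == "SFAC") {
      if (length(tok) >= 10 && !is.na(suppressWarnings(as.numeric(tok[3])))) {
        v <- as.numeric(tok[3:11])
        el <- toupper(tok[2])
        sfac[[el]] <- structure(list(a = v[c(1, 3, 5, 7)], b = v[c(2, 4, 6, 8)],
                                     c = v[9], z = round(sum(v[c(1, 3, 5, 7)]) + v[9])),
                                class = "gaussian_coefficients")
        sfac_labels <- c(sfac_labels, el)
      } else {
        for (el in toupper(tok[-1])) {
          sfac[[el]] <- sfac_coefficients(el)
          sfac_labels <- c(sfac_labels, el)
        }
      }
      next
    }
    if (kw == "FVAR") { osf <- as.numeric(tok[2]); next }
    if (kw == "WGHT") {
      wa <- as.numeric(tok[2])
      wb <- if (length(tok) >= 3) as.numeric(tok[3]) else 0
      next
    }
    if (kw == "KSCL") { ks <- as.numeric(tok[2:4]); next }
    if (kw == "ELON") { elong <- as.numeric(tok[2]); next }
    if (kw == "RIDE") { riding[[tok[2]]] <- tok[3]; next }
    if (kw == "BEDE") {
      v <- as.numeric(tok[4:7])
      cards <- c(cards, list(bede(tok[2], tok[3], v[1], v[2], v[3], v[4])))
      next
    }
    if (kw == "LONE") {
      m <- as.integer(tok[2])
      v <- as.numeric(tok[4:length(tok)])
      ang <- if (length(v) >= 5) v[5] else NULL
      cards <- c(cards, list(lone(m, tok[3], v[1], v[2], v[3], v[4], ang)))
      next
    }
    # atom record: label sfac# x y z sof [U...]
    if (length(tok) >= 5 && length(sfac_labels) > 0 &&
        !is.na(suppressWarnings(as.integer(tok[2]))) &&
        !is.na(suppressWarnings(as.numeric(tok[3])))) {
      v <- as.numeric(tok[-(1:2)])
      isf <- as.integer(tok[2])
      if (isf < 1 || isf > length(sfac_labels))
        stop("atom ", tok[1], " references SFAC index ", isf, " out of range")
      sof <- if (length(v) >= 4) v[4] else 11
      occ <- if (sof > 5) sof - 10 else sof
      at <- list(label = tok[1], element = sfac_labels[isf],
                 x = v[1], y = v[2], z = v[3], occ = occ,
                 aniso = FALSE, uiso = 0.03,
                 u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
                 u23 = NA_real_, u13 = NA_real_, u12 = NA_real_,
                 riding_parent = NA_character_)
      if (length(v) >= 10) {
        at$aniso <- TRUE
        at[c("u11", "u22", "u33", "u23", "u13", "u12")] <- as.list(v[5:10])
        at$uiso <- NA_real_
      } else if (length(v) >= 5) {
        at$uiso <- v[5]
      }
      atoms <- c(atoms, list(at))
      next
    }
    extra <- c(extra, raw)
  }

  if (is.null(cell)) stop("fatal: INS file has no CELL card")
  if (length(atoms) == 0) stop("fatal: INS file has no atom records")
  adf <- do.call(rbind, lapply(atoms, function(a) as.data.frame(a, stringsAsFactors = FALSE)))
  for (h in names(riding)) {
    i <- match(h, adf$label)
    if (is.na(i)) stop("RIDE names unknown atom '", h, "'")
    adf$riding_parent[i] <- riding[[h]]
  }
  ops <- latt_ops(latt, symm)
  st <- crystal_structure(cell, adf, ops, wavelength = wavelength, sfac = sfac)
  st$extra_cards <- extra
  st$latt <- latt
  st$sfac_order <- sfac_labels
  # validate card atom references
  for (cd in cards) {
    labs <- if (cd$kind == "BEDE") c(cd$atom1, cd$atom2) else cd$atom
    bad <- setdiff(labs, adf$label)
    if (length(bad))
      stop("instruction card references unknown atom label(s): ",
           paste(bad, collapse = ", "))
  }
  cfg <- refinement_config(osf = osf, k_A = ks[1], k_B1 = ks[2], k_B2 = ks[3],
                           weight_a = wa, weight_b = wb, elongation = elong)
  list(structure = st, instructions = cards, config = cfg)
}

resolve_includes <- function(lines, base) {
  out <- character(0)
  for (ln in lines) {
    t <- trimws(ln)
    if (startsWith(t, "+")) {
      f <- sub("^\\+\\s*", "", t)
      path <- if (file.exists(f)) f else file.path(base, f)
      if (!file.exists(path)) stop("include file not found: ", f)
      out <- c(out, readLines(path, warn = FALSE))
    } else out <- c(out, ln)
  }
  out
}

join_continuations <- function(lines) {
  out <- character(0)
  buf <- NULL
  for (ln in lines) {
    t <- sub("\\s+$", "", ln)
    if (!is.null(buf)) { t <- paste(buf, sub("^\\s+", "", t)); buf <- NULL }
    if (grepl("=\\s*$", t)) { buf <- sub("=\\s*$", "", t); next }
    out <- c(out, t)
  }
  if (!is.null(buf)) out <- c(out, buf)
  out
}

parse_symm <- function(txt) {
  parts <- strsplit(toupper(gsub("\\s", "", txt)), ",")[[1]]
  if (length(parts) != 3) stop("malformed SYMM card: ", txt)
  R <- matrix(0, 3, 3); tvec <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize into signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (term in terms) {
      sign <- if (startsWith(term, "-")) -1 else 1
      body <- sub("^[+-]", "", term)
      axis <- regmatches(body, regexpr("[XYZ]", body))
      coef <- gsub("[XYZ*/]*$", "", sub("[XYZ]", "", body))
      if (length(axis) == 1) {
        num <- sub("\\*?[XYZ]\\*?", "", body)
        val <- if (nzchar(num)) parse_frac(num) else 1
        j <- match(axis, c("X", "Y", "Z"))
        R[i, j] <- R[i, j] + sign * val
      } else {
        tvec[i] <- tvec[i] + sign * parse_frac(body)
      }
    }
  }
  cbind(R, tvec)
}

parse_frac <- function(x) {
  x <- gsub("\\*", "", x)
  if (grepl("/", x)) {
    p <- as.numeric(strsplit(x, "/")[[1]])
    p[1] / p[2]
  } else as.numeric(x)
}

format_symm <- function(op) {
  ax <- c("X", "Y", "Z")
  comps <- vapply(1:3, function(i) {
    s <- ""
    if (abs(op[i, 4]) > 1e-9) s <- sprintf("%.5g", op[i, 4])
    for (j in 1:3) {
      c <- op[i, j]
      if (abs(c) < 1e-9) next
      sg <- if (c < 0) "-" else if (nzchar(s)) "+" else ""
      mag <- if (abs(abs(c) - 1) < 1e-9) "" else sprintf("%.5g*", abs(c))
      s <- paste0(s, sg, mag, ax[j])
    }
    s
  }, character(1))
  paste(comps, collapse = ", ")
}

latt_ops <- function(latt, symm) {
  ops <- normalize_symm_ops(symm)
  cent <- switch(as.character(abs(latt)),
    "1" = matrix(0, 1, 3),
    "2" = rbind(c(0, 0, 0), c(0.5, 0.5, 0.5)),
    "3" = rbind(c(0, 0, 0), c(2 / 3, 1 / 3, 1 / 3), c(1 / 3, 2 / 3, 2 / 3)),
    "4" = rbind(c(0, 0, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5), c(0.5, 0.5, 0)),
    "5" = rbind(c(0, 0, 0), c(0, 0.5, 0.5)),
    "6" = rbind(c(0, 0, 0), c(0.5, 0, 0.5)),
    "7" = rbind(c(0, 0, 0), c(0.5, 0.5, 0)),
    stop("unsupported LATT code ", latt))
  if (latt > 0) ops <- c(ops, lapply(ops, function(m) cbind(-m[, 1:3], -m[, 4])))
  out <- list()
  for (i in seq_len(nrow(cent)))
    for (op in ops)
      out <- c(out, list(cbind(op[, 1:3], op[, 4] + cent[i, ])))
  out
}

#' Write a SHELX RES file
#'
#' Inverse of [read_ins()]: `read_ins(write_res(x))` reproduces the
#' structure, instruction cards and configuration up to floating-point
#' formatting. Preserved unknown keywords are re-emitted verbatim.
#'
#' @param structure A [crystal_structure()].
#' @param instructions List of BEDE/LONE cards (may be empty).
#' @param config A [refinement_config()].
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of lines, invisibly when written to `path`.
#' @export
write_res <- function(structure, instructions = list(),
                      config = refinement_config(), path = NULL) {
  st <- structure
  sfac_order <- st$sfac_order
  if (is.null(sfac_order)) sfac_order <- names(st$sfac)
  lines <- c(
    sprintf("CELL %.5f %.6f %.6f %.6f %.4f %.4f %.4f",
            st$wavelength, st$cell[1], st$cell[2], st$cell[3],
            st$cell[4], st$cell[5], st$cell[6]),
    sprintf("LATT %d", if (is.null(st$latt)) -1L else st$latt))
  for (op in drop_identity(st$symmetry_ops))
    lines <- c(lines, paste("SYMM", format_symm(op)))
  lines <- c(lines, paste("SFAC", paste(sfac_order, collapse = " ")))
  lines <- c(lines, st$extra_cards)
  lines <- c(lines,
             sprintf("FVAR %.6f", config$osf),
             sprintf("WGHT %.6f %.6f", config$weight_a, config$weight_b),
             sprintf("KSCL %.6f %.6f %.6f", config$k_A, config$k_B1, config$k_B2),
             sprintf("ELON %.6f", config$elongation))
  a <- st$atoms
  for (i in seq_len(nrow(a))) {
    if (!is.na(a$riding_parent[i]))
      lines <- c(lines, sprintf("RIDE %s %s", a$label[i], a$riding_parent[i]))
  }
  for (i in seq_len(nrow(a))) {
    isf <- match(toupper(a$element[i]), sfac_order)
    head <- sprintf("%-5s %d %11.7f %11.7f %11.7f %10.7f",
                    a$label[i], isf, a$x[i], a$y[i], a$z[i], 10 + a$occ[i])
    if (a$aniso[i]) {
      lines <- c(lines, paste0(head, sprintf(" %.7f %.7f =", a$u11[i], a$u22[i])),
                 sprintf("   %.7f %.7f %.7f %.7f",
                         a$u33[i], a$u23[i], a$u13[i], a$u12[i]))
    } else {
      lines <- c(lines, paste0(head, sprintf(" %.7f", a$uiso[i])))
    }
  }
  for (cd in instructions) lines <- c(lines, format(cd))
  lines <- c(lines, "HKLF 4", "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

drop_identity <- function(ops) {
  ident <- cbind(diag(3), c(0, 0, 0))
  Filter(function(m) !all(abs(m - ident) < 1e-9), ops)
}

#' Read a SHELX HKLF 4 reflection file
#'
#' Fixed-width records 3I4 + 2F8 holding h k l Fo^2 sigma(Fo^2); the
#' conventional 0 0 0 terminator row ends the file and is not stored.
#' Symmetry-equivalent duplicates of the same h k l are merged with a
#' 1/sigma^2-weighted mean; reflections with sigma <= 0 are dropped with
#' a warning.
#'
#' @param src File path or character vector of lines.
#' @param cell Optional six lattice parameters; when given, the resolution
#'   column `s` = sin(theta)/lambda is filled in.
#' @return A `reflection_set` data frame: h, k, l, fo2, sigma, s.
#' @export
read_hkl <- function(src, cell = NULL) {
  lines <- if (length(src) == 1 && !grepl("\n", src) && file.exists(src))
    readLines(src, warn = FALSE)
  else unlist(strsplit(paste(src, collapse = "\n"), "\n"))
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  rec <- matrix(NA_real_, n, 5)
  for (i in seq_len(n)) {
    ln <- lines[i]
    if (nchar(ln) < 28) ln <- formatC(ln, width = -28)
    f <- c(substr(ln, 1, 4), substr(ln, 5, 8), substr(ln, 9, 12),
           substr(ln, 13, 20), substr(ln, 21, 28))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v[1:5]) && anyNA(suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))))
      stop("non-numeric field in HKL line ", i, ": ", lines[i])
    if (anyNA(v)) v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])[1:5]
    if (anyNA(v)) stop("non-numeric field in HKL line ", i, ": ", lines[i])
    rec[i, ] <- v
  }
  term <- rowSums(abs(rec[, 1:3, drop = FALSE])) == 0
  if (any(term)) rec <- rec[seq_len(which(term)[1] - 1), , drop = FALSE]
  bad <- rec[, 5] <= 0
  if (any(bad)) {
    warning(sum(bad), " reflection(s) with sigma <= 0 excluded")
    rec <- rec[!bad, , drop = FALSE]
  }
  df <- data.frame(h = rec[, 1], k = rec[, 2], l = rec[, 3],
                   fo2 = rec[, 4], sigma = rec[, 5])
  key <- paste(df$h, df$k, df$l)
  if (anyDuplicated(key)) {
    w <- 1 / df$sigma^2
    agg <- lapply(split(seq_len(nrow(df)), key), function(ix) {
      ws <- w[ix]
      c(df$h[ix[1]], df$k[ix[1]], df$l[ix[1]],
        sum(ws * df$fo2[ix]) / sum(ws), sqrt(1 / sum(ws)))
    })
    m <- do.call(rbind, agg)
    df <- data.frame(h = m[, 1], k = m[, 2], l = m[, 3],
                     fo2 = m[, 4], sigma = m[, 5])
    df <- df[order(df$h, df$k, df$l), ]
    rownames(df) <- NULL
  }
  df$s <- if (!is.null(cell)) s_of_hkl(as.matrix(df[, 1:3]), cell) else NA_real_
  class(df) <- c("reflection_set", "data.frame")
  df
}

#' Write a SHELX HKLF 4 reflection file
#'
#' @param refl A `reflection_set` data frame.
#' @param path Output path; `NULL` returns the lines.
#' @return Lines, invisibly when written.
#' @export
write_hkl <- function(refl, path = NULL) {
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f",
                   as.integer(refl$h), as.integer(refl$k), as.integer(refl$l),
                   refl$fo2, refl$sigma)
  lines <- c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0L, 0L, 0L, 0, 0))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Write an FCF-style phased reflection listing
#'
#' Plain-text columns h k l Fo^2 sigma Fc^2 phase(deg), the standard
#' LIST-style output used downstream for map synthesis.
#'
#' @param refl Reflection set with fo2/sigma.
#' @param fc Complex calculated structure factors matching `refl` rows.
#' @param path Output path; `NULL` returns the lines.
#' @return Lines, invisibly when written.
#' @export
write_fcf <- function(refl, fc, path = NULL) {
  lines <- c("# h k l Fo2 sigma Fc2 phase",
             sprintf("%4d%4d%4d %11.4f %10.4f %11.4f %8.2f",
                     as.integer(refl$h), as.integer(refl$k), as.integer(refl$l),
                     refl$fo2, refl$sigma, Mod(fc)^2, Arg(fc) * 180 / pi))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Attach resolution to a reflection set
#'
#' @param refl Reflection set.
#' @param cell Six lattice parameters.
#' @return The set with `s` = sin(theta)/lambda recomputed.
#' @export
attach_resolution <- function(refl, cell) {
  refl$s <- s_of_hkl(as.matrix(refl[, c("h", "k", "l")]), cell)
  refl
}
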