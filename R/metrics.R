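#' Crystallographic residuals
#'
#' R1 = sum | |Fo| - |Fc| | / sum |Fo| over reflections with
#' Fo^2 > threshold * sigma (conventional observed cut, default 2);
#' wR2 = sqrt(sum w (Fo^2 - Fc^2)^2 / sum w (Fo^2)^2) over all
#' reflections; GooF = sqrt(sum w (Fo^2 - Fc^2)^2 / (n - p)).
#'
#' @param fo2,sigma Observed intensities and esds.
#' @param fc2 Calculated intensities on the observed scale.
#' @param weights Weight vector (see [compute_weights()]).
#' @param threshold Observed criterion multiplier on sigma for R1.
#' @param n_params Parameter count for the GooF denominator.
#' @return Named vector R1, wR2, GooF.
#' @export
r_factors <- function(fo2, sigma, fc2, weights = 1 / sigma^2,
                      threshold = 2, n_params = 1) {
  stopifnot(length(fo2) == length(fc2), length(fo2) == length(sigma))
  sel <- fo2 > threshold * sigma
  if (!any(sel)) stop("no reflections satisfy the observed criterion")
  fo <- sqrt(pmax(fo2[sel], 0)); fc <- sqrt(pmax(fc2[sel], 0))
  r1 <- sum(abs(fo - fc)) / sum(fo)
  wr2 <- sqrt(sum(weights * (fo2 - fc2)^2) / sum(weights * fo2^2))
  goof <- sqrt(sum(weights * (fo2 - fc2)^2) /
                 max(length(fo2) - n_params, 1))
  c(R1 = r1, wR2 = wr2, GooF = goof)
}

#' Cross-validated R_complete
#'
#' Reflections are partitioned into k seeded random folds. For each fold
#' the model is re-refined with that fold excluded, after a small seeded
#' coordinate shake decorrelates the start from the full-data solution;
#' the excluded reflections' amplitude residual contributions are then
#' computed from that refinement. R_complete assembles all excluded-set
#' contributions over all reflections, so every reflection is evaluated
#' by a model that never saw it. The gap between R_complete and R1
#' measures overfitting bias.
#'
#' @param structure Refined [crystal_structure()] to start folds from.
#' @param instructions BEDE/LONE cards (empty for IAM).
#' @param reflections Reflection set.
#' @param config [refinement_config()] of the converged model.
#' @param k Number of folds (>= 2).
#' @param seed RNG seed for partition and shake.
#' @param shake Coordinate shake amplitude in Angstrom (default 0.005).
#' @param threshold R1 observed cut, as in [r_factors()].
#' @param ... Passed to [refine_structure()] (e.g. `refine_k`, `ride`).
#' @return R_complete (scalar) with attribute `folds_used`.
#' @export
rcomplete <- function(structure, instructions, reflections, config,
                      k = 10, seed = 1, shake = 0.005, threshold = 2, ...) {
  if (k < 2) stop("k must be at least 2")
  n <- nrow(reflections)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  m <- cell_metrics(structure$cell)
  num <- 0; den <- 0; used <- 0
  for (f in seq_len(k)) {
    ex <- fold == f
    st <- structure
    sh <- matrix(stats::rnorm(3 * nrow(st$atoms), 0, shake), ncol = 3)
    shf <- sh %*% t(m$frac)
    st$atoms$x <- st$atoms$x + shf[, 1]
    st$atoms$y <- st$atoms$y + shf[, 2]
    st$atoms$z <- st$atoms$z + shf[, 3]
    res <- tryCatch(
      refine_structure(st, instructions, reflections, config,
                       free_mask = ex, ...),
      error = function(e) NULL)
    if (is.null(res) || !res$converged) {
      warning("R_complete fold ", f, " did not converge; excluded")
      next
    }
    hkl <- as.matrix(reflections[ex, c("h", "k", "l")])
    placed <- expand_instructions(instructions, res$structure)
    fc2 <- Mod(structure_factor(res$structure, placed, res$config, hkl))^2
    sel <- reflections$fo2[ex] > threshold * reflections$sigma[ex]
    if (!any(sel)) next
    fo <- sqrt(pmax(reflections$fo2[ex][sel], 0))
    fc <- sqrt(pmax(fc2[sel], 0))
    num <- num + sum(abs(fo - fc))
    den <- den + sum(fo)
    used <- used + 1
  }
  if (den == 0) stop("R_complete: no usable folds")
  structure(num / den, folds_used = used)
}

#' Model-bias statistic b
#'
#' Default definition: b = (Rcomplete_IAM - R1_IAM) -
#' (Rcomplete_BODD - R1_BODD), the change in the cross-validation gap. A
#' positive b means the deformation model shrank the gap, i.e. reduced
#' bias; a negative b means bias was added. The definition is a named,
#' swappable strategy (`definition` may be a function of the four
#' arguments) because competing conventions exist.
#'
#' @param r1_iam,r1_bodd Working R1 of the two models.
#' @param rc_iam,rc_bodd R_complete of the two models.
#' @param definition "gap_difference" (default) or a function.
#' @return Scalar b.
#' @export
bias_b <- function(r1_iam, r1_bodd, rc_iam, rc_bodd,
                   definition = "gap_difference") {
  if (is.function(definition))
    return(definition(r1_iam, r1_bodd, rc_iam, rc_bodd))
  switch(definition,
         gap_difference = (rc_iam - r1_iam) - (rc_bodd - r1_bodd),
         stop("unknown bias definition '", definition, "'"))
}

#' ADP comparison statistics
#'
#' Component-wise differences of corresponding displacement parameters
#' between two models of the same atoms (a - b convention). Anisotropic
#' atoms contribute their six U_ij, isotropic atoms one U_iso. Reported
#' are the mean difference MD and its population standard deviation
#' (divisor N, the root-mean-square deviation about MD).
#'
#' @param model_a,model_b Two [crystal_structure()]s with identical atom
#'   labels.
#' @param elements Optional element filter (e.g. exclude hydrogens with
#'   `elements = setdiff(unique(...), "H")`).
#' @return An `adp_comparison`: list(MD, sd, n, differences).
#' @export
adp_stats <- function(model_a, model_b, elements = NULL) {
  a <- model_a$atoms; b <- model_b$atoms
  if (!setequal(a$label, b$label))
    stop("atom label mismatch: ",
         paste(c(setdiff(a$label, b$label), setdiff(b$label, a$label)),
               collapse = ", "))
  d <- numeric(0)
  for (lb in a$label) {
    i <- match(lb, a$label); j <- match(lb, b$label)
    if (!is.null(elements) && !toupper(a$element[i]) %in% toupper(elements))
      next
    if (a$aniso[i] != b$aniso[j])
      stop("atom ", lb, " is anisotropic in one model only")
    if (a$aniso[i]) {
      cols <- c("u11", "u22", "u33", "u23", "u13", "u12")
      d <- c(d, unlist(a[i, cols]) - unlist(b[j, cols]))
    } else {
      d <- c(d, a$uiso[i] - b$uiso[j])
    }
  }
  n <- length(d)
  md <- mean(d)
  sd_ <- sqrt(mean((d - md)^2))
  structure(list(MD = md, sd = sd_, n = n, differences = unname(d)),
            class = "adp_comparison")
}

#' IAM-versus-BODD metrics report
#'
#' Convenience wrapper collecting the paired quality indicators: R1 of
#' both models, their difference, R_complete of both, the bias statistic
#' and the two overall scale factors.
#'
#' @param iam,bodd Two `refinement_result`s for the same data.
#' @param reflections Reflection set both models were refined against.
#' @param instructions The BODD card list (IAM is card-free).
#' @param k,seed R_complete controls.
#' @param ... Passed to [rcomplete()].
#' @return A `metrics_report` list.
#' @export
metrics_report <- function(iam, bodd, reflections, instructions,
                           k = 10, seed = 1, ...) {
  rc_iam <- rcomplete(iam$structure, list(), reflections, iam$config,
                      k = k, seed = seed, refine_k = FALSE, ...)
  rc_bodd <- rcomplete(bodd$structure, instructions, reflections,
                       bodd$config, k = k, seed = seed, ...)
  b <- bias_b(iam$r1, bodd$r1, as.numeric(rc_iam), as.numeric(rc_bodd))
  structure(list(r1_iam = iam$r1, r1_bodd = bodd$r1,
                 delta_r1 = iam$r1 - bodd$r1,
                 rcomplete_iam = as.numeric(rc_iam),
                 rcomplete_bodd = as.numeric(rc_bodd),
                 bias_b = b,
                 osf_iam = iam$config$osf, osf_bodd = bodd$config$osf),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("R1(IAM) = %.4f  R1(BODD) = %.4f  dR1 = %.4f\n",
              x$r1_iam, x$r1_bodd, x$delta_r1))
  cat(sprintf("Rcomplete(IAM) = %.4f  Rcomplete(BODD) = %.4f  b = %.4f\n",
              x$rcomplete_iam, x$rcomplete_bodd, x$bias_b))
  cat(sprintf("OSF(IAM) = %.4f  OSF(BODD) = %.4f\n", x$osf_iam, x$osf_bodd))
  invisible(x)
}
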