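#' nCounter normalization chain
#'
#' Normalizes raw nCounter counts in the standard order: (1) per-sample
#' positive-control scaling to the cohort geometric mean of positive-control
#' geometric means; (2) background subtraction using the negative-control
#' probes (policy configurable: mean, mean + 2 SD, or max), floored at zero;
#' (3) per-sample scaling by the geometric mean of the reference
#' (housekeeping) genes, computed after steps 1-2, to the cohort geometric
#' mean; (4) log2(x + 1). Control and reference probes are removed from the
#' output.
#'
#' After step 3 every sample has an identical reference-gene geometric mean,
#' and rescaling a whole sample by a constant leaves its normalized values
#' unchanged (the positive-control step cancels global factors).
#'
#' @param raw an [expression_matrix()] with platform `"ncounter-raw"`.
#' @param background background policy, one of `"mean"`, `"mean_2sd"`, `"max"`.
#' @param flag_range scale factors outside this range are flagged in the
#'   report (assay QC hint; no values are altered).
#' @return list with `matrix` (log2 [expression_matrix()] of endogenous genes,
#'   platform `"ncounter-normalized"`) and `report` (per-sample data frame of
#'   scale factors, background levels and flags).
#' @export
normalize_ncounter <- function(raw, background = c("mean", "mean_2sd", "max"),
                               flag_range = c(1 / 3, 3)) {
  background <- match.arg(background)
  if (raw$platform != "ncounter-raw")
    stopf("normalize_ncounter expects platform 'ncounter-raw', got '%s'", raw$platform)
  v <- raw$values
  roles <- raw$gene_roles
  pos <- names(roles)[roles == "positive-control"]
  neg <- names(roles)[roles == "negative-control"]
  ref <- names(roles)[roles == "reference"]
  endo <- names(roles)[roles == "endogenous"]
  if (!length(pos) || !length(neg) || !length(ref))
    stopf("need at least one positive-control, negative-control and reference probe")

  # (1) positive-control scaling
  pos_gm <- apply(v[pos, , drop = FALSE], 2, geomean)
  if (any(pos_gm == 0))
    stopf("zero positive-control geometric mean in sample(s): %s",
          paste(colnames(v)[pos_gm == 0], collapse = ", "))
  pos_factor <- geomean(pos_gm) / pos_gm
  v <- sweep(v, 2, pos_factor, `*`)

  # (2) negative-control background, floored at zero
  negv <- v[neg, , drop = FALSE]
  bg <- switch(background,
               mean = colMeans(negv),
               mean_2sd = colMeans(negv) + 2 * apply(negv, 2, stats::sd),
               max = apply(negv, 2, max))
  keep <- c(endo, ref)
  v[keep, ] <- pmax(sweep(v[keep, , drop = FALSE], 2, bg, `-`), 0)

  # (3) reference-gene scaling (geomeans after steps 1-2)
  ref_gm <- apply(v[ref, , drop = FALSE], 2, geomean)
  if (any(ref_gm == 0))
    stopf("reference-gene geometric mean is zero after background subtraction in sample(s): %s",
          paste(colnames(v)[ref_gm == 0], collapse = ", "))
  ref_factor <- geomean(ref_gm) / ref_gm
  v[keep, ] <- sweep(v[keep, , drop = FALSE], 2, ref_factor, `*`)

  out <- expression_matrix(log2(v[endo, , drop = FALSE] + 1),
                           "ncounter-normalized",
                           stats::setNames(rep("endogenous", length(endo)), endo))
  report <- data.frame(
    sample_id = colnames(v),
    pos_scale = unname(pos_factor),
    background = unname(bg),
    ref_scale = unname(ref_factor),
    flagged = pos_factor < flag_range[1] | pos_factor > flag_range[2] |
      ref_factor < flag_range[1] | ref_factor > flag_range[2],
    stringsAsFactors = FALSE)
  attr(report, "assumptions") <-
    sprintf("background policy = %s of negative controls; pipeline order = positive-control scaling, background subtraction, reference-gene scaling, log2(x+1)",
            background)
  class(report) <- c("normalization_report", "data.frame")
  list(matrix = out, report = report)
}

#' Quantile normalization of a log2 matrix
#'
#' Forces every sample (column) to share the same distribution: the mean of
#' the across-sample order statistics. Ties within a sample receive the mean
#' of the quantile values they span. Backed by
#' [limma::normalizeQuantiles()][limma::normalizeQuantiles].
#'
#' @param x an [expression_matrix()] on the log2 scale, at least 2 samples,
#'   no missing values.
#' @return an [expression_matrix()] of the same shape and platform.
#' @export
quantile_normalize <- function(x) {
  if (x$platform == "ncounter-raw")
    stopf("quantile_normalize expects log2-scale values")
  if (ncol(x$values) < 2) stopf("quantile normalization needs >= 2 samples")
  if (any(is.na(x$values)))
    stopf("missing values are not allowed (imputation is out of scope)")
  q <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(q) <- dimnames(x$values)
  expression_matrix(q, x$platform, x$gene_roles)
}

#' Normalize a cohort's expression according to its platform
#'
#' Raw nCounter counts go through [normalize_ncounter()]; log2 microarray
#' values are quantile normalized (keeping only endogenous and reference
#' genes, the latter dropped from the result for symmetry with the nCounter
#' path).
#'
#' @param expr an [expression_matrix()].
#' @param ... passed to [normalize_ncounter()].
#' @return list with `matrix` and (for nCounter input) `report`.
#' @export
normalize_cohort <- function(expr, ...) {
  if (expr$platform == "ncounter-raw") return(normalize_ncounter(expr, ...))
  q <- quantile_normalize(expr)
  endo <- genes(q, role = "endogenous")
  list(matrix = subset_em(q, genes = endo), report = NULL)
}
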