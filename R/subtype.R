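#' Call MIBC subtypes by consensus-panel clustering
#'
#' Samples are clustered on their per-gene z-scored consensus-gene profiles
#' (distance 1 - Pearson across genes, Ward agglomeration, tree cut at k = 3).
#' Each cluster is then named after the signature whose mean z-score is
#' highest in it, via the same optimal 3!-permutation assignment used for
#' gene-cluster labeling; the p53-like signature labels the "infiltrated"
#' subtype (the alias is kept in the result).
#'
#' @param x a log2-scale [expression_matrix()].
#' @param consensus a `consensus_panel` (from [intersect_cohorts()] or
#'   [panel_consensus()]).
#' @param k number of sample clusters.
#' @param min_present minimum fraction of consensus genes that must be present
#'   in `x`.
#' @return a `subtype_assignment` data frame: `sample_id`, `subtype`
#'   (luminal/basal/infiltrated), `cluster`, `score_basal`, `score_luminal`,
#'   `score_infiltrated`; attributes `method = "cluster"`, `alias`, `hclust`.
#' @export
call_subtypes <- function(x, consensus, k = 3, min_present = 0.8) {
  cg <- consensus_genes(consensus)
  present <- intersect(cg, rownames(x$values))
  if (length(present) < min_present * length(cg))
    stopf("only %d/%d consensus genes present (< %d%%)",
          length(present), length(cg), round(100 * min_present))
  if (length(present) < length(cg))
    message(sprintf("note: %d consensus gene(s) missing from matrix",
                    length(cg) - length(present)))
  if (ncol(x$values) < k) stopf("need at least k = %d samples", k)
  z <- zscore_rows(x$values[present, , drop = FALSE])
  d <- stats::as.dist(1 - stats::cor(z))
  hc <- stats::hclust(d, method = "ward.D")
  cl <- stats::cutree(hc, k = k)

  scores <- signature_scores(z, consensus)
  labs <- c("basal", "luminal", "p53-like")
  M <- t(vapply(1:k, function(ci) colMeans(scores[cl == ci, , drop = FALSE]),
                numeric(3)))
  colnames(M) <- labs
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  sc <- vapply(perms, function(p) sum(M[cbind(1:3, p)]), numeric(1))
  best <- which(abs(sc - max(sc)) < 1e-12)
  if (length(best) > 1)
    stopf("ambiguous cluster-to-subtype assignment (tied signature scores)")
  assign <- stats::setNames(labs[perms[[best]]], 1:3)
  subtype <- unname(assign[as.character(cl)])
  subtype[subtype == "p53-like"] <- "infiltrated"

  out <- data.frame(sample_id = colnames(x$values),
                    subtype = factor(subtype, levels = subtype_levels),
                    cluster = unname(cl),
                    score_basal = scores[, "basal"],
                    score_luminal = scores[, "luminal"],
                    score_infiltrated = scores[, "p53-like"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("subtype_assignment", "data.frame"),
            method = "cluster", alias = c(infiltrated = "p53-like"),
            hclust = hc)
}

# per-sample mean z-score of each signature (columns basal, luminal, p53-like)
signature_scores <- function(z, consensus) {
  labs <- c("basal", "luminal", "p53-like")
  s <- vapply(labs, function(l) {
    g <- intersect(consensus$sets[[l]], rownames(z))
    if (!length(g)) return(rep(NA_real_, ncol(z)))
    colMeans(z[g, , drop = FALSE])
  }, numeric(ncol(z)))
  if (!is.matrix(s)) s <- matrix(s, ncol = 3, dimnames = list(NULL, labs))
  rownames(s) <- colnames(z)
  s
}

#' Fit subtype centroids from a reference cohort
#'
#' Per-subtype mean of the per-gene z-scored consensus-gene expression, for
#' nearest-centroid prediction of a new cohort.
#'
#' @param x the reference log2 [expression_matrix()].
#' @param assignment a `subtype_assignment` covering the samples of `x`.
#' @param consensus the `consensus_panel` used for the assignment.
#' @return a `subtype_centroids` object: genes x 3 matrix plus the consensus.
#' @export
fit_centroids <- function(x, assignment, consensus) {
  cg <- intersect(consensus_genes(consensus), rownames(x$values))
  z <- zscore_rows(x$values[cg, , drop = FALSE])
  st <- stats::setNames(as.character(assignment$subtype), assignment$sample_id)
  st <- st[colnames(z)]
  if (any(is.na(st))) stopf("assignment does not cover all samples")
  cnt <- table(factor(st, levels = subtype_levels))
  if (any(cnt == 0))
    stopf("subtype(s) with 0 samples: %s", paste(names(cnt)[cnt == 0], collapse = ", "))
  cen <- vapply(subtype_levels, function(s)
    rowMeans(z[, st == s, drop = FALSE]), numeric(nrow(z)))
  structure(list(centroids = cen, consensus = consensus),
            class = "subtype_centroids")
}

#' Predict subtypes by Pearson nearest centroid
#'
#' Each new sample is assigned the subtype of the centroid with the highest
#' Pearson correlation to its z-scored consensus-gene profile; the margin
#' between the best and second-best correlation is reported per sample. An
#' exact correlation tie is a hard error naming the sample.
#'
#' @param x the new cohort's log2 [expression_matrix()].
#' @param centroids a `subtype_centroids` from [fit_centroids()].
#' @param min_present minimum fraction of centroid genes required in `x`.
#' @return a `subtype_assignment` with `method = "centroid"` and a `margin`
#'   column.
#' @export
predict_subtypes <- function(x, centroids, min_present = 0.8) {
  cen <- centroids$centroids
  present <- intersect(rownames(cen), rownames(x$values))
  if (length(present) < min_present * nrow(cen))
    stopf("only %d/%d centroid genes present (< %d%%)",
          length(present), nrow(cen), round(100 * min_present))
  z <- zscore_rows(x$values[present, , drop = FALSE])
  r <- stats::cor(z, cen[present, ])   # samples x subtypes
  ord <- t(apply(r, 1, order, decreasing = TRUE))
  best <- subtype_levels[ord[, 1]]
  margin <- r[cbind(seq_len(nrow(r)), ord[, 1])] -
    r[cbind(seq_len(nrow(r)), ord[, 2])]
  if (any(margin == 0))
    stopf("exact centroid-correlation tie for sample(s): %s",
          paste(rownames(r)[margin == 0], collapse = ", "))
  scores <- signature_scores(z, centroids$consensus)
  out <- data.frame(sample_id = colnames(x$values),
                    subtype = factor(best, levels = subtype_levels),
                    cluster = ord[, 1],
                    score_basal = scores[, "basal"],
                    score_luminal = scores[, "luminal"],
                    score_infiltrated = scores[, "p53-like"],
                    margin = margin,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("subtype_assignment", "data.frame"),
            method = "centroid", alias = c(infiltrated = "p53-like"))
}

#' Dichotomize an assignment into luminal vs non-luminal
#'
#' @param assignment a `subtype_assignment`.
#' @return named integer vector, 1 for luminal and 0 for basal/infiltrated.
#' @export
stratify_luminal <- function(assignment) {
  stats::setNames(as.integer(assignment$subtype == "luminal"),
                  assignment$sample_id)
}
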