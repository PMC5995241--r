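#' Hierarchical clustering of panel genes
#'
#' Clusters genes on correlation distance d(g, h) = 1 - Pearson(g, h) across
#' samples with Ward agglomeration, and cuts the tree into exactly `k`
#' clusters. Genes are z-scored across samples first by default (correlation
#' is scale-free but Ward merge heights are not, so standardization makes
#' cohorts comparable).
#'
#' @param x a log2-scale [expression_matrix()].
#' @param gene_ids genes to cluster (default: all endogenous genes of `x`).
#' @param k number of clusters.
#' @param standardize z-score genes across samples before clustering.
#' @param ward_on `"distance"` applies the Ward update to d = 1 - r directly
#'   (hclust `ward.D`); `"squared"` uses squared dissimilarities (`ward.D2`).
#' @return list with `clusters` (named integer vector gene -> cluster index)
#'   and `hclust` (the linkage record, for audit).
#' @export
cluster_genes <- function(x, gene_ids = NULL, k = 3, standardize = TRUE,
                          ward_on = c("distance", "squared")) {
  ward_on <- match.arg(ward_on)
  gene_ids <- gene_ids %||% genes(x, role = "endogenous")
  miss <- setdiff(gene_ids, rownames(x$values))
  if (length(miss)) stopf("gene(s) not in matrix: %s", paste(miss, collapse = ", "))
  m <- x$values[gene_ids, , drop = FALSE]
  vr <- row_sds(m)^2
  if (any(vr == 0))
    stopf("zero-variance gene(s), correlation undefined: %s",
          paste(gene_ids[vr == 0], collapse = ", "))
  if (standardize) m <- zscore_rows(m)
  d <- stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(d, method = if (ward_on == "distance") "ward.D" else "ward.D2")
  list(clusters = stats::cutree(hc, k = k), hclust = hc)
}

#' Semi-supervised labeling of gene clusters
#'
#' Assigns the labels basal / luminal / p53-like to the k = 3 gene clusters
#' using seed marker lists: over all 3! label permutations, the one
#' maximizing the total number of seed markers falling in their matching
#' cluster is chosen. A tie between permutations is a hard error (supply more
#' seed markers) rather than a silent guess.
#'
#' @param clustering result of [cluster_genes()] with k = 3.
#' @param seeds named list of seed marker vectors for `basal`, `luminal`,
#'   `p53-like` (see [seed_markers()]).
#' @param cohort optional cohort identifier carried through to the consensus.
#' @return a `labeled_gene_clusters` object: `gene_labels` (named character),
#'   `cluster_labels`, `overlap` (cluster x label seed-hit matrix), `hclust`,
#'   `cohort`.
#' @export
label_clusters <- function(clustering, seeds, cohort = NA_character_) {
  cl <- clustering$clusters
  k <- length(unique(cl))
  labs <- c("basal", "luminal", "p53-like")
  if (k != 3) stopf("label_clusters requires exactly 3 clusters, got %d", k)
  if (!all(labs %in% names(seeds))) stopf("seeds must name basal, luminal, p53-like")
  for (l in labs) if (!any(seeds[[l]] %in% names(cl)))
    stopf("no seed marker of label '%s' present among the clustered genes", l)
  ov <- matrix(0L, 3, 3, dimnames = list(cluster = 1:3, label = labs))
  for (ci in 1:3) for (l in labs)
    ov[ci, l] <- sum(seeds[[l]] %in% names(cl)[cl == ci])
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  score <- vapply(perms, function(p) sum(ov[cbind(1:3, p)]), numeric(1))
  best <- which(score == max(score))
  if (length(best) > 1)
    stopf("ambiguous cluster labeling (total seed overlap %d achieved by %d permutations); supply more seed markers",
          max(score), length(best))
  assign <- stats::setNames(labs[perms[[best]]], 1:3)
  structure(list(gene_labels = stats::setNames(unname(assign[as.character(cl)]),
                                               names(cl)),
                 cluster_labels = assign, overlap = ov,
                 hclust = clustering$hclust, cohort = cohort),
            class = "labeled_gene_clusters")
}

new_consensus_panel <- function(sets, unstable, n_cohorts, provenance = NULL) {
  structure(list(sets = sets, unstable = unstable, n_cohorts = n_cohorts,
                 provenance = provenance),
            class = "consensus_panel")
}

#' Cross-cohort consensus panel by Venn intersection
#'
#' A gene enters the consensus set of a label only if it carried that label in
#' every cohort; genes with discordant labels across cohorts are reported as
#' unstable with their per-cohort labels. Only genes present in all cohorts
#' are considered.
#'
#' @param labeled list of [label_clusters()] results, one per cohort (>= 2).
#' @param require_nonempty error (TRUE) or warn (FALSE, default) when a
#'   label's consensus set comes out empty.
#' @return a `consensus_panel`: `sets` (label -> genes), `unstable` (data
#'   frame of discordant genes with per-cohort labels), `n_cohorts`,
#'   `provenance` (gene x cohort label matrix).
#' @export
intersect_cohorts <- function(labeled, require_nonempty = FALSE) {
  if (length(labeled) < 2) stopf("need labeled clusters from >= 2 cohorts")
  glists <- lapply(labeled, `[[`, "gene_labels")
  universe <- Reduce(intersect, lapply(glists, names))
  prov <- vapply(glists, function(gl) gl[universe], character(length(universe)))
  rownames(prov) <- universe
  cid <- vapply(seq_along(labeled), function(i)
    if (is.na(labeled[[i]]$cohort)) paste0("cohort", i) else labeled[[i]]$cohort,
    character(1))
  colnames(prov) <- cid
  concordant <- apply(prov, 1, function(r) length(unique(r)) == 1)
  labs <- c("basal", "luminal", "p53-like")
  sets <- lapply(labs, function(l) universe[concordant & prov[, 1] == l])
  names(sets) <- labs
  for (l in labs) if (!length(sets[[l]])) {
    if (require_nonempty) stopf("empty consensus set for label '%s'", l)
    warnf("empty consensus set for label '%s'", l)
  }
  unstable <- data.frame(gene = universe[!concordant],
                         prov[!concordant, , drop = FALSE],
                         row.names = NULL, check.names = FALSE)
  new_consensus_panel(sets, unstable, length(labeled), prov)
}

#' @export
print.consensus_panel <- function(x, ...) {
  cat(sprintf("consensus_panel: %d genes (basal %d, luminal %d, p53-like/infiltrated %d), %d cohorts, %d unstable\n",
              sum(lengths(x$sets)), length(x$sets[["basal"]]),
              length(x$sets[["luminal"]]), length(x$sets[["p53-like"]]),
              x$n_cohorts, nrow(x$unstable)))
  invisible(x)
}

#' Genes of a consensus panel
#' @param consensus a `consensus_panel`.
#' @export
consensus_genes <- function(consensus) unname(unlist(consensus$sets))

#' Derive a consensus panel from normalized cohorts
#'
#' Convenience wrapper running [cluster_genes()] and [label_clusters()] on
#' each cohort and intersecting the labels.
#'
#' @param mats list of normalized log2 [expression_matrix()]s.
#' @param panel the [gene_panel()] defining subtyping genes and seed markers.
#' @param k number of gene clusters.
#' @param ... passed to [cluster_genes()].
#' @return a `consensus_panel`.
#' @export
derive_consensus <- function(mats, panel, k = 3, ...) {
  seeds <- seed_markers(panel)
  labeled <- lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    gs <- intersect(subtyping_genes(panel), rownames(m$values))
    label_clusters(cluster_genes(m, gs, k = k, ...), seeds,
                   cohort = names(mats)[i] %||% paste0("cohort", i))
  })
  intersect_cohorts(labeled)
}
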