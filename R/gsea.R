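#' Rank genes by differential expression between two phenotype classes
#'
#' Orders genes by a signal-to-noise ratio (difference of class means over the
#' sum of class standard deviations, with the usual floor of each SD at 20% of
#' the absolute class mean) or a two-sample t statistic, descending; ties are
#' broken deterministically by gene symbol. Positive scores mean higher
#' expression in the positive class.
#'
#' @param x log2 [expression_matrix()].
#' @param phenotype logical vector (aligned with samples or named by sample
#'   id); `TRUE` is the positive class. Both classes need >= 3 samples (the
#'   signal-to-noise variance floor is undefined below that).
#' @param metric `"signal2noise"` or `"t"`.
#' @return data frame `gene`, `score`, ordered by decreasing score.
#' @export
rank_genes <- function(x, phenotype, metric = c("signal2noise", "t")) {
  metric <- match.arg(metric)
  if (!is.null(names(phenotype))) phenotype <- phenotype[colnames(x$values)]
  phenotype <- as.logical(phenotype)
  if (length(phenotype) != ncol(x$values) || any(is.na(phenotype)))
    stopf("phenotype must cover every sample")
  if (sum(phenotype) < 3 || sum(!phenotype) < 3)
    stopf("each phenotype class needs >= 3 samples")
  a <- x$values[, phenotype, drop = FALSE]
  b <- x$values[, !phenotype, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  sa <- row_sds(a); sb <- row_sds(b)
  score <- if (metric == "signal2noise") {
    sa <- pmax(sa, 0.2 * abs(ma), 0.2)
    sb <- pmax(sb, 0.2 * abs(mb), 0.2)
    (ma - mb) / (sa + sb)
  } else {
    (ma - mb) / sqrt(sa^2 / ncol(a) + sb^2 / ncol(b) + 1e-12)
  }
  ord <- order(-score, rownames(x$values))
  data.frame(gene = rownames(x$values)[ord], score = unname(score[ord]),
             stringsAsFactors = FALSE)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Running-sum statistic over a ranked gene list: hits increment by
#' |score|^p normalized over the in-set total, misses decrement by
#' 1/(N - Nh); the enrichment score is the extremum (maximum deviation from
#' zero, signed). When the set spans the whole list there are no misses and
#' the running sum climbs monotonically to 1.
#'
#' @param ranked data frame `gene`, `score` from [rank_genes()].
#' @param gene_set character vector; must intersect the list.
#' @param p hit weight exponent (1 = standard weighted statistic).
#' @return list with `es` and `running` (the full running-sum curve).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  hit <- ranked$gene %in% gene_set
  if (!any(hit)) stopf("gene set is disjoint from the ranked list")
  N <- nrow(ranked); Nh <- sum(hit)
  w <- abs(ranked$score)^p
  wh <- sum(w[hit])
  if (wh == 0) w[hit] <- 1 / Nh else w[hit] <- w[hit] / wh
  inc <- ifelse(hit, w, if (N > Nh) -1 / (N - Nh) else 0)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' Gene-set enrichment test by phenotype permutation
#'
#' Computes the observed enrichment score, then permutes the phenotype labels
#' to build the null: the nominal p is the add-one-smoothed fraction of
#' same-sign permuted scores at least as extreme as the observed one (so p is
#' never 0 and has resolution 1/(n_perm + 1)); NES is the observed score over
#' the mean magnitude of same-sign permuted scores; the FDR q follows the
#' standard NES-ratio construction (for a single set it reduces to the
#' fraction of same-sign permuted NES beating the observed NES, capped at 1).
#' When fewer distinct labelings exist than requested permutations the
#' permutation space is enumerated exhaustively with a warning.
#'
#' @param x log2 [expression_matrix()].
#' @param phenotype logical class labels (see [rank_genes()]).
#' @param gene_set character vector of set members.
#' @param n_perm number of label permutations (>= 100).
#' @param seed RNG seed; all randomness derives from it.
#' @param metric ranking metric, see [rank_genes()].
#' @param weight hit weight exponent.
#' @return a `gsea_result` list: `es`, `nes`, `p.value`, `fdr_q`, `n_perm`,
#'   `seed`, `metric`, `exhaustive`.
#' @export
gsea_test <- function(x, phenotype, gene_set, n_perm = 1000, seed = 1,
                      metric = "signal2noise", weight = 1) {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  if (!is.null(names(phenotype))) phenotype <- phenotype[colnames(x$values)]
  phenotype <- as.logical(phenotype)
  obs <- enrichment_score(rank_genes(x, phenotype, metric), gene_set, weight)$es
  n <- length(phenotype); n1 <- sum(phenotype)
  n_distinct <- choose(n, n1)
  exhaustive <- n_distinct <= n_perm
  perm_es <- with_seed(seed, {
    if (exhaustive) {
      warnf("only %d distinct labelings; enumerating exhaustively", n_distinct)
      cmb <- utils::combn(n, n1)
      vapply(seq_len(ncol(cmb)), function(j) {
        ph <- rep(FALSE, n); ph[cmb[, j]] <- TRUE
        enrichment_score(rank_genes(x, ph, metric), gene_set, weight)$es
      }, numeric(1))
    } else {
      vapply(seq_len(n_perm), function(j) {
        ph <- sample(phenotype)
        enrichment_score(rank_genes(x, ph, metric), gene_set, weight)$es
      }, numeric(1))
    }
  })
  same <- perm_es[sign(perm_es) == sign(obs)]
  p <- (1 + sum(abs(same) >= abs(obs))) / (1 + length(same))
  denom <- if (length(same)) mean(abs(same)) else abs(obs)
  nes <- obs / denom
  nes_perm <- same / denom
  q <- if (length(same)) min(1, sum(abs(nes_perm) >= abs(nes)) /
                               max(1, length(same)) / (1 / 1)) else p
  structure(list(es = obs, nes = nes, p.value = p, fdr_q = max(q, 0),
                 n_perm = length(perm_es), seed = seed, metric = metric,
                 exhaustive = exhaustive),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("gsea_result: ES = %.3f, NES = %.3f, p = %.4g, FDR q = %.3g (%d permutations%s)\n",
              x$es, x$nes, x$p.value, x$fdr_q, x$n_perm,
              if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}
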