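#' Exact r x c Fisher test (Freeman-Halton)
#'
#' Two-sided exact test for an r x c contingency table under the
#' multivariate-hypergeometric null with fixed margins, using the
#' probability-ordering rule: p is the total probability of all tables with
#' the observed margins whose probability does not exceed that of the
#' observed table (up to a small relative tolerance on the comparison, since
#' floating-point table probabilities that are mathematically equal can
#' differ in the last bits). Tables are enumerated exactly while the
#' enumeration stays below `cap` tables; beyond that a margin-preserving
#' Monte-Carlo estimate (via [r2dtable()]) with a fixed seed is returned
#' instead. Table probabilities are computed in log space.
#'
#' @param tab matrix of non-negative integer counts, at least 2 x 2, no
#'   all-zero row or column margin.
#' @param cap maximum number of tables to enumerate exactly.
#' @param mc_reps Monte-Carlo replicates for the fallback.
#' @param mc_seed seed of the Monte-Carlo fallback.
#' @param rel_tol relative tolerance of the probability-ordering comparison.
#' @return a `group_test_result` list: `test`, `p.value`, `method`
#'   (`"exact-enumeration"` or `"monte-carlo"`), `n_tables` (enumerated) or
#'   `mc_reps`/`mc_seed`.
#' @export
fisher_exact_rxc <- function(tab, cap = 5e6, mc_reps = 1e5, mc_seed = 1,
                             rel_tol = 1e-7) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stopf("table must be at least 2 x 2")
  if (any(tab < 0) || any(tab != round(tab))) stopf("counts must be non-negative integers")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stopf("margin with all zeros")
  n <- sum(tab)
  const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  logp_obs <- const - sum(lgamma(tab + 1))
  thresh <- logp_obs + log1p(rel_tol)

  lp <- enumerate_logp(rs, cs, const, cap)
  if (!is.null(lp)) {
    return(structure(list(test = "fisher-exact-rxc",
                          p.value = min(1, sum(exp(lp[lp <= thresh]))),
                          method = "exact-enumeration",
                          n_tables = length(lp)),
                     class = "group_test_result"))
  }
  lp <- with_seed(mc_seed, {
    tabs <- stats::r2dtable(mc_reps, rs, cs)
    vapply(tabs, function(tb) const - sum(lgamma(tb + 1)), numeric(1))
  })
  structure(list(test = "fisher-exact-rxc",
                 p.value = (1 + sum(lp <= thresh)) / (mc_reps + 1),
                 method = "monte-carlo", mc_reps = mc_reps, mc_seed = mc_seed),
            class = "group_test_result")
}

# all compositions of s into length(bounds) cells with 0 <= x_i <= bounds_i
compositions <- function(s, bounds) {
  C <- length(bounds)
  if (C == 1) {
    if (s > bounds) return(matrix(numeric(0), 0, 1))
    return(matrix(s, 1, 1))
  }
  g <- as.matrix(expand.grid(lapply(bounds[-C], function(b) 0:min(s, b)),
                             KEEP.OUT.ATTRS = FALSE))
  last <- s - rowSums(g)
  ok <- last >= 0 & last <= bounds[C]
  unname(cbind(g[ok, , drop = FALSE], last[ok]))
}

# log-probabilities of every table with the given margins, or NULL if the
# enumeration would exceed cap tables
enumerate_logp <- function(rs, cs, const, cap) {
  R <- length(rs)
  partial <- matrix(0, 1, length(cs))
  acc <- 0
  for (i in seq_len(R - 1)) {
    cmp <- compositions(rs[i], pmin(rs[i], cs))
    lf <- rowSums(lgamma(cmp + 1))
    nP <- nrow(partial); K <- nrow(cmp)
    if (nP * K > cap) return(NULL)
    newp <- partial[rep(seq_len(nP), each = K), , drop = FALSE] +
      cmp[rep(seq_len(K), nP), , drop = FALSE]
    newacc <- acc[rep(seq_len(nP), each = K)] + lf[rep(seq_len(K), nP)]
    rem <- sum(rs[(i + 1):R])
    ok <- colSums(t(newp) > cs) == 0 & colSums(cs - t(newp) > rem) == 0
    partial <- newp[ok, , drop = FALSE]
    acc <- newacc[ok]
    if (!nrow(partial)) break
  }
  last <- sweep(-partial, 2, cs, `+`)
  const - (acc + rowSums(lgamma(last + 1)))
}

#' Kruskal-Wallis rank test
#'
#' H statistic with midranks and tie correction, p from the chi-square
#' distribution with df = groups - 1 (via [stats::kruskal.test()]). The
#' degenerate all-values-tied case returns H = 0, p = 1 by convention.
#'
#' @param values_by_group list of >= 2 non-empty numeric vectors.
#' @return a `group_test_result` list: `test`, `statistic` (H), `df`,
#'   `p.value`.
#' @export
kruskal_wallis <- function(values_by_group) {
  if (length(values_by_group) < 2) stopf("need >= 2 groups")
  ns <- lengths(values_by_group)
  if (any(ns == 0)) stopf("empty group(s): %s",
                          paste(which(ns == 0), collapse = ", "))
  x <- unlist(values_by_group)
  if (length(x) < 3) stopf("need total n >= 3")
  g <- factor(rep(seq_along(values_by_group), ns))
  df <- length(values_by_group) - 1
  if (length(unique(x)) == 1)
    return(structure(list(test = "kruskal-wallis", statistic = 0, df = df,
                          p.value = 1), class = "group_test_result"))
  kt <- stats::kruskal.test(x, g)
  structure(list(test = "kruskal-wallis", statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p.value = kt$p.value),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("%s: p = %.4g%s%s\n", x$test, x$p.value,
              if (!is.null(x$statistic)) sprintf(", statistic = %.4g (df = %d)",
                                                 x$statistic, x$df) else "",
              if (!is.null(x$method)) paste0(" [", x$method, "]") else ""))
  invisible(x)
}

#' Subtype-specific drug-target screen
#'
#' Tests each drug-target gene for subtype-specific expression with a
#' Kruskal-Wallis test across the called subtypes on normalized expression,
#' reporting the subtype with the highest median as direction. Targets must
#' be disjoint from the subtyping gene set so that their subtype attribution
#' is independent of the clustering; unadjusted p-values are reported.
#'
#' @param x normalized log2 [expression_matrix()].
#' @param assignment a `subtype_assignment` covering the samples.
#' @param target_genes character vector of drug-target genes.
#' @param consensus optional `consensus_panel`; any target overlapping its
#'   genes is a hard error.
#' @return data frame `gene`, `H`, `df`, `p`, `direction`.
#' @export
drug_target_screen <- function(x, assignment, target_genes, consensus = NULL) {
  if (!is.null(consensus)) {
    bad <- intersect(target_genes, consensus_genes(consensus))
    if (length(bad))
      stopf("target gene(s) overlap the subtyping panel: %s",
            paste(bad, collapse = ", "))
  }
  miss <- setdiff(target_genes, rownames(x$values))
  if (length(miss)) stopf("target gene(s) absent from matrix: %s",
                          paste(miss, collapse = ", "))
  st <- stats::setNames(as.character(assignment$subtype), assignment$sample_id)
  st <- st[colnames(x$values)]
  if (any(is.na(st))) stopf("assignment does not cover all samples")
  res <- lapply(target_genes, function(g) {
    v <- x$values[g, ]
    by_g <- split(v, factor(st, levels = subtype_levels))
    kt <- kruskal_wallis(by_g)
    med <- vapply(by_g, stats::median, numeric(1))
    data.frame(gene = g, H = kt$statistic, df = kt$df, p = kt$p.value,
               direction = names(med)[which.max(med)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
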