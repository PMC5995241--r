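#' Expression matrix container
#'
#' A genes-by-samples expression grid with a platform tag and a probe role for
#' every gene. Counts from the nCounter platform are non-negative integers
#' (`platform = "ncounter-raw"`); normalized nCounter data and microarray
#' intensities are on the log2 scale.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param platform one of `"ncounter-raw"`, `"ncounter-normalized"`,
#'   `"log2-array"`.
#' @param gene_roles named character vector mapping every gene to one of
#'   `"endogenous"`, `"reference"`, `"positive-control"`, `"negative-control"`.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, platform, gene_roles) {
  platforms <- c("ncounter-raw", "ncounter-normalized", "log2-array")
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("'values' needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene id: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample id: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  platform <- match.arg(platform, platforms)
  miss <- setdiff(rownames(values), names(gene_roles))
  if (length(miss))
    stopf("no probe role for gene(s): %s", paste(miss, collapse = ", "))
  gene_roles <- gene_roles[rownames(values)]
  roles <- c("endogenous", "reference", "positive-control", "negative-control")
  bad <- setdiff(unique(gene_roles), roles)
  if (length(bad)) stopf("unknown probe role(s): %s", paste(bad, collapse = ", "))
  if (platform == "ncounter-raw") {
    if (any(is.na(values))) stopf("raw counts must not be missing")
    if (any(values < 0) || any(values != round(values))) {
      idx <- which(values < 0 | values != round(values), arr.ind = TRUE)[1, ]
      stopf("invalid raw count %s for gene '%s' in sample '%s' (counts must be non-negative integers)",
            format(values[idx[1], idx[2]]), rownames(values)[idx[1]],
            colnames(values)[idx[2]])
    }
  }
  structure(list(values = values, platform = platform, gene_roles = gene_roles),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(x$gene_roles)
  cat(sprintf("expression_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$platform))
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Gene ids of an expression matrix
#' @param x an [expression_matrix()].
#' @param role optional probe role filter.
#' @export
genes <- function(x, role = NULL) {
  g <- rownames(x$values)
  if (!is.null(role)) g <- g[x$gene_roles[g] %in% role]
  g
}

#' Sample ids of an expression matrix
#' @param x an [expression_matrix()].
#' @export
samples <- function(x) colnames(x$values)

# subset an expression matrix by gene and/or sample ids
subset_em <- function(x, genes = NULL, samples = NULL) {
  g <- genes %||% rownames(x$values)
  s <- samples %||% colnames(x$values)
  expression_matrix(x$values[g, s, drop = FALSE], x$platform, x$gene_roles[g])
}
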