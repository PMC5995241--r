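#' Read raw nCounter counts
#'
#' Reads either a genes-by-samples TSV (first column `gene`, optional second
#' column `role`, remaining columns one per sample) or an RCC-style per-sample
#' count file with `CodeClass`/`Name`/`Count` columns. Probe roles come from
#' the file's role/CodeClass column when present, otherwise from `panel`.
#'
#' @param path file path (for RCC-style input, a vector of per-sample files).
#' @param panel optional [gene_panel()] supplying probe roles; required when
#'   the file carries no role column. A gene present in the file but absent
#'   from the panel is an error.
#' @return An [expression_matrix()] with platform `"ncounter-raw"`.
#' @export
read_counts <- function(path, panel = NULL) {
  first <- readLines(path[1], n = 1L)
  if (grepl("^CodeClass", first)) return(read_rcc(path))
  if (length(path) != 1L) stopf("TSV input must be a single file")
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene" %in% names(d)) stopf("count TSV needs a 'gene' column")
  gene <- as.character(d$gene)
  if (anyDuplicated(gene))
    stopf("duplicate gene id: %s", paste(unique(gene[duplicated(gene)]), collapse = ", "))
  has_role <- "role" %in% names(d)
  if (has_role) roles <- stats::setNames(as.character(d$role), gene)
  else {
    if (is.null(panel)) stopf("file has no 'role' column and no panel was given")
    miss <- setdiff(gene, panel$gene)
    if (length(miss))
      stopf("gene(s) absent from panel roles: %s", paste(miss, collapse = ", "))
    roles <- stats::setNames(panel$role[match(gene, panel$gene)], gene)
  }
  vals <- as.matrix(d[, setdiff(names(d), c("gene", "role")), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- gene
  check_counts(vals)
  expression_matrix(vals, "ncounter-raw", roles)
}

check_counts <- function(vals) {
  if (!is.numeric(vals)) stopf("counts must be numeric")
  bad <- which(is.na(vals) | vals < 0 | vals != round(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, ]
    stopf("invalid count %s for gene '%s' in sample '%s'",
          format(vals[i[1], i[2]]), rownames(vals)[i[1]], colnames(vals)[i[2]])
  }
}

rcc_role <- c(Endogenous = "endogenous", Housekeeping = "reference",
              Positive = "positive-control", Negative = "negative-control")

#' Read RCC-style per-sample count files
#'
#' Each file holds one sample as `CodeClass<TAB>Name<TAB>Count` rows; the
#' sample id is the file name without extension.
#'
#' @param paths character vector of file paths, one per sample.
#' @return An [expression_matrix()] with platform `"ncounter-raw"`.
#' @export
read_rcc <- function(paths) {
  per <- lapply(paths, function(p) {
    d <- utils::read.delim(p, stringsAsFactors = FALSE)
    if (!all(c("CodeClass", "Name", "Count") %in% names(d)))
      stopf("'%s' is not an RCC-style file (needs CodeClass/Name/Count)", p)
    if (anyDuplicated(d$Name))
      stopf("duplicate gene id in '%s': %s", p,
            paste(unique(d$Name[duplicated(d$Name)]), collapse = ", "))
    bad <- setdiff(unique(d$CodeClass), names(rcc_role))
    if (length(bad)) stopf("unknown CodeClass in '%s': %s", p, paste(bad, collapse = ", "))
    d
  })
  g0 <- per[[1]]$Name
  for (d in per) if (!identical(d$Name, g0))
    stopf("RCC files disagree on probe set or order")
  vals <- vapply(per, function(d) as.numeric(d$Count), numeric(length(g0)))
  if (!is.matrix(vals)) vals <- matrix(vals, ncol = length(per))
  rownames(vals) <- g0
  colnames(vals) <- sub("\\.[^.]*$", "", basename(paths))
  check_counts(vals)
  expression_matrix(vals, "ncounter-raw",
                    stats::setNames(unname(rcc_role[per[[1]]$CodeClass]), g0))
}

#' Write an expression matrix as TSV
#'
#' Genes in rows with `gene` and `role` columns, one column per sample.
#' Counts are written as integers; log2 values with 6 significant digits so
#' that write/read round-trips are exact.
#'
#' @param x an [expression_matrix()].
#' @param path output file.
#' @export
write_expression <- function(x, path) {
  v <- x$values
  chr <- if (x$platform == "ncounter-raw") format(v, trim = TRUE, scientific = FALSE)
         else vapply(seq_len(ncol(v)), function(j)
           formatC(v[, j], format = "g", digits = 6), character(nrow(v)))
  chr <- matrix(as.character(chr), nrow = nrow(v), dimnames = dimnames(v))
  d <- data.frame(gene = rownames(v), role = unname(x$gene_roles[rownames(v)]),
                  chr, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a log2 expression TSV written by [write_expression()]
#'
#' @param path file path.
#' @param platform platform tag of the stored values.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, platform = "log2-array") {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("gene", "role") %in% names(d)))
    stopf("expression TSV needs 'gene' and 'role' columns")
  vals <- as.matrix(d[, setdiff(names(d), c("gene", "role")), drop = FALSE])
  rownames(vals) <- d$gene
  expression_matrix(vals, platform, stats::setNames(d$role, d$gene))
}

clinical_levels <- list(
  sex = c("F", "M"),
  stage = c("pTa/pT1/pTis", "pT2", "pT3", "pT4"),
  node = c("N0", "N+"),
  metastasis = c("M0", "M+"))

#' Read a clinical table
#'
#' Expects a TSV with columns `sample_id, age, sex, stage, node, metastasis,
#' nac, ac, os_time, os_event, dss_time, dss_event`. Missing cells are empty
#' strings on disk and become `NA` in memory — never dropped. Stage labels
#' `pTa`, `pT1`, `pTis` are folded into the combined non-muscle-invasive
#' category `pTa/pT1/pTis`.
#'
#' @param path file path.
#' @return a `clinical_table` data frame with typed columns.
#' @export
read_clinical <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = "character")
  as_clinical(d)
}

#' Coerce a data frame to a typed clinical table
#' @param d data frame with the clinical columns (character or typed).
#' @export
as_clinical <- function(d) {
  need <- c("sample_id", "age", "sex", "stage", "node", "metastasis",
            "nac", "ac", "os_time", "os_event", "dss_time", "dss_event")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("clinical table lacks column(s): %s", paste(miss, collapse = ", "))
  out <- data.frame(sample_id = as.character(d$sample_id), stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) stopf("duplicate sample_id in clinical table")
  out$age <- as.numeric(d$age)
  st <- as.character(d$stage)
  st[st %in% c("pTa", "pT1", "pTis")] <- "pTa/pT1/pTis"
  for (col in names(clinical_levels)) {
    v <- if (col == "stage") st else as.character(d[[col]])
    bad <- setdiff(v[!is.na(v)], clinical_levels[[col]])
    if (length(bad))
      stopf("unparseable %s label(s): %s", col, paste(unique(bad), collapse = ", "))
    out[[col]] <- factor(v, levels = clinical_levels[[col]])
  }
  for (col in c("nac", "ac")) {
    v <- d[[col]]
    if (!is.logical(v)) v <- as.logical(as.integer(v))
    out[[col]] <- v
  }
  for (col in c("os_time", "dss_time")) {
    v <- as.numeric(d[[col]])
    if (any(v < 0, na.rm = TRUE))
      stopf("negative %s for sample(s): %s", col,
            paste(out$sample_id[which(v < 0)], collapse = ", "))
    out[[col]] <- v
  }
  for (col in c("os_event", "dss_event")) {
    v <- d[[col]]
    if (!is.logical(v)) v <- as.logical(as.integer(v))
    out[[col]] <- v
  }
  out <- out[c("sample_id", "age", "sex", "stage", "node", "metastasis",
               "nac", "ac", "os_time", "os_event", "dss_time", "dss_event")]
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Write a clinical table as TSV (missing values as empty cells)
#' @param x a clinical table.
#' @param path output file.
#' @export
write_clinical <- function(x, path) {
  d <- as.data.frame(x)
  for (col in c("nac", "ac", "os_event", "dss_event"))
    d[[col]] <- as.integer(d[[col]])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then tab-separated member symbols.
#' Duplicate members within a line are removed with a warning.
#'
#' @param path file path.
#' @return named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("GMT line %d has fewer than 3 fields", i)
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warnf("GMT set '%s' (line %d) has duplicate members; de-duplicated", f[1], i)
      members <- unique(members)
    }
    if (f[1] %in% names(sets)) stopf("duplicate GMT set name '%s'", f[1])
    sets[[f[1]]] <- members
    desc[f[1]] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description optional named descriptions.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  desc <- description %||% attr(sets, "description") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
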