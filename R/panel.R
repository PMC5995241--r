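#' Gene panel construction
#'
#' A gene panel describes every probe the screening assay carries: the
#' subtyping genes with their signature group (basal, luminal, p53-like, or
#' the late-cell-cycle axis shared by basal and luminal tumors), the drug
#' target genes kept out of the subtyping set so their subtype attribution can
#' be tested independently, the reference (housekeeping) genes used for
#' normalization, and the positive/negative control probes.
#'
#' @param gene character vector of unique gene/probe identifiers.
#' @param role probe role, one of `"endogenous"`, `"reference"`,
#'   `"positive-control"`, `"negative-control"`.
#' @param group signature group for endogenous probes: `"basal"`, `"luminal"`,
#'   `"p53-like"`, `"late-cycle"` or `"drug-target"`; `NA` for non-endogenous
#'   probes.
#' @param seed logical; is the gene one of the named seed markers anchoring
#'   the semi-supervised cluster labeling?
#' @param core logical; does the gene belong to the stable consensus core used
#'   as ground truth by the synthetic-cohort generator?
#' @param immune logical; does the gene carry immune/inflammation signal
#'   (elevated further in infiltrated tumors)?
#' @return A `gene_panel` data frame.
#' @export
gene_panel <- function(gene, role, group = NA_character_, seed = FALSE,
                       core = FALSE, immune = FALSE) {
  roles <- c("endogenous", "reference", "positive-control", "negative-control")
  p <- data.frame(gene = as.character(gene), role = as.character(role),
                  group = as.character(group), seed = as.logical(seed),
                  core = as.logical(core), immune = as.logical(immune),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(p$gene)) stopf("duplicate gene in panel: %s",
                                   paste(unique(p$gene[duplicated(p$gene)]), collapse = ", "))
  bad <- setdiff(p$role, roles)
  if (length(bad)) stopf("unknown probe role(s): %s", paste(bad, collapse = ", "))
  class(p) <- c("gene_panel", "data.frame")
  p
}

#' Default 64-gene MIBC subtyping panel
#'
#' Builds the package's default assay design: 64 subtyping genes split into
#' basal, luminal, p53-like and late-cell-cycle signature groups (anchored by
#' the canonical urothelial markers, e.g. KRT5/KRT14 for basal, KRT20/UPK2 for
#' luminal, immune genes FAS/NCAM1/CCL2/CD14 for p53-like), 14 drug-target
#' genes excluded from subtyping, the 6 reference genes CALM2, RPL37A, B2M,
#' TUBB, GAPDH and G6PD, 6 positive and 8 negative control probes.
#'
#' The 36 genes flagged `core` (16 basal, 8 luminal, 12 p53-like) are the
#' stable consensus core the synthetic multicohort generator treats as ground
#' truth; the remaining 28 subtyping genes are eligible to be planted as
#' cohort-unstable.
#'
#' @return A [gene_panel()] data frame with 98 probes.
#' @export
default_panel <- function() {
  basal_core <- c("KRT5", "KRT14", "CD44", "KRT6A", "KRT6B", "KRT16", "KRT1",
                  "CDH3", "TP63", "DSC3", "GSDMC", "TGM1", "PI3", "VIM",
                  "ZEB2", "MSN")
  luminal_core <- c("KRT20", "UPK2", "PPARG", "FGFR3", "CD24", "UPK1A",
                    "UPK3A", "GPX2")
  p53_core <- c("FAS", "NCAM1", "CCL2", "CD14", "MDM4", "CDK6", "CDKN1A",
                "CXCL12", "CCL5", "CD2", "HLA-DRA", "C1QA")
  late_cycle <- c("AURKA", "AURKB", "CCNB1", "CCNA2", "MAD2L1")
  basal_extra <- c("SERPINB3", "SERPINB4", "SFN", "COL17A1", "ITGA6", "ITGB4",
                   "PLAU", "MMP9")
  luminal_extra <- c("GATA3", "FOXA1", "ERBB3", "XBP1", "KRT18", "KRT8",
                     "SPINK1")
  p53_extra <- c("ACTG2", "CNN1", "MYH11", "DES", "PGM5", "CD3E", "PTPRC",
                 "CSF1R")
  targets <- c("ERBB2", "EGFR", "ERBB4", "FGFR1", "FGFR2", "FGFR4", "PDGFRB",
               "AR", "ESR1", "ESR2", "PGR", "CLDN3", "CLDN4", "CLDN7")
  refs <- c("CALM2", "RPL37A", "B2M", "TUBB", "GAPDH", "G6PD")
  pos <- paste0("POS_", LETTERS[1:6])
  neg <- paste0("NEG_", LETTERS[1:8])

  seeds <- c("KRT5", "KRT14", "CD44", "KRT20", "UPK2", "PPARG", "FGFR3",
             "CD24", "FAS", "NCAM1", "CCL2", "CD14", "MDM4", "CDK6", "CDKN1A")
  immune <- c("FAS", "NCAM1", "CCL2", "CD14", "CXCL12", "CCL5", "CD2",
              "HLA-DRA", "C1QA", "CD3E", "PTPRC", "CSF1R")

  gene <- c(basal_core, basal_extra, luminal_core, luminal_extra, p53_core,
            p53_extra, late_cycle, targets, refs, pos, neg)
  group <- c(rep("basal", length(basal_core) + length(basal_extra)),
             rep("luminal", length(luminal_core) + length(luminal_extra)),
             rep("p53-like", length(p53_core) + length(p53_extra)),
             rep("late-cycle", length(late_cycle)),
             rep("drug-target", length(targets)),
             rep(NA_character_, length(refs) + length(pos) + length(neg)))
  role <- c(rep("endogenous", 64 + length(targets)),
            rep("reference", length(refs)),
            rep("positive-control", length(pos)),
            rep("negative-control", length(neg)))
  core <- gene %in% c(basal_core, luminal_core, p53_core)
  gene_panel(gene, role, group, seed = gene %in% seeds, core = core,
             immune = gene %in% immune)
}

#' Subtyping genes of a panel
#'
#' @param panel a [gene_panel()].
#' @param core_only keep only the stable consensus core.
#' @return character vector of gene symbols.
#' @export
subtyping_genes <- function(panel, core_only = FALSE) {
  keep <- panel$role == "endogenous" &
    panel$group %in% c("basal", "luminal", "p53-like", "late-cycle")
  if (core_only) keep <- keep & panel$core
  panel$gene[keep]
}

#' Drug-target genes of a panel
#' @inheritParams subtyping_genes
#' @export
drug_target_genes <- function(panel) {
  panel$gene[panel$role == "endogenous" & panel$group %in% "drug-target"]
}

#' Seed marker lists for semi-supervised cluster labeling
#'
#' @inheritParams subtyping_genes
#' @return named list of character vectors for labels basal, luminal, p53-like.
#' @export
seed_markers <- function(panel) {
  lab <- c("basal", "luminal", "p53-like")
  out <- lapply(lab, function(l) panel$gene[panel$seed & panel$group %in% l])
  names(out) <- lab
  out
}

#' Ground-truth consensus panel implied by a gene panel
#'
#' Builds a [consensus_panel] directly from the planted signature groups of a
#' panel, bypassing data-driven clustering. Used as the truth reference when
#' evaluating consensus recovery on synthetic cohorts, and to subtype cohorts
#' against the planted signature structure.
#'
#' @inheritParams subtyping_genes
#' @param core_only use only the stable core genes (default) or the full
#'   subtyping set (late-cycle genes then count to the basal group, whose
#'   expression axis they share).
#' @return a `consensus_panel` object (see [intersect_cohorts()]).
#' @export
panel_consensus <- function(panel, core_only = TRUE) {
  grp <- panel$group
  grp[grp == "late-cycle"] <- "basal"
  keep <- panel$role == "endogenous" & grp %in% c("basal", "luminal", "p53-like")
  if (core_only) keep <- keep & panel$core
  sets <- split(panel$gene[keep], grp[keep])[c("basal", "luminal", "p53-like")]
  new_consensus_panel(sets, unstable = data.frame(gene = character(0)),
                      n_cohorts = 0L)
}
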