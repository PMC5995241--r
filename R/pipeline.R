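#' End-to-end subtyping pipeline on synthetic or user cohorts
#'
#' Runs the full analysis in order: cohort generation (or loading), per-cohort
#' normalization, consensus-panel derivation (gene clustering, semi-supervised
#' labeling, Venn intersection), subtype calling on the index cohort,
#' Kaplan-Meier / log-rank / forward-selection Cox survival analysis,
#' clinical-association tests (exact Fisher for categorical covariates,
#' Kruskal-Wallis for age), drug-target screening and an immune-signature
#' enrichment test (infiltrated vs rest). Intermediate artifacts are written
#' as TSV, the run summary as JSON; re-running with the same config reproduces
#' all outputs. Every stage draws its seed deterministically from the global
#' seed and the stage name, so inserting a stage does not perturb the others.
#'
#' @param config list with elements: `cohorts` — a list of
#'   [simulation_config()]s (the first is the index cohort) or of paths to
#'   count/expression TSVs; `clinical` — optional list of clinical TSV paths
#'   (required when `cohorts` are paths and survival is requested); `seed` —
#'   global seed; `k` — number of clusters (default 3); `endpoints` —
#'   subset of `c("os", "dss")`; `covariates` — Cox covariates (default
#'   luminal, stage_t34, node_pos, ac); `n_perm` — GSEA permutations;
#'   `immune_set` — gene set for the enrichment test (default: the panel's
#'   immune-flagged genes); `panel` — a [gene_panel()].
#' @param out_dir output directory (created if needed).
#' @return the run report (invisibly), also written to
#'   `<out_dir>/report.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  cfg$k <- cfg$k %||% 3
  cfg$endpoints <- cfg$endpoints %||% c("os", "dss")
  cfg$covariates <- cfg$covariates %||% c("luminal", "stage_t34", "node_pos", "ac")
  cfg$n_perm <- cfg$n_perm %||% 200
  panel <- cfg$panel %||% default_panel()
  if (is.null(cfg$cohorts) || length(cfg$cohorts) < 1)
    stopf("config$cohorts must list at least one cohort")
  simulated <- inherits(cfg$cohorts[[1]], "simulation_config")
  if (!simulated && is.null(cfg$clinical) && length(cfg$endpoints))
    stopf("survival analysis requested but config$clinical is missing")
  report <- list(seed = cfg$seed %||% NA, k = cfg$k, stages = list())
  note <- function(stage, ...) report$stages[[stage]] <<- list(...)

  # --- cohorts -------------------------------------------------------------
  if (simulated) {
    cohorts <- lapply(seq_along(cfg$cohorts), function(i) {
      ci <- cfg$cohorts[[i]]
      if (!is.null(cfg$seed))
        ci$seed <- stage_seed(cfg$seed, paste0("simulate", i))
      generate_cohort(ci, panel)
    })
    exprs <- lapply(cohorts, `[[`, "expression")
    clinical <- cohorts[[1]]$clinical
    for (i in seq_along(cohorts)) {
      write_expression(exprs[[i]], file.path(out_dir, sprintf("cohort%d_expr.tsv", i)))
      utils::write.table(
        data.frame(sample_id = names(cohorts[[i]]$truth),
                   subtype = as.character(cohorts[[i]]$truth)),
        file.path(out_dir, sprintf("cohort%d_truth.tsv", i)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_clinical(clinical, file.path(out_dir, "cohort1_clinical.tsv"))
    note("simulate", n_cohorts = length(cohorts),
         seeds = vapply(cohorts, function(co) co$config$seed, numeric(1)))
  } else {
    exprs <- lapply(cfg$cohorts, function(p) {
      first <- readLines(p, n = 1L)
      if (grepl("\trole\t", first) && !grepl("^CodeClass", first) &&
          !grepl("Count", first)) {
        d <- utils::read.delim(p, nrows = 2, check.names = FALSE)
        if (any(d[[3]] != round(d[[3]]))) return(read_expression(p))
      }
      tryCatch(read_counts(p, panel), error = function(e) read_expression(p))
    })
    clinical <- read_clinical(cfg$clinical[[1]])
    note("load", n_cohorts = length(exprs))
  }

  # --- normalization -------------------------------------------------------
  norm <- lapply(exprs, normalize_cohort)
  mats <- lapply(norm, `[[`, "matrix")
  for (i in seq_along(norm)) if (!is.null(norm[[i]]$report))
    utils::write.table(norm[[i]]$report,
                       file.path(out_dir, sprintf("cohort%d_norm_report.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  note("normalize", platforms = vapply(exprs, `[[`, "", "platform"))

  # --- consensus panel -----------------------------------------------------
  if (length(mats) >= 2) {
    consensus <- derive_consensus(mats, panel, k = cfg$k)
  } else {
    labeled <- label_clusters(
      cluster_genes(mats[[1]], intersect(subtyping_genes(panel),
                                         rownames(mats[[1]]$values)), k = cfg$k),
      seed_markers(panel), cohort = "cohort1")
    consensus <- new_consensus_panel(
      split(names(labeled$gene_labels), labeled$gene_labels)[c("basal", "luminal", "p53-like")],
      data.frame(gene = character(0)), 1L)
  }
  utils::write.table(
    data.frame(gene = consensus_genes(consensus),
               label = rep(names(consensus$sets), lengths(consensus$sets))),
    file.path(out_dir, "consensus_panel.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  note("consensus", sizes = lengths(consensus$sets),
       n_unstable = nrow(consensus$unstable))

  # --- subtype calling (index cohort) --------------------------------------
  assignment <- call_subtypes(mats[[1]], consensus, k = cfg$k)
  utils::write.table(as.data.frame(assignment),
                     file.path(out_dir, "subtypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("subtype", counts = as.list(table(assignment$subtype)))

  # --- survival ------------------------------------------------------------
  cov <- encode_covariates(clinical, assignment)
  surv_out <- list()
  for (ep in cfg$endpoints) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    by_st <- split(data.frame(times = cov[[tcol]], events = cov[[ecol]]),
                   assignment$subtype[match(cov$sample_id, assignment$sample_id)])
    lr <- logrank_test(by_st)
    km <- do.call(rbind, lapply(names(by_st), function(s) {
      cur <- km_estimate(by_st[[s]]$times, by_st[[s]]$events, label = s)
      cbind(subtype = s, as.data.frame(cur))
    }))
    utils::write.table(km, file.path(out_dir, sprintf("km_%s.tsv", ep)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cx <- cox_fit(cov, cfg$covariates, endpoint = ep, selection = "forward")
    surv_out[[ep]] <- list(logrank = lr,
                           surv8y = lapply(names(by_st), function(s)
                             survival_at(km_estimate(by_st[[s]]$times,
                                                     by_st[[s]]$events), 96)),
                           cox = cx$table, cox_trace = cx$trace)
  }
  note("survival", endpoints = cfg$endpoints,
       logrank_p = lapply(surv_out, function(s) s$logrank$p.value))

  # --- clinical associations ----------------------------------------------
  st <- assignment$subtype[match(cov$sample_id, assignment$sample_id)]
  assoc <- list()
  for (v in c("sex", "stage", "node", "metastasis", "nac", "ac")) {
    val <- clinical[[v]]
    if (is.logical(val)) val <- factor(val, levels = c(FALSE, TRUE))
    tt <- table(val, st)
    tt <- tt[rowSums(tt) > 0, , drop = FALSE]
    assoc[[v]] <- if (nrow(tt) >= 2 && all(colSums(tt) > 0))
      fisher_exact_rxc(unclass(tt))$p.value else NA_real_
  }
  assoc$age <- kruskal_wallis(split(clinical$age, st))$p.value
  utils::write.table(data.frame(covariate = names(assoc),
                                p = unlist(assoc)),
                     file.path(out_dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("associations", p = assoc)

  # --- drug targets --------------------------------------------------------
  targets <- intersect(drug_target_genes(panel), rownames(mats[[1]]$values))
  screen <- drug_target_screen(mats[[1]], assignment, targets, consensus)
  utils::write.table(screen, file.path(out_dir, "drug_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("drug_targets", n = nrow(screen))

  # --- immune enrichment ---------------------------------------------------
  immune_set <- cfg$immune_set %||% panel$gene[panel$immune]
  pheno <- stats::setNames(assignment$subtype == "infiltrated",
                           assignment$sample_id)
  gsea <- gsea_test(mats[[1]], pheno, immune_set, n_perm = cfg$n_perm,
                    seed = stage_seed(cfg$seed %||% 1, "gsea"))
  note("gsea", es = gsea$es, nes = gsea$nes, p = gsea$p.value, fdr = gsea$fdr_q)

  report$survival <- lapply(surv_out, function(s)
    list(logrank_p = s$logrank$p.value, cox = s$cox, trace = s$cox_trace))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
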