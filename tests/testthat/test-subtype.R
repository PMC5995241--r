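make_prototypes <- function(cons, n_rep = 1, noise = 0) {
  g <- consensus_genes(cons)
  labs <- rep(names(cons$sets), lengths(cons$sets))
  prof <- function(up) 4 * as.numeric(labs == up)
  cols <- list(basal = prof("basal"), luminal = prof("luminal"),
               infiltrated = prof("p53-like"))
  m <- do.call(cbind, rep(cols, each = n_rep))
  m <- m + matrix(rnorm(length(m), 0, max(noise, 1e-6)), nrow(m))
  dimnames(m) <- list(g, paste0("s", seq_len(ncol(m))))
  toy_em(m)
}

test_that("pure signature prototypes each get their own subtype", {
  cons <- panel_consensus(default_panel())
  set.seed(1)
  em <- make_prototypes(cons, n_rep = 2, noise = 0.01)
  a <- call_subtypes(em, cons)
  expect_equal(as.character(a$subtype),
               rep(c("basal", "basal", "luminal", "luminal",
                     "infiltrated", "infiltrated")))
  expect_true(all(is.finite(as.matrix(a[, 4:6]))))
})

test_that("subtype calls are invariant to gene and sample order", {
  co <- generate_cohort(simulation_config(n_samples = 60, seed = 12))
  nm <- normalize_ncounter(co$expression)$matrix
  cons <- panel_consensus(default_panel())
  a <- call_subtypes(nm, cons)
  set.seed(3)
  gp <- sample(nrow(nm$values)); sp <- sample(ncol(nm$values))
  em2 <- expression_matrix(nm$values[gp, ], nm$platform, nm$gene_roles[gp])
  b <- call_subtypes(em2, cons)
  expect_equal(a$subtype, b$subtype)
  em3 <- expression_matrix(nm$values[, sp], nm$platform, nm$gene_roles)
  c3 <- call_subtypes(em3, cons)
  expect_equal(stats::setNames(a$subtype, a$sample_id)[c3$sample_id],
               stats::setNames(c3$subtype, c3$sample_id))
})

test_that("synthetic default cohorts are recovered almost perfectly", {
  co <- generate_cohort(simulation_config(n_samples = 150, seed = 17))
  nm <- normalize_ncounter(co$expression)$matrix
  a <- call_subtypes(nm, panel_consensus(default_panel()))
  expect_gte(mclust::adjustedRandIndex(a$subtype, co$truth), 0.9)
  # proportions within 99% binomial bands of the configured mixture
  cnt <- table(a$subtype)
  for (s in names(cnt)) {
    p0 <- co$config$subtype_proportions[[s]]
    band <- qbinom(c(0.005, 0.995), 150, p0)
    expect_gte(cnt[[s]], band[1]); expect_lte(cnt[[s]], band[2])
  }
})

test_that("missing consensus genes are tolerated up to the 80% floor", {
  co <- generate_cohort(simulation_config(n_samples = 60, seed = 13))
  nm <- normalize_ncounter(co$expression)$matrix
  cons <- panel_consensus(default_panel())
  keep <- setdiff(rownames(nm$values), c("KRT5", "UPK2", "CCL5"))
  em <- expression_matrix(nm$values[keep, ], nm$platform, nm$gene_roles[keep])
  expect_message(a <- call_subtypes(em, cons), "3 consensus gene")
  expect_equal(nrow(a), 60)
  few <- intersect(consensus_genes(cons)[1:20], keep)
  em2 <- expression_matrix(nm$values[few, ], nm$platform, nm$gene_roles[few])
  expect_error(call_subtypes(em2, cons), "consensus genes present")
})

test_that("centroids summarize clusters and reject empty subtypes", {
  cons <- panel_consensus(default_panel())
  set.seed(2)
  em <- make_prototypes(cons, n_rep = 4, noise = 0.05)
  a <- call_subtypes(em, cons)
  cen <- fit_centroids(em, a, cons)
  expect_equal(dim(cen$centroids), c(36L, 3L))
  # clusters of near-identical samples: centroid equals the common z-profile
  z <- mibcSubtyper:::zscore_rows(em$values[rownames(cen$centroids), ])
  for (s in c("basal", "luminal", "infiltrated")) {
    idx <- which(a$subtype == s)
    expect_equal(cen$centroids[, s], z[, idx[1]], tolerance = 0.1,
                 ignore_attr = TRUE)
  }
  bad <- a; bad$subtype[bad$subtype == "luminal"] <- "basal"
  expect_error(fit_centroids(em, bad, cons), "0 samples")
})

test_that("nearest-centroid prediction transfers across cohorts", {
  cons <- panel_consensus(default_panel())
  co <- generate_cohort(simulation_config(n_samples = 150, seed = 21))
  nm <- normalize_ncounter(co$expression)$matrix
  a <- call_subtypes(nm, cons)
  cen <- fit_centroids(nm, a, cons)
  self <- predict_subtypes(nm, cen)
  expect_gte(mean(self$subtype == a$subtype), 0.95)
  expect_true(all(self$margin > 0))

  co2 <- generate_cohort(simulation_config(n_samples = 100, seed = 22,
                                           platform = "log2-array"))
  nm2 <- normalize_cohort(co2$expression)$matrix
  pred <- predict_subtypes(nm2, cen)
  expect_gte(mclust::adjustedRandIndex(pred$subtype, co2$truth), 0.8)
  expect_equal(attr(pred, "method"), "centroid")
})

test_that("signature prototypes are predicted as their own subtype with wide margin", {
  cons <- panel_consensus(default_panel())
  set.seed(5)
  em <- make_prototypes(cons, n_rep = 3, noise = 0.05)
  a <- call_subtypes(em, cons)
  cen <- fit_centroids(em, a, cons)
  probes <- make_prototypes(cons, n_rep = 1, noise = 0.05)
  pred <- predict_subtypes(probes, cen)
  expect_equal(as.character(pred$subtype), c("basal", "luminal", "infiltrated"))
  expect_true(all(pred$margin > 0.5))
})

test_that("exact centroid-correlation ties are a named hard error", {
  cons <- panel_consensus(default_panel())
  g <- consensus_genes(cons)
  cen <- structure(list(centroids = matrix(rep(stats::rnorm(36), 3), ncol = 3,
                                           dimnames = list(g, c("luminal", "basal", "infiltrated"))),
                        consensus = cons), class = "subtype_centroids")
  m <- matrix(rnorm(72), ncol = 2, dimnames = list(g, c("x1", "x2")))
  expect_error(predict_subtypes(toy_em(m), cen), "tie.*x1|x1.*tie")
})

test_that("luminal dichotomization is a deterministic indicator", {
  a <- data.frame(sample_id = c("s1", "s2", "s3"),
                  subtype = factor(c("luminal", "basal", "infiltrated"),
                                   levels = c("luminal", "basal", "infiltrated")))
  class(a) <- c("subtype_assignment", "data.frame")
  expect_equal(stratify_luminal(a), c(s1 = 1L, s2 = 0L, s3 = 0L))
  empty <- a[0, ]
  expect_length(stratify_luminal(empty), 0)
})
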