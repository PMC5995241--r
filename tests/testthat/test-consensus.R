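test_that("three orthogonal block patterns cluster into their blocks", {
  set.seed(4)
  n <- 24
  blk <- rbind(rep(c(1, 0, 0), each = n / 3), rep(c(0, 1, 0), each = n / 3),
               rep(c(0, 0, 1), each = n / 3))
  m <- blk[rep(1:3, each = 2), ] * 4 + matrix(rnorm(6 * n, 0, 0.05), 6, n)
  dimnames(m) <- list(paste0("g", 1:6), paste0("s", 1:n))
  cl <- unname(cluster_genes(toy_em(m), k = 3)$clusters)
  expect_equal(cl[1], cl[2]); expect_equal(cl[3], cl[4]); expect_equal(cl[5], cl[6])
  expect_length(unique(cl[c(1, 3, 5)]), 3)
})

test_that("Ward linkage matches the naive O(n^3) agglomeration oracle", {
  set.seed(10)
  for (rep_i in 1:20) {
    ng <- sample(5:10, 1)
    m <- matrix(rnorm(ng * 15), ng, 15,
                dimnames = list(paste0("g", 1:ng), paste0("s", 1:15)))
    res <- cluster_genes(toy_em(m), k = 3)
    D <- 1 - cor(t(mibcSubtyper:::zscore_rows(m)))
    orc <- ward_oracle(D)
    expect_equal(res$hclust$height, orc$heights, tolerance = 1e-8)
    for (k in 2:(ng - 1)) {
      part_o <- orc$partitions[[ng - k]]
      expect_true(same_partition(unname(stats::cutree(res$hclust, k)), part_o))
    }
  }
})

test_that("gene clustering ignores sample order and flags zero variance", {
  set.seed(2)
  m <- matrix(rnorm(8 * 20), 8, 20,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:20)))
  a <- cluster_genes(toy_em(m), k = 3)$clusters
  perm <- sample(20)
  b <- cluster_genes(toy_em(m[, perm]), k = 3)$clusters
  expect_identical(a, b)
  m[1, ] <- 7
  expect_error(cluster_genes(toy_em(m), k = 3), "zero-variance.*g1")
})

test_that("seed-based labeling is optimal over all permutations and errors on ties", {
  seeds <- list(basal = c("KRT5", "KRT14"), luminal = c("KRT20", "UPK2"),
                `p53-like` = c("CD14", "CCL2"))
  gl <- c(KRT5 = 1, KRT14 = 1, KRT20 = 2, UPK2 = 2, CD14 = 3, CCL2 = 3)
  lab <- label_clusters(list(clusters = gl), seeds)
  expect_equal(unname(lab$cluster_labels),
               c("basal", "luminal", "p53-like"))
  expect_equal(unname(lab$gene_labels["KRT20"]), "luminal")

  # overlap matrix [[2,0,0],[1,3,0],[0,0,2]]: optimum is the identity
  # permutation with total 7, confirmed by the exhaustive 3! oracle
  seeds2 <- list(basal = c("b1", "b2", "b3"), luminal = c("l1", "l2", "l3"),
                 `p53-like` = c("p1", "p2"))
  gl2 <- c(b1 = 1, b2 = 1, b3 = 2, l1 = 2, l2 = 2, l3 = 2, p1 = 3, p2 = 3)
  lab2 <- label_clusters(list(clusters = gl2), seeds2)
  expect_equal(unname(lab2$overlap),
               rbind(c(2, 0, 0), c(1, 3, 0), c(0, 0, 2)))
  orc <- assign_oracle(lab2$overlap)
  expect_false(orc$tied)
  expect_equal(orc$total, 7)
  expect_equal(unname(lab2$cluster_labels), c("basal", "luminal", "p53-like")[orc$perm])

  # identical overlap rows across two clusters: a tie, not a guess
  gl3 <- c(b1 = 1, l1 = 1, b2 = 2, l2 = 2, p1 = 3, p2 = 3)
  expect_error(label_clusters(list(clusters = gl3), seeds2), "ambiguous")
  gl4 <- c(b1 = 1, b2 = 2, l1 = 2, l2 = 3)
  expect_error(label_clusters(list(clusters = gl4), seeds2), "p53-like")
})

test_that("Venn intersection keeps concordant labels and reports discordance", {
  mk <- function(labels) structure(list(gene_labels = labels, cohort = NA),
                                   class = "labeled_gene_clusters")
  full <- c(A = "basal", B = "basal", C = "basal", D = "luminal", E = "p53-like")
  same <- lapply(1:4, function(i) mk(full))
  cons <- intersect_cohorts(same)
  expect_setequal(cons$sets$basal, c("A", "B", "C"))
  expect_equal(nrow(cons$unstable), 0)

  flip <- full; flip["A"] <- "luminal"
  cons2 <- intersect_cohorts(c(same[1:3], list(mk(flip))))
  expect_setequal(cons2$sets$basal, c("B", "C"))
  expect_equal(cons2$unstable$gene, "A")
  # order invariance and monotonicity
  cons3 <- intersect_cohorts(c(list(mk(flip)), same[1:3]))
  expect_equal(lapply(cons3$sets, sort), lapply(cons2$sets, sort))
  for (l in names(cons2$sets))
    expect_true(all(cons2$sets[[l]] %in% cons$sets[[l]]))
  expect_error(intersect_cohorts(same[1]), ">= 2")
})

test_that("an empty consensus label warns (or errors when required)", {
  mk <- function(labels) structure(list(gene_labels = labels, cohort = NA),
                                   class = "labeled_gene_clusters")
  a <- mk(c(A = "basal", B = "luminal", C = "p53-like"))
  b <- mk(c(A = "basal", B = "luminal", C = "luminal"))
  expect_warning(intersect_cohorts(list(a, b)), "empty consensus.*p53-like")
  expect_error(intersect_cohorts(list(a, b), require_nonempty = TRUE),
               "empty consensus")
})

test_that("planted-stable genes are recovered exactly across 4 synthetic cohorts", {
  cfgs <- lapply(1:4, function(i)
    simulation_config(n_samples = 80, seed = 20 + i,
                      platform = if (i == 1) "ncounter-raw" else "log2-array"))
  mc <- generate_multicohort(cfgs, n_unstable = 28)
  mats <- lapply(mc, function(co) normalize_cohort(co$expression)$matrix)
  cons <- derive_consensus(mats, default_panel())
  sl <- attr(mc, "stable_labels")
  got <- stats::setNames(rep(names(cons$sets), lengths(cons$sets)),
                         consensus_genes(cons))
  expect_setequal(names(got), names(sl))
  expect_equal(got[names(sl)], sl)
  expect_setequal(cons$unstable$gene, attr(mc, "unstable_genes"))
})
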