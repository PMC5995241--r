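test_that("a sample already at cohort targets with zero negatives passes through", {
  # two identical samples: every scale factor is 1 and background is 0,
  # so the output is log2(count + 1) of the endogenous genes
  v <- rbind(G1 = c(100, 100), G2 = c(7, 7), REF1 = c(50, 50),
             POS_A = c(200, 200), NEG_A = c(0, 0))
  colnames(v) <- c("s1", "s2")
  em <- expression_matrix(v, "ncounter-raw",
                          c(G1 = "endogenous", G2 = "endogenous",
                            REF1 = "reference", POS_A = "positive-control",
                            NEG_A = "negative-control"))
  out <- normalize_ncounter(em)
  expect_equal(out$matrix$values, log2(v[c("G1", "G2"), ] + 1))
  expect_equal(out$report$pos_scale, c(1, 1))
  expect_equal(out$report$background, c(0, 0))
  expect_equal(out$report$ref_scale, c(1, 1))
})

test_that("normalization equals the independent four-step hand oracle", {
  em <- toy_raw()
  out <- normalize_ncounter(em)
  expect_equal(out$matrix$values,
               ncounter_oracle(em$values, em$gene_roles), tolerance = 1e-12)
  expect_equal(out$matrix$platform, "ncounter-normalized")
  expect_setequal(unique(out$matrix$gene_roles), "endogenous")

  co <- generate_cohort(simulation_config(n_samples = 25, seed = 3))
  out2 <- normalize_ncounter(co$expression)
  expect_equal(out2$matrix$values,
               ncounter_oracle(co$expression$values, co$expression$gene_roles),
               tolerance = 1e-12)
})

test_that("a global rescaling of one sample is cancelled up to the cohort constant", {
  # positive-control scaling removes the factor from the sample itself; only
  # the cohort-wide target moves, by 2^(1/n) for an n-sample cohort, so every
  # pre-log value shifts by exactly that constant and within-sample structure
  # is untouched
  em <- toy_raw()
  n <- ncol(em$values)
  v2 <- em$values
  v2[, "s2"] <- v2[, "s2"] * 2
  em2 <- expression_matrix(v2, "ncounter-raw", em$gene_roles)
  lin <- function(m) 2^m$values - 1
  a <- lin(normalize_ncounter(em)$matrix)
  b <- lin(normalize_ncounter(em2)$matrix)
  expect_equal(b, a * 2^(1 / n), tolerance = 1e-12)
})

test_that("reference geomeans are equalized and re-scaling is idempotent", {
  co <- generate_cohort(simulation_config(n_samples = 20, seed = 8))
  out <- normalize_ncounter(co$expression)
  rep <- out$report
  raw <- co$expression$values
  refs <- genes(co$expression, "reference")
  gm <- vapply(seq_along(rep$sample_id), function(j) {
    x <- pmax(raw[refs, j] * rep$pos_scale[j] - rep$background[j], 0)
    exp(mean(log(x * rep$ref_scale[j])))
  }, numeric(1))
  expect_lt(diff(range(gm)) / mean(gm), 1e-9)
  # re-deriving reference factors on already-normalized data changes nothing
  refac <- exp(mean(log(gm))) / gm
  expect_equal(refac, rep(1, length(gm)), tolerance = 1e-9)
  expect_true(all(rep$pos_scale > 0 & rep$ref_scale > 0))
})

test_that("raising one endogenous count never lowers its normalized value", {
  em <- toy_raw()
  base <- normalize_ncounter(em)$matrix$values["GENE1", "s1"]
  v2 <- em$values; v2["GENE1", "s1"] <- v2["GENE1", "s1"] + 50
  up <- normalize_ncounter(expression_matrix(v2, "ncounter-raw",
                                             em$gene_roles))$matrix$values["GENE1", "s1"]
  expect_gt(up, base)
})

test_that("degenerate control probes raise named errors", {
  em <- toy_raw()
  v <- em$values; v["REF1", "s2"] <- 5; v["NEG_A", "s2"] <- 2000
  expect_error(normalize_ncounter(expression_matrix(v, "ncounter-raw", em$gene_roles)),
               "reference-gene geometric mean is zero.*s2")
  v <- em$values; v["POS_A", "s1"] <- 0
  expect_error(normalize_ncounter(expression_matrix(v, "ncounter-raw", em$gene_roles)),
               "positive-control.*s1")
  expect_error(normalize_ncounter(normalize_ncounter(em)$matrix), "ncounter-raw")
})

test_that("background policy switches change the subtracted level", {
  em <- toy_raw()
  m1 <- normalize_ncounter(em, background = "mean")$report$background
  m2 <- normalize_ncounter(em, background = "max")$report$background
  expect_true(all(m2 >= m1))
})

test_that("quantile normalization equalizes sorted columns with tie averaging", {
  m <- cbind(s1 = c(2, 4, 6), s2 = c(1, 2, 3))
  rownames(m) <- paste0("g", 1:3)
  q <- quantile_normalize(toy_em(m))
  expect_equal(unname(q$values[, "s1"]), c(1.5, 3, 4.5))
  expect_equal(unname(q$values[, "s2"]), c(1.5, 3, 4.5))

  set.seed(1)
  r <- matrix(rnorm(200), 40, 5,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:5)))
  qr <- quantile_normalize(toy_em(r))
  sorted <- apply(qr$values, 2, sort)
  for (j in 2:5) expect_equal(sorted[, j], sorted[, 1])
  # rank order within each sample is preserved
  for (j in 1:5) expect_equal(order(qr$values[, j]), order(r[, j]))

  tied <- cbind(s1 = c(1, 1, 5), s2 = c(2, 3, 4))
  rownames(tied) <- paste0("g", 1:3)
  qt <- quantile_normalize(toy_em(tied))
  expect_equal(unname(qt$values[1:2, "s1"]), rep(mean(c(1.5, 2)), 2))

  r[1, 1] <- NA
  expect_error(quantile_normalize(toy_em(r)), "missing")
  expect_error(quantile_normalize(toy_em(m[, 1, drop = FALSE])), ">= 2 samples")
})
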