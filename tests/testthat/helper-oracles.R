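# Independent oracles used to cross-check the package implementations.
# Each is written naively (loops, brute force) and never shares code with R/.

# --- naive O(n^3) Ward agglomeration (Lance-Williams on the raw distances,
# the ward.D convention) -------------------------------------------------
ward_oracle <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  d <- D
  heights <- numeric(0)
  partitions <- list()
  while (length(members) > 1) {
    m <- length(members)
    bh <- Inf; bi <- NA; bj <- NA
    for (i in seq_len(m - 1)) for (j in (i + 1):m)
      if (d[i, j] < bh) { bh <- d[i, j]; bi <- i; bj <- j }
    heights <- c(heights, bh)
    ni <- sizes[bi]; nj <- sizes[bj]
    others <- setdiff(seq_len(m), c(bi, bj))
    newrow <- vapply(others, function(k)
      ((ni + sizes[k]) * d[bi, k] + (nj + sizes[k]) * d[bj, k] -
         sizes[k] * bh) / (ni + nj + sizes[k]), numeric(1))
    members <- c(members[others], list(c(members[[bi]], members[[bj]])))
    sizes <- c(sizes[others], ni + nj)
    nd <- matrix(0, length(members), length(members))
    if (length(others)) {
      nd[seq_along(others), seq_along(others)] <- d[others, others]
      nd[length(members), seq_along(others)] <- newrow
      nd[seq_along(others), length(members)] <- newrow
    }
    d <- nd
    part <- integer(n)
    for (ci in seq_along(members)) part[members[[ci]]] <- ci
    partitions[[length(partitions) + 1]] <- part
  }
  list(heights = heights, partitions = partitions)
}

# partition agreement up to label permutation
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# --- four-step nCounter normalization, written as plain loops -----------
ncounter_oracle <- function(counts, roles, background = "mean") {
  v <- counts
  pos <- rownames(v)[roles == "positive-control"]
  neg <- rownames(v)[roles == "negative-control"]
  ref <- rownames(v)[roles == "reference"]
  endo <- rownames(v)[roles == "endogenous"]
  gm <- function(x) exp(mean(log(x)))
  pg <- sapply(colnames(v), function(s) gm(v[pos, s]))
  target <- gm(pg)
  for (s in colnames(v)) v[, s] <- v[, s] * target / pg[s]
  for (s in colnames(v)) {
    bg <- mean(v[neg, s])
    for (g in c(endo, ref)) v[g, s] <- max(v[g, s] - bg, 0)
  }
  rg <- sapply(colnames(v), function(s) gm(v[ref, s]))
  rt <- gm(rg)
  for (s in colnames(v)) for (g in c(endo, ref)) v[g, s] <- v[g, s] * rt / rg[s]
  log2(v[endo, , drop = FALSE] + 1)
}

# --- two-group log-rank by explicit O-E tabulation ----------------------
logrank_oracle <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  U <- 0; V <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d1 <- sum(t1 == tt & e1 == 1); d2 <- sum(t2 == tt & e2 == 1); dd <- d1 + d2
    U <- U + d1 - dd * n1 / n
    if (n > 1) V <- V + dd * (n1 / n) * (n2 / n) * (n - dd) / (n - 1)
  }
  U^2 / V
}

# --- Cox partial log-likelihood for a single covariate, brute force -----
coxlik_oracle <- function(beta, time, event, z) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * z[i] - log(sum(exp(beta * z[risk])))
  }
  ll
}

cox_grid_mle <- function(time, event, z, lo = -5, hi = 5) {
  g1 <- seq(lo, hi, by = 0.01)
  b1 <- g1[which.max(vapply(g1, coxlik_oracle, numeric(1), time, event, z))]
  g2 <- seq(b1 - 0.02, b1 + 0.02, by = 1e-4)
  g2[which.max(vapply(g2, coxlik_oracle, numeric(1), time, event, z))]
}

# --- naive GSEA running sum ---------------------------------------------
es_oracle <- function(genes, scores, set, p = 1) {
  N <- length(genes)
  hit <- genes %in% set
  Nh <- sum(hit)
  wsum <- sum(abs(scores[hit])^p)
  cur <- 0; best <- 0
  for (i in seq_len(N)) {
    if (hit[i]) cur <- cur + (if (wsum > 0) abs(scores[i])^p / wsum else 1 / Nh)
    else cur <- cur - (if (N > Nh) 1 / (N - Nh) else 0)
    if (abs(cur) > abs(best)) best <- cur
  }
  best
}

# --- exhaustive 3!-permutation assignment on an overlap matrix ----------
assign_oracle <- function(ov) {
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  tot <- vapply(perms, function(p) sum(ov[cbind(1:3, p)]), numeric(1))
  list(perm = perms[[which.max(tot)]], total = max(tot),
       tied = sum(tot == max(tot)) > 1)
}

# --- shared toy builders -------------------------------------------------
toy_em <- function(values, platform = "log2-array", roles = NULL) {
  roles <- roles %||% stats::setNames(rep("endogenous", nrow(values)),
                                      rownames(values))
  expression_matrix(values, platform, roles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small raw nCounter toy: 2 endogenous + 1 reference + 1 positive + 1 negative
toy_raw <- function() {
  v <- rbind(GENE1 = c(100, 220), GENE2 = c(40, 95), REF1 = c(400, 810),
             POS_A = c(200, 390), NEG_A = c(4, 9))
  colnames(v) <- c("s1", "s2")
  expression_matrix(v, "ncounter-raw",
                    c(GENE1 = "endogenous", GENE2 = "endogenous",
                      REF1 = "reference", POS_A = "positive-control",
                      NEG_A = "negative-control"))
}
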