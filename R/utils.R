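#' @keywords internal
"_PACKAGE"

# geometric mean; returns 0 if any value is 0 (callers decide how to react)
geomean <- function(x) {
  if (any(x < 0)) stop("geometric mean undefined for negative values")
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

row_sds <- function(m) {
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2), 0) / (ncol(m) - 1))
}

# per-gene (row) z-score across samples; constant rows become 0
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sdv <- row_sds(m)
  sdv[sdv == 0] <- 1
  (m - mu) / sdv
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed derived from a global seed and a stage name,
# so inserting a stage does not perturb the streams of the others.
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 7919 + h * 104729) %% 2147483629)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
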