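# Shared fixtures and independent oracles.

BASES4 <- c("A", "C", "G", "T")

# all length-w windows over ACGT, as strings (column-major enumeration)
all_windows <- function(w) {
  grid <- do.call(expand.grid, rep(list(BASES4), w))
  apply(as.matrix(grid), 1, paste, collapse = "")
}

# Brute-force null tail P(discretized score >= k*granularity) by
# enumerating all 4^w windows; per-column scores rounded to bins exactly
# as the DP does, probabilities from the background product.
brute_force_tail <- function(model, granularity, score) {
  w <- model$width
  colbins <- round(model$log_odds / granularity)
  grid <- as.matrix(do.call(expand.grid, rep(list(1:4), w)))
  binsum <- numeric(nrow(grid))
  logp <- numeric(nrow(grid))
  for (i in seq_len(w)) {
    binsum <- binsum + colbins[i, grid[, i]]
    logp <- logp + log(model$background[grid[, i]])
  }
  k <- round(score / granularity)
  sum(exp(logp)[binsum >= k])
}

# toy genotype_matrix from a calls matrix (subjects x variants)
toy_gm <- function(calls, ids = NULL) {
  nv <- ncol(calls)
  variants <- data.frame(contig = "chrT", pos = seq_len(nv) * 100L,
                         ref = "A", alt = "G",
                         rsid = ids %||% paste0("v", seq_len(nv)),
                         stringsAsFactors = FALSE)
  genotype_matrix(calls, variants)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random background sequence
random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES4, n, replace = TRUE), collapse = "")
}

# published candidate reference rows (shipped extdata fixture)
ref_candidates <- function() reference_candidates()

# small synthetic study used by several files (cached per session)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 11, region_length = 60000,
                               n_variants = 500, n_cohort = 1763)
      cache <<- simulate_study(cfg, dir = file.path(tempdir(), "ereseq-small"))
    }
    cache
  }
})
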