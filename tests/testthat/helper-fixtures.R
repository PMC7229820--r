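options(nonotet.quiet = TRUE)

# compact simulation used across tests; genome small enough to keep the
# suite fast but large enough for non-degenerate counts
small_sim_cfg <- function(seed = 1L, ...) {
  simulation_config(n_chroms = 2L, chrom_len_bp = 3e6, n_genes = 150L,
                    n_dep_up = 25L, n_dep_down = 15L,
                    n_null_up = 20L, n_null_down = 10L, seed = seed, ...)
}

.bundle_cache <- new.env(parent = emptyenv())
small_bundle <- function(seed = 1L) {
  key <- as.character(seed)
  if (is.null(.bundle_cache[[key]])) {
    .bundle_cache[[key]] <- simulate_all(small_sim_cfg(seed = seed))
  }
  .bundle_cache[[key]]
}

# O(n^2) all-pairs overlap oracle, independent of the sweep implementation
brute_hits <- function(q, r) {
  vapply(seq_len(nrow(q)), function(i) {
    any(r$chrom == q$chrom[i] & r$start < q$end[i] & q$start[i] < r$end)
  }, logical(1))
}

# per-bp expansion oracle for binned coverage
brute_bins <- function(df, bin_size, chrom_sizes) {
  lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    bp <- numeric(len)
    sub <- df[df$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      bp[(sub$start[i] + 1):sub$end[i]] <- sub$value[i]
    }
    nb <- ceiling(len / bin_size)
    vapply(seq_len(nb), function(b) {
      mean(bp[((b - 1) * bin_size + 1):min(b * bin_size, len)])
    }, numeric(1))
  })
}

# direct-formula Pearson correlation, independent of stats::cor
pearson_direct <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# exhaustive hypergeometric upper tail P[X >= k] via binomial coefficients
hyper_tail_enum <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# ad-hoc expression matrix from a bare value matrix
make_expr <- function(values, genotype, timepoint) {
  replicate <- stats::ave(seq_along(genotype), genotype, timepoint, FUN = seq_along)
  ids <- sprintf("%s_d%d_r%d", genotype, timepoint, replicate)
  colnames(values) <- ids
  expression_matrix(values, sample_meta(ids, genotype, timepoint, replicate))
}

random_peaks <- function(n, chrom_len = 1e5, chroms = "chrA", name = "rnd") {
  ch <- sample(chroms, n, replace = TRUE)
  st <- sample.int(chrom_len - 2000, n, replace = TRUE) - 1L
  w <- sample(50:1500, n, replace = TRUE)
  peak_set(ch, st, st + w, signal = runif(n, 0, 10), name = name)
}
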