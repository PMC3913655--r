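# Brute-force reference implementations, kept deliberately naive and
# independent of the package's algorithms.

oracle_window_median <- function(mid, val, window, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep("*", length(mid))
  vapply(seq_along(mid), function(i) {
    inwin <- chrom == chrom[i] & abs(mid - mid[i]) <= window / 2
    median(val[inwin])
  }, numeric(1))
}

oracle_top_k <- function(records, k) {
  df <- records[order(-records$max400, records$promoter_id), ]
  df$promoter_id[seq_len(min(k, nrow(df)))]
}

oracle_consensus_counts <- function(sets) {
  ids <- sort(unique(unlist(sets)))
  vapply(ids, function(id)
    sum(vapply(sets, function(s) id %in% s, logical(1))), integer(1))
}

# largest group of positions pairwise within tol = longest run in sorted
# order with max - min <= tol; leftmost run on ties. Checked by all-pairs
# scan over every (start, end) index pair.
oracle_concordant_group <- function(positions, tol) {
  p <- sort(positions)
  n <- length(p)
  best <- c(1, 1)
  for (i in seq_len(n)) for (j in i:n) {
    if (p[j] - p[i] <= tol && (j - i) > (best[2] - best[1]))
      best <- c(i, j)
  }
  p[best[1]:best[2]]
}

# per-base stabbing count over integer positions, distinct samples
oracle_max_stab <- function(segments) {
  pos <- seq(min(segments$start), max(segments$end) - 1)
  cover <- vapply(pos, function(x)
    length(unique(segments$sample_id[segments$start <= x & segments$end > x])),
    integer(1))
  list(max_support = max(cover), at = pos[which.max(cover)])
}

# small simulated data set shared across tests
small_sim <- function(seed = 11, n_genes = 60, n_bound = 10, ...) {
  cfg <- sim_config(n_genes = n_genes, n_bound = n_bound, seed = seed, ...)
  list(cfg = cfg, sim = simulate_tiling_arrays(cfg))
}

# hand-built two-promoter fixture on opposite strands with one probe grid
fixture_promoters <- function() {
  make_promoters(c("gplus", "gminus"), "chrF", c("+", "-"),
                 c(10000L, 50000L))
}
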