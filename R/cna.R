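#' Threshold copy-number state calls from probe log-ratios
#'
#' Probes are grouped into fixed-width genomic bins; each bin's median
#' log-ratio is compared to the thresholds (default: <= -1.2 homozygous
#' loss, <= -0.3 hemizygous loss, >= +0.3 gain, else neutral) and adjacent
#' same-state bins are merged into segments. A deliberately minimal,
#' deterministic caller: sufficient for commonly-deleted-region logic, not a
#' replacement for full aCGH segmentation.
#'
#' @param probes `data.frame(chrom, pos, log2ratio)` for one sample (sorted
#'   internally by position).
#' @param sample_id label stored in the output.
#' @param bin_size bin width, bp.
#' @param thresholds named numeric `c(hom=, het=, gain=)`, log2 units, with
#'   `hom < het < 0 < gain`.
#' @return `data.frame(sample_id, chrom, start, end, state)` with
#'   non-overlapping half-open segments; zero rows for an empty sample.
#' @export
call_states <- function(probes, sample_id = "sample", bin_size = 5000,
                        thresholds = c(hom = -1.2, het = -0.3, gain = 0.3)) {
  stopifnot(all(c("hom", "het", "gain") %in% names(thresholds)))
  if (!(thresholds["hom"] < thresholds["het"] &&
        thresholds["het"] < 0 && 0 < thresholds["gain"]))
    .stopf("thresholds must satisfy hom < het < 0 < gain")
  empty <- data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      state = character(), stringsAsFactors = FALSE)
  if (nrow(probes) == 0) return(empty)
  probes <- probes[order(probes$chrom, probes$pos), , drop = FALSE]
  segs <- lapply(split(probes, probes$chrom), function(p) {
    bin <- floor(p$pos / bin_size)
    med <- tapply(p$log2ratio, bin, median)
    b <- as.numeric(names(med))
    state <- ifelse(med <= thresholds["hom"], "loss_hom",
             ifelse(med <= thresholds["het"], "loss_het",
             ifelse(med >= thresholds["gain"], "gain", "neutral")))
    # merge runs of adjacent bins with identical state
    new_run <- c(TRUE, state[-1] != state[-length(state)] |
                   b[-1] != b[-length(b)] + 1)
    run <- cumsum(new_run)
    data.frame(sample_id = sample_id, chrom = p$chrom[1],
               start = tapply(b, run, min) * bin_size,
               end = (tapply(b, run, max) + 1) * bin_size,
               state = state[new_run], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering of samples on copy-number states
#'
#' Average-linkage agglomerative clustering on the Hamming distance (mean
#' state mismatch fraction) between per-bin state vectors. Rows are ordered
#' by sample id before clustering so leaf order is reproducible.
#'
#' @param state_matrix character matrix, samples in rows (rownames are
#'   sample ids), bins in columns.
#' @return list with `hclust` (the tree) and `order` (leaf sample ids).
#' @export
cluster_samples <- function(state_matrix) {
  if (nrow(state_matrix) < 2) .stopf("clustering needs >= 2 samples")
  m <- state_matrix[order(rownames(state_matrix)), , drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- mean(m[i, ] != m[j, ])
  hc <- hclust(as.dist(d), method = "average")
  list(hclust = hc, order = rownames(m)[hc$order])
}

#' Per-bin state matrix across samples
#'
#' Convenience: calls states per sample and rasterizes them onto a shared
#' bin grid (missing coverage is neutral).
#'
#' @param sample_tables named list of per-sample probe tables.
#' @param bin_size,thresholds see [call_states()].
#' @return character matrix samples x bins, with `chrom:start` column names.
#' @export
cna_state_matrix <- function(sample_tables, bin_size = 5000,
                             thresholds = c(hom = -1.2, het = -0.3,
                                            gain = 0.3)) {
  segs <- lapply(names(sample_tables), function(sid)
    call_states(sample_tables[[sid]], sample_id = sid, bin_size = bin_size,
                thresholds = thresholds))
  all <- do.call(rbind, segs)
  bins <- unique(do.call(rbind, lapply(split(all, all$chrom), function(a)
    data.frame(chrom = a$chrom[1],
               start = seq(min(a$start), max(a$end) - bin_size,
                           by = bin_size)))))
  key <- paste0(bins$chrom, ":", bins$start)
  m <- matrix("neutral", length(sample_tables), nrow(bins),
              dimnames = list(names(sample_tables), key))
  for (k in seq_len(nrow(all))) {
    s <- all[k, ]
    hit <- bins$chrom == s$chrom & bins$start >= s$start & bins$start < s$end
    m[s$sample_id, hit] <- s$state
  }
  m
}

#' Commonly deleted region across samples
#'
#' Sweep-line interval stabbing over loss segments: returns the genomic
#' interval covered by loss segments of the largest number of distinct
#' samples (support). When several intervals tie, the leftmost (by
#' chromosome name, then coordinate) is returned; overlapping loss segments
#' within one sample count once.
#'
#' @param segments `data.frame(sample_id, chrom, start, end, state)`; only
#'   `loss_het`/`loss_hom` rows are used.
#' @param states states counted as loss.
#' @return `list(chrom, start, end, support)`, or `NULL` when no loss
#'   segment exists.
#' @export
commonly_deleted_region <- function(segments,
                                    states = c("loss_het", "loss_hom")) {
  loss <- segments[segments$state %in% states, , drop = FALSE]
  if (nrow(loss) == 0) return(NULL)
  best <- NULL
  for (ch in sort(unique(loss$chrom))) {
    l <- loss[loss$chrom == ch, , drop = FALSE]
    # union per sample so a sample never counts twice at one position
    ev <- do.call(rbind, lapply(split(l, l$sample_id), function(s) {
      s <- s[order(s$start), , drop = FALSE]
      merged_start <- numeric(); merged_end <- numeric()
      cs <- s$start[1]; ce <- s$end[1]
      for (i in seq_len(nrow(s))[-1]) {
        if (s$start[i] <= ce) ce <- max(ce, s$end[i])
        else { merged_start <- c(merged_start, cs)
               merged_end <- c(merged_end, ce)
               cs <- s$start[i]; ce <- s$end[i] }
      }
      data.frame(start = c(merged_start, cs), end = c(merged_end, ce))
    }))
    bp <- sort(unique(c(ev$start, ev$end)))
    if (length(bp) < 2) next
    lo <- bp[-length(bp)]; hi <- bp[-1]
    cover <- vapply(seq_along(lo), function(i)
      sum(ev$start <= lo[i] & ev$end >= hi[i]), integer(1))
    mx <- max(cover)
    # merge adjacent elementary intervals at maximal support; take leftmost
    at <- which(cover == mx)
    first <- at[1]
    last <- first
    while (last + 1 <= length(cover) && cover[last + 1] == mx &&
           lo[last + 1] == hi[last]) last <- last + 1
    cand <- list(chrom = ch, start = lo[first], end = hi[last], support = mx)
    if (is.null(best) || cand$support > best$support) best <- cand
  }
  best
}
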