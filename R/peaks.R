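#' Collect per-replicate peak locations
#'
#' @param max_tables list of [max400_scores()] tables, one per replicate.
#' @return `data.frame(promoter_id, replicate_id, position)`; one row per
#'   replicate per scored promoter (promoters missing from a replicate
#'   simply contribute fewer rows).
#' @export
peak_locations <- function(max_tables) {
  out <- do.call(rbind, lapply(max_tables, function(t)
    t[, c("promoter_id", "replicate_id", "peak_position")]))
  names(out)[3] <- "position"
  rownames(out) <- NULL
  out
}

# largest group of positions that are pairwise within `tolerance`
# (equivalently max - min <= tolerance on a sorted run); ties go to the
# leftmost such run, so the result is deterministic and symmetric in input
# order.
.largest_concordant_group <- function(positions, tolerance) {
  p <- sort(positions)
  n <- length(p)
  best_i <- 1L; best_len <- 1L
  lo <- 1L
  for (hi in seq_len(n)) {
    while (p[hi] - p[lo] > tolerance) lo <- lo + 1L
    len <- hi - lo + 1L
    if (len > best_len) { best_len <- len; best_i <- lo }
  }
  p[best_i:(best_i + best_len - 1L)]
}

#' Concordant peak call from replicate positions
#'
#' A call exists iff at least `m` replicate peak positions are pairwise
#' within `tolerance` bp of each other; the consensus position is the median
#' of the agreeing group. The default tolerance of one probe spacing
#' (100 bp) reflects that positions are probe-quantized.
#'
#' @param positions numeric replicate peak positions for one promoter.
#' @param tolerance maximal pairwise distance, bp (`>= 0`).
#' @param m minimal group size (default 2 of 3).
#' @return `list(position, support)` or `NULL` when no group qualifies.
#' @export
concordant_peak <- function(positions, tolerance = 100, m = 2) {
  if (tolerance < 0) .stopf("tolerance must be >= 0")
  positions <- positions[!is.na(positions)]
  if (length(positions) < m) return(NULL)
  g <- .largest_concordant_group(positions, tolerance)
  if (length(g) < m) return(NULL)
  list(position = median(g), support = length(g))
}

#' Concordant peak calls across promoters
#'
#' Applies [concordant_peak()] per promoter and attaches the strand-aware
#' TSS offset (negative = upstream on both strands).
#'
#' @param locations table from [peak_locations()].
#' @param promoters promoter table.
#' @param tolerance,m see [concordant_peak()].
#' @return `data.frame(promoter_id, consensus_position, tss_offset,
#'   support)`, one row per called promoter.
#' @export
concordant_peaks <- function(locations, promoters, tolerance = 100, m = 2) {
  idx <- match(promoters$gene_id, promoters$gene_id)
  tss <- setNames(promoters$tss, promoters$gene_id)
  strand <- setNames(promoters$strand, promoters$gene_id)
  calls <- lapply(split(locations$position, locations$promoter_id),
                  concordant_peak, tolerance = tolerance, m = m)
  keep <- !vapply(calls, is.null, logical(1))
  ids <- names(calls)[keep]
  pos <- vapply(calls[keep], `[[`, numeric(1), "position")
  sup <- vapply(calls[keep], `[[`, integer(1), "support")
  off <- ifelse(strand[ids] == "+", pos - tss[ids], tss[ids] - pos)
  out <- data.frame(promoter_id = ids, consensus_position = unname(pos),
                    tss_offset = unname(off), support = unname(sup),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Extract a genomic sequence, strand-aware
#'
#' Returns the uppercase sequence of a 0-based half-open interval,
#' reverse-complemented for minus-strand promoters.
#'
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param chrom chromosome name; an absent chromosome is an error naming it.
#' @param start,end 0-based half-open interval within the chromosome.
#' @param strand `"+"` or `"-"`.
#' @return character scalar of length `end - start`.
#' @export
extract_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  if (!chrom %in% names(genome))
    .stopf("chromosome %s absent from genome FASTA", chrom)
  if (start < 0 || end > nchar(genome[[chrom]]) || start >= end)
    .stopf("interval [%d, %d) outside chromosome %s", start, end, chrom)
  s <- toupper(substr(genome[[chrom]], start + 1L, end))
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Peak probe sequences for concordant calls
#'
#' For each call, the sequence extracted is the interval of the promoter's
#' probe whose midpoint is nearest the consensus position (the peak probe's
#' own interval, which is why reported lengths track the 50-75 bp probe
#' design).
#'
#' @param calls table from [concordant_peaks()].
#' @param probes probe table.
#' @param promoters promoter table.
#' @param genome named character vector or `DNAStringSet`.
#' @return named character vector of sequences, one per call.
#' @export
peak_sequences <- function(calls, probes, promoters, genome) {
  p <- probes[!probes$is_control, , drop = FALSE]
  strand <- setNames(promoters$strand, promoters$gene_id)
  out <- vapply(seq_len(nrow(calls)), function(i) {
    pp <- p[p$promoter_id == calls$promoter_id[i], , drop = FALSE]
    j <- which.min(abs(pp$mid - calls$consensus_position[i]))
    extract_sequence(genome, pp$chrom[j], pp$start[j], pp$end[j],
                     strand[calls$promoter_id[i]])
  }, character(1))
  setNames(out, calls$promoter_id)
}

.offset_bins <- function(upstream, downstream, bin_width) {
  # bins centred on multiples of bin_width so the canonical -500 offset is a
  # bin centre, covering [-upstream, +downstream]
  centers <- seq(-ceiling(upstream / bin_width) * bin_width,
                 ceiling(downstream / bin_width) * bin_width,
                 by = bin_width)
  list(centers = centers, breaks = c(centers - bin_width / 2,
                                     centers[length(centers)] + bin_width / 2))
}

#' TSS-relative histogram of peak offsets
#'
#' Only promoters with a single annotated TSS contribute; multi-TSS
#' promoters are excluded and counted in the `excluded` attribute. Bins are
#' `bin_width` bp wide, centred on multiples of `bin_width`, spanning the
#' promoter design.
#'
#' @param calls table from [concordant_peaks()] (needs `tss_offset`).
#' @param promoters promoter table carrying `n_tss`.
#' @param bin_width bin width, bp.
#' @param upstream,downstream span of the histogram around the TSS, bp.
#' @return `data.frame(offset, count)` with attribute `excluded` (number of
#'   multi-TSS promoters dropped).
#' @export
tss_profile <- function(calls, promoters, bin_width = 100, upstream = 2200,
                        downstream = 500) {
  n_tss <- setNames(promoters$n_tss, promoters$gene_id)
  keep <- n_tss[calls$promoter_id] == 1L
  bins <- .offset_bins(upstream, downstream, bin_width)
  idx <- findInterval(calls$tss_offset[keep], bins$breaks,
                      rightmost.closed = TRUE)
  idx <- idx[idx >= 1 & idx <= length(bins$centers)]
  counts <- tabulate(idx, nbins = length(bins$centers))
  out <- data.frame(offset = bins$centers, count = counts)
  attr(out, "excluded") <- sum(!keep)
  out
}

#' Average binding intensity along the promoter
#'
#' Replicate-mean smoothed intensity per probe, averaged within TSS-offset
#' bins over all (or a subset of) single-TSS promoters: the smoothed
#' positional binding profile.
#'
#' @param probes probe table.
#' @param smoothed_list list of named smoothed-value vectors, one per
#'   replicate (from [smooth_probes()]).
#' @param promoters promoter table.
#' @param subset optional promoter ids to restrict to (e.g. consensus
#'   targets).
#' @param bin_width bin width, bp.
#' @return `data.frame(offset, mean_intensity, n_probes)`.
#' @export
average_binding_curve <- function(probes, smoothed_list, promoters,
                                  subset = NULL, bin_width = 100) {
  p <- probes[!probes$is_control, , drop = FALSE]
  single <- promoters$gene_id[promoters$n_tss == 1L]
  if (!is.null(subset)) single <- intersect(single, subset)
  p <- p[p$promoter_id %in% single, , drop = FALSE]
  sm <- rowMeans(vapply(smoothed_list, function(s) s[p$probe_id],
                        numeric(nrow(p))))
  tss <- setNames(promoters$tss, promoters$gene_id)
  strand <- setNames(promoters$strand, promoters$gene_id)
  off <- ifelse(strand[p$promoter_id] == "+", p$mid - tss[p$promoter_id],
                tss[p$promoter_id] - p$mid)
  bin <- round(off / bin_width) * bin_width
  agg <- tapply(sm, bin, mean)
  out <- data.frame(offset = as.numeric(names(agg)),
                    mean_intensity = as.numeric(agg),
                    n_probes = as.integer(table(bin)))
  out[order(out$offset), , drop = FALSE]
}

#' Cross-replicate concordance of peak locations
#'
#' Pearson correlation of per-promoter peak positions between every pair of
#' replicates, reported separately for a promoter subset (e.g. the consensus
#' targets) and for all remaining promoters. Pairs with fewer than 3
#' complete promoters are reported as `NA`.
#'
#' @param locations table from [peak_locations()].
#' @param subset character promoter ids forming the target subset.
#' @return `data.frame(rep_a, rep_b, subset, n, r)`.
#' @export
peak_location_concordance_stats <- function(locations, subset = character()) {
  reps <- sort(unique(locations$replicate_id))
  if (length(reps) < 2) .stopf("need >= 2 replicates")
  ids <- sort(unique(locations$promoter_id))
  wide <- matrix(NA_real_, length(ids), length(reps),
                 dimnames = list(ids, reps))
  wide[cbind(match(locations$promoter_id, ids),
             match(locations$replicate_id, reps))] <- locations$position
  groups <- list(subset = intersect(ids, subset),
                 rest = setdiff(ids, subset))
  rows <- list()
  for (g in names(groups)) {
    w <- wide[groups[[g]], , drop = FALSE]
    for (a in seq_along(reps)) for (b in seq_along(reps)) {
      if (a >= b) next
      ok <- complete.cases(w[, c(a, b), drop = FALSE])
      r <- if (sum(ok) < 3) NA_real_ else cor(w[ok, a], w[ok, b])
      rows[[length(rows) + 1L]] <-
        data.frame(rep_a = reps[a], rep_b = reps[b], subset = g,
                   n = sum(ok), r = r, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
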