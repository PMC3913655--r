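#' Global-median normalization on control probes
#'
#' Subtracts from every probe the median log-ratio of the array's control
#' probes, so that the control-probe median is exactly zero afterwards. With
#' an even number of controls the median is the mean of the two middle
#' values.
#'
#' @param array a [log_ratio_array()] (or plain named numeric vector).
#' @param control_ids probe ids of the control probes.
#' @param fallback_all if no control probe is present: when `TRUE`, the
#'   all-probe median is used instead (with a message); when `FALSE`
#'   (default) this is an error.
#' @return the normalized array, same shape as the input.
#' @export
global_median_normalize <- function(array, control_ids,
                                    fallback_all = FALSE) {
  vals <- if (inherits(array, "log_ratio_array")) array$values else array
  ctrl <- intersect(control_ids, names(vals))
  if (length(ctrl) == 0) {
    if (!fallback_all)
      .stopf(paste("no control probes on array; rerun with",
                   "fallback_all = TRUE to centre on the all-probe median"))
    message("no control probes; centring on all-probe median")
    shift <- median(vals)
  } else {
    shift <- median(vals[ctrl])
  }
  out <- vals - shift
  if (inherits(array, "log_ratio_array"))
    log_ratio_array(array$replicate_id, out)
  else out
}

#' Windowed-median smoothing along the genome
#'
#' Moving along each chromosome, the smoothed value at a probe is the median
#' log-ratio of all probes (including the probe itself) whose interval
#' midpoints lie within `window/2` bp of its own midpoint, boundaries
#' inclusive. Windows never span chromosomes. An isolated probe is its own
#' median.
#'
#' @param midpoints numeric probe midpoints, non-decreasing within each
#'   chromosome; unsorted input is an error, never silently reordered.
#' @param values probe log-ratios, parallel to `midpoints`.
#' @param window window width in bp (default 400).
#' @param chrom optional chromosome per probe; smoothing is done per
#'   chromosome in input order.
#' @return numeric vector of smoothed values, parallel to the input.
#' @export
smooth_window_median <- function(midpoints, values, window = 400,
                                 chrom = NULL) {
  if (window <= 0) .stopf("window must be positive")
  if (length(midpoints) != length(values))
    .stopf("midpoints and values differ in length")
  if (is.null(chrom)) chrom <- rep("*", length(midpoints))
  out <- numeric(length(values))
  for (idx in split(seq_along(values), chrom)) {
    m <- midpoints[idx]
    if (is.unsorted(m))
      .stopf("probe midpoints are not sorted within chromosome %s",
             chrom[idx[1]])
    out[idx] <- .window_median_sorted(m, values[idx], window / 2)
  }
  out
}

# two-pointer running window over sorted midpoints; median computed by
# partial sort of the (small) window
.window_median_sorted <- function(mid, val, half) {
  n <- length(mid)
  sm <- numeric(n)
  lo <- 1L; hi <- 1L
  for (i in seq_len(n)) {
    while (mid[lo] < mid[i] - half) lo <- lo + 1L
    if (hi < i) hi <- i
    while (hi < n && mid[hi + 1L] <= mid[i] + half) hi <- hi + 1L
    w <- sort.int(val[lo:hi], method = "quick")
    k <- hi - lo + 1L
    sm[i] <- if (k %% 2L == 1L) w[(k + 1L) %/% 2L]
             else (w[k %/% 2L] + w[k %/% 2L + 1L]) / 2
  }
  sm
}

#' Smooth one replicate's probe log-ratios
#'
#' Convenience wrapper: aligns a log-ratio array to the (sorted) probe
#' table, smooths non-control probes per chromosome, and returns a named
#' vector of smoothed values.
#'
#' @param probes probe table (see [read_probe_table()]; must be sorted,
#'   which the reader guarantees).
#' @param array a [log_ratio_array()].
#' @param window smoothing window, bp.
#' @return named numeric vector of smoothed values for non-control probes.
#' @export
smooth_probes <- function(probes, array, window = 400) {
  p <- probes[!probes$is_control, , drop = FALSE]
  vals <- array$values[p$probe_id]
  if (anyNA(vals))
    .stopf("replicate %s lacks values for some probes", array$replicate_id)
  setNames(smooth_window_median(p$mid, vals, window = window,
                                chrom = p$chrom),
           p$probe_id)
}

#' Per-promoter Max400 scores for one replicate
#'
#' The Max400 score of a promoter is the highest smoothed value among its
#' probes; the peak probe is the one attaining it, ties broken toward the
#' probe nearest the TSS, then toward the smallest genomic coordinate.
#' Promoters without probes yield no row and are recorded in the `missing`
#' attribute rather than scored 0.
#'
#' @param probes probe table.
#' @param smoothed named numeric vector from [smooth_probes()].
#' @param promoters promoter table.
#' @param replicate_id label stored in the output.
#' @return `data.frame(promoter_id, replicate_id, max400, peak_probe_id,
#'   peak_position)`, one row per scored promoter; `peak_position` is the
#'   peak probe's midpoint.
#' @export
max400_scores <- function(probes, smoothed, promoters,
                          replicate_id = NA_character_) {
  p <- probes[!probes$is_control, , drop = FALSE]
  sm <- smoothed[p$probe_id]
  tss <- setNames(promoters$tss, promoters$gene_id)
  groups <- split(seq_len(nrow(p)), p$promoter_id)
  ids <- names(groups)
  res <- lapply(ids, function(g) {
    i <- groups[[g]]
    v <- sm[i]
    top <- i[v == max(v)]
    if (length(top) > 1L) {
      d <- abs(p$mid[top] - tss[g])
      top <- top[order(d, p$mid[top])][1L]
    }
    c(max400 = unname(max(v)), pos = p$mid[top], row = top)
  })
  res <- do.call(rbind, res)
  out <- data.frame(promoter_id = ids,
                    replicate_id = replicate_id,
                    max400 = res[, "max400"],
                    peak_probe_id = p$probe_id[res[, "row"]],
                    peak_position = res[, "pos"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "missing") <- setdiff(promoters$gene_id, ids)
  out
}

#' Top-k promoters of one replicate by Max400 score
#'
#' Deterministic boundary handling: ordering is by score descending, then
#' promoter id ascending.
#'
#' @param records a [max400_scores()] table.
#' @param k list size (default 500, the published cut).
#' @return character vector of promoter ids, `min(k, n)` long.
#' @export
top_k <- function(records, k = 500) {
  if (k < 1) .stopf("k must be >= 1")
  ord <- order(-records$max400, records$promoter_id)
  records$promoter_id[head(ord, k)]
}

#' Replicate-consensus target calls
#'
#' A promoter is a consensus member when it appears in the per-replicate
#' top-k sets of at least `m` replicates (the published rule: top 500 in at
#' least 2 of 3 arrays).
#'
#' @param sets list of per-replicate promoter-id sets.
#' @param m minimal number of supporting replicates.
#' @return `data.frame(promoter_id, n_support, member)` over the union of
#'   the sets, ordered by support descending then id.
#' @export
consensus <- function(sets, m = 2) {
  if (m < 1 || m > length(sets))
    .stopf("m must satisfy 1 <= m <= number of replicate sets (%d)",
           length(sets))
  all_ids <- unlist(lapply(sets, unique), use.names = FALSE)
  tab <- table(all_ids)
  out <- data.frame(promoter_id = names(tab),
                    n_support = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$member <- out$n_support >= m
  out <- out[order(-out$n_support, out$promoter_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the replicated ChIP scoring pipeline
#'
#' Normalizes each replicate on its control probes, smooths with the
#' windowed median, scores promoters (Max400), takes per-replicate top-k
#' lists and forms the m-of-n consensus.
#'
#' @param promoters,probes,replicates as produced by
#'   [simulate_tiling_arrays()] or the readers.
#' @param window smoothing window, bp.
#' @param k per-replicate list size.
#' @param m consensus support threshold.
#' @param normalize `"control-median"` (default) or `"none"`.
#' @return list with `max_tables` (per replicate), `smoothed` (per
#'   replicate, named vectors), `top_sets`, `consensus` (the full table) and
#'   `members` (consensus promoter ids).
#' @export
chip_score_pipeline <- function(promoters, probes, replicates, window = 400,
                                k = 500, m = 2,
                                normalize = c("control-median", "none")) {
  normalize <- match.arg(normalize)
  control_ids <- probes$probe_id[probes$is_control]
  max_tables <- list(); smoothed_list <- list()
  for (arr in replicates) {
    if (normalize == "control-median")
      arr <- global_median_normalize(arr, control_ids)
    sm <- smooth_probes(probes, arr, window = window)
    smoothed_list[[arr$replicate_id]] <- sm
    max_tables[[arr$replicate_id]] <-
      max400_scores(probes, sm, promoters, replicate_id = arr$replicate_id)
  }
  top_sets <- lapply(max_tables, top_k, k = k)
  cons <- consensus(top_sets, m = m)
  list(max_tables = max_tables, smoothed = smoothed_list,
       top_sets = top_sets, consensus = cons,
       members = cons$promoter_id[cons$member])
}
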