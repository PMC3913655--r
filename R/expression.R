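#' Quantile normalization of an expression matrix
#'
#' After normalization every column's sorted values equal the across-column
#' mean of order statistics; ties within a column receive the mean of the
#' tied normalized values and column rank orders are preserved. Delegates to
#' \code{limma::normalizeQuantiles(ties = TRUE)}, which implements exactly
#' this contract.
#'
#' @param x numeric matrix (genes x samples) or an [expression_matrix()];
#'   at least 2 samples.
#' @return same type as the input, normalized.
#' @export
quantile_normalize <- function(x) {
  em <- inherits(x, "expression_matrix")
  m <- if (em) x$values else as.matrix(x)
  if (ncol(m) < 2) .stopf("quantile normalization needs >= 2 samples")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  if (em) expression_matrix(out, x$arms) else out
}

#' Correlation-based QC of silenced samples
#'
#' Per-gene log-ratios are formed for each silenced sample by subtracting
#' the control-arm mean; pairwise Pearson correlations among silenced
#' samples are computed on these log-ratios. Outliers are removed
#' iteratively: at each step the sample with the lowest mean pairwise
#' correlation is flagged if that mean falls below `threshold` or sits more
#' than `margin` below the arm's mean correlation; correlations among the
#' remaining samples are then re-examined. Flagging stops when no sample
#' qualifies or only two silenced samples remain (a pair cannot identify its
#' own outlier). This mechanizes the published visual pairs-plot judgment
#' that reduced three silenced arrays to two.
#'
#' @param em an [expression_matrix()] with both arms present.
#' @param threshold absolute mean-correlation floor (default 0.5).
#' @param margin below-arm-mean margin (default 0.25).
#' @return list with `correlations` (full silenced-sample correlation
#'   matrix), `mean_cor` (initial per-sample means), `flagged`, `kept`, and
#'   `log` (one entry per removal, with the statistics at the time of
#'   flagging).
#' @export
qc_correlations <- function(em, threshold = 0.5, margin = 0.25) {
  sil <- names(em$arms)[em$arms == "silenced"]
  ctl <- names(em$arms)[em$arms == "control"]
  if (length(sil) < 2 || length(ctl) < 1)
    .stopf("QC needs >= 2 silenced and >= 1 control samples")
  lr <- em$values[, sil, drop = FALSE] -
    rowMeans(em$values[, ctl, drop = FALSE])
  cors <- cor(lr)
  kept <- sil
  flagged <- character()
  log <- list()
  mean_pairwise <- function(k)
    vapply(k, function(s) mean(cors[s, setdiff(k, s)]), numeric(1))
  mc0 <- mean_pairwise(sil)
  while (length(kept) > 2) {
    mc <- mean_pairwise(kept)
    worst <- kept[order(mc, kept)][1]
    if (mc[worst] < threshold || mean(mc) - mc[worst] > margin) {
      flagged <- c(flagged, worst)
      log[[worst]] <- list(mean_cor = mc[worst], arm_mean = mean(mc))
      kept <- setdiff(kept, worst)
    } else break
  }
  list(correlations = cors, mean_cor = mc0, flagged = flagged, kept = kept,
       log = log)
}

#' Differential expression between silenced and control arms
#'
#' The default `"modt"` method is a two-sample t on the pooled SD moderated
#' by adding the median per-gene pooled SD to every gene's SD -- a shrinkage
#' guard against spuriously small variances at 2-3 samples per arm, which
#' also keeps zero-variance genes finite. The `"rank"` alternative is the
#' exact permutation test over all arm-label assignments (10 at 2v3, 20 at
#' 3v3) using the arm mean difference as statistic.
#'
#' @param em an [expression_matrix()] (post-QC).
#' @param method `"modt"` or `"rank"`.
#' @param samples optional character vector restricting the samples used
#'   (e.g. `qc$kept` plus the controls); both arms need >= 2 samples.
#' @return `data.frame(gene_id, log_ratio, statistic, p_value, rank_up,
#'   rank_down)`; `log_ratio` is mean(silenced) - mean(control) in log2,
#'   ranks are permutations with deterministic `(statistic, gene_id)`
#'   tie-breaks.
#' @export
differential_expression <- function(em, method = c("modt", "rank"),
                                    samples = NULL) {
  method <- match.arg(method)
  arms <- em$arms
  if (!is.null(samples)) arms <- arms[names(arms) %in% samples]
  sil <- names(arms)[arms == "silenced"]
  ctl <- names(arms)[arms == "control"]
  if (length(sil) < 2 || length(ctl) < 2)
    .stopf("differential expression needs >= 2 samples per arm (have %d silenced, %d control)",
           length(sil), length(ctl))
  x <- em$values[, sil, drop = FALSE]
  y <- em$values[, ctl, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  lr <- rowMeans(x) - rowMeans(y)

  if (method == "modt") {
    v1 <- apply(x, 1, var); v2 <- apply(y, 1, var)
    s <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
    s_mod <- s + median(s)
    se <- s_mod * sqrt(1 / n1 + 1 / n2)
    stat <- ifelse(se > 0, lr / se, 0)
    p <- 2 * pt(-abs(stat), df = n1 + n2 - 2)
    p[se == 0] <- 1
  } else {
    cols <- cbind(x, y)
    assigns <- combn(n1 + n2, n1)
    eps <- 1e-12
    obs <- lr
    exceed <- integer(length(lr))
    for (j in seq_len(ncol(assigns))) {
      a <- assigns[, j]
      d <- rowMeans(cols[, a, drop = FALSE]) -
        rowMeans(cols[, -a, drop = FALSE])
      exceed <- exceed + (abs(d) >= abs(obs) - eps)
    }
    stat <- obs
    p <- exceed / ncol(assigns)
  }

  gene_id <- rownames(em$values)
  ord_up <- order(-stat, gene_id)
  ord_dn <- order(stat, gene_id)
  rank_up <- integer(length(stat)); rank_up[ord_up] <- seq_along(stat)
  rank_dn <- integer(length(stat)); rank_dn[ord_dn] <- seq_along(stat)
  out <- data.frame(gene_id = gene_id, log_ratio = unname(lr),
                    statistic = unname(stat), p_value = unname(p),
                    rank_up = rank_up, rank_down = rank_dn,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "samples") <- c(sil, ctl)
  rownames(out) <- NULL
  out
}

#' Top-n up- and down-regulated gene lists
#'
#' @param de a [differential_expression()] table.
#' @param n list length (`<=` gene count); the published analyses use 30 for
#'   reporting and 2000 for the expanded functional set.
#' @return `list(up, down)` of gene-id character vectors.
#' @export
top_n_lists <- function(de, n) {
  if (n > nrow(de)) .stopf("n exceeds gene count")
  list(up = de$gene_id[de$rank_up <= n],
       down = de$gene_id[de$rank_down <= n])
}
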