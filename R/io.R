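#' @importFrom stats median rnorm runif rbinom cor t.test wilcox.test
#'   ks.test pt hclust as.dist var complete.cases setNames
#' @importFrom utils read.table write.table combn head
NULL

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

## All genomic coordinates are 0-based, half-open ([start, end)) internally
## and on disk (BED dialect). Strand enters only TSS-relative transforms.

#' Read promoter models from a tab-delimited annotation file
#'
#' The file must carry columns `gene_id`, `chrom`, `strand`, `tss` and
#' optionally `n_tss` (number of annotated transcription start sites for the
#' gene; defaults to 1). The promoter interval is derived from the TSS as
#' `[tss - upstream, tss + downstream)` on the plus strand and mirrored
#' (`[tss - downstream, tss + upstream)`) on the minus strand, matching a
#' tiling design covering 2200 bp upstream and 500 bp downstream of the TSS.
#'
#' @param path path to a TSV file with a header row.
#' @param upstream,downstream promoter span relative to the TSS, in bp.
#' @param chrom_sizes optional named integer vector of chromosome lengths;
#'   when given, promoter intervals are clipped to `[0, size)` and a message
#'   records each clipped record.
#' @return a `data.frame` with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `start`, `end`, `n_tss` (one row per promoter), 0-based half-open.
#' @export
read_promoters <- function(path, upstream = 2200, downstream = 500,
                           chrom_sizes = NULL) {
  if (!file.exists(path)) .stopf("promoter file not found: %s", path)
  df <- if (file.size(path) == 0) data.frame() else
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               quote = "", comment.char = "")
  if (nrow(df) == 0) {
    .warnf("promoter file %s is empty", path)
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tss = integer(),
                      start = integer(), end = integer(), n_tss = integer(),
                      stringsAsFactors = FALSE))
  }
  req <- c("gene_id", "chrom", "strand", "tss")
  miss <- setdiff(req, names(df))
  if (length(miss))
    .stopf("promoter file %s lacks column(s): %s", path,
           paste(miss, collapse = ", "))
  if (!"n_tss" %in% names(df)) df$n_tss <- 1L
  bad <- which(!df$strand %in% c("+", "-") | is.na(df$tss) | df$n_tss < 1)
  if (length(bad))
    .stopf("malformed promoter record at line %d of %s", bad[1] + 1L, path)
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    .stopf("duplicate gene_id in %s: %s", path, dup[1])
  make_promoters(df$gene_id, df$chrom, df$strand, as.integer(df$tss),
                 n_tss = as.integer(df$n_tss), upstream = upstream,
                 downstream = downstream, chrom_sizes = chrom_sizes)
}

#' Build promoter records from annotation vectors
#'
#' @inheritParams read_promoters
#' @param gene_id,chrom,strand,tss,n_tss parallel annotation vectors.
#' @return see [read_promoters()].
#' @export
make_promoters <- function(gene_id, chrom, strand, tss, n_tss = 1L,
                           upstream = 2200, downstream = 500,
                           chrom_sizes = NULL) {
  chrom <- rep_len(as.character(chrom), length(gene_id))
  strand <- rep_len(as.character(strand), length(gene_id))
  stopifnot(length(gene_id) == length(tss))
  n_tss <- rep_len(as.integer(n_tss), length(gene_id))
  up <- ifelse(strand == "+", upstream, downstream)
  dn <- ifelse(strand == "+", downstream, upstream)
  start <- as.integer(tss - up)
  end <- as.integer(tss + dn)
  if (!is.null(chrom_sizes)) {
    sz <- chrom_sizes[chrom]
    clip <- which(start < 0 | (!is.na(sz) & end > sz))
    if (length(clip)) {
      start <- pmax(start, 0L)
      end <- as.integer(ifelse(is.na(sz), end, pmin(end, sz)))
      message(length(clip), " promoter interval(s) clipped at chromosome ends")
    }
  } else {
    start <- pmax(start, 0L)
  }
  bad <- which(tss < start | tss >= end | start >= end)
  if (length(bad))
    .stopf("TSS outside derived promoter interval for gene %s", gene_id[bad[1]])
  data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
             strand = as.character(strand), tss = as.integer(tss),
             start = start, end = end, n_tss = n_tss,
             stringsAsFactors = FALSE)
}

#' Read a tiling probe table
#'
#' Expects a TSV with columns `probe_id`, `chrom`, `start`, `end`,
#' `promoter_id`, `is_control`. Control probes are positionless labels and
#' may carry `NA` coordinates; every non-control probe must map to exactly
#' one promoter. Output is sorted by `(chrom, start)` with control probes
#' last, so a second read of a written table is a no-op.
#'
#' @param path TSV path.
#' @param promoters optional promoter table; when given, each non-control
#'   probe's `promoter_id` must occur in it.
#' @param min_len,max_len accepted probe lengths in bp (isothermal designs
#'   use variable 50-75 bp probes).
#' @return `data.frame` with the input columns plus `mid` (interval
#'   midpoint, bp).
#' @export
read_probe_table <- function(path, promoters = NULL, min_len = 50,
                             max_len = 75) {
  if (!file.exists(path)) .stopf("probe table not found: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "",
                   colClasses = c(probe_id = "character"))
  req <- c("probe_id", "chrom", "start", "end", "promoter_id", "is_control")
  miss <- setdiff(req, names(df))
  if (length(miss))
    .stopf("probe table %s lacks column(s): %s", path,
           paste(miss, collapse = ", "))
  df$is_control <- as.logical(df$is_control)
  validate_probes(df, promoters = promoters, min_len = min_len,
                  max_len = max_len)
}

validate_probes <- function(df, promoters = NULL, min_len = 50,
                            max_len = 75) {
  ok <- !df$is_control
  len <- df$end[ok] - df$start[ok]
  bad <- which(is.na(len) | len < min_len | len > max_len)
  if (length(bad))
    .stopf("probe %s has length outside [%d, %d]",
           df$probe_id[ok][bad[1]], min_len, max_len)
  if (any(is.na(df$promoter_id[ok]) | df$promoter_id[ok] == ""))
    .stopf("non-control probe without promoter assignment")
  if (!is.null(promoters)) {
    unknown <- setdiff(df$promoter_id[ok], promoters$gene_id)
    if (length(unknown))
      .stopf("probe assigned to unknown promoter: %s", unknown[1])
  }
  if (anyDuplicated(df$probe_id))
    .stopf("duplicate probe_id: %s", df$probe_id[duplicated(df$probe_id)][1])
  df$mid <- (df$start + df$end) / 2
  ord <- order(df$is_control, df$chrom, df$start, df$probe_id,
               na.last = TRUE)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a probe table as TSV
#' @param probes probe `data.frame` (see [read_probe_table()]).
#' @param path output path.
#' @export
write_probe_table <- function(probes, path) {
  cols <- c("probe_id", "chrom", "start", "end", "promoter_id", "is_control")
  write.table(probes[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write promoter models as TSV
#' @param promoters promoter `data.frame`.
#' @param path output path.
#' @export
write_promoters <- function(promoters, path) {
  cols <- c("gene_id", "chrom", "strand", "tss", "n_tss")
  write.table(promoters[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Construct a per-replicate log-ratio array
#'
#' A thin container for one array's probe-level log2(IP/input) ratios.
#'
#' @param replicate_id character scalar.
#' @param values named numeric vector, names are probe ids; all values must
#'   be finite.
#' @param probes optional probe table against which names are resolved.
#' @return object of class `log_ratio_array`.
#' @export
log_ratio_array <- function(replicate_id, values, probes = NULL) {
  if (is.null(names(values)) || anyNA(names(values)))
    .stopf("log-ratio values must be named by probe_id")
  if (any(!is.finite(values)))
    .stopf("non-finite log-ratio for probe %s",
           names(values)[which(!is.finite(values))[1]])
  if (!is.null(probes)) {
    unknown <- setdiff(names(values), probes$probe_id)
    if (length(unknown))
      .stopf("log-ratio probe id not in probe table: %s", unknown[1])
  }
  structure(list(replicate_id = as.character(replicate_id), values = values),
            class = "log_ratio_array")
}

#' Read one replicate's log ratios from TSV (`probe_id`, `value`)
#' @param path TSV path.
#' @param replicate_id identifier for the array; defaults to the file name.
#' @param probes optional probe table for id validation.
#' @export
read_log_ratios <- function(path, replicate_id = basename(path),
                            probes = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(probe_id = "character"))
  if (!all(c("probe_id", "value") %in% names(df)))
    .stopf("log-ratio file %s needs columns probe_id, value", path)
  log_ratio_array(replicate_id, setNames(df$value, df$probe_id),
                  probes = probes)
}

#' Write one replicate's log ratios as TSV
#' @param array a `log_ratio_array`.
#' @param path output path.
#' @export
write_log_ratios <- function(array, path) {
  write.table(data.frame(probe_id = names(array$values),
                         value = unname(array$values)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an expression matrix with arm labels
#'
#' @param values numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids), log2 intensities.
#' @param arms named character vector mapping every sample id to
#'   `"silenced"` or `"control"`.
#' @param log2_transform set `TRUE` if `values` are on the raw intensity
#'   scale and should be log2-transformed on construction.
#' @return object of class `expression_matrix` with elements `values`,
#'   `arms`.
#' @export
expression_matrix <- function(values, arms, log2_transform = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("expression matrix needs gene rownames and sample colnames")
  if (log2_transform) values <- log2(values)
  arms <- arms[colnames(values)]
  if (anyNA(arms) || !all(arms %in% c("silenced", "control")))
    .stopf("every sample needs an arm label in {silenced, control}")
  structure(list(values = values, arms = arms), class = "expression_matrix")
}

#' Read an expression matrix and its arm labels
#'
#' @param values_path TSV, first column `gene_id`, remaining columns one per
#'   sample.
#' @param arms_path TSV with columns `sample_id`, `arm`.
#' @param log2_transform see [expression_matrix()].
#' @export
read_expression_matrix <- function(values_path, arms_path,
                                   log2_transform = FALSE) {
  df <- read.table(values_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  am <- read.table(arms_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  expression_matrix(m, setNames(am$arm, am$sample_id),
                    log2_transform = log2_transform)
}

#' Write an expression matrix and its arm labels
#' @param em an `expression_matrix`.
#' @param values_path,arms_path output TSV paths.
#' @export
write_expression_matrix <- function(em, values_path, arms_path) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE)
  write.table(df, values_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(em$arms), arm = unname(em$arms)),
              arms_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(values_path)
}

#' Write genomic records in BED6
#'
#' @param records `data.frame` with columns `chrom`, `start`, `end`, `name`
#'   and optionally `score` (default 0) and `strand` (default `"."`);
#'   coordinates 0-based half-open as BED requires.
#' @param path output path.
#' @export
write_bed <- function(records, path) {
  if (nrow(records) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (!"score" %in% names(records)) records$score <- 0
  if (!"strand" %in% names(records)) records$strand <- "."
  stopifnot(all(records$start < records$end))
  write.table(records[, c("chrom", "start", "end", "name", "score", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#' @param path BED path.
#' @return `data.frame` with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  names(df)[seq_len(min(6, ncol(df)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6, ncol(df)))]
  df
}

#' Write named sequences as FASTA
#' @param sequences named character vector of DNA sequences (may be empty).
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  if (length(sequences) == 0) {
    file.create(path)
    return(invisible(path))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Names are truncated at the first whitespace, as genome FASTA headers
#' usually carry descriptions after the sequence name.
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) return(setNames(character(), character()))
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
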