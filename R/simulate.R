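#' Simulation configuration
#'
#' Collects the parameters of the synthetic tiling-array / expression /
#' copy-number generator. Defaults describe the emulated study design: 3
#' replicate promoter tiling arrays spanning -2200..+500 bp around each TSS
#' at 100 bp probe spacing with 50-75 bp probes, a designated subset of
#' bound promoters carrying a Gaussian enrichment bump centred near -500 bp,
#' and paired 3 silenced + 3 control expression arrays in which bound genes
#' are down-regulated upon silencing (activator model).
#'
#' @param n_genes number of promoters/genes.
#' @param n_bound number of truly bound promoters (`<= n_genes`).
#' @param probe_spacing centre-to-centre probe distance, bp.
#' @param upstream,downstream promoter span around the TSS, bp.
#' @param n_replicates number of tiling-array replicates.
#' @param noise_sd SD of background probe log-ratio noise and of expression
#'   sample noise, log2 units.
#' @param peak_amplitude height of the binding enrichment bump, log2 units.
#' @param peak_center_offset bump centre relative to the TSS, bp (negative =
#'   upstream; strand-aware).
#' @param peak_width_sd Gaussian SD of the bump along the promoter, bp.
#' @param knockdown_effect log2 down-shift of bound genes in the silenced
#'   arm.
#' @param indirect_fraction fraction of unbound genes receiving an indirect
#'   expression shift of random sign and magnitude `knockdown_effect`.
#' @param probe_length probe length, bp (must lie in the 50-75 design
#'   bounds).
#' @param n_control number of positionless control probes per array.
#' @param array_shift_sd SD of the per-array global intensity shift removed
#'   by control-median normalization.
#' @param multi_tss_fraction fraction of genes annotated with >1 TSS
#'   (excluded from TSS-relative positional analyses).
#' @param expr_baseline_mean,expr_baseline_sd distribution of per-gene
#'   baseline log2 expression.
#' @param seed integer seed; all generators are deterministic given the
#'   config.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_bound = 108L, probe_spacing = 100,
                       upstream = 2200, downstream = 500, n_replicates = 3L,
                       noise_sd = 0.25, peak_amplitude = 1.0,
                       peak_center_offset = -500, peak_width_sd = 200,
                       knockdown_effect = 1.0, indirect_fraction = 0.10,
                       probe_length = 60, n_control = 300L,
                       array_shift_sd = 0.1, multi_tss_fraction = 0.05,
                       expr_baseline_mean = 8, expr_baseline_sd = 1.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_bound > cfg$n_genes) .stopf("n_bound must be <= n_genes")
  if (cfg$noise_sd <= 0) .stopf("noise_sd must be positive")
  for (f in c("n_genes", "n_bound", "n_replicates", "probe_spacing",
              "probe_length"))
    if (cfg[[f]] < 1) .stopf("%s must be a positive count", f)
  n_probes <- floor((cfg$upstream + cfg$downstream) / cfg$probe_spacing)
  if (n_probes < 3)
    .stopf("promoter span / probe spacing yields %d probes per promoter; >= 3 required",
           n_probes)
  cfg$probes_per_promoter <- as.integer(n_probes)
  structure(cfg, class = "sim_config")
}

# Independent deterministic seed per generator stage, kept inside 32-bit
# integer range.
.derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 97L + salt * 1009L) %% 2147483647)
}

#' Simulate replicated promoter tiling arrays
#'
#' Each promoter is tiled with `probes_per_promoter` probes whose midpoints
#' sit at `seq(-upstream, by = probe_spacing)` relative to the TSS
#' (strand-aware). Background log-ratios are i.i.d. Normal(0, `noise_sd`)
#' plus a per-array global shift; bound promoters add a Gaussian bump of
#' height `peak_amplitude` centred at `tss + peak_center_offset`, shared
#' across replicates and re-noised independently in each. Control probes
#' carry background plus the array shift only.
#'
#' @param config a [sim_config()].
#' @return list with `promoters` (see [read_promoters()]), `probes`
#'   (see [read_probe_table()]), `replicates` (list of
#'   [log_ratio_array()]), and `bound` (character truth set of bound gene
#'   ids; for tests only, never read by the analysis stages).
#' @export
simulate_tiling_arrays <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.derive_seed(config$seed, 1L))
  n <- config$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  gap <- 4 * (config$upstream + config$downstream)
  tss <- as.integer(gap + (seq_len(n) - 1L) * gap)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_tss <- 1L + stats::rbinom(n, 1L, config$multi_tss_fraction)
  promoters <- make_promoters(gene_id, "chr1", strand, tss, n_tss = n_tss,
                              upstream = config$upstream,
                              downstream = config$downstream)
  bound <- sort(sample(gene_id, config$n_bound))

  k <- config$probes_per_promoter
  offsets <- seq(-config$upstream, by = config$probe_spacing,
                 length.out = k)
  off_all <- rep(offsets, times = n)
  gene_all <- rep(gene_id, each = k)
  strand_all <- rep(strand, each = k)
  mid <- rep(tss, each = k) + ifelse(strand_all == "+", off_all, -off_all)
  half <- floor(config$probe_length / 2)
  probes <- data.frame(
    probe_id = paste0(gene_all, "_P", sprintf("%02d", rep(seq_len(k), n))),
    chrom = "chr1",
    start = as.integer(mid - half),
    end = as.integer(mid - half + config$probe_length),
    promoter_id = gene_all,
    is_control = FALSE,
    stringsAsFactors = FALSE)
  if (config$n_control > 0) {
    probes <- rbind(probes, data.frame(
      probe_id = sprintf("CTRL%05d", seq_len(config$n_control)),
      chrom = NA_character_, start = NA_integer_, end = NA_integer_,
      promoter_id = NA_character_, is_control = TRUE,
      stringsAsFactors = FALSE))
  }
  probes <- validate_probes(probes, promoters = promoters,
                            min_len = 50, max_len = 75)

  # bump is a function of TSS-relative offset, so it is strand-aware by
  # construction and identical across replicates
  is_bound_probe <- gene_all %in% bound
  bump_prom <- config$peak_amplitude *
    exp(-(off_all - config$peak_center_offset)^2 /
          (2 * config$peak_width_sd^2)) * is_bound_probe
  bump <- setNames(rep(0, nrow(probes)), probes$probe_id)
  bump[paste0(gene_all, "_P", sprintf("%02d", rep(seq_len(k), n)))] <- bump_prom

  replicates <- lapply(seq_len(config$n_replicates), function(r) {
    shift <- rnorm(1, 0, config$array_shift_sd)
    vals <- bump + shift + rnorm(nrow(probes), 0, config$noise_sd)
    log_ratio_array(paste0("rep", r), vals, probes = probes)
  })
  list(promoters = promoters, probes = probes, replicates = replicates,
       bound = bound)
}

#' Simulate a genome covering simulated promoters
#'
#' Uniform random nucleotides over each chromosome up to the furthest probe
#' or promoter coordinate plus `flank`. Intended for sequence-extraction
#' round trips on small simulations; clearly synthetic.
#'
#' @param promoters promoter table.
#' @param flank extra bp beyond the last interval.
#' @param seed integer seed.
#' @return named character vector, one element per chromosome.
#' @export
simulate_genome <- function(promoters, flank = 1000, seed = 1L) {
  set.seed(.derive_seed(seed, 7L))
  out <- vapply(split(promoters, promoters$chrom), function(p) {
    len <- max(p$end) + flank
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  out
}

#' Simulate paired silenced/control expression arrays
#'
#' Control-arm samples are per-gene baseline Normal(`expr_baseline_mean`,
#' `expr_baseline_sd`) plus Normal(0, `noise_sd`) sample noise. The silenced
#' arm subtracts `knockdown_effect` from bound genes (activator model) and
#' applies a shift of the same magnitude but random sign to an
#' `indirect_fraction` of unbound genes (indirect, downstream response).
#' Optionally one silenced sample is corrupted with inflated noise to
#' exercise the correlation-based QC.
#'
#' @param config a [sim_config()].
#' @param bound character vector of bound gene ids (the tiling truth set).
#' @param n_silenced,n_control samples per arm.
#' @param bad_sample if `TRUE`, the last silenced sample's noise SD is
#'   multiplied by `bad_noise_factor`.
#' @param bad_noise_factor noise inflation of the corrupted sample.
#' @return list with `em` (an [expression_matrix()]) and `truth` (bound,
#'   indirect_up, indirect_down, bad_sample).
#' @export
simulate_expression <- function(config, bound, n_silenced = 3L,
                                n_control = 3L, bad_sample = FALSE,
                                bad_noise_factor = 6) {
  stopifnot(inherits(config, "sim_config"))
  gene_id <- sprintf("G%05d", seq_len(config$n_genes))
  if (!all(bound %in% gene_id)) .stopf("truth set contains unknown gene ids")
  set.seed(.derive_seed(config$seed, 2L))
  mu <- rnorm(config$n_genes, config$expr_baseline_mean,
              config$expr_baseline_sd)
  names(mu) <- gene_id

  unbound <- setdiff(gene_id, bound)
  n_ind <- floor(config$indirect_fraction * length(unbound))
  ind <- sample(unbound, n_ind)
  sign_ind <- sample(c(-1, 1), n_ind, replace = TRUE)
  shift <- setNames(rep(0, config$n_genes), gene_id)
  shift[bound] <- -config$knockdown_effect
  shift[ind] <- sign_ind * config$knockdown_effect

  samples <- c(paste0("S", seq_len(n_silenced)),
               paste0("C", seq_len(n_control)))
  arms <- setNames(rep(c("silenced", "control"), c(n_silenced, n_control)),
                   samples)
  vals <- matrix(NA_real_, config$n_genes, length(samples),
                 dimnames = list(gene_id, samples))
  for (s in samples) {
    sd_s <- config$noise_sd
    if (bad_sample && s == paste0("S", n_silenced))
      sd_s <- sd_s * bad_noise_factor
    base <- mu + if (arms[s] == "silenced") shift else 0
    vals[, s] <- base + rnorm(config$n_genes, 0, sd_s)
  }
  list(em = expression_matrix(vals, arms),
       truth = list(bound = bound,
                    indirect_up = sort(ind[sign_ind > 0]),
                    indirect_down = sort(ind[sign_ind < 0]),
                    bad_sample = if (bad_sample) paste0("S", n_silenced)))
}

#' Simulate copy-number probe tables with a shared deleted core
#'
#' A probe grid spans `region`; samples carrying a deletion lose an interval
#' that contains `core` with independent random endpoint extensions, shifted
#' by -1 (hemizygous) or -2 (homozygous) log2 units plus noise. Remaining
#' samples are pure noise.
#'
#' @param n_samples total samples.
#' @param core integer `c(start, end)` of the commonly deleted core,
#'   half-open.
#' @param chrom chromosome name.
#' @param n_with_deletion samples whose deletion contains the core.
#' @param hom_samples how many of the deleted samples are homozygous (-2).
#' @param max_extension maximal random extension of each deletion endpoint
#'   beyond the core, bp.
#' @param region probe grid span `c(start, end)`; default core +/- 4
#'   extensions.
#' @param probe_spacing grid spacing, bp.
#' @param noise_sd probe noise SD, log2 units.
#' @param seed integer seed.
#' @return list with `samples` (named list of `data.frame(probe_id, chrom,
#'   pos, log2ratio)`), and `truth` (core, per-sample deletion intervals and
#'   states).
#' @export
simulate_cna <- function(n_samples = 22L, core = c(1000000L, 1040000L),
                         chrom = "chr9", n_with_deletion = 10L,
                         hom_samples = 1L, max_extension = 50000,
                         region = NULL, probe_spacing = 1000,
                         noise_sd = 0.2, seed = 1L) {
  if (core[2] <= core[1]) .stopf("deletion core interval is empty")
  if (n_with_deletion > n_samples)
    .stopf("n_with_deletion must be <= n_samples")
  set.seed(.derive_seed(seed, 3L))
  if (is.null(region))
    region <- c(core[1] - 4 * max_extension, core[2] + 4 * max_extension)
  pos <- seq(region[1], region[2], by = probe_spacing)
  ids <- sprintf("CN%05d", seq_along(pos))
  sample_ids <- sprintf("P%02d", seq_len(n_samples))
  del_samples <- if (n_with_deletion > 0) sample(sample_ids, n_with_deletion)
                 else character()
  hom <- if (hom_samples > 0 && length(del_samples) > 0)
    sample(del_samples, min(hom_samples, length(del_samples))) else character()
  intervals <- list(); states <- character()
  samples <- lapply(sample_ids, function(sid) {
    lr <- rnorm(length(pos), 0, noise_sd)
    if (sid %in% del_samples) {
      s <- core[1] - runif(1, 0, max_extension)
      e <- core[2] + runif(1, 0, max_extension)
      depth <- if (sid %in% hom) -2 else -1
      lr[pos >= s & pos < e] <- lr[pos >= s & pos < e] + depth
      intervals[[sid]] <<- c(floor(s), ceiling(e))
      states[sid] <<- if (depth == -2) "loss_hom" else "loss_het"
    }
    data.frame(probe_id = ids, chrom = chrom, pos = pos, log2ratio = lr,
               stringsAsFactors = FALSE)
  })
  names(samples) <- sample_ids
  list(samples = samples,
       truth = list(core = core, intervals = intervals, states = states))
}
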