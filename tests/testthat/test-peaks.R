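test_that("concordant peak calling follows the m-of-n same-location rule", {
  expect_equal(concordant_peak(c(1000, 1000, 5000), tolerance = 0),
               list(position = 1000, support = 2L))
  expect_null(concordant_peak(c(1000, 1100), tolerance = 0))
  expect_equal(concordant_peak(c(1000, 1100), tolerance = 100)$position,
               1050)
  expect_null(concordant_peak(1000, tolerance = 100))  # below m = 2
  expect_error(concordant_peak(c(1, 2), tolerance = -1), "tolerance")
})

test_that("concordant grouping matches the oracle, is order-symmetric and
           monotone in tolerance", {
  set.seed(61)
  for (i in 1:40) {
    pos <- sample.int(2000, sample(2:7, 1), replace = TRUE)
    tol <- sample(c(0, 50, 100, 300), 1)
    call <- concordant_peak(pos, tolerance = tol, m = 2)
    g <- oracle_concordant_group(pos, tol)
    if (length(g) < 2) {
      expect_null(call)
    } else {
      expect_equal(call$support, length(g))
      expect_equal(call$position, median(g))
    }
    expect_equal(concordant_peak(rev(pos), tolerance = tol, m = 2), call)
    wider <- concordant_peak(pos, tolerance = tol + 200, m = 2)
    if (!is.null(call)) expect_gte(wider$support, call$support)
  }
})

test_that("tss offsets are negative upstream on both strands", {
  proms <- fixture_promoters()  # gplus TSS 10000 (+), gminus TSS 50000 (-)
  loc <- data.frame(
    promoter_id = rep(c("gplus", "gminus"), each = 2),
    replicate_id = rep(c("r1", "r2"), 2),
    position = c(9500, 9500, 50500, 50500))
  calls <- concordant_peaks(loc, proms, tolerance = 0, m = 2)
  expect_equal(calls$tss_offset[calls$promoter_id == "gplus"], -500)
  expect_equal(calls$tss_offset[calls$promoter_id == "gminus"], -500)

  loc$position <- c(10200, 10200, 49800, 49800)  # downstream of the TSS
  calls <- concordant_peaks(loc, proms, tolerance = 0, m = 2)
  expect_true(all(calls$tss_offset == 200))
})

test_that("sequence extraction is strand-aware and round-trips via FASTA", {
  genome <- c(chrF = paste(rep("A", 200), collapse = ""))
  expect_equal(extract_sequence(genome, "chrF", 10, 70),
               paste(rep("A", 60), collapse = ""))
  genome2 <- c(chrF = "ACGTACGTAC")
  expect_equal(extract_sequence(genome2, "chrF", 0, 4), "ACGT")
  expect_equal(extract_sequence(genome2, "chrF", 0, 4, strand = "-"), "ACGT")
  expect_equal(extract_sequence(genome2, "chrF", 1, 5, strand = "-"), "TACG")
  expect_error(extract_sequence(genome2, "chrZ", 0, 4), "chrZ")

  fa <- tempfile(fileext = ".fa")
  write_fasta(c(pk = extract_sequence(genome2, "chrF", 1, 5)), fa)
  expect_equal(unname(read_fasta(fa)["pk"]),
               extract_sequence(genome2, "chrF", 1, 5))
})

test_that("peak sequences come from the consensus peak probe interval", {
  s <- small_sim(seed = 37, n_genes = 40, n_bound = 8)
  genome <- simulate_genome(s$sim$promoters, seed = 37)
  res <- chip_score_pipeline(s$sim$promoters, s$sim$probes,
                             s$sim$replicates, k = 16, m = 2)
  calls <- concordant_peaks(peak_locations(res$max_tables), s$sim$promoters)
  calls <- calls[calls$promoter_id %in% res$members, ]
  seqs <- peak_sequences(calls, s$sim$probes, s$sim$promoters, genome)
  expect_length(seqs, nrow(calls))
  expect_true(all(nchar(seqs) == 60))  # probe length under the design
})

test_that("tss profile excludes multi-TSS promoters and localizes peaks", {
  proms <- make_promoters(c("a", "b", "c"), "chr1", "+",
                          c(10000L, 50000L, 90000L), n_tss = c(1L, 1L, 2L))
  calls <- data.frame(promoter_id = c("a", "b", "c"),
                      consensus_position = c(10000, 50000, 90000),
                      tss_offset = c(0, 0, 0), support = 3L)
  prof <- tss_profile(calls, proms)
  expect_equal(attr(prof, "excluded"), 1)
  expect_equal(sum(prof$count), 2)
  expect_equal(prof$offset[which.max(prof$count)], 0)
})

test_that("average binding curve is flat on constant arrays and peaked on
           enriched promoters", {
  s <- small_sim(seed = 67, n_genes = 60, n_bound = 12,
                 multi_tss_fraction = 0)
  probes <- s$sim$probes
  const <- setNames(rep(1.25, sum(!probes$is_control)),
                    probes$probe_id[!probes$is_control])
  curve <- average_binding_curve(probes, list(const), s$sim$promoters)
  expect_true(all(abs(curve$mean_intensity - 1.25) < 1e-12))

  res <- chip_score_pipeline(s$sim$promoters, probes, s$sim$replicates,
                             k = 24, m = 2)
  curve2 <- average_binding_curve(probes, res$smoothed, s$sim$promoters,
                                  subset = s$sim$bound)
  peak_at <- curve2$offset[which.max(curve2$mean_intensity)]
  expect_lte(abs(peak_at - (-500)), 100)
})

test_that("peak location concordance is 1 for identical replicates and NA
           for tiny subsets", {
  loc <- data.frame(promoter_id = rep(sprintf("g%02d", 1:10), 3),
                    replicate_id = rep(c("r1", "r2", "r3"), each = 10),
                    position = rep(seq(100, 1000, 100), 3))
  st <- peak_location_concordance_stats(loc, subset = sprintf("g%02d", 1:5))
  expect_true(all(abs(st$r - 1) < 1e-12))
  st2 <- peak_location_concordance_stats(loc, subset = sprintf("g%02d", 1:2))
  expect_true(all(is.na(st2$r[st2$subset == "subset"])))
  expect_error(peak_location_concordance_stats(loc[loc$replicate_id == "r1", ]),
               ">= 2 replicates")
})
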