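test_that("state calling thresholds and merges binned medians", {
  pos <- seq(0, 99000, by = 1000)
  flat <- data.frame(chrom = "chr9", pos = pos, log2ratio = 0)
  seg <- call_states(flat, "s1", bin_size = 5000)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$state, "neutral")
  expect_equal(c(seg$start, seg$end), c(0, 100000))

  het <- flat
  het$log2ratio[het$pos >= 20000 & het$pos < 60000] <- -1
  seg2 <- call_states(het, "s1", bin_size = 5000)
  loss <- seg2[seg2$state == "loss_het", ]
  expect_equal(c(loss$start, loss$end), c(20000, 60000))

  hom <- flat
  hom$log2ratio[hom$pos >= 20000 & hom$pos < 60000] <- -2
  expect_true("loss_hom" %in% call_states(hom, "s1", bin_size = 5000)$state)

  gain <- flat
  gain$log2ratio[gain$pos < 10000] <- 0.8
  expect_equal(call_states(gain, "s1", bin_size = 5000)$state[1], "gain")

  expect_equal(nrow(call_states(flat[0, ], "s1")), 0)
  expect_error(call_states(flat, thresholds = c(hom = -0.1, het = -0.5,
                                                gain = 0.3)),
               "hom < het")
})

test_that("noisy seeded deletions are recovered to within a bin", {
  hits <- 0
  for (s in 1:10) {
    cn <- simulate_cna(n_samples = 1, n_with_deletion = 1, hom_samples = 0,
                       seed = 200 + s)
    # bin width of two probe spacings keeps boundary quantization well
    # under 10% of the deleted interval
    seg <- call_states(cn$samples[[1]], names(cn$samples)[1],
                       bin_size = 2000)
    # a -1 shift is recovered as loss; individual bins may straddle the
    # hom/het depth boundary, so both loss states count as recovered
    loss <- seg[seg$state %in% c("loss_het", "loss_hom"), ]
    truth <- cn$truth$intervals[[1]]
    covered <- sum(pmax(0, pmin(loss$end, truth[2]) -
                          pmax(loss$start, truth[1])))
    hits <- hits + (covered >= 0.9 * (truth[2] - truth[1]))
  }
  expect_gte(hits, 9)
})

test_that("sample clustering separates deleted from diploid samples", {
  # modest endpoint extensions keep within-group distances below the
  # deleted-vs-diploid contrast the test asserts
  cn <- simulate_cna(n_samples = 8, n_with_deletion = 4, hom_samples = 0,
                     max_extension = 10000, seed = 33)
  m <- cna_state_matrix(cn$samples)
  cl <- cluster_samples(m)
  grp <- cutree(cl$hclust, k = 2)
  del <- names(cn$truth$intervals)
  expect_equal(length(unique(grp[del])), 1)
  expect_equal(length(unique(grp[setdiff(rownames(m), del)])), 1)
  expect_true(grp[del[1]] != grp[setdiff(rownames(m), del)[1]])

  # duplicate samples merge at distance zero
  m2 <- rbind(a = c("neutral", "loss_het"), b = c("neutral", "loss_het"),
              c = c("gain", "neutral"))
  cl2 <- cluster_samples(m2)
  expect_equal(min(cl2$hclust$height), 0)
  expect_error(cluster_samples(m2[1, , drop = FALSE]), ">= 2 samples")
})

test_that("commonly deleted region matches per-base stabbing on random
           segment sets", {
  set.seed(91)
  for (i in 1:25) {
    n <- sample(2:10, 1)
    segs <- do.call(rbind, lapply(seq_len(n), function(j) {
      k <- sample(1:3, 1)
      st <- sort(sample.int(1900, k))
      data.frame(sample_id = paste0("s", j), chrom = "chrX",
                 start = st, end = st + sample.int(100, k),
                 state = "loss_het", stringsAsFactors = FALSE)
    }))
    got <- commonly_deleted_region(segs)
    want <- oracle_max_stab(segs)
    expect_equal(got$support, want$max_support)
    # the returned interval attains the maximal support at every base
    mids <- seq(got$start, got$end - 1)
    cover <- vapply(mids, function(x)
      length(unique(segs$sample_id[segs$start <= x & segs$end > x])),
      integer(1))
    expect_true(all(cover == want$max_support))
  }
})

test_that("commonly deleted region recovers the seeded shared core", {
  cn <- simulate_cna(n_samples = 22, n_with_deletion = 10, seed = 55)
  segs <- do.call(rbind, lapply(names(cn$samples), function(s)
    call_states(cn$samples[[s]], s, bin_size = 5000)))
  cdr <- commonly_deleted_region(segs)
  expect_equal(cdr$support, 10)
  core <- cn$truth$core
  expect_lte(cdr$start, core[1] + 5000)
  expect_gte(cdr$end, core[2] - 5000)

  # support never increases when the query interval widens
  one <- segs[segs$state != "neutral" & segs$sample_id == segs$sample_id[1], ]
  expect_lte(cdr$support, nrow(unique(segs[segs$state %in%
    c("loss_het", "loss_hom"), "sample_id", drop = FALSE])))
})

test_that("single-sample losses are their own commonly deleted region", {
  segs <- data.frame(sample_id = "s1", chrom = "chr9", start = 100,
                     end = 500, state = "loss_het")
  cdr <- commonly_deleted_region(segs)
  expect_equal(cdr[c("start", "end", "support")],
               list(start = 100, end = 500, support = 1L))
})
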