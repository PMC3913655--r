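test_that("control-median normalization centres controls at zero", {
  vals <- c(a = 1.2, b = -0.4, c1 = 0.5, c2 = 0.7, c3 = 0.9)
  out <- global_median_normalize(vals, c("c1", "c2", "c3"))
  expect_equal(median(out[c("c1", "c2", "c3")]), 0)
  expect_equal(unname(out["a"]), 1.2 - 0.7)

  # even control count: median is the mean of the middle two
  out2 <- global_median_normalize(c(x = 1, c1 = 0.2, c2 = 0.8),
                                  c("c1", "c2"))
  expect_equal(unname(out2["x"]), 1 - 0.5)

  # shift invariance: adding a constant before normalizing changes nothing
  out3 <- global_median_normalize(vals + 3.7, c("c1", "c2", "c3"))
  expect_equal(out3, out)

  expect_error(global_median_normalize(vals, "nope"), "fallback_all")
  expect_message(out4 <- global_median_normalize(vals, "nope",
                                                 fallback_all = TRUE),
                 "all-probe median")
  expect_equal(median(out4), 0)
})

test_that("windowed median matches hand-worked values", {
  mid <- c(0, 100, 200, 300, 400)
  val <- c(1, 2, 9, 2, 1)
  sm <- smooth_window_median(mid, val, window = 400)
  expect_equal(sm[3], median(val))        # full window at the centre probe
  expect_equal(sm, rep(2, 5))             # every 400 bp window has median 2

  expect_equal(smooth_window_median(mid, rep(3.3, 5)), rep(3.3, 5))

  # isolated probe is its own median; windows never span chromosomes
  sm2 <- smooth_window_median(c(0, 100, 5000), c(1, 2, 7))
  expect_equal(sm2[3], 7)
  sm3 <- smooth_window_median(c(0, 100, 50), c(1, 2, 7),
                              chrom = c("c1", "c1", "c2"))
  expect_equal(sm3, c(1.5, 1.5, 7))

  expect_error(smooth_window_median(c(100, 0), c(1, 2)), "not sorted")
})

test_that("windowed median equals the brute-force oracle on random tracks", {
  set.seed(71)
  for (i in 1:30) {
    n <- sample(5:300, 1)
    mid <- sort(sample.int(5000, n))
    val <- rnorm(n)
    w <- sample(c(150, 400, 900), 1)
    expect_equal(smooth_window_median(mid, val, window = w),
                 oracle_window_median(mid, val, w))
  }
})

test_that("Max400 is the promoter max with TSS-proximal tie-breaking", {
  proms <- make_promoters("a", "chr1", "+", 2200L)
  probes <- chipmax:::validate_probes(data.frame(
    probe_id = paste0("p", 1:5), chrom = "chr1",
    start = as.integer(seq(0, 400, 100) - 30),
    end = as.integer(seq(0, 400, 100) + 30),
    promoter_id = "a", is_control = FALSE))
  sm <- setNames(c(2, 2, 2, 2, 2), probes$probe_id)
  rec <- max400_scores(probes, sm, proms)
  expect_equal(rec$max400, 2)
  # five-way tie: the probe nearest the TSS (2200) wins
  expect_equal(rec$peak_probe_id, "p5")

  # single probe promoter: its own value
  rec1 <- max400_scores(probes[3, ], setNames(0.7, "p3"), proms)
  expect_equal(rec1$max400, 0.7)

  # promoters without probes are reported missing, not scored zero
  proms2 <- rbind(proms, make_promoters("b", "chr1", "+", 99000L))
  rec2 <- max400_scores(probes, sm, proms2)
  expect_equal(attr(rec2, "missing"), "b")
})

test_that("Max400 is order-invariant and monotone under constant shifts", {
  s <- small_sim(seed = 23)
  probes <- s$sim$probes
  arr <- s$sim$replicates[[1]]
  sm <- smooth_probes(probes, arr)
  base <- max400_scores(probes, sm, s$sim$promoters)

  # permuting raw probe rows and re-validating (mandatory sort) changes nothing
  set.seed(1)
  shuf <- probes[sample.int(nrow(probes)), ]
  shuf <- chipmax:::validate_probes(shuf, s$sim$promoters)
  sm2 <- smooth_probes(shuf, arr)
  expect_equal(max400_scores(shuf, sm2, s$sim$promoters), base)

  # adding a constant to all log-ratios adds it to every Max400
  arr_c <- log_ratio_array("r", arr$values + 1.5)
  sm3 <- smooth_probes(probes, arr_c)
  up <- max400_scores(probes, sm3, s$sim$promoters)
  expect_equal(up$max400, base$max400 + 1.5)
  expect_equal(up$peak_probe_id, base$peak_probe_id)
})

test_that("top_k matches the full-sort oracle and handles k >= n", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(3:200, 1)
    rec <- data.frame(promoter_id = sprintf("g%03d", sample.int(999, n)),
                      max400 = sample(rnorm(max(3, n %/% 2)), n,
                                      replace = TRUE))
    k <- sample.int(n + 10, 1)
    expect_equal(sort(top_k(rec, k)), sort(oracle_top_k(rec, k)))
    expect_equal(top_k(rec, k), oracle_top_k(rec, k))
  }
  rec <- data.frame(promoter_id = c("a", "b"), max400 = c(1, 2))
  expect_setequal(top_k(rec, 10), c("a", "b"))
  expect_error(top_k(rec, 0), "k must")
})

test_that("consensus counts supporting replicates over the union", {
  same <- list(c("a", "b"), c("a", "b"), c("a", "b"))
  cs <- consensus(same, m = 2)
  expect_setequal(cs$promoter_id[cs$member], c("a", "b"))
  expect_true(all(cs$n_support == 3))

  disj <- list("a", "b", "c")
  expect_false(any(consensus(disj, m = 2)$member))
  expect_error(consensus(disj, m = 4), "1 <= m")

  set.seed(51)
  for (i in 1:30) {
    sets <- lapply(1:3, function(.) sample(letters, sample.int(20, 1)))
    cs <- consensus(sets, m = 2)
    counts <- oracle_consensus_counts(sets)
    expect_equal(setNames(cs$n_support, cs$promoter_id)[names(counts)],
                 counts)
    expect_equal(cs$member, cs$n_support >= 2)
    expect_lte(sum(cs$member), sum(lengths(sets)))
    expect_gte(sum(cs$member),
               length(Reduce(intersect, sets)))
  }
})

test_that("bound promoters dominate the consensus on enriched data", {
  s <- small_sim(seed = 83, n_genes = 120, n_bound = 15)
  res <- chip_score_pipeline(s$sim$promoters, s$sim$probes,
                             s$sim$replicates, k = 30, m = 2)
  expect_gte(mean(s$sim$bound %in% res$members), 0.95)
})
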