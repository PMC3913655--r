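---
title: "Methods: windowed-median ChIP-chip target calling and knockdown integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed-median ChIP-chip target calling and knockdown integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipmax)
```

## The problem

A chimeric transcription factor is assayed by ChIP-chip on a promoter
tiling array: each gene's promoter, from 2200 bp upstream to 500 bp
downstream of its transcription start site (TSS), is tiled with 50--75 bp
probes at 100 bp spacing, and each probe reports a log2(IP/input) ratio.
The experiment is run in triplicate. Two companion data sets complete the
picture: expression arrays from cells in which the factor was silenced by
siRNA (three silenced, three control samples), and copy-number probe
tables from patient samples. `chipmax` implements the full analysis chain:

1. **Direct targets** -- windowed-median ("Max400") scoring of each
   promoter per replicate, per-replicate top-*k* lists, and an *m*-of-*n*
   replicate consensus.
2. **Peak localization** -- cross-replicate concordant peak positions,
   TSS-relative binding profiles, and peak-probe sequence extraction.
3. **Functional targets** -- quantile normalization, correlation-based
   sample QC, and silenced-vs-control differential expression.
4. **Integration** -- a collective expression-shift test of the direct
   set, MA-style overlay tables, and direct/functional intersections.
5. **Copy number** -- threshold segmentation, sample clustering, and the
   commonly-deleted-region query.

## Scoring model

All coordinates are 0-based half-open; strand enters only TSS-relative
transforms (offsets are negative upstream on both strands).

**Normalization.** Each array is centred by subtracting the median
log-ratio of its control probes, so the control median is exactly zero.
The published description of global-median normalization names the tiling
design's own control probes, but the sentence sits in a paragraph about
the aCGH arrays; because the attribution is ambiguous the normalization is
exposed as a flag (`normalize = "control-median"` or `"none"`) rather than
hard-wired.

**Windowed median.** Moving along each chromosome, the smoothed value at a
probe is the median log-ratio of all probes whose interval midpoints lie
within a 400 bp window centred on its own midpoint, boundaries inclusive
and the probe itself included. Midpoints (rather than starts) are used
because they are symmetric for variable 50--75 bp probes; including the
probe itself makes isolated probes well defined (they are their own
median). The median of an even count is the mean of the two middle values.
Windows never cross chromosomes, and control probes take no part in
smoothing or scoring.

**Max400 and consensus.** A promoter's Max400 score is the maximum
smoothed value over its probes; the peak probe is the one attaining it,
with exact ties broken toward the probe nearest the TSS, then the smallest
coordinate. Per replicate, the top *k* = 500 promoters by Max400 are taken
(boundary ties resolved by score, then promoter id), and a promoter is a
consensus direct target when it is in the top-*k* list of at least *m* = 2
of the 3 replicates. The caller is deliberately rank-based: no
significance model is attached to individual peaks.

**Peak concordance.** A concordant peak exists when at least *m* = 2
replicate peak positions agree pairwise within a tolerance; the default
tolerance of 100 bp equals one probe spacing, since peak positions are
probe-quantized. The consensus position is the median of the agreeing
group, and the reported peak sequence is the interval of the probe nearest
that position -- which is why extracted sequences track the probe-length
design.

## Differential expression and integration

Expression matrices are quantile normalized (every column receives the
mean order statistics; ties get the mean of the tied values). Sample QC
forms, for each silenced sample, per-gene log-ratios against the
control-arm mean, and examines pairwise Pearson correlations among the
silenced samples. Outliers are removed iteratively: the sample with the
lowest mean pairwise correlation is flagged when that mean is below an
absolute threshold (default 0.5) or more than a margin (default 0.25)
below the arm average, and the correlations are then re-examined. The
iterative form matters: a single corrupted array drags down its partners'
mean correlations, so applying the absolute threshold to all samples at
once would flag clean arrays too. Flagging stops when two samples remain,
because a pair cannot identify its own outlier; this mechanizes the
published workflow in which a pairs plot reduced three silenced arrays to
two.

The default DE statistic is a two-sample t with the pooled SD moderated by
adding the median per-gene pooled SD to every gene's SD -- a simple
shrinkage guard against spuriously small variances at two or three samples
per arm that also keeps zero-variance genes finite. An exact permutation
alternative (`method = "rank"`) enumerates all arm-label assignments (10
at 2v3, 20 at 3v3). The criterion defining a "significant" gene list is
not part of the method contract: it is an explicit `alpha` knob in
`intersect_targets()`, and the expanded functional sets are simply the top
*n* (default 2000) genes by up- and down-ranking.

The collective shift of the direct-target set is tested by the two-sided
Wilcoxon rank-sum on per-gene log-ratios (direct vs all other genes);
Welch's t and Kolmogorov--Smirnov are reported alongside so that no single
distributional choice is over-committed to. The rank-sum default reflects
that the comparison is between two groups of per-gene changes with no
distributional claim.

## The synthetic-data generator

`sim_config()` fixes the emulated design: 2000 promoters, 108 bound, three
replicates, 100 bp spacing over -2200..+500 (27 probes per promoter), 60 bp
probes, background noise SD 0.25 log2 units, a Gaussian enrichment bump of
height 1.0 (four noise SDs) and positional SD 200 bp centred 500 bp
upstream of the TSS, a knockdown effect of 1.0 log2 on bound genes, and an
indirect response touching 10% of unbound genes with random sign. A
Gaussian bump is the minimal smooth unimodal shape consistent with the
observed positional profile; replicates share the bump and draw
independent noise (no replicate covariance is modelled). Each array also
receives a global intensity shift (SD 0.1) that control-median
normalization removes. Five percent of genes carry a second annotated TSS
and are excluded from positional analyses.

Two generator choices deserve justification. The *indirect fraction*
(10%) encodes that silencing a master regulator perturbs a sizeable
downstream program; it is what gives clean silenced replicates a
between-sample log-ratio correlation near 0.6, the regime in which the
published correlation-plot QC is meaningful. The *bad sample* used in QC
tests inflates one silenced array's noise six-fold, a magnitude typical of
a failed hybridization. Noise magnitudes themselves are free parameters --
the source study reports none -- and are documented here rather than
inferred.

The generator emulates the statistical structure the analysis assumes:
i.i.d. Gaussian probe noise, a shared smooth enrichment shape, and
gene-level expression shifts. It does **not** emulate probe-sequence
effects (GC/Tm affinity biases shared across replicates), spatial artefacts
on the array surface, cross-hybridization, or intensity-dependent variance.
Passing recovery tests therefore demonstrates correctness of the
algorithms under the assumed model, not robustness to every failure mode
of real arrays.

Truth sets are returned alongside the data and are read only by tests and
design-evaluation code, never by the analysis stages.

## Numerical choices and degenerate inputs

* Median of an even count = mean of the middle two, everywhere.
* A promoter with no probes yields an explicit missing record, never a
  zero score.
* Zero-variance genes receive a finite statistic through the median-SD
  moderation; if every SD is zero the statistic is 0 and p = 1.
* `top_k` and `top_n_lists` break ties by (score, id) so outputs are
  deterministic under permutation of the input.
* Promoter intervals are clipped at chromosome ends when sizes are
  supplied, with a logged message.
* Copy-number calling bins probes into fixed-width windows (bin median vs
  thresholds -1.2 / -0.3 / +0.3 log2) and merges adjacent same-state
  bins; it is a deliberately minimal deterministic caller sufficient for
  commonly-deleted-region logic, not a replacement for full aCGH
  segmentation. The commonly deleted region is found by sweep-line
  interval stabbing over per-sample merged loss segments; ties go to the
  leftmost interval.
* Hierarchical clustering of copy-number states uses average linkage on
  the Hamming (state-mismatch) distance with rows pre-sorted by sample id
  for reproducible leaf order. Note that a homozygous deletion is a
  different state from a hemizygous one, so a lone homozygous sample need
  not join the hemizygous cluster.

## Known limitations

**Peak-position quantization.** For a symmetric unimodal enrichment bump
sampled at 100 bp spacing, the 400 bp windowed median takes *exactly* the
same value at the peak probe and at both 100 bp shoulder probes: each of
those three 5-probe windows has the same median element, the smaller
shoulder value. The smoothed track is therefore flat, to the last floating
point digit, across a three-probe plateau, and the TSS-proximal tie-break
places the reported peak at the downstream edge of the plateau. The
Max400 *score* is unaffected, but the reported peak *position* carries a
systematic one-probe (100 bp) bias toward the TSS, and the modal bin of
the TSS-offset histogram sits one bin downstream of the true bump centre.
The mean binding curve (`average_binding_curve()`), which averages rather
than takes an argmax, does not suffer from this and peaks at the true
centre. Positional conclusions at sub-probe-spacing resolution should rest
on the mean curve, not the peak histogram.

**Consensus precision at relaxed list sizes.** With per-replicate top-*k*
lists of twice the true target count and independent replicate noise, the
excess list slots are filled by noise promoters independently per
replicate; the expected number of 2-of-3 false agreements is
`n_unbound * 3p^2(1-p) + p^3` with `p = (k - n_true)/n_unbound`. At the
default design (2000 genes, 108 bound, k = 216) that is ~18 false
positives, capping consensus precision near 0.85 regardless of how strong
the binding signal is. Requiring all three replicates (m = 3) restores
precision above 0.99 at a negligible recall cost on strong signal.
Choosing k close to the expected number of targets, or m = n, is advisable
when precision matters more than sensitivity.

**Scale.** The evaluation sizes used in tests and the acceptance script --
2000 promoters x 27 probes x 3 replicates, 20 simulation seeds, 200 null
replicates -- are the package's chosen design-evaluation scale; they keep a
full run in a couple of minutes while leaving Monte-Carlo error on the
reported rates below a few percent.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 300, n_bound = 30, seed = 1)
sim <- simulate_tiling_arrays(cfg)
res <- chip_score_pipeline(sim$promoters, sim$probes, sim$replicates,
                           k = 60, m = 2)
length(res$members)                      # called direct targets
mean(sim$bound %in% res$members)         # recall against seeded truth

calls <- concordant_peaks(peak_locations(res$max_tables), sim$promoters)
head(tss_profile(calls[calls$promoter_id %in% res$members, ],
                 sim$promoters))

ex <- simulate_expression(cfg, sim$bound)
em <- quantile_normalize(ex$em)
qc <- qc_correlations(em)
de <- differential_expression(em, samples = c(qc$kept,
        names(em$arms)[em$arms == "control"]))
set_shift_test(setNames(de$log_ratio, de$gene_id), res$members)$direction
intersect_targets(res$members, de, n_expanded = 60)$counts
```
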