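---
title: "Estimating measurable residual disease from DNA methylation patterns"
author: "epiMRD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating measurable residual disease from DNA methylation patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiMRD)
```

## The problem

Measurable residual disease (MRD) in acute myeloid leukemia (AML) is usually
tracked with mutation-specific PCR assays or flow cytometry, both of which
require a suitable marker in each patient. epiMRD implements an alternative
that uses aberrant DNA methylation, which is nearly universal in AML: a small
set of CpG sites that are tightly regulated in healthy blood but flip to the
opposite methylation state in leukemic cells. The package covers the whole
workflow: selecting such CpGs from methylation-array cohorts, summarizing
four of them into an AML-score, and — at much higher resolution — classifying
individual bisulfite amplicon sequencing (BA-seq) reads as normal or
anomalous with machine-learning models, so that a residual leukemic clone
shows up as an excess of anomalous reads.

## Candidate CpG selection

Given a beta-value matrix (CpG x sample, values in $[0,1]$) with a
control/AML group map, `filter_invariant_cpgs()` keeps CpGs that are

* extreme in healthy samples: control mean $\beta < 0.1$ or $> 0.9$, and
* stable in healthy samples: control standard deviation $< 0.05$
  (sample s.d., $n-1$ denominator, the usual array-workflow convention).

`rank_and_select()` then ranks eligible CpGs by
$\Delta\beta = \bar\beta_{\text{AML}} - \bar\beta_{\text{control}}$ and keeps
the top 100 per direction (hyper- and hypomethylated in AML), breaking ties
lexicographically so results are deterministic. `intersect_candidates()`
intersects the per-study-pair lists, mirroring the design in which several
independent control/AML cohort pairs are selected separately and only the
consensus survives.

Two readings of the filter were possible: the extremeness criterion could
apply to the control *mean* or to *every* control sample. We apply it to the
mean — the separate s.d. criterion already bounds the spread, which makes
the per-sample reading redundant — and we rank within direction classes, so
signed versus absolute ranking coincide.

## The AML-score

Four anchor CpGs summarize a sample:

$$\mathrm{score} = \tfrac{1}{4}\bigl(\beta_{\text{cg15289427}} +
\beta_{\text{cg22797031}} + (1-\beta_{\text{cg27630153}}) +
(1-\beta_{\text{cg19586199}})\bigr)$$

i.e. the mean of direction-adjusted betas: 0 for the healthy archetype,
1 for a fully aberrant sample. On array cohorts the cutoff is calibrated as
the 99.5th percentile of healthy scores (`calibrate_cutoff()`); for BA-seq
data the carried-over convention is a fixed cutoff of 0.125, and a sample is
positive when its score is *strictly* above the cutoff. Percentiles use
linear interpolation between order statistics (R's default `quantile`
type 7) — the package does not depend on any other percentile convention,
and tests pin it against an independent sort-and-interpolate oracle.

For BA-seq input, the anchor beta is the count-weighted methylated fraction
at the region's target CpG column (`baseq_anchor_betas()`); the score is
defined on the four cg-identifiers, not on amplicon means, though the
amplicon-mean variant is available via `use_amplicon_mean = TRUE`.

## Read patterns and quality control

Each BA-seq read over an amplicon is reduced to its binary epiallele
pattern — the ordered methylation states of all CpGs it covers (14, 10, 15
and 9 CpGs on the default panel). `from_bismark_calls()` consumes
per-read CpG calls from a bisulfite aligner; a read contributes only when
it covers *all* CpGs of a region (partial reads are tallied and dropped, not
imputed — imputation would fabricate pattern structure). Samples with fewer
than 50 reads on any amplicon are excluded (`qc_filter()`; the comparison is
strict, so exactly 50 reads pass). Control samples are split 7:3 into
training and validation at the *sample* level (`split_controls()`), never at
the read level, to keep a donor's reads from leaking across the split.

## Read-level anomaly detection

Two model families classify individual reads, each per region:

**Random forest** (`train_rf_model()`): supervised, 100 trees with maximal
depth 5, features are the CpG bit columns. Every control-training read is
labeled normal and every read of AML first-diagnosis samples abnormal —
deliberate label noise, since diagnosis samples also contain normal reads.
Pattern counts enter as case weights rescaled so both classes carry equal
total weight, protecting the minority class. The forest itself is fit with
the ranger package (seeded, single-threaded, so training is deterministic).

**Autoencoder** (`train_ae_model()`): unsupervised, trained on control
training reads only. Patterns are encoded as $-1$/$+1$ and pushed through a
feed-forward network with hidden widths 8–3–8 (encoder, latent, decoder) and
tanh activations on all hidden and output layers; the input and output
width equals the region's CpG count (9–15) — a literal 8-unit input could
not accept a 14-CpG pattern, so "8-3-8" is read as the hidden architecture.
The loss is mean squared reconstruction error; a read is abnormal when its
loss exceeds the 99th percentile of the training reads' losses. The
clustered variant first partitions training reads into $k = 5$ epiallele
clusters with count-weighted K-means (10 restarts, seeded; intended to
separate cell-type-specific patterns) and trains one autoencoder with its
own threshold per cluster; unseen reads are routed to the nearest centroid.
`k = 1` reduces exactly to the unclustered variant. K-means is fit on the
pooled control training reads, not per sample — the only reading that
yields a model reusable on new samples.

Training details the architecture leaves open were fixed as: full-batch
gradient descent with adaptive-moment (Adam) updates, learning rate 0.01,
at most 2000 epochs with a 50-epoch loss-plateau early stop, Glorot-uniform
initialization. The epoch budget matters: in our experiments the network
needs on the order of 1000–2000 full-batch epochs before the training loss
plateaus; stopped much earlier it reconstructs out-of-distribution reads
almost as well as training reads and loses its anomaly signal, whereas at
the plateau a whole-amplicon-flipped read sits far above the threshold.
All of these, and the seed, are recorded in the model objects.

**Aggregation** is shared: per region, the anomaly ratio is the
count-weighted fraction of reads classified abnormal; the sample's anomaly
score is the mean of the available region ratios (a QC-dropped region
contributes nothing and raises a warning); the score cutoff is the 99th
percentile of the control training samples' scores, positive strictly
above. By percentile construction a control-like sample is positive about
1% of the time — the methods' floor, since even healthy blood contains a
few abnormal-classified reads.

## Allele symmetry

When an amplicon contains a heterozygous SNP (both of the top two bases at
$\geq 30\%$ — our operationalization of "around 50%", tolerant of
allele-specific amplification bias; the SNP must be at least 3 bp from both
the C and the G of every CpG), `split_by_allele()` partitions reads by
allele and `symmetry_stat()` quantifies symmetry two ways: the per-CpG
absolute beta difference between alleles, and half the L1 distance between
the two alleles' pattern-frequency distributions. Both are reported because
"identical patterns" is a statement about whole epialleles, not only about
marginal betas. The default panel annotates rs115701567 (chr16:88844998)
and rs917911737 (chr19:14225172) on the two hypomethylated regions.

## Synthetic data

`clone_profile()` defines a normal and an aberrant clone: per region, the
normal clone follows the healthy state (unmethylated on
hypermethylated-in-AML regions, methylated on hypomethylated ones) with an
error rate $\varepsilon = 0.02$ per CpG, approximating bisulfite-conversion
failure plus sequencing error; the aberrant clone is the whole-amplicon
flip of that archetype with the same $\varepsilon$. Reads are drawn CpG-wise
independently from the profile — for these near-binary profiles this is
distribution-identical to drawing one per-read "epiallele switch" and
adding independent errors, so whole-read coherence of aberrant patterns is
preserved by construction. `simulate_sample()` mixes the clones read-wise
at a given fraction (the in-silico limiting dilution), `simulate_dilution()`
builds a series over fractions 1, 0.5, 0.25, 0.10, 0.05, 0.01, 0,
`simulate_het_sample()` assigns each read an allele at probability 0.5, and
`simulate_beta_matrix()` plants aberrant CpGs (control mean 0.05 or 0.95,
AML mean shifted by $\Delta\beta$) among null CpGs for selection tests.
Every generator is seeded and emits its ground truth (planted ids, realized
fractions, allele counts) so recovery is checkable.

What the generator does *not* emulate: PCR and amplification bias,
correlated errors along a read, cell-type mixtures in controls beyond what
$k$-means clustering would absorb, CpG-density effects, and the long tail
of patient-specific partial aberrations. Passing tests therefore show the
machinery is correct and calibrated under clean mixture assumptions, not
that real-cohort sensitivities are reproduced; detection limits on real
dilution series are coarser (about 5–25% aberrant DNA) than on separable
synthetic patterns.

## Problem sizes and numerical choices

The test suite and the acceptance script run on desk-scale cohorts chosen
to mirror the study layout: 62 control and 48 first-diagnosis samples at
300 reads per amplicon for training (43/19 after the 7:3 split), 1,000
reads per amplicon for dilution samples (deep relative to training, as
dilution experiments are in practice), 10 replicate series, and 10,000
reads where binomial recovery is asserted. Selection tests use 500-CpG
matrices with 50 controls and 20 AML samples. Degenerate inputs are handled
explicitly: CpGs with fewer than two non-missing control values are
excluded and reported; empty eligible sets yield an empty candidate set
with a warning; K-means reduces $k$ below the number of distinct patterns
with a warning and drops empty clusters; ranking ties break
lexicographically; classification at exactly the cutoff is negative.

## A worked example

```{r example, eval = FALSE}
panel <- default_panel()
normal <- clone_profile(panel, "normal")
aberrant <- clone_profile(panel, "aberrant")

ctrl <- simulate_cohort(normal, aberrant, panel, n_samples = 62,
                        fraction = 0, reads_per_region = 300,
                        prefix = "ctrl", seed = 101)
dx <- simulate_cohort(normal, aberrant, panel, n_samples = 48,
                      fraction = 1, reads_per_region = 300,
                      prefix = "dx", seed = 202)
fitted <- train_all_methods(ctrl, dx, panel, seed = 1)

mrd <- simulate_sample(normal, aberrant, panel, fraction = 0.25,
                       reads_per_region = 1000, sample_id = "followup",
                       seed = 9)
score_sample_all(fitted, mrd)
```

## Limitations

The default panel ships with synthetic placeholder coordinates (counts,
anchors, directions and SNP positions are the defining content); real
alignments need the primer-table coordinates. The supervised forest
inherits the label-noise bias of calling every diagnosis read abnormal. The
autoencoder threshold guarantees a ~1% false-positive read rate on data
resembling its training distribution, which bounds achievable sample-level
specificity. None of the methods distinguishes residual leukemia from
clonal hematopoiesis with similar epigenetic aberrations.
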