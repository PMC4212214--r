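---
title: "Methods: Rank Product screening and stem-to-root identity tracking"
author: "ARShift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Rank Product screening and stem-to-root identity tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological question and the data model

When a cutting is excised, the basal segment of its stem (the stem base)
gradually loses its shoot character and acquires root identity as
adventitious roots (ARs) form. ARShift quantifies that transition from a
time course of transcriptome-wide expression intensities: stem-base
samples at 0, 2, 6, 24, 72, 96, 144 and 192 hours post-excision (hpe),
fresh and wounded leaves (to isolate the generic wound response triggered
by excision), and a fully developed root (the target identity). Each
condition carries 3–4 biological replicates.

The central container, `ExpressionDataset`, extends
`SummarizedExperiment`: one `intensity` assay of normalized fluorescence
values and a column design (`tissue`, `hpe`, `replicate`). Intensities are
kept on their absolute input scale and are never re-normalized, because
the organ-identity analysis uses an absolute cutoff (500 fluorescence
units by default) that is only meaningful on that scale. Gene identifiers
are opaque, case-sensitive strings. The package takes gene-level input;
how multiple probes per gene were summarized upstream is outside its
scope.

## The Rank Product screen

For a contrast of condition A (nA replicates) over condition B (nB
replicates), every pairwise replicate ratio is formed: K = nA × nB columns
with entries a_gi / b_gj (intensities are floored at 1 unit first so
ratios stay finite). Within each column genes are ranked by fold change
(rank 1 = most up-regulated; ties get average ranks), and the statistic is
the geometric mean of a gene's ranks across columns,

    RP_g = (prod_k r_gk)^(1/K),

computed separately for up- and down-regulation (the down ranks are the
mirror n + 1 − r). A small RP marks consistently extreme regulation. The
mixed 3- and 4-replicate design is handled naturally by K = nA × nB.

Significance is assessed by permutation (1000 permutations by default)
with p-values pooled over genes and permutations:

    p_g = (1 + #{permuted RP <= RP_g}) / (1 + B × n),

so p is never exactly zero, and the estimated percentage of false
positives at the gene's position in the RP ranking is
pfp_g = p_g × n / rank(RP_g). A gene is called regulated when its M-value
(below) exceeds 1 in magnitude **and** its significance value is below
0.01. The "RP value < 0.01" rule is read as the raw permutation p-value by
default; `threshold_on = "pfp"` switches the rule to the pfp, since either
reading of the published threshold is defensible and we make no claim of
matching the original choice.

### Two permutation nulls, and why the default is the array shuffle

Two null constructions are implemented, and the difference matters for
replicated designs:

* `scheme = "column"` (`permutationSignificance()`): the rank values
  within each ratio column are shuffled independently. This is the
  construction that can be checked exactly — on instances of up to 5 genes
  and 2 columns the test suite enumerates every (n!)^K rank configuration
  and the Monte-Carlo p-values must match — but it treats the K columns as
  independent.
* `scheme = "array"` (the `rankProduct()` default): each random experiment
  shuffles gene labels independently within every replicate array and
  recomputes all pairwise ratio ranks.

With both conditions replicated, ratio columns that share a replicate are
strongly correlated (sharing the numerator replicate gives a rank
correlation near 0.5), so the observed RP spreads far wider than an
independent-column null predicts. Empirically, the column null at 4 vs 4
replicates calls roughly 10% of null genes significant at p < 0.01,
whereas the array null — which preserves exactly that correlation
structure — is calibrated (fraction below 0.01 ≈ 0.01, Kolmogorov–Smirnov
distance from uniform < 0.02 at 5000 genes; both are recomputed by the
test suite and `scripts/acceptance.R`). The pipeline therefore uses the
array null throughout; the column variant remains available and exactly
testable.

Both nulls draw their shuffles from the column-sorted values, which makes
results invariant to the gene order of the input without changing the null
distribution.

## M-values and the joint significance rule

The M-value of a contrast is the log2 ratio of the arithmetic replicate
means, M = log2(mean_A / mean_B), computed on means rather than as a mean
of per-replicate log ratios — the most literal reading of screening on
mean expression values. Internally the quotient is taken
larger-over-smaller and signed, so the antisymmetry M(a,b) = −M(b,a) is
exact in floating point. The call is `up` iff M > 1 and p_up < 0.01,
`down` iff M < −1 and p_down < 0.01, otherwise `ns` — exactly one call per
gene per contrast.

The standard contrasts of the design are: every stem-base timepoint
against 0 hpe, consecutive stem-base timepoints (including 72 vs 24 hpe,
the interval where the identity shift peaks), wounded vs fresh leaf, and
root vs stem base at 0 hpe.

A small utility computes qPCR relative expression as 2^−ΔCT with
ΔCT = CT_target − CT_reference, without efficiency correction.

## Wound subtraction and organ-identity tracking

Excision wounds the cutting, so early stem-base regulation mixes wound
response with rooting-specific regulation. Genes regulated between wounded
and fresh leaves define the wound set; subtracting it from each
timepoint's regulated set isolates wound-independent AR regulation. The
subtraction is applied at every timepoint (the narrative motivation is the
early 2–6 hpe window, but the tabulated minus-wound counts span all
dates).

Organ-identity sets are built by an explicit, configurable policy, since
the original sets' construction is not published: a gene is organ-specific
if it is significantly higher (same joint rule) in the focal organ than in
*each* of the other two organs (stem base at 0 hpe, fresh leaf, root) and
its focal-organ mean exceeds the 500-unit cutoff. The identity-shift table
then counts, per timepoint: regulated genes (all and minus wound),
stem-base identity genes whose mean has fallen below the cutoff
(repressed), and root-identity genes whose mean has risen above it
(expressed). The largest-shift interval maximizes the summed absolute
change of the last two counts over consecutive timepoints, ties resolved
toward the earlier interval.

## Functional-category representation

For each category and direction, over/under-representation is the ratio of
the category's share among regulated genes to its share among all genes,

    ratio = (n_xp / n_xt) / (n_ap / n_at),

with n_xp the regulated genes of the category, n_xt the category size,
n_ap all regulated genes, n_at all genes. Its log2 is the category
M-value. The flag is `over` when ratio ≥ 2 and `under` when ratio ≤ 1/2
(the 2-fold criterion; no enrichment p-value is computed, matching the
method's purely fold-based criterion). Categories smaller than
`min_category_size` (default 10 — the published analysis excluded small
hormone classes without stating a bound) are marked excluded and carry no
flag. A ratio of zero yields m = −Inf with raw counts retained, rather
than a fabricated finite value. Unannotated genes count toward n_at and
n_ap by default — they are genes and can be regulated — with a switch to
restrict the universe to annotated genes. The hormone time-course applies
the same computation per phytohormone category across all baseline
contrasts plus root vs stem base.

## The synthetic generator: what it emulates and what it does not

`generateDataset()` produces data with planted, exactly known structure:

* log-normal baseline intensities (median 500, log-sd 1 — tens to
  thousands of units, matching the scale on which the 500 cutoff sits);
* mean-unbiased multiplicative log-normal replicate noise,
  intensity = mean × exp(N(−s²/2, s²)) with s² = log(1 + cv²); the default
  cv of 0.3 is typical replicate variability for two-color array
  intensities;
* per-baseline-comparison DE genes at a planted fold (default 4, i.e.
  |M| = 2, comfortably beyond the M > 1 threshold), disjoint across
  comparisons so every stage can be scored exactly; defaults scale with
  platform size (3% of genes per comparison, identity sets of 1.4% and
  1.9% — the proportions of the emulated study's stem-base and root sets);
* a configurable fraction of early (2 and 6 hpe) DE genes shared with the
  leaf-wounding response — the ground truth for wound subtraction;
* organ-identity genes as step functions crossing the 500 cutoff at
  configured timepoints, making identity-shift counts exactly predictable
  at zero noise;
* category labels assigned so each planned category attains its planted
  enrichment ratio among true up-regulated genes of every baseline
  comparison; the default plan mirrors a curated rooting-transcriptome
  classification and plants ethylene- and jasmonate-related
  over-representation, the qualitative pattern the analysis is designed to
  surface, and keeps the cytokinin/brassinosteroid/salicylic-acid classes
  tiny so the exclusion rule is exercised.

The generator does **not** emulate dye bias, spatial or batch artifacts,
probe-level effects, or correlated gene-gene noise. Tests passing on this
generator therefore demonstrate the correctness of the statistics and
bookkeeping, not robustness to those real-data artifacts.

## Numerical choices

* Intensity floor 1.0 (input scale) before any ratio or M-value, shared
  across modules, so log-ratios are always finite.
* Average ranks on ties; ranks are conserved under ties, and a fully tied
  column gives every gene rank (n+1)/2.
* The K-th root of the rank product is computed as `prod(r)^(1/K)`, which
  is exact for K = 1 (the statistic equals the rank).
* Add-one permutation p-values; the smallest attainable p is
  1 / (1 + B × n).
* One master seed per run, split deterministically into per-stage
  substreams; identical config + seed reproduces every output byte for
  byte (the run manifest records md5 checksums).
* Problem sizes in the validation suite: calibration at 5000 genes / 1000
  permutations, spike recovery at 5000 genes over 5 seeds, exactness
  checks at a few hundred genes — large enough for stable estimates while
  a full run stays in the minutes range on one CPU.

## Worked example

```{r example}
library(ARShift)

cfg <- pipelineConfig(
  out_dir = "ar_run",
  sim = simulationConfig(n_genes = 2000, seed = 42),
  n_permutations = 1000, seed = 42)
manifest <- runPipeline(cfg)

read.delim(file.path("ar_run", "identity_shift_table.tsv"))
manifest$largest_shift
```

## Known limitations

* The organ-identity policy is one defensible reading of "organ-expressed
  genes"; published identity-set sizes cannot be reproduced because the
  original array data are not redistributed here.
* The pfp is an estimate of the expected false-positive percentage at a
  rank position, not an FDR-adjusted p-value; no further multiple-testing
  correction is applied.
* Custom `category_plan` data frames are not serialized into the YAML
  config snapshot; runs needing a custom plan should call `runPipeline()`
  from R.
* qPCR relative expression uses plain 2^−ΔCT without amplification
  efficiency correction.
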