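---
title: "Quantifying exon-intron marking from tiled ChIP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying exon-intron marking from tiled ChIP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(exonmark)
library(dplyr)
```

## The problem

Nucleosomes, histone modifications and RNA polymerase II are not spread
uniformly across gene bodies: many chromatin signals sit preferentially on
exons (or, for some marks and cell types, on introns). Detecting this
"exon-intron marking" from tiled two-channel ChIP-chip arrays or from
ChIP-seq read counts is delicate for two reasons. First, exons are short
and sparse, so the effect must be averaged over many genes aligned on a
consensus gene structure. Second, nucleosome density itself differs
between exons and introns, so a naive modification track can show an exon
bias that reflects nothing but nucleosome abundance. `exonmark`
implements the full analysis: tile-level normalization with an explicit
histone-density correction, feature assignment against multi-transcript
gene models, consensus metaprofiles, and a coordinate-randomization
bootstrap for significance — plus a synthetic-data generator that plants
known effects so every stage can be validated end to end.

## The normalization chain

For each array tile, each replicate, the enrichment ratio is

$$ r = \frac{\text{ChIP} - \text{ChIP}_{bg}}{\text{Input} - \text{Input}_{bg}}, $$

with not-found spots and non-positive ratios set missing, duplicate spots
averaged, and the surviving ratios scaled to median 1. Replicates are
combined by a per-tile median ("composite"). Histone-modification
composites are then divided, tile by tile, by the combined histone-density
composite (the mean of the H2B and H3 ratio composites) and by an IgG
control composite. Finally the track is log2-transformed, centred on its
median, and divided by the sample standard deviation of the whole dataset,
giving "log2 centred Z-scores" with median 0 and sample SD 1.

Choices the chain had to make where the procedure could be read more than
one way:

* **Centring statistic.** The median of the log2 values, applied
  uniformly (the sequential-ChIP branch is explicitly median-centred, and
  a single convention keeps the chain order-auditable).
* **Standard deviation.** The conventional sample estimator (n − 1) over
  every non-missing tile.
* **Order of corrections.** Histone density first, then IgG. Tile-wise
  division commutes, so the order affects only the audit record
  (`track_record()`), never the values.
* **Missingness.** Missing values propagate; every downstream statistic
  uses available tiles only. Non-positive corrected signals become
  missing rather than being clamped, because a clamped zero is
  log2-degenerate.

For sequential ChIP (two consecutive immunoprecipitations), the control
(second-round IgG) signal must be subtracted in intensity space before
ratios are formed. Both datasets are background-corrected per channel and
placed on a common scale by dividing each replicate's channels by its
median background-corrected input; this input-defined scale is what makes
the experimental and control ChIP channels comparable. Equalizing the two
ChIP-channel medians instead would force the corrected signal toward zero
at the median tile and destroy the subtraction, so it was rejected. After
subtraction the chain proceeds as above.

## Gene models and feature assignment

Gene models come from GFF3/GTF (converted internally to 0-based half-open
coordinates). An exon is *canonical* when the identical interval occurs
in every transcript of the gene, *alternative* when it occurs in some but
not all; its inclusion fraction is the proportion of transcripts carrying
it. Bases covered by two distinct overlapping exon variants have an
ambiguous class and are excluded from assignment altogether. Introns are
the gaps in the union of all exon intervals. The default gene filter
keeps genes spanning at least 6 kb with at least three exons; a relaxed
mode drops the span constraint.

Tiles (and 200-bp ChIP-seq bins) are assigned to the feature containing
their midpoint — the midpoint rule is this package's choice; it is
unambiguous, strand-symmetric, and appropriate when tiles are much
smaller than the features they interrogate. The 5'-most 25% of each gene
span is labelled `five_prime`, the rest `body`, so promoter-proximal
marking can be separated from gene-body marking.

## Metaprofiles and class summaries

Consensus profiles average tile Z-scores over ordered slots — exon 1,
intron 1, ..., exon 10 from the 5' end, or the last five exons and four
introns from the 3' end — across all genes in a set (e.g. the expressed
genes). Profiles use canonical exons only; alternative exons are
summarized separately. Slots weight tiles equally (a gene-equal weighting
would up-weight sparse genes; tile-equal is what the per-slot confidence
intervals describe). Per class, the summary reports the mean Z, n, a 95%
normal-approximation interval (mean ± 1.96·SD/√n), and the headline bias

$$ \Delta Z = \overline{Z}_{\text{canonical exon}} - \overline{Z}_{\text{intron}}, $$

positive for exon biases and negative for intron biases.

## Significance: the coordinate-randomization bootstrap

The null model asks: could the observed class means have arisen if tile
values bore no relation to gene structure? Each randomization permutes
the observed values uniformly over the observed tile coordinates — for
tile-mean statistics this is equivalent to throwing the datapoints onto
random genomic coordinates, while avoiding the edge effects of literal
uniform placement — and the class means are recomputed against the fixed
annotation. Two p-values are reported:

* **empirical**: `(1 + #randomized at least as extreme) / (R + 1)`,
  two-sided by absolute deviation from the randomized mean (one-sided on
  request). With the conventional R = 100 its floor is 1/101, so very
  strong effects saturate it.
* **parametric**: the normal tail of `z = (obs − mean_rand)/sd_rand`,
  which can express the extremely small significance levels real
  datasets produce.

Neither is silently preferred; both appear in every result table. For
ChIP-seq, reads can alternatively be re-thrown uniformly
(`simulate_reads()` with uniform weights) and re-binned, matching the
read-randomization description for sequencing data.

Adjacent-pair t-tests compare each canonical exon's tiles against the
preceding intron's tiles (exon k vs intron k−1, k = 2..10; the first exon
is skipped because promoter marking would confound it), Welch by default
since tile counts and variances differ between classes; a pooled option
exists. The median of the nine p-values is the headline statistic, and a
3' mode covers the last four pairs. Pairs whose genes do not extend far
enough are skipped silently; degenerate-variance pairs are skipped with a
warning.

## Expression stratification

Expression values are consumed, not computed (RMA or array Z-scores
upstream). Genes are ranked to percentiles (`100·(rank−1)/n`); ON is the
top two quartiles, OFF the bottom quartile (top/bottom 25% in
whole-genome mode); calls from two platforms are intersected, a gene
keeping a status only when both agree. The 12-bin percentile scheme uses
edges 0/5/10/20/.../90/95/100: the extremes are resolved at 5% because
that is where expression-coupled marking changes fastest, while the
middle uses deciles. Bins are half-open `[lo, hi)` with the last closed,
so a gene at exactly the 95th percentile belongs to the 95-100 bin, and
an alternative exon included in exactly half the transcripts belongs to
the 50-100% inclusion group.

For tiling-array expression, the per-gene score averages the oligo-dT
channel over the 3'-most 2000 bases (oligo-dT priming reads out 3' ends)
with the random-primed channel over the whole gene; genes shorter than
the window use all their tiles. The upstream description of this score is
ambiguous; this reading is documented as the package's interpretation.

## The synthetic-data generator

`sim_config()` fixes the simulated study conditions: 3-12 exons per gene,
lognormal exon lengths (median 150 b) and intron lengths (median
1500 b), 1-4 transcripts per gene, a contiguous 500-b tiling emulating a
PCR-product array, 36-b reads, three bioreplicates, lognormal replicate
noise with SD 0.3 on the log2 scale, and lognormal expression. Where a
test needs several tiles per feature (the effect-recovery properties),
the config used is 700-b exons on a 100-b tiling with 100 genes, stated
in each test.

Truth is planted in ratio space: the input channel is flat reference, the
modification ChIP channel carries `density × 2^(effect)`, the H2B/H3
assays carry `density`, and IgG a flat baseline, each times lognormal
replicate noise plus a constant additive background. The chain therefore
recovers the planted log2 effects *exactly* at zero noise, and dividing
by the H2B/H3 composite removes the density confound exactly — chosen
over a mechanistic hybridization model precisely because it makes
recovery tests sharp. Alternative exons carry `inclusion × effect` in the
default inclusion-weighted mode. What the generator does *not* emulate:
probe-sequence effects (GC, cross-hybridization), spatial array
artefacts, dye bias, mappability, or correlated noise along the genome —
so passing tests certify the statistical machinery, not robustness to
those platform artefacts.

One unit matters when interpreting recovery: planted effects are log2
enrichment differences, while Z tracks are scaled by the dataset SD. The
SD recorded by the Z-scoring step (`track_sd()`) converts a Z-track
ΔZ back to log2 units (`Δlog2 = ΔZ × track_sd`), and recovery is judged
on that scale, where "recovered = planted" is well defined.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open everywhere; GFF3/GTF (1-based
  inclusive) are converted on read and write.
* Z-scoring requires ≥ 3 non-missing positive values and errors on a
  constant track ("degenerate track") rather than emitting NaNs.
* A fully tied expression ranking errors unless explicitly forced, and
  ties crossing a quartile edge are broken by stable gene-id order with a
  message.
* Overlapping genes are resolved deterministically (smallest feature
  start, then end, then gene id); assignment is idempotent.
* All randomness flows from explicit seeds; a fixed seed reproduces every
  table byte for byte.

## Validation summary

The test suite checks, among others: calibration of the bootstrap null
(false-positive rate at α = 0.05 inside the exact binomial band over 200
null datasets); agreement of the empirical p with exhaustive permutation
enumeration on an 8-tile instance; recovery of a planted 0.5 log2 exon
effect with parametric p < 0.01; disappearance of a planted 1.5× density
confound after histone-density correction; intermediate marking of
inclusion-weighted alternative exons; sign agreement of the ChIP-chip and
ChIP-seq paths on matched occupancy; and exactness of the whole chain at
zero noise. Problem sizes (50-100 genes, 25-200 replicate simulations,
R = 100-10,000) were chosen so each property is decided by its sampling
error, not by runtime convenience. The vignette states no number these
tests do not themselves compute.

## A compact worked run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_genes = 60, exon_effect = 0.5,
                  density_exon_mult = 1.3, noise_sd = 0.3,
                  exon_len_meanlog = log(700), tile_length = 100)
ann <- simulate_annotation(cfg)
sim <- simulate_chipchip(cfg, ann)

density <- histone_density_track(
  composite_ratio_track(sim$measurements$h2b, "histone_density"),
  composite_ratio_track(sim$measurements$h3, "histone_density")
)
igg <- composite_ratio_track(sim$measurements$igg, "igg_control")
z <- preprocess_assay(sim$measurements$mod, density, igg)

models <- filter_genes(ann$models, relaxed = TRUE)
asn <- assign_tiles(sim$tiles, models)

class_means(z, asn)                      # class means, CIs, delta Z
bootstrap_pvalues(z, asn, R = 100, seed = 1) |> tidy()
adjacent_pair_ttests(z, asn) |> glance() # median pair p
autoplot(exon_intron_profile(z, asn, models))
```

## Known limitations

* The package consumes aligned reads and expression summaries; it does
  no alignment, image quantitation, RMA/MAS5, peak calling or FDR
  control.
* Canonical/alternative status depends entirely on the annotation's
  transcript catalogue; an incomplete catalogue inflates the canonical
  class.
* The midpoint rule mis-assigns a tile whose midpoint sits in a feature
  covering less than half of it; with 500-b tiles over 150-b exons a
  substantial fraction of exonic signal is diluted into neighbouring
  slots — real analyses mitigate this with denser designs, and the
  recovery tests use such a design deliberately.
* Bootstrap randomizations preserve the value multiset but not spatial
  autocorrelation; strongly autocorrelated tracks will look slightly
  anticonservative against this null.
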