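# exonmark

Chromatin signals are not uniform across gene bodies: nucleosomes, many
histone modifications and RNA polymerase II associate preferentially with
exons — or, for some marks and cell types, with introns. `exonmark` is an
R package for quantifying this **exon-intron marking** from tiled
two-channel ChIP-chip arrays and from ChIP-seq read counts, for
epigenomics groups who have tile- or read-level enrichment data and a
multi-transcript gene annotation and want defensible, confound-corrected
bias estimates with significance.

## What it computes

For each array tile the enrichment ratio is the background-corrected ChIP
signal over the background-corrected input signal, median-scaled,
replicate-combined by a per-tile median, divided tile by tile by a
combined H2B/H3 **histone-density** composite (so nucleosome abundance
cannot masquerade as modification signal) and by an IgG control, then
log2-transformed, median-centred and scaled by the dataset SD
("log2 centred Z-scores"). Sequential-ChIP experiments subtract their
IgG-round control in intensity space first; ChIP-seq reads are filed into
200-bp bins by their 5' start and flow through the same feature
statistics.

Exons are classified **canonical** (present in every transcript of the
gene) or **alternative** (present in some, with a known inclusion
fraction); tiles and bins are assigned to the feature containing their
midpoint. The headline bias per dataset is

&Delta;Z = mean Z(canonical exons) − mean Z(introns),

positive for exon biases, negative for intron biases. Significance comes
from a coordinate-randomization bootstrap — observed values permuted over
the observed tile coordinates, class means recomputed against the fixed
annotation, with both an empirical p (floor 1/(R+1)) and a parametric
normal-approximation p — plus Welch t-tests between each canonical exon
and its preceding intron (exons 2→10), summarized by their median p.
A synthetic-data generator plants known effects (exon/intron log2
enrichment, nucleosome-density multipliers, inclusion-weighted
alternative-exon coupling, expression coupling, replicate noise) so the
entire pipeline is testable without any external download.

## Worked example

Simulate 60 genes with a planted 0.5 log2 exon effect *and* a 1.3×
nucleosome-density exon bias, run the corrected chain, and test the bias:

```r
library(exonmark)

cfg <- sim_config(seed = 1, n_genes = 60, exon_effect = 0.5,
                  density_exon_mult = 1.3, noise_sd = 0.3,
                  exon_len_meanlog = log(700), tile_length = 100)
ann <- simulate_annotation(cfg)
sim <- simulate_chipchip(cfg, ann)

density <- histone_density_track(
  composite_ratio_track(sim$measurements$h2b, "histone_density"),
  composite_ratio_track(sim$measurements$h3, "histone_density"))
igg <- composite_ratio_track(sim$measurements$igg, "igg_control")
z <- preprocess_assay(sim$measurements$mod, density, igg)

models <- filter_genes(ann$models, relaxed = TRUE)
asn <- assign_tiles(sim$tiles, models)
class_means(z, asn)
#> <class_summary>
#> # A tibble: 3 × 5
#>   type             region mean_z     n     ci
#>   <chr>            <chr>   <dbl> <int>  <dbl>
#> 1 canonical_exon   all     1.04   2708 0.0316
#> 2 alternative_exon all     0.364   662 0.0653
#> 3 intron           all    -0.290  6772 0.0199
#> delta Z (canonical exon - intron; + = exon bias):
#> # A tibble: 1 × 2
#>   region delta_z
#>   <chr>    <dbl>
#> 1 all       1.33
```

Canonical exons sit ~1 Z above the dataset median, introns below it, and
alternative exons in between (they carry inclusion-weighted signal). The
Z-track delta of 1.33, converted back to log2 units with the recorded
dataset SD (`1.33 * track_sd(z)` = 0.506), recovers the planted 0.5 —
the 1.3× density confound has been removed by the histone-density
division. Significance:

```r
tidy(bootstrap_pvalues(z, asn, R = 100, seed = 1))
#> # A tibble: 4 × 7
#>   class            observed  rand_mean rand_sd p_empirical p_parametric n_tiles
#> 1 canonical_exon      1.04  0.0375     0.0166      0.00990    0            2708
#> 2 alternative_exon    0.364 0.0364     0.0352      0.00990    1.32e- 20     662
#> 3 intron             -0.290 0.0375     0.00888     0.00990    1.56e-298    6772
#> 4 delta_z             1.33  0.00000923 0.0232      0.00990    0            9480

glance(adjacent_pair_ttests(z, asn))
#> # A tibble: 1 × 3
#>   mode       n_pairs median_p
#> 1 five_prime       9 9.80e-79
```

Every empirical p saturates at its floor 1/101 = 0.0099 (hence the
parametric column), and all nine adjacent exon-intron pairs separate
cleanly. `autoplot()` methods render the consensus exon1…exon10 profile,
class means, proportional gene-length profiles and bootstrap null
distributions; `run_pipeline("config.yaml")` drives the whole analysis
(simulation or supplied files) from one config and writes report tables.

## Package layout

* `R/annotation.R` — gene models, exon classification, introns, filters,
  midpoint assignment
* `R/tracks.R`, `R/seqchip.R` — the normalization chain and sequential
  ChIP subtraction
* `R/chipseq.R` — read binning and bin assignment
* `R/expression.R` — ON/OFF calls, platform intersection, percentile
  bins, inclusion strata
* `R/metaprofile.R` — consensus profiles, class means, proportional gene
  profiles
* `R/stats.R` — randomization bootstrap, adjacent-pair t-tests, bias
  calls and concordance
* `R/simulate.R` — the synthetic-data generator
* `R/pipeline.R` — config-driven orchestration and report tables

See `vignettes/exon-intron-marking.Rmd` for the methods account.
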