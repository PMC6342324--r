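# allelefish

Simulation and model-based analysis of allele-specific single-molecule RNA
FISH in tissue.

## The problem

Allele-specific single-molecule RNA FISH tags each detected mRNA as coming
from one of the two parental chromosomes (here the C57BL/6J and JF1/Ms
alleles of F1 hybrid mice, discriminated by SNV-specific probes
colocalized with a guide probe). At the single-cell level this raises a
basic question about random monoallelic expression: when a cell contains,
say, 4 BL6 and 2 JF1 transcripts, is that because

- **all-or-none**: the cell transcribes only one allele, and the minority
  counts are technical false detections;
- **coin-flip**: each RNA's allelic origin is an independent Bernoulli draw
  at the population ratio *p*<sub>BL6</sub>, so per-cell imbalance is pure
  binomial sampling; or
- **transcriptional bursting**: each allele fires independently in bursts,
  with per-cell counts *n* ~ NB(*r*, *p*) — mean *r*(1−*p*)/*p*, burst size
  (1−*p*)/*p*, burst frequency *r* — which produces strong but transient
  imbalance and zero BL6–JF1 correlation?

`allelefish` implements the full quantitative toolkit for answering this
with Monte-Carlo likelihood tests, together with the upstream image and
spot computations and generators for every kind of synthetic input:

- **Synthetic data**: per-cell allelic count tables under each generative
  model, spatially clustered tissue layouts, three-channel spot fields with
  chromatic offset, and foci images with ground truth.
- **Allelic models**: binomial NLL and its conditional Monte-Carlo null
  (`coin_flip_test()`); majority assignment plus constrained technical-noise
  simulation (`all_or_none_test()`); negative-binomial moments fits
  (*p* = mean/variance, *r* = mean²/(variance−mean)), goodness-of-fit,
  burst-size scans and the random-pairing correlation null
  (`paired_correlation_test()`); detection-efficiency robustness checks.
- **Spot colocalization**: 2D Gaussian subpixel refinement, median
  displacement correction for chromatic aberration, greedy nearest-first
  matching, a radius scan with pixel-shift negative control, and per-cell
  aggregation.
- **Foci classification**: LoG-based detection of bright foci (background
  subtraction, grayscale opening, border clearing, component filters) and
  two-cluster (k-means) classification of the SNV intensity-ratio angle
  θ = atan2(I<sub>JF1</sub>, I<sub>BL6</sub>).
- **Spatial clustering**: the grid-variance metric of X-inactivation
  patchiness, permutation and seeded-cluster nulls, and estimation of the
  minimal cluster ("seed") size of cells sharing an X-inactivation choice.

Everything takes and returns tibbles, chains with the pipe, and has
broom-style `tidy()`/`glance()` and ggplot2 `autoplot()` methods.

## Worked example

Simulate an all-or-none population (1,000 cells, Poisson(3) totals, 2%
false-detection rates) and test both count models:

```r
library(allelefish)

cfg <- generator_config(n_cells = 1000, p_bl6 = 0.5,
                        fdr_bl6 = 0.02, fdr_jf1 = 0.02, rng_seed = 11)
counts <- gen_all_or_none_population(cfg)

population_stats(counts)
#> # A tibble: 1 × 7
#>   n_cells p_bl6_hat mean_bl6 var_bl6 mean_jf1 var_jf1 correlation
#>     <int>     <dbl>    <dbl>   <dbl>    <dbl>   <dbl>       <dbl>
#> 1    1000     0.470     1.40    3.27     1.58    3.82      -0.637

coin_flip_test(counts, n_sims = 1000, rng_seed = 12)
#> <allele_model_test> coin_flip model, nll statistic
#>   observed 1994.3902 | null 1142.0665 +/- 13.6012 (1000 sims)
#>   percentile 100.0, two-sided empirical p = 0.001998

all_or_none_test(counts, fdr_bl6 = 0.02, fdr_jf1 = 0.02,
                 n_sims = 1000, rng_seed = 13)
#> <allele_model_test> all_or_none model, nll statistic
#>   observed 195.0230 | null 202.0270 +/- 19.4549 (1000 sims)
#>   percentile 35.7, two-sided empirical p = 0.7153
```

Read: the strongly negative per-cell correlation (−0.64) already hints at
mutually exclusive alleles. The coin-flip null is rejected outright — the
observed negative log-likelihood sits ~63 SDs above every one of 1,000
simulated datasets — while the all-or-none model's NLL falls at the 36th
percentile of its own noise-constrained null, i.e. the data look exactly
like monoallelic cells viewed through 2% technical noise.

The same grammar drives the other modules, e.g.

```r
layout <- gen_tissue_layout(5000, p_bl6 = 0.5, seed_size = 4, rng_seed = 1)
estimate_seed_size(layout, rng_seed = 2)   # ~4: recovers the cluster size
```

and `run_allele_pipeline(demo_config())` chains simulate → models and
writes tables, a manifest, and a plain-text report when given `out_dir`.

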