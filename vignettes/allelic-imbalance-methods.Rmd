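---
title: "Models and methods for single-cell allelic imbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for single-cell allelic imbalance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelefish)
```

# Overview

`allelefish` analyses allele-specific single-molecule RNA FISH data from
tissue: per-cell counts of transcripts assigned to the C57BL/6J ("BL6") or
JF1/Ms ("JF1") allele, spot tables from the guide and SNV probe channels,
and guide-channel images of bright RNA foci (such as the Xist cloud marking
the inactive X chromosome). This vignette records the statistical models,
the tunable parameters, and the numerical and design choices the package
makes — especially where a published description of such an analysis leaves
the mechanism open.

# The three generative models of per-cell allelic counts

Let $n^j_{B}$ and $n^j_{J}$ be the uniquely assigned BL6 and JF1 RNAs in
cell $j$, $t_j = n^j_B + n^j_J$, and
$\hat p_B = \sum_j n^j_B / \sum_j t_j$ the pooled allelic ratio.

**Coin-flip (binomial null).** Every RNA draws its allele independently:
$n^j_B \sim \mathrm{Binomial}(t_j, \hat p_B)$, conditional on the observed
totals. `coin_flip_test()` computes the observed negative log-likelihood
(NLL) $-\sum_j \log \mathrm{BinomialPMF}(n^j_B; t_j, \hat p_B)$, simulates
`n_sims` datasets from the conditional null (default 10,000), and reports
the observed NLL's percentile in the simulated NLL distribution together
with a two-sided empirical p-value. Cells with $t_j = 0$ contribute nothing.

**All-or-none (random monoallelic).** Each cell commits to one allele; the
minority counts are technical noise. `all_or_none_assign()` idealizes the
observed data by reassigning every RNA to the cell's majority allele (exact
ties by fair coin). `all_or_none_test()` then simulates technical noise:
RNAs flip to the opposite identity at the false-detection rates
(`fdr_bl6`, `fdr_jf1`) measured in homozygous control tissue, under the
constraint that each simulation's population totals equal the observed
totals exactly. The NLL uses two separate binomial nulls: within
BL6-assigned cells the minority count is
$\mathrm{Binomial}(t_j, \mathrm{fdr}_{B})$, and symmetrically for JF1
cells. The simulated (BL6, JF1) correlation distribution is returned
alongside, because mutually exclusive counts make the per-cell correlation
strongly negative — a signature the coin-flip and bursting models lack.

Two design points deserve emphasis:

* *Flip-count distribution under the total constraint.* A description of
  the form "flip RNAs at the measured rates while keeping the population
  totals fixed" does not determine the joint distribution of the two flip
  counts. We draw the BL6→JF1 count $k_B$ from the exact conditional law
  of $U_B \sim \mathrm{Bin}(N_B, \mathrm{fdr}_B)$ given
  $U_B - U_J = d$, with $U_J \sim \mathrm{Bin}(N_J, \mathrm{fdr}_J)$
  independent and $d$ the net flip required by the constraint; the pmf is
  computed directly on its integer support and sampled exactly. This keeps
  the per-identity flip rates at their measured values in conditional
  expectation while honouring the constraint in every draw, and it
  reproduces the full binomial variability of the noise (a scheme that
  splits the adjustment deterministically halves the null variance and
  mis-calibrates the test).
* *Parametric bootstrap symmetry.* The observed data pass through majority
  re-assignment before their NLL is computed, so every simulated
  population is pushed through the same re-assignment before its NLL is
  evaluated. At low per-cell totals this matters: a 1-RNA cell whose only
  transcript flips is silently re-labelled rather than counted as a
  minority RNA, and only a null that undergoes the same processing is
  exchangeable with the observation.

**Independent bursting (negative binomial).** Each allele's counts follow
$\mathrm{NB}(r, p)$ with mean $r(1-p)/p$; the two-state promoter reading is
burst size $(1-p)/p$ (RNAs per burst) and burst frequency $r$.
`fit_negbin_moments()` uses the method of moments, $p = m/v$ and
$r = m^2/(v - m)$ with the sample mean $m$ and sample variance $v$
($n-1$ denominator), and refuses underdispersed input ($v \le m$).
`bursting_fit_test()` is the Monte-Carlo NLL goodness-of-fit;
`burst_size_scan()` re-parameterizes over a burst-size grid (default 0.5–5)
while holding the observed mean fixed ($p = 1/(1+b)$, $r = m/b$), calling a
configuration a good fit when the observed NLL lies in the central 95% of
its null. `paired_correlation_test()` draws the two alleles independently,
pairs them randomly into cells, optionally applies one round of
false-detection flips, and locates the observed Pearson correlation in the
simulated correlation null. Pearson is used throughout (a rank variant
would discard the count magnitudes that carry the burst signal).

**Empirical p-values** everywhere use add-one smoothing,
$p = 2\min(P(\mathrm{null} \le \mathrm{obs}), P(\mathrm{null} \ge
\mathrm{obs}))$ with numerator and denominator incremented by one, so they
are never 0 and never exceed 1.

**Detection-efficiency robustness.** Roughly half of guide spots typically
get a unique allelic identity, so `downsampling_robustness()` repeats the
chosen model's simulation at each cell's *full* RNA total, thins every
simulated cell back to its uniquely assigned count by hypergeometric
sampling, and compares downsampled and direct null distributions with a
two-sample Kolmogorov–Smirnov test. For the coin-flip model the two are
distributionally identical by the thinning property of the binomial, which
the KS check confirms numerically. The direct and downsampled runs share
one RNG stream, so at full detection they agree draw for draw. For the
all-or-none variant the population-total constraint must be restated at
full scale; we scale it to the observed allelic ratio applied to the full
totals, the natural analogue when unassigned RNAs carry no identity.

# Spot colocalization

Guide spots receive an allelic identity by colocalization with SNV-channel
spots, in pixel units throughout (at the calibration of the source scans,
2.5 px ≈ 360 nm; the equivalence is metadata only):

1. **Subpixel refinement** (`refine_spot_center()`): least-squares fit of a
   symmetric 2D Gaussian plus constant offset (L-BFGS-B, center bounded to
   the patch, $\sigma \ge 0.3$ px). Non-convergence falls back to the
   intensity centroid with a flag.
2. **Chromatic correction** (`estimate_displacement()`): nearest-neighbour
   matching within a 2.5 px window, then the componentwise *median*
   displacement — a single global vector, not an interpolated field; the
   median keeps the estimate robust when a large share of the channel is
   spurious. At least 10 matched pairs are required.
3. **Matching** (`colocalize_spots()`): after subtracting the displacement,
   candidate pairs within the radius are visited nearest-first and accepted
   greedily, so each allele spot serves at most one guide. A guide matched
   in one channel is assigned that allele, in both channels `"both"`,
   otherwise `"none"`. z planes must agree within ±1 plane by default
   (synthetic fixtures are single-plane). `unique_coloc` counts exactly-one
   assignments, `overall_coloc` any assignment.
4. **Pixel-shift control** (`pixel_shift_null()`): the guide channel is
   translated by $(+2r, +2r)$ and re-matched; what survives is chance
   colocalization. For spurious spots of density $\rho$ per channel the
   chance rate is approximately $1 - e^{-2\rho\pi r^2}$; greedy uniqueness
   depresses it a few percent below the Poisson value when many shifted
   guides compete for the same spots.
5. **Radius selection** (`select_radius()`): rates are scanned over radii
   0.1–2.5 px (step 0.1). Rather than visual inspection, the radius is
   chosen automatically as the maximizer of (real − shifted) among radii
   whose real rate is at least 95% of the maximum real rate, ties toward
   the smaller radius; the full scan table is returned for inspection.

`per_cell_counts()` aggregates assignments into the per-cell count table
consumed by the model tests; guides without a cell label are dropped with a
message.

# Foci detection and classification

`detect_foci()` runs: background subtraction (the background is a
large-σ Gaussian blur of the image, default 10× the LoG σ), grayscale
morphological opening over a 3×3 diamond (removes sub-resolution speckle),
Laplacian-of-Gaussian filtering (σ matched to the focus radius, default
2 px), binarization, connected components, border clearing (components
touching the frame are dropped), and component filters: area within
[`min_area`, `max_area`] (default 4–500 px²), solidity ≥ 0.8, minimum mean
intensity. Because the thresholds of the original scans are instrument
specific, the binarization threshold is expressed in robust noise units:
`threshold_nsd` (default 6) times the median absolute deviation of the LoG
response around zero. Solidity is component area over the convex-hull area
of its pixel centers (clipped at 1); EBImage provides neither border
clearing nor solidity, so both are computed directly.

`measure_snv_intensities()` takes each focus's mean SNV-channel intensity
over its component mask, subtracts a local background (median of an
expanded bounding box excluding all components), normalizes by the
whole-image mean of that channel, clips negatives to zero, and forms the
intensity-ratio angle $\theta = \mathrm{atan2}(I_{JF1}, I_{BL6}) \in [0,
\pi/2]$. `classify_by_kmeans()` partitions $\theta$ with 1D k-means
(k = 2, 10 restarts under a fixed seed); the critical angle is the midpoint
of the two cluster centers, JF1 above, BL6 below. With exactly two distinct
angles the optimal two-means solution is taken directly. All angles
identical is an error (a single cluster cannot be split).

# Spatial clustering of X-inactivation choice

`grid_variance()` tiles the bounding box of the foci into equal rectangles
and returns the sample variance (n−1) of the per-rectangle BL6 fraction
over *occupied* rectangles; empty rectangles have no defined fraction and
are excluded. Two nulls calibrate the observed variance:

* `permutation_null()` — identities permuted over fixed positions
  (default 1,000 permutations): spatially unstructured allelic choice.
* `seeded_cluster_null()` — identities regenerated on the same positions by
  randomly seeding clusters of a fixed size (1–10, 500 simulations each)
  at the observed allelic ratio. Clusters are grown by picking a random
  unassigned cell and absorbing its nearest unassigned neighbours (a grid
  index in compiled code makes this fast); whole clusters are labelled by
  a shuffled quota, with one cluster flipped when that exactly removes
  residual rounding imbalance. Seed size 1 reduces to the permutation
  null, which the tests verify by a KS comparison.

`match_seed_size()` selects, per grid, the seed size whose *mean* simulated
variance is closest to the observed variance (ties toward the smaller
seed), and summarises across grids by mean and SD. "Deviated least" needs a
point summary of the 500 simulated variances and the mean is the natural
one. The default grids are all square subdivisions from 4×4 to 16×16
(16–256 rectangles). Using every grid in the range, rather than a subset,
averages appreciable per-grid matching noise: the observed variance is a
single draw whose fluctuations are correlated across grids, and the
variance-versus-seed curve flattens at large seeds, so individual grids
misjudge large seeds more easily than the average does. One simulated
identity set per seed size is shared across grids — positions are fixed
and only the binning changes, and the matching consumes only the null
mean, so sharing is immaterial at 500 simulations.

# The synthetic-data generators

The generators produce every input the pipeline consumes, with the
statistical structure the analysis assumes:

* `gen_coin_flip_population()`, `gen_all_or_none_population()`,
  `gen_bursting_population()` — count tables under each model.
  Per-cell totals default to Poisson(λ = 3): the tissue data this mirrors
  have means of roughly 2.6–3.5 allele-resolved RNAs per cell, and the
  low-count regime is what makes the model comparison delicate. λ is a
  config field, and an `empirical` total model resamples a supplied count
  vector instead.
* `apply_false_detection()` and `apply_detection_downsampling()` —
  per-RNA binomial flips and binomial thinning (the latter mimics the
  ~50% unique-colocalization regime; thinning a negative binomial leaves
  it negative binomial, which the tests exploit).
* `gen_tissue_layout()` — uniform positions with seeded clusters of
  identical X-inactivation choice, as in the spatial null.
* `gen_spot_field()` — guide spots plus allele channels with a chromatic
  offset, isotropic Gaussian localization jitter, Bernoulli partner
  assignment and uniform spurious spots; the generator records per-guide
  ground truth. Cell labels come from a rectangular tiling.
* `gen_foci_image()` / `render_foci_image()` — single-plane images of
  well-separated Gaussian blobs (rejection placement at ≥ 4 PSF σ) on a
  constant background with additive Gaussian noise; SNV channels are
  rendered from the same truth table with chosen amplitudes.

Every generator is bit-reproducible under a fixed seed; multi-stage
operations derive child seeds from the root seed by a fixed affine rule, so
partial reruns reproduce. What the generators deliberately do *not*
emulate: realistic optics (the PSF is Gaussian, there is no depth
structure — fixtures are single-plane), autofluorescent tissue background,
segmentation errors in cell boundaries, spatially varying chromatic
aberration, or probe-specific binding efficiencies. Passing tests on these
fixtures therefore validate the statistical machinery, not the upstream
microscopy; on real scans the colocalization rates, false-detection rates
and detection thresholds must come from the data (homozygous controls, the
radius scan, and the QC outputs).

# Numerical choices and degenerate inputs

* Cells with zero assigned RNAs stay in the tables, contribute zero to any
  NLL, and are excluded from correlations.
* `binomial_nll()` at $p \in \{0, 1\}$ with incompatible counts is infinite
  and flagged with a warning rather than an error.
* Monte-Carlo NLL simulations run in memory chunks (~2,000 simulations at a
  time) so `n_sims = 10,000` at a thousand cells stays within a laptop's
  memory.
* Radius-limited neighbour search and cluster seeding use a uniform grid
  index in C++ (no suitable fixed-radius/kNN search was available among
  the installed packages); everything else is vectorized R on top of base
  distributions.
* Degenerate correlation draws (a constant simulated margin) yield `NaN`
  and are dropped from percentile and p-value computations.

# Problem sizes in the shipped tests

The test suite exercises the study-scale conditions directly: coin-flip
calibration over 200 populations of 500 cells (1,000 simulations each);
model discrimination over 20 replicates of 1,000 cells per generative
class, with false-detection rates estimated from simulated homozygous
controls; spatial seed recovery at 5,000 cells for true seed sizes
{1, 2, 4, 8} with 500 simulated nulls per seed size and all grids
4×4–16×16; bursting correlation nulls at 10,000 simulations of
1,000-cell populations; colocalization fields of 5,000 guides. Inside the
Monte-Carlo test calls of the replicate loops the suite uses 1,000
simulations per test — the percentile rule at the 2.5/97.5 cut needs far
fewer than the 10,000-simulation default, which remains the default for
analyses of real data.

# Known limitations

* The all-or-none noise model assumes false detections are independent
  across RNAs; correlated failures (e.g. a dim SNV channel in one cell)
  are not modelled.
* The bursting comparison uses the negative-binomial approximation of the
  two-state promoter; kinetic inference (burst timing, switching rates) is
  out of scope.
* The spatial estimator returns the seed size whose null best matches the
  variance profile; it is a point summary with grid-to-grid spread (both
  are reported), not a posterior over cluster sizes, and it saturates at
  the top of the scanned range (seed sizes 1–10).
* A single global displacement vector corrects chromatic aberration;
  spatially varying aberration across very large scans would need a
  per-tile correction.
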