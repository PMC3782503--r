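---
title: "Methods: colocalization, zymography scoring, and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colocalization, zymography scoring, and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invadoquant)
```

# Scope

invadoquant quantifies three things: the co-dependence of two fluorescence
channels (Li's intensity correlation analysis), focal matrix proteolysis by
invadopodia in in situ zymography images (the Invadopodia Index), and the
association of IHC marker positivity with clinico-pathological strata in a
patient cohort. Because the microscopy and patient data such studies rest on
are rarely shareable, the package ships seeded generators that produce
ground-truthed stand-ins with the statistical structure each analysis
assumes; every pipeline stage is benchmarked against that ground truth.

# Intensity correlation analysis

For channels $A$ and $B$ over an analysis mask of $N$ pixels,
$\mathrm{PDM}_i = (A_i - \bar A)(B_i - \bar B)$ and
$\mathrm{ICQ} = \#\{\mathrm{PDM}_i > 0\}/N - 0.5$. The statistic only uses
the *sign* of the joint deviation, which is what makes it robust to
intensity nonlinearity: it is exactly invariant under positive affine
rescaling of either channel, bounded in $[-0.5, 0.5]$, and symmetric in the
two channels. The mean PDM equals the population covariance of the two
channels over the mask, which the tests verify to $10^{-10}$ relative
tolerance.

Numerical conventions that needed a decision:

* **PDM exactly 0 counts as non-positive.** For continuous-valued data a
  channel paired with itself then attains exactly $+0.5$, while the
  degenerate all-constant image returns $-0.5$ deterministically instead of
  propagating NaN.
* **Significance** is the exact two-sided sign test: with $k$ positive-PDM
  pixels, $p = \min(1, 2\min(P(X \le k), P(X \ge k)))$ for
  $X \sim \mathrm{Bin}(N, 1/2)$. We compute it from the binomial CDF at
  every $N$ — `pbinom` is $O(1)$ and numerically stable, so no
  normal-approximation cutover is needed. Note the test treats pixels as
  independent; on spatially smooth images the effective sample size is far
  below the pixel count, so the p-value is anti-conservative and should be
  read as a descriptive index (on generator images with 3-px-smoothed
  fields, roughly the area divided by $4\pi\sigma^2 \approx 113$ pixels is
  independent). The null-calibration test in the suite uses per-pixel
  independent channels, where the nominal level does hold.
* **Analysis region** defaults to the whole volume; per-cell or per-ROI ICQ
  is obtained by passing a mask. 3-D stacks are analysed volume-wise over
  the mask.
* **Colocalized-pixel mask.** The legacy "colocalization" plugin rule is
  under-documented; we adopt the symmetric reading: a pixel colocalizes
  when both channels reach their thresholds (default 50) and
  $100\cdot\min(a,b)/\max(a,b) \ge$ ratio (default 97), skipping the ratio
  test when both intensities are zero. A brute-force per-pixel oracle in
  the test suite pins the vectorized implementation to this rule.

## The coloc generator

`gen_coloc_stack()` mixes a shared smooth field $S$ into both channels:
$A = wS + (1-w)U_A + \varepsilon_A$ and likewise for $B$, where $S, U_A,
U_B$ are Gaussian white-noise fields low-pass filtered at $\sigma = 3$ px
(raw white noise would make colocalization masks degenerate), renormalised
to mean 10 000 / sd 1 500 on a 16-bit-range intensity convention, with
$\varepsilon \sim N(0, 200^2)$ read noise by default. The mean level keeps
the probability of a negative pixel below $10^{-10}$, so intensities are
continuous and unclamped — no pixel ever ties with a channel mean. For
unit-variance fields the channel correlation is
$\rho = w^2/(w^2 + (1-w)^2 + v)$ with $v$ the noise-to-field variance
ratio, and the expected ICQ is $\arcsin(\rho)/\pi$: $w = 0.8$ gives
$\mathrm{ICQ} \approx 0.37$, the strongly co-dependent regime reported for
invadopodial marker pairs, and the mean ICQ is monotone in $w$ (verified
over 20 seeds per grid point). Each field draws from its own PRNG stream
derived from the spec seed, so the generator is bit-reproducible.

# Zymography scoring

Both acquisition dialects reduce to bright-spot detection on a *digestion
signal*:

* **gain** (dequenched substrate): signal = image − coarse Gaussian
  background (σ = 20 µm equivalent, computed on an 8× down-sampled copy;
  when the field of view is smaller than the kernel the blur degrades
  gracefully to the coarsest kernel that fits);
* **loss** (labeled gelatin): signal = plateau − image, clamped at 0, with
  the plateau estimated as the median of the brightest intensity quartile.

The signal is smoothed at σ = 1 px and thresholded at median + k·MAD
(k = 3 by default; Otsu is available as an alternative). Connected
components survive a physical size filter — minimum area that of a 0.5 µm
circle, maximum major-axis extent 8 µm — bracketing the ~1 µm × 3–5 µm
invadopodial morphology with margin. Spot `pixel_density` integrates the
(non-negative) digestion signal over the component, so rescaling the image
by a positive constant rescales densities and changes nothing else.

Downstream decisions:

* **Assignment**: a spot belongs to the cell whose mask contains its
  centroid, else the nearest cell centroid within 10 µm, else it is
  retained unassigned.
* **Active flag**: a spot is proteolytically *active* when the mean of both
  the actin and the cortactin channel over its footprint reaches
  median + 2·MAD of the respective channel. The multiplier is deliberately
  lower than the detection k = 3 because the decision is on a footprint
  mean: even a marker blob at full amplitude averages to roughly 0.4–0.7 of
  its peak over the footprint.
* **Per-cell accounting**: focal density is the sum of the cell's spot
  densities; pericellular density is the signal under the cell footprint
  dilated by 2 µm (dilation claims background only — a cell's own mask
  always keeps its label), excluding all spot pixels. Focal + pericellular
  equals the total under-footprint signal exactly, which the suite checks
  to $10^{-9}$.
* **Invadopodia Index** = % positive cells × mean active spots per positive
  cell. Whether the mean should run over positive cells only or all cells
  is ambiguous in common usage; we adopt positive-cells-only (a cell is
  positive via *active* spots only) and also report the all-cells mean in
  the result object, selectable via `average_over`.

## The scene generator

Cells are disks (radius 10 µm ± 15 %) on a jittered grid with one 26 µm
tile per cell, each cell drawing from its own seed-derived PRNG stream —
adding cells never perturbs earlier ones. Spots are anisotropic Gaussians
truncated at 2σ whose footprints span diameter × length (1 µm × U(3, 5) µm
by default), placed fully inside their cell with centre separations of at
least the sum of half-lengths + 0.6 µm, so the ground truth itself is
resolvable and benchmark misses indict the detector rather than merged
truth. Spot peak amplitude is snr × noise sd (defaults 5 × 400 on the
16-bit-range convention); active spots render both marker channels at full
amplitude, inactive ones put at least one marker at 20 %. Per-spot
activity is Bernoulli(0.8) by default. At snr = 5 and 20 cells/scene the
detector achieves ≥ 95 % recall and precision over 20 seeds, and the
Invadopodia Index is recovered within 10 % on 50-cell scenes.

What the generator does *not* emulate: optics (no PSF, the spots are
ideal Gaussians), photobleaching or quench-release kinetics, irregular
cell shapes, touching cells, uneven illumination, and background
structure in the matrix. Passing benchmarks therefore demonstrate the
correctness of the scoring machinery under the stated noise model, not
segmentation robustness on real micrographs — cell masks are expected
from upstream segmentation (a basic threshold+watershed fallback is
included for convenience only).

# Cohort statistics

Positivity is scored at the inclusive 30 % cutoff on the fraction of
stained tumor cells. Counts are summarised binomially
($\sigma = \sqrt{n p (1-p)}$). Contingency rows render percentages
rounded half-up to integers, except that an exact half-percent keeps one
decimal — published tables of this kind mix both renderings, and no single
rule reproduces every historically printed row; the unrounded percentages
always sum to 100. Association testing dispatches Mann-Whitney for two
groups (exact enumeration for total n ≤ 12 without ties, tie-corrected
normal approximation otherwise), Kruskal-Wallis (χ² approximation) for
three or more, and Spearman rank correlation for paired numeric data —
all via the standard R implementations, with midrank tie handling and
two-sided p-values. NPI grouping uses the published bins (< 2.5, 2.5–3.5,
> 4.5); the gap (3.5, 4.5] the bins leave open is classified MPG *and
flagged* (warning + `gap` attribute) rather than silently reassigned.

The cohort generator draws one chosen stratifier's levels from the
observed marginals of a 75-patient series and makes positivity Bernoulli
with the per-stratum probability; the continuous marker fraction is then
drawn uniformly on the matching side of the cutoff. Other covariates are
independent draws from their marginals — the generator reproduces
per-stratum positivity (within 3 binomial σ at n = 750, verified), not the
full correlation structure of a real cohort.

# I/O and reproducibility

Stacks are multi-page TIFF, pages z-major over `(z, c)`, intensities
scaled to [0, 1] and stored at 32 bits per sample (quantization step
≈ 1.5 × 10⁻⁵ intensity units on the 16-bit-range convention — far below
any realistic noise floor); calibration, axis sizes and channel names
travel in an OME-style JSON sidecar. Tables are UTF-8 CSV with headers;
reports are JSON with the configuration and seed echoed so every number is
recomputable. Pixel coordinates are 1-based (row = y, col = x), R-native;
physical positions are (index − 1) × spacing, pixel-centred.

Problem sizes used by the shipped benchmarks — 20-cell scenes for
detection (20 seeds), 50-cell scenes for index recovery, 128 × 128 × 2
stacks for the ICQ-monotonicity sweep, 500 null simulations at 10⁴ pixels
for sign-test calibration, cohorts of 750 for positivity recovery — were
chosen as the smallest sizes at which the binomial/Monte-Carlo error of
each check is comfortably below its acceptance margin.

# Known limitations

* The sign-test p-value ignores spatial autocorrelation (see above); for
  smooth images prefer comparing ICQs across conditions over interpreting
  a single p-value.
* The threshold/ratio mask rule is our reading of an under-documented
  legacy plugin parameterisation; the ratio is interpreted symmetrically.
* Detection assumes roughly flat backgrounds after the coarse-blur
  correction; strongly structured matrix autofluorescence would require a
  dedicated background model.
* No deconvolution is performed; users who deconvolve should do so before
  `read_stack()` (any external tool can serve as the preprocessing hook).
* `segment_cells()` is a convenience fallback, not a contribution — use a
  real segmentation for crowded fields.
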