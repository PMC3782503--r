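# invadoquant

Quantification toolkit for invadopodia biology — the actin-rich, protease-bearing
membrane protrusions through which invasive tumor cells focally degrade
extracellular matrix. The package implements the three measurements this kind of
study runs on, together with seeded synthetic generators that make every stage
testable against known ground truth:

1. **Intensity-correlation colocalization** of two fluorescence channels
   (Li's method). For channels A and B over an analysis region, the per-pixel
   *product of the differences from the mean* is

   PDM_i = (A_i − Ā)(B_i − B̄),

   and the *intensity correlation quotient* is

   ICQ = #{PDM_i > 0} / N − 0.5 ∈ [−0.5, +0.5].

   Independent staining gives ICQ ≈ 0; co-dependent localization pushes it
   toward +0.5, mutual exclusion toward −0.5. Significance is the exact
   two-sided sign test of the positive-PDM count against Binomial(N, ½).
   Intensity-correlation-analysis (ICA) scatter data and the classic
   threshold/ratio "colocalized points" mask (defaults: ratio 97, threshold 50
   on both channels) are also produced.

2. **In situ zymography scoring.** Focal proteolysis spots are detected either
   as bright dequenched-substrate puncta on a dark background (*gain* mode) or
   as dark holes in a bright labeled-gelatin background (*loss* mode; inverted
   against the background plateau so both dialects reduce to the same
   bright-spot problem). Spots are assigned to cells, flagged *active* when
   both the actin and cortactin channels are co-positive over the spot
   footprint, and each cell's digestion is split into focal (in-spot) and
   pericellular (under the dilated cell footprint, outside spots) components.
   The headline statistic is the

   **Invadopodia Index** = (% of cells with ≥ 1 active spot) × (mean number of
   active spots per positive cell).

3. **Cohort statistics.** IHC positivity scoring (positive when ≥ 30 % of tumor
   cells stain), binomial summaries with σ = √(n·p·(1−p)), Table-style
   contingency breakdowns of marker status by clinico-pathological strata,
   Mann-Whitney / Kruskal-Wallis / Spearman association tests, and Nottingham
   Prognostic Index grouping (< 2.5 good, 2.5–3.5 intermediate, > 4.5 poor;
   values in the unpublished gap (3.5, 4.5] are flagged, not silently binned).

Intended users: image-analysis and biostatistics staff quantifying
invadopodia/podosome matrix-degradation assays and their clinical correlates.

## Worked example

```r
library(invadoquant)

## Two-channel stack with strong (w = 0.8) channel co-dependence
out <- gen_coloc_stack(coloc_spec(256, 256, 10, w = 0.8, seed = 7))
icq(out$stack)
#> ICQ = 0.3717  (n = 655360 pixels, 571249 with PDM > 0), p = 0

## Gain-mode zymography scene: detect, assign, classify, score
sc <- gen_digestion_scene(scene_spec(n_cells = 20, snr = 5, seed = 1))
ss <- detect_digestion(sc$stack, mode = "gain")
ss <- assign_spots(ss, sc$cell_labels)
ss <- classify_active(ss, get_channel(sc$stack, "actin"),
                      get_channel(sc$stack, "cortactin"))
invadopodia_index(quantify_cells(ss, sc$cell_labels))
#> Invadopodia Index = 175.00  (90.0% positive cells x 1.94 active
#> spots/positive cell; n = 20)
sc$truth$index$index     # generator ground truth
#> [1] 175

## Synthetic 75-patient cohort, graded contingency + association test
coh <- gen_cohort(cohort_spec(n_patients = 75, seed = 11))
contingency(coh, "grade")
#>     stratum n_negative pct_negative n_positive pct_positive total
#> I         I         23           77          7           23    30
#> II       II         16           59         11           41    27
#> III     III         13           72          5           28    18
```

An ICQ of 0.37 at w = 0.8 sits in the strongly co-dependent regime (the
theoretical value for this mixture is asin(ρ)/π with ρ the channel
correlation); the recovered Invadopodia Index (175) matches the scene's
ground truth exactly here because at snr = 5 detection and active-marker
classification are essentially error-free.

A thin command-line wrapper for shell pipelines lives at
`inst/cli/invadoquant.R`:

```sh
Rscript inst/cli/invadoquant.R simulate --what scene --n-cells 6 --out sim
Rscript inst/cli/invadoquant.R zymo --input sim/scene.tif \
    --cells sim/scene_cells.tif --out results
```

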