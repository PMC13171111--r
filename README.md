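# punctaging

Quantitative microscopy of nucleo-cytoplasmic protein redistribution in
aging brain tissue, packaged as a tested, reusable R pipeline.

## The problem

DNA polymerase kappa (POLK), a Y-family translesion-synthesis polymerase,
is highly expressed in mouse cortical neurons. In young brains it forms
small nuclear **speckles**; with chronological age the nuclear signal
declines while POLK accumulates in larger cytoplasmic **granules**. The
shift differs by cell class (GABAergic interneurons, IN > pyramidal
neurons, PN > non-neuronal cells, NN), co-varies with DNA-damage markers
measured inside individual speckles, is modulated by microglia contact,
and is predictive enough of tissue age to train an "aging clock"
classifier on per-cell image features.

`punctaging` implements the full quantification chain needed to study
such phenotypes — and, because no raw image data are publicly deposited
for this system, a synthetic tissue-image generator with exact ground
truth so that every stage is testable end to end:

1. **simulate** — multi-channel fields (Nissl, NeuN, Gad67, Iba1, POLK,
   damage markers) of elliptical somata with class-specific marker
   positivity, Poisson-placed Gaussian puncta per compartment with
   age-dependent counts and sizes, marker intensities affinely coupled to
   spot amplitude, replicate-level clustering; plus a per-cell
   feature-table generator with the same effect structure.
2. **segment** — soma detection from the Nissl channel (smooth → Otsu →
   hole filling → watershed on the distance transform → size filter) and
   nucleus/cytoplasm partitioning (largest low-Nissl interior region,
   concentric-erosion fallback).
3. **gate** — cell classes from marker positivity (Iba1⁺ → MG; Nissl⁺
   NeuN⁺ Gad67⁺ → IN; Nissl⁺ NeuN⁺ → PN; Nissl⁺ → NN) and
   microglia-association scoring (TIED / NEAR / FREE by boundary distance
   against each microglial body length).
4. **quantify** — per-compartment punctum detection (white top-hat →
   robust threshold → connected components → area filter, centroid
   compartment assignment), per-object marker measurement, aggregation to
   a per-cell feature table (counts, counts·µm⁻², median intensities,
   areas).
5. **stats** — Cohen's d, exact/approximate Mann–Whitney U, the
   subsampled rank-test procedure (200 draws of 100 cells per group,
   median p and d), covariate-adjusted marginal-mean contrasts with
   Tukey/Bonferroni adjustment, Gaussian GEE with exchangeable or
   independence working correlation and cluster-robust (sandwich) t
   inference, Benjamini–Hochberg adjustment, Pearson correlation.
6. **clock** — deterministic stratified train/validation/test splits
   (floor/ceil convention), random-forest and gradient-boosting
   classifiers, one-vs-rest AUROC per class, normalised feature
   importances.

## Core statistics

For clustered single-cell data (cells nested in biological replicates),
the marginal linear model `E[y] = Xβ` is estimated by generalized
estimating equations with working correlation `R(α)` (exchangeable:
`R = (1−α)I + αJ`), and inference uses the sandwich covariance
`A⁻¹ (Σᵢ XᵢᵀVᵢ⁻¹eᵢeᵢᵀVᵢ⁻¹Xᵢ) A⁻¹` with a t reference on `K − p` degrees
of freedom (K clusters). Effect sizes are pooled-SD Cohen's d,
`d = (x̄₁ − x̄₂)/s_p`. Group contrasts are covariate-adjusted estimated
marginal means averaged over brain area, with studentized-range (Tukey)
and Bonferroni adjustment. For very large cell counts the subsampled
Mann–Whitney procedure reports the median p and median d over repeated
fixed-size subsamples.

## Worked example

```r
library(punctaging)

# a 128 x 128 µm synthetic field: 3 IN, 5 PN, 3 NN, 3 microglia
sim   <- simulate_image(sim_image_params(
           n_cells = c(IN = 3, PN = 5, NN = 3, MG = 3),
           field_px = 1280, seed = 101))
st    <- sim$stack
cells <- detect_somata(st$channels$Nissl, st$pixel_size_um)
cells <- classify_cells(cells, st)
cells <- partition_nucleus_cytoplasm(cells, st$channels$Nissl,
           which_cells = cells$cells$cell_id[
             cells$cells$cell_class %in% c("IN", "PN")])
cells <- score_mg_association(cells)
cells
#> <cell_set> 14 cell(s), 0.1 um/px
#> IN MG NN PN
#>  3  3  3  5

puncta   <- quantify_cells(st, cells, marker_channels = "gH2AX")
features <- build_feature_table(cells, puncta,
              metadata = list(age_group = "1M", replicate_id = "r1"))
head(features[, c("cell_class", "nuclear_count", "cyto_count",
                  "nuclear_count_per_area", "mg_association")], 3)
#>   cell_class nuclear_count cyto_count nuclear_count_per_area mg_association
#> 1         NN            12          0                 0.1500           <NA>
#> 2         PN            34         93                 0.1661           NEAR
#> 3         PN            36         82                 0.1857           TIED
```

All 14 simulated cells are recovered and correctly gated. Counts are per
compartment; `nuclear_count_per_area` is in µm⁻², so the PN above carries
~0.17 speckles per µm² of nucleus. Damage-marker intensity inside each
speckle tracks POLK intensity:

```r
sp <- puncta[puncta$compartment == "NUCLEAR_SPECKLE", ]
pearson_r(sp$polk_mean_intensity, sp$marker_gH2AX)
#> Pearson r (gH2AX vs POLK in 364 speckles): 0.862, p = 5.19e-109
```

(the generator couples marker level affinely to spot amplitude; with
replicated data the cluster-aware path is `gee_slope()`). The aging
clock on a simulated three-age feature table:

```r
tab   <- simulate_feature_table(n_per_group = 1000, seed = 5)$table
spl   <- split_data(tab, "age_group", seed = 5)     # 1800 / 600 / 600
model <- train_classifier(spl$train, spl$val, "age_group", seed = 5)
report <- evaluate_classifier(model, spl$test, split_sizes = spl$sizes)
round(report$class_auroc, 3)
#>   10M   18M    1M
#> 0.792 0.871 0.951
round(head(report$feature_importances, 4), 3)
#>    cyto_mean_area_um2            cyto_count cyto_median_intensity
#>                 0.151                 0.146                 0.145
#>   cyto_count_per_area
#>                 0.104
```

The young group is easiest to recognise and cytoplasmic granule features
dominate the importances, matching the direction of the biology the
generator emulates. `run_pipeline(default_config(), out_dir)` chains all
stages (simulate → segment → gate → quantify → stats → clock) from a
single YAML-able config with one master seed.

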