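---
title: "Methods: simulation, segmentation, quantification and inference in punctaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, segmentation, quantification and inference in punctaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `punctaging`, in the spirit of a methods section: what
each stage assumes, which knobs matter, what the synthetic data do and do
not emulate, and what the tests consequently do and do not demonstrate.

## The measurement model

The pipeline quantifies a protein (POLK, a Y-family translesion
polymerase) that appears as discrete fluorescent objects in two
subcellular compartments of brain-tissue sections: nuclear *speckles* and
cytoplasmic *granules*. The derived per-cell observables are object
counts, counts per compartment area (µm⁻², so values are invariant to
pixel size), median per-object mean intensity, mean object area, and
compartment areas, together with cell class (IN/PN/NN/MG), microglia
association, age group, biological replicate and brain area. Median, not
mean, is the per-cell intensity summary: per-object mean intensities are
right-skewed and a single bright object should not dominate a cell.

## Synthetic data generator

No public raw images exist for this system, so the generator is the
package's testbed and defines its study conditions.

**Image generator** (`simulate_image`). Somata are non-overlapping
ellipses; IN/PN carry an interior nuclear ellipse at 50% of soma area
(within the 45–60% range typical of neurons), rendered dim in Nissl
(fluorescent Nissl binds ribosomal RNA, so cytoplasm is bright) and
bright in NeuN; IN add a GABA-marker channel; NN are small Nissl-only
cells without a compartment split; MG are Iba1-positive lobed shapes
placed touching a neuron, within one body length, or far, so the spatial
scorer sees all three categories. Puncta are isotropic 2-D Gaussians
truncated at 3σ — the standard testbed for spot detectors — with
Poisson-drawn counts per compartment and uniform peak amplitudes of 8–16
background-noise SDs. A minimum centre separation of 4 spot radii is
enforced by bounded rejection sampling (both the Poisson draw and the
placed count are recorded; conservation is asserted against the placed
count).

Defaults are chosen to be *resolvable at realistic scale*: 0.1 µm pixels,
neuron somata of 10–11 µm radius, spot σ of 0.15–0.24 µm. At the
coarser geometry of an early draft the default spot rates packed
footprints so densely that no detector could separate them; real 40×
confocal sampling (0.078 µm/px, somata ≳150 px across) is
self-consistently resolvable, and the defaults mirror that regime.

Age trajectories follow the reported directions: nuclear speckle count
means 40 → 22 → 20 and radii shrinking ~20% across 1M → 10M → 18M;
cytoplasmic granule count means 90 → 31 → 24 with radii growing ~60%.
Absolute levels are free parameters (only mean differences are published)
and are order-of-magnitude choices. Nuclear spot rates are scaled per
class (IN 1.2, PN 1.0, NN 0.42), following the reported class ordering of
nuclear counts. Inside each nuclear speckle, every coupled damage-marker
channel takes the value `a + b·amplitude + N(0, σ)` over a 2σ disc; at
the default separation these discs do not overlap, so with σ = 0 the
per-speckle marker mean is an exact affine function of amplitude (a
closed-form oracle used by the tests).

**Feature-table generator** (`simulate_feature_table`). Each feature is
`age mean + class offset + replicate effect + residual`; counts are
rounded and truncated at zero. The replicate-effect SD is
`σ·sqrt(ρ/(1−ρ))`, giving latent intra-replicate correlation ρ (default
0.05, three replicates per age — a realistic animal-study layout).
Count residual SDs are calibrated by Monte-Carlo so that, *after*
truncation, pooled Cohen's d for the young-vs-older contrasts lands in
the published ranges: σ = 20.6 gives d ≈ 0.87/0.96 for nuclear counts
(target ≈ 0.85–0.95) and σ = 45 gives d ≈ 1.30/1.44 for cytoplasmic
counts (target ≈ 1.3–1.45). Class offsets reproduce the reported class
geometry of nuclear counts (IN +7.6, NN −21.8 against PN, pooled SD
12.2) and encode cortical size dimorphism (PN somata largest, IN nuclei
−6 µm², NN −15 µm²); the opposed count and size offsets are what make
nuclear count *per unit area* the leading separator of the cell-class
task, consistent with the reported feature importances. Cytoplasmic
median intensity rises with age and is the main separator of the two
older brackets, mirroring the reported importance of cytoplasmic
intensity for middle-to-old discrimination.

**What the generator does not emulate**: optics (PSF, chromatic shift),
uneven illumination, autofluorescence, tissue deformation, 3-D structure,
touching/overlapping neurons, or biological heterogeneity beyond
Gaussian replicate effects. Passing tests therefore demonstrate
correctness of the algorithms under controlled conditions, not
performance on real tissue.

## Segmentation

`detect_somata` fixes one deterministic operator chain: Gaussian smooth
(σ = 2 px) → global Otsu threshold → hole filling → watershed on the
distance transform (tolerance = half the equivalent radius of the
minimum area, which splits touching somata without oversplitting
ellipses) → area filter (defaults 15–800 µm²). Labels are ordered by
centroid (row, col), so output is reproducible. An empty image yields
zero cells, not an error.

`partition_nucleus_cytoplasm` takes the largest connected region below
the per-cell median Nissl intensity as the nucleus (hole-filled). Two
guards matter: the candidate must cover at least 25% of the soma
(otherwise the cell falls back to concentric erosion to ~50% of soma
area), and at most 80% — a thin low-intensity boundary rim, once
hole-filled, would otherwise swallow the soma. Cells below 50 px are
flagged `UNPARTITIONED` and excluded downstream. Nucleus and cytoplasm
partition the soma exactly by construction.

## Gating and microglia association

Positivity per channel is *mean soma intensity > background median +
k·MAD* (k = 3), background being all non-soma pixels. Means are taken on
2-px-eroded masks: after a watershed split of a touching microglia–neuron
pair a few boundary pixels can land on the wrong side, and with a
zero-noise threshold a single bled Iba1 pixel would flip a neuron to MG.
Decision order: Iba1⁺ → MG; Nissl⁺NeuN⁺GABA⁺ → IN; Nissl⁺NeuN⁺ → PN;
Nissl⁺ → NN; else UNCLASSIFIED. A Gad67 antibody channel and a tdTomato
reporter channel are interchangeable in the GABA role.

"One microglial body length" is operationalised as the equivalent-circle
diameter of that MG's mask, evaluated per MG — scale-free and computable
from the masks alone. "Contact" is adjacency after 1-px dilation, i.e.
minimum pixel distance ≤ √2. A neuron is TIED if any MG touches it, FREE
if every MG is farther than its own body length, otherwise NEAR. NEAR
neurons are excluded from TIED/FREE contrasts by default (whether the
original analysis pooled them is unknowable; the category is labelled so
callers can pool). The implementation scans boundary pixels; tests check
exact agreement with an exhaustive all-pixel-pair oracle.

## Punctum detection and measurement

Per cell: white top-hat (disc radius 10 px ≈ 3× the largest expected
punctum radius) flattens diffuse signal; within each compartment the
threshold is `median + k·MAD` (k = 5) of the top-hat values, with the MAD
estimated one-sidedly from the lower tail, `(med − q25)/Φ⁻¹(0.75)` —
puncta contaminate only the upper tail, and a two-sided MAD inflates the
threshold enough to lose low-amplitude spots once footprints cover
~20% of a compartment. Connected components are filtered by area
(0.04–20 µm²) and assigned to the compartment containing their centroid,
so boundary-straddling objects land in exactly one compartment.
Intensities are raw (no background subtraction — acquisition parameters,
not normalisation, are assumed constant). NN cells are quantified on the
whole soma with the signal booked as nuclear, since their nucleus
occupies most of the cell.

## Statistical layer

*Cohen's d* is the pooled-SD variant without small-sample correction,
matching common statistical-software output. *Mann–Whitney U* is exact
(permutation distribution) when both groups have ≤ 8 observations and no
ties, else a tie- and continuity-corrected normal approximation; with
identical samples the approximation returns p = 1 exactly. The
*subsampled procedure* draws `n_per_group` cells per group without
replacement `n_iter` times (defaults 100 and 200) and reports median p
and median d — its purpose is to blunt the huge-n significance inflation
of per-cell data, so it is *deliberately conservative* when the parent
groups are much larger than the subsample; its type-I error is nominal
only in the regime where the subsample spans the group, and that is the
regime in which calibration is tested.

*Covariate-adjusted contrasts* fit `response ~ group + covariate (+
averaging factor)` and compare covariate-adjusted estimated marginal
means averaged over the averaging factor (brain area), with Tukey
(studentized-range, family = number of comparisons) and clamped
Bonferroni p-values, and d = adjusted difference / residual SD.

*GEE*: Gaussian identity-link marginal model, exchangeable (default) or
independence working correlation, moment estimator for α, sandwich
covariance, and Wald t tests on `K − p` degrees of freedom. The t
reference (rather than normal) is the standard guard against
anticonservative sandwich inference with few clusters: with 10 clusters
the normal reference gives ~0.86 empirical CI coverage at the nominal
95%, the t reference ~0.93. With independence working correlation the
point estimates equal pooled OLS exactly, and with singleton clusters
the fit reduces to OLS — both asserted in tests. The link/family is
identity/Gaussian (intensity responses); both the working structure and
this choice are explicit arguments, not silent defaults.

*Multiplicity*: Benjamini–Hochberg step-up with monotonicity enforcement
and family-size Bonferroni, both via `p.adjust`-grade routines; Pearson
correlation is provided as the descriptive single-cell statistic, with
GEE as the inferential path.

## The aging-clock stage

`split_data` uses `n_test = floor(0.2·n)`, then `n_val =
ceiling(0.2·(n − n_test))`, stratified by label with largest-remainder
apportionment so the totals are exact; this convention reproduces the
published split sizes at n = 1,232 (788/198/246) and n = 28,680
(18,355/4,589/5,736) simultaneously. The random forest uses 500 trees
and Gini node-purity importances; gradient boosting uses multinomial
log-loss, learning rate 0.1, up to 300 rounds with early stopping (20
rounds) on the validation set, and total-gain importances. Neither
model's hyperparameters are published; these are conventional defaults.
AUROC is one-vs-rest per class from predicted class scores (a rank
statistic, invariant to monotone score transforms), plus a macro
average. Replicate identity is accepted as a feature only when
explicitly enabled — it leaks acquisition structure into the label and
is off by default. Importances are clipped at zero, normalised to sum
to one, and sorted.

## Problem sizes used in testing

Unit tests run on a 14-cell 128×128 µm field (cached across test files);
the recovery check runs the full 50-cell default field once. Null
calibrations use 500 simulations each (1,500 for the subsampled
procedure, whose binary rejections carry the largest Monte-Carlo error);
the contrasts null uses 3 groups × 100 cells, the GEE null 100 clusters
× 8 (the sandwich estimator's validity regime), and GEE recovery 10
clusters × 50 at ρ = 0.5. Classifier checks use 3,000-cell tables.
These sizes make the full suite complete in a few minutes on one CPU
while keeping Monte-Carlo SEs a few times smaller than the tolerance
bands.

## Known limitations

- The segmentation chain is a reference implementation, not a re-creation
  of any specific interactive pipeline; on real tissue with overlapping
  somata and uneven staining it will under-segment.
- The GEE α estimator assumes a common exchangeable correlation across
  clusters; strongly unbalanced or tiny clusters push inference toward
  the robust-but-noisy end.
- The generator's marker coupling is linear with Gaussian noise; real
  colocalization is thresholded and nonlinear.
- 3-D stacks, proprietary microscope formats and learned segmentation
  models are out of scope; convert to single-plane TIFF first and supply
  channel names in the config, since exported channel order is
  vendor-dependent.
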