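---
title: "Quantifying 3D leukemia–stroma co-cultures: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D leukemia-stroma co-cultures: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chronic lymphocytic leukemia (CLL) B cells depend on contact with bone
marrow stromal cells (BMSCs). In scaffold-based 3D co-cultures, malignant B
cells, autologous T cells and stromal cells organize into a tissue-like
structure with a drug-resistant core and an accessible periphery. Two
kinds of readout arise from such cultures and both are covered here:

1. **Spatial image quantification.** Multi-channel confocal z-stacks
   (nuclear stain, CD19 for B cells, CD3 for T cells, CD90/phalloidin for
   stroma, optionally cleaved caspase-3) are segmented into a stromal
   scaffold mask and per-nucleus instance masks; cells are then classified
   from marker intensities, B–T co-localization is counted, and the
   apoptotic fraction of B cells is quantified per condition.
2. **Crosstalk inference.** Differential-expression (DE) tables — B cells
   contrasted between core and periphery, and stromal single-cell clusters
   contrasted against each other — are cross-referenced against a curated
   protein–protein interaction (PPI) edge table to nominate
   ligand/receptor-level communication channels, and stromal clusters that
   exist only under tumor contact are flagged.

Raw imaging and sequencing data for such experiments are typically not
deposited, so the package ships a synthetic-data module that generates
stacks, label volumes and omics tables with known ground truth. Every
quantitative claim in the test suite is a recovery of a planted quantity.

## Scaffold segmentation

The stromal scaffold is segmented with a fixed five-stage pipeline:

1. **Channel combination** — each structural channel is min–max rescaled
   to [0, 1] and the voxelwise maximum is taken, so structure visible in
   any of the channels survives.
2. **3D median filter**, radius 1 voxel in x, y and z (reflect padding).
3. **Contrast enhancement** — a saturation-quantile linear rescale to
   8-bit: the 0.35% and 99.65% intensity quantiles map to 0 and 255 with
   clipping outside. The 0.35%-per-tail default mirrors the common Fiji
   "enhance contrast" convention; a constant volume maps to all zeros by
   definition rather than erroring.
4. **Fixed threshold** — foreground iff intensity strictly greater than
   T = 16 on the 8-bit scale. The comparison is strict, and the threshold
   is applied after the 8-bit conversion (the natural reading when the
   threshold is quoted on an 8-bit scale).
5. **Morphological cleanup** — 3D closing with a Euclidean ball (radius 1)
   followed by removal of 26-connected components below 27 voxels.
   "Morphological filters to remove artifacts and enhance structure" is
   underdetermined; closing plus small-object removal is the minimal pair
   that does both, and both are parameters.

All neighbourhood filters use half-sample symmetric reflection at borders
(the edge voxel is repeated), which avoids edge darkening on thin stacks;
connectivity is 26-neighbourhood throughout.

## Nuclei instance segmentation

The published workflow trained a learning-based segmenter whose weights
are not available; the package substitutes a deterministic classical
pipeline with the same contract, honouring the nominal nucleus diameter
of 6.2 voxels (defined as the full width at half maximum):

Gaussian smoothing (σ = 1) → global Otsu foreground threshold → seed
detection → seeded watershed → size filter (regions outside 20%–500% of
the nominal sphere volume are removed) → contiguous relabelling.

Seeds are local maxima of the *smoothed intensity* inside the foreground,
thinned greedily to a minimum separation of 0.7 × diameter (ordered by
intensity, ties broken by smaller (z, y, x) — this makes the result
deterministic). The watershed floods the inverted smoothed intensity.
An earlier variant seeded from maxima of the Euclidean distance transform,
as is common for round well-separated objects; it systematically merged
nuclei planted directly adjacent to each other (surface gap ≤ 1 voxel),
because the distance transform of the merged blob has a single maximum
while the intensity field remains bimodal whenever the center separation
exceeds 2σ of the rendered nucleus profile. Seeding and flooding on
intensity resolves exactly the configurations the co-localization analysis
cares about.

Externally produced label volumes (e.g. from a trained segmenter) are
accepted as first-class input via `read_labels()`, which validates an
integer pixel type and relabels ids contiguously with a reported mapping.

## Phenotyping: normalization, thresholds, classification

Per mask and marker, the mean voxel intensity is computed. Within each
z-stack and marker, means are divided by their sum (so they add to 1) and
natural-log transformed; zeros are replaced by half the smallest positive
scaled value of that stack and marker before the log. The log base is
irrelevant to percentile thresholds (monotone), and the per-stack sum
scaling makes classification invariant under any uniform intensity
rescaling of a stack — a property the test suite checks directly.

Thresholds are percentiles of the **combined** pooled distribution: the
normalized log intensities of all classification markers and all stacks
are pooled into a single vector, and each marker's threshold is read from
it — by default the 40th percentile for CD19 and the 95th for CD3. The
asymmetry matches the skewness of that combined distribution: in a
co-culture where B cells outnumber T cells roughly ten-fold, the bulk of
high values are CD19 signals of B cells (so a low percentile separates
them from the background mass), while CD3 signals of the rare T cells
occupy only the extreme upper tail. Pooling per marker instead is
available (`pool = "per_marker"`), but note that a per-marker percentile
*p* fixes the positive fraction at 1 − p/100 by construction, regardless
of the data — it cannot recover an unknown population composition.
Percentiles are computed by linear interpolation between order statistics
(`quantile(type = 7)`), and positivity is strict (`>`): a cell exactly at
the threshold is negative.

A cell positive for both markers is `double_pos`; for neither,
`negative`. Counts per stack report CD19⁺ and CD3⁺ including double
positives in both.

## Co-localization

Methods-style texts and figure legends sometimes differ on what counts as
co-localized: double-positive masks only, or double-positive *or directly
adjacent* masks. Both are implemented behind an explicit `mode` argument;
the default (`double_pos_or_adjacent`) matches the figure-level
quantification. "Directly adjacent" means a surface-to-surface gap of at
most one voxel: the regions touch after dilating one of them with a
3×3×3 element, i.e. the Chebyshev distance between their closest voxels
is at most 2. Both members of an adjacent CD19⁺/CD3⁺ pair enter the
co-localized set.

## Apoptotic fraction

Per stack, the apoptotic fraction is |CD19⁺ ∧ caspase-3⁺| / |CD19⁺|;
stacks without CD19⁺ cells are excluded with a warning. Condition means
are unweighted means over 3–4 stacks and are reported as ratios against a
control condition (0/0 is reported as ratio 0).

Caspase-3 positivity was a manual call in the original workflow, so the
automated rule here is a design choice. The default is an Otsu split of
the pooled caspase norm-log distribution, accepted only if the two classes
separate by at least one natural-log unit (about e-fold); otherwise the
distribution is treated as unimodal and no cell is flagged. The guard is
what makes the all-negative case come out as exactly zero rather than as
an arbitrary split of noise. A fixed-percentile rule
(`rule = "percentile"`) is also provided; it is appropriate when the
expected positive fraction is known a priori, but a fixed percentile pins
the flagged fraction and therefore cannot measure an unknown apoptotic
rate — which is why it is not the default.

## Crosstalk inference

A PPI edge survives cross-referencing when its partners match the DE
evidence. Three classes are emitted, each selectable: `B_BMSC` (one
partner in the B-cell core-vs-periphery DE set at adjusted p < 0.05, the
other a qualifying stromal gene), `B_B` (both partners B-DE — the
core/periphery communication pairs), and `self_ligand` (self-edges whose
gene qualifies on either side). A stromal gene qualifies iff it is DE in
at least one cluster contrast (adjusted p < 0.05, strict) *and* expressed
in at least 10% of cells in at least one cluster (inclusive ≥, so a gene
at exactly 10% qualifies). Genes present in both the B and stromal sets
produce records for both orientations, flagged `dual`, rather than being
deduplicated. Symbol matching is exact after uppercasing; no alias or
ortholog resolution is attempted. No confidence cutoff is applied by
default (`min_confidence = 0`), since curated-database confidence scales
are dataset-specific; the HIPPIE v2.3 native tab dialect and a generic
three-column TSV are both supported.

Condition exclusivity of a cluster is the largest fraction of its cells
coming from one experimental condition; clusters at or above 0.95 are
flagged condition-exclusive with their dominant condition — the logic that
identifies a contact-induced stromal population.

The whole procedure is exact set logic, so the test suite holds it to
exact agreement with an independent brute-force triple loop, and to
sensitivity and specificity 1.0 on planted bundles.

## The synthetic-data generator

`generate_coculture_stack()` renders nuclei as Gaussian blobs whose full
width at half maximum equals the nominal diameter (6.2 voxels), placed by
rejection sampling with a minimum center distance of 1.2 × diameter;
planted co-localized pairs are placed at center distance diameter + 1
voxel (surface gap ≤ 1). B cells carry CD19 signal, T cells CD3, with a
configurable bleed-through fraction between the two; caspase-3 signal
appears only on the planted apoptotic B cells; stromal filaments are
rendered into CD90 but never labelled as cells. The label volume contains
one sphere of the nominal diameter per cell, ids matching the ground-truth
table.

Free parameters not fixed by the study design were chosen once as
realistic confocal conditions and are not tuned per analysis: peak
signal-to-background ratio 5, bleed-through 0.02, Poisson photon noise,
default volume 64×128×128 with 50 B and 5 T cells (the 10:1 B:T ratio of
the co-culture protocol), 60% of T cells planted adjacent to a B cell.
The recovery analyses in the tests and the acceptance script additionally
use 128×256×256 stacks with 100 cells for the segmentation study, 4
stacks per condition for the apoptosis study, and planted apoptotic
fractions 0.1/0.3/0.5.

Stromal filaments are random walks stamped with continuous-center spheres
(radius 4 voxels) branching off the existing network, which keeps the
planted mask a single 26-connected component. The raw stamped mask is
regularized to a (near) fixed point of the radius-1 binary median filter:
discrete sphere stamping leaves a knobbly surface that a median filter
systematically shaves, which would make the planted mask unrecoverable by
*any* median-based pipeline; the regularized mask is the structure the
generator actually commits to. If regularization erodes too much mass,
more filaments are grown and the cycle repeats, so the requested density
is approximately honoured.

What the generator does **not** emulate: optics-accurate point-spread
functions, anisotropic voxels (isotropic by default; anisotropy only via
scale factors in placement distances), autofluorescence gradients,
realistic single-cell count matrices (only DE summary tables are
emulated), or segmentation-hostile nucleus shapes. Passing the recovery
tests therefore shows the quantification logic is correct under the
stated geometry and noise model, not that the stand-in segmenter matches
a trained model on real tissue.

## Numerical choices and degenerate inputs

- Percentile definition: linear interpolation between order statistics.
- All threshold comparisons are strict (`>`); ties go negative/background.
- Borders: half-sample symmetric reflection for all sliding-window
  filters; out-of-bounds treated as background for binary morphology.
- Watershed determinism: flooding order is (priority, then smaller linear
  index); seed thinning order is (value, then (z, y, x)).
- Constant volumes: contrast enhancement returns all zeros; the variance
  filter returns zeros; nuclei segmentation returns an empty label volume
  with a message rather than an error.
- A marker whose means are all zero in a stack yields `NA` normalized
  values and all-negative classifications, with a message.
- Empty pools (no finite normalized values) are errors.

## Problem sizes

Classification, co-localization and apoptosis recovery are evaluated on
the generator's label volumes so that the quantification logic is tested
in isolation; segmentation quality has its own recovery study (count and
centroid accuracy against planted ground truth). On segmented masks the
same pipeline runs unchanged, but mask extent then depends on the
foreground threshold, which can add contacts between nearby cells that
the nominal-diameter ground-truth masks do not have.

The shipped tests and the acceptance script run entirely on synthetic
data: three to five 128×256×256 stacks of 100 cells for segmentation
recovery,
five default stacks for classification and co-localization recovery,
twenty default stacks for the apoptosis study, 200 random volumes up to
7³ for the filter oracles, and 50 random toy bundles (up to 200 genes /
2000 edges) plus planted bundles for crosstalk exactness.

## Known limitations

- The nuclei segmenter is a classical stand-in; real tissue with variable
  nucleus size, texture or strong anisotropy will favour a trained model.
  External masks can be supplied to keep the rest of the pipeline intact.
- Percentile thresholds assume the pooled intensity distribution reflects
  the population structure the percentiles were chosen for; they are
  configuration, not estimates.
- Crosstalk inference nominates candidate interactions by set logic; it
  scores no expression correlation and models no ligand–receptor
  directionality.
- Statistical testing across patients/conditions (paired tests, ANOVA) is
  out of scope; the package stops at per-condition summaries.
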