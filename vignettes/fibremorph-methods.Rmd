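---
title: "Methods: automated muscle and nerve histomorphometry in fibremorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated muscle and nerve histomorphometry in fibremorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Skeletal muscle adapts to chronic electrical stimulation, denervation and
reinnervation by shifting its fibre-type composition. In laryngeal-pacing
research the readouts of interest are, per cross-section image: the fibre
type ratio (FTR = number of slow fibres / number of fast fibres), the
percentage of hybrid fibres (fibres expressing both slow and fast myosin,
a sign of ongoing conversion), the fibre sizes (minimum Feret diameter,
MFD), and the intramuscular collagen area fraction (a fibrosis marker).
For the innervating nerve, semithin cross-sections yield per-axon axon
diameter (AD), overall diameter (OD) and myelin thickness
MT = (OD − AD)/2.

`fibremorph` implements this measurement chain for three-channel
immunofluorescence images (red = myosin slow, green = myosin fast,
orange = collagen) as a three-step workflow — pre-processing, fibre
segmentation, fibre classification — followed by morphometry and a
mixed-model statistical layer. Because real cohorts of this kind are
rarely redistributable, the package also contains a synthetic-image
generator with complete ground truth, and every stage is validated by
parameter recovery against it.

# Image analysis

## Pre-processing

1. **8-bit conversion** (`to_grayscale8()`): channels are linearly
   rescaled from their nominal range to [0, 255], rounding half up.
2. **Collagen enhancement** (`enhance_collagen()`): percentile-based
   histogram stretching of the orange channel. Defaults are the 1st and
   99th percentiles; the operation is standard but its parameters are not
   canonical, so both are explicit configuration echoed into the run
   manifest.
3. **Channel composition** (`compose_segmentation_input()`): the enhanced
   collagen image is subtracted from the sum of the two myosin channels
   and clipped to [0, 255]. Fibre interiors (bright in at least one
   myosin channel) stay bright while the interstitial lattice (bright in
   collagen) is driven to black — exactly the contrast an
   instance-segmentation step wants.
4. **Binarisation** (`binarise_channel()`): Otsu's threshold by default
   for the myosin channels; any fixed threshold can be pinned instead
   (`"fixed:<t>"`), which is useful for bit-exact reproduction across
   environments. The collagen mask uses the fixed mid-range cut 128 on
   the *stretched* channel by default: the stretch normalises the
   collagen structures to the top of the 8-bit range, making the
   midpoint the natural area-preserving threshold, whereas Otsu
   misplaces its cut when the foreground is a small minority of the
   pixels (as a 5% collagen lattice is). A constant channel binarises to
   all-background with a warning rather than an arbitrary split.

## Segmentation

`segment_fibres()` has two backends behind one contract (a label matrix;
everything downstream is a pure function of it):

* **`watershed`** (default): the composed input is thresholded, the
  Euclidean distance transform of the foreground is computed, and
  watershed flooding from its regional maxima splits touching fibres.
  The merge tolerance is tied to `min_fibre_diameter` (default 15 µm, a
  physiological lower bound for adult large-mammal fibres): maxima
  shallower than a quarter of that diameter are merged, which suppresses
  over-segmentation inside large fibres.
* **`external`**: ingest any instance label image (e.g. from a learned
  segmentation model such as Cellpose). This keeps the package
  self-contained — no model download, no GPU — while remaining
  bit-compatible with a learned backend: feed the external label TIFF
  and the rest of the pipeline is unchanged.

Labels become ROIs (`labels_to_rois()`); any ROI with a pixel on the
outermost row or column is flagged and removed (`filter_border_rois()`) —
fibres cut by the field of view would bias both size and coverage.

## Classification

Each interior ROI is classified (`classify_roi()`) from its area and its
coverage in the binarised myosin channels:

* area < `min_area_um2` → **noise** (other structures);
* both coverages ≥ T → **hybrid**;
* exactly one coverage ≥ T → **slow** or **fast**;
* neither ≥ T → **noise** (unstained object).

Defaults: T = 0.3 shared by both channels, `min_area_um2` = area of a
15 µm circle (≈ 177 µm²). Neither cut-off has a canonical published
value; both are mandatory configuration and are echoed into output
provenance. Per-channel thresholds exist but are off by default. The size
rule is a lower bound only — we found no justification for discarding
unusually large objects, which are better caught by the coverage rule.
Classification is monotone by construction: raising T can only move ROIs
towards noise, never rescue one.

## Morphometry

* **MFD** (`min_feret_diameter()`): rotating calipers on the convex hull
  of the ROI's pixel corner points (the Feret widths of a set equal those
  of its hull; the minimum width is attained flush against a hull edge).
  Using pixel corners rather than centres makes a single pixel one pixel
  size wide instead of degenerate.
* **FTR** (`fibre_type_ratio()`): slow/fast counts of pure classes only;
  hybrids are counted in neither, since they are in transition by
  definition. FTR is undefined (NA, flagged) when no fast fibre is
  present — undefined is a value, not an error.
* **Collagen fraction** (`collagen_area_fraction()`): foreground
  percentage of the binarised (enhanced) collagen channel, optionally
  within an analysis region.
* **Nerve metrics** (`nerve_metrics()`, `measure_nerve_image()`): AD and
  OD are equivalent-circle diameters (2·√(area/π)) of the axoplasm region
  and the filled fibre disc; MT = (OD − AD)/2 exactly. Equivalent
  diameters were chosen because the commercial tool they stand in for
  does not document its diameter definition; a Feret-based variant is a
  one-line swap (`min_feret_diameter()` on the same masks).

# Statistics

Each per-image metric is modelled once across all conditions as

    value ~ condition + (1 | animal)

with the animal as a random factor, because several images per animal
enter the analysis and images are not independent replicates. The single
omnibus model (rather than separate per-pair fits) pools the residual
variance estimate and is the default; pairwise contrasts are extracted
from it with Satterthwaite degrees of freedom. The alternative —
per-pair models — can be had by subsetting the input table and is not a
package switch.

Decisions worth stating:

* **FTR is modelled on the log scale** (ratios are positive and
  multiplicative; plots of such data are conventionally log-scaled) and
  back-transformed as `estimate_ratio = exp(estimate)`.
* **Satterthwaite df** come from the `lmerTest`/`emmeans` machinery; a
  between-within fallback is not silently substituted — if the machinery
  is unavailable the fit errors.
* **Multiplicity**: Benjamini–Hochberg across all pairwise contrasts of
  one metric (one family per metric). `bh_adjust()` is the step-up rule;
  the test suite checks it against an independently coded implementation.
* **Significance** means q < 0.1, annotated `*` (q ≤ 0.1), `**`
  (q < 0.01), `***` (q < 0.001), `****` (q < 0.0001).
* **Effect sizes**: unsigned Cohen's d with pooled sd, binned
  [0, 0.2) none, [0.2, 0.5) small, [0.5, 0.8) medium, [0.8, ∞) large.
  (Figure-legend conventions in this literature sometimes label the
  d ≥ 0.2 colour "medium"; the bin labels here follow the textual
  definition, the cut-offs are identical.)
* **Singular fits**: zero estimated animal variance is a boundary fit;
  it is kept (the model then reduces to the fixed-effects fit, and the
  contrast p-values coincide with ordinary two-sample results) and
  flagged via `boundary_fit`, never silent.
* **Nerve morphometrics** use a two-sample t-test (Welch by default) at
  p < 0.05; axons are the unit of analysis, which matches how such
  sections are conventionally summarised but overstates independence if
  few animals contribute many axons — a known caveat, not a package
  default we can fix without per-animal axon tables.
* **Boxplot convention** (`boxplot_summary()`, `plot()` method): box from
  Q1 to Q3 (linear-interpolation quartiles, `quantile()` type 7), median
  line, white dot at the mean, whiskers at Q1/Q3 ± 1.5·IQR, outliers
  beyond.

# The synthetic cohort generator

`generate_fibre_geometry()` builds a cross-section as a Poisson-disc
point set tessellated into convex cells (discrete Voronoi on the pixel
grid, two Lloyd relaxation iterations for fibre-like isotropy). The
interstitial collagen lattice falls out of the same computation: a pixel
belongs to the lattice when the difference between its second-nearest
and nearest seed distances is below the band width, which carves a band
of the requested physical width between neighbouring cells.
`calibrate_collagen_band()` bisects the band so the lattice hits a
designed area percentage.

Types are assigned independently per fibre (`assign_fibre_types()`):
hybrid with probability `hybrid_fraction`, otherwise slow with the
conditional probability that makes `slow_fraction` the marginal slow
proportion. The realised composition — not the requested one — is
recorded as ground truth.

`render_channels()` paints class means (defaults: pure-class myosin mean
180, collagen 160, background 10 on the 8-bit scale), with hybrids at
60% of the pure mean in both myosin channels — hybrids express both
isoforms, at reduced intensity. Gaussian blur (σ = 1 px) then Gaussian
noise (sd = 8) emulate acquisition; rendering refuses configurations
whose class-background contrast does not exceed the noise sd.

`generate_cohort()` arranges this into a study-like design: groups with
per-group animal counts (defaults CT = 4, SHAM = 8, DC04 = 4, DC07 = 6),
two sides (naturally innervated vs cryo-damaged nerve), two
electrode-distance regions (the unimplanted control group has a single
region), several images per condition, and — crucially for the
statistics layer — a per-animal random intercept on log-FTR
(sd = `animal_sd`, default 0.3). Acting on log-FTR keeps the ratio
positive and makes the animal effect exactly the quantity the mixed
model assumes, so parameter recovery is a fair test of the statistical
layer. Default condition FTRs (CT 0.45, SHAM 0.6, DC04 4.0, DC07 3.8,
with multiplicative shifts of 1.3 on the damaged side and 1.2 near the
electrode) emulate a strong stimulation-induced fast-to-slow shift over
a slow-minority baseline, the regime this kind of study operates in.

The nerve counterpart (`random_nerve_spec()`, `generate_nerve_image()`)
renders non-overlapping axons as an intermediate-grey axoplasm disc
inside a dark myelin annulus on a light background — a toy
toluidine-blue section. ADs are drawn uniformly from 4–10 µm and MTs
from 1–2.5 µm, plausible for a large-mammal peripheral nerve at the
0.1 µm/px default.

**What the generator does not emulate**: uneven illumination, chromatic
aberration, staining gradients, sectioning artefacts (oblique cuts,
folds), anisotropic or non-convex fibre outlines, vascular structures,
and electrode scar tissue. Passing recovery tests on these images
demonstrates that the measurement chain is correct on well-behaved
input; it does not certify performance on degraded real acquisitions,
where the pluggable external (learned) segmentation backend is the
intended route.

The paper-scale acquisition parameters (pixel size, image dimensions,
fibres per field of view) are not published for this kind of study;
0.5 µm/px as a stand-in for a 20× objective and 512² px defaults are
engineering choices, and everything downstream reads the pixel size
from the image container.

# Numerical choices and degenerate inputs

* Half-up rounding in 8-bit conversion (so 16-bit mid-scale maps to 128).
* Otsu on a constant channel: all-background with a warning.
* Degenerate (collinear) ROIs: MFD 0 with a warning.
* Fibres erased by the collagen shrink: dropped with a warning, never a
  crash.
* `n_fast = 0`: FTR undefined (NA) and flagged; such rows are dropped
  from the mixed model with a logged message.
* Watershed tolerance `min_fibre_diameter / 4` in pixels, floor 1.
* All simulation randomness flows through explicit integer seeds;
  identical seeds give bit-identical images, metadata and CSV outputs.
  RNG state of the caller is saved and restored.

# Validation harnesses and problem sizes

The test suite validates each stage against independent oracles
(brute-force Otsu, a dense-angle MFD oracle with golden-section
refinement, an independently coded BH step-up, closed-form annulus
areas) and the whole chain by parameter recovery. The end-to-end checks
run at deliberately moderate sizes chosen as the package's own test
conditions: ten noise-free 800² px sections (~300 fibres each) for
classification accuracy; four-image batches at 512² px per designed FTR;
1000 null replicates (two conditions × 6 animals × 4 images) for type-I
calibration of the mixed model; 200 replicates for CI coverage; 50 axons
at 0.1 µm/px for nerve recovery.

The field-of-view representativeness harness
(`validate_fov_representativeness()`) samples *disjoint* FOVs — the FOV
FTRs are then independent, and a one-sample t-test against the
full-section FTR is calibrated; overlapping FOVs would share fibres and
overstate the evidence. The section FTR uses the same border-exclusion
rule as the FOVs, so a full-section FOV reproduces it exactly.

# Known limitations

* The watershed backend assumes convex, lattice-separated fibres; heavily
  merged or dye-bled real images need the external backend.
* Collagen quantification inherits any bias of the binarisation. Thin
  lattices are broadened by the acquisition blur: a band narrower than
  about three pixels (e.g. a 5% fraction sampled at 1 µm/px with a 1 px
  PSF) is over-counted at any threshold, so the fraction should be
  measured at the native 0.5 µm/px sampling — the recovery checks cover
  5–25% there.
* The classification threshold T and `min_area_um2` must be tuned to the
  staining protocol; the defaults are sensible for the synthetic
  contrast model, not universal constants.
* Nerve measurement assumes rings resolvable at the given threshold and
  non-touching axons; it discards border-touching rings.
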