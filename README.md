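# fibremorph

Automated histomorphometry of fluorescently stained skeletal muscle
cross-sections, with a synthetic ground-truth generator and a
mixed-model statistical layer.

## What it is for

Studies of muscle plasticity (electrical stimulation, denervation,
reinnervation) quantify, per cross-section image stained for myosin slow
(red), myosin fast (green) and collagen (orange):

* **FTR** — fibre type ratio, `n_slow / n_fast`;
* **hybrid %** — fibres positive for both myosin isoforms
  (`100 · n_hybrid / (n_slow + n_fast + n_hybrid)`), a marker of ongoing
  fibre-type conversion;
* **MFD** — per-fibre minimum Feret diameter (smallest caliper width,
  robust to oblique sectioning);
* **collagen %** — area fraction of the binarised collagen channel
  (fibrosis marker);

and for nerve semithin sections: per-axon axon diameter AD, overall
diameter OD and myelin thickness `MT = (OD − AD)/2`.

The image pipeline is the classical three-step workflow — (i)
pre-processing (8-bit conversion, collagen enhancement by histogram
stretching, subtraction of the enhanced collagen from the summed myosin
channels, binarisation), (ii) fibre instance segmentation
(distance-transform watershed, or any external label image, e.g. from a
learned model), (iii) classification of interior ROIs into slow / fast /
hybrid / noise from their size and their coverage in the binarised
myosin channels.

Per-image metrics are analysed with a linear mixed model per metric,

    value ~ condition + (1 | animal)

(the animal is a random factor because several images per animal enter
the analysis), with Satterthwaite degrees of freedom for pairwise
contrasts, Benjamini–Hochberg q-values (significance at q < 0.1) and
unsigned Cohen's d binned at 0.2 / 0.5 / 0.8. FTR is modelled on the log
scale and back-transformed.

Because microscopy cohorts of this kind are rarely shareable, the
package includes a seeded simulator: Poisson-disc/Voronoi tessellated
fibres with an interstitial collagen lattice of designed width, typed
fibres with a per-animal random intercept on log-FTR, rendered
three-channel images with blur and noise — plus a toy nerve-section
model. Every stage is validated by parameter recovery against this
ground truth.

## Worked example

Simulate a small two-group cohort (control-like FTR 0.45 vs a strongly
stimulated group at FTR 4, per-animal log-FTR sd 0.2), run the full
pipeline, and test the group effect:

```r
library(fibremorph)

design <- cohort_design(
  groups = c(CT = 3L, DC04 = 3L), sides = "nPCA", regions = "PCA+",
  images_per_condition = 3L, base_ftr = c(CT = 0.45, DC04 = 4),
  animal_sd = 0.2, width_px = 384, height_px = 384,
  mean_fibre_diameter = 40, pixel_size = 0.5, seed = 7)
cohort <- generate_cohort(design)
run <- run_pipeline(cohort, pipeline_config())

head(run$image_metrics[, c("image_id", "group", "true_ftr", "ftr",
                           "hybrid_pct", "collagen_pct")], 4)
#>                image_id group  true_ftr       ftr hybrid_pct collagen_pct
#> 1 CT_a01_nPCA_PCA-_im01    CT 0.0800000 0.0000000   18.18182     12.21856
#> 2 CT_a01_nPCA_PCA-_im02    CT 0.4736842 0.5000000    0.00000     12.23416
#> 3 CT_a01_nPCA_PCA-_im03    CT 0.4500000 0.5000000    0.00000     12.08767
#> 4 CT_a02_nPCA_PCA-_im01    CT 0.4000000 0.4444444    0.00000     12.29451

run$stats$ftr
#> Linear mixed model for 'ftr' (log scale): value ~ condition + (1 | animal)
#> Satterthwaite df; BH-adjusted q; significance at q < 0.1; boundary fit (animal variance 0)
#>
#>                           contrast estimate    se df        p        q    d
#>  (CT_nPCA_PCA-) - (DC04_nPCA_PCA+)    -2.39 0.266 15 1.97e-07 1.97e-07 4.37
#>  d_category label
#>       large  ****
```

Reading the output: each row of `image_metrics` is one image — the
measured FTR tracks the simulator's recorded truth (`true_ftr`; images
here are small, so per-image values are noisy), and the designed 12%
collagen lattice is recovered within fractions of a percentage point.
The contrast table shows the log-scale group difference (−2.39, i.e. a
ratio of `exp(-2.39) ≈ 0.09`, matching the designed 0.45 vs 4), its
Satterthwaite df, BH-adjusted q, Cohen's d with category, and the
significance label. With only three animals per group this fit sits on
the random-effect boundary and is flagged as such.

`plot(run$stats$ftr)` draws the per-condition boxes with the Q1/Q3 ±
1.5·IQR whisker convention, median line and white mean dot.

See `vignettes/fibremorph-methods.Rmd` for the full account of the
model, parameters and design decisions.

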