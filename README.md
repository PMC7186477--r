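# dcehabitat

Habitat-based texture analysis of dynamic contrast-enhanced (DCE) breast MRI
in R.

## The problem

Breast tumors with an equivocal HER2 immunohistochemistry score ("HER2 2+")
must currently be resolved into amplified / non-amplified status by FISH, an
expensive and slow assay. Tumor heterogeneity visible on DCE-MRI carries
information about the underlying biology, and *habitat imaging* sharpens that
signal: instead of describing the whole lesion at once, the lesion is split
into kinetically coherent subregions and each is described separately.
`dcehabitat` implements the complete analysis pipeline for this question —
and, because clinical DCE-MRI datasets of this kind are not publicly
available, ships a synthetic phantom generator with known ground truth so
every stage is testable end to end.

## The model

For a series with pre-contrast signal `SI(x,y,t0)` and 8 post-contrast phases
`SI(x,y,t)`, `t = 1..8` (80 s apart), the per-pixel kinetic curve is the
relative enhancement in percent

    E(x,y,t) = (SI(x,y,t) - SI(x,y,t0)) / SI(x,y,t0) x 100

and the time-to-peak is its earliest argmax

    TTP(x,y) = argmax_t E(x,y,t).

Lesion pixels are grouped by TTP into **rapid** (phases 1–4), **medium**
(5–6) and **slow** (7–8) habitats. The lesion itself is delineated
semi-automatically on subtraction images (post − pre) at phases 2, 4 and 6
(P-1, P-2, P-3) by spatial fuzzy C-means clustering inside a rectangular ROI
plus morphological refinement.

From the whole lesion and each habitat, a fixed catalogue of **488 texture
features** is extracted: 4 histogram moments, 380 gray-level co-occurrence
statistics (19 Haralick-family statistics × 16 directed offsets × 4
per-distance angular means), 44 gray-level run-length statistics (11 × 4
angles) and 60 wavelet subband scalars (haar, Daubechies-2, Symlet-4 × 4
levels × 5 scalars). Classification is a linear SVM under leave-one-out
cross-validation; in every fold the feature table is pre-filtered (variance
< 0.01, pairwise Pearson |r| > 0.95), z-scored, and reduced by PCA, LASSO, or
bidirectional stepwise logistic selection — all fitted on the training rows
only. Evaluation covers ROC/AUC with DeLong confidence intervals and the
paired DeLong test, Yates-corrected chi-square and exact Fisher tests for
cohort tables, and ICC(2,1) for inter-rater agreement.

## Worked example

```r
library(dcehabitat)

pcfg <- phantom_config(n_cases = 12, image_size = 64, lesion_radius_range = c(9, 13),
                       texture_effect = 1.5, kinetic_effect = 0.2, noise_sd = 2, seed = 42)
cohort <- generate_cohort(pcfg)

cs  <- cohort[[1]]
E   <- relative_enhancement(cs$series)
lab <- partition_subregions(ttp_map(E), cs$truth$lesion_mask)
round(subregion_fractions(lab), 3)
#>  rapid medium   slow
#>  0.601  0.239  0.160

sub <- subtract_phases(cs$series$pre, cs$series$post[[4]])   # P-2 subtraction
fv  <- extract_all(sub, cs$truth$lesion_mask)
round(fv[c("mean", "variance", "ACOR (0,1)", "0°LRE", "haar L_4")], 3)
#>       mean   variance ACOR (0,1)      0°LRE   haar L_4
#>     70.329    544.349    849.757      1.074    413.180

cfg <- pipeline_config(phases = "P-2", regions = c("whole", "rapid"),
                       selector = "lasso", use_truth_mask = TRUE, seed = 42)
res <- run_pipeline(cohort, cfg)
res$report
#>   region phase auc sensitivity specificity accuracy  n
#> 1  whole   P-2   1         100         100      100 12
#> 2  rapid   P-2   1         100         100      100 12

head(feature_importance(res$cv[["rapid|P-2"]]), 3)
#>     feature count
#> 1  variance    12
#> 2 haar HH_3     8
#> 3  CP (2,2)     7
```

This positive case peaks early in 60% of its pixels (the rapid rim), and with
the configured class effect (wider amplitude dispersion plus a rapid-shifted
habitat mix in positives) the 12-case toy cohort separates perfectly under
LOOCV; `feature_importance` counts how often each feature was selected across
the 12 folds. Whole-lesion variance and wavelet detail scalars — the feature
families that directly sense amplitude dispersion — dominate, as they should
for this effect channel.

## Command line

```sh
Rscript inst/cli/dcehabitat simulate --seed 3 --out cohort_dir --n-cases 12
Rscript inst/cli/dcehabitat run-all  --seed 3 --out run_dir --selector lasso
```
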