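# hippotex

Hippocampal MRI texture and latent disease-time modelling across the
Alzheimer's continuum, as a tested R package plus a numbered analysis
workflow — exercised end-to-end on synthetic data (no access-controlled
clinical data is required or shipped).

## What it does, and for whom

Structural MRI volumetry detects Alzheimer's-related atrophy late; spatial
*texture* of the hippocampal signal may change earlier, while pathology is
still modifiable. This package is for biostatisticians and imaging
researchers who want a reproducible, oracle-tested implementation of that
analysis chain:

1. **Texture extraction** — first-order, grey-level co-occurrence (GLCM)
   and grey-level run-length (GLRLM) features from masked 3D ROIs, after
   μ ± 3σ trimming, z-scoring and 32-bin discretisation; 26-direction
   averaging (13 sign-unique directions for runs), hemispheres averaged.
2. **Feature reduction** — outlier-cell and low-variance exclusion, then
   PCA trained on cognitively unimpaired baselines and projected to all
   sessions; components with ≥ 5% variance share become texture scores.
3. **Cross-sectional models** —
   `y ~ group + age_bl + sex + education + ICV + (1 | site)` per texture
   component and volume, with Satterthwaite F tests, pairwise contrasts
   against the healthy group, Cohen's f/d, Holm correction, and a CSF
   amyloid rule (980 pg/mL, 5% borderline exclusion).
4. **Latent disease time** — the core model. Outcomes
   y<sub>ijk</sub> = θ<sub>k</sub>(t<sub>ij</sub> + s<sub>fixed(i)</sub> + s<sub>i</sub>) + x<sub>ik</sub> + e<sub>ijk</sub>,
   with 9-DoF natural-spline means θ<sub>k</sub>, group + baseline-age
   fixed shifts, Gaussian subject shifts s<sub>i</sub>, per-outcome random
   intercepts and residual variances, fitted by an alternating ML scheme;
   disease times are predicted by posterior-mode shifts and Time 0 is
   anchored where median CSF Aβ<sub>1-42</sub> exceeds the healthy bounds.
5. **Trajectories** — spline-over-disease-time mixed models with BIC DoF
   selection (3–6) and REML refit; abnormality curves
   (θ̂(t) − q<sub>0.5</sub>)/(q<sub>0.95</sub> − q<sub>0.5</sub>) relative
   to the healthy group; sensitivity-to-change curves θ̂′(t)/σ̂; and
   dual-timescale (age × disease time) model selection over five forms.
6. **Cognitive prediction** — nested regressions (covariates / + volume /
   + texture) for 24-month cognitive change in non-demented subjects,
   compared via 1000-repetition subject-level bootstrap of adjusted R².

A synthetic-cohort generator (four baseline groups on a known latent
timeline, monotone outcome curves with floors/ceilings, dropout, site
effects) and a 3D texture-phantom generator make every stage testable
against ground truth. See `vignettes/methods.Rmd` for the models,
assumptions and design decisions.

## Worked example

```r
library(hippotex)

# a small synthetic cohort with known latent structure
co  <- generate_cohort(cohort_spec(n_per_group = 100, shift_sd = 3, seed = 42))

# align subjects on the latent disease timeline
fit <- fit_progression(co$data, c("adas13", "cdrsb", "mmse", "centiloid"),
                       max_iter = 150)
fit
#> <progression_fit> 4 outcomes, 400 subjects, shift SD 2.16 y, converged after 119 iterations

# how well are the generating subject shifts recovered?
truth <- co$truth$subjects
j <- match(fit$shifts$subject_id, truth$subject_id)
cor(fit$shifts$shift_total, truth$shift_total[j])
#> [1] 0.954
```

The estimated shift SD (2.16 y) is mildly compressed relative to the
generating 3 y — the documented shrinkage of posterior-mode alignment —
while subject ordering on the timeline is recovered almost exactly
(r = 0.95). Texture from a phantom pair:

```r
left  <- generate_phantom(phantom_spec(shape = c(12, 12, 12), seed = 1), "left")
right <- generate_phantom(phantom_spec(shape = c(12, 12, 12), seed = 2), "right")
fv <- extract_all(left, right)   # trim -> z-score -> 32 bins -> 3 families
round(fv[c("fo_entropy", "glcm_contrast", "glrlm_sre", "volume")], 3)
#>    fo_entropy glcm_contrast     glrlm_sre        volume 
#>         4.285        27.820         0.944       912.000
```

## The analysis workflow

`analysis/01_simulate.R` … `analysis/07_predict_decline.R` run the full
study on a 160-subject synthetic cohort, writing tables under `results/`
(cohort, features, PCA scores, cross-sectional statistics, staged disease
times, trajectory/sensitivity curves, bootstrap model comparisons). Run
them in order from the repository root:

```sh
Rscript analysis/01_simulate.R
...
Rscript analysis/07_predict_decline.R
```

Each driver prints what it found; e.g. the final one reports the adjusted
R² gain of texture over volume for each cognitive score with
Holm-adjusted p-values. `run_pipeline()` executes the same chain in one
call with a manifest (config hash, seeds, row and exclusion counts).

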