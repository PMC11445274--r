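---
title: "Supervoxel-level response assessment in glioblastoma: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervoxel-level response assessment in glioblastoma: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(svxresp)
```

## The problem

After radiochemotherapy, a growing contrast-enhancing lesion in a
glioblastoma patient can be vital, progressing tumor (true progression, TP)
or a treatment-related change that will stabilize or regress
(pseudoprogression, PsP). The two look alike on conventional MRI but demand
opposite clinical responses. Worse, the distinction is usually not
all-or-nothing: a single lesion often contains both kinds of tissue side by
side, so a whole-scan verdict discards exactly the spatial information a
local therapy (resection, targeted re-irradiation) would need.

`svxresp` implements a spatially resolved alternative. The baseline
contrast-enhancing tumor (CET) is partitioned into *supervoxels* — spatially
connected groups of roughly 200 voxels with similar multi-channel intensity —
and each supervoxel is classified as TP or PsP from radiomics features of
three physiologically complementary channels:

* **CBV** — leakage-corrected cerebral blood volume from dynamic
  susceptibility contrast (DSC) perfusion MRI, a proxy for angiogenesis;
* **TBR** — tumor-to-background-normalized amino-acid (FET) PET uptake, a
  proxy for tumor cell metabolism;
* **T1c** — contrast-enhanced T1-weighted MRI, the conventional morphology
  channel.

Ground truth at the voxel level comes from a co-registered follow-up scan:
enhancement that progresses further is TP, enhancement that stays or fades
is PsP. Because the patient data underlying this design are not public, the
package ships a multimodal digital phantom generator that reproduces the
structure of the problem with known ground truth, so every stage is testable
end to end.

## Pipeline stages and their models

### Perfusion: leakage-corrected CBV

DSC signal is converted to a relaxivity change under the standard
single-echo gradient-echo model,
$$\Delta R_2^*(t) = -\tfrac{1}{TE}\,\ln\!\big(S(t)/S_0\big),$$
with $S_0$ the per-voxel mean over the pre-bolus baseline window. Voxels
with non-positive signal are flagged and excluded from fits rather than
raised as errors, because isolated reconstruction artifacts should not abort
a case.

In enhancing tissue the contrast agent extravasates, biasing the plain
integral $\int \Delta R_2^*$. We adopt the Boxerman–Weisskoff linear model,
the canonical correction: each voxel's curve is regressed on the average
nonenhancing-brain curve $\bar{\Delta R_2^*}(t)$ and its running integral,
$$\Delta R_2^*(t) \approx K_1\,\bar{\Delta R_2^*}(t)
  - K_2 \int_0^t \bar{\Delta R_2^*}(\tau)\,d\tau,$$
and the corrected CBV is $\int \Delta R_2^* + K_2 \iint \bar{\Delta
R_2^*}$. The fit is a closed-form two-parameter least squares, vectorized
over voxels; integration is trapezoidal. The reference region is brain
minus CET, necrosis and edema — standard practice when no contralateral
mask is drawn. For leakage-free voxels $K_2 = 0$ and the correction is the
identity, which the tests assert. A `normalize_cbv_to_wm()` variant divides
by the white-matter mean; raw corrected CBV is the default since
normalization conventions vary between sites. Precomputed CBV maps are
accepted as an alternative input, bypassing the module.

### PET: tumor-to-background ratio

FET uptake is divided by the mean uptake over white matter with all lesion
compartments removed: TBR $= u / \bar{u}_{WM \setminus lesion}$. The mean
(not median) over whole-brain lesion-free WM is the convention in FET
quantification; a contralateral-only region can be supplied explicitly via
the reference mask argument. A floor of 100 reference voxels guards against
degenerate tissue maps. TBR is scale-invariant by construction, which the
tests verify.

### Voxel labeling from follow-up

The study design this package follows labeled voxels manually; automation
needs an explicit, reproducible rule. Both T1c volumes are first
z-normalized to the mean/SD of the nonenhancing brain (making the two
acquisitions comparable without assuming a common intensity scale), then a
CET voxel is TP when its relative enhancement change
$(FU - BL)/BL$ exceeds a threshold, default **0.10**, else PsP. The
threshold is deliberately modest: it should flag genuine growth while
tolerating scan-to-scan noise. On the default phantom the rule recovers the
planted truth on ≥ 95 % of CET voxels (asserted in the tests), which is the
sense in which the surrogate is validated. Voxels with non-positive
baseline intensity (the ratio is undefined there) are filled by the
majority label of their 26-neighbourhood. New enhancement outside the
baseline CET is ignored: labels live on the baseline CET, where features
are extracted. Clinically "stable" and "decreasing" enhancement are
distinct readings; both are pooled into PsP here because the classifier's
target is binary.

### Supervoxels: masked 3D SLIC

SLIC is local k-means over a combined distance
$$D = \sqrt{d_{int}^2 + (d_{spatial}/S)^2\, m^2},$$
where $d_{int}$ is the Euclidean distance over the three channels
(z-scored over the CET per case — CBV, TBR and T1c live on incommensurate
scales), $d_{spatial}$ is physical distance in mm (anisotropic spacing
honoured), $S$ the seed interval and $m$ the compactness. We default
$m = 0.1$ after standardization, favouring intensity homogeneity: the point
of supervoxels here is semantically coherent regions, not a regular tiling.

Three implementation choices matter on masked, often hollow, enhancing
rims:

* the volume-derived regular seed grid under-fills thin or hollow masks, so
  missing seeds are topped up by deterministic farthest-point sampling;
* clusters that empty during iterations are reseeded at the voxel farthest
  from the occupied centroids (standard k-means repair), keeping the
  supervoxel count near $|CET| / \text{target size}$;
* after convergence, 26-connectivity is enforced: orphan fragments merge
  into the adjacent supervoxel with the nearest centroid, and ids are
  canonicalized by ascending centroid order so identical inputs give an
  identical id volume.

The target size of 200 voxels balances statistical stability of the
features against spatial granularity. Masks smaller than one target size
become a single supervoxel with a warning. Each supervoxel inherits the
label of the majority of its voxels; exact ties go to TP, a deliberate,
configurable bias toward not missing progression.

### Radiomics: 18 first-order + 24 GLCM features per channel

Per supervoxel and channel we compute the standard IBSI-style roster: 18
first-order statistics (energy, total energy, entropy, minimum, 10th
percentile, 90th percentile, maximum, mean, median, interquartile range,
range, mean absolute deviation, robust MAD, RMS, skewness, kurtosis,
variance, uniformity) and 24 gray-level co-occurrence matrix features
(autocorrelation, joint average, cluster prominence/shade/tendency,
contrast, correlation, difference average/entropy/variance, joint
energy/entropy, IMC1, IMC2, inverse difference (+ normalized), inverse
difference moment (+ normalized), inverse variance, maximum probability,
sum average, sum entropy, sum of squares, MCC) — 42 per channel, 126 per
supervoxel, with the stable naming scheme `<channel>__<family>__<feature>`.

Conventions, fixed and documented because each has alternatives:

* percentiles use linear interpolation (type 7, matching the common
  scientific-Python default); moments use the population convention and
  kurtosis is not excess-corrected (a Gaussian scores 3);
* discretization is a fixed bin count of **32** per supervoxel per channel —
  supervoxels are small and each channel spans its own range, so fixed bin
  widths would leave many regions with a handful of levels;
* GLCMs use distance 1, the 13 unique 3D directions, symmetric
  accumulation, per-direction normalization to sum 1, and per-direction
  feature averaging; co-occurrences are only counted between voxel pairs
  both inside the supervoxel;
* T1c features are computed on the case-level z-scored volume (T1w
  intensities are arbitrary units; TBR and CBV are already ratio scales and
  enter raw);
* supervoxels with a single gray level on any channel have no texture and
  are excluded from the table with a logged reason rather than imputed.

The whole feature stack is validated against an independent brute-force
oracle (all-ordered-pairs co-occurrence counting, textbook formulas) to
1e-9 on random patches.

### Classifier and evaluation

The classifier is a random forest of 100 CART trees grown with an entropy
(information-gain) split criterion. No installed R forest offers entropy
splits, so the ensemble is built in-package from `rpart` trees: each tree
sees a bootstrap resample of the supervoxels and a random
$\lfloor\sqrt{p}\rfloor$-feature subset (per tree rather than per node —
the random-subspace variant of the canonical algorithm, which is what the
tree library's interface permits; with 126 heavily redundant features the
decorrelation effect is comparable). Class probability is the fraction of
trees voting TP; impurity importances are accumulated over trees and
normalized to sum 1. Single-class bootstrap resamples (possible in small
folds) degenerate to constant-vote trees rather than errors.

Validation is **patient-grouped tenfold cross-validation**: all supervoxels
of a patient — including repeat inclusions — share one fold, so no
supervoxel is ever scored by a model that saw its patient. Folds are
balanced by greedy largest-first assignment of patients by supervoxel
count, with seeded tie-breaking. The no-leakage property is asserted
programmatically on every run. Out-of-fold probabilities are pooled and
binarized at the pre-defined cutoff 0.5; we report accuracy, balanced
accuracy, sensitivity, specificity, per-class precision/recall/F1, and the
macro AUC, read as the unweighted mean of per-class one-vs-rest AUCs (for
a binary problem with complementary scores the two are identical; both are
computed). Group contrasts use the Mann-Whitney U test (midranks,
tie-corrected normal approximation — the `wilcox.test` machinery behind a
typed result), with significance stars at 0.05/0.01/0.001.

## The phantom generator

`generate_cohort()` emulates the study's per-case bundle on a common voxel
grid (default 64³ at 2 mm isotropic): a brain sphere with a GM shell, a CSF
pocket and WM interior; an off-centre tumor with necrotic core, enhancing
rim (the CET) and edema shell; and three channels built as *crisp
per-tissue mean map + spatially correlated within-class heterogeneity +
independent scan noise* (optionally Rician). The TP/PsP geography is
planted by thresholding a smoothed Gaussian random field inside the CET at
the quantile matching the target TP fraction — producing contiguous blobs
and mixed-response lesions rather than salt-and-pepper labels. The
follow-up T1c is clean anatomy × response factor + *fresh* noise of the
baseline magnitude: TP regions brighten by 30 % and grow outward by 2 mm,
PsP regions fade by 20 %. Growth is applied outside the baseline CET
(progression visibly expands beyond the current enhancement); inside the
CET the planted classes stay crisp so the voxel-labeling task has an
unambiguous answer.

Default class-conditional means are chosen to reproduce the *direction* of
the clinically reported contrasts at realistic magnitudes, not any absolute
values (which are not published at voxel level): TBR 2.6 (TP) vs 1.9 (PsP)
— bracketing the common FET positivity cutoffs; relative CBV 2.1 vs 1.3 —
hyper- vs near-normo-perfusion; z-scored T1c 3.4 vs 3.0 — deliberately
weak, as morphology alone discriminates poorly. Within-class SDs (0.35 /
0.45 / 0.7) and channel noise (0.15 / 0.2 / 0.2) put per-voxel class
overlap in a regime where single voxels are ambiguous but 200-voxel
supervoxels are mostly separable, which is the premise of the method. The
default cohort has 30 patients of which 3 are included twice (repeat
inclusion exercises grouped CV), TP fraction 0.5, heterogeneity correlation
length 3 mm, label-field scale 8 mm.

What the phantom does **not** emulate: MR physics (no k-space, bias
fields, partial voluming), anatomical variability, registration error,
segmentation error, or scanner effects. Passing tests therefore demonstrate
the correctness and internal consistency of the pipeline under known
ground truth — not clinical performance. Numbers obtained on the phantom
(macro AUC ≈ 0.98 at the default effect sizes) are a well-posedness check,
deliberately above the clinically reported regime, because the phantom
lacks exactly the nuisance factors that make real data hard.

## Problem sizes used in validation

The shipped tests and the acceptance script use scaled-down but fully
representative problem sizes, chosen so a complete run stays comfortable on
a single CPU: the study-analogue cohort is 30 patients (33 cases, ≈ 3300
CET voxels and ≈ 16 supervoxels per case, ≈ 530 supervoxels in total);
oracle suites use 100 random 5³ patches (radiomics) and 100 simulated
voxel curves (perfusion); the partition/majority oracle runs on 50 small
phantom cases; the permutation null uses label shuffles within patients
over several seeds.

## Known limitations

* The voxel-labeling rule is a surrogate for expert reading; its 0.10
  threshold is validated against phantom truth, not against raters.
* Supervoxels are classified independently; neighbourhood context (Markov
  random fields, graph models) is out of scope.
* Per-tree (not per-node) feature subsampling is a variant of the textbook
  forest; with strongly redundant radiomics features the practical
  difference is small, but it is a difference.
* The phantom's spherical geometry and crisp class map are idealizations;
  none of the reported phantom metrics transfer to patients.
* Dynamic PET information (time-to-peak, slope) is not modelled.
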