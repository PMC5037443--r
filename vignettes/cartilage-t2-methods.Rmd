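---
title: "Layer-specific cartilage T2 analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-specific cartilage T2 analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartT2)
```

## The problem

Cartilage spin-spin relaxation time (T2) reflects the composition of the
extracellular matrix — hydration, collagen content and fiber orientation —
and is therefore studied as an imaging biomarker of early osteoarthritis,
before radiographic joint-space narrowing appears. Because T2 varies
strongly with tissue depth (collagen fibers are parallel to the surface
superficially and perpendicular near the bone), modern analyses split the
cartilage into a superficial and a deep layer and analyze them separately.

`cartT2` implements that full analysis chain for multi-echo spin-echo
(MESE) knee MRI: voxelwise T2 fitting, depth-based layer partition,
plate-level aggregation over the four femorotibial cartilage plates
(medial/lateral tibia MT/LT, weight-bearing medial/lateral femoral condyle
cMF/cLF), and the group statistics used to compare cohorts with and
without osteoarthritis risk factors. Real MESE cohort images (e.g. the
Osteoarthritis Initiative, OAI) are access-controlled, so the package also
ships synthetic generators — a digital phantom with exact voxelwise ground
truth and a subject-cohort simulator parameterized by published group
summary statistics — that make every stage testable end to end.

## Signal model and T2 fitting

A MESE acquisition samples the transverse-decay curve at echo times
$TE_1 < \dots < TE_k$; the package default is the standard 3T knee
protocol, $TE = 10, 20, \dots, 70$ ms with TR 2700 ms, in-plane resolution
0.3125 mm and slice thickness 3.0 mm. Each voxel is modeled as

$$S(TE) = S_0 \, e^{-TE/T_2},$$

fitted by nonlinear least squares (Levenberg–Marquardt with analytic
Jacobian, via `minpack.lm`), initialized from the ordinary-least-squares
line fit of $\log S$ versus $TE$ over the positive intensities. Two
protocol details matter:

* **First-echo exclusion** (`exclude_first = TRUE`). The first echo of a
  MESE train is contaminated by stimulated echoes; fitting echoes 2–$k$
  removes that bias. The phantom generator exposes this with
  `first_echo_bias_frac`, a multiplicative inflation of echo 1 only: with
  the first echo excluded the fit is provably invariant to any value of
  echo 1, and with it included the fitted T2 is visibly biased. The
  contamination model is deliberately minimal — enough to demonstrate
  that exclusion removes the bias, with no claim to model the physics of
  stimulated-echo pathways.
* **Goodness-of-fit elimination** (`r2_threshold = 0.66`). Voxels whose
  fit $R^2$ (computed over the echoes actually used, with the total sum
  of squares about their mean) falls *strictly below* 0.66 are eliminated
  as low-image-quality voxels. A voxel exactly at the threshold is kept.
  $R^2$ of a constant echo train is undefined and reported as `NA`.

Fit parameters are bounded ($T_2 \in [1, 1000]$ ms, $S_0 \in
[0, 10\,\max S]$); a solution on a bound is flagged non-converged rather
than silently accepted, and invalid voxels carry `NA`, never zero. Voxels
are fitted independently — no spatial regularization — so results cannot
depend on traversal order.

## Depth normalization and the layer split

For each plate, every voxel receives a normalized depth

$$d = \frac{d_{\mathrm{bone}}}{d_{\mathrm{bone}} + d_{\mathrm{surface}}},$$

where $d_{\mathrm{bone}}$ and $d_{\mathrm{surface}}$ are Euclidean
distances to the nearest labeled bone-interface and articular-surface
voxel. The default computes both distance transforms per sagittal slice
(exact 2D Euclidean distance transform via `EBImage::distmap`, verified in
the test suite against an all-pairs brute-force oracle to $10^{-9}$):
slice thickness is roughly ten times the in-plane resolution, so in-plane
distances dominate, and the within-slice ratio is invariant to pixel size.
A 3D variant that measures distances in millimetres with anisotropic
spacing is available via `method = "3d"`.

Voxels are labeled **superficial** when $d > 0.5$ and **deep** otherwise.
The tie at $d = 0.5$ goes to the deep layer — a documented convention that
only matters at discretization boundaries. Single-voxel-thick columns
(bone interface and surface coincide) get $d = 0.5$, hence deep, and are
counted in a message.

The femoral plates are restricted to a weight-bearing region of interest
before aggregation: per sagittal slice, the contiguous anteroposterior
span starting at the trochlear-notch landmark and covering a configurable
fraction (default 0.6) of the condyle's anteroposterior extent. The exact
extent of the weight-bearing region is a convention that differs between
laboratories, so the fraction is an explicit, provenance-tracked
parameter rather than a hard-coded rule; the ROI is monotone in the
fraction (nesting is property-tested).

Plate summaries are means of valid voxels per plate × layer; the
knee-level value is the unweighted mean of the four plate means (a
voxel-count-weighted variant is available behind `weights = "voxel"`).
An empty valid set produces an undefined (`NA`) mean — a data state, not
an error — which propagates through aggregation and is reported as such.

## The phantom generator

Phantoms are deliberately *not* anatomically realistic knees: the pipeline
is geometry-agnostic, and simple geometries have exact ground truth.
Tibial plates are flat slabs (bone at the bottom row); femoral plates are
downward-facing half-annular shells (bone at the inner radius). Each plate
carries a through-thickness T2 profile — a two-compartment step (deep
value below mid-depth, superficial above) or a linear gradient — with
default levels 35.8/45.4 ms, typical deep/superficial values for healthy
femorotibial cartilage. Ground truth per voxel comprises the exact
analytic depth (row-based for slabs, radial for shells), the layer label
(superficial iff depth > 0.5), and the true T2.

Default geometry choices, made once for testability:

* **Thickness 16 voxels** per plate. On curved shells the EDT-based depth
  disagrees with the analytic radial depth only in a roughly half-voxel
  band around the mid-depth contour; at 16 voxels that band captures about
  1% of shell voxels (the suite measures ≈99.4% label agreement over the
  default mixed-geometry phantom). Thinner plates inflate this purely
  discrete disagreement without testing anything new.
* **Gaussian noise by default**, because at the signal-to-noise ratio of
  cartilage MESE the Gaussian approximation is adequate and keeps the
  least-squares fit unbiased to first order; a Rician option (magnitude of
  a complex signal with Gaussian noise in both channels) is available
  since magnitude MRI noise is Rician. The true noise level of clinical
  MESE acquisitions is not publicly documented; the defaults here are
  chosen for testability, not fidelity.
* Noiseless background would make "empty" voxels trivially rejectable, so
  with `noise_sd > 0` the background is pure noise — which is also what
  the $R^2$ filter tests use.

What passing phantom tests does **not** show: performance under
anatomically curved, thin (2–8 voxel) cartilage with partial-volume
effects, B1 inhomogeneity, motion, or segmentation error. The phantom
validates the computational chain, not the acquisition physics.

### A numerical note on mean T2 recovery

The nonlinear least-squares T2 estimator is consistent but, like any
maximum-likelihood estimator of a curved model, carries a second-order
positive skew bias at finite signal-to-noise. At noise SD equal to 2% of
$S_0$ with echoes 20–70 ms, the *mean* fitted T2 across many voxels sits
about 0.45–0.5% above the truth (the median is essentially unbiased,
which is what the suite's consistency test checks). Plate-mean recovery
at that noise level is therefore accurate to about half a percent; the
residual is estimator skew, not an implementation artifact, and shrinks
quadratically with noise.

## The cohort generator

The subject-level simulator draws three groups mirroring a published
OAI-based early-osteoarthritis cohort: `riskROA` (n = 28; risk factors,
no radiographic OA), `earlyROA` (n = 32; a definite osteophyte, no joint
space narrowing) and `healthy` (n = 89; the OAI non-exposed reference
cohort). Group sizes, age, BMI and sex composition, per-layer baseline T2
(mean ± SD) and one-year change distributions are the published summary
statistics shipped in `oai_t2_reference()` / `oai_demographics()`; these
defaults *are* the study conditions and are not tuning knobs. Follow-up
rows exist for the first `n_followup` subjects per group (26/24/89), so
longitudinal analyses automatically operate on the baseline subset with
both visits.

Change scores are drawn independently of baseline by default (published
tables report change mean/SD only); an optional `baseline_change_cor`
induces correlation. Covariate effects enter linearly:
$t_2 \mathrel{+}= \beta_{\mathrm{age}}(\mathrm{age}-55) +
\beta_{\mathrm{sex}}\mathbb{1}[\mathrm{female}] +
\beta_{\mathrm{bmi}}(\mathrm{BMI}-25)$, all zero by default. Centering at
a fixed reference (55 y, 25 kg/m²) keeps simulated T2 in a realistic range
and makes the group-mean parameters the "covariates held fixed" group
effects.

All generators take explicit seeds and restore the global RNG state;
identical spec + seed gives bit-identical output.

## Statistical plan

The statistics module mirrors the analysis plan of laminar T2 cohort
studies:

* **Crude comparisons**: unpaired two-sided t-tests. The *pooled-variance*
  Student form is the default because the printed confidence intervals of
  the reference study's contrasts are reproduced exactly by the pooled
  form (the Welch form gives visibly different bounds, e.g. a lower bound
  near −4.0 instead of −3.8 for the superficial healthy-vs-risk contrast
  computed from the printed summaries); Welch is available behind
  `welch = TRUE`.
* **`comparison_from_summary()`** computes the identical inference from
  printed mean/SD/n cells, which is exactly determined for the pooled t —
  this is how the package reproduces published contrasts without subject
  data.
* **Cohen's d** uses the pooled SD without Hedges' small-sample
  correction; the reference study's printed effect sizes (1.04, 0.81,
  0.96, 0.73) are consistent with this form within the rounding of its
  printed inputs.
* **ANCOVA**: ordinary least squares `t2 ~ group + age + sex + bmi` with
  sex as a 0/1 indicator and no interactions; the adjusted difference is
  the group coefficient. Rank-deficient designs are an error naming the
  collinear columns.
* **Multiplicity**: the primary baseline family is 6 comparisons
  (3 group pairs × 2 layers), so significance is flagged at
  $p < 0.05/6 = 0.00833$, strictly. Plate-level analyses are exploratory
  and carry no further adjustment.
* **Longitudinal change**: paired two-sided t-tests of within-subject
  year-1 minus baseline, per group and layer, plus the within-subject
  superficial-minus-deep change contrast.

Reproduction checks against printed values use ±0.1 ms on differences and
CI bounds and ±0.05 on Cohen's d, because the printed inputs are rounded
to one decimal.

### Calibration experiments and their sizes

The suite verifies (sizes chosen to make Monte-Carlo error small relative
to the tolerance being checked):

* Type-I error of the pooled t at group sizes 28/89 over 2,000 null
  simulations (expected 0.05 ± 0.015), with the CI/test duality
  ($p < 0.05 \Leftrightarrow$ 95% CI excludes 0) holding in every
  simulation.
* ANCOVA = crude under zero covariate effects, over 200 seeds.
* Confounding removal: an injected age effect of 0.4 ms/year combined
  with the cohort's ~6-year age imbalance biases the crude contrast by
  ≈2.4 ms; adjustment must land closer to the true group effect in ≥95%
  of 200 seeds. The injection is deliberately strong — about 4.4× the
  adjusted estimator's sampling SD at these group sizes — so the per-seed
  comparison measures bias removal rather than sampling noise. (With a
  weak injection, e.g. 0.2 ms/year, crude and adjusted estimates are
  close enough that the comparison approaches a coin flip even though
  adjustment is working.)
* Unbiasedness of group-difference estimates at the study's group sizes
  over 500 seeds.
* Layer-contrast power against the closed-form one-sample t power
  (`power.t.test`) over 500 seeds.

## Known limitations

* Segmentation is an input; the package neither segments cartilage nor
  models segmentation error.
* The weight-bearing ROI fraction (0.6) is a configurable placeholder for
  a landmark-based convention, not an assertion of any laboratory's exact
  rule.
* The within-slice (2D) depth default assumes sagittal acquisitions with
  coarse slice spacing; for near-isotropic data use `method = "3d"`.
* The cohort simulator draws independent subjects; it does not model
  contralateral-knee correlation (the reference design compared right
  knees across persons for the same reason) or measurement error shared
  across visits beyond what the change-score SD encodes.
* Whether the "top/bottom 50%" split should threshold depth or equalize
  voxel counts per column is ambiguous in the field; the depth threshold
  is implemented, with the tie convention documented above.
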