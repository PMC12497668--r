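---
title: "Methods: simulating and stress-testing ROI configurations for ALPS indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and stress-testing ROI configurations for ALPS indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpsroi)
```

## The ALPS method and what this package models

Diffusion along the perivascular space (ALPS) is an indirect, noninvasive
probe of periventricular interstitial-fluid dynamics. At the level of the
lateral-ventricle bodies, three tissue systems meet with mutually
orthogonal principal directions: the projection fibers of the superior
corona radiata run head--foot (z), the association fibers of the superior
longitudinal fasciculus run anterior--posterior (y), and the
periventricular medullary veins -- with their surrounding perivascular
spaces -- run left--right (x), perpendicular to both fiber systems. Because
neither fiber system is oriented along x, the left--right diffusivity in
these two areas is dominated by the small perivascular fluid component,
and the ratio

$$\mathrm{ALPS} = \frac{\mathrm{mean}(D_{x,\mathrm{proj}},\, D_{x,\mathrm{assoc}})}
                      {\mathrm{mean}(D_{y,\mathrm{proj}},\, D_{z,\mathrm{assoc}})}$$

rises above 1 exactly insofar as that component is present. `alpsroi`
computes the ratio two ways, mirroring clinical practice: **DTI-ALPS**
takes $D_x, D_y, D_z$ from the diagonal of a tensor fitted to a
64-direction acquisition; **DWI-ALPS** reads them directly from a
three-orthogonal-direction acquisition. We evaluate the expanded form
$(D_{x,p} + D_{x,a}) / (D_{y,p} + D_{z,a})$, algebraically identical to
the ratio of two-argument means but without intermediate rounding.

The scientific question the package addresses is not the index value of
any cohort -- that is data-dependent -- but the *reliability structure* of
the measurement: how the choice among eleven ROI configurations (single
voxel; lines of 2--4 voxels parallel or orthogonal to the ventricle;
3x2 / 2x3 six-voxel grids; 2x2 and 3x3 squares) affects interhemispheric
consistency, inter-method agreement, and inter-configuration
correlation. Because no human data are deposited for this design, the
package ships a synthetic cohort generator with a known ground truth, so
every step of the analysis chain is testable against an oracle.

## The phantom

`phantom_spec()` defines a voxel grid (default 40 x 40 x 24 at 2 mm
isotropic, matching the emulated acquisitions) in RAS orientation with
axial slices at constant z. Indices are 1-based throughout -- the
R/RNifti convention; every geometric statement in the documentation and
tests uses this convention consistently.

Axis-aligned boxes define, per hemisphere: the lateral ventricle
(isotropic CSF, 3.0e-3 mm^2/s), the projection area (principal
eigenvalue 1.4e-3 along z, transverse 0.4e-3), the association area
(principal along y), a subcortical band (principal along x), and
isotropic background (0.8e-3). These diffusivities are *configuration,
not truth*: the source study reports no subject-level diffusivities, so
textbook-plausible white-matter values are used and every downstream
result is reported relative to the configurable ground truth. All
diffusivities are capped at the free-water ceiling 3.5e-3 mm^2/s.

Two additive left--right components encode the perivascular physiology:

* `perivascular_delta` (default 0.3e-3 mm^2/s) is added to $D_{xx}$ in
  the projection and association areas -- the quantity the ALPS index
  targets. The population ground-truth index has the closed form
  $1 + \delta/D_\perp$ (`alps_ground_truth()`), strictly increasing in
  the delta; this monotonicity is verified through the full
  simulate-fit-extract chain.
* `periventricular_delta` (default 1.2e-3) is added to $D_{xx}$ in the
  one-voxel margin hugging the ventricle, where paravenous flow is
  strongest. This band is what makes the placement rules *matter*: an
  ROI pushed against the ventricle picks up the band's strong x
  component and inflates the index. It also resolves a subtlety: adding
  purely isotropic CSF to a projection ROI raises the denominator
  ($D_y$: 0.4 to 3.0, a 7.5-fold step) proportionally more than the
  numerator ($D_x$: 0.7 to 3.0) and therefore *lowers* a
  supra-unity index -- isotropic partial volume alone cannot reproduce
  the inflation that motivates the one-voxel rule. The anisotropic
  periventricular band can, and in this package it is the modeled
  mechanism, together with subcortical (x-oriented) contamination of
  the association ROI.

Between-subject variability uses two independent log-normal scalars per
subject (both with coefficient of variation `subject_cv`, default 0.05):
one multiplies every diffusivity, one multiplies the perivascular
deltas. A single global scalar would be invisible to the index -- the
ALPS ratio is scale-invariant -- and would leave the inter-method ICC
degenerate: all between-subject variance in the *index* would be noise.
The delta scalar moves the true index (subject-to-subject SD about
0.0375 at the defaults), which is what makes agreement statistics
non-trivial. Both scalars are drawn deterministically from
`(seed, subject_index)`, so subject $k$'s data never depend on the
cohort size.

Signals follow the monoexponential tensor model
$S = S_0 \exp(-b\, g^\top D g)$ at $b \in \{0, 1000\}$ s/mm^2, with
Rician noise $\sqrt{(S+n_1)^2 + n_2^2}$,
$n_1, n_2 \sim N(0, (\sigma S_0)^2)$ -- the standard magnitude-MRI model
(default $\sigma = 0.02$, i.e. SNR 50 at $b=0$). The 64-direction set is
a deterministic golden-angle (Fibonacci) hemisphere spiral: closed-form,
well spread, and rank-6 for the tensor design; the DWI arm uses exactly
the three scanner axes. What the generator does **not** emulate: EPI
distortion, motion, eddy currents, multi-compartment or free-water
signal, head tilt (DWI axes are taken as exactly the scanner axes), or
vein anatomy beyond the band. Passing tests therefore demonstrate
correctness of the *analysis chain* under the stated model, not
robustness to real-world acquisition artifacts.

## Fitting

The reference tensor fit is ordinary log-linear least squares: per voxel,
$\ln(S_i/S_0) = -b_i g_i^\top D g_i$ solved by QR for the six unique
elements, with $S_0$ the mean of the $b=0$ volumes. This deterministic,
oracle-friendly estimator inverts noise-free simulation to machine
precision (the round-trip tolerance asserted in tests is 1e-8; observed
error is ~1e-16). Numerical guards: signals at or below zero are clamped
to $10^{-6} S_0$ before the log; voxels with $S_0 \le 0$ get a zero
tensor and a flag; rank-deficient direction schemes are rejected.
Directional ADCs use the same inversion per axis,
$d = -\ln(S/S_0)/b$, with negative estimates floored at zero and
counted (the count is surfaced so excessive noise is visible). No
spatial interpolation is used anywhere in the package. FA and the
color-coded maps (RGB = |principal direction| x FA for DTI, normalized
dx/dy/dz channels for DWI) are provided for ROI guidance; eigenvalues
are clipped at zero before the FA formula.

## ROI engine

The eleven configurations live in `roi_catalog()` with stable order and
in-plane `(row-along-y, col-along-x)` offsets. "Parallel" means extended
along y -- at the evaluation slice the ventricle wall runs approximately
anterior--posterior -- and "orthogonal" along x; the six-voxel grids are
3 (y) x 2 (x) parallel and 2 (y) x 3 (x) orthogonal, following the
visual geometry of the configurations.

The "at least one voxel away" rule is formalized as an in-plane
Chebyshev distance of at least 2 voxels (one empty voxel, diagonals
included) between the ROI and the forbidden regions: ventricle and
association area for projection ROIs; projection and subcortical for
association ROIs. This is the strictest reading -- it forbids corner
adjacency, which a city-block reading would allow.

`auto_place()` is the deterministic surrogate for the human rater: on
the single evaluation slice (the slice with the largest ventricle
cross-section; the rater's actual slice-selection rule is unknowable, so
this rule is declared, not inferred), it returns the valid placement
whose centroid is nearest the target-area centroid, ties broken by the
lexicographically smallest anchor *in a frame mirrored across the
midline for the left hemisphere*. The mirroring matters: without it, the
tie-break would asymmetrically favor one direction and the two
hemispheres would not be mirror images on a symmetric phantom.
Internally the search uses summed-area tables (O(1) per anchor);
`validate_placement()` remains the reference checker and a property test
asserts that every auto-placement validates. Configurations that cannot
be placed (e.g. 3x3 squares in a deliberately narrowed projection area)
raise a typed error naming the failed constraints; the pipeline drops
them and records the reason rather than force-placing them.

## Statistics

All five procedures are implemented from their definitions and
cross-checked in the test suite against independent routes
(`stats::wilcox.test`, `nortest::lillie.test`, `aov()` mean squares,
brute-force enumeration):

* **Lilliefors**: KS statistic against a normal with estimated moments;
  Monte Carlo p-value `(1 + #{D* >= D})/(R + 1)` from a seeded null
  (default 10^4 replicates), deterministic given the seed.
* **Wilcoxon signed-rank**: zeros dropped, midranks for ties; exact
  two-sided p for up to 25 nonzero differences via subset-sum
  convolution over doubled ranks (identical to full 2^m enumeration,
  which the tests verify for m <= 12); tie-corrected normal
  approximation with continuity correction above that.
  `p = min(1, 2 min(P(W<=w), P(W>=w)))`.
* **ICC(2,1)**: absolute agreement from the two-way ANOVA mean squares;
  F test `MSR/MSE` on `(n-1, (n-1)(k-1))` df; primary CI is the F-based
  McGraw--Wong interval (bounded above by 1); a Wald interval from the
  large-sample intraclass-correlation variance is reported alongside
  and may exceed 1 -- the same behavior seen in published agreement
  tables whose upper bounds exceed 1. Consistency-type ICC is available
  behind a flag. Zero-variance inputs are flagged `degenerate` and
  return `NA` rather than a spurious 1. Categories use the conventional
  0.5 / 0.75 / 0.9 cuts.
* **Bland--Altman**: bias = mean difference, limits of agreement
  bias +/- 1.96 SD with the n-1 sample SD.
* **Sample size**: the normal-approximation paired-z formula
  $n = ((z_{1-\alpha/2} + z_{\mathrm{power}})/\mathrm{effect})^2$, which
  gives 11.67 at effect 0.82, alpha 0.05, power 0.80; a 10% inflation
  for non-normality then rounds up to 13. The effect value 0.82 is
  treated as a standardized paired effect; with that reading the
  formula reproduces the published intermediate value to within 0.02
  participants.

One estimator property worth knowing: with k = 2 raters the ICC(2,1)
estimate is biased upward by a few hundredths when the rater variance is
large, because MSC has a single degree of freedom and its chi-square
fluctuation sits in the denominator; the bias does not vanish with n.
The parameter-recovery check therefore uses components on the scale of
the actual inter-method comparison -- subject SD 0.04, method-offset SD
0.005, error SD 0.03 on the index scale, n = 60 -- where the method
offset is small (as it is between DTI- and DWI-ALPS, whose bias is near
zero) and the estimator recovers the analytic ratio to well within 0.02.

## Pipeline and reporting

`run_study()` chains everything: cohort simulation (default 13
subjects), both fits, placement, indices for every (subject, hemisphere,
method, configuration), then interhemispheric Wilcoxon per configuration
and method, inter-method Wilcoxon on hemisphere-averaged indices,
inter-method ICC per configuration (computed on the unaveraged
subject-by-hemisphere values), the 55-pair inter-configuration ICC
matrix per method with category counts and percentages, pairwise
inter-configuration Wilcoxon comparisons per hemisphere and method --
from which the "stable" configuration subset (no significant
interhemispheric or inter-method differences at alpha = 0.05) is
recomputed, never hard-coded -- and pooled Bland--Altman agreement.
Per-hemisphere reporting is the default; averaging is an explicit,
flagged derivation, because lateralized disease makes the average lossy.
The master seed fans out via a documented linear-congruential splitter,
so reruns are byte-identical down to the rendered CSVs. Everything
tabular is a tibble; `tidy()`/`glance()` and `autoplot()` methods cover
the fitted objects, and `render_report()` writes CSV/JSON plus the three
standard figures (box plot; ICC profile with 0.75 solid and 0.5 red
dashed reference lines; Bland--Altman scatter with bias and LOA lines).

## Problem sizes and numerical choices in the test suite

Unit and property tests run on a 40 x 20 x 8 phantom (6400 voxels) --
large enough to host every configuration with the full adjacency rules,
small enough that the whole suite completes in well under a minute. The
calibration checks use 10^4 null cohorts of n = 13 for the signed-rank
size (against the 99% binomial band around 0.05), 10^3 seeded replicates
for ICC recovery, 10^5 differences for LOA coverage, and a
down-scaled Lilliefors null calibration (200 repetitions of n = 100 with
10^3 Monte Carlo replicates each); these sizes are the package's chosen
balance between statistical resolution and a fast default test run.

## Limitations

The phantom's regions are axis-aligned boxes with tensors diagonal in
the scanner frame; real periventricular anatomy is curved, tilted and
heterogeneous, and real DWI-ALPS depends on slice planning that this
model idealizes away. Human-cohort values (means near 1.43/1.40, ICC
0.83, LOA -0.36 to 0.43) are not reproduction targets: they depend on
undisclosed data, and this package reproduces the *structure* of those
analyses, not their values. Circular or spherical ROIs, atlas
registration, and automated anatomical ROI tools are out of scope.
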