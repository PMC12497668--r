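# alpsroi

Reliability analysis of region-of-interest (ROI) configurations for
diffusion-MRI **ALPS** indices, with a fully synthetic, ground-truth
phantom so that every step of the analysis chain is testable.

## The problem

The ALPS (diffusion **a**long the **p**erivascular **s**pace) index is a
noninvasive proxy for periventricular interstitial-fluid dynamics, often
discussed in the context of the glymphatic system. At the level of the
lateral-ventricle bodies, projection fibers (superior corona radiata) run
head–foot (z), association fibers (superior longitudinal fasciculus) run
anterior–posterior (y), and the periventricular veins — with their
perivascular spaces — run left–right (x), perpendicular to both. The index

```
ALPS = mean(Dx_proj, Dx_assoc) / mean(Dy_proj, Dz_assoc)
```

isolates the small left–right diffusion component that neither fiber
system explains. It can be computed from the diagonal of a fitted
diffusion tensor (**DTI-ALPS**, 64 directions) or directly from a
three-orthogonal-direction acquisition (**DWI-ALPS**). Its Achilles' heel
is the ROI definition: the two small ROIs must be placed at least one
voxel away from the ventricle, from each other, and from subcortical
fibers, and published studies disagree on ROI shape, size and
orientation.

`alpsroi` implements the complete ROI-reliability study design for this
problem, aimed at methods researchers in diffusion MRI:

* a **synthetic phantom** (`phantom_spec()`, `build_phantom()`,
  `simulate_cohort()`): a periventricular tensor field with a tunable
  ground-truth perivascular component, per-subject variability and Rician
  noise, simulated at b = 0/1000 s/mm², 2 mm isotropic voxels, for both a
  64-direction and a 3-direction acquisition;
* **fitting** (`fit_tensor_loglinear()`, `directional_adc()`,
  `compute_fa()`): log-linear tensor fit, directional ADCs, FA/RGB maps;
* an **ROI engine** (`roi_catalog()`, `auto_place()`,
  `validate_placement()`, `extract_mean()`): the eleven configurations
  (v1; v2o–v6o orthogonal; v2p–v6p parallel; v4s, v9s squares; volumes
  8–72 mm³ at 2 mm voxels) with the one-voxel-away adjacency rules and a
  deterministic, mirror-symmetric auto-placement surrogate for the human
  rater;
* **ALPS computation** (`alps_index()`, `subject_alps()`,
  `hemisphere_average()`);
* the **reliability battery** (`lilliefors_test()`,
  `wilcoxon_signed_rank()` with an exact small-sample null, `icc_2_1()`
  with F test and two confidence intervals, `bland_altman()`,
  `paired_sample_size()`);
* a **study pipeline** (`run_study()`, `render_report()`,
  `autoplot()`/`tidy()`/`glance()` methods) that emits the standard
  result tables: interhemispheric and inter-method Wilcoxon comparisons,
  inter-method ICC per configuration, the 55-pair inter-configuration
  ICC matrix per method, pooled descriptives and Bland–Altman agreement.

Real acquisitions enter through `read_diffusion_volume()` (NIfTI +
FSL-style bval/bvec) with manual ROI masks or placement records.

## Worked example

```r
library(alpsroi)

# the power computation behind a 13-subject paired design
paired_sample_size(effect_size = 0.82, alpha = 0.05, power = 0.80)
#> paired sample size: n_raw = 11.67, +10% inflation -> n = 13

# simulate and analyze a full 13-subject study (deterministic in the seed)
study <- run_study(study_config(n_subjects = 13, seed = 1))
study
#> <alps_study> 13 subjects, 11 configurations, seed 1
#>   DTI ALPS: mean 1.752, median 1.749 [q1 1.726, q3 1.774]
#>   DWI ALPS: mean 1.742, median 1.744 [q1 1.692, q3 1.788]
#>   inter-method ICC: mean 0.227 (range 0.085-0.386)
#>   Bland-Altman bias 0.0107, LOA [-0.0957, 0.1171]
#>   stable configurations: v2o, v3o, v4o, v6o, v3p, v4p, v4s, v9s

study$table3[study$table3$config %in% c("v1", "v4s", "v9s"),
             c("config", "icc", "f_p", "ci_lower", "ci_upper")]
#> # A tibble: 3 × 5
#>   config   icc    f_p ci_lower ci_upper
#>   <fct>  <dbl>  <dbl>    <dbl>    <dbl>
#> 1 v1     0.161 0.206  -0.218      0.504
#> 2 v4s    0.185 0.178  -0.209      0.528
#> 3 v9s    0.386 0.0262 -0.00379    0.671
```

What the numbers mean: the phantom's configured ground-truth index is
1.75 (`alps_ground_truth(phantom_spec())`), and both methods recover it
on average; their near-zero Bland–Altman bias says neither method is
systematically offset. The inter-method ICC per configuration is driven
by the ratio of true between-subject variance (the per-subject
perivascular component) to measurement noise — larger ROIs average more
voxels, so the 3×3 square `v9s` shows the strongest inter-method
agreement, the same qualitative ordering that motivates recommending
square ROIs. `tidy(study)` returns every index traceable to (subject,
hemisphere, method, configuration); `autoplot(study, "icc")` draws the
ICC profile with the 0.75/0.5 agreement reference lines;
`render_report(study, "out/")` writes the tables as CSV/JSON.

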