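Package: alpsroi
Title: Reliability of ROI Configurations for Diffusion MRI ALPS Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates periventricular diffusion-MRI acquisitions with a
    known ground-truth tensor field, computes DTI-ALPS and DWI-ALPS
    (diffusion along perivascular spaces) indices under eleven
    region-of-interest configurations, and runs the full reliability
    battery used in ALPS methods research: interhemispheric and
    inter-method Wilcoxon signed-rank comparisons, intraclass correlation
    ICC(2,1) with F test and confidence intervals, Bland-Altman agreement,
    Lilliefors normality testing, and paired sample-size computation.
    Real data enter as NIfTI volumes with FSL-style bval/bvec files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
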