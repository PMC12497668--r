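test_that("the ALPS ratio follows the printed formula and its invariances", {
  expect_equal(alps_index(1e-3, 1e-3, 1e-3, 1e-3), 1)
  expect_equal(alps_index(1.2e-3, 1.0e-3, 0.7e-3, 0.8e-3), 1.4667,
               tolerance = 1e-4)
  # scale invariance
  expect_equal(alps_index(1.2e-3, 1.0e-3, 0.7e-3, 0.8e-3),
               alps_index(3 * 1.2e-3, 3 * 1.0e-3, 3 * 0.7e-3, 3 * 0.8e-3))
  expect_error(alps_index(1e-3, 1e-3, -1e-3, 0),
               class = "alpsroi_computation_error")
})

test_that("subject indices equal the closed-form region ratio on noise-free phantoms", {
  spec <- noise_free_spec()
  lab <- build_labels(spec)
  rois <- place_study_rois(lab)
  f <- build_phantom(spec, 1)
  sch <- scheme_dti()
  tf <- fit_tensor_loglinear(simulate_dwi(f, sch$bvals, sch$bvecs, noise_sigma = 0))
  res <- subject_alps(tf, rois, "DTI", 1)
  truth <- alps_ground_truth(spec)
  expect_equal(nrow(res), 22)
  expect_true(all(abs(res$index - truth) < 1e-8))
})

test_that("DTI and DWI agree on axis-aligned noise-free phantoms", {
  spec <- tiny_spec(noise_sigma = 0)
  lab <- build_labels(spec)
  rois <- place_study_rois(lab)
  f <- build_phantom(spec, 2)
  d64 <- scheme_dti(); d3 <- scheme_dwi()
  tf <- fit_tensor_loglinear(simulate_dwi(f, d64$bvals, d64$bvecs, noise_sigma = 0))
  adc <- directional_adc(simulate_dwi(f, d3$bvals, d3$bvecs, noise_sigma = 0))
  r_dti <- subject_alps(tf, rois, "DTI", 2)
  r_dwi <- subject_alps(adc, rois, "DWI", 2)
  expect_true(all(abs(r_dti$index - r_dwi$index) < 1e-8))
})

test_that("the measured index increases strictly with the perivascular delta", {
  deltas <- c(0, 1e-4, 2e-4, 3e-4, 5e-4)
  sch <- scheme_dti()
  idx <- vapply(deltas, function(d) {
    spec <- noise_free_spec(perivascular_delta = d)
    lab <- build_labels(spec)
    rois <- place_study_rois(lab, configs = c("v1", "v4s", "v9s"))
    f <- build_phantom(spec, 1)
    tf <- fit_tensor_loglinear(simulate_dwi(f, sch$bvals, sch$bvecs, noise_sigma = 0))
    mean(subject_alps(tf, rois, "DTI", 1)$index)
  }, numeric(1))
  expect_true(all(diff(idx) > 0))
})

test_that("violating the placement constraints inflates the index", {
  # the stated inflation mechanism: ROIs too close to the ventricle pick
  # up the strong left-right periventricular component; association ROIs
  # reaching into subcortical fibers pick up their Dxx
  spec <- noise_free_spec()
  lab <- build_labels(spec)
  sl <- alps_slice(lab)
  f <- build_phantom(spec, 1)
  maps <- list(dx = f$tensors[, , , 1], dy = f$tensors[, , , 2],
               dz = f$tensors[, , , 3])
  proj_ok <- auto_place(lab, "v2o", "right", "projection", sl)
  assoc_ok <- auto_place(lab, "v3o", "right", "association", sl)
  baseline <- alps_index(extract_mean(maps$dx, proj_ok),
                         extract_mean(maps$dx, assoc_ok),
                         extract_mean(maps$dy, proj_ok),
                         extract_mean(maps$dz, assoc_ok))
  # shift the projection ROI into the periventricular band (distance 0-1
  # from the ventricle): invalid and inflated
  proj_bad <- roi_placement("v2o", c(sl, proj_ok$anchor[2], 25), "right",
                            "projection")
  expect_false(validate_placement(proj_bad, lab)$valid)
  inflated1 <- alps_index(extract_mean(maps$dx, proj_bad),
                          extract_mean(maps$dx, assoc_ok),
                          extract_mean(maps$dy, proj_bad),
                          extract_mean(maps$dz, assoc_ok))
  expect_gt(inflated1, baseline)
  # stretch the association ROI across the gap into subcortical fibers
  assoc_bad <- roi_placement("v3o", c(sl, assoc_ok$anchor[2], 34), "right",
                             "association")
  expect_false(validate_placement(assoc_bad, lab)$valid)
  inflated2 <- alps_index(extract_mean(maps$dx, proj_ok),
                          extract_mean(maps$dx, assoc_bad),
                          extract_mean(maps$dy, proj_ok),
                          extract_mean(maps$dz, assoc_bad))
  expect_gt(inflated2, baseline)
})

test_that("hemisphere averaging is the arithmetic mean and demands both sides", {
  res <- tibble::tibble(
    subject = c(1, 1), hemisphere = c("left", "right"),
    method = "DTI", config = "v4s", index = c(1.3, 1.5)
  )
  avg <- hemisphere_average(res)
  expect_equal(avg$index, 1.4)
  expect_equal(avg$hemisphere, "avg")
  expect_error(hemisphere_average(res[1, ]), class = "alpsroi_input_error")
  # identical hemispheres average to themselves
  res$index <- c(1.42, 1.42)
  expect_equal(hemisphere_average(res)$index, 1.42)
})

test_that("a symmetric noise-free phantom yields identical hemispheres", {
  spec <- noise_free_spec()
  lab <- build_labels(spec)
  rois <- place_study_rois(lab)
  f <- build_phantom(spec, 1)
  sch <- scheme_dti()
  tf <- fit_tensor_loglinear(simulate_dwi(f, sch$bvals, sch$bvecs, noise_sigma = 0))
  res <- subject_alps(tf, rois, "DTI", 1)
  w <- tidyr::pivot_wider(res[, c("config", "hemisphere", "index")],
                          names_from = "hemisphere", values_from = "index")
  expect_true(all(abs(w$left - w$right) < 1e-10))
})
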