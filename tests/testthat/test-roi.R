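test_that("the catalog holds the eleven configurations with the printed volumes", {
  cat11 <- roi_catalog(voxel_size_mm = 2)
  expect_equal(nrow(cat11), 11)
  expect_setequal(sort(unique(cat11$volume_mm3)), c(8, 16, 24, 32, 48, 72))
  counts <- setNames(cat11$n_voxels, cat11$name)
  expect_equal(counts[["v1"]], 1)
  expect_equal(unname(counts[c("v2o", "v2p")]), c(2, 2))
  expect_equal(unname(counts[c("v6o", "v6p")]), c(6, 6))
  expect_equal(counts[["v4s"]], 4)
  expect_equal(counts[["v9s"]], 9)
  offs <- setNames(cat11$offsets, cat11$name)
  expect_equal(offs[["v1"]], cbind(0L, 0L), ignore_attr = TRUE)
  # parallel lines extend along y (rows), orthogonal along x (cols)
  expect_equal(max(offs[["v4p"]][, 1]), 3); expect_equal(max(offs[["v4p"]][, 2]), 0)
  expect_equal(max(offs[["v4o"]][, 2]), 3); expect_equal(max(offs[["v4o"]][, 1]), 0)
  # v6p is 3 (y) x 2 (x); v6o is 2 (y) x 3 (x); squares are square
  expect_equal(c(max(offs[["v6p"]][, 1]), max(offs[["v6p"]][, 2])), c(2, 1))
  expect_equal(c(max(offs[["v6o"]][, 1]), max(offs[["v6o"]][, 2])), c(1, 2))
  expect_equal(dim(offs[["v9s"]]), c(9L, 2L))
  expect_equal(c(max(offs[["v9s"]][, 1]), max(offs[["v9s"]][, 2])), c(2, 2))
})

test_that("placement validation enforces the one-voxel-away rules", {
  spec <- tiny_spec()
  lab <- build_labels(spec)
  sl <- alps_slice(lab)
  # projection v1 directly adjacent to the ventricle (periventricular
  # band column): invalid, distance rule flagged
  p_adj <- roi_placement("v1", c(sl, 10, 25), "right", "projection")
  v <- validate_placement(p_adj, lab)
  expect_false(v$valid)
  expect_true(any(grepl("ventricle", v$violations)))
  # v4s with one empty voxel to the ventricle (distance 2) is valid
  p_ok <- roi_placement("v4s", c(sl, 10, 26), "right", "projection")
  expect_true(validate_placement(p_ok, lab)$valid)
  # association ROI overlapping a subcortical voxel is invalid
  p_sub <- roi_placement("v2o", c(sl, 10, 35), "right", "association")
  v2 <- validate_placement(p_sub, lab)
  expect_false(v2$valid)
  expect_true(any(grepl("subcortical", v2$violations)))
})

test_that("auto-placement is valid, centroid-seeking and mirror-symmetric", {
  lab <- build_labels(tiny_spec())
  rois <- place_study_rois(lab)
  expect_equal(nrow(rois), 44)           # 11 configs x 2 hemispheres x 2 areas
  expect_equal(nrow(attr(rois, "dropped")), 0)
  ok <- vapply(rois$placement, function(p) validate_placement(p, lab)$valid,
               logical(1))
  expect_true(all(ok))
  nx <- dim(lab)[1]
  for (cfg in c("v1", "v4s", "v9s", "v6o")) {
    for (ar in c("projection", "association")) {
      pl <- auto_place(lab, cfg, "left", ar)
      pr <- auto_place(lab, cfg, "right", ar)
      ml <- placement_voxels(pl); mr <- placement_voxels(pr)
      expect_setequal(paste(nx + 1 - ml[, "x"], ml[, "y"]),
                      paste(mr[, "x"], mr[, "y"]))
    }
  }
  # brute-force oracle: v4s projection anchor minimizes the centroid
  # distance among all valid anchors
  sl <- alps_slice(lab)
  best <- auto_place(lab, "v4s", "right", "projection", sl)
  codes <- region_codes()
  target <- which(lab[, , sl] == codes[["projection"]], arr.ind = TRUE)
  target <- target[target[, 1] > nx / 2, ]
  cx <- mean(target[, 1]); cy <- mean(target[, 2])
  scores <- c()
  for (r in 1:(dim(lab)[2] - 1)) {
    for (cc in (nx / 2 + 1):(nx - 1)) {
      p <- roi_placement("v4s", c(sl, r, cc), "right", "projection")
      if (validate_placement(p, lab)$valid) {
        scores <- c(scores, (r + 0.5 - cy)^2 + (cc + 0.5 - cx)^2)
      }
    }
  }
  bscore <- (best$anchor[2] + 0.5 - cy)^2 + (best$anchor[3] + 0.5 - cx)^2
  expect_equal(bscore, min(scores))
})

test_that("regions too narrow for a configuration raise a placement error", {
  geom <- default_region_geometry(c(40L, 20L, 8L))
  narrow <- geom
  narrow$x1[narrow$region == "projection" & narrow$hemisphere == "right"] <- 27L
  narrow$x0[narrow$region == "projection" & narrow$hemisphere == "left"] <- 14L
  spec <- tiny_spec(region_geometry = narrow)
  lab <- build_labels(spec)
  expect_error(auto_place(lab, "v9s", "right", "projection"),
               class = "alpsroi_placement_error")
  # monotone feasibility: smaller subset geometries still place
  expect_s3_class(auto_place(lab, "v4s", "right", "projection"), "roi_placement")
  expect_s3_class(auto_place(lab, "v1", "right", "projection"), "roi_placement")
})

test_that("180-degree in-plane rotation maps valid placements across hemispheres", {
  lab <- build_labels(tiny_spec())
  nx <- dim(lab)[1]; ny <- dim(lab)[2]
  rot <- lab[nx:1, ny:1, , drop = FALSE]
  for (cfg in c("v1", "v3p", "v6o", "v9s")) {
    p <- auto_place(lab, cfg, "left", "projection")
    vox <- placement_voxels(p)
    anchor2 <- c(p$anchor[1], min(ny + 1 - vox[, "y"]), min(nx + 1 - vox[, "x"]))
    p2 <- roi_placement(cfg, anchor2, "right", "projection")
    expect_true(validate_placement(p2, rot)$valid)
  }
})

test_that("ROI means are interpolation-free arithmetic means", {
  lab <- build_labels(tiny_spec())
  gs <- dim(lab)
  const <- array(2.5e-3, dim = gs)
  p1 <- roi_placement("v1", c(3, 10, 27), "right", "projection")
  expect_equal(extract_mean(const, p1), 2.5e-3)
  # v2p over two known values
  m <- array(0, dim = gs)
  p2 <- roi_placement("v2p", c(3, 10, 27), "right", "projection")
  vox <- placement_voxels(p2)
  m[vox] <- c(1.0e-3, 1.2e-3)
  expect_equal(extract_mean(m, p2), 1.1e-3)
  # v9s over an in-plane linear gradient equals the central value
  g <- array(0, dim = gs)
  for (x in 1:gs[1]) for (y in 1:gs[2]) g[x, y, ] <- 3 * x + 7 * y
  p9 <- roi_placement("v9s", c(3, 8, 26), "right", "projection")
  expect_equal(extract_mean(g, p9), 3 * 27 + 7 * 9)
  # non-finite member values propagate with a warning
  bad <- const
  bad[vox[1, 1], vox[1, 2], vox[1, 3]] <- NA
  expect_warning(res <- extract_mean(bad, p2))
  expect_true(is.na(res))
})
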