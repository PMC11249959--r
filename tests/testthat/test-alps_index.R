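# ROI rasterization, axis diffusivity extraction and the ALPS index.

test_that("a tiny radius keeps only the voxel at the centre", {
  aff <- dtialps:::centered_affine(c(9L, 9L, 9L))
  roi <- sphere_roi("projection_left", c(-2, 0, 0), radius = 0.49)
  mask <- rasterize_sphere(roi, aff, c(9L, 9L, 9L))
  expect_equal(sum(mask), 1L)
  expect_true(mask[3, 5, 5])   # x = -2 -> index 3 on this grid
})

test_that("rasterization matches exhaustive enumeration on several geometries", {
  geoms <- list(
    list(dim3 = c(15L, 15L, 15L), vox = c(1, 1, 1), r = 5),
    list(dim3 = c(9L, 9L, 9L), vox = c(2, 2, 2), r = 5),
    list(dim3 = c(13L, 9L, 11L), vox = c(1.5, 2.5, 1), r = 4))
  for (g in geoms) {
    aff <- dtialps:::centered_affine(g$dim3, g$vox)
    roi <- sphere_roi("association_right", c(1.2, 0.3, -0.7), g$r)
    expect_identical(rasterize_sphere(roi, aff, g$dim3),
                     brute_force_sphere(roi$center, g$r, aff, g$dim3))
  }
})

test_that("spheres outside the grid raise an empty-ROI error", {
  aff <- dtialps:::centered_affine(c(9L, 9L, 9L))
  roi <- sphere_roi("projection_right", c(100, 0, 0), 2)
  expect_error(rasterize_sphere(roi, aff, c(9L, 9L, 9L)), "outside the grid")
})

test_that("roi_set enforces the four-label scheme and hemisphere signs", {
  expect_error(sphere_roi("projection_left", c(3, 0, 0)), "x < 0")
  expect_error(sphere_roi("association_right", c(-3, 0, 0)), "x > 0")
  expect_error(sphere_roi("projection_left", c(-3, 0, 0), radius = -1), "> 0")
  rs <- small_roi_set()
  expect_s3_class(rs, "roi_set")
  expect_error(roi_set(rs$projection_left, rs$projection_right,
                       rs$projection_left, rs$association_right),
               "exactly one ROI")
  expect_error(roi_set(
    sphere_roi("projection_left", c(-3, 0, 0)),
    sphere_roi("association_left", c(-3, 0, 0)),
    sphere_roi("projection_right", c(3, 0, 0)),
    sphere_roi("association_right", c(7, 0, 0))), "coincide")
})

test_that("axis diffusivity extraction averages the diagonal entries", {
  tv <- uniform_tensor_volume(c(1.0e-3, 0, 0, 0.8e-3, 0, 0.9e-3))
  mask <- array(FALSE, c(12L, 12L, 12L)); mask[4:6, 4:6, 4:6] <- TRUE
  m <- extract_axis_diffusivities(tv, mask)
  expect_equal(c(m$dxx, m$dyy, m$dzz), c(1.0e-3, 0.8e-3, 0.9e-3))
  # two-voxel mean
  tv$components[4, 4, 4, 1] <- 1.0e-3
  tv$components[5, 4, 4, 1] <- 1.2e-3
  mask2 <- array(FALSE, c(12L, 12L, 12L)); mask2[4:5, 4, 4] <- TRUE
  expect_equal(extract_axis_diffusivities(tv, mask2)$dxx, 1.1e-3)
  # non-finite voxels are excluded, all-bad masks are an error
  tv$components[4, 4, 4, c(1, 4, 6)] <- NaN
  m3 <- extract_axis_diffusivities(tv, mask2)
  expect_equal(m3$dxx, 1.2e-3)
  expect_equal(m3$n_excluded, 1L)
  tv$components[5, 4, 4, 1] <- Inf
  expect_error(extract_axis_diffusivities(tv, mask2), "non-finite")
})

test_that("extraction equals brute-force accumulation on a random field", {
  set.seed(9)
  d3 <- c(10L, 10L, 10L)
  arr <- array(runif(prod(d3) * 6, 1e-4, 3e-3), c(d3, 6L))
  tv <- tensor_volume(arr, dtialps:::centered_affine(d3))
  mask <- array(runif(prod(d3)) < 0.3, d3)
  m <- extract_axis_diffusivities(tv, mask)
  acc <- c(0, 0, 0); n <- 0
  for (k in 1:d3[3]) for (j in 1:d3[2]) for (i in 1:d3[1])
    if (mask[i, j, k]) {
      acc <- acc + arr[i, j, k, c(1, 4, 6)]; n <- n + 1
    }
  expect_equal(c(m$dxx, m$dyy, m$dzz), acc / n, tolerance = 1e-12)
})

test_that("the index follows the printed formula and bilateral averaging", {
  # hemisphere means 1.0/1.2 over 0.8/0.9 -> 1.1 / 0.85
  d3 <- c(24L, 12L, 12L)
  aff <- dtialps:::centered_affine(d3)
  arr <- array(0, c(d3, 6L))
  xs <- (seq_len(d3[1]) - 1) - (d3[1] - 1) / 2
  proj <- abs(xs) <= 5.5; assoc <- abs(xs) > 5.5
  arr[proj, , , 1] <- 1.0e-3; arr[proj, , , 4] <- 0.8e-3
  arr[proj, , , 6] <- 1.7e-3
  arr[assoc, , , 1] <- 1.2e-3; arr[assoc, , , 4] <- 1.7e-3
  arr[assoc, , , 6] <- 0.9e-3
  tv <- tensor_volume(arr, aff)
  rs <- small_roi_set(radius = 2, px = 3, ax = 9)
  r <- compute_alps(tv, rs, qc = FALSE)
  expect_equal(r$alps_left, 1.1 / 0.85, tolerance = 1e-12)
  expect_equal(r$alps_right, 1.1 / 0.85, tolerance = 1e-12)
  expect_equal(r$alps_mean, (r$alps_left + r$alps_right) / 2)
  expect_equal(1.1 / 0.85, 1.29412, tolerance = 1e-5)
})

test_that("bilateral mean is the average of the hemispheric indices", {
  expect_equal((1.19 + 1.25) / 2, 1.22)
  ph <- make_phantom(phantom_spec(tensor_noise_sd = 2e-5, seed = 8))
  r <- compute_alps(ph$tensor, ph$rois, qc = FALSE)
  expect_identical(r$alps_mean, (r$alps_left + r$alps_right) / 2)
})

test_that("isotropy forces an index of exactly 1 for any placement", {
  tv <- uniform_tensor_volume(c(8e-4, 0, 0, 8e-4, 0, 8e-4),
                              c(20L, 20L, 20L))
  for (rs in list(small_roi_set(radius = 2, px = 2, ax = 6),
                  small_roi_set(radius = 4, px = 4, ax = 8))) {
    r <- compute_alps(tv, rs, qc = FALSE)
    expect_identical(r$alps_left, 1)
    expect_identical(r$alps_right, 1)
    expect_identical(r$alps_mean, 1)
  }
})

test_that("the index is invariant to uniform tensor scaling", {
  ph <- make_phantom(phantom_spec(tensor_noise_sd = 2e-5, seed = 3))
  r1 <- compute_alps(ph$tensor, ph$rois, qc = FALSE)
  scaled <- tensor_volume(ph$tensor$components * 4.2, ph$tensor$affine)
  r2 <- compute_alps(scaled, ph$rois, qc = FALSE)
  expect_equal(r2$alps_left, r1$alps_left, tolerance = 1e-12)
  expect_equal(r2$alps_right, r1$alps_right, tolerance = 1e-12)
  expect_equal(r2$alps_mean, r1$alps_mean, tolerance = 1e-12)
})

test_that("mirroring across the mid-sagittal plane swaps the hemispheres", {
  ph <- make_phantom(phantom_spec(tensor_noise_sd = 3e-5, seed = 12))
  r1 <- compute_alps(ph$tensor, ph$rois, qc = FALSE)
  flipped <- ph$tensor$components[dim(ph$tensor$components)[1]:1, , , ]
  # mirroring x negates the xy and xz cross terms; diagonals are unchanged
  flipped[, , , 2] <- -flipped[, , , 2]
  flipped[, , , 3] <- -flipped[, , , 3]
  tv2 <- tensor_volume(flipped, ph$tensor$affine)
  r2 <- compute_alps(tv2, ph$rois, qc = FALSE)
  expect_equal(r2$alps_left, r1$alps_right, tolerance = 1e-12)
  expect_equal(r2$alps_right, r1$alps_left, tolerance = 1e-12)
  expect_equal(r2$alps_mean, r1$alps_mean, tolerance = 1e-12)
})

test_that("raising Dxx in one hemisphere strictly raises its index only", {
  ph <- make_phantom(phantom_spec())
  r1 <- compute_alps(ph$tensor, ph$rois, qc = FALSE)
  comp <- ph$tensor$components
  xs <- (seq_len(dim(comp)[1]) - 1) - (dim(comp)[1] - 1) / 2
  left <- xs < 0
  comp[left, , , 1] <- comp[left, , , 1] * 1.15
  r2 <- compute_alps(tensor_volume(comp, ph$tensor$affine), ph$rois,
                     qc = FALSE)
  expect_gt(r2$alps_left, r1$alps_left)
  expect_equal(r2$alps_right, r1$alps_right, tolerance = 1e-12)
})

test_that("placement QC passes on phantoms and fails where expected", {
  ph <- make_phantom(phantom_spec())
  qc <- qc_placement(ph$fa, ph$tensor, ph$rois)
  expect_true(qc$pass)
  expect_length(qc$reasons, 0)

  # projection ROI in isotropic background: low FA
  iso <- uniform_tensor_volume(c(8e-4, 0, 0, 8e-4, 0, 8e-4),
                               c(20L, 20L, 20L))
  rs <- small_roi_set(radius = 3, px = 3, ax = 7)
  qc2 <- qc_placement(fa_map(iso), iso, rs)
  expect_false(qc2$pass)
  expect_true(any(grepl("^low_fa:projection", qc2$reasons)))

  # association ROIs placed inside the projection fibre region: misaligned
  rs3 <- roi_set(
    sphere_roi("projection_left", ph$rois$projection_left$center),
    sphere_roi("projection_right", ph$rois$projection_right$center),
    sphere_roi("association_left",
               ph$rois$projection_left$center + c(0, 1, 0)),
    sphere_roi("association_right",
               ph$rois$projection_right$center + c(0, 1, 0)))
  qc3 <- qc_placement(ph$fa, ph$tensor, rs3)
  expect_false(qc3$pass)
  expect_true(any(grepl("^misaligned:association", qc3$reasons)))
})

test_that("QC failure flags the result but does not suppress the index", {
  iso <- uniform_tensor_volume(c(8e-4, 0, 0, 8e-4, 0, 8e-4),
                               c(20L, 20L, 20L))
  r <- compute_alps(iso, small_roi_set(radius = 3, px = 3, ax = 7))
  expect_false(r$qc$pass)
  expect_identical(r$alps_mean, 1)
  df <- as.data.frame(r)
  expect_false(df$qc_pass)
  expect_match(df$qc_reasons, "low_fa")
})
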