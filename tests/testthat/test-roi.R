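test_that("plateau frame: axis-aligned normal, centroid origin, determinism", {
  ph <- fixture_tibial()
  f1 <- estimate_tibial_frame(ph$volume)
  f2 <- estimate_tibial_frame(ph$volume)
  expect_identical(f1, f2)
  expect_equal(f1$normal, c(0, 0, 1))
  expect_lt(abs(f1$origin[3]), ph$volume$grid$spacing_mm[3] + 1e-9)
  expect_error(estimate_tibial_frame(
    label_volume(array(0L, dim = c(4, 4, 4)), voxel_grid(c(4, 4, 4), c(1, 1, 1)),
                 c(background = 0L, tibia = 1L))), "structure-missing")
})

test_that("plane fit recovers a 5 degree plateau tilt within 1 degree", {
  ph <- generate_tibial_phantom(coarse_tibial(plateau_tilt_deg = 5),
                                oracle_res_mm = 0.1)
  frame <- estimate_tibial_frame(ph$volume, method = "plane_fit")
  cosang <- sum(frame$normal * ph$truth$plateau_normal)
  expect_lt(acos(min(1, abs(cosang))) * 180 / pi, 1)
})

test_that("two-lobed plateau splits into disjoint MT/LT ROIs with correct areas", {
  ph <- generate_tibial_phantom(coarse_tibial(lateral_lobe = TRUE),
                                oracle_res_mm = 0.1)
  frame <- estimate_tibial_frame(ph$volume)
  rois <- build_tibial_rois(ph$volume, frame)
  expect_false(is.null(rois$LT))
  expect_false(any(rois$MT$mask & rois$LT$mask))
  lobe <- pi * 16 * 11
  expect_lt(abs(roi_area(rois$MT) - lobe) / lobe, 0.05)
  expect_lt(abs(roi_area(rois$LT) - lobe) / lobe, 0.05)
  # medial lobe sits at lower mediolateral coordinate
  expect_lt(mean(which(rowSums(rois$MT$mask) > 0)),
            mean(which(rowSums(rois$LT$mask) > 0)))
  # area identity is exact by construction
  expect_identical(roi_area(rois$MT), sum(rois$MT$mask) * prod(frame$cell_size_mm))
})

test_that("single-compartment phantom yields MT only, with a warning", {
  ph <- fixture_tibial()
  frame <- estimate_tibial_frame(ph$volume)
  expect_warning(rois <- build_tibial_rois(ph$volume, frame), "lateral")
  expect_null(rois$LT)
  expect_s3_class(rois$MT, "roi_mask")
})

test_that("femoral cylinder fit recovers the true axis within 1 degree", {
  fp <- fixture_femoral()
  frame <- fit_femoral_cylinder(fp$volume)
  truth <- fp$truth$cylinder_axis
  ang <- acos(min(1, abs(sum(frame$axis * truth$direction)))) * 180 / pi
  expect_lt(ang, 1)
  # fitted radius within half a voxel of the true surface radius
  expect_lt(abs(frame$r_ref - truth$radius), 0.5 * max(fp$volume$grid$spacing_mm))
  expect_identical(frame, fit_femoral_cylinder(fp$volume))
})

test_that("femoral cylinder fit tracks a 10 degree tilted axis", {
  fp <- generate_femoral_phantom(
    femoral_phantom_spec(axis_tilt_deg = 10, spacing_mm = rep(0.3, 3)))
  frame <- fit_femoral_cylinder(fp$volume)
  ang <- acos(min(1, abs(sum(frame$axis * fp$truth$cylinder_axis$direction)))) *
    180 / pi
  expect_lt(ang, 1)
})

test_that("femoral ROI tiles into three regions and 27 subregions", {
  fp <- fixture_femoral()
  frame <- fit_femoral_cylinder(fp$volume)
  rois <- build_femoral_roi(fp$volume, frame)
  expect_named(rois, c("MF", "Trochlea", "LF"))
  expect_false(any(rois$MF$mask & rois$Trochlea$mask))
  expect_false(any(rois$Trochlea$mask & rois$LF$mask))
  n_sub <- sum(vapply(rois, function(r)
    length(unique(stats::na.omit(as.vector(subdivide(r)$subregion)))), 1))
  expect_identical(as.integer(n_sub), 27L)
  # footprint spans the sector's angular and axial extent within a cell ring
  all_mask <- rois$MF$mask | rois$Trochlea$mask | rois$LF$mask
  th_cells <- range(which(rowSums(all_mask) > 0))
  th_lo <- frame$theta0 + (th_cells[1] - 1) * frame$dtheta
  th_hi <- frame$theta0 + th_cells[2] * frame$dtheta
  expect_lt(abs(th_lo - (-pi / 2)), 3 * frame$dtheta)
  expect_lt(abs(th_hi - pi / 2), 3 * frame$dtheta)
})

test_that("3x3 subdivision follows the exact-interval and remainder rules", {
  frame <- kneemorph:::.planar_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                     c(0, 0, 1), 1, 1, 0, 0, 12, 12)
  sq <- matrix(FALSE, 12, 12); sq[2:10, 2:10] <- TRUE
  part <- subdivide(kneemorph:::.roi_mask(frame, sq, "MT"))
  counts <- tabulate(part$subregion[!is.na(part$subregion)], 9)
  expect_identical(counts, rep(9L, 9))

  rect <- matrix(FALSE, 12, 12); rect[1:10, 2:10] <- TRUE
  part2 <- subdivide(kneemorph:::.roi_mask(frame, rect, "MT"))
  widths <- table(part2$subregion[!is.na(part2$subregion)] %/% 3.01 + 1)
  expect_identical(unname(c(widths)), c(27L, 27L, 36L))  # bands 3,3,4 wide

  thin <- matrix(FALSE, 12, 12); thin[5:6, 2:10] <- TRUE
  expect_error(subdivide(kneemorph:::.roi_mask(frame, thin, "MT")),
               "subdivision error")
})

test_that("subdivision partitions every random ROI exactly", {
  for (seed in 1:25) {
    roi <- random_roi(seed)
    part <- subdivide(roi)
    inside <- !is.na(part$subregion)
    expect_identical(inside, roi$mask)
    expect_true(all(part$subregion[inside] %in% 1:9))
  }
})
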