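test_that("uniform slab thickness is recovered within one voxel spacing", {
  ph <- generate_tibial_phantom(
    tibial_phantom_spec(spacing_mm = rep(0.25, 3)), oracle_res_mm = 0.1)
  frame <- estimate_tibial_frame(ph$volume)
  roi <- suppressWarnings(build_tibial_rois(ph$volume, frame))$MT
  map <- project_planar_thickness(ph$volume, frame, roi)
  # interior cells (erode the ROI twice) all read 2.0 +/- one voxel
  interior <- EBImage::erode(roi$mask * 1, EBImage::makeBrush(5, "box")) > 0.5
  v <- map$thickness_mm[interior]
  expect_true(all(abs(v - 2) <= 0.25 + 1e-9))
})

test_that("empty cartilage projects to an all-zero map", {
  ph <- fixture_tibial()
  vol <- ph$volume
  vol$labels[vol$labels == 2L] <- 0L
  frame <- estimate_tibial_frame(vol)
  roi <- suppressWarnings(build_tibial_rois(vol, frame))$MT
  expect_true(all(project_planar_thickness(vol, frame, roi)$thickness_mm == 0))
  expect_error(project_planar_thickness(ph$volume,
                                        fit_femoral_cylinder(fixture_femoral()$volume),
                                        roi), "frame-kind")
})

test_that("a 30 degree slope inflates vertical thickness by about 1/cos", {
  ph <- generate_tibial_phantom(
    tibial_phantom_spec(plateau_tilt_deg = 30, spacing_mm = rep(0.3, 3)),
    oracle_res_mm = 0.1)
  frame <- estimate_tibial_frame(ph$volume)     # axis-aligned, i.e. vertical rays
  roi <- suppressWarnings(build_tibial_rois(ph$volume, frame))$MT
  map <- project_planar_thickness(ph$volume, frame, roi)
  interior <- EBImage::erode(roi$mask * 1, EBImage::makeBrush(7, "box")) > 0.5
  v <- map$thickness_mm[interior]
  v <- v[v > 0]
  expect_lt(abs(mean(v) - 2 / cos(30 * pi / 180)) / (2 / cos(30 * pi / 180)), 0.05)
})

test_that("cylindrical projection reads the radial shell thickness at every angle", {
  fp <- generate_femoral_phantom(
    femoral_phantom_spec(spacing_mm = rep(0.25, 3)))
  frame <- fit_femoral_cylinder(fp$volume)
  rois <- build_femoral_roi(fp$volume, frame)
  roi <- rois$MF; roi$mask <- rois$MF$mask | rois$Trochlea$mask | rois$LF$mask
  map <- project_cylindrical_thickness(fp$volume, frame, roi)
  interior <- EBImage::erode(roi$mask * 1, EBImage::makeBrush(5, "box")) > 0.5
  v <- map$thickness_mm[interior]
  v <- v[v > 0]                      # covered cells of the unwrapped map
  diag2 <- 2 * sqrt(3) * 0.25
  expect_true(all(abs(v - 2) <= diag2))
  expect_lt(abs(mean(v) - 2), 0.25)
  expect_error(project_cylindrical_thickness(fp$volume,
                                             estimate_tibial_frame(fixture_tibial()$volume),
                                             roi), "frame-kind")
})

test_that("planar projection of the shell inflates by 1/cos(theta) while cylindrical does not", {
  fp <- generate_femoral_phantom(
    femoral_phantom_spec(spacing_mm = rep(0.25, 3)))
  vol <- fp$volume
  frame <- fit_femoral_cylinder(vol)
  # vertical-ray thickness measured on the voxel lattice
  g <- vol$grid
  counts <- rowSums(matrix(vol$labels == 2L, g$shape[1] * g$shape[2], g$shape[3]))
  vert <- matrix(counts * g$spacing_mm[3], g$shape[1], g$shape[2])
  cs <- kneemorph:::.axis_coords(g)
  for (theta_deg in c(30, 60)) {
    # sample columns whose (y,z) position crosses the shell at polar angle theta
    y_target <- frame$r_ref * sin(theta_deg * pi / 180)
    jsel <- which(abs(abs(cs[[2]] - frame$origin[2]) - y_target) < 0.4)
    isel <- which(abs(cs[[1]] - frame$origin[1]) < 6)
    v <- as.vector(vert[isel, jsel])
    v <- v[v > 0]
    inflation <- mean(v) / 2
    expect_lt(abs(inflation - 1 / cos(theta_deg * pi / 180)) /
                (1 / cos(theta_deg * pi / 180)), 0.12)
    # the cylindrical map at the same angle stays at the true thickness
    tb <- which(abs(frame$theta0 + (seq_len(frame$grid_dim[1]) - 0.5) *
                      frame$dtheta - theta_deg * pi / 180) < frame$dtheta)
    roi <- kneemorph:::.roi_mask(frame,
                                 matrix(TRUE, frame$grid_dim[1], frame$grid_dim[2]),
                                 "MF")
    map <- project_cylindrical_thickness(vol, frame, roi)
    band <- map$thickness_mm[tb, ]
    band <- band[band > 0]
    expect_lt(abs(mean(band) - 2), 0.25)
  }
})

test_that("footprint conservation identities hold exactly", {
  ph <- fixture_tibial()
  frame <- estimate_tibial_frame(ph$volume)
  fp <- project_footprint(ph$volume, "medial_meniscus", frame)
  vox_vol <- sum(ph$volume$labels == 3L) * prod(ph$volume$grid$spacing_mm)
  expect_equal(sum(fp$column_volume_mm3), vox_vol, tolerance = 1e-12)
  expect_true(all(fp$present == (fp$column_volume_mm3 > 0)))
  # annular wedge footprint area close to the analytic value
  wedge <- (200 / 2 * pi / 180) * (14^2 - 9^2)
  expect_lt(abs(sum(fp$present) * fp$cell_area_mm2 - wedge) / wedge, 0.05)
  expect_error(project_footprint(ph$volume, "lateral_meniscus", frame),
               "structure-missing")
})

test_that("single-voxel structure projects to one cell with one voxel volume", {
  g <- voxel_grid(c(10, 10, 10), c(0.5, 0.5, 0.5))
  labs <- array(0L, dim = c(10, 10, 10))
  labs[4, 7, 5] <- 2L
  labs[, , 1] <- 1L                      # a bone slab to define the frame
  vol <- label_volume(labs, g, c(background = 0L, tibia = 1L,
                                 tibial_cartilage = 2L))
  frame <- estimate_tibial_frame(vol)
  fp <- project_footprint(vol, "tibial_cartilage", frame)
  expect_identical(sum(fp$present), 1L)
  expect_equal(sum(fp$column_volume_mm3), 0.125, tolerance = 1e-12)
  expect_true(fp$present[4, 7])
})

test_that("map volume matches voxel-counted volume under the ray definition", {
  ph <- fixture_tibial()
  frame <- estimate_tibial_frame(ph$volume)
  roi <- suppressWarnings(build_tibial_rois(ph$volume, frame))$MT
  map <- project_planar_thickness(ph$volume, frame, roi)
  map_vol <- sum(map$thickness_mm[roi$mask]) * roi$cell_area_mm2
  vox_vol <- sum(ph$volume$labels == 2L) * prod(ph$volume$grid$spacing_mm)
  expect_lt(abs(map_vol - vox_vol) / vox_vol, 0.02)
})
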