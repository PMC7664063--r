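#' Cartilage thickness profile for phantom plates
#'
#' Defines the thickness field (mm) of a phantom cartilage plate as a
#' function of in-plane position over the covered footprint.
#'
#' * `constant`: thickness `value` everywhere.
#' * `linear`: ramp from `from` at the medial edge to `to` at the lateral
#'   edge of the covered footprint (along the ML axis).
#' * `radial`: tapers from `from` at the footprint centre to `to` at its rim.
#'
#' @param type One of `"constant"`, `"linear"`, `"radial"`.
#' @param value,from,to Thicknesses in mm (all `>= 0`).
#' @return An object of class `thickness_profile`.
#' @export
thickness_profile <- function(type = c("constant", "linear", "radial"),
                              value = 2, from = value, to = value) {
  type <- match.arg(type)
  if (min(value, from, to) < 0) stop("thickness_profile: thickness must be >= 0")
  structure(list(type = type, value = value, from = from, to = to),
            class = "thickness_profile")
}

# Thickness field closure over the covered footprint (ellipse centred at
# (cx, cy) with semi-axes a_cov, b_cov).
.profile_fun <- function(profile, cx, cy, a_cov, b_cov) {
  switch(profile$type,
    constant = function(x, y) rep(profile$value, length(x)),
    linear = function(x, y) {
      s <- (x - (cx - a_cov)) / (2 * a_cov)      # 0 at medial edge, 1 lateral
      profile$from + (profile$to - profile$from) * pmin(pmax(s, 0), 1)
    },
    radial = function(x, y) {
      r <- sqrt(((x - cx) / a_cov)^2 + ((y - cy) / b_cov)^2)
      profile$from + (profile$to - profile$from) * pmin(r, 1)
    })
}

#' Specification of a tibial plateau phantom
#'
#' Describes a synthetic medial (optionally also lateral) tibial compartment:
#' an elliptic-cylinder bone slab whose flat top is the plateau, a cartilage
#' plate of configurable thickness profile covering a central fraction of
#' the plateau footprint, and a C-shaped meniscal wedge that can be rigidly
#' extruded medially by `extrusion_offset_mm`. All linear units mm.
#'
#' The covered cartilage footprint is the concentric ellipse with semi-axes
#' scaled by `sqrt(coverage_fraction)`, so its area is exactly
#' `coverage_fraction` times the plateau ROI area. The meniscal wedge is
#' centred on the medial (-i) direction, opening laterally.
#'
#' @param plateau_semi_axes_mm Length-2 positive: ML and AP semi-axes of the
#'   elliptical plateau footprint (per compartment).
#' @param bone_depth_mm Bone slab depth below the plateau.
#' @param cartilage_profile A [thickness_profile()].
#' @param coverage_fraction Fraction in `[0,1]` of the plateau footprint
#'   bearing cartilage.
#' @param meniscus_inner_radius_mm,meniscus_outer_radius_mm Annulus radii,
#'   inner < outer.
#' @param meniscus_angular_extent_deg Angular extent of the C-shape in
#'   (0, 360).
#' @param meniscus_height_mm Meniscal wedge height above the plateau.
#' @param extrusion_offset_mm Rigid outward (medial) shift of the annulus,
#'   `>= 0`.
#' @param plateau_tilt_deg Tilt of the plateau surface about the AP axis
#'   (degrees); used to exercise plane fitting and oblique-projection
#'   behaviour. Cartilage sits on the tilted surface with true (normal)
#'   thickness given by the profile.
#' @param lateral_lobe If `TRUE`, a mirrored lateral compartment (bone +
#'   cartilage only) is added so the plateau footprint has two lobes.
#' @param spacing_mm Voxel spacing, default `c(0.29, 0.29, 0.3)`.
#' @param grid_shape Optional fixed grid shape; default sizes the grid to
#'   fit the geometry with a margin.
#' @param seed Integer seed recorded in the spec.
#' @return An object of class `tibial_phantom_spec`.
#' @export
tibial_phantom_spec <- function(plateau_semi_axes_mm = c(16, 11),
                                bone_depth_mm = 8,
                                cartilage_profile = thickness_profile("constant", 2),
                                coverage_fraction = 1,
                                meniscus_inner_radius_mm = 9,
                                meniscus_outer_radius_mm = 14,
                                meniscus_angular_extent_deg = 200,
                                meniscus_height_mm = 4,
                                extrusion_offset_mm = 0,
                                plateau_tilt_deg = 0,
                                lateral_lobe = FALSE,
                                spacing_mm = c(0.29, 0.29, 0.3),
                                grid_shape = NULL,
                                seed = 1L) {
  stopifnot(length(plateau_semi_axes_mm) == 2, all(plateau_semi_axes_mm > 0),
            bone_depth_mm > 0, inherits(cartilage_profile, "thickness_profile"),
            meniscus_height_mm > 0, extrusion_offset_mm >= 0)
  if (coverage_fraction < 0 || coverage_fraction > 1)
    stop("tibial_phantom_spec: coverage_fraction must lie in [0,1]")
  if (meniscus_inner_radius_mm >= meniscus_outer_radius_mm)
    stop("tibial_phantom_spec: meniscus inner radius must be < outer radius")
  if (meniscus_angular_extent_deg <= 0 || meniscus_angular_extent_deg >= 360)
    stop("tibial_phantom_spec: meniscus_angular_extent_deg must lie in (0, 360)")
  structure(as.list(environment()), class = "tibial_phantom_spec")
}

#' Generate a tibial plateau phantom with analytic ground truth
#'
#' Voxelizes the geometry described by a [tibial_phantom_spec()] (a voxel
#' carries a label iff its centre lies inside the analytic solid; overlap
#' precedence cartilage > meniscus > bone) and computes the analytic
#' morphometry truth: PCAR at the requested thresholds, mean covered
#' thickness, cartilage volume, and the meniscus extrusion triple. Plateau
#' and cartilage areas come from closed-form ellipse geometry; the
#' wedge-ellipse overlap is evaluated with the independent 2D indicator
#' integration oracle at `oracle_res_mm`.
#'
#' @param spec A [tibial_phantom_spec()].
#' @param thresholds_mm PCAR thresholds, default `c(0, 0.5, 1, 1.5)`.
#' @param oracle_res_mm Integration resolution of the truth oracle (mm).
#' @return A list with elements `volume` (a [label_volume()]) and `truth`
#'   (class `phantom_truth`).
#' @export
generate_tibial_phantom <- function(spec, thresholds_mm = c(0, 0.5, 1, 1.5),
                                    oracle_res_mm = 0.01) {
  stopifnot(inherits(spec, "tibial_phantom_spec"))
  a <- spec$plateau_semi_axes_mm[1]; b <- spec$plateau_semi_axes_mm[2]
  tilt <- spec$plateau_tilt_deg * pi / 180
  r_out <- spec$meniscus_outer_radius_mm
  off <- spec$extrusion_offset_mm
  # compartment centres
  gap <- 4
  if (spec$lateral_lobe) {
    cx_m <- -(a + gap / 2); cx_l <- a + gap / 2
  } else {
    cx_m <- 0; cx_l <- NA_real_
  }
  prof <- spec$cartilage_profile
  t_max <- max(prof$value, prof$from, prof$to)
  xmin <- min(cx_m - a, cx_m - r_out - off) - 2 * spec$spacing_mm[1]
  xmax <- (if (spec$lateral_lobe) cx_l + a else max(a, r_out)) + 2 * spec$spacing_mm[1]
  ymin <- -max(b, r_out) - 2 * spec$spacing_mm[2]
  ymax <- max(b, r_out) + 2 * spec$spacing_mm[2]
  ztop_max <- abs(tan(tilt)) * max(abs(xmin), abs(xmax))
  zmin <- -ztop_max - spec$bone_depth_mm - 2 * spec$spacing_mm[3]
  zmax <- ztop_max + max(t_max / max(cos(tilt), 1e-6), spec$meniscus_height_mm) +
    2 * spec$spacing_mm[3]
  snap_z <- function(oz, dz) {
    # place the plateau surface (z = 0) on a voxel boundary so that the
    # centre-inclusion voxelization is unbiased in the slice direction
    dz * (round((oz - dz / 2) / dz)) + dz / 2
  }
  if (is.null(spec$grid_shape)) {
    shape <- pmax(ceiling(c(xmax - xmin, ymax - ymin, zmax - zmin) / spec$spacing_mm), 4)
    origin <- c(xmin, ymin, zmin) + spec$spacing_mm / 2
    origin[3] <- snap_z(origin[3], spec$spacing_mm[3])
  } else {
    shape <- as.integer(spec$grid_shape)
    ext <- shape * spec$spacing_mm
    # on a fixed grid a single-voxel margin suffices
    slack <- 2 * spec$spacing_mm
    if (any(c(xmax - xmin, ymax - ymin, zmax - zmin) - slack > ext + 1e-9))
      stop("generate_tibial_phantom: shapes exceed the fixed grid bounds (geometry error)")
    # centre the geometry bounding box in the fixed grid
    ctr <- c((xmin + xmax) / 2, (ymin + ymax) / 2, (zmin + zmax) / 2)
    origin <- ctr - ext / 2 + spec$spacing_mm / 2
    origin[3] <- snap_z(origin[3], spec$spacing_mm[3])
  }
  grid <- voxel_grid(shape, spec$spacing_mm, origin)
  cs <- .axis_coords(grid)
  xs <- cs[[1]]; ys <- cs[[2]]; zs <- cs[[3]]

  a_cov <- a * sqrt(spec$coverage_fraction)
  b_cov <- b * sqrt(spec$coverage_fraction)
  tfun_m <- .profile_fun(prof, cx_m, 0, max(a_cov, 1e-12), max(b_cov, 1e-12))
  wedge_cx <- cx_m - off
  half_ext <- spec$meniscus_angular_extent_deg / 2 * pi / 180

  xg <- matrix(xs, length(xs), length(ys))
  yg <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  in_bone_xy <- .ind_ellipse(xg, yg, cx_m, 0, a, b)
  in_cov_xy <- if (spec$coverage_fraction > 0)
    .ind_ellipse(xg, yg, cx_m, 0, a_cov, b_cov) else in_bone_xy & FALSE
  if (spec$lateral_lobe) {
    in_bone_xy <- in_bone_xy | .ind_ellipse(xg, yg, cx_l, 0, a, b)
    a_cov_l <- a_cov; b_cov_l <- b_cov
    in_cov_xy_l <- if (spec$coverage_fraction > 0)
      .ind_ellipse(xg, yg, cx_l, 0, a_cov_l, b_cov_l) else in_bone_xy & FALSE
  }
  in_men_xy <- .ind_annular_wedge(xg, yg, wedge_cx, 0, spec$meniscus_inner_radius_mm,
                                  r_out, pi, half_ext)
  surf <- tan(tilt) * xg                       # plateau surface height z(x)
  tmap <- matrix(0, length(xs), length(ys))
  tmap[in_cov_xy] <- tfun_m(xg[in_cov_xy], yg[in_cov_xy])
  if (spec$lateral_lobe) {
    tfun_l <- .profile_fun(prof, cx_l, 0, max(a_cov, 1e-12), max(b_cov, 1e-12))
    tmap[in_cov_xy_l] <- tfun_l(xg[in_cov_xy_l], yg[in_cov_xy_l])
  }
  t_vert <- tmap / cos(tilt)                   # vertical extent of the plate

  lm <- c(background = 0L, tibia = 1L, tibial_cartilage = 2L, medial_meniscus = 3L)
  labels <- array(0L, dim = shape)
  for (k in seq_along(zs)) {
    z <- zs[k]
    sl <- matrix(0L, length(xs), length(ys))
    sl[in_bone_xy & z <= surf & z >= surf - spec$bone_depth_mm] <- 1L
    sl[in_men_xy & z > surf & z <= surf + spec$meniscus_height_mm] <- 3L
    sl[t_vert > 0 & z > surf & z <= surf + t_vert] <- 2L
    labels[, , k] <- sl
  }
  vol <- label_volume(labels, grid, lm)

  roi_area <- pi * a * b
  oint <- .oracle_thickness_integrals(tfun_m, cx_m, 0, a_cov, b_cov,
                                      thresholds_mm, res = oracle_res_mm)
  pcar <- stats::setNames(oint$area_gt / roi_area, format(thresholds_mm))
  wedge_area <- half_ext * (r_out^2 - spec$meniscus_inner_radius_mm^2)
  overlap <- .oracle_wedge_ellipse_overlap(cx_m, 0, a, b, wedge_cx, 0,
                                           spec$meniscus_inner_radius_mm, r_out,
                                           pi, half_ext, res = oracle_res_mm)
  truth <- structure(list(
    pcar_by_threshold = pcar,
    thc_mm = oint$thc,
    vc_mm3 = oint$vc,
    covered_area_mm2 = oint$area,
    roi_area_mm2 = roi_area,
    mmcr = overlap / roi_area,
    overlap_area_mm2 = overlap,
    meniscus_footprint_area_mm2 = wedge_area,
    mme_area_mm2 = wedge_area - overlap,
    mme_volume_mm3 = (wedge_area - overlap) * spec$meniscus_height_mm,
    plateau_normal = c(-sin(tilt), 0, cos(tilt)),
    cylinder_axis = NULL), class = "phantom_truth")
  list(volume = vol, truth = truth)
}

#' Specification of a femoral condyle phantom
#'
#' A solid cylinder sector (the condylar bone) along the mediolateral axis
#' carrying a partial cartilage shell of uniform radial thickness. The
#' sector and shell are centred on the superior (+k) direction.
#'
#' @param cylinder_radius_mm Bone radius (mm).
#' @param cylinder_length_mm Axial (ML) length (mm).
#' @param shell_thickness_mm Radial cartilage thickness, `< cylinder_radius_mm`.
#' @param shell_angular_extent_deg Angular extent of bone sector and ROI, in
#'   (0, 360].
#' @param coverage_fraction Fraction in `[0,1]` of the sector's angular
#'   extent bearing cartilage (centred).
#' @param axis_tilt_deg Rotation of the cylinder axis about the AP axis.
#' @param spacing_mm Voxel spacing.
#' @param seed Integer seed recorded in the spec.
#' @return An object of class `femoral_phantom_spec`.
#' @export
femoral_phantom_spec <- function(cylinder_radius_mm = 18,
                                 cylinder_length_mm = 24,
                                 shell_thickness_mm = 2,
                                 shell_angular_extent_deg = 180,
                                 coverage_fraction = 1,
                                 axis_tilt_deg = 0,
                                 spacing_mm = c(0.29, 0.29, 0.3),
                                 seed = 1L) {
  stopifnot(cylinder_radius_mm > 0, cylinder_length_mm > 0, shell_thickness_mm > 0)
  if (shell_thickness_mm >= cylinder_radius_mm)
    stop("femoral_phantom_spec: shell thickness must be < cylinder radius")
  if (coverage_fraction < 0 || coverage_fraction > 1)
    stop("femoral_phantom_spec: coverage_fraction must lie in [0,1]")
  if (shell_angular_extent_deg <= 0 || shell_angular_extent_deg > 360)
    stop("femoral_phantom_spec: shell_angular_extent_deg must lie in (0, 360]")
  structure(as.list(environment()), class = "femoral_phantom_spec")
}

#' Generate a femoral condyle phantom with known cylinder axis
#'
#' Voxelizes a [femoral_phantom_spec()]: bone is a solid cylinder sector
#' about an axis along the (possibly tilted) mediolateral direction;
#' cartilage is a shell of exact radial thickness over a centred angular
#' sub-extent whose fraction of the ROI extent equals `coverage_fraction`.
#' The truth records the exact axis, shell thickness, analytic PCAR and
#' shell volume.
#'
#' @inheritParams generate_tibial_phantom
#' @param spec A [femoral_phantom_spec()].
#' @return A list `volume` (a [label_volume()]) and `truth` (`phantom_truth`).
#' @export
generate_femoral_phantom <- function(spec, thresholds_mm = c(0, 0.5, 1, 1.5)) {
  stopifnot(inherits(spec, "femoral_phantom_spec"))
  R <- spec$cylinder_radius_mm; L <- spec$cylinder_length_mm
  t <- spec$shell_thickness_mm
  ext <- spec$shell_angular_extent_deg * pi / 180
  phi <- spec$axis_tilt_deg * pi / 180
  dir <- c(cos(phi), 0, sin(phi))
  Rout <- R + t
  margin <- 2 * max(spec$spacing_mm)
  half_len <- L / 2
  half_span <- half_len * abs(dir) + Rout * sqrt(pmax(1 - dir^2, 0)) + margin
  shape <- pmax(ceiling(2 * half_span / spec$spacing_mm), 4)
  origin <- -shape * spec$spacing_mm / 2 + spec$spacing_mm / 2
  grid <- voxel_grid(shape, spec$spacing_mm, origin)
  cs <- .axis_coords(grid)
  axis_origin <- c(0, 0, 0) - dir * half_len   # axial coordinate s in [0, L]

  # reference frame: u = unit projection of +k onto the axis-normal plane
  u <- c(0, 0, 1) - dir[3] * dir
  u <- u / sqrt(sum(u^2))
  w <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  labels <- array(0L, dim = shape)
  half_cov <- ext * spec$coverage_fraction / 2
  yg <- matrix(cs[[2]], nx, ny, byrow = TRUE)
  xg <- matrix(cs[[1]], nx, ny)
  for (k in seq_len(nz)) {
    z <- cs[[3]][k]
    vx <- xg - axis_origin[1]; vy <- yg - axis_origin[2]; vz <- z - axis_origin[3]
    s <- vx * dir[1] + vy * dir[2] + vz * dir[3]
    rx <- vx - s * dir[1]; ry <- vy - s * dir[2]; rz <- vz - s * dir[3]
    rho <- sqrt(rx^2 + ry^2 + rz^2)
    th <- atan2(rx * w[1] + ry * w[2] + rz * w[3],
                rx * u[1] + ry * u[2] + rz * u[3])
    in_len <- s >= 0 & s <= L
    sl <- matrix(0L, nx, ny)
    sl[in_len & rho <= R & abs(th) <= ext / 2] <- 1L
    sl[in_len & rho > R & rho <= Rout & abs(th) <= half_cov] <- 2L
    labels[, , k] <- sl
  }
  lm <- c(background = 0L, femur = 1L, femoral_cartilage = 2L)
  vol <- label_volume(labels, grid, lm)

  cov <- spec$coverage_fraction
  pcar <- stats::setNames(ifelse(t > thresholds_mm, cov, 0), format(thresholds_mm))
  truth <- structure(list(
    pcar_by_threshold = pcar,
    thc_mm = t,
    vc_mm3 = 0.5 * ext * cov * (Rout^2 - R^2) * L,
    covered_area_mm2 = NA_real_,
    roi_area_mm2 = NA_real_,
    mmcr = NA_real_, overlap_area_mm2 = NA_real_,
    meniscus_footprint_area_mm2 = NA_real_,
    mme_area_mm2 = NA_real_, mme_volume_mm3 = NA_real_,
    plateau_normal = NULL,
    cylinder_axis = list(origin = axis_origin, direction = dir,
                         radius = R, length = L,
                         angular_extent_rad = ext)), class = "phantom_truth")
  list(volume = vol, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("phantom_truth\n")
  cat("  PCAR:", paste(sprintf("%s>%s", format(x$pcar_by_threshold, digits = 4),
                               names(x$pcar_by_threshold)), collapse = "  "), "\n")
  cat(sprintf("  ThC %.4g mm, VC %.6g mm^3\n", x$thc_mm, x$vc_mm3))
  if (!is.null(x$mmcr) && is.finite(x$mmcr))
    cat(sprintf("  MMCR %.4g, MME area %.6g mm^2, MME volume %.6g mm^3\n",
                x$mmcr, x$mme_area_mm2, x$mme_volume_mm3))
  if (!is.null(x$cylinder_axis))
    cat("  cylinder axis dir:", paste(signif(x$cylinder_axis$direction, 6),
                                      collapse = ", "), "\n")
  invisible(x)
}

#' Synthesize an intensity volume from a label volume
#'
#' Assigns each structure its class mean and adds independent Gaussian
#' noise, emulating (in the crudest useful way) the MR contrast that a
#' segmentation network is trained on.
#'
#' @param vol A [label_volume()].
#' @param class_means Named numeric vector, one mean per role in
#'   `vol$label_map`.
#' @param noise_sd Gaussian noise standard deviation (same units).
#' @param seed Integer seed; the result is reproducible.
#' @return An [intensity_volume()].
#' @export
generate_intensity <- function(vol, class_means, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(vol, "label_volume"), noise_sd >= 0)
  missing <- setdiff(names(vol$label_map), names(class_means))
  if (length(missing))
    stop("generate_intensity: missing class mean for role(s): ",
         paste(missing, collapse = ", "), " (configuration error)")
  lut <- stats::setNames(as.numeric(class_means[names(vol$label_map)]),
                         as.character(unname(vol$label_map)))
  vals <- lut[as.character(as.vector(vol$labels))]
  if (noise_sd > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
    vals <- vals + stats::rnorm(length(vals), sd = noise_sd)
  }
  intensity_volume(array(vals, dim = vol$grid$shape), vol$grid)
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a paired segmentation dataset of tibial phantoms
#'
#' Produces `n` subject volumes on a fixed grid with per-subject jittered
#' geometry (plateau semi-axes, cartilage thickness, meniscal radii and
#' extrusion offset) plus matched intensity volumes, as training/test data
#' for the segmentation network and the hold-out validation harness.
#'
#' @param n Number of subjects.
#' @param seed Integer seed controlling both geometry jitter and noise.
#' @param grid_shape Fixed grid shape, default `c(32, 32, 32)` (divisible by
#'   8 as the 4-block encoder requires).
#' @param spacing_mm Voxel spacing, default 1 mm isotropic.
#' @param class_means Named means handed to [generate_intensity()].
#' @param noise_sd Intensity noise SD, default 10 (well below the class
#'   separation of 60).
#' @return List of `n` elements, each `list(intensity, labels, spec)`.
#' @export
generate_segmentation_dataset <- function(n, seed = 1L,
                                          grid_shape = c(32, 32, 32),
                                          spacing_mm = c(1, 1, 1),
                                          class_means = c(background = 0, tibia = 60,
                                                          tibial_cartilage = 120,
                                                          medial_meniscus = 180),
                                          noise_sd = 10) {
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n)
  # geometry scales with the grid extent so small grids stay valid
  sc <- min(grid_shape * spacing_mm) / 32
  lapply(seq_len(n), function(i) {
    set.seed(sub_seeds[i])
    jit <- stats::runif(6)
    spec <- tibial_phantom_spec(
      plateau_semi_axes_mm = sc * c(9 + 2 * jit[1], 6 + 2 * jit[2]),
      bone_depth_mm = sc * 6,
      cartilage_profile = thickness_profile("constant", sc * (2 + jit[3])),
      coverage_fraction = 0.8 + 0.2 * jit[4],
      meniscus_inner_radius_mm = sc * (4.5 + jit[5]),
      meniscus_outer_radius_mm = sc * (8.5 + jit[5]),
      meniscus_angular_extent_deg = 200,
      meniscus_height_mm = sc * 3,
      extrusion_offset_mm = sc * 2 * jit[6],
      spacing_mm = spacing_mm, grid_shape = grid_shape,
      seed = sub_seeds[i])
    ph <- generate_tibial_phantom(spec, oracle_res_mm = 0.05)
    list(intensity = generate_intensity(ph$volume, class_means, noise_sd,
                                        seed = sub_seeds[i] %% 100000L + i),
         labels = ph$volume, spec = spec)
  })
}

#' Specification of a synthetic measurement cohort
#'
#' Describes a cohort of subjects whose per-subject morphometry measurements
#' carry planted Spearman rank correlations with body height, realised
#' through a one-factor Gaussian copula.
#'
#' @param n_subjects Number of subjects (`>= 3`).
#' @param height_mean_cm,height_sd_cm Height marginal (cm).
#' @param target_rs Named numeric vector of planted Spearman correlations
#'   with height, one per measurement, all in `(-1, 1)`.
#' @param marginals Data frame with columns `name`, `mean`, `sd` giving each
#'   measurement's Gaussian marginal; defaults to mean 0, sd 1 for any
#'   measurement not listed.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, height_mean_cm = 163, height_sd_cm = 8,
                        target_rs, marginals = NULL, seed = 1L) {
  if (n_subjects < 3) stop("cohort_spec: n_subjects must be >= 3")
  if (is.null(names(target_rs)) || any(!nzchar(names(target_rs))))
    stop("cohort_spec: target_rs must be a named vector")
  if (any(abs(target_rs) >= 1))
    stop("cohort_spec: |target_rs| must be < 1 (configuration error)")
  structure(list(n_subjects = as.integer(n_subjects),
                 height_mean_cm = height_mean_cm, height_sd_cm = height_sd_cm,
                 target_rs = target_rs, marginals = marginals,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic measurement cohort
#'
#' Samples the cohort described by a [cohort_spec()]. Latent Gaussian
#' factors follow a one-factor copula: the latent Pearson correlation
#' between height and measurement m is `rho = 2*sin(pi*rs/6)`, the exact
#' inversion of the Spearman correlation of a bivariate Gaussian, so the
#' planted rank correlations are attained in expectation. Marginals are
#' Gaussian; rank correlations are invariant to these monotone transforms.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame: `subject_id`, `height_cm`, one column per measurement.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  rs <- spec$target_rs
  rho <- 2 * sin(pi * rs / 6)
  m <- length(rho)
  sigma <- diag(m + 1)
  sigma[1, -1] <- rho; sigma[-1, 1] <- rho
  for (i in seq_len(m)) for (j in seq_len(m))
    if (i != j) sigma[i + 1, j + 1] <- rho[i] * rho[j]
  ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
  if (!ok) stop("generate_cohort: correlation structure is not positive definite (configuration error)")
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_subjects
  z0 <- stats::rnorm(n)
  out <- data.frame(subject_id = seq_len(n),
                    height_cm = spec$height_mean_cm + spec$height_sd_cm * z0)
  for (i in seq_len(m)) {
    zi <- rho[i] * z0 + sqrt(1 - rho[i]^2) * stats::rnorm(n)
    nm <- names(rs)[i]
    mu <- 0; sd <- 1
    if (!is.null(spec$marginals) && nm %in% spec$marginals$name) {
      row <- spec$marginals[spec$marginals$name == nm, ][1, ]
      mu <- row$mean; sd <- row$sd
    }
    out[[nm]] <- mu + sd * zi
  }
  out
}
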