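test_that("tibial phantom truths follow from the constructed geometry", {
  full <- generate_tibial_phantom(
    coarse_tibial(coverage_fraction = 1,
                  cartilage_profile = thickness_profile("constant", 2)),
    oracle_res_mm = 0.05)
  expect_equal(unname(full$truth$pcar_by_threshold), rep(1, 4), tolerance = 1e-3)
  expect_equal(full$truth$thc_mm, 2, tolerance = 1e-6)
  expect_equal(full$truth$vc_mm3, pi * 16 * 11 * 2, tolerance = 1e-3)

  half <- generate_tibial_phantom(
    coarse_tibial(coverage_fraction = 0.5,
                  cartilage_profile = thickness_profile("constant", 1.2)),
    oracle_res_mm = 0.05)
  pc <- half$truth$pcar_by_threshold
  expect_equal(unname(pc[1:3]), rep(0.5, 3), tolerance = 1e-3)
  expect_identical(unname(pc[4]), 0)    # 1.2 mm plate has nothing above 1.5 mm

  labs <- half$volume$labels
  expect_setequal(sort(unique(as.vector(labs))), 0:3)
})

test_that("disjoint meniscus gives MMCR 0 and full extruded wedge area", {
  ph <- generate_tibial_phantom(coarse_tibial(extrusion_offset_mm = 32),
                                oracle_res_mm = 0.05)
  wedge <- (200 / 2 * pi / 180) * (14^2 - 9^2)
  expect_identical(ph$truth$mmcr, 0)
  expect_equal(ph$truth$mme_area_mm2, wedge, tolerance = 1e-6)
  expect_equal(ph$truth$mme_volume_mm3, wedge * 4, tolerance = 1e-6)
})

test_that("phantom truth respects PCAR monotonicity and area decomposition", {
  for (seed in 1:4) {
    set.seed(seed)
    ph <- generate_tibial_phantom(
      coarse_tibial(coverage_fraction = runif(1, 0.3, 1),
                    cartilage_profile = thickness_profile("radial",
                                                          from = runif(1, 1, 3),
                                                          to = runif(1, 0, 1)),
                    extrusion_offset_mm = runif(1, 0, 4)),
      oracle_res_mm = 0.05)
    expect_true(all(diff(ph$truth$pcar_by_threshold) <= 1e-12))
    expect_true(all(ph$truth$pcar_by_threshold >= 0 &
                      ph$truth$pcar_by_threshold <= 1))
    expect_true(ph$truth$mmcr >= 0 && ph$truth$mmcr <= 1)
    # footprint = overlap + extruded parts, exactly
    expect_equal(ph$truth$overlap_area_mm2 + ph$truth$mme_area_mm2,
                 ph$truth$meniscus_footprint_area_mm2, tolerance = 1e-9)
  }
})

test_that("voxelized cartilage volume converges to the analytic volume", {
  errs <- vapply(c(1.2, 0.6, 0.3), function(h) {
    ph <- generate_tibial_phantom(
      tibial_phantom_spec(spacing_mm = rep(h, 3)), oracle_res_mm = 0.05)
    abs(sum(ph$volume$labels == 2L) * h^3 - ph$truth$vc_mm3)
  }, numeric(1))
  expect_lt(errs[2], 0.55 * errs[1])
  expect_lt(errs[3], 0.55 * errs[2])
})

test_that("femoral phantom: shell truth and recorded axis", {
  fp <- fixture_femoral()
  tr <- fp$truth
  expect_equal(tr$thc_mm, 2)
  expect_equal(unname(tr$pcar_by_threshold), c(1, 1, 1, 1))
  expect_equal(tr$vc_mm3, 0.5 * pi * (20^2 - 18^2) * 24, tolerance = 1e-6)
  expect_equal(tr$cylinder_axis$direction, c(1, 0, 0))
  half_cov <- generate_femoral_phantom(
    femoral_phantom_spec(coverage_fraction = 0.5, spacing_mm = rep(0.6, 3)))
  expect_equal(unname(half_cov$truth$pcar_by_threshold), rep(0.5, 4))
})

test_that("intensity synthesis: exact means, reproducibility, noise scale", {
  ph <- fixture_tibial()
  means <- c(background = 0, tibia = 60, tibial_cartilage = 120,
             medial_meniscus = 180)
  clean <- generate_intensity(ph$volume, means, noise_sd = 0)
  expect_identical(unique(as.vector(clean$values[ph$volume$labels == 1L])), 60)
  expect_identical(unique(as.vector(clean$values[ph$volume$labels == 0L])), 0)

  a <- generate_intensity(ph$volume, means, noise_sd = 10, seed = 42)
  b <- generate_intensity(ph$volume, means, noise_sd = 10, seed = 42)
  expect_identical(a$values, b$values)
  c2 <- generate_intensity(ph$volume, means, noise_sd = 10, seed = 43)
  expect_false(identical(a$values, c2$values))

  bg <- a$values[ph$volume$labels == 0L]
  expect_gt(length(bg), 1e4)
  expect_lt(abs(stats::sd(bg) - 10) / 10, 0.05)

  expect_error(generate_intensity(ph$volume, means[-2], 1), "configuration error")
})

test_that("cohort generator plants Spearman correlations via the copula", {
  sp <- cohort_spec(5000, target_rs = c(VC = 0.4, PCAR = 0), seed = 9)
  co <- generate_cohort(sp)
  expect_identical(nrow(co), 5000L)
  expect_lt(abs(cor(co$height_cm, co$VC, method = "spearman") - 0.4), 0.03)
  expect_lt(abs(cor(co$height_cm, co$PCAR, method = "spearman")), 0.03)
  # reproducible and boundary n
  expect_identical(generate_cohort(sp), generate_cohort(sp))
  expect_identical(nrow(generate_cohort(
    cohort_spec(3, target_rs = c(VC = 0.4), seed = 1))), 3L)
  expect_error(cohort_spec(2, target_rs = c(VC = 0.4)), "n_subjects")
  expect_error(cohort_spec(10, target_rs = c(VC = 1)), "< 1")
})

test_that("marginals are honoured by the cohort generator", {
  sp <- cohort_spec(4000, target_rs = c(VC = 0.3),
                    marginals = data.frame(name = "VC", mean = 2000, sd = 250),
                    seed = 2)
  co <- generate_cohort(sp)
  expect_lt(abs(mean(co$VC) - 2000), 15)
  expect_lt(abs(stats::sd(co$VC) - 250), 10)
})

test_that("fixed-grid phantom generation rejects oversize geometry", {
  expect_error(generate_tibial_phantom(
    tibial_phantom_spec(plateau_semi_axes_mm = c(30, 20),
                        spacing_mm = c(1, 1, 1), grid_shape = c(32, 32, 32))),
    "geometry error")
})
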