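# Shared fixtures, built once per test run. Coarse voxel spacing keeps unit
# tests fast; acceptance tests regenerate at the spacings they state.

.fixture_env <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

coarse_tibial <- function(...) {
  tibial_phantom_spec(spacing_mm = c(0.6, 0.6, 0.6), ...)
}

fixture_tibial <- function() {
  fixture("tibial_default", function()
    generate_tibial_phantom(coarse_tibial(), oracle_res_mm = 0.02))
}

fixture_femoral <- function() {
  fixture("femoral_default", function()
    generate_femoral_phantom(femoral_phantom_spec(spacing_mm = c(0.4, 0.4, 0.4))))
}

random_label_volume <- function(shape = c(6, 6, 6), n_classes = 2, seed = 1) {
  set.seed(seed)
  lm <- c(background = 0L, tibia = 1L, tibial_cartilage = 2L,
          medial_meniscus = 3L)[seq_len(n_classes + 1)]
  label_volume(array(sample(0:n_classes, prod(shape), TRUE), dim = shape),
               voxel_grid(shape, c(1, 1, 1)), lm)
}

# random blob-shaped 2D ROI on a small grid (always non-empty, >= 3x3 bbox)
random_roi <- function(seed, dim = c(24, 20)) {
  set.seed(seed)
  frame <- kneemorph:::.planar_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                     c(0, 0, 1), 1, 1, 0, 0, dim[1], dim[2])
  cx <- runif(1, 8, dim[1] - 8); cy <- runif(1, 8, dim[2] - 8)
  rx <- runif(1, 4, 7); ry <- runif(1, 4, 7)
  xg <- matrix(seq_len(dim[1]), dim[1], dim[2])
  yg <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  mask <- ((xg - cx) / rx)^2 + ((yg - cy) / ry)^2 <= 1
  extra <- matrix(runif(prod(dim)) < 0.05, dim[1], dim[2])
  mask <- mask | (extra & ((xg - cx)^2 + (yg - cy)^2 <= (rx + 3)^2))
  kneemorph:::.roi_mask(frame, mask, "MT")
}

random_thickness_map <- function(roi, seed) {
  set.seed(seed)
  thick <- matrix(0, nrow(roi$mask), ncol(roi$mask))
  v <- runif(sum(roi$mask), 0, 3)
  v[runif(length(v)) < 0.3] <- 0
  thick[roi$mask] <- v
  kneemorph:::.thickness_map(roi, thick)
}
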