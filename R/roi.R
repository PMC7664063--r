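# Projection frames, bone-derived ROIs, and 3x3 subdivision.

.unit <- function(v) v / sqrt(sum(v^2))

#' Planar projection frame
#'
#' A 2D grid on a plane: `origin` is a point on the plane, `e1`/`e2` an
#' orthonormal in-plane basis (e1 along ML, e2 along AP for the canonical
#' tibial frame), `normal` the projection direction (SI). Cell centres are
#' at `origin + (u0 + (i-1)*du)*e1 + (v0 + (j-1)*dv)*e2`.
#'
#' @keywords internal
.planar_frame <- function(origin, e1, e2, normal, du, dv, u0, v0, nu, nv) {
  stopifnot(abs(sum(e1 * e2)) < 1e-9, abs(sum(e1 * normal)) < 1e-9,
            abs(sqrt(sum(e1^2)) - 1) < 1e-9, abs(sqrt(sum(normal^2)) - 1) < 1e-9)
  structure(list(kind = "planar", origin = origin, e1 = e1, e2 = e2,
                 normal = normal, cell_size_mm = c(du, dv),
                 u0 = u0, v0 = v0, grid_dim = c(nu, nv)),
            class = "projection_frame")
}

.cylindrical_frame <- function(axis_origin, axis_dir, u_ref, w_ref, r_ref,
                               dtheta, ds, s0, ntheta, ns) {
  stopifnot(abs(sqrt(sum(axis_dir^2)) - 1) < 1e-9)
  structure(list(kind = "cylindrical", origin = axis_origin, axis = axis_dir,
                 u_ref = u_ref, w_ref = w_ref, r_ref = r_ref,
                 cell_size_mm = c(r_ref * dtheta, ds),
                 dtheta = dtheta, ds = ds, theta0 = -pi, s0 = s0,
                 grid_dim = c(ntheta, ns)),
            class = "projection_frame")
}

#' @export
print.projection_frame <- function(x, ...) {
  if (x$kind == "planar")
    cat(sprintf("planar projection_frame: origin (%s), normal (%s), grid %dx%d, cell %s mm\n",
                paste(signif(x$origin, 4), collapse = ", "),
                paste(signif(x$normal, 4), collapse = ", "),
                x$grid_dim[1], x$grid_dim[2],
                paste(signif(x$cell_size_mm, 4), collapse = " x ")))
  else
    cat(sprintf("cylindrical projection_frame: axis dir (%s), r_ref %.3g mm, grid %dx%d (theta x axial)\n",
                paste(signif(x$axis, 4), collapse = ", "), x$r_ref,
                x$grid_dim[1], x$grid_dim[2]))
  invisible(x)
}

# in-plane coordinates of points (n x 3 mm) in a planar frame
.frame_uv <- function(frame, pts) {
  rel <- sweep(pts, 2, frame$origin)
  cbind(rel %*% frame$e1, rel %*% frame$e2)
}

# cell index pair (possibly outside grid) for planar frame coordinates
.uv_to_cell <- function(frame, uv) {
  cbind(round((uv[, 1] - frame$u0) / frame$cell_size_mm[1]) + 1,
        round((uv[, 2] - frame$v0) / frame$cell_size_mm[2]) + 1)
}

# Top-of-bone (plateau) surface voxels: for each (i,j) column containing the
# role, the maximal k. Returns mm coordinates (n x 3) and index triples.
.plateau_surface <- function(vol, role = "tibia") {
  mask <- .role_mask(vol, role)
  if (!any(mask)) stop("estimate_tibial_frame: ", role,
                       " label is empty (structure-missing error)")
  d <- dim(mask)
  flat <- matrix(mask, d[1] * d[2], d[3])
  any_col <- rowSums(flat) > 0
  ktop <- max.col(flat[any_col, , drop = FALSE] *
                    rep(seq_len(d[3]), each = sum(any_col)), ties.method = "last")
  ij <- which(matrix(any_col, d[1], d[2]), arr.ind = TRUE)
  cs <- .axis_coords(vol$grid)
  pts <- cbind(cs[[1]][ij[, 1]], cs[[2]][ij[, 2]], cs[[3]][ktop])
  list(pts = pts, ij = ij, ktop = ktop)
}

#' Estimate the tibial plateau projection frame
#'
#' Builds the planar frame used for the vertical projection of tibial
#' cartilage. The plateau surface is taken as the topmost (most superior)
#' tibial bone voxel in each (i, j) column; the frame origin is the centroid
#' of these surface voxels. With `method = "axis_aligned"` (default) the
#' normal is the canonical superoinferior axis, which matches axis-aligned
#' phantoms and keeps projected cells exactly aligned with voxel columns;
#' `method = "plane_fit"` least-squares fits a plane to the surface voxels
#' (needed for tilted anatomy).
#'
#' @param vol A [label_volume()] containing a `tibia` label.
#' @param method `"axis_aligned"` or `"plane_fit"`.
#' @param cell_size_mm Projection cell size; default the in-plane voxel
#'   spacing (no information is lost and area identities stay exact).
#' @return A planar `projection_frame` covering the full volume footprint.
#' @export
estimate_tibial_frame <- function(vol, method = c("axis_aligned", "plane_fit"),
                                  cell_size_mm = NULL) {
  method <- match.arg(method)
  surf <- .plateau_surface(vol, "tibia")
  origin <- colMeans(surf$pts)
  if (method == "axis_aligned") {
    normal <- c(0, 0, 1)
  } else {
    xy <- cbind(1, surf$pts[, 1] - origin[1], surf$pts[, 2] - origin[2])
    cf <- stats::lm.fit(xy, surf$pts[, 3])$coefficients
    normal <- .unit(c(-cf[2], -cf[3], 1))
  }
  e1 <- .unit(c(1, 0, 0) - sum(c(1, 0, 0) * normal) * normal)
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  sp <- vol$grid$spacing_mm
  if (is.null(cell_size_mm)) {
    du <- if (method == "axis_aligned") sp[1] else mean(sp[1:2])
    dv <- if (method == "axis_aligned") sp[2] else mean(sp[1:2])
  } else { du <- dv <- cell_size_mm }
  # grid window: cover the projection of the full volume
  cs <- .axis_coords(vol$grid)
  corners <- as.matrix(expand.grid(range(cs[[1]]), range(cs[[2]]), range(cs[[3]])))
  frame0 <- .planar_frame(origin, e1, e2, normal, du, dv, 0, 0, 1, 1)
  uv <- .frame_uv(frame0, corners)
  if (method == "axis_aligned") {
    # snap cell centres onto voxel column centres
    u0 <- cs[[1]][1] - origin[1]; v0 <- cs[[2]][1] - origin[2]
    nu <- vol$grid$shape[1]; nv <- vol$grid$shape[2]
  } else {
    u0 <- min(uv[, 1]); v0 <- min(uv[, 2])
    nu <- ceiling((max(uv[, 1]) - u0) / du) + 1
    nv <- ceiling((max(uv[, 2]) - v0) / dv) + 1
  }
  .planar_frame(origin, e1, e2, normal, du, dv, u0, v0, nu, nv)
}

#' 2D region-of-interest mask on a projection grid
#' @keywords internal
.roi_mask <- function(frame, mask, region) {
  if (!any(mask)) stop("ROI '", region, "' is empty (structure-missing error)")
  structure(list(frame = frame, mask = mask, region = region,
                 cell_area_mm2 = prod(frame$cell_size_mm)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask %s: %d cells, area %.4g mm^2 (cell %.4g mm^2)\n",
              x$region, sum(x$mask), sum(x$mask) * x$cell_area_mm2,
              x$cell_area_mm2))
  invisible(x)
}

#' Area of a 2D ROI
#' @param roi A `roi_mask`.
#' @return Included-cell count times cell area (mm^2) - an exact identity.
#' @export
roi_area <- function(roi) sum(roi$mask) * roi$cell_area_mm2

.close_mask <- function(mask) {
  k <- EBImage::makeBrush(3, "box")
  EBImage::closing(mask * 1, k) > 0.5
}

#' Build medial and lateral tibial plateau ROIs
#'
#' Projects the tibial plateau surface voxels onto the frame grid to form
#' the plateau footprint, closes small gaps morphologically, and splits the
#' footprint into medial (MT) and lateral (LT) compartment ROIs. When the
#' footprint has two connected components the two largest are used and the
#' component whose centroid lies at lower ML coordinate is called medial
#' (the canonical convention for a right knee with i increasing laterally);
#' a single-component footprint is returned as MT alone with a warning,
#' since a missing lateral compartment is a data property, not a failure.
#'
#' @param vol A [label_volume()] with a `tibia` label.
#' @param frame Planar frame from [estimate_tibial_frame()] on the same grid.
#' @return List with elements `MT` and `LT` (`roi_mask` or `NULL`).
#' @export
build_tibial_rois <- function(vol, frame) {
  if (frame$kind != "planar") stop("build_tibial_rois: planar frame required (frame-kind error)")
  surf <- .plateau_surface(vol, "tibia")
  cells <- .uv_to_cell(frame, .frame_uv(frame, surf$pts))
  keep <- cells[, 1] >= 1 & cells[, 1] <= frame$grid_dim[1] &
    cells[, 2] >= 1 & cells[, 2] <= frame$grid_dim[2]
  mask <- matrix(FALSE, frame$grid_dim[1], frame$grid_dim[2])
  mask[cells[keep, , drop = FALSE]] <- TRUE
  mask <- .close_mask(mask)
  comp <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(comp[comp > 0])
  ord <- order(sizes, decreasing = TRUE)
  if (length(sizes) >= 2 && sizes[ord[2]] >= 0.1 * sizes[ord[1]]) {
    m1 <- comp == ord[1]; m2 <- comp == ord[2]
    cx1 <- mean(which(rowSums(m1) > 0)); cx2 <- mean(which(rowSums(m2) > 0))
    if (cx1 <= cx2) { mt <- m1; lt <- m2 } else { mt <- m2; lt <- m1 }
    list(MT = .roi_mask(frame, mt, "MT"), LT = .roi_mask(frame, lt, "LT"))
  } else {
    warning("build_tibial_rois: single plateau component; lateral compartment missing")
    list(MT = .roi_mask(frame, comp == ord[1], "MT"), LT = NULL)
  }
}

# Boundary voxels of a 3D mask (voxels with at least one 6-neighbour
# outside the mask or on the array edge).
.mask_boundary <- function(mask) {
  d <- dim(mask)
  interior <- mask
  shift_and <- function(m, axis, by) {
    out <- array(FALSE, dim(m))
    idx_src <- lapply(dim(m), seq_len)
    idx_dst <- idx_src
    n <- dim(m)[axis]
    if (by == 1) { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
    else { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (axis in 1:3) for (by in c(1, -1))
    interior <- interior & shift_and(mask, axis, by)
  mask & !interior
}

# Surface voxels of the femur as the outermost-radius voxel per (theta, s)
# bin about a given axis. Returns mm points and their (theta, s, rho).
.condylar_surface <- function(pts, axis_origin, axis_dir, u, w,
                              ntheta = 72, ds = 1.5) {
  rel <- sweep(pts, 2, axis_origin)
  s <- as.vector(rel %*% axis_dir)
  rad <- rel - outer(s, axis_dir)
  rho <- sqrt(rowSums(rad^2))
  th <- atan2(rad %*% w, rad %*% u)
  tb <- pmin(floor((th + pi) / (2 * pi / ntheta)), ntheta - 1)
  sb <- floor((s - min(s)) / ds)
  bin <- interaction(tb, sb, drop = TRUE)
  idx <- vapply(split(seq_along(s), bin), function(ii) ii[which.max(rho[ii])], 1L)
  list(pts = pts[idx, , drop = FALSE], s = s[idx], theta = th[idx], rho = rho[idx])
}

#' Fit the femoral condylar cylinder axis
#'
#' Estimates the cylinder used for the cylindrical unwrapping of femoral
#' cartilage. The axis is initialised at the principal (mediolateral) axis
#' of the femur mask, condylar surface voxels are extracted as the
#' outermost-radius voxel per (theta, axial) bin, and the axis (2 direction
#' + 2 position parameters) is refined by minimising the summed squared
#' radial residuals about the mean radius (a circle has constant radius
#' from its axis). Deterministic: no randomness anywhere.
#'
#' @param vol A [label_volume()] with a `femur` label.
#' @param cell_size_mm Unwrapped grid cell size; default ML voxel spacing.
#' @return A cylindrical `projection_frame`; its `r_ref` is the mean fitted
#'   surface radius.
#' @export
fit_femoral_cylinder <- function(vol, cell_size_mm = NULL) {
  mask <- .role_mask(vol, "femur")
  if (!any(mask)) stop("fit_femoral_cylinder: femur label is empty (structure-missing error)")
  cs <- .axis_coords(vol$grid)
  idx <- which(.mask_boundary(mask), arr.ind = TRUE)
  if (nrow(idx) > 8000) idx <- idx[seq(1, nrow(idx), length.out = 8000), ]
  pts <- cbind(cs[[1]][idx[, 1]], cs[[2]][idx[, 2]], cs[[3]][idx[, 3]])
  ctr <- colMeans(pts)
  pc <- eigen(stats::cov(pts), symmetric = TRUE)
  # initialize from the principal axis closest to the mediolateral direction
  dir0 <- pc$vectors[, which.max(abs(pc$vectors[1, ]))]
  if (dir0[1] < 0) dir0 <- -dir0
  if (nrow(pts) < 20 || pc$values[2] < 1e-9 || abs(dir0[1]) < 0.3)
    stop("fit_femoral_cylinder: degenerate femur geometry (fit error)")
  # Fit in two stages. Stage 1 uses the superior condylar surface (topmost
  # boundary voxel per (i, j) column), which excludes the flat sector faces
  # that otherwise contaminate the radius statistics: a Kasa algebraic
  # circle fit in the plane normal to the initial direction seeds the
  # centre, then BFGS refines (centre, direction) by minimising the radial
  # variance. Stage 2 re-extracts the outermost-radius-per-bin surface
  # about the fitted axis (from which flat faces project onto the rim) and
  # refits once.
  top <- .plateau_surface(vol, "femur")
  fit_points <- function(sp_pts, d, o) {
    objective <- function(p) {
      dd <- .unit(c(1, p[3], p[4]))
      oo <- c(ctr[1], p[1], p[2])
      rel <- sweep(sp_pts, 2, oo)
      s <- as.vector(rel %*% dd)
      rad <- rel - outer(s, dd)
      rho <- sqrt(rowSums(rad^2))
      sum((rho - mean(rho))^2)
    }
    u <- .unit(c(0, 0, 1) - d[3] * d)
    w <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
           d[1] * u[2] - d[2] * u[1])
    rel0 <- sweep(sp_pts, 2, o)
    yz0 <- cbind(rel0 %*% u, rel0 %*% w)
    ka <- stats::lm.fit(cbind(2 * yz0, 1), rowSums(yz0^2))$coefficients
    centre0 <- o + ka[1] * u + ka[2] * w
    p0 <- c(centre0[2], centre0[3], d[2] / d[1], d[3] / d[1])
    # robust trim: drop points (cap faces, stray bins) whose radius about
    # the initial axis deviates from the median by more than 3 MAD
    rel <- sweep(sp_pts, 2, c(ctr[1], p0[1], p0[2]))
    dd0 <- .unit(c(1, p0[3], p0[4]))
    s <- as.vector(rel %*% dd0)
    rho <- sqrt(rowSums((rel - outer(s, dd0))^2))
    keep <- abs(rho - stats::median(rho)) <=
      max(3 * stats::mad(rho), 2 * max(vol$grid$spacing_mm))
    if (sum(keep) >= 20) sp_pts <- sp_pts[keep, , drop = FALSE]
    fit <- stats::optim(p0, objective, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-12))
    list(d = .unit(c(1, fit$par[3], fit$par[4])),
         o = c(ctr[1], fit$par[1], fit$par[2]))
  }
  st1 <- fit_points(top$pts, dir0, ctr)
  u <- .unit(c(0, 0, 1) - st1$d[3] * st1$d)
  w <- c(st1$d[2] * u[3] - st1$d[3] * u[2], st1$d[3] * u[1] - st1$d[1] * u[3],
         st1$d[1] * u[2] - st1$d[2] * u[1])
  surf2 <- .condylar_surface(pts, st1$o, st1$d, u, w)
  st2 <- fit_points(surf2$pts, st1$d, st1$o)
  d <- st2$d; o <- st2$o
  u <- .unit(c(0, 0, 1) - d[3] * d)
  w <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  surf <- .condylar_surface(pts, o, d, u, w)
  r_ref <- mean(surf$rho)
  cell <- if (is.null(cell_size_mm)) vol$grid$spacing_mm[1] else cell_size_mm
  dtheta <- cell / r_ref
  ntheta <- ceiling(2 * pi / dtheta)
  dtheta <- 2 * pi / ntheta
  rel <- sweep(pts, 2, o)
  s_all <- as.vector(rel %*% d)
  s0 <- min(s_all) - cell
  ns <- ceiling((max(s_all) + cell - s0) / cell) + 1
  .cylindrical_frame(o, d, u, w, r_ref, dtheta, cell, s0, ntheta, ns)
}

#' Build the femoral cartilage ROI on the unwrapped grid
#'
#' Unwraps the condylar surface onto the (theta, axial) grid of a
#' cylindrical frame: a cell is in the ROI iff it contains a femoral surface
#' voxel within 1.5 voxels of the reference radius (which excludes the flat
#' sector faces), followed by morphological closing. The footprint is then
#' split into three regions - MF, Trochlea, LF - by equal mediolateral
#' (axial) thirds of its extent, a geometric stand-in for anatomy-derived
#' region boundaries.
#'
#' @param vol A [label_volume()] with a `femur` label.
#' @param frame Cylindrical frame from [fit_femoral_cylinder()].
#' @return Named list of three `roi_mask` objects (`MF`, `Trochlea`, `LF`)
#'   sharing the frame grid.
#' @export
build_femoral_roi <- function(vol, frame) {
  if (frame$kind != "cylindrical")
    stop("build_femoral_roi: cylindrical frame required (frame-kind error)")
  mask <- .role_mask(vol, "femur")
  cs <- .axis_coords(vol$grid)
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind(cs[[1]][idx[, 1]], cs[[2]][idx[, 2]], cs[[3]][idx[, 3]])
  rel <- sweep(pts, 2, frame$origin)
  s <- as.vector(rel %*% frame$axis)
  rad <- rel - outer(s, frame$axis)
  rho <- sqrt(rowSums(rad^2))
  near <- rho >= frame$r_ref - 1.5 * max(vol$grid$spacing_mm)
  th <- atan2(rad[near, ] %*% frame$w_ref, rad[near, ] %*% frame$u_ref)
  tb <- pmin(floor((th + pi) / frame$dtheta), frame$grid_dim[1] - 1) + 1
  sb <- round((s[near] - frame$s0) / frame$ds) + 1
  keep <- sb >= 1 & sb <= frame$grid_dim[2]
  m <- matrix(FALSE, frame$grid_dim[1], frame$grid_dim[2])
  m[cbind(tb[keep], sb[keep])] <- TRUE
  m <- .close_mask(m)
  scols <- which(colSums(m) > 0)
  if (!length(scols)) stop("build_femoral_roi: empty footprint (structure-missing error)")
  lo <- min(scols); hi <- max(scols); n <- hi - lo + 1
  b1 <- lo + floor(n / 3) - 1; b2 <- lo + 2 * floor(n / 3) - 1
  thirds <- list(MF = lo:b1, Trochlea = (b1 + 1):b2, LF = (b2 + 1):hi)
  out <- lapply(names(thirds), function(nm) {
    mm <- m & col(m) %in% thirds[[nm]]
    .roi_mask(frame, mm, nm)
  })
  names(out) <- names(thirds)
  out
}

#' Partition an ROI into 3x3 subregions at equal intervals
#'
#' Cuts the ROI's tight bounding box in the 2D grid into thirds along both
#' axes at equal cell intervals; remainder rows/columns are assigned to the
#' last band, deterministically. Subregion indices run 1..9 row-major over
#' the 3x3 band grid, so index 5 is the middle-central subregion (mcMT for
#' the MT ROI). Every ROI cell receives exactly one index; cells outside
#' the ROI receive none.
#'
#' @param roi A `roi_mask`.
#' @return An object of class `region_partition`: the ROI plus an integer
#'   matrix `subregion` (NA outside the ROI).
#' @export
subdivide <- function(roi) {
  stopifnot(inherits(roi, "roi_mask"))
  rows <- which(rowSums(roi$mask) > 0)
  cols <- which(colSums(roi$mask) > 0)
  bb <- c(max(rows) - min(rows) + 1, max(cols) - min(cols) + 1)
  if (bb[1] < 3) stop("subdivide: ROI thinner than 3 cells along the first (ML/theta) axis (subdivision error)")
  if (bb[2] < 3) stop("subdivide: ROI thinner than 3 cells along the second (AP/axial) axis (subdivision error)")
  band <- function(offset, n) {
    w <- floor(n / 3)
    # bands of width w, w, n - 2w: remainder cells go to the last band
    cut <- c(w, 2 * w)
    b <- rep(3L, n)
    b[seq_len(cut[2])] <- 2L
    b[seq_len(cut[1])] <- 1L
    b
  }
  rb <- integer(nrow(roi$mask)); cb <- integer(ncol(roi$mask))
  rb[rows[1]:(rows[1] + bb[1] - 1)] <- band(0, bb[1])
  cb[cols[1]:(cols[1] + bb[2] - 1)] <- band(0, bb[2])
  sub <- matrix(NA_integer_, nrow(roi$mask), ncol(roi$mask))
  rmat <- matrix(rb, nrow(roi$mask), ncol(roi$mask))
  cmat <- matrix(cb, nrow(roi$mask), ncol(roi$mask), byrow = TRUE)
  inside <- roi$mask & rmat > 0 & cmat > 0
  sub[inside] <- 3L * (rmat[inside] - 1L) + cmat[inside]
  structure(list(roi = roi, subregion = sub), class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("region_partition of", x$roi$region, ":",
      paste(tabulate(x$subregion[!is.na(x$subregion)], 9), collapse = "/"),
      "cells per subregion\n")
  invisible(x)
}
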