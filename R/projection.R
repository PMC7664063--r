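# Projection of 3D structures onto 2D frames: thickness maps and footprints.

#' 2D thickness map aligned to an ROI
#' @keywords internal
.thickness_map <- function(roi, thickness) {
  stopifnot(all(dim(thickness) == dim(roi$mask)), all(thickness >= 0),
            all(is.finite(thickness)))
  structure(list(roi = roi, thickness_mm = thickness), class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  v <- x$thickness_mm[x$roi$mask]
  cat(sprintf("thickness_map on %s: %d ROI cells, covered %.1f%%, mean covered %.3g mm\n",
              x$roi$region, length(v), 100 * mean(v > 0),
              if (any(v > 0)) mean(v[v > 0]) else 0))
  invisible(x)
}

# TRUE when a planar frame is exactly aligned with the voxel lattice of g,
# with cells coincident with voxel columns (the lossless fast path).
.frame_axis_aligned <- function(frame, g) {
  frame$kind == "planar" &&
    all(abs(frame$normal - c(0, 0, 1)) < 1e-12) &&
    all(abs(frame$e1 - c(1, 0, 0)) < 1e-12) &&
    all(abs(frame$e2 - c(0, 1, 0)) < 1e-12) &&
    all(abs(frame$cell_size_mm - g$spacing_mm[1:2]) < 1e-9) &&
    identical(frame$grid_dim, g$shape[1:2]) &&
    abs(frame$origin[1] + frame$u0 - g$origin_mm[1]) < 1e-9 &&
    abs(frame$origin[2] + frame$v0 - g$origin_mm[2]) < 1e-9
}

#' Vertical (planar) cartilage thickness projection
#'
#' For every ROI cell, thickness is the total length of the structure
#' intersected by the ray through the cell centre along the frame normal;
#' disjoint segments along one ray are summed. On the canonical
#' axis-aligned tibial frame the ray through a cell is exactly a voxel
#' column and the intersection length is the in-structure voxel count times
#' the SI spacing (a continuous boundary-crossing length, since labeled
#' voxels are boxes). Tilted (plane-fit) frames use fixed-step ray marching
#' at a quarter of the smallest voxel spacing.
#'
#' This vertical projection is exactly the one that inflates the apparent
#' thickness of sloped cartilage by 1/cos(slope), which is why the femur
#' uses [project_cylindrical_thickness()] instead.
#'
#' @param vol A [label_volume()] containing `role`.
#' @param frame A planar `projection_frame` on the same grid.
#' @param roi A `roi_mask` on `frame`.
#' @param role Structure role to measure, default `"tibial_cartilage"`.
#' @return A `thickness_map`.
#' @export
project_planar_thickness <- function(vol, frame, roi, role = "tibial_cartilage") {
  if (frame$kind != "planar")
    stop("project_planar_thickness: planar frame required (frame-kind error)")
  mask <- .role_mask(vol, role)
  g <- vol$grid
  if (.frame_axis_aligned(frame, g)) {
    counts <- rowSums(matrix(mask, g$shape[1] * g$shape[2], g$shape[3]))
    thick <- matrix(counts * g$spacing_mm[3], g$shape[1], g$shape[2])
  } else {
    thick <- matrix(0, frame$grid_dim[1], frame$grid_dim[2])
    cells <- which(roi$mask, arr.ind = TRUE)
    if (nrow(cells)) {
      u <- frame$u0 + (cells[, 1] - 1) * frame$cell_size_mm[1]
      v <- frame$v0 + (cells[, 2] - 1) * frame$cell_size_mm[2]
      ctr <- t(frame$origin + outer(frame$e1, u) + outer(frame$e2, v))
      ext <- sum(g$shape * g$spacing_mm)
      starts <- ctr - ext * matrix(frame$normal, nrow(ctr), 3, byrow = TRUE)
      dirs <- matrix(frame$normal, nrow(ctr), 3, byrow = TRUE)
      step <- min(g$spacing_mm) / 4
      len <- ray_label_length(vol$labels, g$shape, g$spacing_mm, g$origin_mm,
                              vol$label_map[[role]], starts, dirs, step, 2 * ext)
      thick[cells] <- len
    }
  }
  .thickness_map(roi, thick)
}

#' Cylindrical cartilage thickness projection
#'
#' For every (theta, axial) cell of the unwrapped grid, thickness is the
#' radial extent of the structure along the ray from the cylinder axis
#' through the cell centre (outer minus inner crossing; disjoint runs
#' summed), measured by fixed-step marching at a quarter of the smallest
#' voxel spacing. Because the ray is radial, a shell of constant radial
#' thickness measures the same at every angle - the slope-inflation of a
#' vertical projection does not occur.
#'
#' @param vol A [label_volume()] containing `role`.
#' @param frame A cylindrical `projection_frame`.
#' @param roi A `roi_mask` on `frame`; thickness is evaluated on its cells.
#' @param role Structure role, default `"femoral_cartilage"`.
#' @return A `thickness_map`.
#' @export
project_cylindrical_thickness <- function(vol, frame, roi, role = "femoral_cartilage") {
  if (frame$kind != "cylindrical")
    stop("project_cylindrical_thickness: cylindrical frame required (frame-kind error)")
  mask_code <- vol$label_map[[.check_role(vol, role)]]
  g <- vol$grid
  thick <- matrix(0, frame$grid_dim[1], frame$grid_dim[2])
  cells <- which(roi$mask, arr.ind = TRUE)
  if (nrow(cells)) {
    theta <- frame$theta0 + (cells[, 1] - 0.5) * frame$dtheta
    s <- frame$s0 + (cells[, 2] - 1) * frame$ds
    raydir <- t(outer(frame$u_ref, cos(theta)) + outer(frame$w_ref, sin(theta)))
    starts <- t(frame$origin + outer(frame$axis, s))
    step <- min(g$spacing_mm) / 4
    rmax <- sqrt(sum((g$shape * g$spacing_mm)^2))
    len <- ray_label_length(vol$labels, g$shape, g$spacing_mm, g$origin_mm,
                            mask_code, starts, raydir, step, rmax)
    thick[cells] <- len
  }
  .thickness_map(roi, thick)
}

.check_role <- function(vol, role) {
  if (!role %in% names(vol$label_map))
    stop("structure role '", role, "' absent from label_map (structure-missing error)")
  role
}

#' Project a structure footprint onto a planar frame
#'
#' Marks every frame cell into which at least one voxel centre of the
#' structure projects, and accumulates per-cell column volume (voxel count
#' times voxel volume), so that the column-volume sum equals the structure's
#' voxel-counted volume exactly - the conservation identity used by the
#' meniscus extrusion metrics.
#'
#' @param vol A [label_volume()].
#' @param role Structure role (e.g. `"medial_meniscus"`).
#' @param frame A planar `projection_frame` whose window covers the volume.
#' @return An object of class `footprint2d`: `present` (logical matrix),
#'   `column_volume_mm3` (numeric matrix), `frame`, `cell_area_mm2`.
#' @export
project_footprint <- function(vol, role, frame) {
  if (frame$kind != "planar")
    stop("project_footprint: planar frame required (frame-kind error)")
  mask <- .role_mask(vol, role)
  g <- vol$grid
  colvol <- matrix(0, frame$grid_dim[1], frame$grid_dim[2])
  if (any(mask)) {
    cs <- .axis_coords(g)
    idx <- which(mask, arr.ind = TRUE)
    pts <- cbind(cs[[1]][idx[, 1]], cs[[2]][idx[, 2]], cs[[3]][idx[, 3]])
    cells <- .uv_to_cell(frame, .frame_uv(frame, pts))
    if (any(cells[, 1] < 1 | cells[, 1] > frame$grid_dim[1] |
            cells[, 2] < 1 | cells[, 2] > frame$grid_dim[2]))
      stop("project_footprint: structure projects outside the frame window")
    vv <- prod(g$spacing_mm)
    lin <- cells[, 1] + (cells[, 2] - 1L) * frame$grid_dim[1]
    counts <- tabulate(lin, nbins = prod(frame$grid_dim))
    colvol <- matrix(counts * vv, frame$grid_dim[1], frame$grid_dim[2])
  }
  structure(list(frame = frame, present = colvol > 0,
                 column_volume_mm3 = colvol,
                 cell_area_mm2 = prod(frame$cell_size_mm)),
            class = "footprint2d")
}

#' @export
print.footprint2d <- function(x, ...) {
  cat(sprintf("footprint2d: %d cells (%.4g mm^2), volume %.6g mm^3\n",
              sum(x$present), sum(x$present) * x$cell_area_mm2,
              sum(x$column_volume_mm3)))
  invisible(x)
}
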