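# Independent 2D indicator-integration oracle.
#
# Ground-truth areas and overlap fractions for the phantom geometry are
# computed here by dense midpoint integration of indicator functions on a
# fine in-plane grid, completely independently of the projection /
# morphometry pipeline those truths are later used to validate. Keep this
# file free of any pipeline code.

# Indicator of an axis-aligned ellipse centred at (cx, cy).
.ind_ellipse <- function(x, y, cx, cy, a, b) {
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

# Indicator of a C-shaped annular wedge: radii in [r_in, r_out], polar angle
# (about the shifted centre) within half_extent of the central angle.
.ind_annular_wedge <- function(x, y, cx, cy, r_in, r_out, angle_center, half_extent) {
  dx <- x - cx; dy <- y - cy
  r2 <- dx^2 + dy^2
  th <- atan2(dy, dx)
  d <- abs(((th - angle_center + pi) %% (2 * pi)) - pi)
  r2 >= r_in^2 & r2 <= r_out^2 & d <= half_extent
}

# Midpoint-rule integration of f(x, y) -> logical/numeric over a bounding
# box at resolution `res` mm. Returns the integral in mm^2 (logical f) or
# the integral of f dA. Evaluates in y-strips to bound memory.
.integrate2d <- function(f, xlim, ylim, res = 0.01) {
  xs <- seq(xlim[1] + res / 2, xlim[2], by = res)
  ys <- seq(ylim[1] + res / 2, ylim[2], by = res)
  total <- 0
  chunk <- max(1L, floor(4e6 / length(xs)))
  i <- 1L
  while (i <= length(ys)) {
    j <- min(i + chunk - 1L, length(ys))
    yy <- rep(ys[i:j], each = length(xs))
    xx <- rep(xs, times = j - i + 1L)
    total <- total + sum(as.numeric(f(xx, yy)))
    i <- j + 1L
  }
  total * res^2
}

# Overlap area (mm^2) between the plateau ellipse and the (possibly
# extruded) meniscal annular wedge, by indicator integration.
.oracle_wedge_ellipse_overlap <- function(cx_e, cy_e, a, b,
                                          cx_w, cy_w, r_in, r_out,
                                          angle_center, half_extent,
                                          res = 0.01) {
  xlim <- range(cx_e + c(-a, a), cx_w + c(-r_out, r_out))
  ylim <- range(cy_e + c(-b, b), cy_w + c(-r_out, r_out))
  .integrate2d(function(x, y)
    .ind_ellipse(x, y, cx_e, cy_e, a, b) &
      .ind_annular_wedge(x, y, cx_w, cy_w, r_in, r_out, angle_center, half_extent),
    xlim, ylim, res)
}

# Integrals of a thickness field t(x, y) over the covered part of an
# ellipse-footprint cartilage plate: returns covered area, mean covered
# thickness, volume, and the area with t > each threshold.
.oracle_thickness_integrals <- function(thickness_fun, cx, cy, a_cov, b_cov,
                                        thresholds, res = 0.01) {
  if (a_cov <= 0 || b_cov <= 0) {
    z <- stats::setNames(rep(0, length(thresholds)), format(thresholds))
    return(list(area = 0, thc = 0, vc = 0, area_gt = z))
  }
  xs <- seq(cx - a_cov + res / 2, cx + a_cov, by = res)
  ys <- seq(cy - b_cov + res / 2, cy + b_cov, by = res)
  area <- 0; vol <- 0
  area_gt <- stats::setNames(rep(0, length(thresholds)), format(thresholds))
  chunk <- max(1L, floor(4e6 / length(xs)))
  i <- 1L
  while (i <= length(ys)) {
    j <- min(i + chunk - 1L, length(ys))
    yy <- rep(ys[i:j], each = length(xs))
    xx <- rep(xs, times = j - i + 1L)
    inside <- .ind_ellipse(xx, yy, cx, cy, a_cov, b_cov)
    t <- ifelse(inside, thickness_fun(xx, yy), 0)
    covered <- t > 0
    area <- area + sum(covered)
    vol <- vol + sum(t)
    for (k in seq_along(thresholds))
      area_gt[k] <- area_gt[k] + sum(t > thresholds[k])
    i <- j + 1L
  }
  list(area = area * res^2,
       thc = if (area > 0) vol / area else 0,
       vc = vol * res^2,
       area_gt = area_gt * res^2)
}
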