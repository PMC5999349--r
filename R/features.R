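# Per-cell morphological features computed from a pixel contour.
# Unit convention: lengths in um (pixel coordinates scaled by pixel_size),
# areas in um^2, volumes in um^3; ratios dimensionless.

#' Projected cell area
#'
#' Shoelace area of the contour polygon, scaled to square micrometers.
#' The projected area defines the size of the cell.
#'
#' @param ct An [contour()] object.
#' @return Area in um^2.
#' @export
contour_area <- function(ct) {
  assert_contour(ct)
  xy <- contour_matrix(ct)
  assert_nondegenerate(xy)
  polygon_area(xy) * contour_pixel_size(ct)^2
}

#' Bounding-box extents
#'
#' Axis-aligned bounding box of the contour: `lx` along the flow direction
#' and `ly` orthogonal to it, in micrometers.
#'
#' @inheritParams contour_area
#' @return Named numeric vector `c(lx, ly)`.
#' @export
contour_bounding_box <- function(ct) {
  assert_contour(ct)
  ps <- contour_pixel_size(ct)
  c(lx = diff(range(ct$x)) * ps, ly = diff(range(ct$y)) * ps)
}

#' Circularity and deformation
#'
#' Circularity is `C = 2 * sqrt(pi * A) / l` where `A` is the contour area
#' and `l` the perimeter of the convex hull of the contour; deformation is
#' `D = 1 - C`. The hull perimeter is used because corrugated, non-convex
#' contours would otherwise inflate the perimeter and overestimate the
#' deformation. `C = 1` (and `D = 0`) for a circle.
#'
#' @inheritParams contour_area
#' @param use_hull Use the convex-hull perimeter (default, the standard
#'   definition). `FALSE` uses the raw contour perimeter, for comparison.
#' @return A list with `circularity`, `deformation` and `hull` (the convex
#'   hull as an [contour()] object).
#' @export
contour_deformation <- function(ct, use_hull = TRUE) {
  assert_contour(ct)
  xy <- contour_matrix(ct)
  assert_nondegenerate(xy)
  ps <- contour_pixel_size(ct)
  hull <- polygon_hull(xy)
  per <- polygon_perimeter(if (use_hull) hull else xy) * ps
  area <- polygon_area(xy) * ps^2
  circ <- 2 * sqrt(pi * area) / per
  list(circularity = circ, deformation = 1 - circ,
       hull = contour(hull[, 1L], hull[, 2L], pixel_size = ps,
                      id = attr(ct, "id")))
}

#' Cell volume under rotational symmetry
#'
#' Treats the central axis through the centroid along the flow direction as
#' an axis of rotational symmetry and revolves the contour around it. The
#' volume is computed twice -- once from the contour half below the axis and
#' once from the half above -- and the two estimates are averaged. Each half
#' is clipped to its side of the axis and its solid-of-revolution volume is
#' `2 * pi * |ybar| * A_half` (Pappus), which for the piecewise-linear
#' contour equals the exact frustum sum.
#'
#' @inheritParams contour_area
#' @return Volume in um^3.
#' @export
contour_volume <- function(ct) {
  assert_contour(ct)
  xy <- contour_matrix(ct)
  assert_nondegenerate(xy)
  ps <- contour_pixel_size(ct)
  cen <- polygon_centroid(xy)
  xy0 <- cbind(xy[, 1L] - cen[1L], xy[, 2L] - cen[2L])

  half_volume <- function(sgn) {
    # clip to { sgn * y >= 0 }
    clip <- polygon_clip_halfplane(xy0, c(0, 0), c(0, sgn))
    if (nrow(clip) < 3L) return(NA_real_)
    mom <- tryCatch(polygon_moments(clip), error = function(e) NULL)
    if (is.null(mom)) return(NA_real_)
    2 * pi * abs(mom$centroid[2L]) * mom$area
  }
  lower <- half_volume(-1)  # image y grows downward; sign is immaterial here
  upper <- half_volume(1)
  if (is.na(lower) && is.na(upper)) {
    stop("cannot compute volume: both contour halves are degenerate",
         call. = FALSE)
  }
  if (is.na(lower) || is.na(upper)) {
    warning("one contour half is degenerate; using a single-side volume estimate",
            call. = FALSE)
  }
  mean(c(lower, upper), na.rm = TRUE) * ps^3
}

#' Inertia ratio
#'
#' Ratio `I = Iyy / Ixx` of the axial second moments of the enclosed area
#' about the centroid. `I = 1` for a circle; elongation along the flow
#' direction increases `I`. Computed on the raw contour (no convex hull):
#' the area integral is robust to pixelation and small shape irregularities.
#'
#' @inheritParams contour_area
#' @return Dimensionless inertia ratio.
#' @export
contour_inertia_ratio <- function(ct) {
  assert_contour(ct)
  xy <- contour_matrix(ct)
  assert_nondegenerate(xy)
  mom <- polygon_moments(xy)
  if (mom$ixx <= 0) stop("degenerate contour: Ixx is zero", call. = FALSE)
  mom$iyy / mom$ixx
}

#' Principal-axis orientation
#'
#' Angle between the flow axis and the principal axes of the enclosed area,
#' from the second moments: `phi = 0.5 * atan2(2 * Mxy, Iyy - Ixx)` with
#' `Mxy` the product moment about the centroid, mapped to `(-pi/2, pi/2]`.
#' Isotropic shapes (circle, square) have no preferred axis and return 0.
#'
#' @inheritParams contour_area
#' @return Orientation in radians.
#' @export
contour_orientation <- function(ct) {
  assert_contour(ct)
  xy <- contour_matrix(ct)
  assert_nondegenerate(xy)
  mom <- polygon_moments(xy)
  num <- 2 * mom$mxy
  den <- mom$iyy - mom$ixx
  scale <- mom$ixx + mom$iyy
  if (abs(num) < 1e-12 * scale && abs(den) < 1e-12 * scale) return(0)
  phi <- 0.5 * atan2(num, den)
  if (phi <= -pi / 2) phi <- phi + pi
  if (phi > pi / 2) phi <- phi - pi
  phi
}

#' Area ratio (convexity gate)
#'
#' `Delta = A_hull / A_contour`, the convex-hull area over the contour area.
#' Equals 1 for convex contours and grows with corrugation. Events used for
#' elastic-modulus extraction are conventionally gated to
#' `1.0 <= Delta <= 1.05` because the underlying linear-elastic model only
#' produces convex shapes.
#'
#' @inheritParams contour_area
#' @return Dimensionless area ratio (>= 1 up to numerical tolerance).
#' @export
contour_area_ratio <- function(ct) {
  assert_contour(ct)
  xy <- contour_matrix(ct)
  assert_nondegenerate(xy)
  polygon_area(polygon_hull(xy)) / polygon_area(xy)
}

#' Symmetry ratios about the central axes
#'
#' Splits the contour by the axis through the centroid along the flow
#' direction and reports `sx = (A_upper - A_lower) / (A_upper + A_lower)`;
#' `sy` uses the orthogonal axis. Both lie in `[-1, 1]` and approach 0 for
#' mirror-symmetric shapes.
#'
#' @inheritParams contour_area
#' @return Named numeric vector `c(sx, sy)`.
#' @export
contour_symmetry <- function(ct) {
  assert_contour(ct)
  xy <- contour_matrix(ct)
  assert_nondegenerate(xy)
  cen <- polygon_centroid(xy)
  half_area <- function(nrm) {
    clip <- polygon_clip_halfplane(xy, cen, nrm)
    if (nrow(clip) < 3L) return(0)
    polygon_area(clip)
  }
  ratio <- function(a_up, a_lo) {
    tot <- a_up + a_lo
    if (tot <= 0) stop("symmetry split failed: zero total area", call. = FALSE)
    (a_up - a_lo) / tot
  }
  # split by the flow axis (y = cy): "upper" is smaller y (image convention)
  sx <- ratio(half_area(c(0, -1)), half_area(c(0, 1)))
  sy <- ratio(half_area(c(-1, 0)), half_area(c(1, 0)))
  c(sx = sx, sy = sy)
}

#' Equivalent spherical diameter
#'
#' Diameter of the circle with the same projected area,
#' `d = 2 * sqrt(A / pi)`, used to compare cluster mean areas with known
#' cell sizes.
#'
#' @param area Projected area(s) in um^2, positive.
#' @return Diameter(s) in um.
#' @examples
#' equivalent_diameter(174)  # ~14.9 um
#' @export
equivalent_diameter <- function(area) {
  if (!is.numeric(area) || any(!is.finite(area)) || any(area <= 0)) {
    stop("`area` must be positive and finite", call. = FALSE)
  }
  2 * sqrt(area / pi)
}

#' Extract the full per-event feature table
#'
#' Computes every contour feature (and, when image patches are supplied,
#' brightness and the 13 Haralick texture features) for a list of contours
#' and returns one row per event.
#'
#' @param contours A list of [contour()] objects (as from [read_contours()]).
#' @param patches Optional named list of image patches (see [image_patch()]);
#'   names are matched against contour ids.
#' @param n_levels Gray levels for the Haralick co-occurrence matrix.
#' @return A tibble with one row per event: `event`, `area`, `volume`,
#'   `lx`, `ly`, `circ`, `deform`, `inertia_ratio`, `orientation`,
#'   `area_ratio`, `sx`, `sy`, `d_eq`, and when patches are available
#'   `bright`, `bright_sd`, `haralick_01` .. `haralick_13`.
#' @export
extract_features <- function(contours, patches = NULL, n_levels = 16L) {
  if (is_contour(contours)) contours <- list(contours)
  rows <- purrr::map(contours, function(ct) {
    assert_contour(ct)
    bb <- contour_bounding_box(ct)
    def <- contour_deformation(ct)
    sym <- contour_symmetry(ct)
    area <- contour_area(ct)
    row <- tibble::tibble(
      event = attr(ct, "id"),
      area = area,
      volume = contour_volume(ct),
      lx = bb[["lx"]], ly = bb[["ly"]],
      circ = def$circularity, deform = def$deformation,
      inertia_ratio = contour_inertia_ratio(ct),
      orientation = contour_orientation(ct),
      area_ratio = contour_area_ratio(ct),
      sx = sym[["sx"]], sy = sym[["sy"]],
      d_eq = equivalent_diameter(area)
    )
    patch <- if (!is.null(patches)) patches[[attr(ct, "id")]] else NULL
    if (!is.null(patch)) {
      br <- patch_brightness(patch, ct)
      har <- patch_haralick(patch, ct, n_levels = n_levels)
      row$bright <- br[["mean"]]
      row$bright_sd <- br[["sd"]]
      hmat <- tibble::as_tibble(as.list(stats::setNames(
        har, sprintf("haralick_%02d", seq_along(har)))))
      row <- dplyr::bind_cols(row, hmat)
    }
    row
  })
  dplyr::bind_rows(rows)
}
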