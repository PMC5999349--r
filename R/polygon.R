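# Low-level polygon geometry on plain two-column matrices (x, y).
# All routines are internal; user-facing feature functions live in features.R.

# Signed shoelace area; positive for counter-clockwise vertex order.
polygon_signed_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(xy) abs(polygon_signed_area(xy))

polygon_perimeter <- function(xy) {
  d <- xy[c(seq_len(nrow(xy))[-1L], 1L), , drop = FALSE] - xy
  sum(sqrt(rowSums(d^2)))
}

polygon_centroid <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * max(1, sum(abs(xy)))) {
    # degenerate polygon: fall back to the vertex mean
    return(colMeans(xy))
  }
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Convex hull, counter-clockwise vertex order.
polygon_hull <- function(xy) {
  xy[rev(grDevices::chull(xy[, 1L], xy[, 2L])), , drop = FALSE]
}

# Axial second moments of the enclosed area about the centroid:
# Ixx = int y^2 dA, Iyy = int x^2 dA, Mxy = int x*y dA (product moment).
# Closed-form Green's-theorem sums over the vertex list; orientation-safe.
polygon_moments <- function(xy) {
  cen <- polygon_centroid(xy)
  x <- xy[, 1L] - cen[1L]; y <- xy[, 2L] - cen[2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  s <- sign(sum(cr))
  if (s == 0) stop("degenerate polygon: zero area", call. = FALSE)
  ixx <- s * sum((y^2 + y * yn + yn^2) * cr) / 12
  iyy <- s * sum((x^2 + x * xn + xn^2) * cr) / 12
  mxy <- s * sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  list(ixx = ixx, iyy = iyy, mxy = mxy, centroid = cen,
       area = abs(sum(cr)) / 2)
}

# Sutherland-Hodgman clip of a polygon against the half-plane
# {p : dot(p - p0, nrm) >= 0}. Returns a matrix (possibly 0 rows).
polygon_clip_halfplane <- function(xy, p0, nrm) {
  n <- nrow(xy)
  d <- (xy[, 1L] - p0[1L]) * nrm[1L] + (xy[, 2L] - p0[2L]) * nrm[2L]
  out_x <- numeric(0); out_y <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di >= 0) {
      out_x <- c(out_x, xy[i, 1L]); out_y <- c(out_y, xy[i, 2L])
    }
    if ((di > 0 && dj < 0) || (di < 0 && dj > 0)) {
      t <- di / (di - dj)
      out_x <- c(out_x, xy[i, 1L] + t * (xy[j, 1L] - xy[i, 1L]))
      out_y <- c(out_y, xy[i, 2L] + t * (xy[j, 2L] - xy[i, 2L]))
    }
  }
  cbind(x = out_x, y = out_y)
}

# Even-odd (ray casting) point-in-polygon test for pixel centers.
points_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (yn[i] > py))
    if (any(crosses)) {
      xint <- x[i] + (py[crosses] - y[i]) / (yn[i] - y[i]) * (xn[i] - x[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}
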