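# Shared fixtures and independent oracles, all built in code.

circle_contour <- function(r = 10, n = 360, center = c(0, 0),
                           pixel_size = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour(center[1] + r * cos(th), center[2] + r * sin(th),
          pixel_size = pixel_size)
}

ellipse_contour <- function(a = 8, b = 4, n = 720, angle = 0,
                            center = c(0, 0), pixel_size = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(th); y <- b * sin(th)
  xr <- x * cos(angle) - y * sin(angle)
  yr <- x * sin(angle) + y * cos(angle)
  contour(center[1] + xr, center[2] + yr, pixel_size = pixel_size)
}

square_contour <- function(side = 1, pixel_size = 1) {
  contour(c(0, side, side, 0), c(0, 0, side, side), pixel_size = pixel_size)
}

star_contour <- function(r = 10, n = 240, spikes = 5, depth = 0.5) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  rad <- r * (1 - depth / 2 * (1 + cos(spikes * th)))
  contour(rad * cos(th), rad * sin(th))
}

# independent shoelace oracle (direct formula, no package code)
shoelace_oracle <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  abs(s) / 2
}

# pixel-integration oracle for the axial/product second moments of a
# rasterized shape given a membership predicate
raster_moment_oracle <- function(inside_fun, lim = 12, step = 0.05) {
  g <- seq(-lim, lim, by = step)
  px <- rep(g, times = length(g))
  py <- rep(g, each = length(g))
  keep <- inside_fun(px, py)
  px <- px[keep]; py <- py[keep]
  cx <- mean(px); cy <- mean(py)
  da <- step^2
  list(ixx = sum((py - cy)^2) * da,
       iyy = sum((px - cx)^2) * da,
       mxy = sum((px - cx) * (py - cy)) * da)
}

# brute-force symmetric GLCM oracle: explicit loop over every pixel pair
glcm_oracle <- function(values, mask, n_levels = 16, max_value = 255) {
  lev <- pmin(floor(values / (max_value + 1) * n_levels) + 1, n_levels)
  nr <- nrow(values); nc <- ncol(values)
  cm <- matrix(0, n_levels, n_levels)
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (!mask[r, cc]) next
      for (off in offs) {
        r2 <- r + off[1]; c2 <- cc + off[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (!mask[r2, c2]) next
        cm[lev[r, cc], lev[r2, c2]] <- cm[lev[r, cc], lev[r2, c2]] + 1
        cm[lev[r2, c2], lev[r, cc]] <- cm[lev[r2, c2], lev[r, cc]] + 1
      }
    }
  }
  cm / sum(cm)
}
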