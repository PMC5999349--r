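# Geometric feature extraction from contours.

test_that("polygon area matches exact shapes and pixel scaling", {
  expect_equal(contour_area(square_contour(1)), 1.0)
  expect_equal(contour_area(circle_contour(10, n = 360)), pi * 100,
               tolerance = 1e-3)
  sq10 <- contour(c(0, 10, 10, 0), c(0, 0, 10, 10), pixel_size = 0.34)
  expect_equal(contour_area(sq10), 11.56, tolerance = 1e-12)
  # orientation of the vertex walk must not matter
  rev_sq <- contour(rev(c(0, 1, 1, 0)), rev(c(0, 0, 1, 1)))
  expect_equal(contour_area(rev_sq), 1.0)
})

test_that("area matches an independent shoelace oracle on irregular shapes", {
  set.seed(42)
  for (i in 1:5) {
    ct <- gen_contour("blob", r = 8, seed = i)
    expect_equal(contour_area(ct), shoelace_oracle(ct$x, ct$y),
                 tolerance = 1e-12)
  }
})

test_that("degenerate collinear contour errors", {
  ct <- contour(c(0, 1, 2), c(0, 1, 2))
  expect_error(contour_area(ct), "degenerate")
})

test_that("bounding box gives axis-aligned extents in um", {
  expect_equal(unname(contour_bounding_box(square_contour(1))), c(1, 1))
  ell <- ellipse_contour(a = 8, b = 4)
  bb <- contour_bounding_box(ell)
  expect_equal(unname(bb), c(16, 8), tolerance = 0.01)
  # rotating by 90 degrees swaps the extents
  ell90 <- ellipse_contour(a = 8, b = 4, angle = pi / 2)
  bb90 <- contour_bounding_box(ell90)
  expect_equal(bb90[["lx"]], bb[["ly"]], tolerance = 0.01)
  expect_equal(bb90[["ly"]], bb[["lx"]], tolerance = 0.01)
})

test_that("deformation is near zero for a circle and uses the hull perimeter", {
  d <- contour_deformation(circle_contour(10, n = 720))
  expect_lt(d$deformation, 1e-3)
  # dense-polygon perimeter oracle for an ellipse with a = 2b
  ell <- ellipse_contour(a = 8, b = 4, n = 2000)
  th <- seq(0, 2 * pi, length.out = 20001)
  per_oracle <- sum(sqrt(diff(8 * cos(th))^2 + diff(4 * sin(th))^2))
  c_oracle <- 2 * sqrt(pi * contour_area(ell)) / per_oracle
  expect_equal(contour_deformation(ell)$circularity, c_oracle,
               tolerance = 1e-3)
  # a star's hull-based deformation is below its raw-perimeter deformation
  star <- star_contour()
  expect_lt(contour_deformation(star)$deformation,
            contour_deformation(star, use_hull = FALSE)$deformation)
})

test_that("volume of revolution matches sphere and spheroid closed forms", {
  expect_equal(contour_volume(circle_contour(5, n = 360)), 4 / 3 * pi * 125,
               tolerance = 0.01)
  # spheroid: revolve ellipse with semi-axis a along the flow -> 4/3 pi a b^2
  ell <- ellipse_contour(a = 8, b = 4, n = 720)
  expect_equal(contour_volume(ell), 4 / 3 * pi * 8 * 16, tolerance = 0.01)
  # pixel size enters cubed
  small <- circle_contour(5, n = 360, pixel_size = 0.5)
  expect_equal(contour_volume(small), 4 / 3 * pi * 125 * 0.125,
               tolerance = 0.01)
})

test_that("volume error shrinks monotonically with vertex count", {
  truth <- 4 / 3 * pi * 1000
  errs <- vapply(c(90, 180, 360, 720), function(n) {
    abs(contour_volume(circle_contour(10, n = n)) - truth) / truth
  }, numeric(1))
  expect_lt(errs[2], 0.01)
  expect_true(all(diff(errs) < 0))
})

test_that("mirror-symmetric contours give equal half-volumes", {
  ell <- ellipse_contour(a = 6, b = 3, n = 360)
  # both halves identical -> averaging changes nothing; compare against a
  # single-half computation via a vertically flipped copy
  flipped <- contour(ell$x, -ell$y)
  expect_equal(contour_volume(ell), contour_volume(flipped),
               tolerance = 1e-10)
})

test_that("inertia ratio is 1 for isotropic shapes and (a/b)^2 for ellipses", {
  expect_equal(contour_inertia_ratio(circle_contour(10, n = 720)), 1,
               tolerance = 1e-3)
  expect_equal(contour_inertia_ratio(square_contour()), 1, tolerance = 1e-9)
  expect_equal(contour_inertia_ratio(ellipse_contour(a = 8, b = 4)), 4,
               tolerance = 0.01)
})

test_that("second moments agree with a pixel-integration oracle", {
  ell <- ellipse_contour(a = 8, b = 4, angle = pi / 7, n = 1440)
  oracle <- raster_moment_oracle(function(px, py) {
    xr <- px * cos(-pi / 7) - py * sin(-pi / 7)
    yr <- px * sin(-pi / 7) + py * cos(-pi / 7)
    (xr / 8)^2 + (yr / 4)^2 <= 1
  })
  expect_equal(contour_inertia_ratio(ell), oracle$iyy / oracle$ixx,
               tolerance = 0.01)
  phi_oracle <- 0.5 * atan2(2 * oracle$mxy, oracle$iyy - oracle$ixx)
  expect_equal(contour_orientation(ell), phi_oracle, tolerance = 0.01)
})

test_that("orientation recovers rotation angles and handles isotropy", {
  expect_equal(contour_orientation(ellipse_contour(a = 8, b = 4)), 0,
               tolerance = 1e-6)
  expect_equal(contour_orientation(ellipse_contour(a = 8, b = 4,
                                                   angle = pi / 6)),
               pi / 6, tolerance = 1e-2)
  expect_equal(contour_orientation(circle_contour(10)), 0)
  expect_equal(contour_orientation(square_contour()), 0)
})

test_that("rigid motions transform features as expected", {
  ct <- gen_contour("blob", r = 8, seed = 7)
  shifted <- contour(ct$x + 13.5, ct$y - 4.2)
  expect_equal(contour_area(shifted), contour_area(ct))
  expect_equal(contour_inertia_ratio(shifted), contour_inertia_ratio(ct))
  expect_equal(contour_volume(shifted), contour_volume(ct),
               tolerance = 1e-10)
  # rotation by 90 degrees maps I -> 1/I
  rot <- contour(-ct$y, ct$x)
  expect_equal(contour_inertia_ratio(rot), 1 / contour_inertia_ratio(ct),
               tolerance = 1e-9)
})

test_that("area ratio is 1 for convex shapes and matches the hull oracle", {
  expect_equal(contour_area_ratio(circle_contour(10)), 1, tolerance = 1e-6)
  star <- star_contour()
  expect_gt(contour_area_ratio(star), 1)
  hull_idx <- grDevices::chull(star$x, star$y)
  oracle <- shoelace_oracle(star$x[hull_idx], star$y[hull_idx]) /
    shoelace_oracle(star$x, star$y)
  expect_equal(contour_area_ratio(star), oracle, tolerance = 1e-6)
})

test_that("the convexity gate excludes Delta above 1.05", {
  lut <- build_modulus_lut(area_grid = seq(40, 120, by = 5),
                           modulus_grid = seq(1, 5, by = 0.1))
  d <- surrogate_deformation(80, 2.5)
  expect_true(is.na(lookup_modulus(lut, 80, d, area_ratio = 1.06)))
  expect_false(is.na(lookup_modulus(lut, 80, d, area_ratio = 1.04,
                                    d_max = Inf)))
})

test_that("symmetry ratios vanish for mirror-symmetric shapes and stay in [-1, 1]", {
  s <- contour_symmetry(ellipse_contour(a = 8, b = 4, n = 360))
  expect_equal(unname(s), c(0, 0), tolerance = 1e-6)
  set.seed(99)
  for (i in 1:10) {
    ct <- gen_contour("blob", r = 8, seed = i + 100)
    s <- contour_symmetry(ct)
    expect_true(all(abs(s) <= 1))
  }
})

test_that("asymmetric symmetry ratio matches a rasterized area-count oracle", {
  # egg-like shape: circle with a bulge in +y
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  rad <- 8 * (1 + 0.25 * sin(th))
  ct <- contour(rad * cos(th), rad * sin(th))
  # oracle: count raster points above/below the centroid flow axis
  g <- seq(-12, 12, by = 0.02)
  px <- rep(g, times = length(g)); py <- rep(g, each = length(g))
  r2 <- sqrt(px^2 + py^2); thp <- atan2(py, px)
  inside <- r2 <= 8 * (1 + 0.25 * sin(thp))
  cy <- mean(py[inside])
  upper <- sum(inside & py < cy); lower <- sum(inside & py > cy)
  oracle_sx <- (upper - lower) / (upper + lower)
  expect_equal(contour_symmetry(ct)[["sx"]], oracle_sx, tolerance = 0.01)
})

test_that("equivalent diameter follows d = 2 sqrt(A / pi)", {
  expect_equal(equivalent_diameter(pi), 2)
  expect_equal(signif(equivalent_diameter(174), 3), 14.9)
  expect_equal(equivalent_diameter(281), 18.91, tolerance = 1e-3)
  expect_error(equivalent_diameter(-1), "positive")
})

test_that("extract_features assembles a full per-event row", {
  cts <- list(circle_contour(10), ellipse_contour(a = 8, b = 4))
  feats <- extract_features(cts)
  expect_equal(nrow(feats), 2)
  expect_true(all(c("area", "volume", "lx", "ly", "circ", "deform",
                    "inertia_ratio", "orientation", "area_ratio", "sx",
                    "sy", "d_eq") %in% names(feats)))
  expect_equal(feats$area[1], pi * 100, tolerance = 1e-3)
  expect_gt(feats$inertia_ratio[2], 3.9)
})
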