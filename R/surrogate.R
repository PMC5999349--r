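# Surrogate mechanical model linking cell area and elastic modulus to
# deformation, its tabulated inverse, and isoelasticity lines.
#
# The surrogate is an explicit stand-in behind a small interface: it has
# the qualitative properties the statistical methods rely on (deformation
# grows with area at fixed modulus, falls with modulus at fixed area,
# vanishes as the modulus diverges, and a normally distributed modulus
# yields a right-skewed deformation distribution), but it makes no claim of
# absolute accuracy in kPa. A faithful hydrodynamic model can be plugged in
# through the same signature.

#' Flow conditions of an RT-DC measurement
#'
#' @param flow_rate Total flow rate in ul/s.
#' @param viscosity Effective buffer viscosity in mPa s (supply the
#'   shear-thinned value at the working flow rate).
#' @param channel_width Side length of the square channel cross-section in
#'   um.
#' @return A `flow_conditions` list.
#' @export
flow_conditions <- function(flow_rate = 0.04, viscosity = 15,
                            channel_width = 20) {
  if (any(c(flow_rate, viscosity, channel_width) <= 0)) {
    stop("all flow conditions must be positive", call. = FALSE)
  }
  structure(list(flow_rate = flow_rate, viscosity = viscosity,
                 channel_width = channel_width),
            class = "flow_conditions")
}

#' Surrogate deformation of a cell under channel flow
#'
#' Closed-form monotone surrogate
#' `D = c * (Q * eta / W^3) * exp(A / A0) / E` with flow rate `Q` (ul/s),
#' viscosity `eta` (mPa s), channel width `W` (um), projected area `A`
#' (um^2), area scale `A0` (um^2) and elastic modulus `E` (kPa). The
#' hydrodynamic stress scale `Q * eta / W^3` multiplies a confinement
#' factor growing exponentially with area (isoelasticity lines are convex
#' increasing curves in the (area, deformation) plane, steepening as the
#' cell fills the channel); deformation is inversely proportional to
#' stiffness and tends to 0 as `E` grows. A normally distributed area then
#' contributes an exactly Gaussian term `A / A0` to `log(D)` while a
#' normally distributed modulus adds a mild right skew, so normal (area,
#' modulus) inputs yield the characteristic right-skewed, approximately
#' log-normal deformation distribution. The defaults `c = 360`,
#' `A0 = 150` place the default artificial population (mean area 343
#' um^2, mean modulus 7 kPa, 0.04 ul/s, 15 mPa s, 20 um channel) at a
#' median deformation of about 0.04, inside the small-deformation regime.
#'
#' @param area Projected area(s), um^2. The rotational-symmetry assumption
#'   behind volume and modulus extraction holds for cells up to about 90%
#'   of the channel width; set `enforce_range = TRUE` to reject larger
#'   cells instead of evaluating the surrogate anyway.
#' @param modulus Elastic modulus in kPa, positive.
#' @param flow [flow_conditions()].
#' @param calibration Calibration constant `c` (default 360).
#' @param area_scale Area scale `A0` in um^2 (default 150).
#' @param enforce_range Error when the equivalent diameter exceeds 90% of
#'   the channel width (default `FALSE`: the surrogate itself is defined
#'   for any positive area).
#' @return Deformation value(s).
#' @export
surrogate_deformation <- function(area, modulus, flow = flow_conditions(),
                                  calibration = 360, area_scale = 150,
                                  enforce_range = FALSE) {
  if (any(area <= 0) || any(modulus <= 0)) {
    stop("`area` and `modulus` must be positive", call. = FALSE)
  }
  if (enforce_range &&
      any(equivalent_diameter(area) > 0.9 * flow$channel_width)) {
    stop("cell diameter exceeds 90% of the channel width: outside the ",
         "validity range of the rotational-symmetry assumption",
         call. = FALSE)
  }
  stress <- flow$flow_rate * flow$viscosity / flow$channel_width^3
  calibration * stress * exp(area / area_scale) / modulus
}

#' Build an area/deformation to modulus lookup table
#'
#' Tabulates the surrogate deformation over an (area, modulus) grid and
#' inverts it so that the modulus can be looked up from measured (area,
#' deformation) pairs by monotone interpolation. Queries outside the
#' tabulated deformation range of a given area are masked as invalid
#' rather than extrapolated.
#'
#' @param flow [flow_conditions()].
#' @param area_grid Increasing grid of areas (um^2).
#' @param modulus_grid Increasing grid of moduli (kPa).
#' @param calibration,area_scale Passed to [surrogate_deformation()].
#' @return A `modulus_lut` object.
#' @export
build_modulus_lut <- function(flow = flow_conditions(),
                              area_grid = seq(20, 250, by = 2),
                              modulus_grid = seq(0.5, 12, by = 0.05),
                              calibration = 360, area_scale = 150) {
  if (is.unsorted(area_grid, strictly = TRUE) ||
      is.unsorted(modulus_grid, strictly = TRUE)) {
    stop("grids must be strictly increasing", call. = FALSE)
  }
  d <- outer(area_grid, modulus_grid,
             function(a, e) surrogate_deformation(a, e, flow, calibration,
                                                  area_scale))
  # at fixed area, D must be strictly decreasing in E for the inversion
  if (any(apply(d, 1L, function(r) any(diff(r) >= 0)))) {
    stop("surrogate is not monotone in the modulus over this grid",
         call. = FALSE)
  }
  structure(list(flow = flow, area_grid = area_grid,
                 modulus_grid = modulus_grid, deform = d,
                 calibration = calibration, area_scale = area_scale),
            class = "modulus_lut")
}

#' @export
print.modulus_lut <- function(x, ...) {
  cat(sprintf(
    "<modulus_lut> %d x %d grid, area %g..%g um^2, modulus %g..%g kPa\n",
    length(x$area_grid), length(x$modulus_grid),
    min(x$area_grid), max(x$area_grid),
    min(x$modulus_grid), max(x$modulus_grid)))
  invisible(x)
}

#' Look up the elastic modulus from area and deformation
#'
#' Interpolates the inverted lookup table at each (area, deformation) pair.
#' Events failing the convexity gate (`area_ratio > 1.05`) or, when the
#' small-deformation gate is active, with `deformation > d_max`, and
#' queries outside the table's validity mask return `NA` -- invalid is a
#' value, not an error.
#'
#' @param lut A [build_modulus_lut()] table.
#' @param area,deformation Measured values (vectors of equal length).
#' @param area_ratio Optional convexity gate values; events with
#'   `area_ratio > 1.05` are invalid for modulus extraction.
#' @param d_max Small-deformation validity gate (default 0.03); set to
#'   `Inf` to disable.
#' @return Modulus values in kPa, `NA` where invalid.
#' @export
lookup_modulus <- function(lut, area, deformation, area_ratio = NULL,
                           d_max = 0.03) {
  stopifnot(inherits(lut, "modulus_lut"))
  n <- length(area)
  if (length(deformation) != n) {
    stop("`area` and `deformation` must have the same length", call. = FALSE)
  }
  out <- rep(NA_real_, n)
  ok <- area >= min(lut$area_grid) & area <= max(lut$area_grid) &
    deformation <= d_max
  if (!is.null(area_ratio)) ok <- ok & area_ratio <= 1.05 & area_ratio >= 1.0
  for (i in which(ok)) {
    # interpolate the deformation profile D(E) at this area, then invert
    ai <- findInterval(area[i], lut$area_grid, all.inside = TRUE)
    t <- (area[i] - lut$area_grid[ai]) /
      (lut$area_grid[ai + 1L] - lut$area_grid[ai])
    prof <- (1 - t) * lut$deform[ai, ] + t * lut$deform[ai + 1L, ]
    # prof is strictly decreasing in E
    if (deformation[i] > max(prof) || deformation[i] < min(prof)) next
    out[i] <- stats::approx(x = rev(prof), y = rev(lut$modulus_grid),
                            xout = deformation[i])$y
  }
  out
}

#' Isoelasticity lines of the surrogate model
#'
#' Constant-modulus level sets in the (area, deformation) plane. Distinct
#' moduli give non-crossing, monotonically increasing curves.
#'
#' @param moduli Moduli (kPa) for which to trace lines.
#' @param flow [flow_conditions()].
#' @param area_grid Areas at which to evaluate each line.
#' @param calibration,area_scale Passed to [surrogate_deformation()].
#' @return Tibble with columns `modulus`, `area`, `deform`.
#' @export
isoelasticity_lines <- function(moduli = c(1, 2.5, 5, 7.5),
                                flow = flow_conditions(),
                                area_grid = seq(20, 250, by = 5),
                                calibration = 360, area_scale = 150) {
  purrr::map_dfr(moduli, function(e) {
    tibble::tibble(modulus = e, area = area_grid,
                   deform = surrogate_deformation(area_grid, e, flow,
                                                  calibration, area_scale))
  })
}
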