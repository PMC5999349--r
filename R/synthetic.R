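# Synthetic-data generators: parametric contours with known geometry,
# artificial (area, modulus) populations mapped to deformation through the
# surrogate model, the two-population shrinking-separation inputs, planted
# rare sub-populations for PCA screening, and replicate-structured
# two-condition datasets for LMM / differential-deformation testing.
# Every generator is a pure function of (parameters, seed).

#' Generate a parametric test contour
#'
#' Produces polygons with analytically known geometry: `circle` (radius
#' `r`), `ellipse` (semi-axes `a` along the flow and `b` across, optional
#' rotation `angle`), `star` (`n_spikes` spikes alternating between radii
#' `r` and `r * (1 - spike_depth)`) and `blob` (a smooth random radial
#' perturbation of a circle). Optionally rasterizes a textured image patch
#' covering the contour.
#'
#' @param shape One of `"circle"`, `"ellipse"`, `"star"`, `"blob"`.
#' @param r,a,b Radii in pixels (circle/star/blob use `r`; ellipse `a`, `b`).
#' @param n_vertices Number of polygon vertices (>= 12).
#' @param angle Rotation in radians (ellipse).
#' @param n_spikes,spike_depth Star parameters; `spike_depth` in (0, 1).
#' @param center Center in pixel coordinates.
#' @param pixel_size um per pixel.
#' @param pixelate Round vertex coordinates to integer pixel centers.
#' @param with_patch Also build an [image_patch()] filled with Gaussian
#'   texture (`patch_mean`, `patch_sd`) inside the contour over a
#'   background of `background`.
#' @param patch_mean,patch_sd,background Gray levels for the texture fill.
#' @param seed Seed for the blob perturbation and texture.
#' @param id Event id.
#' @return A [contour()], or a list `(contour, patch)` when
#'   `with_patch = TRUE`.
#' @export
gen_contour <- function(shape = c("circle", "ellipse", "star", "blob"),
                        r = 10, a = 10, b = 6, n_vertices = 96L, angle = 0,
                        n_spikes = 5L, spike_depth = 0.5,
                        center = c(32, 32), pixel_size = 1,
                        pixelate = FALSE, with_patch = FALSE,
                        patch_mean = 120, patch_sd = 15, background = 30,
                        seed = NULL, id = NA_character_) {
  shape <- match.arg(shape)
  if (n_vertices < 12L) stop("need at least 12 vertices", call. = FALSE)
  if (any(c(r, a, b) <= 0)) stop("radii must be positive", call. = FALSE)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  xy <- with_seed(seed, switch(shape,
    circle = cbind(r * cos(th), r * sin(th)),
    ellipse = {
      e <- cbind(a * cos(th), b * sin(th))
      rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
      e %*% t(rot)
    },
    star = {
      if (spike_depth <= 0 || spike_depth >= 1) {
        stop("`spike_depth` must be in (0, 1)", call. = FALSE)
      }
      rad <- r * (1 - spike_depth / 2 * (1 + cos(n_spikes * th)))
      cbind(rad * cos(th), rad * sin(th))
    },
    blob = {
      k <- 2:4
      amp <- stats::rnorm(length(k), 0, 0.06 * r)
      phs <- stats::runif(length(k), 0, 2 * pi)
      rad <- r + colSums(amp * sin(outer(k, th) + phs))
      cbind(rad * cos(th), rad * sin(th))
    }))
  xy <- sweep(xy, 2L, center, `+`)
  if (pixelate) xy <- unique(round(xy))
  ct <- contour(xy[, 1L], xy[, 2L], pixel_size = pixel_size, id = id)
  if (!with_patch) return(ct)
  pad <- 2L
  x0 <- floor(min(ct$x)) - pad; x1 <- ceiling(max(ct$x)) + pad
  y0 <- floor(min(ct$y)) - pad; y1 <- ceiling(max(ct$y)) + pad
  vals <- matrix(background, nrow = y1 - y0 + 1L, ncol = x1 - x0 + 1L)
  patch <- image_patch(vals, origin = c(x0, y0))
  mask <- patch_mask(patch, ct)
  tex <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                   stats::rnorm(sum(mask), patch_mean, patch_sd))
  vals[mask] <- pmin(pmax(round(tex), 0), 255)
  list(contour = ct, patch = image_patch(vals, origin = c(x0, y0)))
}

# draw from N(mean, sd) truncated to positive values by resampling
rnorm_positive <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  guard <- 0L
  while (length(bad) > 0L && guard < 100L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out <= 0)
    guard <- guard + 1L
  }
  if (length(bad) > 0L) stop("could not draw positive values", call. = FALSE)
  out
}

#' Generate an artificial RT-DC population
#'
#' Samples projected area and elastic modulus from normal distributions
#' (non-positive draws are resampled) and maps each event to a deformation
#' value through the surrogate model, optionally with multiplicative
#' log-normal measurement noise. The defaults reproduce the artificial
#' dataset conditions: `A ~ N(343, 80^2)` um^2, `E ~ N(7, 1.2^2)` kPa at
#' 0.04 ul/s, 15 mPa s, 20 um channel.
#'
#' @param n Number of events.
#' @param mean_area,sd_area Area distribution, um^2.
#' @param mean_modulus,sd_modulus Modulus distribution, kPa.
#' @param flow [flow_conditions()].
#' @param calibration,area_scale Surrogate constants, see
#'   [surrogate_deformation()].
#' @param d_noise sdlog of multiplicative log-normal noise on deformation
#'   (default 0: deformation is a deterministic function of area and
#'   modulus).
#' @param seed Integer seed.
#' @return Tibble with columns `area`, `modulus`, `deform`, `log_deform`.
#' @export
gen_population <- function(n, mean_area = 343, sd_area = 80,
                           mean_modulus = 7, sd_modulus = 1.2,
                           flow = flow_conditions(), calibration = 360,
                           area_scale = 150, d_noise = 0, seed = NULL) {
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  with_seed(seed, {
    area <- rnorm_positive(n, mean_area, max(sd_area, 0))
    modulus <- rnorm_positive(n, mean_modulus, max(sd_modulus, 0))
    deform <- surrogate_deformation(area, modulus, flow, calibration,
                                    area_scale)
    if (d_noise > 0) deform <- deform * stats::rlnorm(n, 0, d_noise)
    tibble::tibble(area = area, modulus = modulus, deform = deform,
                   log_deform = log(deform))
  })
}

#' Generate the two-population shrinking-separation inputs
#'
#' Paired populations for the overlap assay: population 1 stationary at a
#' mean area of 70 um^2, population 2 starting larger and shrinking by 5
#' um^2 per step, 1000 events each, both at a constant modulus of 2.5 kPa
#' so population 2 moves along an isoelasticity line as it shrinks.
#'
#' @param step_count Number of steps (>= 1).
#' @param n_events Events per population.
#' @param modulus Common modulus, kPa.
#' @param stationary_area,start_area,step_area Mean-area schedule, um^2.
#' @param sd_area Within-population area SD, um^2.
#' @param sd_modulus Modulus spread (default 0, constant modulus).
#' @param d_noise Deformation measurement noise (sdlog).
#' @param flow [flow_conditions()].
#' @param seed Integer seed.
#' @return A list with one element per step, each a list
#'   `(pop1, pop2, mean_area_2)`.
#' @export
gen_two_population_assay <- function(step_count = 11L, n_events = 1000L,
                                     modulus = 2.5, stationary_area = 70,
                                     start_area = 120, step_area = 5,
                                     sd_area = 7, sd_modulus = 0,
                                     d_noise = 0.05,
                                     flow = flow_conditions(), seed = 1L) {
  if (step_count < 1L) stop("`step_count` must be >= 1", call. = FALSE)
  purrr::map(seq_len(step_count), function(step) {
    mean2 <- start_area - (step - 1L) * step_area
    list(
      pop1 = gen_population(n_events, stationary_area, sd_area, modulus,
                            sd_modulus, flow = flow, d_noise = d_noise,
                            seed = seed + 7919L * step),
      pop2 = gen_population(n_events, mean2, sd_area, modulus, sd_modulus,
                            flow = flow, d_noise = d_noise,
                            seed = seed + 7919L * step + 1L),
      mean_area_2 = mean2)
  })
}

#' Plant a rare sub-population in a multi-feature table
#'
#' Builds a base population with a realistic 11-feature profile (area,
#' volume, deformation, inertia ratio, area ratio, both symmetry ratios,
#' brightness, brightness SD and two texture features) and replaces a small
#' fraction of events with a shifted sub-population -- by default smaller,
#' darker cells with distinct texture, emulating a rare cell type hiding in
#' a morphometric screen. Ground-truth labels are retained for recall
#' scoring.
#'
#' @param n Total number of events.
#' @param rare_fraction Fraction of planted events, in `[0, 0.5)`.
#' @param shift Named list of additive shifts applied to the rare events'
#'   generating parameters; see Details. Defaults lower area (x 0.4),
#'   volume, brightness (-40) and shift both texture features.
#' @param mean_area,sd_area,mean_modulus,sd_modulus Base population, as in
#'   [gen_population()].
#' @param flow [flow_conditions()].
#' @param seed Integer seed.
#' @return Tibble with the 11 feature columns plus `rare` (logical truth).
#' @export
gen_rare_subpopulation <- function(n = 5000L, rare_fraction = 0.02,
                                   shift = NULL,
                                   mean_area = 40, sd_area = 8,
                                   mean_modulus = 2, sd_modulus = 0.4,
                                   flow = flow_conditions(), seed = 1L) {
  if (rare_fraction < 0 || rare_fraction >= 0.5) {
    stop("`rare_fraction` must be in [0, 0.5)", call. = FALSE)
  }
  defaults <- list(area_factor = 0.4, bright = -40, bright_sd = 4,
                   haralick_01 = 0.15, haralick_02 = 2)
  shift <- utils::modifyList(defaults, shift %||% list())
  with_seed(seed, {
    n_rare <- stats::rbinom(1L, n, rare_fraction)
    rare <- c(rep(TRUE, n_rare), rep(FALSE, n - n_rare))
    area <- rnorm_positive(n, mean_area, sd_area)
    area[rare] <- area[rare] * shift$area_factor
    modulus <- rnorm_positive(n, mean_modulus, sd_modulus)
    deform <- surrogate_deformation(area, modulus, flow)
    d_eq <- equivalent_diameter(area)
    volume <- 4 / 3 * pi * (d_eq / 2)^3 * stats::rlnorm(n, 0, 0.05)
    bright <- stats::rnorm(n, 120, 6) + ifelse(rare, shift$bright, 0)
    bright_sd <- abs(stats::rnorm(n, 12, 2) +
                       ifelse(rare, shift$bright_sd, 0))
    tibble::tibble(
      area = area, volume = volume, deform = deform,
      inertia_ratio = 1 + abs(stats::rnorm(n, 0.15, 0.05)),
      area_ratio = 1 + abs(stats::rnorm(n, 0.01, 0.008)),
      sx = stats::rnorm(n, 0, 0.04), sy = stats::rnorm(n, 0, 0.04),
      bright = bright, bright_sd = bright_sd,
      haralick_01 = stats::rnorm(n, 0.2, 0.03) +
        ifelse(rare, shift$haralick_01, 0),
      haralick_02 = stats::rnorm(n, 6, 1) +
        ifelse(rare, shift$haralick_02, 0),
      rare = rare)
  })
}

#' Generate replicate-structured two-condition data
#'
#' Emulates paired control/treatment measurements over biological
#' replicates for mixed-model testing: each replicate `r` draws a random
#' intercept `a_r ~ N(0, sd_intercept^2)` and a random slope
#' `b_r ~ N(0, sd_slope^2)`, and observations follow
#' `y = mu + a_r + (beta + b_r) * treatment + eps` with
#' `eps ~ N(0, sd_residual^2)`. Unequal replicate counts per condition
#' (incomplete pairing, e.g. 2 control vs 3 treatment replicates) are
#' supported: a replicate present in only one condition simply contributes
#' no paired observations.
#'
#' @param n_rep_control,n_rep_treatment Numbers of replicates carrying each
#'   condition. Replicates `1..max(...)` exist; the first `n_rep_control`
#'   carry control observations and the first `n_rep_treatment` carry
#'   treatment observations.
#' @param n_per_cell Observations per replicate-condition cell.
#' @param mu Baseline level.
#' @param beta Fixed treatment effect.
#' @param sd_intercept,sd_slope Random-effect SDs across replicates.
#' @param sd_residual Residual SD.
#' @param seed Integer seed.
#' @return Tibble with columns `value`, `condition` (factor control /
#'   treatment) and `replicate` (factor).
#' @export
gen_replicates <- function(n_rep_control = 3L, n_rep_treatment = 3L,
                           n_per_cell = 100L, mu = 0, beta = 0,
                           sd_intercept = 0.5, sd_slope = 0.2,
                           sd_residual = 1, seed = 1L) {
  if (max(n_rep_control, n_rep_treatment) < 2L) {
    stop("need at least 2 replicates", call. = FALSE)
  }
  with_seed(seed, {
    n_rep <- max(n_rep_control, n_rep_treatment)
    a <- stats::rnorm(n_rep, 0, sd_intercept)
    b <- stats::rnorm(n_rep, 0, sd_slope)
    rows <- purrr::map_dfr(seq_len(n_rep), function(r) {
      out <- list()
      if (r <= n_rep_control) {
        out$control <- tibble::tibble(
          value = mu + a[r] + stats::rnorm(n_per_cell, 0, sd_residual),
          condition = "control", replicate = paste0("rep", r))
      }
      if (r <= n_rep_treatment) {
        out$treatment <- tibble::tibble(
          value = mu + a[r] + beta + b[r] +
            stats::rnorm(n_per_cell, 0, sd_residual),
          condition = "treatment", replicate = paste0("rep", r))
      }
      dplyr::bind_rows(out)
    })
    rows$condition <- factor(rows$condition, levels = c("control", "treatment"))
    rows$replicate <- factor(rows$replicate)
    rows
  })
}
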