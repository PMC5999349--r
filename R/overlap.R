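# Population overlap from 20%-of-maximum density contours, and the
# shrinking-separation assay that probes how far BIC-based mixture
# selection can still resolve two sub-populations.

#' Density-contour overlap of two 2D populations
#'
#' Both populations are pooled and jointly z-scored (features have
#' incommensurate units), then each is summarized by the Gaussian density
#' with its sample mean and covariance. The region of a population is where
#' its density exceeds `level` (default 20%) of its maximum. With `a1` the
#' area of the first (stationary) population's region and `a3` the area
#' shared with the second population's region, the overlap is
#' `a3 / a1 * 100` percent. Areas are summed on a regular grid spanning the
#' pooled data plus a 5-SD margin.
#'
#' @param pop_a,pop_b Data frames or matrices with the two feature columns;
#'   `pop_a` is the reference population whose region area normalizes the
#'   overlap.
#' @param vars Optional character vector of the two columns to use.
#' @param level Density fraction defining the contour (default 0.2).
#' @param grid_n Grid resolution per axis (default 512).
#' @return Overlap percentage in `[0, 100]`.
#' @export
contour_overlap <- function(pop_a, pop_b, vars = NULL, level = 0.2,
                            grid_n = 512L) {
  A <- as_feature_matrix(pop_a, vars)
  B <- as_feature_matrix(pop_b, vars)
  if (ncol(A) != 2L || ncol(B) != 2L) {
    stop("overlap is defined for exactly 2 features", call. = FALSE)
  }
  pooled <- rbind(A, B)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2L, stats::sd)
  if (any(sdv == 0)) stop("a feature is constant across both populations",
                          call. = FALSE)
  zA <- sweep(sweep(A, 2L, mu), 2L, sdv, `/`)
  zB <- sweep(sweep(B, 2L, mu), 2L, sdv, `/`)
  pa <- list(mean = colMeans(zA), cov = stats::cov(zA))
  pb <- list(mean = colMeans(zB), cov = stats::cov(zB))
  for (p in list(pa, pb)) {
    if (!is.finite(determinant(p$cov)$modulus) ||
        min(eigen(p$cov, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("singular sample covariance", call. = FALSE)
    }
  }
  z <- rbind(zA, zB)
  lim_x <- range(z[, 1L]) + c(-5, 5) * stats::sd(z[, 1L])
  lim_y <- range(z[, 2L]) + c(-5, 5) * stats::sd(z[, 2L])
  gx <- seq(lim_x[1L], lim_x[2L], length.out = grid_n)
  gy <- seq(lim_y[1L], lim_y[2L], length.out = grid_n)
  pts <- cbind(rep(gx, times = grid_n), rep(gy, each = grid_n))
  # density >= level * max  <=>  Mahalanobis^2 <= -2 log(level)
  inside <- function(p) {
    ch <- chol(p$cov)
    w <- backsolve(ch, t(pts) - p$mean, transpose = TRUE)
    colSums(w^2) <= -2 * log(level)
  }
  in_a <- inside(pa)
  in_b <- inside(pb)
  a1 <- sum(in_a)
  if (a1 == 0) stop("reference region is empty on the grid", call. = FALSE)
  a3 <- sum(in_a & in_b)
  100 * a3 / a1
}

#' Shrinking-separation overlap assay
#'
#' Generates two synthetic populations at a common elastic modulus whose
#' deformation follows the isoelasticity surface of the surrogate model:
#' population 1 stays at a fixed mean area while population 2's mean area
#' is reduced step by step toward it, so the 20%-density-contour overlap
#' grows. At each step the assay records the overlap, the BIC-selected
#' component count on (area, log deformation), and the accuracy of
#' max-posterior assignment against the generating population.
#'
#' @param n_events Events per population (default 1000).
#' @param modulus Common elastic modulus in kPa (default 2.5).
#' @param stationary_area Mean area of population 1 in um^2 (default 70).
#' @param start_area Starting mean area of population 2 (default 120).
#' @param step_area Step size in um^2 by which population 2 shrinks
#'   (default 5).
#' @param n_steps Number of steps; default walks population 2 all the way
#'   down to the stationary mean.
#' @param sd_area Within-population area SD in um^2 (default 7).
#' @param d_noise Log-normal measurement noise sdlog on deformation
#'   (default 0.05).
#' @param flow Flow conditions, see [flow_conditions()].
#' @param k_max Largest component count offered to BIC (default 4).
#' @param seed Integer seed.
#' @param fixed_k Optionally skip BIC and fit exactly this many components.
#' @return A tibble ordered by increasing overlap with columns
#'   `mean_area_2`, `delta_area`, `overlap_pct`, `selected_k`, `accuracy`.
#' @export
overlap_assay <- function(n_events = 1000L, modulus = 2.5,
                          stationary_area = 70, start_area = 120,
                          step_area = 5, n_steps = NULL, sd_area = 7,
                          d_noise = 0.05, flow = flow_conditions(),
                          k_max = 4L, seed = 1L, fixed_k = NULL) {
  if (is.null(n_steps)) {
    n_steps <- floor((start_area - stationary_area) / step_area) + 1L
  }
  rows <- purrr::map_dfr(seq_len(n_steps), function(step) {
    mean2 <- start_area - (step - 1L) * step_area
    res <- overlap_assay_step(
      n_events = n_events, modulus = modulus,
      stationary_area = stationary_area, mean_area_2 = mean2,
      sd_area = sd_area, d_noise = d_noise, flow = flow, k_max = k_max,
      seed = seed + 7919L * step, fixed_k = fixed_k)
    tibble::tibble(mean_area_2 = mean2,
                   delta_area = mean2 - stationary_area,
                   overlap_pct = res$overlap_pct,
                   selected_k = res$selected_k,
                   accuracy = res$accuracy)
  })
  dplyr::arrange(rows, .data$overlap_pct)
}

# One assay step: generate, measure overlap, cluster, score.
overlap_assay_step <- function(n_events, modulus, stationary_area,
                               mean_area_2, sd_area, d_noise, flow, k_max,
                               seed, fixed_k = NULL) {
  pop1 <- gen_population(n = n_events, mean_area = stationary_area,
                         sd_area = sd_area, mean_modulus = modulus,
                         sd_modulus = 0, d_noise = d_noise, flow = flow,
                         seed = seed)
  pop2 <- gen_population(n = n_events, mean_area = mean_area_2,
                         sd_area = sd_area, mean_modulus = modulus,
                         sd_modulus = 0, d_noise = d_noise, flow = flow,
                         seed = seed + 1L)
  ov <- contour_overlap(pop1, pop2, vars = c("area", "log_deform"))
  both <- dplyr::bind_rows(pop1, pop2)
  truth <- rep(1:2, each = n_events)
  if (is.null(fixed_k)) {
    sel <- select_gmm_k(both, vars = c("area", "log_deform"), k_max = k_max,
                        seed = seed + 2L)
    fit <- sel$fits[[sel$selected_k]]
    selected_k <- sel$selected_k
  } else {
    fit <- fit_gmm(both, vars = c("area", "log_deform"), k = fixed_k,
                   seed = seed + 2L)
    selected_k <- fixed_k
  }
  labels <- assign_clusters(fit, both)
  list(overlap_pct = ov, selected_k = as.integer(selected_k),
       accuracy = assignment_accuracy(labels, truth))
}
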