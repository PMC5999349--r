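# broom-style tidiers for the fitted-object classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Gaussian mixture fit
#'
#' One row per component with its weight, mean of every clustering feature
#' and the marginal SDs.
#'
#' @param x A `gmm_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gmm_fit <- function(x, ...) {
  rows <- purrr::map_dfr(seq_len(x$n_comp), function(i) {
    mu <- stats::setNames(as.list(x$means[i, ]), paste0("mean_", x$vars))
    sds <- stats::setNames(as.list(sqrt(diag(as.matrix(x$covs[[i]])))),
                           paste0("sd_", x$vars))
    tibble::as_tibble(c(list(component = i, weight = x$weights[i]), mu, sds))
  })
  rows
}

#' @rdname tidy.gmm_fit
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble::tibble(n_comp = x$n_comp, k = x$k, n = x$n, loglik = x$loglik,
                 bic = gmm_bic(x), converged = x$converged,
                 n_iter = x$n_iter)
}

#' Tidy a BIC model-selection trace
#'
#' @param x A `gmm_selection`.
#' @param ... Unused.
#' @return The selection table (`K`, `loglik`, `n_params`, `bic`).
#' @export
tidy.gmm_selection <- function(x, ...) x$selection

#' @rdname tidy.gmm_selection
#' @export
glance.gmm_selection <- function(x, ...) {
  tibble::tibble(selected_k = x$selected_k,
                 bic_min = min(x$selection$bic),
                 k_max = max(x$selection$K))
}

#' Tidy a mixed-model significance fit
#'
#' @param x An `rtdc_lmm`.
#' @param ... Unused.
#' @return `tidy()`: one row per fixed effect; `glance()`: one row with the
#'   likelihoods, likelihood ratio and p-value.
#' @export
tidy.rtdc_lmm <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' @rdname tidy.rtdc_lmm
#' @export
glance.rtdc_lmm <- function(x, ...) {
  tibble::tibble(effect = unname(x$beta[2L]),
                 loglik_full = x$loglik_full, loglik_null = x$loglik_null,
                 lambda = x$lambda, statistic = x$statistic,
                 p_value = x$p_value, converged = x$converged,
                 singular = x$singular)
}

#' Tidy a PCA model
#'
#' @param x An `rtdc_pca`.
#' @param ... Unused.
#' @return `tidy()`: long table of loadings (`feature`, `component`,
#'   `loading`); `glance()`: per-component explained variance.
#' @export
tidy.rtdc_pca <- function(x, ...) {
  long <- as.data.frame(x$loadings)
  long$feature <- rownames(x$loadings)
  tidyr::pivot_longer(tibble::as_tibble(long), -"feature",
                      names_to = "component", values_to = "loading")
}

#' @rdname tidy.rtdc_pca
#' @export
glance.rtdc_pca <- function(x, ...) {
  ev <- x$explained_variance
  tibble::tibble(component = paste0("PC", seq_along(ev)),
                 explained_variance = ev,
                 pct_variance = 100 * ev / sum(ev))
}

#' Tidy a bootstrap differential-deformation distribution
#'
#' @param x A `bootstrap_dd`.
#' @param ... Unused.
#' @return `tidy()`: tibble of the bootstrap values; `glance()`: mean, SD,
#'   normal-probability-plot `r2` and sample sizes.
#' @export
tidy.bootstrap_dd <- function(x, ...) {
  tibble::tibble(iteration = seq_len(x$b), dd = x$dd_values)
}

#' @rdname tidy.bootstrap_dd
#' @export
glance.bootstrap_dd <- function(x, ...) {
  tibble::tibble(b = x$b, n_ch = x$n_ch, n_res = x$n_res,
                 statistic = x$statistic_name,
                 mean = mean(x$dd_values), sd = stats::sd(x$dd_values),
                 normality_r2 = probability_plot_r2(x$dd_values))
}

#' Tidy a modulus lookup table
#'
#' Long-format serialization of the tabulated surrogate: one row per
#' (area, modulus) grid cell with its deformation. Written to TSV via
#' [write_event_table()], this makes the table portable and diffable.
#'
#' @param x A `modulus_lut`.
#' @param ... Unused.
#' @return A tibble with columns `area`, `modulus`, `deform`.
#' @export
tidy.modulus_lut <- function(x, ...) {
  tibble::tibble(
    area = rep(x$area_grid, times = length(x$modulus_grid)),
    modulus = rep(x$modulus_grid, each = length(x$area_grid)),
    deform = as.vector(x$deform))
}
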