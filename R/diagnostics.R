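# Normal vs log-normal screening of per-event feature distributions via
# Filliben probability-plot correlation.

#' Filliben order-statistic probabilities
#'
#' Probability positions of the order statistics of a sample of size `n`:
#' `m[1] = 1 - 0.5^(1/n)`, `m[i] = (i - 0.3175) / (n + 0.365)` for interior
#' `i`, and `m[n] = 0.5^(1/n)`. The sequence is strictly increasing and the
#' interior is symmetric about 0.5 (`m[i] + m[n + 1 - i] = 1`).
#'
#' @param n Sample size (>= 1).
#' @return Numeric vector of `n` probabilities in (0, 1).
#' @export
filliben_quantiles <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  if (n == 1L) return(0.5)
  m <- (seq_len(n) - 0.3175) / (n + 0.365)
  m[1L] <- 1 - 0.5^(1 / n)
  m[n] <- 0.5^(1 / n)
  m
}

#' Probability-plot squared correlation
#'
#' Sorts the values ascending and correlates them with the standard-normal
#' inverse CDF of the Filliben probabilities. The squared Pearson
#' correlation `r2` is close to 1 when the sample is Gaussian; curvature in
#' the probability plot (skew) lowers it.
#'
#' @param values Numeric vector, `n >= 3`, non-constant, finite.
#' @return Squared correlation in `[0, 1]`.
#' @export
probability_plot_r2 <- function(values) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("`values` must be finite", call. = FALSE)
  n <- length(values)
  if (n < 3L) stop("need at least 3 values", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("constant values: probability plot undefined", call. = FALSE)
  }
  theo <- stats::qnorm(filliben_quantiles(n))
  stats::cor(sort(values, method = "radix"), theo)^2
}

#' Compare normal against log-normal fit of a feature
#'
#' Computes the probability-plot `r2` for the raw values and, when all
#' values are positive, for their natural logarithm. The verdict is
#' `"lognormal"` when the log-transformed plot is more linear
#' (`r2_log > r2`), `"normal"` when the raw plot wins, and `"tie"` on exact
#' equality. Non-positive values skip the log branch with `log_valid =
#' FALSE`.
#'
#' @inheritParams probability_plot_r2
#' @return A one-row tibble: `n`, `r2`, `r2_log`, `log_valid`, `verdict`.
#' @examples
#' x <- exp(rnorm(500))
#' compare_normal_lognormal(x)
#' @export
compare_normal_lognormal <- function(values) {
  r2 <- probability_plot_r2(values)
  log_valid <- all(values > 0)
  r2_log <- if (log_valid) probability_plot_r2(log(values)) else NA_real_
  verdict <- if (!log_valid) {
    "normal"
  } else if (r2_log > r2) {
    "lognormal"
  } else if (r2_log < r2) "normal" else "tie"
  tibble::tibble(n = length(values), r2 = r2, r2_log = r2_log,
                 log_valid = log_valid, verdict = verdict)
}

#' Distribution diagnostics for each feature column
#'
#' Applies [compare_normal_lognormal()] to each requested feature of an
#' event table.
#'
#' @param data A data frame of per-event features.
#' @param features Character vector of column names (default: all numeric
#'   columns).
#' @return A tibble with one row per feature.
#' @export
diagnose_features <- function(data, features = NULL) {
  if (is.null(features)) {
    features <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  missing <- setdiff(features, names(data))
  if (length(missing) > 0L) {
    stop("features not in `data`: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  purrr::map_dfr(features, function(f) {
    dplyr::bind_cols(tibble::tibble(feature = f),
                     compare_normal_lognormal(data[[f]]))
  })
}
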