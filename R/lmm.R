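# Significance testing across biological replicates with a linear mixed
# model and a likelihood-ratio test.

#' Fit the replicate mixed model and test the treatment effect
#'
#' Fits `value ~ condition + (1 + condition | replicate)` (random intercept
#' for the varying mean level of each replicate, random slope for the
#' varying treatment response; independent by default) by maximum
#' likelihood, together with a null model that drops only the fixed
#' condition effect. Significance comes from Wilks' theorem:
#' `-2 ln(L_null / L_full)` is referred to a chi-squared distribution with
#' one degree of freedom. Maximum likelihood (not REML) is used so the two
#' likelihoods are comparable; incomplete pairing (replicates observed in
#' only one condition) is handled by the likelihood itself, no data are
#' dropped.
#'
#' @param data Data frame with the observation column, a two-level
#'   condition column and a replicate column (at least 2 replicates).
#' @param value,condition,replicate Column names (strings).
#' @param correlated Model the random intercept and slope as correlated
#'   (default `FALSE`: independent, diagonal covariance).
#' @return An `rtdc_lmm` object: list with `beta` (named fixed effects),
#'   `loglik_full`, `loglik_null`, `lambda` (likelihood ratio
#'   `L_full / L_null`), `statistic` (`-2 ln(L_null/L_full)`, clamped at
#'   0), `p_value`, `converged`, `singular`, and the two `lme4` fits.
#' @examples
#' d <- gen_replicates(beta = 1, seed = 1)
#' fit <- fit_lmm(d)
#' glance(fit)
#' @export
fit_lmm <- function(data, value = "value", condition = "condition",
                    replicate = "replicate", correlated = FALSE) {
  for (col in c(value, condition, replicate)) {
    if (!col %in% names(data)) {
      stop(sprintf("column `%s` not found", col), call. = FALSE)
    }
  }
  df <- data.frame(.value = data[[value]],
                   .condition = factor(data[[condition]]),
                   .replicate = factor(data[[replicate]]))
  if (nlevels(df$.condition) != 2L) {
    stop("`condition` must have exactly 2 levels", call. = FALSE)
  }
  if (nlevels(df$.replicate) < 2L) {
    stop("need at least 2 replicates", call. = FALSE)
  }
  cells <- table(df$.replicate, df$.condition)
  if (any(cells == 1L)) {
    stop("a replicate-condition cell has a single observation; ",
         "residual variance would be confounded", call. = FALSE)
  }
  # numeric 0/1 treatment indicator: the double-bar (independent random
  # effects) syntax is only reliable for numeric predictors
  df$.treat <- as.numeric(df$.condition) - 1
  re <- if (correlated) "(1 + .treat | .replicate)" else
    "(1 | .replicate) + (0 + .treat | .replicate)"
  f_full <- stats::as.formula(paste(".value ~ .treat +", re))
  f_null <- stats::as.formula(paste(".value ~ 1 +", re))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit1 <- suppressMessages(suppressWarnings(
    lme4::lmer(f_full, data = df, REML = FALSE, control = ctrl)))
  fit0 <- suppressMessages(suppressWarnings(
    lme4::lmer(f_null, data = df, REML = FALSE, control = ctrl)))
  ll1 <- as.numeric(stats::logLik(fit1))
  ll0 <- as.numeric(stats::logLik(fit0))
  stat <- max(0, -2 * (ll0 - ll1))  # boundary slack: nested models
  conv <- function(m) {
    cc <- m@optinfo$conv$opt
    is.null(cc) || cc == 0L
  }
  structure(list(
    beta = lme4::fixef(fit1),
    loglik_full = ll1, loglik_null = ll0,
    lambda = exp(ll1 - ll0),
    statistic = stat,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    converged = conv(fit1) && conv(fit0),
    singular = lme4::isSingular(fit1) || lme4::isSingular(fit0),
    correlated = correlated,
    fit_full = fit1, fit_null = fit0
  ), class = "rtdc_lmm")
}

#' @export
print.rtdc_lmm <- function(x, ...) {
  cat(sprintf(
    "<rtdc_lmm> effect = %.5g, lnL full = %.3f, null = %.3f, p = %.3g%s\n",
    x$beta[2L], x$loglik_full, x$loglik_null, x$p_value,
    if (x$converged) "" else " (non-convergence flagged)"))
  invisible(x)
}

#' Welch t-test reference
#'
#' Two-sided unequal-variance t-test between two pooled samples; the
#' standard test that a replicate-aware mixed model is compared against.
#' With very large event counts it declares even tiny distributional
#' offsets significant, which is exactly the failure mode the mixed model
#' avoids.
#'
#' @param values_a,values_b Numeric vectors (n >= 2 each).
#' @return The two-sided p-value.
#' @export
t_test_reference <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) return(1)
    stop("degenerate zero-variance groups with different means",
         call. = FALSE)
  }
  stats::t.test(values_a, values_b, var.equal = FALSE)$p.value
}
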