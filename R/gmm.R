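# Full-covariance Gaussian mixture models fitted by expectation
# maximization, with BIC-based selection of the number of components.

# Run code under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is restored afterwards. seed = NULL leaves the stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Multivariate Gaussian density
#'
#' Density of `N(mean, sigma)` evaluated at one or more points:
#' `(2 pi)^(-k/2) |Sigma|^(-1/2) exp(-(x - mu)' Sigma^{-1} (x - mu) / 2)`.
#'
#' @param x Numeric vector of length `k`, or an `n x k` matrix of points.
#' @param mean Length-`k` mean vector.
#' @param sigma `k x k` symmetric positive-definite covariance.
#' @param log Return the log density.
#' @return Numeric vector of densities.
#' @export
mvn_density <- function(x, mean, sigma, log = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  sigma <- as.matrix(sigma)
  k <- ncol(x)
  ch <- tryCatch(chol(sigma), error = function(e) {
    stop("covariance is not positive definite", call. = FALSE)
  })
  z <- backsolve(ch, t(x) - mean, transpose = TRUE)
  ld <- -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * k * log(2 * pi)
  if (log) ld else exp(ld)
}

# log density matrix n x K for all components
gmm_log_dens <- function(X, means, covs) {
  K <- length(covs)
  out <- matrix(NA_real_, nrow(X), K)
  for (i in seq_len(K)) {
    out[, i] <- mvn_density(X, means[i, ], covs[[i]], log = TRUE)
  }
  out
}

log_sum_exp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# one EM run from a given hard initial assignment
em_run <- function(X, k_comp, init_labels, ridge, tol, max_iter) {
  n <- nrow(X); k <- ncol(X)
  # init from hard labels
  w <- tabulate(init_labels, nbins = k_comp) / n
  w[w == 0] <- 1 / n
  w <- w / sum(w)
  means <- matrix(0, k_comp, k)
  covs <- vector("list", k_comp)
  glob_cov <- stats::cov(X) + diag(ridge, k)
  for (i in seq_len(k_comp)) {
    idx <- which(init_labels == i)
    if (length(idx) >= 2L) {
      means[i, ] <- colMeans(X[idx, , drop = FALSE])
      ci <- stats::cov(X[idx, , drop = FALSE]) * (length(idx) - 1) / length(idx)
      covs[[i]] <- ci + diag(ridge, k)
    } else {
      means[i, ] <- X[sample.int(n, 1L), ]
      covs[[i]] <- glob_cov
    }
  }
  em_iterate(X, w, means, covs, ridge, tol, max_iter)
}

# continue EM from an earlier run's parameters
em_resume <- function(X, run, ridge, tol, max_iter) {
  em_iterate(X, run$weights, run$means, run$covs, ridge, tol, max_iter)
}

em_iterate <- function(X, w, means, covs, ridge, tol, max_iter) {
  n <- nrow(X); k <- ncol(X)
  k_comp <- length(w)
  loglik_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step
    ld <- sweep(gmm_log_dens(X, means, covs), 2L, log(w), `+`)
    lse <- log_sum_exp_rows(ld)
    ll <- sum(lse)
    loglik_trace <- c(loglik_trace, ll)
    resp <- exp(ld - lse)
    # M-step
    nk <- colSums(resp)
    nk <- pmax(nk, .Machine$double.eps)
    w <- nk / n
    for (i in seq_len(k_comp)) {
      mu <- colSums(resp[, i] * X) / nk[i]
      xc <- sweep(X, 2L, mu)
      covs[[i]] <- crossprod(xc * resp[, i], xc) / nk[i] + diag(ridge, k)
      means[i, ] <- mu
    }
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(weights = w, means = means, covs = covs,
       loglik = loglik_trace[length(loglik_trace)],
       loglik_trace = loglik_trace, converged = converged,
       n_iter = length(loglik_trace))
}

#' Fit a K-component Gaussian mixture by EM
#'
#' Expectation maximization with unconstrained (full) covariance matrices.
#' Each restart is seeded by a k-means partition of the data; the run with
#' the highest maximized log-likelihood is kept. Components are stored in
#' canonical order (increasing first mean coordinate) so labels are stable.
#'
#' @param data Data frame (or matrix) of observations.
#' @param vars Columns to cluster on (character); default all numeric
#'   columns (or all columns of a matrix).
#' @param k Number of mixture components.
#' @param n_init Number of EM restarts (default 10).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param ridge Diagonal regularization added to each covariance update for
#'   numerical safety (default 1e-6).
#' @param seed Optional integer seed making restarts reproducible; the
#'   caller's RNG stream is left untouched.
#' @return A `gmm_fit` object: list with `weights`, `means`, `covs`,
#'   `loglik`, `loglik_trace`, `converged`, `n`, `k`, `n_comp`, `vars`.
#' @seealso [select_gmm_k()], [assign_clusters()], [gmm_bic()]
#' @export
fit_gmm <- function(data, vars = NULL, k = 2L, n_init = 10L, max_iter = 500L,
                    tol = 1e-6, ridge = 1e-6, seed = NULL) {
  X <- as_feature_matrix(data, vars)
  n <- nrow(X); kdim <- ncol(X)
  if (any(!is.finite(X))) stop("non-finite values in the data", call. = FALSE)
  if (n <= k * kdim) {
    stop(sprintf("need more than k * n_features = %d observations", k * kdim),
         call. = FALSE)
  }
  # restart strategy: run every k-means-seeded restart for a short burn-in,
  # keep the best by log-likelihood, then iterate that one to convergence
  # (the log-likelihood path of the winning run is continuous, so the EM
  # monotonicity guarantee is preserved across the two phases)
  burn_in <- min(25L, max_iter)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      init <- if (k == 1L) {
        rep(1L, n)
      } else {
        suppressWarnings(stats::kmeans(X, centers = k, nstart = 1L,
                                       iter.max = 100L)$cluster)
      }
      run <- em_run(X, k, init, ridge = ridge, tol = tol,
                    max_iter = if (k == 1L) max_iter else burn_in)
      if (is.null(best) || run$loglik > best$loglik) best <- run
      if (k == 1L) break  # single component: EM is deterministic
    }
    if (!best$converged && k > 1L) {
      cont <- em_resume(X, best, ridge = ridge, tol = tol,
                        max_iter = max_iter - best$n_iter)
      cont$loglik_trace <- c(best$loglik_trace, cont$loglik_trace)
      cont$n_iter <- length(cont$loglik_trace)
      best <- cont
    }
  })
  ord <- order(best$means[, 1L])
  structure(list(
    weights = best$weights[ord],
    means = best$means[ord, , drop = FALSE],
    covs = best$covs[ord],
    loglik = best$loglik,
    loglik_trace = best$loglik_trace,
    converged = best$converged,
    n_iter = best$n_iter,
    n = n, k = kdim, n_comp = k,
    vars = colnames(X)
  ), class = "gmm_fit")
}

as_feature_matrix <- function(data, vars = NULL) {
  if (is.matrix(data)) {
    X <- data
    if (!is.null(vars)) X <- X[, vars, drop = FALSE]
    if (is.null(colnames(X))) {
      colnames(X) <- paste0("x", seq_len(ncol(X)))
    }
    return(X)
  }
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  missing <- setdiff(vars, names(data))
  if (length(missing) > 0L) {
    stop("columns not in `data`: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as.matrix(data[vars])
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("<gmm_fit> %d components in %d dimensions, n = %d, logLik = %.3f%s\n",
              x$n_comp, x$k, x$n, x$loglik,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Bayesian information criterion of a mixture fit
#'
#' `BIC = -2 ln L + t ln n` with `t = (K - 1) + K k + K k (k + 1) / 2` free
#' parameters (weights, means, full covariances). Lower is better.
#'
#' @param model A `gmm_fit`.
#' @return The BIC value.
#' @export
gmm_bic <- function(model) {
  stopifnot(inherits(model, "gmm_fit"))
  t <- gmm_n_params(model$n_comp, model$k)
  -2 * model$loglik + t * log(model$n)
}

gmm_n_params <- function(K, k) (K - 1) + K * k + K * k * (k + 1) / 2

#' Select the number of mixture components by BIC
#'
#' Fits mixtures with `K = 1 .. k_max` components and picks the `K`
#' minimizing the BIC; the number of sub-populations is read off where the
#' BIC has its minimum.
#'
#' @inheritParams fit_gmm
#' @param k_max Largest component count to try (default 4).
#' @param ... Passed to [fit_gmm()].
#' @return A `gmm_selection` object: list with `selection` (tibble of `K`,
#'   `loglik`, `n_params`, `bic`), `selected_k`, and `fits` (one `gmm_fit`
#'   per `K`).
#' @export
select_gmm_k <- function(data, vars = NULL, k_max = 4L, seed = NULL, ...) {
  if (k_max < 1L) stop("`k_max` must be at least 1", call. = FALSE)
  fits <- vector("list", k_max)
  for (K in seq_len(k_max)) {
    fits[[K]] <- fit_gmm(data, vars = vars, k = K,
                         seed = if (is.null(seed)) NULL else seed + K, ...)
  }
  tab <- tibble::tibble(
    K = seq_len(k_max),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    n_params = vapply(seq_len(k_max),
                      function(K) gmm_n_params(K, fits[[K]]$k), numeric(1)),
    bic = vapply(fits, gmm_bic, numeric(1))
  )
  structure(list(selection = tab,
                 selected_k = tab$K[which.min(tab$bic)],
                 fits = fits),
            class = "gmm_selection")
}

#' @export
print.gmm_selection <- function(x, ...) {
  cat(sprintf("<gmm_selection> BIC minimum at K = %d\n", x$selected_k))
  print(x$selection)
  invisible(x)
}

#' Assign events to mixture components
#'
#' Each event goes to the component where it has the highest posterior
#' probability, i.e. the argmax of `w_i N(x | mu_i, Sigma_i)`. Exact ties
#' resolve to the lowest component index.
#'
#' @param model A `gmm_fit`.
#' @param data Data with the model's feature columns (or a matrix).
#' @return Integer vector of component labels in `1..K`.
#' @export
assign_clusters <- function(model, data) {
  stopifnot(inherits(model, "gmm_fit"))
  cn <- colnames_of(data)
  vars <- if (all(model$vars %in% cn)) model$vars else NULL
  X <- as_feature_matrix(data, vars)
  if (ncol(X) != model$k) {
    stop("data dimension does not match the fitted model", call. = FALSE)
  }
  ld <- sweep(gmm_log_dens(X, model$means, model$covs), 2L,
              log(model$weights), `+`)
  max.col(ld, ties.method = "first")
}

colnames_of <- function(data) {
  if (is.matrix(data)) colnames(data) %||% character(0) else names(data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster-assignment accuracy against known labels
#'
#' `(TP + TN) / total`, maximized over the mapping between arbitrary
#' cluster labels and ground-truth classes (labels are identifiable only up
#' to permutation). With all events lumped into a single cluster and two
#' equal-size true populations, the accuracy is exactly 0.5.
#'
#' @param labels Cluster labels.
#' @param truth Ground-truth class labels (same length).
#' @return Accuracy in `[0, 1]`.
#' @export
assignment_accuracy <- function(labels, truth) {
  if (length(labels) != length(truth)) {
    stop("`labels` and `truth` must have the same length", call. = FALSE)
  }
  lf <- factor(labels); tf <- factor(truth)
  m <- max(nlevels(lf), nlevels(tf))
  if (m > 8L) stop("more than 8 classes: exhaustive matching not supported",
                   call. = FALSE)
  conf <- matrix(0, m, m)
  conf[seq_len(nlevels(lf)), seq_len(nlevels(tf))] <-
    table(lf, tf)
  perms <- permutations_of(m)
  best <- 0
  for (p in perms) {
    hit <- sum(conf[cbind(seq_len(m), p)])
    if (hit > best) best <- hit
  }
  best / length(labels)
}

permutations_of <- function(m) {
  if (m == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(m)) {
    for (rest in permutations_of(m - 1L)) {
      tail <- seq_len(m)[-i][rest]
      out[[length(out) + 1L]] <- c(i, tail)
    }
  }
  out
}
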