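# Gaussian mixture fitting, BIC selection and cluster assignment.

make_two_gaussians <- function(n1 = 300, n2 = 300, shift = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(
    cbind(rnorm(n1, 0, 1), rnorm(n1, 0, 1)),
    cbind(rnorm(n2, shift, 1), rnorm(n2, shift / 2, 1.5)))
  colnames(X) <- c("f1", "f2")
  X
}

test_that("mvn_density matches closed-form anchor points and integrates to 1", {
  expect_equal(mvn_density(0, 0, 1), 1 / sqrt(2 * pi))
  expect_equal(mvn_density(c(1, 2), c(1, 2), diag(2)), 1 / (2 * pi))
  # quadrature over a wide grid
  g <- seq(-8, 8, by = 0.05)
  pts <- cbind(rep(g, times = length(g)), rep(g, each = length(g)))
  sig <- matrix(c(1.2, 0.5, 0.5, 0.9), 2)
  total <- sum(mvn_density(pts, c(0.3, -0.2), sig)) * 0.05^2
  expect_equal(total, 1, tolerance = 1e-3)
  expect_error(mvn_density(c(0, 0), c(0, 0), matrix(c(1, 1, 1, 1), 2)),
               "positive definite")
})

test_that("EM recovers parameters of a single Gaussian", {
  set.seed(2)
  X <- cbind(a = rnorm(2000, 5, 2), b = rnorm(2000, -1, 0.5))
  fit <- fit_gmm(X, k = 1, seed = 1)
  se <- c(2, 0.5) / sqrt(2000)
  expect_true(all(abs(fit$means[1, ] - c(5, -1)) < 3 * se))
  expect_equal(fit$weights, 1)
})

test_that("EM recovers two well-separated components and their weights", {
  X <- make_two_gaussians(n1 = 400, n2 = 600, shift = 8, seed = 3)
  fit <- fit_gmm(X, k = 2, seed = 1)
  # canonical order: component 1 has the smaller first mean coordinate
  expect_lt(max(abs(fit$means[1, ] - c(0, 0))), 3 * 1.5 / sqrt(400))
  expect_lt(max(abs(fit$means[2, ] - c(8, 4))), 3 * 1.5 / sqrt(600))
  expect_equal(fit$weights, c(0.4, 0.6), tolerance = 0.05)
})

test_that("EM log-likelihood is monotone non-decreasing", {
  X <- make_two_gaussians(seed = 4)
  for (k in 1:3) {
    fit <- fit_gmm(X, k = k, n_init = 2, seed = 5)
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
  }
})

test_that("mixture weights sum to one and covariances stay positive definite", {
  X <- make_two_gaussians(seed = 6)
  fit <- fit_gmm(X, k = 3, seed = 7)
  expect_equal(sum(fit$weights), 1)
  for (s in fit$covs) {
    expect_true(min(eigen(s, symmetric = TRUE,
                          only.values = TRUE)$values) > 0)
  }
})

test_that("BIC follows -2 lnL + t ln n with the full-covariance parameter count", {
  fake <- structure(list(loglik = -100, n = 1000L, k = 1L, n_comp = 2L),
                    class = "gmm_fit")
  # K=2, k=1: t = 1 + 2 + 2 = 5
  expect_equal(gmm_bic(fake), 200 + 5 * log(1000))
  # K=2, k=2: t = 1 + 4 + 6 = 11
  expect_equal(rtdcstats:::gmm_n_params(2, 2), 11)
  expect_equal(rtdcstats:::gmm_n_params(1, 2), 5)
  # the penalty is monotone in the parameter count at fixed lnL
  fake3 <- structure(list(loglik = -100, n = 1000L, k = 1L, n_comp = 3L),
                     class = "gmm_fit")
  expect_gt(gmm_bic(fake3), gmm_bic(fake))
  # parameter count equals a direct degrees-of-freedom enumeration
  for (K in 1:4) {
    for (k in 1:4) {
      df_direct <- (K - 1) + K * k + K * k * (k + 1) / 2
      expect_equal(rtdcstats:::gmm_n_params(K, k), df_direct)
    }
  }
})

test_that("BIC selects one component for single-Gaussian data", {
  hits <- sum(vapply(1:20, function(s) {
    set.seed(s)
    X <- cbind(rnorm(400), rnorm(400))
    select_gmm_k(X, k_max = 3, seed = s)$selected_k == 1L
  }, logical(1)))
  expect_gte(hits, 18)
})

test_that("BIC finds two components for separated mixtures and k_max=1 degenerates", {
  X <- make_two_gaussians(shift = 7, seed = 8)
  sel <- select_gmm_k(X, k_max = 4, seed = 9)
  expect_identical(sel$selected_k, 2L)
  expect_identical(sel$selection$K[which.min(sel$selection$bic)], 2L)
  sel1 <- select_gmm_k(X, k_max = 1, seed = 9)
  expect_identical(sel1$selected_k, 1L)
})

test_that("assignment picks the max-posterior component with stable tie-break", {
  X <- make_two_gaussians(shift = 10, seed = 10)
  fit <- fit_gmm(X, k = 2, seed = 11)
  expect_identical(assign_clusters(fit, fit$means)[1], 1L)
  expect_identical(assign_clusters(fit, fit$means)[2], 2L)
  # symmetric two-component model: equidistant point goes to component 1
  sym <- structure(list(
    weights = c(0.5, 0.5), means = rbind(c(-1, 0), c(1, 0)),
    covs = list(diag(2), diag(2)), loglik = 0, n = 10L, k = 2L,
    n_comp = 2L, vars = c("f1", "f2")), class = "gmm_fit")
  expect_identical(assign_clusters(sym, rbind(c(0, 0))), 1L)
})

test_that("labels are invariant to feature-order-preserving refits", {
  X <- make_two_gaussians(shift = 8, seed = 12)
  f1 <- fit_gmm(X, k = 2, seed = 13)
  f2 <- fit_gmm(X, k = 2, seed = 99)
  # different restarts, same canonical component order -> same labels
  expect_identical(assign_clusters(f1, X), assign_clusters(f2, X))
})

test_that("fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  # Mclust resolves helpers in the search path, so attach it for this test
  suppressMessages(library(mclust))
  X <- make_two_gaussians(n1 = 500, n2 = 500, shift = 6, seed = 14)
  fit <- fit_gmm(X, k = 2, seed = 15)
  mc <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  ours <- fit$means[order(fit$means[, 1]), ]
  theirs <- t(mc$parameters$mean)[order(t(mc$parameters$mean)[, 1]), ]
  expect_equal(unname(ours), unname(theirs), tolerance = 0.05)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3 * abs(mc$loglik))
})

test_that("accuracy is permutation-maximized and handles the merged case", {
  expect_equal(assignment_accuracy(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  # everything in one cluster, two equal populations -> exactly 0.5
  expect_identical(assignment_accuracy(rep(1, 100), rep(1:2, each = 50)),
                   0.5)
  # brute-force check against all label permutations on a small case
  set.seed(16)
  labels <- sample(1:3, 30, replace = TRUE)
  truth <- sample(1:3, 30, replace = TRUE)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  brute <- max(vapply(perms, function(p) {
    mean(p[labels] == truth)
  }, numeric(1)))
  expect_equal(assignment_accuracy(labels, truth), brute)
  expect_error(assignment_accuracy(1:3, 1:4), "same length")
})

test_that("accuracy is bounded below by the majority class under lumping", {
  truth <- rep(1:2, times = c(70, 30))
  expect_gte(assignment_accuracy(rep(1, 100), truth), 0.7)
})

test_that("tidiers expose component parameters and fit summaries", {
  X <- make_two_gaussians(seed = 17)
  fit <- fit_gmm(X, k = 2, seed = 18)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_true(all(c("component", "weight", "mean_f1", "sd_f2") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$bic, gmm_bic(fit))
  sel <- select_gmm_k(X, k_max = 2, seed = 19)
  expect_identical(tidy(sel), sel$selection)
})
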