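# Synthetic-data generators: determinism, distributional targets and
# end-to-end wiring into the estimators.

test_that("generators are pure functions of their seed", {
  expect_identical(gen_population(200, seed = 5), gen_population(200, seed = 5))
  c1 <- gen_contour("blob", r = 9, seed = 3)
  c2 <- gen_contour("blob", r = 9, seed = 3)
  expect_identical(c1$x, c2$x)
  expect_identical(gen_replicates(seed = 2), gen_replicates(seed = 2))
  r1 <- gen_rare_subpopulation(n = 500, seed = 4)
  expect_identical(r1, gen_rare_subpopulation(n = 500, seed = 4))
})

test_that("generated contours have the requested geometry", {
  circ <- gen_contour("circle", r = 10, n_vertices = 360)
  expect_equal(contour_area(circ), pi * 100, tolerance = 1e-3)
  # a deep star fails the convexity gate
  star <- gen_contour("star", r = 10, spike_depth = 0.5, n_vertices = 240)
  expect_gt(contour_area_ratio(star), 1.05)
  # a shallow star passes it
  shallow <- gen_contour("star", r = 10, spike_depth = 0.02,
                         n_vertices = 240)
  expect_lt(contour_area_ratio(shallow), 1.05)
  expect_error(gen_contour("circle", r = -1), "positive")
  expect_error(gen_contour("circle", n_vertices = 5), "12")
})

test_that("population sampling hits the requested moments", {
  pop <- gen_population(5000, seed = 6)
  expect_equal(mean(pop$area), 343, tolerance = 3 * 80 / sqrt(5000))
  expect_equal(sd(pop$area), 80, tolerance = 3)
  expect_equal(mean(pop$modulus), 7, tolerance = 3 * 1.2 / sqrt(5000))
  expect_true(all(pop$area > 0 & pop$modulus > 0 & pop$deform > 0))
  expect_equal(pop$log_deform, log(pop$deform))
})

test_that("degenerate spreads give identical deformations", {
  pop <- gen_population(50, sd_area = 0, sd_modulus = 0, seed = 7)
  expect_equal(diff(range(pop$deform)), 0)
})

test_that("assay steps approach each other and defaults match the protocol", {
  steps <- gen_two_population_assay(step_count = 3, n_events = 300, seed = 8)
  expect_length(steps, 3)
  expect_equal(steps[[1]]$mean_area_2, 120)
  expect_equal(steps[[2]]$mean_area_2, 115)
  expect_equal(nrow(steps[[1]]$pop1), 300)
  # default protocol: stationary 70 um^2, steps of 5 um^2, modulus 2.5 kPa
  frm <- formals(gen_two_population_assay)
  expect_equal(frm$stationary_area, 70)
  expect_equal(frm$step_area, 5)
  expect_equal(frm$modulus, 2.5)
  expect_equal(frm$n_events, 1000L)
  # overlap grows monotonically in expectation as population 2 shrinks
  ov <- vapply(gen_two_population_assay(step_count = 6, n_events = 400,
                                        start_area = 95, seed = 9),
               function(s) contour_overlap(s$pop1, s$pop2,
                                           c("area", "log_deform")),
               numeric(1))
  expect_gt(ov[6], ov[1])
  expect_gt(cor(seq_along(ov), ov), 0.9)
})

test_that("rare sub-population size follows the binomial plant", {
  tab <- gen_rare_subpopulation(n = 10000, rare_fraction = 0.02, seed = 10)
  expect_equal(sum(tab$rare), 200, tolerance = 3 * sqrt(10000 * 0.02 * 0.98))
  none <- gen_rare_subpopulation(n = 1000, rare_fraction = 0, seed = 11)
  expect_identical(sum(none$rare), 0L)
  expect_error(gen_rare_subpopulation(rare_fraction = 0.7), "0.5")
})

test_that("replicate generator honors the design and supports imbalance", {
  d <- gen_replicates(n_rep_control = 2, n_rep_treatment = 3,
                      n_per_cell = 40, seed = 12)
  tab <- table(d$replicate, d$condition)
  expect_equal(unname(tab["rep3", "control"]), 0)
  expect_equal(unname(tab["rep3", "treatment"]), 40)
  expect_equal(unname(tab["rep1", "control"]), 40)
})

test_that("injected power target is reached at the default effect size", {
  # effect beta = 2 * sd_residual / sqrt(n per replicate-cell); with random
  # slope variability kept below it this is detectable by design
  n_cell <- 100
  beta <- 2 * 1 / sqrt(n_cell)
  hits <- sum(vapply(1:200, function(s) {
    d <- gen_replicates(n_rep_control = 6, n_rep_treatment = 6,
                        n_per_cell = n_cell, beta = beta,
                        sd_intercept = 0.3, sd_slope = 0.02,
                        sd_residual = 1, seed = 5000 + s)
    fit_lmm(d)$p_value < 0.05
  }, logical(1)))
  expect_gte(hits / 200, 0.8)
})

test_that("generated event tables satisfy the feature-record invariants", {
  pop <- gen_population(500, seed = 13)
  expect_true(all(pop$area > 0))
  expect_true(all(pop$deform > 0 & pop$deform < 1))
  tab <- gen_rare_subpopulation(n = 500, seed = 14)
  expect_true(all(tab$area_ratio >= 1))
  expect_true(all(abs(tab$sx) <= 1 & abs(tab$sy) <= 1))
  expect_true(all(tab$volume > 0))
})
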