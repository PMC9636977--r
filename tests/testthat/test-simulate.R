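test_that("instance generation matches the requested topology and is deterministic", {
  spec_empty <- scenario_spec(n = 10, network = list(kind = "empty"),
                              design = list(kind = "crd", p = 0.5), seed = 4)
  inst <- generate_instance(spec_empty)
  expect_identical(max_outdegree(inst$model), 0L)
  expect_equal(total_treatment_effect(inst$model), mean(inst$model$beta))

  spec_star <- scenario_spec(n = 8, network = list(kind = "star"),
                             beta = list(dist = "constant", value = 0.5),
                             gamma = list(dist = "constant", value = 0.25),
                             design = list(kind = "crd", p = 0.5), seed = 4)
  star <- generate_instance(spec_star)$model
  expect_identical(max_outdegree(star), 7L)
  expect_equal(total_treatment_effect(star), 0.5 + 7 * 0.25 / 8)

  spec_er <- scenario_spec(n = 50, network = list(kind = "erdos_renyi",
                                                  q = 0.3), seed = 9)
  a <- generate_instance(spec_er)
  b <- generate_instance(spec_er)
  expect_identical(a$model, b$model)

  spec_chain <- scenario_spec(n = 5, network = list(kind = "chain"), seed = 2)
  chain <- generate_instance(spec_chain)$model
  expect_identical(max_outdegree(chain), 1L)
  expect_identical(nrow(chain$edges), 4L)
})

test_that("Monte-Carlo runs are bit-reproducible", {
  spec <- scenario_spec(n = 12, seed = 6, reps = 50)
  inst <- generate_instance(spec)
  r1 <- run_monte_carlo(inst$model, inst$design, "baseline_adjusted",
                        reps = 50, seed = 77)
  r2 <- run_monte_carlo(inst$model, inst$design, "baseline_adjusted",
                        reps = 50, seed = 77)
  expect_identical(r1, r2)
  expect_gt(r1$se_mean, 0)
})

test_that("empirical moments agree with theory across designs and networks", {
  # a small agreement grid; 4-SE criterion per comparison
  grid <- list(
    list(net = list(kind = "erdos_renyi", q = 0.2), n = 16,
         design = list(kind = "crd", p = 0.5)),
    list(net = list(kind = "planted_clusters", n_clusters = 4,
                    within = 0.5, between = 0.05), n = 16,
         design = list(kind = "cluster", n_clusters = 4, treated = 2)),
    list(net = list(kind = "star"), n = 12,
         design = list(kind = "saturation", n_clusters = 2,
                       saturations = c(1/3, 2/3))))
  for (g in grid) {
    spec <- scenario_spec(n = g$n, network = g$net, design = g$design,
                          seed = 21, reps = 3000)
    inst <- generate_instance(spec)
    res <- run_monte_carlo(inst$model, inst$design, "baseline_adjusted",
                           reps = spec$reps, seed = 31)
    expect_lt(res$mean_dev_se, 4)
    expect_lt(res$var_dev_se, 4)
  }
})

test_that("unbiasedness under no interference shows up empirically", {
  spec <- scenario_spec(n = 20, network = list(kind = "empty"),
                        design = list(kind = "crd", p = 0.5), seed = 3)
  inst <- generate_instance(spec)
  res <- run_monte_carlo(inst$model, inst$design, "baseline_adjusted",
                         reps = 2000, seed = 13)
  expect_lt(abs(res$mean - res$tte) / res$se_mean, 4)
})

test_that("estimator failures are counted, not silently dropped", {
  m <- hane_model(rep(0, 4), rep(1, 4))
  d <- design_bernoulli(4, 0.5)   # can produce empty arms
  res <- run_monte_carlo(m, d, "difference_in_means", reps = 500, seed = 2)
  expect_gt(res$n_failed, 0)
  boom <- function(z, Y) stop("nope")
  expect_error(run_monte_carlo(m, d, boom, reps = 10, seed = 2),
               "failed on draw")
})

test_that("baseline noise leaves the estimator unbiased and inflates variance", {
  spec <- scenario_spec(n = 16, seed = 10)
  inst <- generate_instance(spec)
  # zero noise reproduces the plain Monte-Carlo run
  plain <- run_monte_carlo(inst$model, inst$design, "baseline_adjusted",
                           reps = 400, seed = 55)
  noiseless <- baseline_noise_study(inst$model, inst$design, 0,
                                    reps = 400, seed = 55)
  expect_equal(noiseless$mean, plain$mean, tolerance = exact_tol)
  expect_equal(noiseless$variance, plain$variance, tolerance = exact_tol)
  # zero-mean noise: no bias, predicted inflation noise_sd^2 / p^2
  noisy <- baseline_noise_study(inst$model, inst$design, 0.5,
                                reps = 3000, seed = 56)
  expect_lt(noisy$mean_dev_se, 4)
  expect_lt(noisy$var_dev_se, 4)
})

test_that("a constant baseline offset propagates to bias -delta/p", {
  m <- random_dyadic_hane(8, seed = 17)
  d <- design_crd(8, 4)
  delta <- 0.75
  # enumeration: shift the baseline estimate by delta in average mode
  est <- estimator_baseline_adjusted(design_marginals(d),
                                     alpha_bar = mean(m$alpha) + delta)
  em <- exhaustive_moments(m, d, est)
  expect_equal(em$expectation - total_treatment_effect(m), -delta / 0.5,
               tolerance = exact_tol)
  # the harness reaches the same prediction
  res <- baseline_noise_study(m, d, 0, reps = 500, seed = 18, offset = delta)
  expect_equal(res$predicted_mean,
               total_treatment_effect(m) - delta / 0.5, tolerance = exact_tol)
  expect_lt(res$mean_dev_se, 4)
})

test_that("homogeneous-influence clusters make uniform saturation beat CRD", {
  # clusters grouped by influence level: within-cluster variance is zero,
  # so the saturation design removes all of the CRD variance
  b <- rep(c(0, 2), each = 4)
  m <- hane_model(rep(0, 8), b)
  cl <- rep(1:2, each = 4)
  expect_lte(variance_saturation(m, cl, 1/2), variance_crd(m, 1/2))
  expect_equal(variance_saturation(m, cl, 1/2), 0)
  expect_gt(variance_crd(m, 1/2), 0)
})

test_that("scenario validation rejects incomplete specifications", {
  expect_error(scenario_spec(n = 1), "at least 2")
  expect_error(scenario_spec(network = list(kind = "smallworld")),
               "unknown network kind")
  expect_error(scenario_spec(alpha = list(dist = "gamma")),
               "normal/uniform/constant")
  expect_error(scenario_spec(reps = 0), "reps")
})
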