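test_that("influence sums marginal-weighted outgoing effects", {
  m0 <- hane_model(alpha = c(0, 0), beta = c(1, 0))
  expect_equal(influence_vector(m0, rep(0.5, 2))$L, c(1, 0))

  m <- hane_model(alpha = c(0, 0), beta = c(1, 0),
                  edges = data.frame(source = 1, target = 2, gamma = 2))
  # equal marginals: row sums, and mean(L) = TTE
  L_eq <- influence_vector(m, rep(0.5, 2))$L
  expect_equal(L_eq, c(3, 0))
  expect_equal(mean(L_eq), total_treatment_effect(m))
  # unequal marginals: the displayed ratio
  L_uneq <- influence_vector(m, c(1/2, 1/4))$L
  expect_equal(L_uneq, c(1 + (1/2) * 2 / (1/4), 0))
  expect_error(influence_vector(m, c(0, 0.5)), "zero marginal")
})

test_that("mean influence equals TTE for any equal-marginal design", {
  for (seed in 1:5) {
    m <- random_dyadic_hane(9, seed = seed)
    expect_equal(mean(influence_vector(m, design_crd(9, 3))$L),
                 total_treatment_effect(m), tolerance = exact_tol)
  }
})

test_that("HT bias closed form matches its limiting cases", {
  # all edges inside jointly assigned clusters: zero bias
  m <- hane_model(rep(0, 4), rep(1, 4) / 2,
                  edges = data.frame(source = c(1, 3), target = c(2, 4),
                                     gamma = c(0.5, -0.25)))
  d_cl <- design_cluster(c(1, 1, 2, 2), 1)
  expect_equal(bias_ht(m, d_cl), 0, tolerance = exact_tol)
  # independent treatments: only the network part is lost
  d_b <- design_bernoulli(4, 0.4)
  expect_equal(bias_ht(m, d_b), -sum(m$edges$gamma) / 4,
               tolerance = exact_tol)
  # single-edge CRD value, from the enumerated moments
  m1 <- hane_model(rep(0, 4), rep(0, 4),
                   edges = data.frame(source = 1, target = 2, gamma = 1))
  expect_equal(bias_ht(m1, design_crd(4, 2)), -1 / 3, tolerance = exact_tol)
})

test_that("baseline-adjusted bias closed form matches its limiting cases", {
  m1 <- hane_model(rep(0, 2), rep(0, 2),
                   edges = data.frame(source = 1, target = 2, gamma = 1))
  expect_equal(bias_baseline_adjusted(m1, design_crd(2, 1)), 0)
  # marginals (1/2, 1/4) on the single edge
  d_sat <- design_saturation(c(1, 1, 2, 2, 2, 2), c(1/2, 1/4))
  m2 <- hane_model(rep(0, 6), rep(0, 6),
                   edges = data.frame(source = 1, target = 3, gamma = 1))
  expect_equal(bias_baseline_adjusted(m2, d_sat), (1/2 / (1/4) - 1) * 1 / 6)
  # enumeration confirms the bias on a varying-saturation toy
  mu <- design_marginals(d_sat)
  em <- exhaustive_moments(m2, d_sat,
                           estimator_baseline_adjusted(mu, m2$alpha))
  expect_equal(em$expectation - total_treatment_effect(m2),
               bias_baseline_adjusted(m2, d_sat), tolerance = exact_tol)
})

test_that("enumeration certifies every bias formula on random instances", {
  for (seed in 1:10) {
    m <- random_dyadic_hane(6, seed = seed + 40)
    tte <- total_treatment_effect(m)
    for (d in list(design_crd(6, 2), design_bernoulli(6, 0.5),
                   design_cluster(rep(1:3, each = 2), 1),
                   design_saturation(rep(1:2, each = 3), c(1/3, 2/3)))) {
      mu <- design_marginals(d)
      em_ht <- exhaustive_moments(m, d, estimator_ht(mu))
      expect_equal(em_ht$expectation - tte, bias_ht(m, d),
                   tolerance = exact_tol)
      em_ba <- exhaustive_moments(m, d,
                                  estimator_baseline_adjusted(mu, m$alpha))
      expect_equal(em_ba$expectation - tte, bias_baseline_adjusted(m, d),
                   tolerance = exact_tol)
    }
  }
})

test_that("variance closed forms equal enumeration and the general formula", {
  for (seed in 1:6) {
    m <- random_dyadic_hane(8, seed = seed + 70)
    p <- 0.5
    # completely randomized
    d <- design_crd(8, 4)
    em <- exhaustive_moments(m, d,
            estimator_baseline_adjusted(design_marginals(d), m$alpha))
    expect_equal(variance_crd(m, p), em$variance, tolerance = exact_tol)
    expect_equal(variance_crd(m, p), variance_general(m, d),
                 tolerance = exact_tol)
    # cluster
    cl <- rep(1:4, each = 2)
    d_cl <- design_cluster(cl, 2)
    em_cl <- exhaustive_moments(m, d_cl,
               estimator_baseline_adjusted(design_marginals(d_cl), m$alpha))
    expect_equal(variance_cluster(m, cl, 0.5), em_cl$variance,
                 tolerance = exact_tol)
    expect_equal(variance_cluster(m, cl, 0.5), variance_general(m, d_cl),
                 tolerance = exact_tol)
    # saturation, uniform and varying
    cl2 <- rep(1:2, each = 4)
    for (sats in list(c(1/2, 1/2), c(1/4, 3/4))) {
      d_s <- design_saturation(cl2, sats)
      em_s <- exhaustive_moments(m, d_s,
                estimator_baseline_adjusted(design_marginals(d_s), m$alpha))
      expect_equal(variance_saturation(m, cl2, sats), em_s$variance,
                   tolerance = exact_tol)
      expect_equal(variance_saturation(m, cl2, sats),
                   variance_general(m, d_s), tolerance = exact_tol)
    }
  }
})

test_that("hand-derived variance values hold", {
  # constant influence under fixed treated count: zero variance
  m_const <- hane_model(c(0, 0), c(1, 1))
  expect_equal(variance_crd(m_const, 0.5), 0)
  # n = 2, L = (0, 2): population variance 1, prefactor 1
  m2 <- hane_model(c(0, 0), c(0, 2))
  expect_equal(variance_crd(m2, 0.5), 1)
  em <- exhaustive_moments(m2, design_crd(2, 1),
          estimator_baseline_adjusted(rep(0.5, 2), m2$alpha))
  expect_equal(em$variance, 1)
  # Bernoulli design: diagonal covariance
  m3 <- random_dyadic_hane(5, seed = 3)
  d_b <- design_bernoulli(5, 0.25)
  L <- influence_vector(m3, d_b)$L
  expect_equal(variance_general(m3, d_b),
               sum(L^2) * 0.75 / 0.25 / 25, tolerance = exact_tol)
  # cluster-mean influences (0, 2) over two clusters
  m4 <- hane_model(rep(0, 4), c(0, 0, 2, 2))
  expect_equal(variance_cluster(m4, c(1, 1, 2, 2), 0.5), 1)
  # one cluster of two with L = (0, 2) at half saturation
  expect_equal(variance_saturation(m2, c(1, 1), 1/2), 1)
})

test_that("specialization chain links the variance formulas", {
  m <- random_dyadic_hane(8, seed = 123)
  # singleton clusters reduce the cluster formula to the CRD formula
  expect_equal(variance_cluster(m, 1:8, 0.5), variance_crd(m, 0.5),
               tolerance = exact_tol)
  # uniform saturation is the p_tau = p specialization of the varying form
  cl <- rep(1:2, each = 4)
  p <- 0.5
  Lv <- influence_vector(m, rep(p, 8))$L
  V_tau <- tapply(Lv, cl, function(x) mean(x^2) - mean(x)^2)
  n_tau <- tabulate(cl)
  uniform_display <- (1 - p) / (p * 8) *
    sum(n_tau^2 / (8 * (n_tau - 1)) * V_tau)
  expect_equal(variance_saturation(m, cl, c(p, p)), uniform_display,
               tolerance = exact_tol)
})

test_that("CRD variance obeys the outdegree bound and the 1/pn scaling", {
  for (seed in 1:5) {
    m <- random_dyadic_hane(10, seed = seed + 300)
    B <- max(abs(m$beta), if (nrow(m$edges)) abs(m$edges$gamma) else 0)
    dmax <- max(1L, max_outdegree(m))
    p <- 0.5
    # popvar(L) <= (B (1 + dmax))^2 <= 4 B^2 dmax^2
    expect_lte(variance_crd(m, p),
               (1 - p) / (p * (10 - 1)) * 4 * B^2 * dmax^2)
  }
  # doubling n with the same influence population halves the variance up to
  # the (n - 1) correction
  b <- c(-2, 1, 3, 0.5, -1, 2) / 2
  m_n <- hane_model(rep(0, 6), b)
  m_2n <- hane_model(rep(0, 12), rep(b, 2))
  expect_equal(variance_crd(m_n, 0.5) / variance_crd(m_2n, 0.5),
               (2 * 6 - 1) / (6 - 1), tolerance = exact_tol)
})

test_that("unbiasedness condition reports match design structure", {
  edges <- data.frame(source = c(1, 3), target = c(2, 4), gamma = c(1, 1))
  d_cl <- design_cluster(c(1, 1, 2, 2), 1)
  rep_cl <- check_unbiasedness(d_cl, edges)
  expect_true(rep_cl$joint_assignment$satisfied)
  expect_true(rep_cl$equal_marginals$satisfied)

  d_crd <- design_crd(4, 2)
  rep_crd <- check_unbiasedness(d_crd, edges)
  expect_false(rep_crd$joint_assignment$satisfied)
  expect_equal(nrow(rep_crd$joint_assignment$violations), 2L)
  expect_true(rep_crd$equal_marginals$satisfied)
  expect_true(rep_crd$common_ratio$satisfied)
  expect_equal(unname(rep_crd$common_ratio$rho[c(2, 4)]), c(1, 1))

  # cross-cluster edge between different saturation levels
  d_sat <- design_saturation(rep(1:2, each = 3), c(1/3, 2/3))
  cross <- data.frame(source = 1, target = 4, gamma = 1)
  rep_sat <- check_unbiasedness(d_sat, cross)
  expect_false(rep_sat$equal_marginals$satisfied)
  expect_equal(rep_sat$equal_marginals$violations$target, 4)

  # inconsistent ratios across two in-edges with different source marginals
  m_two <- data.frame(source = c(1, 4), target = c(2, 2), gamma = c(1, 1))
  rep_two <- check_unbiasedness(d_sat, m_two)
  expect_false(rep_two$common_ratio$satisfied)
})

test_that("enumeration oracle enforces its support cap", {
  m <- random_dyadic_hane(24, seed = 1)
  d <- design_crd(24, 12)
  expect_error(exhaustive_moments(m, d, estimator_ht(design_marginals(d)),
                                  cap = 1e4),
               "Monte-Carlo")
})

test_that("single-edge Bernoulli enumeration matches the hand calculation", {
  # four assignments by hand: the HT estimator misses the edge entirely
  m <- hane_model(c(0, 0), c(0, 0),
                  edges = data.frame(source = 1, target = 2, gamma = 0.5))
  d <- design_bernoulli(2, 0.5)
  em <- exhaustive_moments(m, d, estimator_ht(design_marginals(d)))
  expect_equal(em$expectation - total_treatment_effect(m), -0.5 / 2,
               tolerance = exact_tol)
})
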