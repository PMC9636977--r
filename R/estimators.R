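#' Individually weighted linear estimators
#'
#' The estimator class under study has the form
#' \deqn{\widehat{est}(w, v) = \sum_i (w_i z_i + v_i (1 - z_i)) Y_i(z),}
#' where the weights `w` (applied when `i` is treated) and `v` (when `i` is in
#' control) are deterministic: they may depend on design moments but never on
#' the realized treatment vector. The constructors here enforce that purity by
#' accepting only design moments at construction time.
#'
#' @param w,v numeric weight vectors of equal length.
#' @return an object of class `linear_weights`.
#' @export
linear_weights <- function(w, v) {
  w <- as.numeric(w); v <- as.numeric(v)
  if (length(w) != length(v)) stop("`w` and `v` must have the same length")
  if (anyNA(w) || anyNA(v)) stop("weights must not contain NA")
  structure(list(w = w, v = v, n = length(w)), class = "linear_weights")
}

#' Horvitz-Thompson weights from design marginals
#'
#' The unique individually weighted linear estimator that is unbiased for the
#' TTE when no interference is present: `w_i = 1/(n E[z_i])`,
#' `v_i = -1/(n E[1 - z_i])`. Under interference it is generally biased (see
#' [bias_ht()]); unbiasedness would require the design to assign every
#' connected pair jointly.
#'
#' @param marginals numeric vector of treatment probabilities `E[z_i]`, each
#'   strictly inside `(0, 1)`.
#' @return a [linear_weights()] object.
#' @export
ht_weights <- function(marginals) {
  mu <- as.numeric(marginals)
  bad <- which(!is.finite(mu) | mu <= 0 | mu >= 1)
  if (length(bad)) {
    stop("degenerate marginal treatment probability for individual ", bad[1L],
         " (E[z] = ", mu[bad[1L]], "); Horvitz-Thompson weights need 0 < E[z] < 1")
  }
  n <- length(mu)
  linear_weights(w = 1 / (n * mu), v = -1 / (n * (1 - mu)))
}

#' A realized experiment: treatment, outcomes, design marginals, baselines
#'
#' Bundles one draw of an experiment with the quantities estimation needs.
#' Baseline information comes in exactly one of two explicit modes:
#' per-individual estimates (`alpha`) or a single population-average estimate
#' (`alpha_bar`). The two are never mixed, because the population-average
#' shortcut is only valid when all marginal treatment probabilities are equal.
#'
#' @param z binary treatment vector actually assigned.
#' @param Y observed outcome vector.
#' @param marginals design marginals `E[z_i]`, each in `(0, 1)`.
#' @param alpha optional per-individual baseline estimates.
#' @param alpha_bar optional scalar population-average baseline estimate.
#' @return an object of class `experiment_record`.
#' @export
experiment_record <- function(z, Y, marginals, alpha = NULL, alpha_bar = NULL) {
  z <- as.numeric(z); Y <- as.numeric(Y)
  mu <- as.numeric(marginals)
  n <- length(z)
  if (length(Y) != n || length(mu) != n) {
    stop("`z`, `Y` and `marginals` must have equal lengths")
  }
  if (!all(z %in% c(0, 1))) stop("`z` must be binary (0/1)")
  if (any(!is.finite(mu) | mu <= 0 | mu >= 1)) {
    stop("design marginals must lie strictly inside (0, 1)")
  }
  if (!is.null(alpha) && !is.null(alpha_bar)) {
    stop("supply exactly one of `alpha` (per-individual baselines) or ",
         "`alpha_bar` (population average); they are distinct input states")
  }
  if (!is.null(alpha)) {
    alpha <- as.numeric(alpha)
    if (length(alpha) != n) stop("`alpha` must have length n")
  }
  if (!is.null(alpha_bar)) {
    alpha_bar <- as.numeric(alpha_bar)
    if (length(alpha_bar) != 1L) stop("`alpha_bar` must be a single number")
  }
  structure(list(z = z, Y = Y, marginals = mu, alpha = alpha,
                 alpha_bar = alpha_bar, n = n),
            class = "experiment_record")
}

#' Evaluate an individually weighted linear estimator
#'
#' @param weights a [linear_weights()] object.
#' @param rec an [experiment_record()].
#' @return the scalar estimate `sum_i (w_i z_i + v_i (1 - z_i)) Y_i`.
#' @export
evaluate_linear <- function(weights, rec) {
  if (weights$n != rec$n) {
    stop("weights are for n = ", weights$n, " but the record has n = ", rec$n)
  }
  sum((weights$w * rec$z + weights$v * (1 - rec$z)) * rec$Y)
}

#' Baseline-adjusted TTE estimator
#'
#' The headline estimator: subtract baselines, inverse-weight by the marginal
#' treatment probability, and average,
#' \deqn{\widehat{TTE}^{-\alpha} = \frac{1}{n} \sum_i \frac{Y_i(z) - \alpha_i}{E[z_i]}.}
#' It is unbiased whenever marginal treatment probabilities are equal across
#' every interference edge — a condition satisfiable without knowing the
#' network (e.g. any equal-marginal design such as the completely randomized
#' design satisfies it for every network).
#'
#' When every marginal equals a common `p`, the estimator only needs the
#' population-average baseline:
#' \deqn{\widehat{TTE}^{-\alpha} = \frac{1}{p}\Big(\frac{1}{n}\sum_i Y_i(z)
#'   - \frac{1}{n}\sum_i \alpha_i\Big).}
#' The record's baseline mode selects the form; using the population-average
#' mode with unequal marginals is a contract error, because that simplified
#' form is only derived under equal marginals.
#'
#' @param rec an [experiment_record()] carrying either per-individual
#'   baselines or a population-average baseline.
#' @return the scalar estimate.
#' @export
baseline_adjusted_estimate <- function(rec) {
  if (!is.null(rec$alpha)) {
    return(mean((rec$Y - rec$alpha) / rec$marginals))
  }
  if (is.null(rec$alpha_bar)) {
    stop("the record carries no baseline information; supply `alpha` or ",
         "`alpha_bar` to experiment_record()")
  }
  p <- rec$marginals[1L]
  if (max(abs(rec$marginals - p)) > 1e-12) {
    stop("population-average baseline mode requires equal marginal treatment ",
         "probabilities for all individuals; this design's marginals differ, ",
         "so per-individual baselines are needed")
  }
  (mean(rec$Y) - rec$alpha_bar) / p
}

#' Ratio-adjusted baseline-subtracted estimator
#'
#' Generalizes [baseline_adjusted_estimate()] to designs whose treatment
#' moments are merely *symmetric* across each individual's in-edges rather
#' than equal-marginal. For a design satisfying the common-ratio condition
#' (the ratio \eqn{\rho_i = E[z_i(1-z_k)] / E[(1-z_i) z_k]} is the same for
#' every interference source `k` of individual `i` — see
#' [check_unbiasedness()]), the estimator
#' \deqn{\frac{1}{n} \sum_i \big(z_i + \rho_i (1 - z_i)\big)
#'   \frac{Y_i(z) - \alpha_i}{E[z_i]}}
#' is unbiased for the TTE. With `rho = 1` and equal marginals it reduces
#' exactly to [baseline_adjusted_estimate()] in per-individual mode.
#'
#' @param rec an [experiment_record()] with per-individual baselines.
#' @param rho nonnegative ratio, scalar or per-individual vector. Supplied by
#'   the caller or computed from design moments with [rho_from_moments()];
#'   the package never infers it from an unknown network.
#' @return the scalar estimate.
#' @export
ratio_adjusted_estimate <- function(rec, rho) {
  if (is.null(rec$alpha)) {
    stop("ratio-adjusted estimation requires per-individual baselines")
  }
  rho <- as.numeric(rho)
  if (any(!is.finite(rho) | rho < 0)) stop("`rho` must be nonnegative")
  rho <- rep_len(rho, rec$n)
  mean((rec$z + rho * (1 - rec$z)) * (rec$Y - rec$alpha) / rec$marginals)
}

#' Common-ratio value implied by a design for a (target, source) pair
#'
#' The quantity \eqn{\rho_i = E[z_i (1 - z_k)] / E[(1 - z_i) z_k]} for target
#' individual `i` and a designated reference source `k`, computed from exact
#' design moments (equivalently the conditional ratio
#' `P(z_k = 0 | z_i = 1) / P(z_k = 1 | z_i = 0)` scaled by the odds
#' `E[z_i]/E[1 - z_i]`). Equals 1 whenever `E[z_i] = E[z_k]`.
#'
#' @param design a `tte_design`.
#' @param i target individual (the one whose outcome receives interference).
#' @param k reference source individual.
#' @return scalar ratio; `NA` when both joint probabilities vanish (the
#'   jointly-assigned case, where any value satisfies the constraint).
#' @export
rho_from_moments <- function(design, i, k) {
  mu <- design_marginals(design)
  s <- design_second_moment(design, i, k)
  num <- mu[i] - s
  den <- mu[k] - s
  if (abs(num) < 1e-14 && abs(den) < 1e-14) return(NA_real_)
  num / den
}

#' Difference-in-means estimator
#'
#' `mean(Y | treated) - mean(Y | control)`. In weight form, `w_i = 1/#treated`
#' and `v_i = -1/#control`, which are deterministic for fixed-count designs.
#' Under interference it does not target the TTE; with no interference and a
#' completely randomized design it is unbiased for the mean direct effect.
#'
#' @param rec an [experiment_record()].
#' @return the scalar estimate.
#' @export
difference_in_means <- function(rec) {
  n1 <- sum(rec$z)
  if (n1 == 0 || n1 == rec$n) {
    stop("difference in means needs at least one treated and one control unit")
  }
  mean(rec$Y[rec$z == 1]) - mean(rec$Y[rec$z == 0])
}

# ---- estimator factories -------------------------------------------------
# Each factory closes over design moments (and baselines) at construction
# time and returns a pure function(z, Y) -> estimate, usable by both the
# enumeration oracle and the Monte-Carlo harness.

#' Estimator factories for the oracle and Monte-Carlo harness
#'
#' Build pure `function(z, Y)` estimator closures from design moments (and,
#' where relevant, baseline estimates) fixed at construction time — the
#' defining restriction of the individually weighted linear class.
#'
#' @param marginals design marginals `E[z_i]`.
#' @param alpha per-individual baseline estimates (baseline-adjusted /
#'   ratio-adjusted estimators).
#' @param alpha_bar population-average baseline (equal-marginal designs only).
#' @param rho ratio vector for [ratio_adjusted_estimate()].
#' @return a function of `(z, Y)` returning the scalar estimate.
#' @name estimator_factories
NULL

#' @rdname estimator_factories
#' @export
estimator_ht <- function(marginals) {
  wts <- ht_weights(marginals)
  function(z, Y) sum((wts$w * z + wts$v * (1 - z)) * Y)
}

#' @rdname estimator_factories
#' @export
estimator_baseline_adjusted <- function(marginals, alpha = NULL,
                                        alpha_bar = NULL) {
  mu <- as.numeric(marginals)
  if (!is.null(alpha) && !is.null(alpha_bar)) {
    stop("supply exactly one of `alpha` or `alpha_bar`")
  }
  if (is.null(alpha) && is.null(alpha_bar)) {
    stop("baseline-adjusted estimation needs `alpha` or `alpha_bar`")
  }
  if (!is.null(alpha)) {
    alpha <- as.numeric(alpha)
    function(z, Y) mean((Y - alpha) / mu)
  } else {
    p <- mu[1L]
    if (max(abs(mu - p)) > 1e-12) {
      stop("population-average baseline mode requires equal marginals")
    }
    function(z, Y) (mean(Y) - alpha_bar) / p
  }
}

#' @rdname estimator_factories
#' @export
estimator_ratio_adjusted <- function(marginals, alpha, rho) {
  mu <- as.numeric(marginals)
  alpha <- as.numeric(alpha)
  rho <- rep_len(as.numeric(rho), length(mu))
  function(z, Y) mean((z + rho * (1 - z)) * (Y - alpha) / mu)
}

#' @rdname estimator_factories
#' @export
estimator_difference_in_means <- function() {
  function(z, Y) {
    n1 <- sum(z)
    if (n1 == 0 || n1 == length(z)) {
      stop("difference in means needs both arms nonempty")
    }
    mean(Y[z == 1]) - mean(Y[z == 0])
  }
}
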