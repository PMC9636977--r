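#' Influence of each individual on the baseline-adjusted estimator
#'
#' The influence of individual `i` is its total contribution to the
#' baseline-adjusted estimate when `i` is treated — the direct effect on
#' itself plus its marginal-weighted outgoing interference:
#' \deqn{L_i = \beta_i + \sum_k \frac{E[z_i]\,\gamma_{ik}}{E[z_k]}.}
#' Note the transpose: the model stores incoming effects \eqn{\gamma_{ki}}
#' (edge source `k`, target `i`), while `L_i` sums `i`'s *outgoing* edges.
#' With equal marginals `L_i` is simply `beta_i` plus the row sum of `i`'s
#' outgoing `gamma`, and `mean(L)` equals the TTE — the reduction of network
#' causal inference to estimating a population mean.
#'
#' @param model a [hane_model()].
#' @param design a `tte_design`, or a numeric vector of marginals directly.
#' @return an object of class `influence_vector`: list with `L` (length `n`)
#'   and, when the design carries clusters, within-cluster means
#'   `cluster_means` (for uniform cluster sizes these are the `L'_tau` of the
#'   cluster-randomized variance formula), within-cluster variances
#'   `cluster_vars` (`V_tau`) and `cluster_sizes`.
#' @export
influence_vector <- function(model, design) {
  mu <- if (is.numeric(design)) design else design_marginals(design)
  if (length(mu) != model$n) stop("marginals must have length n")
  if (any(mu <= 0)) {
    stop("influence is undefined for zero marginal treatment probability ",
         "(individual ", which(mu <= 0)[1L], ")")
  }
  L <- model$beta
  e <- model$edges
  if (nrow(e)) {
    term <- mu[e$source] * e$gamma / mu[e$target]
    agg <- rowsum(term, e$source)
    idx <- as.integer(rownames(agg))
    L[idx] <- L[idx] + agg[, 1L]
  }
  out <- list(L = L)
  if (!is.numeric(design) && !is.null(design$clusters)) {
    cl <- design$clusters
    sums <- as.numeric(rowsum(L, cl))
    sq <- as.numeric(rowsum(L^2, cl))
    sz <- design$sizes
    out$cluster_means <- sums / sz
    out$cluster_vars <- sq / sz - (sums / sz)^2
    out$cluster_sizes <- sz
  }
  structure(out, class = "influence_vector")
}

#' @export
print.influence_vector <- function(x, ...) {
  cat("Influence vector, n =", length(x$L), "\n")
  cat(sprintf("  mean(L) = %.6g, popvar(L) = %.6g\n",
              mean(x$L), mean(x$L^2) - mean(x$L)^2))
  if (!is.null(x$cluster_means)) {
    cat("  clusters:", length(x$cluster_means), "\n")
  }
  invisible(x)
}

pop_var <- function(x) mean(x^2) - mean(x)^2

#' Bias of the Horvitz-Thompson-form estimator under interference
#'
#' Closed form for the design bias of the HT-form estimator (the unique
#' candidate for unbiasedness within the individually weighted linear class):
#' \deqn{E[\widehat{TTE}] - TTE = \frac{1}{n} \sum_{(k,i) \in E}
#'   \Big(\frac{Cov[z_i, z_k]}{Var[z_i]} - 1\Big) \gamma_{ki}.}
#' Under an independent (Bernoulli) design this is `-(1/n) sum(gamma)`: the
#' estimator captures only direct effects. It vanishes exactly when the design
#' assigns every connected pair jointly.
#'
#' @param model a [hane_model()].
#' @param design a `tte_design` with non-degenerate marginals on edge targets.
#' @return the scalar bias.
#' @export
bias_ht <- function(model, design) {
  e <- model$edges
  if (nrow(e) == 0L) return(0)
  mu <- design_marginals(design)
  v <- mu[e$target] * (1 - mu[e$target])
  if (any(v <= 0)) {
    stop("Var[z_i] = 0 for an edge target; the bias formula is undefined")
  }
  cv <- design_covariance(design, e$target, e$source)
  sum((cv / v - 1) * e$gamma) / model$n
}

#' Bias of the baseline-adjusted estimator
#'
#' \deqn{E[\widehat{TTE}^{-\alpha}] - TTE = \frac{1}{n} \sum_{(k,i) \in E}
#'   \Big(\frac{E[z_k]}{E[z_i]} - 1\Big) \gamma_{ki},}
#' summing over edges with source `k` and target `i`: each interference
#' effect is picked up in proportion to the source's treatment probability but
#' inverse-weighted by the target's. Zero whenever marginals are equal across
#' all edges — the unbiasedness condition that needs no network knowledge.
#'
#' @inheritParams bias_ht
#' @return the scalar bias.
#' @export
bias_baseline_adjusted <- function(model, design) {
  e <- model$edges
  if (nrow(e) == 0L) return(0)
  mu <- design_marginals(design)
  if (any(mu[e$target] <= 0)) {
    stop("zero marginal on an edge target; the estimator is undefined there")
  }
  sum((mu[e$source] / mu[e$target] - 1) * e$gamma) / model$n
}

#' Variance of the baseline-adjusted estimator under any provided design
#'
#' The general design-based variance
#' \deqn{Var[\widehat{TTE}^{-\alpha}] = \sum_{i,j}
#'   \frac{L_i L_j \, Cov(z_i, z_j)}{n^2 E[z_i] E[z_j]}}
#' evaluated by exploiting each design's block covariance structure, so the
#' work is `O(n)` (plus `O(|E|)` for the influence terms), never `O(n^2)`:
#' Bernoulli covariance is diagonal; the completely randomized design has one
#' off-diagonal value; cluster and saturation designs have per-cluster blocks.
#'
#' @param model a [hane_model()].
#' @param design a `tte_design` with marginals strictly inside `(0, 1)`
#'   wherever they enter (size-1 saturation clusters at level 0 or 1 excepted,
#'   as they contribute no randomness).
#' @return the scalar variance.
#' @export
variance_general <- function(model, design) {
  L <- influence_vector(model, design)$L
  n <- model$n
  switch(design$kind,
    bernoulli = {
      p <- design$p
      sum(L^2) * (1 - p) / (p * n^2)
    },
    completely_randomized = {
      m <- design$m
      p <- design$p
      c_off <- m * (m - 1) / (n * (n - 1)) - p^2
      (p * (1 - p) * sum(L^2) + c_off * (sum(L)^2 - sum(L^2))) / (n * p)^2
    },
    cluster_randomized = {
      k <- design$treated
      T <- design$T
      p <- design$p
      S <- as.numeric(rowsum(L, design$clusters))
      c_off <- k * (k - 1) / (T * (T - 1)) - p^2
      (p * (1 - p) * sum(S^2) + c_off * (sum(S)^2 - sum(S^2))) / (n * p)^2
    },
    saturation = {
      total <- 0
      for (tau in seq_len(design$T)) {
        members <- design$clusters == tau
        nt <- design$sizes[tau]
        mt <- design$m_tau[tau]
        pt <- design$saturations[tau]
        if (mt == 0L || mt == nt) next   # no randomness in this cluster
        Lt <- L[members]
        Q <- sum(Lt^2)
        St <- sum(Lt)
        c_t <- if (nt > 1L) mt * (mt - 1) / (nt * (nt - 1)) - pt^2 else 0
        total <- total +
          (pt * (1 - pt) * Q + c_t * (St^2 - Q)) / (n * pt)^2
      }
      total
    },
    stop("unknown design kind: ", design$kind))
}

#' Variance under the completely randomized design (closed form)
#'
#' \deqn{Var[\widehat{TTE}^{-\alpha}] = \frac{1-p}{p(n-1)}
#'   \Big(\frac{1}{n}\sum_i L_i^2 - \big(\frac{1}{n}\sum_i L_i\big)^2\Big),}
#' i.e. `(1-p)/(p(n-1))` times the population variance of the influence
#' terms. The population variance is bounded by `(B(1+dmax))^2` when effects
#' are bounded by `B` and outdegrees by `dmax`, so the variance scales as
#' `B^2 dmax^2 / (p n)`: the estimator is consistent as soon as the number of
#' treated individuals outgrows `B^2 dmax^2`.
#'
#' @param model a [hane_model()].
#' @param p treated fraction; `p * n` must be an integer in `(0, n)`.
#' @return the scalar variance; equals [variance_general()] under the
#'   corresponding design to machine precision.
#' @export
variance_crd <- function(model, p) {
  n <- model$n
  if (n < 2L) stop("variance under CRD needs n >= 2")
  if (!is.finite(p) || p <= 0 || p >= 1) stop("`p` must lie in (0, 1)")
  if (abs(p * n - round(p * n)) > 1e-9) {
    stop("p * n = ", p * n, " is not an integer treated count")
  }
  L <- influence_vector(model, rep(p, n))$L
  (1 - p) / (p * (n - 1)) * pop_var(L)
}

#' Variance under the cluster-randomized design (closed form)
#'
#' For `T` clusters of uniform size `n/T` with `p T` clusters treated,
#' \deqn{Var[\widehat{TTE}^{-\alpha}] = \frac{1-p}{p(T-1)}
#'   \Big(\frac{1}{T}\sum_\tau L'^2_\tau -
#'   \big(\frac{1}{T}\sum_\tau L'_\tau\big)^2\Big),
#'   \quad L'_\tau = \frac{T}{n} \sum_{i: \pi(i)=\tau} L_i:}
#' the completely randomized formula applied to cluster-mean influences. The
#' closed form assumes uniform cluster sizes; for non-uniform clusters use
#' [variance_general()] with a cluster design.
#'
#' @param model a [hane_model()].
#' @param clusters cluster map (length-`n` vector of labels).
#' @param p treated fraction of clusters; `p * T` must be an integer.
#' @return the scalar variance.
#' @export
variance_cluster <- function(model, clusters, p) {
  cl <- normalize_clusters(clusters)
  n <- model$n
  if (length(cl$map) != n) stop("cluster map must have length n")
  sizes <- tabulate(cl$map, nbins = cl$T)
  if (length(unique(sizes)) != 1L) {
    stop("this closed form assumes uniform cluster sizes n/T; got sizes ",
         paste(sizes, collapse = ", "),
         " - use variance_general() with a cluster design instead")
  }
  T <- cl$T
  if (T < 2L) stop("need at least 2 clusters")
  if (!is.finite(p) || p <= 0 || p >= 1) stop("`p` must lie in (0, 1)")
  if (abs(p * T - round(p * T)) > 1e-9) {
    stop("p * T = ", p * T, " is not an integer treated-cluster count")
  }
  L <- influence_vector(model, rep(p, n))$L
  Lp <- as.numeric(rowsum(L, cl$map)) * T / n
  (1 - p) / (p * (T - 1)) * pop_var(Lp)
}

#' Variance under the saturation-randomized design (closed form)
#'
#' With per-cluster saturation levels `p_tau` (treatments independent across
#' clusters, a uniform-at-random fixed-count draw within each cluster),
#' \deqn{Var[\widehat{TTE}^{-\alpha}] = \sum_\tau
#'   \frac{(1-p_\tau) n_\tau^2}{p_\tau n^2 (n_\tau - 1)} V_\tau,}
#' where `V_tau` is the population variance of the influence terms within
#' cluster `tau`. The uniform-saturation formula
#' `(1-p)/(p n) * sum_tau n_tau^2 / (n (n_tau - 1)) * V_tau` is the
#' `p_tau == p` specialization. Size-1 clusters contribute no variance and are
#' skipped (they have no within-cluster pairs, so the `n_tau - 1` divisor is
#' never evaluated for them).
#'
#' @param model a [hane_model()].
#' @param clusters cluster map (length-`n` vector of labels).
#' @param saturations per-cluster treated fractions `p_tau` (recycled if
#'   scalar); each `p_tau * n_tau` must be an integer.
#' @return the scalar variance.
#' @export
variance_saturation <- function(model, clusters, saturations) {
  cl <- normalize_clusters(clusters)
  n <- model$n
  if (length(cl$map) != n) stop("cluster map must have length n")
  sizes <- tabulate(cl$map, nbins = cl$T)
  sat <- rep_len(as.numeric(saturations), cl$T)
  design <- design_saturation(cl$map, sat)
  L <- influence_vector(model, design)$L
  total <- 0
  for (tau in seq_len(cl$T)) {
    nt <- sizes[tau]
    pt <- sat[tau]
    if (nt < 2L) next
    if (pt <= 0 || pt >= 1) next    # deterministic cluster: no variance
    Lt <- L[cl$map == tau]
    Vt <- pop_var(Lt)
    total <- total + (1 - pt) * nt^2 / (pt * n^2 * (nt - 1)) * Vt
  }
  total
}

#' Which unbiasedness conditions does a design satisfy on a given edge set?
#'
#' Reports, per sufficient condition, whether the design's exact moments
#' satisfy it on every edge:
#'
#' * `joint_assignment` — `P(z_k = z_i) = 1` on every edge: the condition for
#'   the HT-form estimator to be unbiased *without* baseline information.
#'   Only designs that treat connected components jointly satisfy it.
#' * `common_ratio` — for every target `i`, the ratio
#'   `E[z_i(1-z_k)] / E[(1-z_i) z_k]` is the same across all of `i`'s
#'   interference sources `k`: the condition for [ratio_adjusted_estimate()]
#'   to be unbiased given baselines. The consistent per-target values `rho`
#'   are returned.
#' * `equal_marginals` — `E[z_i] = E[z_k]` on every edge: the simple
#'   sufficient condition for [baseline_adjusted_estimate()] to be unbiased;
#'   implies `common_ratio` with `rho = 1`.
#'
#' @param design a `tte_design`.
#' @param edges edge data.frame with columns `source`, `target` (a model's
#'   `$edges` works; `gamma` is ignored), or a [hane_model()].
#' @param tol numerical tolerance on the moment comparisons.
#' @return an object of class `unbiasedness_report`: a list of three
#'   condition reports, each with `satisfied` (logical), `violations`
#'   (data.frame of offending edges), and for `common_ratio` a vector `rho`
#'   of per-target ratios (`NA` for targets with inconsistent or degenerate
#'   ratios).
#' @export
check_unbiasedness <- function(design, edges, tol = 1e-10) {
  if (inherits(edges, "hane_model")) edges <- edges$edges
  if (nrow(edges) == 0L) {
    rep0 <- list(satisfied = TRUE,
                 violations = data.frame(source = integer(0),
                                         target = integer(0)))
    out <- list(joint_assignment = rep0, common_ratio = c(rep0, list(rho = numeric(0))),
                equal_marginals = rep0)
    return(structure(out, class = "unbiasedness_report"))
  }
  mu <- design_marginals(design)
  s <- design_second_moment(design, edges$target, edges$source)
  mu_t <- mu[edges$target]
  mu_s <- mu[edges$source]

  # P(z_k = z_i) = 1 - mu_i - mu_k + 2 E[z_i z_k]
  p_equal <- 1 - mu_t - mu_s + 2 * s
  ja_bad <- p_equal < 1 - tol
  joint_assignment <- list(
    satisfied = !any(ja_bad),
    violations = edges[ja_bad, c("source", "target"), drop = FALSE],
    p_equal = p_equal)

  em_bad <- abs(mu_t - mu_s) > tol
  equal_marginals <- list(
    satisfied = !any(em_bad),
    violations = edges[em_bad, c("source", "target"), drop = FALSE])

  # per-edge ratio E[z_i(1-z_k)] / E[(1-z_i) z_k], i = target, k = source
  num <- mu_t - s
  den <- mu_s - s
  ratio <- ifelse(abs(num) < tol & abs(den) < tol, NA_real_, num / den)
  rho <- rep(NA_real_, design$n)
  cr_bad <- logical(nrow(edges))
  for (i in unique(edges$target)) {
    idx <- which(edges$target == i)
    r <- ratio[idx]
    r_def <- r[!is.na(r)]   # NA = jointly assigned pair, any rho works
    if (length(r_def) == 0L) {
      rho[i] <- NA_real_
    } else if (max(r_def) - min(r_def) <= tol * max(1, abs(r_def[1L]))) {
      rho[i] <- r_def[1L]
    } else {
      cr_bad[idx] <- TRUE
    }
  }
  common_ratio <- list(
    satisfied = !any(cr_bad),
    violations = edges[cr_bad, c("source", "target"), drop = FALSE],
    rho = rho)

  structure(list(joint_assignment = joint_assignment,
                 common_ratio = common_ratio,
                 equal_marginals = equal_marginals),
            class = "unbiasedness_report")
}

#' @export
print.unbiasedness_report <- function(x, ...) {
  status <- function(cond) if (cond$satisfied) "satisfied" else
    paste0("VIOLATED on ", nrow(cond$violations), " edge(s)")
  cat("Unbiasedness conditions on the given edge set\n")
  cat("  joint assignment  (HT form, no baselines) :",
      status(x$joint_assignment), "\n")
  cat("  common ratio      (ratio-adjusted)        :",
      status(x$common_ratio), "\n")
  cat("  equal marginals   (baseline-adjusted)     :",
      status(x$equal_marginals), "\n")
  invisible(x)
}

#' Exact expectation and variance of an estimator by exhaustive enumeration
#'
#' The certification oracle behind every closed form in the package:
#' enumerates every treatment assignment in the design's support with its
#' exact probability, computes outcomes via [evaluate_outcomes()], evaluates
#' the estimator on each, and returns the exact first two moments. For the
#' fixed-count designs the support is equiprobable, so the expectation is a
#' plain sum divided by the support size and inherits the summands' exactness.
#'
#' @param model a [hane_model()].
#' @param design a `tte_design` with enumerable support.
#' @param estimator a pure `function(z, Y)` returning a scalar (see the
#'   [estimator_factories]).
#' @param cap maximum support size (default `1e6`); beyond it, an error
#'   suggests the Monte-Carlo harness.
#' @return list with `expectation`, `variance`, and `support_size`.
#' @export
exhaustive_moments <- function(model, design, estimator, cap = 1e6) {
  sup <- design_support(design, cap = cap)
  S <- nrow(sup$z)
  vals <- numeric(S)
  for (s in seq_len(S)) {
    zs <- sup$z[s, ]
    vals[s] <- estimator(zs, evaluate_outcomes(model, zs))
  }
  expectation <- sum(vals * sup$prob)
  variance <- sum((vals - expectation)^2 * sup$prob)
  list(expectation = expectation, variance = variance, support_size = S)
}
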