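#' Scenario specification for synthetic instances
#'
#' Defines the study conditions under which the framework is exercised: the
#' interference network topology, the distributions of the model parameters,
#' the randomized design, and the Monte-Carlo budget. Defaults describe a
#' moderately connected directed Erdős–Rényi network of 30 individuals with
#' unit-scale baselines and direct effects, mixed-sign spillovers a few times
#' smaller than the direct effects, and a completely randomized design
#' treating half the population.
#'
#' @param n population size.
#' @param network list with `kind` in
#'   `c("erdos_renyi", "planted_clusters", "star", "chain", "empty")` and its
#'   parameters: `q` (edge probability, `erdos_renyi`); `n_clusters`,
#'   `within`, `between` (`planted_clusters`).
#' @param alpha,beta parameter distributions, each a list with `dist` in
#'   `c("normal", "uniform", "constant")` and parameters (`mean`/`sd`,
#'   `min`/`max`, or `value`).
#' @param gamma per-edge effect distribution as above, plus optional
#'   `neg_prob`: the probability that an edge's effect magnitude is negated
#'   (mixed positive/negative spillovers). Draws of exactly zero are dropped
#'   with their edges, since the edge set is the support of `gamma`.
#' @param design list with `kind` in `c("bernoulli", "crd", "cluster",
#'   "saturation")` and its parameters (`p`; or `m`; or `clusters`/`n_clusters`
#'   plus `treated`; or `saturations`).
#' @param reps Monte-Carlo repetitions.
#' @param seed master seed; instance generation, design draws and baseline
#'   noise use separate substreams derived from it, so changing `reps` never
#'   changes the generated instance.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(n = 30,
                          network = list(kind = "erdos_renyi", q = 0.2),
                          alpha = list(dist = "normal", mean = 1, sd = 1),
                          beta = list(dist = "normal", mean = 1, sd = 0.5),
                          gamma = list(dist = "uniform", min = 0.1, max = 0.5,
                                       neg_prob = 0.25),
                          design = list(kind = "crd", p = 0.5),
                          reps = 5000, seed = 1) {
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be at least 2")
  if (is.null(network$kind)) stop("network spec needs a `kind`")
  kinds <- c("erdos_renyi", "planted_clusters", "star", "chain", "empty")
  if (!network$kind %in% kinds) {
    stop("unknown network kind: ", network$kind)
  }
  for (d in list(alpha, beta, gamma)) {
    if (is.null(d$dist) ||
        !d$dist %in% c("normal", "uniform", "constant")) {
      stop("parameter distributions must set dist = normal/uniform/constant")
    }
  }
  if (reps < 1L) stop("`reps` must be at least 1")
  structure(list(n = n, network = network, alpha = alpha, beta = beta,
                 gamma = gamma, design = design,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "scenario_spec")
}

draw_dist <- function(spec, n) {
  switch(spec$dist,
    normal = stats::rnorm(n, mean = spec$mean %||% 0, sd = spec$sd %||% 1),
    uniform = stats::runif(n, min = spec$min %||% 0, max = spec$max %||% 1),
    constant = rep(spec$value %||% stop("constant dist needs `value`"), n),
    stop("unknown distribution: ", spec$dist))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a directed interference network
#'
#' @param kind one of `"erdos_renyi"` (each ordered pair an edge independently
#'   with probability `q`), `"planted_clusters"` (directed edges with
#'   probability `within` inside and `between` across contiguous clusters),
#'   `"star"` (hub 1 influences everyone else), `"chain"` (`i` influences
#'   `i+1`), `"empty"`.
#' @param n population size.
#' @param q,within,between,n_clusters kind-specific parameters.
#' @param seed optional integer seed.
#' @return data.frame with columns `source`, `target` (no effect sizes).
#' @export
generate_network <- function(kind, n, q = 0.2, n_clusters = NULL,
                             within = 0.5, between = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  switch(kind,
    empty = data.frame(source = integer(0), target = integer(0)),
    star = data.frame(source = rep(1L, n - 1L), target = 2:n),
    chain = data.frame(source = seq_len(n - 1L), target = 2:n),
    erdos_renyi = {
      pairs <- expand.grid(source = seq_len(n), target = seq_len(n))
      pairs <- pairs[pairs$source != pairs$target, ]
      keep <- stats::runif(nrow(pairs)) < q
      pairs[keep, , drop = FALSE]
    },
    planted_clusters = {
      T <- n_clusters %||% max(2L, n %/% 10L)
      cl <- sort(rep(seq_len(T), length.out = n))
      pairs <- expand.grid(source = seq_len(n), target = seq_len(n))
      pairs <- pairs[pairs$source != pairs$target, ]
      same <- cl[pairs$source] == cl[pairs$target]
      keep <- stats::runif(nrow(pairs)) < ifelse(same, within, between)
      out <- pairs[keep, , drop = FALSE]
      attr(out, "clusters") <- cl
      out
    },
    stop("unknown network kind: ", kind))
}

build_design_from_spec <- function(dspec, n) {
  kind <- dspec$kind %||% "crd"
  switch(kind,
    bernoulli = design_bernoulli(n, dspec$p),
    crd = {
      m <- dspec$m %||% round(n * dspec$p)
      design_crd(n, m)
    },
    cluster = {
      cl <- dspec$clusters %||% sort(rep(seq_len(dspec$n_clusters),
                                         length.out = n))
      design_cluster(cl, dspec$treated %||% round(dspec$p *
                     length(unique(cl))))
    },
    saturation = {
      cl <- dspec$clusters %||% sort(rep(seq_len(dspec$n_clusters),
                                         length.out = n))
      design_saturation(cl, dspec$saturations)
    },
    stop("unknown design kind: ", kind))
}

#' Generate a synthetic HANE instance and design from a scenario
#'
#' Deterministic given `spec$seed` (or the `seed` argument): the network, the
#' parameter draws and the design are all reproducible, and the generation
#' stream is independent of the Monte-Carlo stream used later.
#'
#' @param spec a [scenario_spec()].
#' @param seed optional override of `spec$seed`.
#' @return list with elements `model` (a [hane_model()]) and `design`.
#' @export
generate_instance <- function(spec, seed = NULL) {
  seed <- as.integer(seed %||% spec$seed)
  set.seed(seed)
  n <- spec$n
  net <- generate_network(spec$network$kind, n,
                          q = spec$network$q %||% 0.2,
                          n_clusters = spec$network$n_clusters,
                          within = spec$network$within %||% 0.5,
                          between = spec$network$between %||% 0.05)
  alpha <- draw_dist(spec$alpha, n)
  beta <- draw_dist(spec$beta, n)
  edges <- NULL
  if (nrow(net)) {
    g <- draw_dist(spec$gamma, nrow(net))
    neg_prob <- spec$gamma$neg_prob %||% 0
    if (neg_prob > 0) {
      flip <- stats::runif(nrow(net)) < neg_prob
      g <- ifelse(flip, -abs(g), abs(g))
    }
    keep <- abs(g) > 1e-12
    if (any(keep)) {
      edges <- data.frame(source = net$source[keep],
                          target = net$target[keep],
                          gamma = g[keep])
    }
  }
  model <- hane_model(alpha = alpha, beta = beta, edges = edges)
  dspec <- spec$design
  if (identical(dspec$kind, "cluster") || identical(dspec$kind, "saturation")) {
    if (is.null(dspec$clusters) && !is.null(attr(net, "clusters"))) {
      dspec$clusters <- attr(net, "clusters")
    }
  }
  design <- build_design_from_spec(dspec, n)
  list(model = model, design = design, seed = seed)
}

#' Monte-Carlo bias/variance measurement of an estimator under a design
#'
#' Draws `reps` independent treatment vectors, computes outcomes through the
#' model, evaluates the estimator on each draw, and reports empirical mean
#' and variance with Monte-Carlo standard errors, side by side with the
#' closed-form predictions from the theory module when available.
#'
#' @param model a [hane_model()].
#' @param design a `tte_design`.
#' @param estimator either a pure `function(z, Y)` (see
#'   [estimator_factories]) or a character shortcut: `"baseline_adjusted"`
#'   (per-individual true baselines; predictions attached automatically),
#'   `"ht"`, or `"difference_in_means"`.
#' @param reps number of repetitions, at least 2.
#' @param seed integer seed for the draw stream.
#' @param predicted_mean,predicted_var optional closed-form predictions to
#'   embed in the result (filled automatically for the character shortcuts
#'   where the theory module provides them).
#' @param abort_on_failure if `TRUE` (default) any estimator failure on a
#'   draw aborts the run; otherwise failures are counted, reported, and the
#'   failed draws dropped (appropriate for conditional estimators like the
#'   difference in means under designs that can empty an arm).
#' @return an object of class `sim_result`.
#' @export
run_monte_carlo <- function(model, design, estimator, reps, seed,
                            predicted_mean = NULL, predicted_var = NULL,
                            abort_on_failure = TRUE) {
  if (reps < 2L) stop("`reps` must be at least 2")
  if (is.character(estimator)) {
    mu <- design_marginals(design)
    shortcut <- estimator
    estimator <- switch(shortcut,
      baseline_adjusted = estimator_baseline_adjusted(mu, alpha = model$alpha),
      ht = estimator_ht(mu),
      difference_in_means = estimator_difference_in_means(),
      stop("unknown estimator shortcut: ", shortcut))
    tte <- total_treatment_effect(model)
    if (shortcut == "baseline_adjusted") {
      predicted_mean <- predicted_mean %||%
        (tte + bias_baseline_adjusted(model, design))
      predicted_var <- predicted_var %||% variance_general(model, design)
    } else if (shortcut == "ht") {
      predicted_mean <- predicted_mean %||% (tte + bias_ht(model, design))
    }
    if (shortcut == "difference_in_means") abort_on_failure <- FALSE
  }
  set.seed(as.integer(seed))
  vals <- numeric(reps)
  failed <- logical(reps)
  for (r in seq_len(reps)) {
    z <- sample_treatment(design)
    Y <- evaluate_outcomes(model, z)
    v <- tryCatch(estimator(z, Y), error = function(e) e)
    if (inherits(v, "error")) {
      if (abort_on_failure) {
        stop("estimator failed on draw ", r, ": ", conditionMessage(v))
      }
      failed[r] <- TRUE
    } else {
      vals[r] <- v
    }
  }
  vals <- vals[!failed]
  R <- length(vals)
  if (R < 2L) stop("fewer than 2 successful draws")
  emp_mean <- mean(vals)
  emp_var <- stats::var(vals)
  se_mean <- sqrt(emp_var / R)
  m4 <- mean((vals - emp_mean)^4)
  se_var <- sqrt(max(0, m4 - emp_var^2 * (R - 3) / (R - 1)) / R)
  res <- list(mean = emp_mean, variance = emp_var,
              se_mean = se_mean, se_variance = se_var,
              reps = reps, n_failed = sum(failed), seed = as.integer(seed),
              tte = total_treatment_effect(model),
              predicted_mean = predicted_mean, predicted_var = predicted_var,
              mean_dev_se = if (!is.null(predicted_mean))
                abs(emp_mean - predicted_mean) / se_mean else NA_real_,
              var_dev_se = if (!is.null(predicted_var) && se_var > 0)
                abs(emp_var - predicted_var) / se_var else NA_real_)
  structure(res, class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Monte-Carlo result (", x$reps, " reps, seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  empirical mean     : %.6g (MC se %.3g)\n", x$mean, x$se_mean))
  cat(sprintf("  empirical variance : %.6g (MC se %.3g)\n",
              x$variance, x$se_variance))
  cat(sprintf("  true TTE           : %.6g\n", x$tte))
  if (!is.null(x$predicted_mean)) {
    cat(sprintf("  predicted mean     : %.6g (|emp - pred| = %.2f se)\n",
                x$predicted_mean, x$mean_dev_se))
  }
  if (!is.null(x$predicted_var)) {
    cat(sprintf("  predicted variance : %.6g (|emp - pred| = %.2f se)\n",
                x$predicted_var, x$var_dev_se))
  }
  if (x$n_failed > 0) cat("  failed draws       :", x$n_failed, "\n")
  invisible(x)
}

#' Sensitivity of the estimator to baseline misestimation
#'
#' Re-runs the Monte-Carlo harness for the population-average-baseline
#' estimator while perturbing the baseline estimate each repetition:
#' `alpha_bar_hat = mean(alpha) + offset + N(0, noise_sd^2)`. The estimator is
#' linear in the baseline estimate, so zero-mean noise leaves it unbiased and
#' inflates the variance by exactly `noise_sd^2 / p^2`, while a constant
#' offset `delta` shifts the estimate by exactly `-delta / p`; both
#' predictions are embedded in the result. Requires an equal-marginal design
#' (the population-average mode's contract).
#'
#' @param model a [hane_model()].
#' @param design an equal-marginal `tte_design`.
#' @param noise_sd standard deviation of the zero-mean baseline noise.
#' @param reps,seed Monte-Carlo budget and seed; the noise stream is a
#'   substream separate from the design-draw stream.
#' @param offset constant baseline misestimate `delta` (default 0).
#' @return a `sim_result` with predictions adjusted for the perturbation.
#' @export
baseline_noise_study <- function(model, design, noise_sd, reps, seed,
                                 offset = 0) {
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  mu <- design_marginals(design)
  p <- mu[1L]
  if (max(abs(mu - p)) > 1e-12) {
    stop("the population-average baseline mode requires an equal-marginal design")
  }
  abar <- mean(model$alpha)
  # separate substream for the noise so the design draws match run_monte_carlo
  set.seed(as.integer(seed) + 1000003L)
  noise <- if (noise_sd > 0) stats::rnorm(reps, 0, noise_sd) else numeric(reps)
  r <- 0L
  est <- function(z, Y) {
    r <<- r + 1L
    (mean(Y) - (abar + offset + noise[r])) / p
  }
  tte <- total_treatment_effect(model)
  run_monte_carlo(model, design, est, reps, seed,
                  predicted_mean = tte + bias_baseline_adjusted(model, design)
                                   - offset / p,
                  predicted_var = variance_general(model, design) +
                                  noise_sd^2 / p^2)
}
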