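#' Randomized treatment designs with exact moments
#'
#' A design is a distribution over binary treatment vectors of length `n`.
#' Four standard families are provided; each exposes sampling
#' ([sample_treatment()]) and exact closed-form first and second moments
#' ([design_marginals()], [design_second_moment()], [design_covariance()]),
#' which are all the bias/variance formulas ever need.
#'
#' * `design_bernoulli(n, p)` — each individual treated independently with
#'   probability `p`.
#' * `design_crd(n, m)` — completely randomized design: exactly `m` of the `n`
#'   individuals treated, the subset uniform at random. The constructor takes
#'   an integer count `m` (reported as `p = m/n`); callers round non-integer
#'   budgets explicitly, since silent rounding would change every moment.
#' * `design_cluster(clusters, treated)` — cluster-randomized: `treated` of
#'   the `T` clusters are picked uniformly at random and all of their members
#'   are treated jointly.
#' * `design_saturation(clusters, saturations)` — within each cluster `tau` a
#'   uniform-at-random subset of `p_tau * n_tau` members is treated,
#'   independently across clusters. The matched-pair design is the special
#'   case of pairs as clusters with `p = 1/2`.
#'
#' @param n population size.
#' @param p treatment probability in `(0, 1)`.
#' @param m number of treated individuals, `0 < m < n`.
#' @param clusters integer (or factor) vector of length `n` mapping each
#'   individual to a cluster label; clusters are relabelled to `1..T`.
#' @param treated number of treated clusters, `0 < treated < T`.
#' @param saturations numeric vector of per-cluster treated fractions
#'   `p_tau`, one per cluster (in cluster label order); each `p_tau * n_tau`
#'   must be an integer.
#' @param budget optional overall budget `p`; if supplied, a warning is
#'   issued when `sum(n_tau p_tau) != n * budget` (the variance formulas are
#'   well defined without the budget constraint, so this is not an error).
#' @return an object of class `tte_design`.
#' @name designs
NULL

new_design <- function(kind, n, fields) {
  structure(c(list(kind = kind, n = as.integer(n)), fields),
            class = "tte_design")
}

#' @rdname designs
#' @export
design_bernoulli <- function(n, p) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be positive")
  if (!is.finite(p) || p <= 0 || p >= 1) stop("`p` must lie in (0, 1)")
  new_design("bernoulli", n, list(p = p))
}

#' @rdname designs
#' @export
design_crd <- function(n, m) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  if (m != as.integer(m)) {
    stop("`m` must be an integer treated count; round a non-integer budget ",
         "p*n explicitly before constructing the design")
  }
  m <- as.integer(m)
  if (m < 1L || m >= n) stop("`m` must satisfy 0 < m < n")
  new_design("completely_randomized", n, list(m = m, p = m / n))
}

normalize_clusters <- function(clusters) {
  f <- factor(clusters, levels = unique(clusters))
  list(map = as.integer(f), T = nlevels(f), labels = levels(f))
}

#' @rdname designs
#' @export
design_cluster <- function(clusters, treated) {
  cl <- normalize_clusters(clusters)
  n <- length(cl$map)
  if (treated != as.integer(treated)) stop("`treated` must be an integer")
  k <- as.integer(treated)
  if (k < 1L || k >= cl$T) stop("`treated` must satisfy 0 < treated < T = ", cl$T)
  sizes <- tabulate(cl$map, nbins = cl$T)
  new_design("cluster_randomized", n,
             list(clusters = cl$map, T = cl$T, treated = k,
                  sizes = sizes, p = k / cl$T, labels = cl$labels))
}

#' @rdname designs
#' @export
design_saturation <- function(clusters, saturations, budget = NULL) {
  cl <- normalize_clusters(clusters)
  n <- length(cl$map)
  sizes <- tabulate(cl$map, nbins = cl$T)
  sat <- as.numeric(saturations)
  if (length(sat) != cl$T) {
    stop("`saturations` must have one entry per cluster (T = ", cl$T, ")")
  }
  if (any(!is.finite(sat)) || any(sat < 0) || any(sat > 1)) {
    stop("saturation levels must lie in [0, 1]")
  }
  m_tau <- sat * sizes
  if (any(abs(m_tau - round(m_tau)) > 1e-8)) {
    bad <- which(abs(m_tau - round(m_tau)) > 1e-8)[1L]
    stop("saturation level ", sat[bad], " does not give an integer treated ",
         "count for cluster ", bad, " of size ", sizes[bad])
  }
  m_tau <- as.integer(round(m_tau))
  if (!is.null(budget)) {
    if (abs(sum(m_tau) - n * budget) > 1e-8) {
      warning("saturation levels spend ", sum(m_tau), " treatments but the ",
              "budget n*p = ", n * budget, "; the design is still valid")
    }
  }
  new_design("saturation", n,
             list(clusters = cl$map, T = cl$T, sizes = sizes,
                  saturations = sat, m_tau = m_tau,
                  p = sum(m_tau) / n, labels = cl$labels))
}

#' @export
print.tte_design <- function(x, ...) {
  cat("Randomized design:", x$kind, "\n")
  cat("  n =", x$n)
  switch(x$kind,
    bernoulli = cat(", p =", x$p),
    completely_randomized = cat(", m =", x$m, "(p =", format(x$p), ")"),
    cluster_randomized = cat(", T =", x$T, ", treated clusters =", x$treated),
    saturation = cat(", T =", x$T, ", saturations =",
                     paste(format(x$saturations), collapse = " ")))
  cat("\n")
  invisible(x)
}

#' Draw one treatment vector from a design
#'
#' @param design a `tte_design`.
#' @param seed optional integer; if supplied the draw is a deterministic
#'   function of it (via [set.seed()]). If omitted the current RNG stream is
#'   used, which is what the Monte-Carlo harness does after seeding once.
#' @return binary vector of length `design$n`.
#' @export
sample_treatment <- function(design, seed = NULL) {
  if (!is.null(seed)) {
    if (length(seed) != 1L || seed != as.integer(seed)) {
      stop("`seed` must be a single integer")
    }
    set.seed(as.integer(seed))
  }
  n <- design$n
  z <- numeric(n)
  switch(design$kind,
    bernoulli = {
      z <- as.numeric(stats::runif(n) < design$p)
    },
    completely_randomized = {
      z[sample.int(n, design$m)] <- 1
    },
    cluster_randomized = {
      on_clusters <- sample.int(design$T, design$treated)
      z[design$clusters %in% on_clusters] <- 1
    },
    saturation = {
      for (tau in seq_len(design$T)) {
        members <- which(design$clusters == tau)
        m_tau <- design$m_tau[tau]
        if (m_tau > 0L) {
          z[members[sample.int(length(members), m_tau)]] <- 1
        }
      }
    },
    stop("unknown design kind: ", design$kind))
  z
}

#' Exact first moments of a design
#'
#' `E[z_i]` for every individual: `p` (Bernoulli), `m/n` (completely
#' randomized), `treated/T` (cluster), `p_{cluster(i)}` (saturation).
#'
#' @param design a `tte_design`.
#' @return numeric vector of length `n`.
#' @export
design_marginals <- function(design) {
  switch(design$kind,
    bernoulli = rep(design$p, design$n),
    completely_randomized = rep(design$p, design$n),
    cluster_randomized = rep(design$p, design$n),
    saturation = design$saturations[design$clusters],
    stop("unknown design kind: ", design$kind))
}

#' Exact second moments `E[z_i z_j]` of a design
#'
#' For `i == j` this is the marginal. Off-diagonal closed forms:
#' Bernoulli `p^2`; completely randomized `m(m-1)/(n(n-1))`; cluster design
#' `k/T` for a same-cluster pair and `k(k-1)/(T(T-1))` across clusters;
#' saturation `p_tau (n_tau p_tau - 1)/(n_tau - 1)` within cluster `tau`
#' (never evaluated for size-1 clusters, which have no pairs) and
#' `p_tau p_sigma` across clusters.
#'
#' @param design a `tte_design`.
#' @param i,j individual indices in `1..n` (vectorized, recycled).
#' @return numeric vector of pairwise second moments.
#' @export
design_second_moment <- function(design, i, j) {
  n <- design$n
  i <- as.integer(i); j <- as.integer(j)
  if (any(i < 1L | i > n) || any(j < 1L | j > n)) {
    stop("indices must lie in 1..n")
  }
  k <- pmax(length(i), length(j))
  i <- rep_len(i, k); j <- rep_len(j, k)
  mu <- design_marginals(design)
  out <- numeric(k)
  same <- i == j
  out[same] <- mu[i[same]]
  off <- !same
  if (any(off)) {
    io <- i[off]; jo <- j[off]
    out[off] <- switch(design$kind,
      bernoulli = design$p^2,
      completely_randomized = {
        m <- design$m
        m * (m - 1) / (n * (n - 1))
      },
      cluster_randomized = {
        kT <- design$treated; T <- design$T
        ifelse(design$clusters[io] == design$clusters[jo],
               kT / T,
               kT * (kT - 1) / (T * (T - 1)))
      },
      saturation = {
        ti <- design$clusters[io]; tj <- design$clusters[jo]
        sat <- design$saturations; sz <- design$sizes
        ifelse(ti == tj,
               sat[ti] * (sz[ti] * sat[ti] - 1) / (sz[ti] - 1),
               sat[ti] * sat[tj])
      },
      stop("unknown design kind: ", design$kind))
  }
  out
}

#' Exact treatment covariance `Cov(z_i, z_j)`
#'
#' @inheritParams design_second_moment
#' @return `E[z_i z_j] - E[z_i] E[z_j]`, vectorized.
#' @export
design_covariance <- function(design, i, j) {
  mu <- design_marginals(design)
  design_second_moment(design, i, j) - mu[i] * mu[j]
}

#' Moment tables for a design
#'
#' Bundles the marginal vector with a pairwise-covariance accessor. The
#' accessor never materializes an `n x n` matrix: the covariance of every
#' provided design is block structured (two values for the completely
#' randomized design, per-cluster-pair values for cluster and saturation
#' designs), and the closure computes entries on demand.
#'
#' @param design a `tte_design`.
#' @return list with elements `marginals` (numeric vector) and
#'   `covariance(i, j)` (vectorized function).
#' @export
moment_tables <- function(design) {
  force(design)
  list(marginals = design_marginals(design),
       covariance = function(i, j) design_covariance(design, i, j))
}

#' Enumerate the support of a design
#'
#' Every treatment vector the design can produce, with its exact probability.
#' Used by the exhaustive-enumeration oracle. For the completely randomized,
#' cluster, and saturation designs the support points are equiprobable, so
#' enumeration sums are exact in floating point whenever the summands are.
#'
#' @param design a `tte_design`.
#' @param cap refuse to enumerate supports larger than this.
#' @return list with `z` (matrix, one assignment per row) and `prob`.
#' @export
design_support <- function(design, cap = 1e6) {
  n <- design$n
  size <- switch(design$kind,
    bernoulli = 2^n,
    completely_randomized = choose(n, design$m),
    cluster_randomized = choose(design$T, design$treated),
    saturation = prod(choose(design$sizes, design$m_tau)))
  if (size > cap) {
    stop("design support has ", format(size), " points, above the cap of ",
         format(cap), "; use the Monte-Carlo harness instead")
  }
  switch(design$kind,
    bernoulli = {
      S <- as.integer(2^n)
      z <- matrix(0, S, n)
      for (s in seq_len(S)) {
        z[s, ] <- as.integer(intToBits(s - 1L))[seq_len(n)]
      }
      ones <- rowSums(z)
      list(z = z, prob = design$p^ones * (1 - design$p)^(n - ones))
    },
    completely_randomized = {
      sets <- utils::combn(n, design$m)
      S <- ncol(sets)
      z <- matrix(0, S, n)
      for (s in seq_len(S)) z[s, sets[, s]] <- 1
      list(z = z, prob = rep(1 / S, S))
    },
    cluster_randomized = {
      sets <- utils::combn(design$T, design$treated)
      S <- ncol(sets)
      z <- matrix(0, S, n)
      for (s in seq_len(S)) z[s, design$clusters %in% sets[, s]] <- 1
      list(z = z, prob = rep(1 / S, S))
    },
    saturation = {
      per <- lapply(seq_len(design$T), function(tau) {
        members <- which(design$clusters == tau)
        m_tau <- design$m_tau[tau]
        if (m_tau == 0L) return(list(integer(0)))
        if (m_tau == length(members)) return(list(members))
        sets <- utils::combn(members, m_tau)
        lapply(seq_len(ncol(sets)), function(s) sets[, s])
      })
      grid <- do.call(expand.grid,
                      c(lapply(per, function(x) seq_along(x)),
                        list(KEEP.OUT.ATTRS = FALSE)))
      S <- nrow(grid)
      z <- matrix(0, S, n)
      for (s in seq_len(S)) {
        for (tau in seq_len(design$T)) {
          z[s, per[[tau]][[grid[s, tau]]]] <- 1
        }
      }
      list(z = z, prob = rep(1 / S, S))
    })
}
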