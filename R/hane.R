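#' Heterogeneous additive network effects (HANE) model
#'
#' Constructs a potential-outcomes model for a finite population of `n`
#' individuals in which outcomes respond additively to treatment:
#' \deqn{Y_i(z) = \alpha_i + \beta_i z_i + \sum_{k : (k,i) \in E} \gamma_{ki} z_k,}
#' where \eqn{\alpha_i} is individual `i`'s baseline outcome (outcome under the
#' all-control assignment), \eqn{\beta_i} is the direct effect of treating `i`,
#' and \eqn{\gamma_{ki}} is the interference effect of treating `k` on `i`'s
#' outcome. The edge set `E` of the (possibly unknown-to-the-analyst) directed
#' interference network is exactly the support of the stored `gamma` values.
#'
#' Self-effects live only in `beta`: an edge `(k, k)` is a validation error,
#' never silently folded into the direct effect, because outdegree and the
#' bias/variance formulas distinguish the two.
#'
#' @param alpha numeric baseline outcome per individual (length `n`).
#' @param beta numeric direct effect per individual (length `n`).
#' @param edges `NULL` (no interference) or a data.frame with columns
#'   `source`, `target` (integer indices in `1..n`) and `gamma` (nonzero
#'   numeric). A row `(k, i, g)` means treating `k` shifts `i`'s outcome by `g`.
#' @param ids optional character vector of unique external identifiers, used
#'   only at the I/O boundary; defaults to `"1".."n"`.
#' @param B optional stated bound on `|beta_i|` and `|gamma_ki|`; validated if
#'   supplied and carried along for variance bounds.
#' @return an object of class `hane_model` with fields `n`, `alpha`, `beta`,
#'   `edges`, `ids`, `B`.
#' @examples
#' m <- hane_model(alpha = c(0, 0), beta = c(1, 1),
#'                 edges = data.frame(source = 1, target = 2, gamma = 2))
#' total_treatment_effect(m)  # (1 + 1 + 2) / 2 = 2
#' @export
hane_model <- function(alpha, beta, edges = NULL, ids = NULL, B = NULL) {
  alpha <- as.numeric(alpha)
  beta <- as.numeric(beta)
  n <- length(alpha)
  if (n < 1L) stop("population size must be at least 1")
  if (length(beta) != n) {
    stop("`alpha` and `beta` must have the same length (got ",
         n, " and ", length(beta), ")")
  }
  if (anyNA(alpha) || anyNA(beta)) stop("`alpha`/`beta` must not contain NA")
  edges <- validate_edges(edges, n)
  if (is.null(ids)) {
    ids <- as.character(seq_len(n))
  } else {
    ids <- as.character(ids)
    if (length(ids) != n) stop("`ids` must have length n = ", n)
    if (anyDuplicated(ids)) stop("`ids` must be unique")
  }
  if (!is.null(B)) {
    B <- as.numeric(B)
    if (length(B) != 1L || !is.finite(B) || B < 0) {
      stop("`B` must be a single nonnegative number")
    }
    bad <- max(abs(beta), if (nrow(edges)) abs(edges$gamma) else 0)
    if (bad > B + 1e-12) {
      stop("stated bound B = ", B, " is violated: max |beta|,|gamma| = ", bad)
    }
  }
  structure(list(n = n, alpha = alpha, beta = beta, edges = edges,
                 ids = ids, B = B),
            class = "hane_model")
}

empty_edges <- function() {
  data.frame(source = integer(0), target = integer(0), gamma = numeric(0))
}

validate_edges <- function(edges, n) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0L)) {
    return(empty_edges())
  }
  if (!is.data.frame(edges) ||
      !all(c("source", "target", "gamma") %in% names(edges))) {
    stop("`edges` must be a data.frame with columns source, target, gamma")
  }
  src <- edges$source
  tgt <- edges$target
  if (any(src != as.integer(src)) || any(tgt != as.integer(tgt))) {
    stop("edge endpoints must be integer indices")
  }
  src <- as.integer(src)
  tgt <- as.integer(tgt)
  g <- as.numeric(edges$gamma)
  if (anyNA(src) || anyNA(tgt) || anyNA(g)) stop("edges must not contain NA")
  if (any(src < 1L | src > n) || any(tgt < 1L | tgt > n)) {
    stop("edge endpoints must lie in 1..n = 1..", n)
  }
  loops <- src == tgt
  if (any(loops)) {
    stop("self-loop (", src[which(loops)[1L]], " -> ", tgt[which(loops)[1L]],
         ") is not allowed: direct effects belong in `beta`, not `gamma`")
  }
  if (any(g == 0)) {
    stop("zero gamma entries are not allowed: the edge set is the support ",
         "of gamma, so absent effects are absent rows")
  }
  if (anyDuplicated(cbind(src, tgt))) {
    stop("duplicated (source, target) pair in edge list")
  }
  data.frame(source = src, target = tgt, gamma = g)
}

#' @export
print.hane_model <- function(x, ...) {
  cat("HANE potential-outcomes model\n")
  cat("  n individuals :", x$n, "\n")
  cat("  edges |E|     :", nrow(x$edges), "\n")
  cat("  max outdegree :", max_outdegree(x), "\n")
  cat(sprintf("  TTE           : %.6g\n", total_treatment_effect(x)))
  invisible(x)
}

check_treatment <- function(model, z) {
  z <- as.numeric(z)
  if (length(z) != model$n) {
    stop("treatment vector has length ", length(z),
         " but the model population is n = ", model$n)
  }
  if (anyNA(z) || !all(z %in% c(0, 1))) {
    stop("treatment vector must be binary (0/1)")
  }
  z
}

#' Evaluate potential outcomes under a treatment assignment
#'
#' Computes \eqn{Y_i(z) = \alpha_i + \beta_i z_i + \sum_{(k,i) \in E}
#' \gamma_{ki} z_k} for every individual. A pure function of `(model, z)`.
#'
#' @param model a [hane_model()].
#' @param z binary treatment vector of length `model$n`.
#' @return numeric outcome vector of length `n`.
#' @export
evaluate_outcomes <- function(model, z) {
  z <- check_treatment(model, z)
  Y <- model$alpha + model$beta * z
  e <- model$edges
  if (nrow(e)) {
    add <- e$gamma * z[e$source]
    agg <- rowsum(add, e$target)
    idx <- as.integer(rownames(agg))
    Y[idx] <- Y[idx] + agg[, 1L]
  }
  Y
}

#' Total treatment effect of a HANE model
#'
#' The estimand: the average over the population of the difference between the
#' outcome under the all-ones and the all-zeros treatment vector,
#' \deqn{TTE = \frac{1}{n}\Big(\sum_i \beta_i + \sum_{(k,i)\in E} \gamma_{ki}\Big).}
#'
#' @param model a [hane_model()].
#' @return a single number in outcome units.
#' @export
total_treatment_effect <- function(model) {
  (sum(model$beta) + sum(model$edges$gamma)) / model$n
}

#' Maximum outdegree of the interference network
#'
#' The largest number of individuals any single individual's treatment can
#' affect (excluding itself): `max_k |{i : (k,i) in E}|`. This is the `dmax`
#' entering the variance bound for the completely randomized design.
#'
#' @param model a [hane_model()].
#' @return nonnegative integer; 0 for an empty edge set.
#' @export
max_outdegree <- function(model) {
  if (nrow(model$edges) == 0L) return(0L)
  max(tabulate(model$edges$source, nbins = model$n))
}
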