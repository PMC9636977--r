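#' Linear contagion (peer-effects) model
#'
#' Outcomes that propagate through the network at equilibrium:
#' \deqn{Y_i(z) = a_i + b_i z_i + \sum_k c_{ki} Y_k(z),}
#' where `a_i` is the intrinsic outcome, `b_i` the intrinsic treatment
#' response, and `c_{ki}` the weight with which individual `k`'s *outcome*
#' (not treatment) feeds into `i`'s outcome. The fixed point exists and is
#' unique when the spectral radius of the peer-weight matrix is strictly
#' below 1, which is checked at construction; this contraction condition is
#' what makes the implied geometric series (multihop paths) converge.
#'
#' @param a numeric intrinsic outcome vector.
#' @param b numeric intrinsic treatment-response vector, same length.
#' @param edges `NULL` or a data.frame with columns `source`, `target`, `c`:
#'   a row `(k, i, c)` puts weight `c` on `Y_k` in the equation for `Y_i`.
#'   Self-weights are not allowed.
#' @param ids optional unique identifiers (I/O boundary only).
#' @return an object of class `contagion_model` with fields `n`, `a`, `b`,
#'   `C` (sparse `n x n` Matrix, entry `[k, i] = c_ki`), `edges`, `ids`.
#' @export
contagion_model <- function(a, b, edges = NULL, ids = NULL) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  n <- length(a)
  if (n < 1L) stop("population size must be at least 1")
  if (length(b) != n) stop("`a` and `b` must have the same length")
  if (anyNA(a) || anyNA(b)) stop("`a`/`b` must not contain NA")
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0L)) {
    edges <- data.frame(source = integer(0), target = integer(0),
                        c = numeric(0))
  } else {
    if (!is.data.frame(edges) ||
        !all(c("source", "target", "c") %in% names(edges))) {
      stop("`edges` must be a data.frame with columns source, target, c")
    }
    edges <- data.frame(source = as.integer(edges$source),
                        target = as.integer(edges$target),
                        c = as.numeric(edges$c))
    if (any(edges$source < 1L | edges$source > n) ||
        any(edges$target < 1L | edges$target > n)) {
      stop("peer-weight endpoints must lie in 1..n")
    }
    if (any(edges$source == edges$target)) {
      stop("self-weight c_ii is not allowed in a contagion model")
    }
    if (anyDuplicated(cbind(edges$source, edges$target))) {
      stop("duplicated (source, target) pair in peer-weight list")
    }
  }
  C <- Matrix::sparseMatrix(i = edges$source, j = edges$target, x = edges$c,
                            dims = c(n, n))
  sr <- spectral_radius(C)
  if (sr >= 1) {
    stop("peer-weight matrix is not contractive: spectral radius = ",
         format(sr), " >= 1, so the contagion fixed point need not exist")
  }
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(n = n, a = a, b = b, C = C, edges = edges,
                 ids = as.character(ids), spectral_radius = sr),
            class = "contagion_model")
}

spectral_radius <- function(C) {
  if (all(C@x == 0) || length(C@x) == 0L) return(0)
  max(Mod(eigen(as.matrix(C), only.values = TRUE)$values))
}

#' @export
print.contagion_model <- function(x, ...) {
  cat("Linear contagion model\n")
  cat("  n individuals   :", x$n, "\n")
  cat("  peer weights    :", nrow(x$edges), "\n")
  cat(sprintf("  spectral radius : %.4g\n", x$spectral_radius))
  invisible(x)
}

#' Solve the contagion fixed point by iteration
#'
#' Iterates `Y <- a + b*z + t(C) %*% Y` from `Y = a` until the sup-norm change
#' between successive iterates falls below `tol`. Convergence is guaranteed by
#' the contraction condition enforced at model construction.
#'
#' @param cm a [contagion_model()].
#' @param z binary treatment vector.
#' @param tol positive convergence tolerance on the sup norm.
#' @param max_iter iteration cap; exceeding it is an error that reports the
#'   last residual.
#' @return the equilibrium outcome vector.
#' @export
simulate_contagion_fixed_point <- function(cm, z, tol = 1e-12,
                                           max_iter = 10000L) {
  if (length(z) != cm$n) stop("treatment vector length must equal n")
  if (!all(z %in% c(0, 1))) stop("treatment vector must be binary (0/1)")
  if (tol <= 0) stop("`tol` must be positive")
  drive <- cm$a + cm$b * as.numeric(z)
  Y <- cm$a
  for (it in seq_len(max_iter)) {
    Ynew <- drive + as.numeric(Matrix::crossprod(cm$C, Y))
    delta <- max(abs(Ynew - Y))
    Y <- Ynew
    if (delta < tol) return(Y)
  }
  stop("fixed-point iteration did not converge in ", max_iter,
       " iterations (last sup-norm change ", format(delta), ")")
}

#' Convert a linear contagion model to its equivalent HANE representation
#'
#' The equilibrium outcomes are linear in `z`, so the contagion model is a
#' HANE model in disguise: writing the elementwise recursion in matrix form
#' with `A = I - t(C)`, the equilibrium is `Y(z) = A^{-1} a + A^{-1} diag(b) z`.
#' The baseline is the equilibrium at `z = 0`, the diagonal of the response
#' matrix `A^{-1} diag(b)` is the direct effect, and the off-diagonal entries
#' are the (generally dense, multihop) interference effects. The conversion
#' uses one matrix solve, never a truncated series.
#'
#' @param cm a [contagion_model()].
#' @param drop_tol entries of the response matrix with absolute value below
#'   this are dropped from the HANE edge set so the support stays meaningful.
#' @param dense_limit refuse to materialize the dense `n x n` response matrix
#'   beyond this population size.
#' @return a [hane_model()] whose [evaluate_outcomes()] agrees with
#'   [simulate_contagion_fixed_point()] for every `z`.
#' @export
contagion_to_hane <- function(cm, drop_tol = 1e-12, dense_limit = 2000L) {
  n <- cm$n
  if (n > dense_limit) {
    stop("conversion materializes a dense ", n, " x ", n,
         " response matrix; raise `dense_limit` explicitly if intended")
  }
  A <- diag(n) - as.matrix(Matrix::t(cm$C))
  Ainv <- solve(A)
  alpha <- as.numeric(Ainv %*% cm$a)
  # response of Y to z_j is b_j * Ainv[, j]
  G <- sweep(Ainv, 2L, cm$b, `*`)
  beta <- diag(G)
  diag(G) <- 0
  keep <- which(abs(G) >= drop_tol, arr.ind = TRUE)
  edges <- if (nrow(keep)) {
    data.frame(source = as.integer(keep[, 2L]),   # column j treats, row i responds
               target = as.integer(keep[, 1L]),
               gamma = G[keep])
  } else NULL
  hane_model(alpha = alpha, beta = beta, edges = edges, ids = cm$ids)
}
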