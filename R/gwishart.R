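#' G-Wishart prior parameters
#'
#' The G-Wishart distribution over symmetric positive-definite matrices
#' constrained to exact zeros at the non-edges of a graph G has unnormalized
#' density
#' \deqn{p(\Lambda) \propto |\Lambda|^{(\delta-2)/2}
#'   \exp\{-\tfrac12 \mathrm{tr}(D\Lambda)\}}
#' supported on matrices with \eqn{\Lambda_{ij} = 0} whenever \eqn{(i,j)} is
#' not an edge. On the complete graph this is the Wishart distribution with
#' `dof + q - 1` degrees of freedom and scale `solve(scale)`. It is the
#' conjugate prior for a Gaussian precision matrix.
#'
#' @param pattern Symmetric logical q x q matrix with `TRUE` diagonal (from
#'   [precision_pattern()]).
#' @param dof Shape parameter \eqn{\delta > 2} (default `q + 2`).
#' @param scale Symmetric positive-definite q x q scale matrix D (default
#'   identity).
#' @return An object of class `gwishart_params`.
#' @export
gwishart_params <- function(pattern, dof = ncol(pattern) + 2,
                            scale = diag(ncol(pattern))) {
  pattern <- as.matrix(pattern)
  q <- ncol(pattern)
  if (!isTRUE(all.equal(pattern, t(pattern))) || !all(diag(pattern))) {
    abort("`pattern` must be symmetric with TRUE diagonal")
  }
  if (dof <= 2) abort("`dof` must exceed 2")
  scale <- as.matrix(scale)
  if (!isSymmetric(scale, tol = 1e-10)) abort("`scale` must be symmetric")
  ev <- eigen(scale, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) abort("`scale` must be positive-definite")
  structure(list(pattern = pattern > 0, dof = dof, scale = scale, q = q),
            class = "gwishart_params")
}

#' @export
print.gwishart_params <- function(x, ...) {
  free <- sum(x$pattern[upper.tri(x$pattern)])
  cat(sprintf("<gwishart_params> q = %d, dof = %g, %d/%d free off-diagonals\n",
              x$q, x$dof, free, choose(x$q, 2)))
  invisible(x)
}

#' Unnormalized G-Wishart log-density
#'
#' Evaluates \eqn{((\delta-2)/2)\log|\Lambda| -
#' \tfrac12\mathrm{tr}(D\Lambda)}. The normalizing constant is intractable in
#' general and never needed for a fixed graph, so it is not computed.
#'
#' @param lam Symmetric positive-definite q x q matrix respecting the
#'   pattern's zeros.
#' @param params A [gwishart_params()] object.
#' @return The unnormalized log-density (scalar).
#' @export
gwishart_logdensity_unnorm <- function(lam, params) {
  lam <- as.matrix(lam)
  if (any(lam[!params$pattern] != 0)) {
    abort("`lam` violates the zero pattern")
  }
  ch <- tryCatch(chol(lam), error = function(e) abort("`lam` is not positive-definite"))
  logdet <- 2 * sum(log(diag(ch)))
  (params$dof - 2) / 2 * logdet - 0.5 * sum(params$scale * lam)
}

#' Sample from the G-Wishart distribution
#'
#' Block Gibbs sampler over node columns: for each node, the free elements of
#' its row/column (neighbors plus the diagonal) are drawn from their exact
#' full conditional — a Gaussian for the neighbor entries and a Gamma for the
#' Schur complement of the diagonal — while non-edges stay at exact zero and
#' positive definiteness is preserved by construction.
#'
#' @param params A [gwishart_params()] object.
#' @param init Optional starting matrix (defaults to a pattern-respecting
#'   identity). Must respect the pattern and be positive-definite.
#' @param n_sweeps Number of full Gibbs sweeps to perform (>= 1).
#' @return A q x q positive-definite matrix with exact zeros off the pattern.
#'   Deterministic given the RNG state (use `set.seed()`).
#' @export
sample_gwishart <- function(params, init = NULL, n_sweeps = 1) {
  stopifnot(inherits(params, "gwishart_params"), n_sweeps >= 1)
  q <- params$q
  lam <- if (is.null(init)) diag(q) else as.matrix(init)
  if (any(lam[!params$pattern] != 0)) abort("`init` violates the zero pattern")
  nbrs <- gw_neighbors(params$pattern)
  for (s in seq_len(n_sweeps)) {
    lam <- gw_sweep(lam, nbrs, params$scale, params$dof, q)
  }
  dimnames(lam) <- dimnames(params$pattern)
  lam
}

gw_neighbors <- function(pattern) {
  q <- ncol(pattern)
  lapply(seq_len(q), function(j) setdiff(which(pattern[, j]), j))
}

# one unvalidated block-Gibbs sweep (hot path inside the outer sampler)
gw_sweep <- function(lam, nbrs, D, dof, q) {
  for (j in seq_len(q)) {
    lam <- gw_update_node(lam, j, nbrs[[j]], D, dof, q)
  }
  lam
}

# One node update of the block Gibbs sweep. With node j last, partition
# Lam = [[L11, l12], [l12', l22]]; conditional on L11 the free part of l12 is
# Gaussian with precision d_jj * (L11^-1)[A, A] and the Schur complement
# gamma = l22 - l12' L11^-1 l12 is Gamma(dof/2, d_jj/2), independent.
gw_update_node <- function(lam, j, nbr, D, dof, q) {
  others <- setdiff(seq_len(q), j)
  gam <- rgamma(1, shape = dof / 2, rate = D[j, j] / 2)
  if (length(nbr) == 0) {
    lam[j, ] <- 0
    lam[, j] <- 0
    lam[j, j] <- gam
    return(lam)
  }
  l11 <- lam[others, others, drop = FALSE]
  l11_inv <- chol2inv(chol(l11))
  a <- match(nbr, others)
  prec <- D[j, j] * l11_inv[a, a, drop = FALSE]
  ch <- chol(prec)
  mu <- -backsolve(ch, forwardsolve(t(ch), D[nbr, j]))
  z <- rnorm(length(a))
  l12_a <- mu + backsolve(ch, z)
  l12 <- numeric(q - 1)
  l12[a] <- l12_a
  lam[j, others] <- l12
  lam[others, j] <- l12
  lam[j, j] <- gam + drop(crossprod(l12, l11_inv %*% l12))
  lam
}

#' Draw a sequence of G-Wishart samples
#'
#' Runs a single block-Gibbs chain and returns successive states (one per
#' `thin` sweeps) after `burn_in` sweeps, as a q x q x n array. Convenience
#' wrapper for moment checks and diagnostics.
#'
#' @param n Number of draws to retain.
#' @param params A [gwishart_params()] object.
#' @param burn_in Sweeps to discard (default 100).
#' @param thin Sweeps between retained draws (default 1).
#' @param init Optional starting matrix.
#' @return A q x q x n array.
#' @export
rgwishart <- function(n, params, burn_in = 100, thin = 1, init = NULL) {
  q <- params$q
  out <- array(NA_real_, c(q, q, n))
  lam <- sample_gwishart(params, init = init, n_sweeps = max(burn_in, 1))
  for (i in seq_len(n)) {
    lam <- sample_gwishart(params, init = lam, n_sweeps = thin)
    out[, , i] <- lam
  }
  out
}

#' Conjugate G-Wishart posterior update
#'
#' For random-effect rows \eqn{u_j} with precision \eqn{\Lambda} and kinship
#' K (so the stacked U is N(0, K \eqn{\otimes} \eqn{\Lambda^{-1}})), the
#' G-Wishart prior (dof, scale) updates to (dof + n, scale + U'K^{-1}U) on
#' the same graph.
#'
#' @param params A [gwishart_params()] prior.
#' @param u_mat n x q matrix of random-effect rows (used for `n` and, when
#'   `kinship_inv_quadform` is missing and K = I, for the quadratic form).
#' @param kinship_inv_quadform Optional q x q matrix U'K^-1 U; defaults to
#'   `crossprod(u_mat)` (identity kinship).
#' @return A [gwishart_params()] with updated `dof` and `scale`.
#' @export
gwishart_posterior <- function(params, u_mat, kinship_inv_quadform = NULL) {
  u_mat <- as.matrix(u_mat)
  if (ncol(u_mat) != params$q) abort("`u_mat` must have q columns")
  qf <- if (is.null(kinship_inv_quadform)) crossprod(u_mat) else
    as.matrix(kinship_inv_quadform)
  if (!all(dim(qf) == params$q)) abort("quadratic form must be q x q")
  qf <- (qf + t(qf)) / 2
  if (min(eigen(qf, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("quadratic form must be positive semi-definite")
  }
  gwishart_params(params$pattern, dof = params$dof + nrow(u_mat),
                  scale = params$scale + qf)
}
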