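#' Bundle traits, genotypes and kinship for the multi-trait model
#'
#' The model is the multi-trait polygenic mixed model
#' \deqn{Y = \mu + (X \otimes I_q)\beta + U + \epsilon}
#' with Y the stacked trait vector (individual-major, trait index fastest),
#' X the n x p standardized dosage matrix, U the random polygenic effects
#' with precision \eqn{K^{-1} \otimes \Lambda} (the trait precision
#' \eqn{\Lambda} carries the network zeros), and residuals with covariance
#' \eqn{I_n \otimes R}. Internally everything is held in n x q matrix form.
#'
#' @param y n x q matrix of adjusted, standardized traits (no missing
#'   values).
#' @param x n x p matrix of standardized dosages (no missing values; impute
#'   and standardize upstream).
#' @param kinship Either `NULL`/`"identity"` (unrelated samples, the
#'   default) or a symmetric positive semi-definite n x n matrix (e.g. a
#'   VanRaden genomic relationship matrix).
#' @return An object of class `multi_trait_data`.
#' @export
multi_trait_data <- function(y, x, kinship = NULL) {
  y <- as.matrix(y)
  x <- as.matrix(x)
  if (nrow(y) != nrow(x)) abort("`y` and `x` must have the same rows")
  if (anyNA(y) || anyNA(x)) abort("missing values: impute upstream")
  if (ncol(x) < 1 || ncol(y) < 1) abort("need p >= 1 and q >= 1")
  if (is.null(colnames(y))) colnames(y) <- paste0("trait", seq_len(ncol(y)))
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  keig <- NULL
  if (!is.null(kinship) && !identical(kinship, "identity")) {
    kinship <- as.matrix(kinship)
    if (!all(dim(kinship) == nrow(y))) abort("kinship must be n x n")
    if (!isSymmetric(kinship, tol = 1e-8)) abort("kinship must be symmetric")
    keig <- eigen((kinship + t(kinship)) / 2, symmetric = TRUE)
    if (min(keig$values) < 1e-10) {
      # ridge the null space so K^-1 exists; standard GRM practice
      keig$values <- pmax(keig$values, 1e-8)
    }
  } else {
    kinship <- NULL
  }
  structure(list(y = y, x = x, kinship = kinship, keig = keig,
                 n = nrow(y), q = ncol(y), p = ncol(x),
                 sxx = colSums(x^2), xtx = crossprod(x)),
            class = "multi_trait_data")
}

#' @export
print.multi_trait_data <- function(x, ...) {
  cat(sprintf("<multi_trait_data> n = %d, q = %d traits, p = %d variants, K = %s\n",
              x$n, x$q, x$p, if (is.null(x$kinship)) "identity" else "matrix"))
  invisible(x)
}

#' Model and sampler settings
#'
#' @param pattern Optional symmetric logical q x q precision pattern from
#'   [precision_pattern()]; `NULL` means the complete graph (no zeros).
#' @param gw_dof,gw_scale G-Wishart prior shape and scale for the trait
#'   precision (defaults `q + 2` and identity, resolved at fit time).
#' @param beta_prior_var Either `"hierarchical"` (an inverse-gamma(1, 1)
#'   hyperprior on the common effect-prior variance, the default) or a fixed
#'   positive number.
#' @param resid_dof,resid_scale Inverse-Wishart prior for the residual trait
#'   covariance R (defaults `q + 2` and identity, resolved at fit time).
#' @param burn_in Discarded initial iterations (default 200).
#' @param ci_level Credible-interval level used for selection (default
#'   0.98).
#' @param zeta Quantile-stability stopping threshold: the chain stops once
#'   both credible-interval endpoints of every coefficient move by less than
#'   `zeta` between successive checks (default 0.01, on the standardized
#'   trait scale). `Inf` stops at the first check; `NULL` disables checking
#'   and runs exactly `max_iter` retained iterations.
#' @param check_every Retained iterations between convergence checks
#'   (default 100).
#' @param max_iter Maximum retained iterations (default 2000).
#' @param seed Integer seed for the chain (optional; `run_chain` seeds the
#'   RNG when non-`NULL`).
#' @param store Character vector of extra draw sets to retain: any of
#'   `"lam"`, `"r"`.
#' @return An object of class `ibmt_spec` (a validated list).
#' @export
model_spec <- function(pattern = NULL, gw_dof = NULL, gw_scale = NULL,
                       beta_prior_var = "hierarchical",
                       resid_dof = NULL, resid_scale = NULL,
                       burn_in = 200, ci_level = 0.98, zeta = 0.01,
                       check_every = 100, max_iter = 2000, seed = NULL,
                       store = character()) {
  if (!(ci_level > 0 && ci_level < 1)) abort("0 < ci_level < 1 required")
  if (burn_in < 0) abort("burn_in must be >= 0")
  if (!is.null(zeta) && zeta <= 0) abort("zeta must be positive")
  if (is.numeric(beta_prior_var) && beta_prior_var <= 0) {
    abort("fixed beta_prior_var must be positive")
  }
  structure(list(pattern = pattern, gw_dof = gw_dof, gw_scale = gw_scale,
                 beta_prior_var = beta_prior_var, resid_dof = resid_dof,
                 resid_scale = resid_scale, burn_in = burn_in,
                 ci_level = ci_level, zeta = zeta,
                 check_every = check_every, max_iter = max_iter,
                 seed = seed, store = store),
            class = "ibmt_spec")
}

resolve_priors <- function(data, spec) {
  q <- data$q
  pattern <- spec$pattern
  if (is.null(pattern)) pattern <- matrix(TRUE, q, q)
  if (!all(dim(pattern) == q)) abort("pattern must be q x q")
  gw <- gwishart_params(pattern,
                        dof = spec$gw_dof %||% (q + 2),
                        scale = spec$gw_scale %||% diag(q))
  list(gw = gw, gw_nbrs = gw_neighbors(gw$pattern),
       resid_dof = spec$resid_dof %||% (q + 2),
       resid_scale = spec$resid_scale %||% diag(q),
       sb_a = 1, sb_b = 1)
}

#' Deterministic initial state of the Gibbs chain
#'
#' Trait means for \eqn{\mu}, zero variant effects and random effects, a
#' pattern-respecting identity for the trait precision, and the diagonal of
#' the trait variances for the residual covariance.
#'
#' @param data A [multi_trait_data()] object.
#' @param spec A [model_spec()] object.
#' @return An object of class `ibmt_state`.
#' @export
init_state <- function(data, spec) {
  vars <- apply(data$y, 2, var)
  if (any(vars == 0)) abort("degenerate trait with zero variance")
  pri <- resolve_priors(data, spec)
  structure(list(
    mu = colMeans(data$y),
    beta = matrix(0, data$p, data$q,
                  dimnames = list(colnames(data$x), colnames(data$y))),
    u = matrix(0, data$n, data$q),
    lam = diag(data$q),
    r = diag(vars, data$q),
    sigma_beta2 = if (is.numeric(spec$beta_prior_var)) spec$beta_prior_var else 1,
    priors = pri
  ), class = "ibmt_state")
}

#' One full-conditional Gibbs sweep
#'
#' Updates, in order: the variant effects \eqn{\beta} (one exact joint
#' Gaussian draw of all pq coefficients, computed per rotated trait in the
#' eigenbasis of \eqn{R^{-1}}), the random effects U (Gaussian, precision
#' \eqn{K^{-1}\otimes\Lambda + I_n\otimes R^{-1}}), the trait precision
#' \eqn{\Lambda} (conjugate G-Wishart via [gwishart_posterior()] and
#' [sample_gwishart()]), the residual covariance R (conjugate
#' inverse-Wishart), the effect-prior variance (conjugate inverse-gamma,
#' when hierarchical), and the intercepts \eqn{\mu}. Deterministic given the
#' RNG state.
#'
#' @param state An `ibmt_state`.
#' @param data A [multi_trait_data()].
#' @param spec A [model_spec()].
#' @return The updated `ibmt_state`.
#' @export
gibbs_step <- function(state, data, spec) {
  y <- data$y; x <- data$x
  n <- data$n; q <- data$q; p <- data$p
  pri <- state$priors
  beta <- state$beta; u <- state$u; mu <- state$mu
  lam <- state$lam; r <- state$r; sb2 <- state$sigma_beta2

  r_inv <- chol2inv(chol(r))
  iq <- diag(q)

  # (a) beta | rest: exact joint conjugate draw. Rotating traits into the
  # eigenbasis of R^-1 makes the pq-dimensional full conditional factor
  # into q independent p-dimensional Gaussians (the iid N(0, sb2) prior is
  # rotation-invariant), so the whole block is drawn at once.
  w_resid <- y - rep(mu, each = n) - u
  ev <- eigen(r_inv, symmetric = TRUE)
  vrot <- ev$vectors
  xtw <- crossprod(x, w_resid %*% vrot)
  bt <- matrix(0, p, q)
  g_xx <- data$xtx %||% crossprod(x)
  for (m in seq_len(q)) {
    ch <- chol(ev$values[m] * g_xx + diag(p) / sb2)
    mu_m <- backsolve(ch, forwardsolve(t(ch), ev$values[m] * xtw[, m]))
    bt[, m] <- mu_m + backsolve(ch, rnorm(p))
  }
  beta[, ] <- bt %*% t(vrot)
  e <- w_resid - x %*% beta

  # (b) U | rest
  wu <- e + u
  if (is.null(data$keig)) {
    prec <- lam + r_inv
    ch <- chol(prec)
    m <- t(backsolve(ch, forwardsolve(t(ch), t(wu %*% r_inv))))
    z <- matrix(rnorm(n * q), n, q)
    u <- m + z %*% t(backsolve(ch, iq))
  } else {
    qm <- data$keig$vectors
    dvals <- data$keig$values
    wt <- crossprod(qm, wu)
    ut <- matrix(0, n, q)
    for (i in seq_len(n)) {
      ch <- chol(lam / dvals[i] + r_inv)
      mi <- backsolve(ch, forwardsolve(t(ch), r_inv %*% wt[i, ]))
      ut[i, ] <- mi + backsolve(ch, rnorm(q))
    }
    u <- qm %*% ut
  }
  e <- wu - u

  # (c) Lambda | U (G-Wishart conjugacy)
  qf <- if (is.null(data$keig)) crossprod(u) else {
    ut <- crossprod(data$keig$vectors, u)
    crossprod(ut / sqrt(data$keig$values))
  }
  # conjugate update (dof + n, scale + U'K^-1 U), then one constrained sweep
  lam <- gw_sweep(state$lam, pri$gw_nbrs, pri$gw$scale + qf,
                  pri$gw$dof + n, q)

  # (d) R | residuals (inverse-Wishart conjugacy)
  s_post <- pri$resid_scale + crossprod(e)
  w <- rWishart(1, pri$resid_dof + n, chol2inv(chol(s_post)))[, , 1]
  r <- chol2inv(chol(w))

  # (e) effect-prior variance (hierarchical case)
  if (!is.numeric(spec$beta_prior_var)) {
    sb2 <- 1 / rgamma(1, shape = pri$sb_a + p * q / 2,
                      rate = pri$sb_b + sum(beta^2) / 2)
  }

  # (f) mu | rest (flat prior)
  wm <- e + rep(mu, each = n)
  mbar <- colMeans(wm)
  mu <- mbar + drop(t(chol(r)) %*% rnorm(q)) / sqrt(n)

  state$mu <- mu; state$beta <- beta; state$u <- u
  state$lam <- lam; state$r <- r; state$sigma_beta2 <- sb2
  state
}

#' Equal-tailed credible interval from posterior draws
#'
#' Endpoints are the \eqn{(1-level)/2} and \eqn{1-(1-level)/2} quantiles of
#' the empirical draw distribution, with linear interpolation between order
#' statistics (type-7 quantiles).
#'
#' @param draws Numeric vector of at least 2 posterior draws.
#' @param level Interval level in (0, 1), e.g. 0.98.
#' @return Named numeric vector `c(low, high)` with attribute `"level"`.
#' @export
credible_interval <- function(draws, level = 0.98) {
  if (length(draws) < 2) abort("need at least 2 draws")
  if (!(level > 0 && level < 1)) abort("0 < level < 1 required")
  tail_p <- (1 - level) / 2
  qs <- quantile(draws, c(tail_p, 1 - tail_p), names = FALSE, type = 7)
  structure(c(low = qs[1], high = qs[2]), level = level)
}

#' Quantile-stability stopping rule
#'
#' The chain has converged for a coefficient when both credible-interval
#' endpoints moved by less than `zeta` since the previous check:
#' \eqn{|q_i^L - q_{i-1}^L| < \zeta} and \eqn{|q_i^U - q_{i-1}^U| < \zeta}.
#' Vectorized over coefficients; returns a single flag for all of them.
#'
#' @param prev_low,prev_high,cur_low,cur_high Numeric vectors of interval
#'   endpoints at the previous and current check.
#' @param zeta Positive threshold (default 0.01).
#' @return `TRUE` iff every endpoint difference is below `zeta`.
#' @export
check_convergence <- function(prev_low, prev_high, cur_low, cur_high,
                              zeta = 0.01) {
  all(abs(cur_low - prev_low) < zeta) &&
    all(abs(cur_high - prev_high) < zeta)
}

#' Run the Gibbs chain
#'
#' Discards `burn_in` iterations, then retains draws in batches of
#' `check_every`, monitoring the credible-interval endpoints of every
#' variant-trait coefficient; sampling stops when all endpoints are stable
#' to within `zeta` (see [check_convergence()]) or `max_iter` retained
#' iterations are reached (flagged, not an error). Point estimates are
#' posterior means.
#'
#' @param data A [multi_trait_data()].
#' @param spec A [model_spec()].
#' @return An object of class `ibmt_fit`: retained `beta_draws`
#'   (iterations x p x q), posterior summaries, convergence information, and
#'   optionally `lam_draws` / `r_draws`.
#' @export
run_chain <- function(data, spec = model_spec()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  state <- init_state(data, spec)
  p <- data$p; q <- data$q
  for (b in seq_len(spec$burn_in)) state <- gibbs_step(state, data, spec)

  max_iter <- spec$max_iter
  batch <- if (is.null(spec$zeta)) max_iter else min(spec$check_every, max_iter)
  beta_draws <- array(NA_real_, c(max_iter, p, q),
                      dimnames = list(NULL, colnames(data$x), colnames(data$y)))
  store_lam <- "lam" %in% spec$store
  store_r <- "r" %in% spec$store
  lam_draws <- if (store_lam) array(NA_real_, c(max_iter, q, q))
  r_draws <- if (store_r) array(NA_real_, c(max_iter, q, q))

  tail_p <- (1 - spec$ci_level) / 2
  prev_q <- NULL
  history <- list()
  n_ret <- 0
  converged <- FALSE
  while (n_ret < max_iter && !converged) {
    n_new <- min(batch, max_iter - n_ret)
    for (it in seq_len(n_new)) {
      state <- gibbs_step(state, data, spec)
      n_ret <- n_ret + 1
      beta_draws[n_ret, , ] <- state$beta
      if (store_lam) lam_draws[n_ret, , ] <- state$lam
      if (store_r) r_draws[n_ret, , ] <- state$r
    }
    flat <- matrix(beta_draws[seq_len(n_ret), , , drop = FALSE], nrow = n_ret)
    cur <- apply(flat, 2, quantile, probs = c(tail_p, 1 - tail_p),
                 names = FALSE, type = 7)
    history[[length(history) + 1]] <-
      tibble(iteration = n_ret,
             max_low_change = if (is.null(prev_q)) NA_real_ else
               max(abs(cur[1, ] - prev_q[1, ])),
             max_high_change = if (is.null(prev_q)) NA_real_ else
               max(abs(cur[2, ] - prev_q[2, ])))
    if (!is.null(spec$zeta) && !is.null(prev_q)) {
      converged <- check_convergence(prev_q[1, ], prev_q[2, ],
                                     cur[1, ], cur[2, ], spec$zeta)
    }
    prev_q <- cur
  }

  beta_draws <- beta_draws[seq_len(n_ret), , , drop = FALSE]
  est <- apply(beta_draws, c(2, 3), mean)
  sd_eff <- apply(beta_draws, c(2, 3), sd)
  lo <- apply(beta_draws, c(2, 3), quantile, probs = tail_p, names = FALSE,
              type = 7)
  hi <- apply(beta_draws, c(2, 3), quantile, probs = 1 - tail_p,
              names = FALSE, type = 7)

  structure(list(
    beta_draws = beta_draws,
    lam_draws = if (store_lam) lam_draws[seq_len(n_ret), , , drop = FALSE],
    r_draws = if (store_r) r_draws[seq_len(n_ret), , , drop = FALSE],
    est = est, sd = sd_eff, ci_low = lo, ci_high = hi,
    converged = converged, n_retained = n_ret,
    monitor = bind_rows(history),
    spec = spec, n = data$n, q = q, p = p,
    variant_ids = colnames(data$x), trait_names = colnames(data$y),
    final_state = state
  ), class = "ibmt_fit")
}

#' @export
print.ibmt_fit <- function(x, ...) {
  cat(sprintf(
    "<ibmt_fit> n = %d, q = %d, p = %d; %d retained draws (%s)\n",
    x$n, x$q, x$p, x$n_retained,
    if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' @rdname run_chain
#' @param x An `ibmt_fit`.
#' @param level Credible level (defaults to the fitted spec's `ci_level`).
#' @param ... Unused.
#' @export
tidy.ibmt_fit <- function(x, level = NULL, ...) {
  level <- level %||% x$spec$ci_level
  tail_p <- (1 - level) / 2
  grid <- expand.grid(variant = x$variant_ids, trait = x$trait_names,
                      stringsAsFactors = FALSE)
  lo <- apply(x$beta_draws, c(2, 3), quantile, probs = tail_p,
              names = FALSE, type = 7)
  hi <- apply(x$beta_draws, c(2, 3), quantile, probs = 1 - tail_p,
              names = FALSE, type = 7)
  tibble(
    variant = grid$variant, trait = grid$trait,
    estimate = as.vector(x$est), std.error = as.vector(x$sd),
    conf.low = as.vector(lo), conf.high = as.vector(hi),
    level = level,
    selected = as.vector(lo > 0 | hi < 0)
  )
}

#' @rdname run_chain
#' @export
glance.ibmt_fit <- function(x, ...) {
  tibble(n = x$n, q = x$q, p = x$p, retained = x$n_retained,
         burn_in = x$spec$burn_in, converged = x$converged,
         ci_level = x$spec$ci_level,
         n_selected = sum(tidy(x)$selected))
}

#' Write the per-coefficient effect report as TSV
#'
#' One row per variant-trait pair: posterior mean and SD, credible-interval
#' endpoints, and the selection flag.
#'
#' @param fit An `ibmt_fit` from [run_chain()].
#' @param path Output path.
#' @param level Credible level (defaults to the fitted `ci_level`).
#' @return `path`, invisibly.
#' @export
write_effect_report <- function(fit, path, level = NULL) {
  td <- tidy(fit, level = level)
  out <- data.frame(variant_id = td$variant, trait = td$trait,
                    est_eff = td$estimate, sd_eff = td$std.error,
                    q_low = td$conf.low, q_high = td$conf.high,
                    selected = td$selected)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select variant-trait effects whose credible interval excludes zero
#'
#' @param fit An `ibmt_fit` from [run_chain()].
#' @param level Credible level (defaults to the fitted `ci_level`).
#' @return Tibble of selected (variant, trait) pairs with posterior mean
#'   (`estimate`), posterior SD (`std.error`), and interval endpoints.
#' @export
select_effects <- function(fit, level = NULL) {
  td <- tidy(fit, level = level)
  td[td$selected, , drop = FALSE]
}
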