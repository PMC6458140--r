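test_that("init_state is deterministic with the documented values", {
  set.seed(71)
  y <- cbind(rnorm(50) + 1, rnorm(50) + 2)
  x <- matrix(rnorm(150), 50, 3)
  dat <- multi_trait_data(y, x)
  st <- init_state(dat, model_spec())
  expect_equal(st$beta, matrix(0, 3, 2), ignore_attr = TRUE)
  expect_equal(st$mu, colMeans(y), ignore_attr = TRUE)
  expect_equal(st$u, matrix(0, 50, 2))
  expect_equal(st$lam, diag(2))
  expect_equal(st$r, diag(apply(y, 2, var)))
  y_flat <- y; y_flat[, 1] <- 1
  expect_error(init_state(multi_trait_data(y_flat, x), model_spec()),
               "zero variance")
})

test_that("one Gibbs step moves beta toward a strong planted signal", {
  set.seed(72)
  n <- 200; q <- 2; p <- 4
  x <- scale(matrix(rbinom(n * p, 2, 0.4), n, p))
  b0 <- matrix(0, p, q); b0[2, 1] <- 5
  y <- x %*% b0 + matrix(rnorm(n * q, sd = 0.1), n, q)
  dat <- multi_trait_data(y, x)
  spec <- model_spec(beta_prior_var = 10)
  st <- init_state(dat, spec)
  err0 <- sum((st$beta - b0)^2)
  st1 <- gibbs_step(st, dat, spec)
  expect_lt(sum((st1$beta - b0)^2), err0)
})

test_that("gibbs_step is deterministic given the RNG state", {
  set.seed(73)
  dat <- make_chain_data(100, p = 5)$data
  spec <- model_spec()
  st <- init_state(dat, spec)
  set.seed(99); s1 <- gibbs_step(st, dat, spec)
  set.seed(99); s2 <- gibbs_step(st, dat, spec)
  expect_identical(s1, s2)
})

test_that("with zero design the beta conditional reproduces its prior", {
  set.seed(74)
  n <- 60; q <- 2; p <- 3
  x <- matrix(0, n, p)
  y <- matrix(rnorm(n * q), n, q)
  dat <- multi_trait_data(y, x)
  spec <- model_spec(beta_prior_var = 0.8)
  st <- init_state(dat, spec)
  draws <- replicate(3000, gibbs_step(st, dat, spec)$beta[1, 1])
  expect_equal(mean(draws), 0, tolerance = 3 * sqrt(0.8 / 3000) * 1.5)
  expect_equal(var(draws), 0.8, tolerance = 0.08)
})

test_that("beta conditional matches the closed-form Bayesian regression", {
  # single variant, q = 1: beta | rest ~ N(m, v) with v = (s/r + 1/sb2)^-1,
  # m = v * x'w / r, conditioning on the state passed in
  set.seed(75)
  n <- 150
  x <- matrix(rnorm(n), n, 1)
  y <- matrix(0.7 * x + rnorm(n, sd = 0.8), n, 1)
  dat <- multi_trait_data(y, x)
  spec <- model_spec(beta_prior_var = 2)
  st <- init_state(dat, spec)
  st$r <- matrix(0.64); st$u <- matrix(0, n, 1); st$mu <- 0
  draws <- replicate(4000, gibbs_step(st, dat, spec)$beta[1, 1])
  s <- sum(x^2)
  v <- 1 / (s / 0.64 + 1 / 2)
  m <- v * sum(x * y) / 0.64
  expect_lt(abs(mean(draws) - m), 4 * sqrt(v / 4000))
  expect_equal(var(draws), v, tolerance = 0.15)
})

test_that("credible intervals follow the type-7 quantile rule", {
  ci <- credible_interval(as.numeric(1:100), 0.98)
  expect_equal(as.vector(ci), c(1.99, 99.01))
  expect_equal(attr(ci, "level"), 0.98)
  ci_const <- credible_interval(rep(3.5, 10), 0.98)
  expect_equal(as.vector(ci_const), c(3.5, 3.5))
  expect_error(credible_interval(1), "at least 2")
  # nesting: the 90% interval lies inside the 98% interval
  set.seed(76)
  d <- rnorm(500)
  ci90 <- credible_interval(d, 0.90)
  ci98 <- credible_interval(d, 0.98)
  expect_gte(ci90["low"], ci98["low"])
  expect_lte(ci90["high"], ci98["high"])
})

test_that("the quantile-stability rule compares successive endpoints", {
  expect_true(check_convergence(0.50, 2.00, 0.505, 1.995, zeta = 0.01))
  expect_false(check_convergence(0.50, 2.00, 0.52, 2.00, zeta = 0.01))
  expect_true(check_convergence(0.50, 2.00, 10, -10, zeta = Inf))
  # vectorized over coefficients: one bad endpoint fails the whole check
  expect_false(check_convergence(c(0, 0), c(1, 1), c(0.001, 0.5), c(1, 1),
                                 zeta = 0.01))
})

test_that("run_chain respects burn-in and iteration boundaries", {
  set.seed(77)
  dat <- make_chain_data(80, p = 3)$data
  spec <- model_spec(burn_in = 0, max_iter = 1, zeta = NULL, seed = 5)
  fit <- run_chain(dat, spec)
  expect_equal(fit$n_retained, 1)
  expect_equal(dim(fit$beta_draws), c(1, 3, 3))
})

test_that("run_chain is bit-reproducible under a fixed seed", {
  dat <- make_chain_data(100, p = 4, seed = 78)$data
  spec <- model_spec(burn_in = 20, max_iter = 100, check_every = 50, seed = 11)
  f1 <- run_chain(dat, spec)
  f2 <- run_chain(dat, spec)
  expect_identical(f1$beta_draws, f2$beta_draws)
  expect_identical(f1$est, f2$est)
})

test_that("retained precision draws keep exact pattern zeros", {
  cd <- make_chain_data(150, q = 3, p = 4, seed = 79)
  spec <- model_spec(pattern = cd$pattern, burn_in = 20, max_iter = 100,
                     zeta = NULL, seed = 12, store = "lam")
  fit <- run_chain(cd$data, spec)
  expect_true(all(fit$lam_draws[, 1, 3] == 0))
  expect_true(all(fit$lam_draws[, 3, 1] == 0))
  expect_true(all(fit$lam_draws[, 1, 2] != 0))
})

test_that("a planted effect is recovered and selected; selection is monotone", {
  cd <- make_chain_data(500, q = 3, p = 10, effect = 1, variant = 3,
                        trait = 1, seed = 80)
  spec <- model_spec(pattern = cd$pattern, burn_in = 200, max_iter = 800,
                     check_every = 800, seed = 13)
  fit <- run_chain(cd$data, spec)
  td <- tidy(fit)
  hit <- td[td$variant == "v3" & td$trait == "trait1", ]
  expect_true(hit$selected)
  expect_lt(abs(hit$estimate - 1), 3 * hit$std.error)
  sel98 <- select_effects(fit, 0.98)
  sel90 <- select_effects(fit, 0.90)
  expect_true(all(paste(sel98$variant, sel98$trait) %in%
                    paste(sel90$variant, sel90$trait)))
  gl <- glance(fit)
  expect_equal(gl$retained, fit$n_retained)
  expect_equal(gl$q, 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_effect_report(fit, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 30)
  expect_true(back$selected[back$variant_id == "v3" & back$trait == "trait1"])
})

test_that("null coefficients are selected at roughly the nominal error rate", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    cd <- make_chain_data(200, q = 3, p = 10, seed = 500 + s)
    spec <- model_spec(pattern = cd$pattern, burn_in = 100, max_iter = 400,
                       check_every = 400, seed = 600 + s)
    fit <- run_chain(cd$data, spec)
    td <- tidy(fit)
    hits <- hits + sum(td$selected)
    total <- total + nrow(td)
  }
  # 98% CIs on null data: ~2% per coefficient
  expect_lt(hits / total, 0.06)
})

test_that("a genomic relationship matrix is accepted as kinship", {
  set.seed(81)
  n <- 80; q <- 2; p <- 5
  x <- scale(matrix(rbinom(n * p, 2, 0.3), n, p))
  y <- matrix(rnorm(n * q), n, q)
  k <- tcrossprod(x) / p + diag(n) * 0.05
  dat <- multi_trait_data(y, x, kinship = k)
  spec <- model_spec(burn_in = 10, max_iter = 30, zeta = NULL, seed = 14)
  fit <- run_chain(dat, spec)
  expect_equal(fit$n_retained, 30)
  expect_true(all(is.finite(fit$est)))
})
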