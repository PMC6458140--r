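test_that("cohort split produces disjoint sets of the requested sizes", {
  cfg <- sim_config(n_both = 50, n_pheno_only = 20, n_geno_only = 100,
                    q = 3, p = 20)
  cs <- make_cohort_split(cfg)
  expect_length(cs$both, 50)
  expect_length(cs$pheno_only, 20)
  expect_length(cs$geno_only, 100)
  expect_length(intersect(cs$both, cs$geno_only), 0)
  cs0 <- make_cohort_split(sim_config(n_both = 10, n_pheno_only = 0,
                                      n_geno_only = 0, q = 3, p = 5))
  expect_length(cs0$both, 10)
  expect_length(cs0$pheno_only, 0)
  # demo defaults: fixed three-arm split with a realistic imbalance
  cs_demo <- make_cohort_split(sim_config())
  expect_length(cs_demo$both, 339)
  expect_length(cs_demo$geno_only, 442)
  expect_length(cs_demo$pheno_only, 127)
  expect_error(sim_config(n_both = -1), "negative")
})

test_that("simulated MAFs concentrate near their targets", {
  cfg <- sim_config(n_both = 10000, n_pheno_only = 0, n_geno_only = 0,
                    q = 3, p = 5, maf_range = c(0.5, 0.5),
                    rare_fraction = 0, planted_effects =
                      tibble::tibble(variant = 1, trait = 1, effect = 1),
                    planted_maf = c(`1` = 0.5), seed = 101)
  g <- simulate_genotypes(cfg)
  expect_true(all(abs(g$variants$maf - 0.5) < 0.01))
})

test_that("rare planted variants are guaranteed at least 4 carriers", {
  cfg <- sim_config(n_both = 339, n_pheno_only = 0, n_geno_only = 100,
                    q = 3, p = 50, seed = 102,
                    planted_effects = tibble::tibble(variant = 25, trait = 1,
                                                     effect = 1),
                    planted_maf = c(`25` = 0.0038))
  split <- make_cohort_split(cfg)
  g <- simulate_genotypes(cfg, split)
  carriers <- sum(g$dosages[match(split$both, g$sample_ids), 25] > 0)
  expect_gte(carriers, 4)
  # impossible carrier guarantee errors out with advice
  cfg_bad <- sim_config(n_both = 20, n_pheno_only = 0, n_geno_only = 0,
                        q = 3, p = 10, seed = 103,
                        planted_effects = tibble::tibble(variant = 5,
                                                         trait = 1,
                                                         effect = 1),
                        planted_maf = c(`5` = 0.001))
  expect_error(simulate_genotypes(cfg_bad), "increase n or maf")
})

test_that("genotype simulation is reproducible from the config seed", {
  cfg <- sim_config(n_both = 50, n_pheno_only = 0, n_geno_only = 0, q = 3,
                    p = 30, seed = 104)
  expect_identical(simulate_genotypes(cfg)$dosages,
                   simulate_genotypes(cfg)$dosages)
})

test_that("trait covariance mirrors the generative model", {
  q <- 5
  cfg <- sim_config(n_both = 0, n_pheno_only = 5000, n_geno_only = 0,
                    q = q, p = 10, seed = 105,
                    planted_effects = tibble::tibble(variant = integer(),
                                                     trait = integer(),
                                                     effect = numeric()),
                    covariate_effects = matrix(0, 3, q),
                    true_graph = trait_graph(
                      paste0("trait", 1:q),
                      cbind(paste0("trait", 1:(q - 1)), paste0("trait", 2:q))),
                    true_precision = chain_precision(q))
  sim <- simulate_ibmt_data(cfg)
  y <- as.matrix(sim$phenotypes[, cfg$traits])
  expected <- chol2inv(chol(cfg$true_precision)) + diag(q)
  rel_err <- norm(cov(y) - expected, "F") / norm(expected, "F")
  expect_lt(rel_err, 0.1)
})

test_that("carriers of a planted variant shift by the dosage-weighted effect", {
  cfg <- sim_config(n_both = 3000, n_pheno_only = 0, n_geno_only = 0,
                    q = 3, p = 50, seed = 106,
                    planted_effects = tibble::tibble(variant = 10, trait = 2,
                                                     effect = 1),
                    planted_maf = c(`10` = 0.05),
                    covariate_effects = matrix(0, 3, 3))
  sim <- simulate_ibmt_data(cfg)
  d <- sim$genotypes$dosages[match(sim$split$both, sim$genotypes$sample_ids), 10]
  y2 <- sim$phenotypes$trait2[match(sim$split$both, sim$phenotypes$sample_id)]
  carrier <- d > 0
  shift <- mean(y2[carrier]) - mean(y2[!carrier])
  expected <- mean(d[carrier]) - mean(d[!carrier])  # effect = 1 per allele
  se <- sqrt(var(y2[carrier]) / sum(carrier) +
               var(y2[!carrier]) / sum(!carrier))
  expect_lt(abs(shift - expected), 3 * se)
})

test_that("with no structure the traits are iid standard normal", {
  passes <- vapply(1:10, function(s) {
    q <- 3
    cfg <- sim_config(n_both = 0, n_pheno_only = 500, n_geno_only = 0,
                      q = q, p = 5, seed = 200 + s,
                      planted_effects = tibble::tibble(variant = integer(),
                                                       trait = integer(),
                                                       effect = numeric()),
                      covariate_effects = matrix(0, 3, q),
                      true_precision = diag(q) * 1e6,
                      true_graph = trait_graph(paste0("trait", 1:q), NULL))
    sim <- simulate_ibmt_data(cfg)
    all(vapply(cfg$traits, function(tr) {
      suppressWarnings(ks.test(sim$phenotypes[[tr]], "pnorm")$p.value) > 0.01
    }, TRUE))
  }, TRUE)
  expect_gte(sum(passes), 8)
})

test_that("phenotype-only samples receive no genetic contribution", {
  cfg <- sim_config(n_both = 200, n_pheno_only = 200, n_geno_only = 0,
                    q = 3, p = 20, seed = 107,
                    planted_effects = tibble::tibble(variant = 3, trait = 1,
                                                     effect = 10),
                    planted_maf = c(`3` = 0.3))
  sim <- simulate_ibmt_data(cfg)
  ph <- sim$phenotypes
  v_both <- var(ph$trait1[ph$cohort == "both"])
  v_ponly <- var(ph$trait1[ph$cohort == "pheno_only"])
  expect_gt(v_both, 3 * v_ponly)  # the huge effect inflates only the both arm
})

test_that("the learned network recovers the generative chain", {
  # residual covariance proportional to the random-effect covariance keeps
  # the marginal trait precision sparse, so the observable graph equals the
  # random-effect graph
  hits <- vapply(1:5, function(s) {
    q <- 6
    cfg <- sim_config(n_both = 0, n_pheno_only = 3000, n_geno_only = 0,
                      q = q, p = 5, seed = 300 + s,
                      planted_effects = tibble::tibble(variant = integer(),
                                                       trait = integer(),
                                                       effect = numeric()),
                      covariate_effects = matrix(0, 3, q),
                      true_graph = trait_graph(
                        paste0("trait", 1:q),
                        cbind(paste0("trait", 1:(q - 1)),
                              paste0("trait", 2:q))),
                      true_precision = chain_precision(q),
                      resid_cov = chol2inv(chol(chain_precision(q))))
    sim <- simulate_ibmt_data(cfg)
    g <- learn_trait_graph(as.matrix(sim$phenotypes[, cfg$traits]),
                           alpha = 0.05)
    tk <- paste(cfg$true_graph$edges$trait_a, cfg$true_graph$edges$trait_b)
    gk <- paste(g$edges$trait_a, g$edges$trait_b)
    c(recall = mean(tk %in% gk), false = sum(!gk %in% tk))
  }, c(recall = 0, false = 0))
  # every chain edge found in (almost) every seed; false edges at the
  # per-pair alpha = 0.05 rate (10 non-edges -> about 0.5 per seed)
  expect_gte(sum(hits["recall", ] == 1), 4)
  expect_lte(mean(hits["false", ]), 2)
})

test_that("covariates screened on simulated data keep the planted ones", {
  cfg <- sim_config(n_both = 0, n_pheno_only = 1000, n_geno_only = 0,
                    q = 6, p = 5, seed = 108,
                    planted_effects = tibble::tibble(variant = integer(),
                                                     trait = integer(),
                                                     effect = numeric()))
  sim <- simulate_ibmt_data(cfg)
  ph <- sim$phenotypes
  ph$noise_cov <- rnorm(nrow(ph))
  sc <- screen_covariates(ph, cfg$traits,
                          c("bmi", "sex", "hypertension", "noise_cov"))
  expect_setequal(sc$selected, c("bmi", "sex", "hypertension"))
})
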