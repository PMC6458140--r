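#' Chain-structured precision matrix
#'
#' Tridiagonal precision with unit diagonal and off-diagonal `-rho` on the
#' chain edges 1-2-...-q, so every chain edge has partial correlation `rho`.
#' Positive-definite for `|rho| < 0.5`.
#'
#' @param q Number of traits.
#' @param rho Edge partial correlation (default 0.4).
#' @return A q x q precision matrix.
#' @export
chain_precision <- function(q, rho = 0.4) {
  m <- diag(q)
  for (i in seq_len(q - 1)) m[i, i + 1] <- m[i + 1, i] <- -rho
  m
}

#' Trait names used by the demo fixtures
#'
#' Echocardiographic trait labels for `q = 10` (septal and posterior wall
#' thickness, volumes, ejection fraction, mass/volume indices, wall
#' thickness, atrial diameter and volume index); generic `trait1..q`
#' otherwise.
#' @param q Number of traits.
#' @return Character vector of length `q`.
#' @export
default_trait_names <- function(q) {
  if (q == 10) {
    c("PLAx_IST", "PLAx_PWT", "ED_V", "ES_V", "EF",
      "LV_MI", "LV_RWT", "LV_WT", "Max_LA_APD", "LA_VI")
  } else {
    paste0("trait", seq_len(q))
  }
}

#' Simulation configuration
#'
#' Defines the synthetic study: a three-way cohort split (genotype-only /
#' phenotype-only / both), correlated traits generated from a sparse
#' conditional-dependence structure, a minor-allele-frequency spectrum with
#' a rare tail, planted variant effects (by default one rare pleiotropic
#' variant hitting three traits), and BMI-like, sex, and hypertension
#' covariates. Default cohort sizes (442 genotype-only, 339 both, 127
#' phenotype-only) give a realistic imbalance between the three arms at a
#' size that keeps simulation studies fast.
#'
#' @param n_both,n_pheno_only,n_geno_only Cohort sizes.
#' @param q Number of traits.
#' @param p Number of variants.
#' @param maf_range Range of common-variant MAFs (uniform draw).
#' @param rare_fraction Fraction of variants drawn from the rare tail.
#' @param rare_range Rare-tail MAF range (default 0.25--0.38%).
#' @param true_graph A `trait_graph` over the traits (default: chain).
#' @param true_precision q x q precision of the shared random effects, with
#'   exact zeros off `true_graph` (default [chain_precision()]).
#' @param resid_cov q x q residual trait covariance (default identity).
#' @param planted_effects Tibble with columns `variant` (index), `trait`
#'   (index), `effect` (per minor allele on the trait-SD scale, or on the
#'   standardized-dosage scale when `effect_scale = "standardized"`).
#'   Default: one rare variant at an interior position affecting traits
#'   1-3 with effects 1.1, 1.3, 1.3.
#' @param planted_maf Optional MAFs for the planted variants (default
#'   0.38%).
#' @param effect_scale `"allele"` (effect multiplies the 0/1/2 dosage) or
#'   `"standardized"` (effect multiplies the standardized dosage).
#' @param covariate_effects 3 x q matrix of per-trait coefficients for
#'   (standardized BMI, sex, hypertension).
#' @param mu Trait means (default 0).
#' @param seed Integer master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_both = 339, n_pheno_only = 127, n_geno_only = 442,
                       q = 10, p = 500,
                       maf_range = c(0.01, 0.5), rare_fraction = 0.1,
                       rare_range = c(0.0025, 0.0038),
                       true_graph = NULL, true_precision = NULL,
                       resid_cov = NULL,
                       planted_effects = NULL, planted_maf = NULL,
                       effect_scale = c("allele", "standardized"),
                       covariate_effects = NULL, mu = NULL, seed = 1L) {
  effect_scale <- match.arg(effect_scale)
  if (min(n_both, n_pheno_only, n_geno_only) < 0) abort("negative cohort size")
  traits <- default_trait_names(q)
  if (is.null(true_graph)) {
    true_graph <- trait_graph(traits,
                              cbind(traits[-q], traits[-1]))
  }
  if (is.null(true_precision)) true_precision <- chain_precision(q)
  pat <- precision_pattern(true_graph)
  if (any(true_precision[!pat] != 0)) {
    abort("`true_precision` must be zero off the graph")
  }
  if (min(eigen(true_precision, symmetric = TRUE,
                only.values = TRUE)$values) <= 0) {
    abort("`true_precision` must be positive-definite")
  }
  if (is.null(resid_cov)) resid_cov <- diag(q)
  if (min(eigen(resid_cov, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    abort("`resid_cov` must be positive-definite")
  }
  if (is.null(planted_effects)) {
    planted_effects <- tibble(variant = rep(max(1, p %/% 2), 3),
                              trait = 1:3, effect = c(1.1, 1.3, 1.3))
  }
  planted_effects <- as_tibble(planted_effects)
  if (nrow(planted_effects) && max(planted_effects$variant) > p) {
    abort("planted variant index exceeds p")
  }
  if (is.null(planted_maf)) {
    planted_maf <- setNames(rep(0.0038, length(unique(planted_effects$variant))),
                            unique(planted_effects$variant))
  }
  if (is.null(covariate_effects)) {
    covariate_effects <- rbind(bmi = rep(0.3, q), sex = rep(0.4, q),
                               hypertension = rep(0.35, q))
  }
  if (is.null(mu)) mu <- rep(0, q)
  structure(list(
    n_both = n_both, n_pheno_only = n_pheno_only, n_geno_only = n_geno_only,
    q = q, p = p, traits = traits, maf_range = maf_range,
    rare_fraction = rare_fraction, rare_range = rare_range,
    true_graph = true_graph, true_precision = true_precision,
    resid_cov = resid_cov, planted_effects = planted_effects,
    planted_maf = planted_maf, effect_scale = effect_scale,
    covariate_effects = covariate_effects, mu = mu, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Cohort split for a simulation
#'
#' @param cfg A [sim_config()].
#' @return A [cohort_split()] with ids `g...` (genotype-only), `b...`
#'   (both), `p...` (phenotype-only).
#' @export
make_cohort_split <- function(cfg) {
  mk <- function(prefix, n) if (n > 0) sprintf("%s%04d", prefix, seq_len(n)) else character()
  cohort_split(geno_only = mk("g", cfg$n_geno_only),
               pheno_only = mk("p", cfg$n_pheno_only),
               both = mk("b", cfg$n_both))
}

#' Simulate genotypes
#'
#' Dosages are Binomial(2, MAF) draws, independent across variants. MAFs are
#' uniform on `maf_range` with a `rare_fraction` tail on `rare_range`;
#' planted variants get `planted_maf` and are resampled (up to 1000
#' attempts) until they have at least 4 carriers in the both-cohort, so
#' planted rare effects are estimable.
#'
#' @param cfg A [sim_config()].
#' @param split A [cohort_split()] (default [make_cohort_split()]`(cfg)`).
#' @return A [genotype_matrix()] over the genotyped samples (both cohort
#'   first, then genotype-only).
#' @export
simulate_genotypes <- function(cfg, split = make_cohort_split(cfg)) {
  set.seed(cfg$seed)
  ids <- c(split$both, split$geno_only)
  n <- length(ids)
  p <- cfg$p
  n_both <- length(split$both)
  mafs <- runif(p, cfg$maf_range[1], cfg$maf_range[2])
  rare <- runif(p) < cfg$rare_fraction
  mafs[rare] <- runif(sum(rare), cfg$rare_range[1], cfg$rare_range[2])
  pv <- as.integer(names(cfg$planted_maf))
  mafs[pv] <- cfg$planted_maf

  d <- matrix(rbinom(n * p, 2L, rep(mafs, each = n)), n, p)
  for (k in pv) {
    maf <- mafs[k]
    if (n_both > 0 && pbinom(3, 2 * n_both, maf) > 1 - 1e-4) {
      abort(sprintf(
        "planted variant %d (maf %.4g) cannot reach 4 carriers in n_both = %d; increase n or maf",
        k, maf, n_both))
    }
    attempts <- 0
    while (n_both > 0 && sum(d[seq_len(n_both), k] > 0) < 4) {
      d[, k] <- rbinom(n, 2L, maf)
      attempts <- attempts + 1
      if (attempts > 1000) {
        abort(sprintf("carrier guarantee failed for planted variant %d", k))
      }
    }
  }
  variants <- tibble(
    chrom = "1", pos = seq_len(p) * 100L, id = sprintf("var%05d", seq_len(p)),
    ref = "A", alt = "C", multiallelic = FALSE
  )
  genotype_matrix(d, variants, ids)
}

#' Simulate phenotypes and covariates
#'
#' Generative mirror of the fitted model: for each phenotyped sample,
#' traits = mu + covariate effects + planted genetic effects + a shared
#' random effect with precision `true_precision` + residual noise with
#' covariance `resid_cov`. Phenotype-only samples receive no genetic term
#' (their genotypes are unobserved). BMI is lognormal-like positive, sex and
#' hypertension are Bernoulli with female/male and with/without ratios near
#' 1.3 and 2.5.
#'
#' @param g A [genotype_matrix()] from [simulate_genotypes()] (rows must
#'   start with the both-cohort).
#' @param cfg A [sim_config()].
#' @param split A [cohort_split()].
#' @return A list: `phenotypes` (tibble: `sample_id`, traits, `bmi`, `sex`,
#'   `hypertension`, `cohort`) and `truth` (list of class `sim_truth`:
#'   planted effects realized on the standardized scale, graph, precision,
#'   random effects).
#' @export
simulate_phenotypes <- function(g, cfg, split = make_cohort_split(cfg)) {
  set.seed(cfg$seed + 1L)
  q <- cfg$q
  ids <- c(split$both, split$pheno_only)
  n <- length(ids)
  n_both <- length(split$both)
  if (n_both > 0 && !all(split$both %in% g$sample_ids)) {
    abort("genotypes must cover the both-cohort")
  }

  bmi <- exp(rnorm(n, log(27), 0.15))
  sex <- rbinom(n, 1, 0.565)          # ~1.3 female/male ratio
  hyp <- rbinom(n, 1, 0.715)          # ~2.5 with/without ratio
  cmat <- cbind(as.numeric(scale(bmi)), sex, hyp)

  sigma_u <- chol2inv(chol(cfg$true_precision))
  u <- matrix(rnorm(n * q), n, q) %*% chol(sigma_u)
  e <- matrix(rnorm(n * q), n, q) %*% chol(cfg$resid_cov)
  y <- rep(cfg$mu, each = n) + cmat %*% cfg$covariate_effects + u + e

  genet <- matrix(0, n, q)
  std_effects <- cfg$planted_effects
  std_effects$effect_std <- NA_real_
  if (n_both > 0 && nrow(cfg$planted_effects)) {
    rows <- match(split$both, g$sample_ids)
    for (r in seq_len(nrow(cfg$planted_effects))) {
      k <- cfg$planted_effects$variant[r]
      tr <- cfg$planted_effects$trait[r]
      eff <- cfg$planted_effects$effect[r]
      dk <- g$dosages[rows, k]
      sdk <- sd(dk)
      xk <- if (cfg$effect_scale == "standardized") {
        if (sdk == 0) abort("planted variant monomorphic in both-cohort")
        (dk - mean(dk)) / sdk
      } else dk
      genet[seq_len(n_both), tr] <- genet[seq_len(n_both), tr] + eff * xk
      std_effects$effect_std[r] <-
        if (cfg$effect_scale == "standardized") eff else eff * sdk
    }
  }
  y <- y + genet
  colnames(y) <- cfg$traits

  phenotypes <- dplyr::bind_cols(
    tibble(sample_id = ids),
    as_tibble(as.data.frame(y)),
    tibble(bmi = bmi, sex = sex, hypertension = hyp,
           cohort = rep(c("both", "pheno_only"), c(n_both, n - n_both)))
  )
  truth <- structure(list(
    planted = std_effects, graph = cfg$true_graph,
    precision = cfg$true_precision, resid_cov = cfg$resid_cov,
    u = u, covariate_effects = cfg$covariate_effects
  ), class = "sim_truth")
  list(phenotypes = phenotypes, truth = truth)
}

#' Simulate a full study
#'
#' Convenience wrapper: cohort split, genotypes, phenotypes, truth.
#'
#' @param cfg A [sim_config()].
#' @return A list: `split`, `genotypes`, `phenotypes`, `truth`.
#' @export
simulate_ibmt_data <- function(cfg) {
  split <- make_cohort_split(cfg)
  g <- simulate_genotypes(cfg, split)
  ph <- simulate_phenotypes(g, cfg, split)
  list(split = split, genotypes = g, phenotypes = ph$phenotypes,
       truth = ph$truth)
}
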