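#' Winsorize a numeric vector
#'
#' Clamps values below the empirical `lower_q` quantile and above the
#' `upper_q` quantile to those quantiles. Quantiles use the inverse
#' empirical CDF (type 1), which makes winsorization exactly idempotent at
#' fixed limits; the map is monotone and preserves length and order.
#'
#' @param x Finite numeric vector.
#' @param lower_q,upper_q Quantile limits, `0 <= lower_q < upper_q <= 1`.
#' @return The winsorized vector.
#' @export
winsorize <- function(x, lower_q = 0.005, upper_q = 0.995) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort("`x` must be finite numeric; handle missing values upstream")
  }
  if (!(lower_q >= 0 && lower_q < upper_q && upper_q <= 1)) {
    abort("need 0 <= lower_q < upper_q <= 1")
  }
  lims <- quantile(x, c(lower_q, upper_q), names = FALSE, type = 1)
  pmin(pmax(x, lims[1]), lims[2])
}

#' Normality-guided trait transformation
#'
#' Tests normality (Shapiro-Wilk); when normality is rejected at
#' `normality_alpha`, all values are positive (after an optional `shift`),
#' and the log transform improves the Shapiro-Wilk statistic, the natural log
#' is applied. The result is then standardized to mean 0, SD 1.
#'
#' @param x Finite numeric vector (winsorize first if desired).
#' @param normality_alpha Significance level for the normality test.
#' @param shift Optional constant added before the log for traits with
#'   non-positive values; recorded in the audit.
#' @return A list: `values` (transformed, standardized vector), `log_applied`
#'   (flag), `shapiro_p` (p-value on the raw scale), `shift`.
#' @export
normalize_trait <- function(x, normality_alpha = 0.05, shift = NULL) {
  if (!is.numeric(x) || any(!is.finite(x))) abort("`x` must be finite numeric")
  if (sd(x) == 0) abort("trait has zero variance")
  p_raw <- shapiro_p(x)
  log_applied <- FALSE
  y <- x
  if (p_raw < normality_alpha) {
    xs <- if (is.null(shift)) x else x + shift
    if (any(xs <= 0)) {
      if (is.null(shift)) {
        abort(paste0(
          "normality rejected but trait has non-positive values; ",
          "supply `shift` so that min(x + shift) > 0 to enable the log ",
          "transform"))
      }
      abort("`shift` too small: x + shift must be positive")
    }
    lx <- log(xs)
    if (shapiro_w(lx) > shapiro_w(x)) {
      y <- lx
      log_applied <- TRUE
    }
  }
  list(values = as.numeric(scale(y)), log_applied = log_applied,
       shapiro_p = p_raw, shift = if (log_applied) shift else NULL)
}

# Shapiro-Wilk on a deterministic thinning when n exceeds the test's limit
shapiro_stat <- function(x) {
  n <- length(x)
  if (n > 5000) x <- x[round(seq(1, n, length.out = 5000))]
  shapiro.test(x)
}
shapiro_p <- function(x) shapiro_stat(x)$p.value
shapiro_w <- function(x) unname(shapiro_stat(x)$statistic)

#' Preprocess a table of traits
#'
#' Applies [winsorize()] then [normalize_trait()] to each trait column and
#' returns the transformed table with a per-trait audit.
#'
#' @param data Data frame with a `sample_id` column and numeric trait columns.
#' @param traits Character vector of trait column names (default: all numeric
#'   columns except `sample_id`).
#' @param lower_q,upper_q Winsorization limits.
#' @param normality_alpha Passed to [normalize_trait()].
#' @param shifts Optional named numeric vector of per-trait log shifts.
#' @return A list of class `trait_prep`: `data` (tibble: `sample_id` +
#'   transformed traits) and `audit` (tibble: trait, winsor limits,
#'   `log_applied`, `shapiro_p`).
#' @export
preprocess_traits <- function(data, traits = NULL, lower_q = 0.005,
                              upper_q = 0.995, normality_alpha = 0.05,
                              shifts = NULL) {
  data <- as_tibble(data)
  if (is.null(traits)) {
    traits <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], "sample_id")
  }
  out <- data
  prep <- purrr::map(setNames(traits, traits), function(tr) {
    w <- winsorize(data[[tr]], lower_q, upper_q)
    normalize_trait(w, normality_alpha,
                    shift = if (!is.null(shifts)) shifts[[tr]] else NULL)
  })
  for (tr in traits) out[[tr]] <- prep[[tr]]$values
  audit <- purrr::map_dfr(traits, function(tr) {
    tibble(trait = tr, winsor_lower = lower_q, winsor_upper = upper_q,
           log_applied = prep[[tr]]$log_applied,
           shapiro_p = prep[[tr]]$shapiro_p)
  })
  structure(list(data = out, audit = audit), class = "trait_prep")
}

#' @export
tidy.trait_prep <- function(x, ...) x$audit

#' @export
print.trait_prep <- function(x, ...) {
  cat(sprintf("<trait_prep> %d samples, %d traits (%d log-transformed)\n",
              nrow(x$data), nrow(x$audit), sum(x$audit$log_applied)))
  invisible(x)
}

#' Screen candidate covariates on the phenotype-only cohort
#'
#' For each candidate covariate, fits a univariable regression of every trait
#' on the covariate and retains the covariate when its effect is significant
#' for at least a `majority` fraction of the traits. Run on samples that have
#' phenotypes but no genotypes, so that covariate selection never reuses the
#' association cohort.
#'
#' @param data Data frame holding trait and covariate columns.
#' @param traits Character vector of trait column names.
#' @param candidates Character vector of candidate covariate column names.
#' @param alpha Per-trait significance level (default 0.05).
#' @param majority Minimum fraction of traits with p < `alpha` (default 0.5).
#' @return A list of class `covariate_screen`: `selected` (character),
#'   `p_values` (tibble: covariate, trait, estimate, p.value), `alpha`,
#'   `majority`.
#' @export
screen_covariates <- function(data, traits, candidates, alpha = 0.05,
                              majority = 0.5) {
  data <- as_tibble(data)
  missing_cols <- setdiff(c(traits, candidates), names(data))
  if (length(missing_cols)) {
    abort(paste0("columns not found: ", paste(missing_cols, collapse = ", ")))
  }
  usable <- candidates[vapply(candidates, function(cv) {
    v <- var(data[[cv]])
    if (is.na(v) || v == 0) {
      warn(paste0("covariate '", cv, "' has zero variance; excluded"))
      FALSE
    } else TRUE
  }, TRUE)]

  pvals <- purrr::map_dfr(usable, function(cv) {
    purrr::map_dfr(traits, function(tr) {
      fit <- summary(lm(data[[tr]] ~ data[[cv]]))
      co <- fit$coefficients
      tibble(covariate = cv, trait = tr,
             estimate = co[2, 1], p.value = co[2, 4])
    })
  })
  selected <- if (nrow(pvals)) {
    hits <- dplyr::summarise(dplyr::group_by(pvals, .data$covariate),
                             frac = mean(.data$p.value < alpha))
    hits$covariate[hits$frac >= majority]
  } else character()
  structure(list(selected = selected, p_values = pvals, alpha = alpha,
                 majority = majority), class = "covariate_screen")
}

#' @export
tidy.covariate_screen <- function(x, ...) x$p_values

#' @export
print.covariate_screen <- function(x, ...) {
  cat("<covariate_screen> selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' Residualize traits on covariates and principal components
#'
#' Replaces each trait by its least-squares residual on an intercept, the
#' named covariate columns, and the supplied principal-component matrix.
#' Residuals are exactly orthogonal to every regressor.
#'
#' @param data Data frame with trait and covariate columns.
#' @param traits Character vector of trait column names.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param pcs Optional n x m numeric matrix of principal components.
#' @return Tibble: `sample_id` (if present in `data`) + residualized traits.
#' @export
adjust_traits <- function(data, traits, covariates = character(), pcs = NULL) {
  data <- as_tibble(data)
  n <- nrow(data)
  design <- cbind(`(Intercept)` = rep(1, n))
  if (length(covariates)) {
    design <- cbind(design, as.matrix(data[covariates]))
  }
  if (!is.null(pcs) && NCOL(pcs) > 0) {
    pcs <- as.matrix(pcs)
    if (is.null(colnames(pcs))) colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    design <- cbind(design, pcs)
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- setdiff(colnames(design), colnames(design)[qr_d$pivot[seq_len(qr_d$rank)]])
    abort(paste0("rank-deficient adjustment design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  y <- as.matrix(data[traits])
  res <- qr.resid(qr_d, y)
  out <- as_tibble(as.data.frame(res))
  names(out) <- traits
  if ("sample_id" %in% names(data)) {
    out <- dplyr::bind_cols(data["sample_id"], out)
  }
  out
}

#' Ratio of the two levels of a binary column
#'
#' Count ratio (second level over first) used to compare cohorts for
#' generalizability, e.g. female/male or hypertensive/normotensive ratios
#' between the phenotype-only and the genotype-plus-phenotype cohorts.
#'
#' @param data Data frame.
#' @param binary_col Name of a column with exactly two distinct values (or
#'   one, in which case the ratio is degenerate).
#' @return Ratio `n(level2) / n(level1)` with levels in sort order; `Inf`
#'   (with a warning) when the first level is absent.
#' @export
cohort_ratio <- function(data, binary_col) {
  x <- data[[binary_col]]
  if (is.null(x)) abort(paste0("no column '", binary_col, "'"))
  x <- x[!is.na(x)]
  lev <- sort(unique(x))
  if (length(lev) > 2) abort(paste0("'", binary_col, "' is not binary"))
  if (length(lev) == 1) {
    warn(paste0("'", binary_col, "' has a single level; ratio is infinite"))
    return(Inf)
  }
  sum(x == lev[2]) / sum(x == lev[1])
}

#' Cohort membership split
#'
#' Partition of sample ids into genotype-only, phenotype-only, and
#' genotype-plus-phenotype sets. The network is learned on `pheno_only`; the
#' association model runs on `both`; covariate screening uses `pheno_only`.
#'
#' @param geno_only,pheno_only,both Character vectors of sample ids; must be
#'   pairwise disjoint.
#' @return An object of class `cohort_split` (a named list of the three id
#'   vectors).
#' @export
cohort_split <- function(geno_only, pheno_only, both) {
  sets <- list(geno_only = as.character(geno_only),
               pheno_only = as.character(pheno_only),
               both = as.character(both))
  for (i in 1:2) for (j in (i + 1):3) {
    ov <- intersect(sets[[i]], sets[[j]])
    if (length(ov)) {
      abort(paste0("cohorts overlap (", names(sets)[i], "/", names(sets)[j],
                   "): ", paste(head(ov, 3), collapse = ", ")))
    }
  }
  structure(sets, class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> geno_only %d | pheno_only %d | both %d\n",
              length(x$geno_only), length(x$pheno_only), length(x$both)))
  invisible(x)
}
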