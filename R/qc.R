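#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test: conditional on the observed allele
#' counts, the p-value is the total probability of heterozygote counts whose
#' null probability does not exceed that of the observed count. Probabilities
#' are computed by the standard ratio recurrence over the heterozygote count.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative integers).
#' @return The exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) return(1)
  rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (rare == 0) return(1)

  probs <- numeric(rare + 1)  # probs[h + 1] = P(het = h)
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if ((mid %% 2L) != (rare %% 2L)) mid <- mid + 1L
  probs[mid + 1] <- 1
  hr_mid <- (rare - mid) / 2      # rare homozygotes at het = mid
  hc_mid <- n - mid - hr_mid      # common homozygotes

  h <- mid; hr <- hr_mid; hc <- hc_mid
  while (h >= 2) {
    probs[h - 1] <- probs[h + 1] * h * (h - 1) / (4 * (hr + 1) * (hc + 1))
    h <- h - 2; hr <- hr + 1; hc <- hc + 1
  }
  h <- mid; hr <- hr_mid; hc <- hc_mid
  while (h <= rare - 2 && hr > 0 && hc > 0) {
    probs[h + 3] <- probs[h + 1] * 4 * hr * hc / ((h + 1) * (h + 2))
    h <- h + 2; hr <- hr - 1; hc <- hc - 1
  }

  hs <- seq(rare %% 2L, rare, by = 2L)
  pr <- probs[hs + 1]
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, hs)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

#' Variant quality control
#'
#' Removes variants failing the standard sequencing-QC filters: multi-allelic
#' sites, per-variant missingness above `max_missing`, and exact
#' Hardy-Weinberg equilibrium p-value below `hwe_alpha`. The HWE test is run
#' on hard genotype calls, so variants with fractional (imputed) dosages are
#' exempt from it.
#'
#' @param g A [genotype_matrix()].
#' @param max_missing Maximum tolerated missing fraction (default 0.20:
#'   variants with missing rate above 20% are dropped).
#' @param hwe_alpha HWE exact-test significance threshold (default 5e-6).
#' @param drop_multiallelic Drop variants flagged multi-allelic?
#'
#' @return A list of class `ibmt_qc` with elements `genotypes` (the filtered
#'   [genotype_matrix()]) and `report` (tibble: `variant_id`, `reason`,
#'   `statistic`; one row per failed check).
#' @export
qc_filter_variants <- function(g, max_missing = 0.20, hwe_alpha = 5e-6,
                               drop_multiallelic = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (ncol(g$dosages) == 0) abort("empty genotype matrix")
  v <- g$variants
  reports <- list()

  fail_multi <- if (drop_multiallelic) v$multiallelic else rep(FALSE, nrow(v))
  if (any(fail_multi)) {
    reports$multi <- tibble(variant_id = v$id[fail_multi],
                            reason = "multiallelic", statistic = NA_real_)
  }
  miss <- v$missing_rate
  fail_miss <- miss > max_missing
  if (any(fail_miss)) {
    reports$miss <- tibble(
      variant_id = v$id[fail_miss],
      reason = sprintf("missingness %.4g > %.4g", miss[fail_miss], max_missing),
      statistic = miss[fail_miss]
    )
  }

  hwe_p <- vapply(seq_len(ncol(g$dosages)), function(k) {
    d <- g$dosages[, k]
    d <- d[!is.na(d)]
    if (length(d) == 0 || any(d != round(d))) return(NA_real_)
    hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2))
  }, numeric(1))
  fail_hwe <- !is.na(hwe_p) & hwe_p < hwe_alpha
  if (any(fail_hwe)) {
    reports$hwe <- tibble(
      variant_id = v$id[fail_hwe],
      reason = sprintf("hwe p %.3g < %.3g", hwe_p[fail_hwe], hwe_alpha),
      statistic = hwe_p[fail_hwe]
    )
  }

  keep <- !(fail_multi | fail_miss | fail_hwe)
  report <- if (length(reports)) bind_rows(reports) else
    tibble(variant_id = character(), reason = character(),
           statistic = numeric())
  if (!any(keep)) {
    warn("all variants removed by QC")
  }
  out <- subset_variants(g, keep)
  structure(list(genotypes = out, report = report), class = "ibmt_qc")
}

#' @export
print.ibmt_qc <- function(x, ...) {
  cat(sprintf("<ibmt_qc> %d variants retained, %d removal records\n",
              ncol(x$genotypes$dosages), nrow(x$report)))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param qc An `ibmt_qc` object from [qc_filter_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  utils::write.table(qc$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

subset_variants <- function(g, keep) {
  gm <- g
  gm$dosages <- g$dosages[, keep, drop = FALSE]
  gm$variants <- g$variants[keep, , drop = FALSE]
  gm
}

#' Mean-dosage imputation of missing genotypes
#'
#' Replaces missing dosages by the per-variant mean of the observed dosages
#' (the expected dosage under the estimated allele frequency). Run after
#' [qc_filter_variants()], before modelling.
#'
#' @param g A [genotype_matrix()].
#' @return A [genotype_matrix()] with no missing dosages (columns that are
#'   entirely missing are left untouched).
#' @export
impute_dosages <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  for (k in seq_len(ncol(d))) {
    nas <- is.na(d[, k])
    if (any(nas) && !all(nas)) d[nas, k] <- mean(d[, k], na.rm = TRUE)
  }
  g$dosages <- d
  g
}

#' Standardize dosages to mean zero, unit variance
#'
#' @param g A [genotype_matrix()] without missing values (impute first).
#' @return List with `x` (n x p standardized matrix), `keep` (logical vector:
#'   FALSE for monomorphic columns, which are dropped from `x`).
#' @keywords internal
standardize_dosages <- function(g) {
  d <- g$dosages
  if (anyNA(d)) abort("missing dosages: run impute_dosages() first")
  sds <- apply(d, 2, sd)
  keep <- sds > 0
  x <- scale(d[, keep, drop = FALSE])
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  list(x = x, keep = keep, sd = sds)
}
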