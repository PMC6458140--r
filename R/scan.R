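#' Sliding windows over ordered variants
#'
#' Windows of `size` variants advancing by `step`, restarting on each
#' chromosome (windows never span chromosomes). Starts are 0, `step`,
#' 2`step`, ... and the final window ends at the last variant, so every
#' variant is covered; with the defaults (size 100, step 25) every interior
#' variant falls in exactly 4 windows.
#'
#' @param p Number of variants (when `chrom` is `NULL`) .
#' @param size Window width in variants (default 100).
#' @param step Step between window starts (default 25; must be `<= size`).
#' @param chrom Optional character vector of per-variant chromosomes, in
#'   genomic order; windows are built per chromosome over global indices.
#' @return Tibble of class `ibmt_windows`: `index`, `chrom`, `start`, `end`
#'   (0-based, half-open global variant indices).
#' @export
make_windows <- function(p, size = 100, step = 25, chrom = NULL) {
  if (p < 1) abort("need p >= 1")
  if (step < 1 || step > size) abort("need 1 <= step <= size (coverage gaps)")
  if (is.null(chrom)) chrom <- rep("1", p)
  if (length(chrom) != p) abort("`chrom` must have length p")
  if (is.unsorted(match(chrom, unique(chrom)))) {
    abort("variants must be grouped by chromosome")
  }
  offs <- unname(c(0, cumsum(table(factor(chrom, levels = unique(chrom))))))
  wins <- purrr::map_dfr(seq_along(unique(chrom)), function(ci) {
    pc <- offs[ci + 1] - offs[ci]
    last_start <- max(0, step * ceiling((pc - size) / step))
    starts <- seq(0, last_start, by = step)
    tibble(chrom = unique(chrom)[ci],
           start = offs[ci] + starts,
           end = offs[ci] + pmin(starts + size, pc))
  })
  wins$index <- seq_len(nrow(wins))
  structure(wins[, c("index", "chrom", "start", "end")],
            class = c("ibmt_windows", class(tibble())))
}

#' Windows containing a variant
#'
#' @param variant_index 0-based variant index.
#' @param windows Window table from [make_windows()].
#' @return The subset of `windows` whose half-open `[start, end)` slice
#'   contains `variant_index`.
#' @export
windows_containing <- function(variant_index, windows) {
  if (variant_index < 0 || variant_index >= max(windows$end)) {
    abort("variant index out of range")
  }
  windows[windows$start <= variant_index & windows$end > variant_index, ,
          drop = FALSE]
}

#' Exome-wide sliding-window IBMT scan
#'
#' Runs the Gibbs sampler window by window over QC'd genotypes and adjusted
#' traits, selecting variant-trait effects whose credible intervals exclude
#' zero, and reports a variant only when it is selected in *every* window
#' containing it (edge variants fall in fewer windows; the all-windows rule
#' applies to however many contain them). A trait appears in the report only
#' if that same trait is selected in all containing windows; pooled
#' estimates are the arithmetic means of the per-window posterior means and
#' SDs. Monomorphic variants are dropped (their standardization is
#' undefined) and listed in the result.
#'
#' The chain for window w is seeded with `spec$seed + w`, so the scan is
#' reproducible and independent of window processing order.
#'
#' @param g A QC'd, imputed [genotype_matrix()] with samples restricted to
#'   the genotype-plus-phenotype cohort.
#' @param y_adj n x q matrix of adjusted traits, rows aligned with `g`.
#' @param pattern Trait precision pattern from [precision_pattern()].
#' @param spec A [model_spec()] (its `pattern` field is overridden by
#'   `pattern`).
#' @param size,step Window geometry (defaults 100 and 25).
#' @return An object of class `ibmt_scan`: `windows`, `per_window`
#'   (selections per window), `reported` (pooled per variant-trait rows),
#'   `dropped` (monomorphic variant ids), `spec`.
#' @export
ibmt_scan <- function(g, y_adj, pattern = NULL, spec = model_spec(),
                      size = 100, step = 25) {
  stopifnot(inherits(g, "genotype_matrix"))
  y_adj <- as.matrix(y_adj)
  if (nrow(y_adj) != nrow(g$dosages)) abort("trait rows must match samples")
  std <- standardize_dosages(g)
  dropped <- g$variants$id[!std$keep]
  gk <- subset_variants(g, std$keep)
  p <- ncol(std$x)
  if (p == 0) abort("no polymorphic variants to scan")

  windows <- make_windows(p, size = size, step = step,
                          chrom = gk$variants$chrom)
  spec$pattern <- pattern
  base_seed <- spec$seed %||% 0L

  per_window <- purrr::map_dfr(seq_len(nrow(windows)), function(w) {
    idx <- (windows$start[w] + 1):windows$end[w]
    wspec <- spec
    wspec$seed <- base_seed + w
    dat <- multi_trait_data(y_adj, std$x[, idx, drop = FALSE])
    colnames(dat$x) <- gk$variants$id[idx]
    fit <- run_chain(dat, wspec)
    sel <- select_effects(fit)
    if (nrow(sel) == 0) return(tibble())
    dplyr::mutate(sel, window = windows$index[w],
                  converged = fit$converged)
  })

  reported <- aggregate_selections(per_window, windows, gk)
  structure(list(windows = windows, per_window = per_window,
                 reported = reported, dropped = dropped,
                 variants = gk$variants, spec = spec),
            class = "ibmt_scan")
}

aggregate_selections <- function(per_window, windows, gk) {
  empty <- tibble(variant = character(), trait = character(),
                  est_eff = numeric(), sd_eff = numeric(),
                  n_windows_containing = integer(),
                  n_windows_selected = integer())
  if (NROW(per_window) == 0 || nrow(per_window) == 0) return(empty)
  n_contain <- vapply(unname(per_window$variant), function(v) {
    k <- match(v, gk$variants$id) - 1L
    nrow(windows_containing(k, windows))
  }, integer(1), USE.NAMES = FALSE)
  per_window$n_contain <- n_contain
  agg <- per_window |>
    dplyr::group_by(.data$variant, .data$trait) |>
    dplyr::summarise(
      est_eff = mean(.data$estimate), sd_eff = mean(.data$std.error),
      n_windows_containing = .data$n_contain[1],
      n_windows_selected = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_windows_selected == .data$n_windows_containing)
  if (nrow(agg) == 0) return(empty)
  dplyr::arrange(agg, match(.data$variant, gk$variants$id), .data$trait)
}

#' @export
print.ibmt_scan <- function(x, ...) {
  cat(sprintf("<ibmt_scan> %d windows, %d reported variant-trait pairs\n",
              nrow(x$windows), nrow(x$reported)))
  invisible(x)
}

#' @export
tidy.ibmt_scan <- function(x, ...) x$reported

#' Final per-variant report table
#'
#' One row per reported (variant, trait) pair with variant metadata, MAF in
#' percent, pooled posterior-mean effect and SD, and window bookkeeping. A
#' variant spanning several trait rows indicates pleiotropy.
#'
#' @param result An `ibmt_scan` from [ibmt_scan()].
#' @param variant_meta Optional variant tibble (defaults to the scan's own
#'   variant table).
#' @return A tibble: `id`, `chrom`, `pos`, `maf_pct`, `trait`, `est_eff`,
#'   `sd_eff`, `n_windows_containing`, `n_windows_selected`.
#' @export
aggregate_report <- function(result, variant_meta = NULL) {
  v <- variant_meta %||% result$variants
  rep_tab <- result$reported
  if (nrow(rep_tab) == 0) {
    return(tibble(id = character(), chrom = character(), pos = integer(),
                  maf_pct = numeric(), trait = character(),
                  est_eff = numeric(), sd_eff = numeric(),
                  n_windows_containing = integer(),
                  n_windows_selected = integer()))
  }
  meta <- tibble(id = v$id, chrom = as.character(v$chrom), pos = v$pos,
                 maf_pct = 100 * v$maf)
  out <- dplyr::left_join(rep_tab, meta, by = c(variant = "id"))
  tibble(id = out$variant, chrom = out$chrom, pos = out$pos,
         maf_pct = out$maf_pct, trait = out$trait, est_eff = out$est_eff,
         sd_eff = out$sd_eff,
         n_windows_containing = out$n_windows_containing,
         n_windows_selected = out$n_windows_selected)
}

#' Plot pooled effects from a scan
#'
#' Reported variant-trait effects with +/- 2 pooled-SD bars, faceted by
#' trait.
#'
#' @param object An `ibmt_scan`.
#' @param ... Unused.
#' @return A \pkg{ggplot2} object.
#' @export
autoplot.ibmt_scan <- function(object, ...) {
  rep_tab <- object$reported
  if (nrow(rep_tab) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no reported variants") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(rep_tab, ggplot2::aes(x = .data$variant, y = .data$est_eff)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$est_eff - 2 * .data$sd_eff,
      ymax = .data$est_eff + 2 * .data$sd_eff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = NULL, y = "pooled posterior-mean effect (SD units)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
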