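#' Genotype dosage matrix
#'
#' Container for biallelic genotype dosages (counts of the minor/alternate
#' allele in 0/1/2, `NA` for missing) together with per-variant metadata.
#' Built by [read_genotypes()] or [simulate_genotypes()].
#'
#' Minor-allele frequency is computed from non-missing dosages only. When the
#' counted allele has frequency above 0.5 the dosages are flipped
#' (`d -> 2 - d`), REF/ALT labels are swapped, and the flip is recorded in the
#' `flipped` column so that `maf <= 0.5` always holds.
#'
#' @param dosages Numeric n x p matrix with entries in \{0, 1, 2, NA\}.
#' @param variants Data frame with one row per variant: columns `chrom`,
#'   `pos`, `id`, `ref`, `alt`, and optionally `multiallelic`.
#' @param sample_ids Character vector of n unique sample identifiers.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants` (tibble incl. `maf`, `missing_rate`, `flipped`)
#'   and `sample_ids`.
#' @export
genotype_matrix <- function(dosages, variants, sample_ids) {
  dosages <- as.matrix(dosages)
  variants <- as_tibble(variants)
  if (nrow(variants) != ncol(dosages)) {
    abort("`variants` must have one row per dosage column.")
  }
  if (length(sample_ids) != nrow(dosages)) {
    abort("`sample_ids` must have one entry per dosage row.")
  }
  if (anyDuplicated(sample_ids)) abort("duplicate sample ids")
  if (!all(is.na(dosages) | (dosages %in% c(0, 1, 2) | dosages >= 0))) {
    abort("dosages must be in [0, 2] or NA")
  }
  if (!"multiallelic" %in% names(variants)) variants$multiallelic <- FALSE
  key <- paste(variants$chrom, variants$pos, variants$alt, sep = ":")
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (chrom, pos, alt) records: ",
                 paste(unique(key[duplicated(key)]), collapse = ", ")))
  }

  n_obs <- colSums(!is.na(dosages))
  af <- ifelse(n_obs > 0, colSums(dosages, na.rm = TRUE) / (2 * n_obs), NA_real_)
  flip <- !is.na(af) & af > 0.5
  if (any(flip)) {
    dosages[, flip] <- 2 - dosages[, flip]
    tmp <- variants$ref[flip]
    variants$ref[flip] <- variants$alt[flip]
    variants$alt[flip] <- tmp
    af[flip] <- 1 - af[flip]
  }
  variants$maf <- af
  variants$missing_rate <- 1 - n_obs / nrow(dosages)
  variants$flipped <- flip

  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  structure(
    list(dosages = dosages, variants = variants,
         sample_ids = as.character(sample_ids)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  MAF range: %.4g-%.4g; missing overall: %.2f%%\n",
              min(x$variants$maf, na.rm = TRUE),
              max(x$variants$maf, na.rm = TRUE),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' @rdname genotype_matrix
#' @param x A `genotype_matrix`.
#' @param ... Unused.
#' @export
tidy.genotype_matrix <- function(x, ...) x$variants

#' Read genotypes from VCF or PLINK files
#'
#' Reads biallelic genotype calls into a [genotype_matrix()]. VCF files are
#' parsed with \pkg{vcfR}; PLINK binary filesets (`.bed`/`.bim`/`.fam`) are
#' decoded directly. Multi-allelic VCF records are loaded but flagged in the
#' variant table (the first ALT allele is counted); [qc_filter_variants()]
#' removes them by default.
#'
#' @param path Path to a `.vcf`/`.vcf.gz` file, or a PLINK prefix (or any of
#'   the three PLINK member files).
#' @param format `"auto"` (from the extension), `"vcf"`, or `"plink"`.
#'
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "plink")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "plink"
  }
  switch(format,
         vcf = read_genotypes_vcf(path),
         plink = read_genotypes_plink(path))
}

read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  # validate the header up front (malformed input must not reach the C parser)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  head_lines <- readLines(con, n = 500L)
  close(con)
  chrom_line <- grep("^#CHROM\t", head_lines)
  if (!length(grep("^##fileformat=VCF", head_lines)) || !length(chrom_line)) {
    abort(paste0("failed to parse VCF '", path,
                 "': missing ##fileformat or #CHROM header line"))
  }
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse VCF '", path, "': ",
                                     conditionMessage(e)))
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort(paste0("no variants in VCF: ", path))
  gtm <- v@gt
  if (is.null(gtm) || ncol(gtm) == 0) {
    abort(paste0("VCF has no genotype columns: ", path))
  }
  if (colnames(gtm)[1] == "FORMAT") {
    fmt <- gtm[, 1]
    gtm <- gtm[, -1, drop = FALSE]
  } else {
    fmt <- rep("GT", nrow(gtm))
  }
  gt_pos <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) match("GT", f), 1L)
  if (anyNA(gt_pos)) abort(paste0("VCF record lacks a GT field: ", path))
  gt <- gtm
  for (i in seq_len(nrow(gtm))) {
    gt[i, ] <- vapply(strsplit(gtm[i, ], ":", fixed = TRUE),
                      `[`, "", gt_pos[i])
  }

  multi <- grepl(",", fix$ALT %||% "")
  alt1 <- vapply(strsplit(fix$ALT, ",", fixed = TRUE), `[`, "", 1L)
  # count non-reference alleles per call; "." or ./. is missing
  count_alt <- function(calls) {
    alleles <- strsplit(calls, "[/|]")
    vapply(alleles, function(a) {
      if (length(a) == 0 || anyNA(a) || any(a == "." | a == "")) {
        return(NA_real_)
      }
      sum(a != "0")
    }, numeric(1))
  }
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt))
  for (i in seq_len(nrow(gt))) dos[i, ] <- count_alt(gt[i, ])
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS, ":", fix$REF, ":", alt1)[is.na(ids) | ids == "."]
  variants <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS), id = ids,
    ref = fix$REF, alt = alt1, multiallelic = multi
  )
  genotype_matrix(t(dos), variants, colnames(gt))
}

read_genotypes_plink <- function(path) {
  prefix <- sub("\\.(bed|bim|fam)$", "", path)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) abort(paste0("PLINK member file not found: ", f))
  }
  bim_df <- utils::read.table(bim, stringsAsFactors = FALSE,
                              col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam_df <- utils::read.table(fam, stringsAsFactors = FALSE)
  n <- nrow(fam_df)
  p <- nrow(bim_df)
  if (p == 0) abort(paste0("no variants in ", bim))

  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort(paste0("not a PLINK .bed file (bad magic): ", bed))
  }
  if (raw[3] != as.raw(0x01)) abort("only SNP-major .bed files are supported")
  bpv <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpv * p) {
    abort(sprintf("truncated .bed: expected %d data bytes, found %d",
                  bpv * p, length(body)))
  }
  # 2-bit codes, sample-fastest within byte: 00 hom A1, 01 missing, 10 het, 11 hom A2
  code_map <- c(`0` = 2, `1` = NA_real_, `2` = 1, `3` = 0)
  byte_int <- as.integer(body)
  codes <- cbind(byte_int %% 4L, (byte_int %/% 4L) %% 4L,
                 (byte_int %/% 16L) %% 4L, (byte_int %/% 64L) %% 4L)
  dos_a1 <- matrix(code_map[as.character(t(codes))], nrow = 4L * bpv)[1:n, , drop = FALSE]
  dim(dos_a1) <- c(n, p)

  variants <- tibble(
    chrom = as.character(bim_df$chrom), pos = as.integer(bim_df$pos),
    id = as.character(bim_df$id), ref = bim_df$a2, alt = bim_df$a1,
    multiallelic = FALSE
  )
  genotype_matrix(dos_a1, variants, as.character(fam_df[[2]]))
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits an uncompressed VCF v4.2 with GT calls reconstructed from dosages
#' (heterozygote phase is arbitrary; missing dosages become `./.`). Intended
#' for exporting simulated fixtures, not round-tripping arbitrary VCFs.
#'
#' @param g A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$variants
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "FORMAT",
            g$sample_ids), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(k) {
    d <- g$dosages[, k]
    calls <- ifelse(is.na(d), "./.", gt_str[as.character(d)])
    paste(c(v$chrom[k], v$pos[k], v$id[k], v$ref[k], v$alt[k], ".", "PASS",
            "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
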