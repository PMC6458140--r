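# Tiny genotype fixtures written at test time (no binary files in the repo).

demo_vcf_lines <- function(gt1 = c("0/0", "0/1", "1/1"),
                           gt2 = c("0/1", "0/0", "0/0")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "FORMAT",
            "s1", "s2", "s3"), collapse = "\t"),
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", "GT", gt1),
          collapse = "\t"),
    paste(c("1", "200", "rs2", "C", "T", ".", "PASS", "GT", gt2),
          collapse = "\t"))
}

write_demo_vcf <- function(path, ...) {
  writeLines(demo_vcf_lines(...), path)
  path
}

# PLINK bed/bim/fam writer (SNP-major), independent of the package reader.
# dosages: n x p matrix of alt-allele counts (NA = missing); alt = bim A1.
write_demo_plink <- function(prefix, dosages, chrom, pos, ids, ref, alt,
                             sample_ids) {
  n <- nrow(dosages)
  p <- ncol(dosages)
  write(t(cbind(chrom, ids, 0, pos, alt, ref)), paste0(prefix, ".bim"),
        ncolumns = 6, sep = "\t")
  write(t(cbind(sample_ids, sample_ids, 0, 0, 0, -9)),
        paste0(prefix, ".fam"), ncolumns = 6, sep = " ")
  code_of <- function(d) {
    if (is.na(d)) 1L else if (d == 2) 0L else if (d == 1) 2L else 3L
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (k in seq_len(p)) {
    codes <- vapply(dosages[, k], code_of, integer(1))
    pad <- c(codes, rep(0L, (4 - n %% 4) %% 4))
    bytes <- vapply(seq_len(length(pad) / 4), function(b) {
      i <- (b - 1) * 4
      pad[i + 1] + pad[i + 2] * 4L + pad[i + 3] * 16L + pad[i + 4] * 64L
    }, numeric(1))
    writeBin(as.raw(bytes), con)
  }
  prefix
}

# Chain-precision multi-trait data with an optional planted effect on the
# standardized dosage scale; the generative mirror of the fitted model.
make_chain_data <- function(n, q = 3, p = 10, effect = 0, variant = 3,
                            trait = 1, maf = 0.3, seed = 1) {
  set.seed(seed)
  lam0 <- chain_precision(q)
  x <- matrix(rbinom(n * p, 2, maf), n, p)
  x <- scale(x)
  u <- rmvn_prec(n, lam0)
  y <- u + matrix(rnorm(n * q), n, q)
  if (effect != 0) y[, trait] <- y[, trait] + effect * x[, variant]
  list(data = multi_trait_data(y, x), lam0 = lam0, pattern = lam0 != 0)
}
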