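# Independent oracles used across tests. These deliberately take different
# computational routes than the package implementations.

# HWE exact p-value by direct log-factorial enumeration of all heterozygote
# counts compatible with the observed allele counts.
hwe_brute_force <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab  # allele A count
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  logp <- vapply(hets, function(h) {
    a <- (na - h) / 2
    b <- n - h - a
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
      h * log(2) +
      lfactorial(na) + lfactorial(2 * n - na) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  sum(pr[pr <= obs * (1 + 1e-10)])
}

# Partial correlation via explicit residual regression: correlate the
# residuals of i and j after regressing each on all remaining columns.
pcor_residual_oracle <- function(m, i, j) {
  others <- setdiff(seq_len(ncol(m)), c(i, j))
  if (length(others) == 0) return(cor(m[, i], m[, j]))
  ri <- lm.fit(cbind(1, m[, others, drop = FALSE]), m[, i])$residuals
  rj <- lm.fit(cbind(1, m[, others, drop = FALSE]), m[, j])$residuals
  cor(ri, rj)
}

# Hamming distance by brute force over all unordered node pairs.
hamming_brute_force <- function(g1, g2) {
  nodes <- g1$nodes
  has_edge <- function(g, a, b) {
    any((g$edges$trait_a == a & g$edges$trait_b == b) |
          (g$edges$trait_a == b & g$edges$trait_b == a))
  }
  d <- 0
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i < j) {
        d <- d + (has_edge(g1, nodes[i], nodes[j]) !=
                    has_edge(g2, nodes[i], nodes[j]))
      }
    }
  }
  d
}

# Random graph on q named nodes with edge probability pr.
random_graph <- function(q, pr = 0.4) {
  nodes <- paste0("t", seq_len(q))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < pr
  trait_graph(nodes, pairs[keep, , drop = FALSE])
}

# Multivariate normal rows with a given precision matrix.
rmvn_prec <- function(n, prec) {
  q <- ncol(prec)
  matrix(stats::rnorm(n * q), n, q) %*% chol(chol2inv(chol(prec)))
}
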