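# Shared fixture builders and independent oracles. Oracles re-derive expected
# values by a different route than the implementation under test.

# Quick aligned sumstats builder from a Z vector.
mk_ss <- function(z, n = 10000, ids = sprintf("v%04d", seq_along(z)),
                  pos = seq_along(z), chrom = "1",
                  ea = "A", oa = "G", trait_name = "trait",
                  trait_type = "quantitative") {
  as_sumstats(
    tibble::tibble(
      variant_id = ids, chrom = chrom, pos = pos,
      effect_allele = ea, other_allele = oa,
      beta = z / sqrt(n), se = 1 / sqrt(n), z = z,
      pvalue = 2 * stats::pnorm(-abs(z)), n = n
    ),
    trait_name = trait_name, trait_type = trait_type
  )
}

# Random valid correlation matrix of dimension k (unit diagonal, PSD).
random_corr <- function(k, jitter = 0.5) {
  A <- matrix(stats::rnorm(k * k), k)
  S <- tcrossprod(A) + diag(jitter, k)
  stats::cov2cor(S)
}

# Brute-force re-execution of the sorted-greedy pruning definition:
# visit variants in ascending (p, chrom, pos, id) order and keep a variant
# iff its r^2 with every kept variant is <= cut (0 across blocks).
oracle_prune <- function(df, ld, cut) {
  ord <- order(df$pvalue, df$chrom, df$pos, df$variant_id)
  kept <- character(0)
  for (i in ord) {
    ok <- TRUE
    for (kid in kept) {
      k_row <- which(df$variant_id == kid)
      if (df$block_id[i] == df$block_id[k_row]) {
        R <- ld[[df$block_id[i]]]
        if (R[df$variant_id[i], kid]^2 > cut) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) kept <- c(kept, df$variant_id[i])
  }
  kept
}

# Brute-force colocalisation posteriors by configuration enumeration in
# linear space, with per-SNP ABFs computed from normal density ratios
# (independent of the closed-form log-ABF used by the package).
oracle_coloc_pp <- function(z1, se1, z2, se2, pr) {
  k <- length(z1)
  abf1 <- stats::dnorm(z1, 0, sqrt(1 + pr$W1 / se1^2)) / stats::dnorm(z1, 0, 1)
  abf2 <- stats::dnorm(z2, 0, sqrt(1 + pr$W2 / se2^2)) / stats::dnorm(z2, 0, 1)
  L <- c(h0 = 1, h1 = 0, h2 = 0, h3 = 0, h4 = 0)
  for (j in seq_len(k)) {
    L["h1"] <- L["h1"] + pr$p1 * abf1[j]
    L["h2"] <- L["h2"] + pr$p2 * abf2[j]
    L["h3"] <- L["h3"] + pr$p12 * abf1[j] * abf2[j]
  }
  for (j in seq_len(k)) {
    for (l in seq_len(k)) {
      if (j != l) L["h4"] <- L["h4"] + pr$p1 * pr$p2 * abf1[j] * abf2[l]
    }
  }
  L / sum(L)
}

# Draw n rows from N(0, R).
rmvn <- function(n, R) {
  matrix(stats::rnorm(n * nrow(R)), n) %*% chol(R)
}
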