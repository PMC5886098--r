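# Internal numeric helpers shared across modules.

# log(sum(exp(x))) without overflow; -Inf for an empty or all -Inf input.
logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log(exp(x) - exp(y)) for x >= y; returns -Inf when the difference underflows
# (or when rounding makes y >= x).
logdiffexp <- function(x, y) {
  if (!is.finite(x) && x == -Inf) return(-Inf)
  if (y >= x) return(-Inf)
  d <- -expm1(y - x)
  x + log(d)
}

# AR(1) correlation matrix: r_ij = rho^|i-j|. rho = 0 gives the identity.
ar1_corr <- function(k, rho) {
  stopifnot(k >= 1, abs(rho) < 1)
  rho^abs(outer(seq_len(k), seq_len(k), "-"))
}

# Symmetric PSD square root via eigendecomposition (negative eigenvalues
# clamped to zero, so a numerically semi-definite input is accepted).
sym_sqrt <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

# Nearest positive-definite repair for a correlation matrix: floor the
# eigenvalues and rescale back to unit diagonal. attr(out, "repaired") records
# whether anything was changed.
near_pd <- function(R, eig_floor = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eig_floor) {
    attr(R, "repaired") <- FALSE
    return(R)
  }
  v <- pmax(e$values, eig_floor)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  dimnames(out) <- dimnames(R)
  attr(out, "repaired") <- TRUE
  out
}

#' Effective sample size of a case-control study
#'
#' For a binary trait the effective sample size \code{4 / (1/n_cases +
#' 1/n_controls)} puts case-control Z-scores on the same footing as a
#' quantitative trait of that size.
#'
#' @param n_cases,n_controls Case and control counts.
#' @return Effective sample size (numeric).
#' @export
#' @examples
#' effective_n(7410, 11009)
effective_n <- function(n_cases, n_controls) {
  stopifnot(n_cases > 0, n_controls > 0)
  4 / (1 / n_cases + 1 / n_controls)
}

# Deterministic derived seed kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) %% 2147483647) * 7919 + offset) %% 2147483647L
}

# Cheap structural signature of an LD matrix, used to cache square roots
# across identical blocks (dimension, entry sum, first off-diagonal).
ld_sig <- function(R) {
  k <- nrow(R)
  paste(k, signif(sum(R), 12),
        if (k > 1) signif(R[1, 2], 12) else 0, sep = "_")
}

ALLELE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_alleles <- function(x) chartr("ACGT", "TGCA", x)

two_sided_p <- function(z) 2 * pnorm(-abs(z))
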