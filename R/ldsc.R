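# LD score regression: SNP heritability, cross-trait genetic covariance and
# correlation, and sample-overlap intercepts, with block-jackknife standard
# errors.
#
# Model: E[chi2_j]   = 1 + n * h2 * l_j / m                    (univariate)
#        E[z1_j z2_j] = c + sqrt(n1 n2) * gcov * l_j / m       (bivariate)
# where l_j is the LD score. The free intercepts absorb confounding (1 + a)
# and sample overlap (c) respectively.

# Weighted least squares of y on x with intercept, via sufficient sums.
wls_sums <- function(x, y, w) {
  c(sw = sum(w), swx = sum(w * x), swy = sum(w * y),
    swxx = sum(w * x * x), swxy = sum(w * x * y))
}

wls_coef_from_sums <- function(s) {
  # s: vector or matrix with columns sw, swx, swy, swxx, swxy
  if (is.null(dim(s))) s <- matrix(s, nrow = 1, dimnames = list(NULL, names(s)))
  d <- s[, "sw"] * s[, "swxx"] - s[, "swx"]^2
  slope <- (s[, "sw"] * s[, "swxy"] - s[, "swx"] * s[, "swy"]) / d
  intercept <- (s[, "swxx"] * s[, "swy"] - s[, "swx"] * s[, "swxy"]) / d
  cbind(intercept = intercept, slope = slope)
}

# Full-sample fit plus delete-one-block fits for fixed weights.
wls_jackknife <- function(x, y, w, grp) {
  M <- rowsum(cbind(w, w * x, w * y, w * x * x, w * x * y), grp)
  colnames(M) <- c("sw", "swx", "swy", "swxx", "swxy")
  tot <- colSums(M)
  full <- wls_coef_from_sums(tot)
  loo <- wls_coef_from_sums(matrix(tot, nrow(M), 5, byrow = TRUE,
                                   dimnames = list(NULL, colnames(M))) - M)
  list(full = full[1, ], loo = loo, n_blocks = nrow(M))
}

jackknife_se <- function(theta) {
  theta <- theta[is.finite(theta)]
  b <- length(theta)
  if (b < 2) return(NA_real_)
  sqrt((b - 1) / b * sum((theta - mean(theta))^2))
}

ldsc_prepare <- function(s, ld_sc) {
  df <- dplyr::inner_join(
    tibble::as_tibble(s), ld_sc, by = "variant_id"
  )
  # Standard hygiene filters, applied only when the fields are populated
  # (synthetic data carries neither).
  if (any(!is.na(df$info))) df <- df[is.na(df$info) | df$info > 0.9, ]
  if (any(!is.na(df$eaf))) {
    df <- df[is.na(df$eaf) | (df$eaf > 0.01 & df$eaf < 0.99), ]
  }
  dplyr::arrange(df, .data$chrom, .data$pos)
}

univariate_weights <- function(l, n, h2, m) {
  h2 <- min(max(h2, 0), 1)
  1 / (2 * (1 + n * h2 * l / m)^2)
}

#' Univariate LD score regression
#'
#' Regresses per-SNP chi-square statistics on LD scores by weighted least
#' squares: the slope estimates `n * h2 / m` and the free intercept absorbs
#' confounding and overcounting. Heteroskedasticity weights
#' `1 / (2 (1 + n h2 l/m)^2)` are iterated twice from an OLS start; standard
#' errors come from a delete-one block jackknife over `n_blocks` contiguous
#' SNP blocks (weights held fixed at the final fit).
#'
#' @param s A `sumstats` tibble with `z` and `n`.
#' @param ld_sc LD-score tibble from [ld_scores()].
#' @param m Number of SNPs the heritability refers to; defaults to the number
#'   of regression SNPs.
#' @param n_blocks Jackknife blocks (default 200, standard practice).
#' @return An `ldsc_h2` object: `h2`, `h2_se`, `intercept`, `intercept_se`,
#'   `n_snps`, `m`, `n`, `n_blocks`.
#' @export
univariate_ldsc <- function(s, ld_sc, m = NULL, n_blocks = 200) {
  df <- ldsc_prepare(s, ld_sc)
  if (nrow(df) < 200) stop("need at least 200 SNPs with LD scores")
  if (nrow(df) < n_blocks) stop("fewer SNPs than jackknife blocks")
  if (anyNA(df$n) || any(df$n <= 0)) stop("non-positive or missing n")
  m <- m %||% nrow(df)
  n <- mean(df$n)
  x <- df$l
  y <- df$z^2

  w <- rep(1, nrow(df))
  for (it in 1:3) {
    fit <- wls_coef_from_sums(wls_sums(x, y, w))
    h2 <- fit[1, "slope"] * m / n
    if (it < 3) w <- univariate_weights(x, n, h2, m)
  }

  grp <- as.integer(cut(seq_len(nrow(df)), n_blocks))
  jk <- wls_jackknife(x, y, w, grp)
  h2_loo <- jk$loo[, "slope"] * m / n
  structure(
    list(
      h2 = unname(jk$full["slope"]) * m / n,
      h2_se = jackknife_se(h2_loo),
      intercept = unname(jk$full["intercept"]),
      intercept_se = jackknife_se(jk$loo[, "intercept"]),
      n_snps = nrow(df), m = m, n = n, n_blocks = jk$n_blocks,
      weights_trace = NULL
    ),
    class = "ldsc_h2"
  )
}

#' @export
print.ldsc_h2 <- function(x, ...) {
  cat(sprintf("LD score regression: h2 = %.4f (SE %.4f), intercept = %.4f (SE %.4f), %d SNPs\n",
              x$h2, x$h2_se, x$intercept, x$intercept_se, x$n_snps))
  invisible(x)
}

#' Bivariate LD score regression (genetic correlation)
#'
#' Regresses the per-SNP product `z1 * z2` on LD scores: the slope estimates
#' `sqrt(n1 n2) * gcov / m` and the free intercept estimates the
#' sample-overlap term (the cross-trait null Z correlation). The genetic
#' correlation is assembled from the two univariate fits as
#' `rg = gcov / sqrt(h2_1 h2_2)`; its standard error and p-value come from a
#' delete-one-block jackknife of the full assembly.
#'
#' @param a,b Harmonised `sumstats` tibbles on a common variant panel.
#' @param ld_sc LD-score tibble.
#' @param m SNP count for scaling (default: regression SNPs).
#' @param n_blocks Jackknife blocks.
#' @return An `ldsc_rg` object with `h2_1`, `h2_2`, `gcov`, `rg`, their SEs,
#'   the three intercepts, `p_rg`, `n_snps_used`, `n_jackknife_blocks`.
#' @export
bivariate_ldsc <- function(a, b, ld_sc, m = NULL, n_blocks = 200) {
  common <- intersect(a$variant_id, b$variant_id)
  if (!length(common)) stop("no shared variants")
  aa <- tibble::as_tibble(a)[match(common, a$variant_id), ]
  bb <- tibble::as_tibble(b)[match(common, b$variant_id), ]

  df <- ldsc_prepare(restamp_sumstats(aa, a), ld_sc)
  bb <- bb[match(df$variant_id, bb$variant_id), ]
  if (nrow(df) < 200) stop("need at least 200 SNPs with LD scores")
  if (nrow(df) < n_blocks) stop("fewer SNPs than jackknife blocks")
  m <- m %||% nrow(df)
  n1 <- mean(df$n)
  n2 <- mean(bb$n)
  x <- df$l
  y1 <- df$z^2
  y2 <- bb$z^2
  y12 <- df$z * bb$z
  grp <- as.integer(cut(seq_len(nrow(df)), n_blocks))

  # Univariate fits (iterated weights) on the shared panel.
  fit_uni <- function(y, n) {
    w <- rep(1, length(y))
    for (it in 1:3) {
      fit <- wls_coef_from_sums(wls_sums(x, y, w))
      h2 <- fit[1, "slope"] * m / n
      if (it < 3) w <- univariate_weights(x, n, h2, m)
    }
    list(w = w, h2 = h2, intercept = fit[1, "intercept"])
  }
  u1 <- fit_uni(y1, n1)
  u2 <- fit_uni(y2, n2)

  # Bivariate fit with iterated weights.
  w12 <- rep(1, length(y12))
  h1c <- min(max(u1$h2, 0), 1)
  h2c <- min(max(u2$h2, 0), 1)
  for (it in 1:3) {
    fit <- wls_coef_from_sums(wls_sums(x, y12, w12))
    gcov <- fit[1, "slope"] * m / sqrt(n1 * n2)
    icc <- fit[1, "intercept"]
    if (it < 3) {
      w12 <- 1 / ((1 + n1 * h1c * x / m) * (1 + n2 * h2c * x / m) +
                    (icc + sqrt(n1 * n2) * gcov * x / m)^2)
    }
  }

  jk1 <- wls_jackknife(x, y1, u1$w, grp)
  jk2 <- wls_jackknife(x, y2, u2$w, grp)
  jk12 <- wls_jackknife(x, y12, w12, grp)

  h1_loo <- jk1$loo[, "slope"] * m / n1
  h2_loo <- jk2$loo[, "slope"] * m / n2
  gcov_loo <- jk12$loo[, "slope"] * m / sqrt(n1 * n2)
  rg_loo <- ifelse(h1_loo > 0 & h2_loo > 0,
                   gcov_loo / sqrt(h1_loo * h2_loo), NA_real_)

  h2_1 <- unname(jk1$full["slope"]) * m / n1
  h2_2 <- unname(jk2$full["slope"]) * m / n2
  gcov_hat <- unname(jk12$full["slope"]) * m / sqrt(n1 * n2)
  rg_defined <- h2_1 > 0 && h2_2 > 0
  rg <- if (rg_defined) gcov_hat / sqrt(h2_1 * h2_2) else NA_real_
  rg_se <- jackknife_se(rg_loo)
  p_rg <- if (rg_defined && is.finite(rg_se) && rg_se > 0) {
    two_sided_p(rg / rg_se)
  } else NA_real_

  structure(
    list(
      h2_1 = h2_1, h2_1_se = jackknife_se(h1_loo),
      h2_2 = h2_2, h2_2_se = jackknife_se(h2_loo),
      gcov = gcov_hat, gcov_se = jackknife_se(gcov_loo),
      rg = rg, rg_se = rg_se, p_rg = p_rg,
      intercept_1 = unname(jk1$full["intercept"]),
      intercept_2 = unname(jk2$full["intercept"]),
      intercept_cross = unname(jk12$full["intercept"]),
      intercept_cross_se = jackknife_se(jk12$loo[, "intercept"]),
      rg_defined = rg_defined,
      n_snps_used = nrow(df), n_jackknife_blocks = n_blocks,
      m = m, n1 = n1, n2 = n2,
      trait_1 = attr(a, "trait_name") %||% "trait1",
      trait_2 = attr(b, "trait_name") %||% "trait2"
    ),
    class = "ldsc_rg"
  )
}

#' @export
print.ldsc_rg <- function(x, ...) {
  cat(sprintf("Bivariate LD score regression: %s vs %s\n", x$trait_1, x$trait_2))
  cat(sprintf("  h2_1 = %.4f (SE %.4f)   h2_2 = %.4f (SE %.4f)\n",
              x$h2_1, x$h2_1_se, x$h2_2, x$h2_2_se))
  cat(sprintf("  gcov = %.4f (SE %.4f)   rg = %.4f (SE %.4f), p = %.3g\n",
              x$gcov, x$gcov_se, x$rg, x$rg_se, x$p_rg))
  cat(sprintf("  cross-trait intercept (sample overlap) = %.4f (SE %.4f)\n",
              x$intercept_cross, x$intercept_cross_se))
  cat(sprintf("  %d SNPs, %d jackknife blocks\n",
              x$n_snps_used, x$n_jackknife_blocks))
  invisible(x)
}

# Correlation of a standard bivariate normal with correlation rho after
# restriction to the square |x| < a, |y| < a, by 1-D quadrature over x.
truncated_bvn_cor <- function(rho, a) {
  s <- sqrt(1 - rho^2)
  moms <- function(x) {
    al <- (-a - rho * x) / s
    be <- (a - rho * x) / s
    p <- pnorm(be) - pnorm(al)
    dphi <- stats::dnorm(be) - stats::dnorm(al)
    m1 <- rho * x * p - s * dphi
    m2 <- (rho * x)^2 * p - 2 * rho * x * s * dphi +
      s^2 * (p - (be * stats::dnorm(be) - al * stats::dnorm(al)))
    cbind(p, m1, m2)
  }
  f <- function(x, j) moms(x)[, j] * stats::dnorm(x)
  mass <- stats::integrate(function(x) f(x, 1), -a, a)$value
  exy <- stats::integrate(function(x) x * f(x, 2), -a, a)$value / mass
  ex <- stats::integrate(function(x) x * f(x, 1), -a, a)$value / mass
  ey <- stats::integrate(function(x) f(x, 2), -a, a)$value / mass
  ex2 <- stats::integrate(function(x) x^2 * f(x, 1), -a, a)$value / mass
  ey2 <- stats::integrate(function(x) f(x, 3), -a, a)$value / mass
  (exy - ex * ey) / sqrt((ex2 - ex^2) * (ey2 - ey^2))
}

# Invert rho -> truncated correlation; observations beyond the attainable
# range (e.g. a study against itself) are returned unchanged.
invert_truncated_cor <- function(r_obs, a) {
  if (!is.finite(r_obs)) return(r_obs)
  hi <- 0.999
  lim <- truncated_bvn_cor(hi, a)
  if (abs(r_obs) >= lim) return(r_obs)
  stats::uniroot(function(rho) truncated_bvn_cor(rho, a) - r_obs,
                 lower = -hi, upper = hi, tol = 1e-8)$root
}

#' Sample-overlap estimate from null-SNP Z-score correlation
#'
#' Estimates the null cross-trait Z correlation induced by shared samples
#' from the Pearson correlation of the two traits' Z-scores over
#' approximately independent SNPs (greedy pruning at `r2_cut`, in genomic
#' order so the retained set does not condition on the association signal)
#' that are associated with neither trait (`|z| < z_cut` in both). Because
#' restricting a bivariate normal to the square `|z| < z_cut` attenuates its
#' correlation by a known factor (about 0.78 at the default cut), the raw
#' truncated Pearson estimate is mapped back through the exact
#' truncated-bivariate-normal relationship, giving a consistent estimator of
#' the underlying correlation. This scalar is the default overlap correction
#' fed to colocalisation and the cross-phenotype statistics.
#'
#' @param a,b Harmonised `sumstats` tibbles, row-aligned.
#' @param ld Named list of block LD matrices (`NULL` treats all variants as
#'   independent).
#' @param blocks `ld_blocks` used to assign variants when `a` lacks a
#'   `block_id` column.
#' @param z_cut Null-SNP cut on `|z|` (default 1.96).
#' @param r2_cut Pruning threshold (default 0.2).
#' @return The estimated correlation (scalar). Attributes `n_snps` (SNPs
#'   entering the correlation) and `raw` (the uncorrected truncated Pearson
#'   value).
#' @export
z_correlation_overlap <- function(a, b, ld = NULL, blocks = NULL,
                                  z_cut = 1.96, r2_cut = 0.2) {
  common <- intersect(a$variant_id, b$variant_id)
  aa <- tibble::as_tibble(a)[match(common, a$variant_id), ]
  bb <- tibble::as_tibble(b)[match(common, b$variant_id), ]
  if (!is.null(ld)) {
    ss <- restamp_sumstats(aa, a)
    if (!"block_id" %in% names(ss) && !is.null(blocks)) {
      ss <- assign_blocks(ss, blocks)
    }
    keep_ids <- prune_by_position(ss, ld, prune_r2 = r2_cut)
    sel <- aa$variant_id %in% keep_ids
    aa <- aa[sel, ]
    bb <- bb[sel, ]
  }
  null_snps <- abs(aa$z) < z_cut & abs(bb$z) < z_cut
  if (sum(null_snps) < 30) stop("fewer than 30 qualifying null SNPs")
  raw <- cor(aa$z[null_snps], bb$z[null_snps])
  est <- invert_truncated_cor(raw, z_cut)
  attr(est, "n_snps") <- sum(null_snps)
  attr(est, "raw") <- raw
  est
}
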