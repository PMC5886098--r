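# Cross-phenotype association statistics for correlated studies (S_hom,
# S_het), the study correlation matrix they require, inverse-variance-weighted
# fixed-effects meta-analysis, and the direction-of-effect sign test.

#' Estimate the between-study correlation matrix from null SNPs
#'
#' For every study pair: harmonise, prune to approximately independent SNPs
#' (greedy r-squared pruning at `r2_cut`), keep SNPs associated with neither
#' study (`|z| < z_cut` in both), and take the Pearson correlation of their
#' Z-scores. The diagonal is 1; if the assembled matrix is not positive
#' definite it is repaired by flooring the eigenvalues at 1e-6 and rescaling
#' to unit diagonal (the repair is recorded and messaged).
#'
#' @param studies Named list of `sumstats` tibbles (>= 2).
#' @param ld Named list of block LD matrices (`NULL`: no pruning).
#' @param blocks `ld_blocks` for block assignment when pruning.
#' @param z_cut,r2_cut Null-SNP and pruning cuts (defaults 1.96, 0.2).
#' @return Correlation matrix with study names as dimnames; attribute
#'   `repaired` records whether a positive-definite repair was applied.
#' @export
estimate_corr_matrix <- function(studies, ld = NULL, blocks = NULL,
                                 z_cut = 1.96, r2_cut = 0.2) {
  k <- length(studies)
  if (k < 2) stop("need at least two studies")
  labels <- names(studies) %||% paste0("study", seq_len(k))
  labels[labels == ""] <- paste0("study", which(labels == ""))
  R <- diag(1, k)
  dimnames(R) <- list(labels, labels)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      hp <- harmonize_pair(studies[[i]], studies[[j]])
      R[i, j] <- R[j, i] <- z_correlation_overlap(
        hp$a, hp$b, ld = ld, blocks = blocks, z_cut = z_cut, r2_cut = r2_cut
      )
    }
  }
  out <- near_pd(R)
  if (attr(out, "repaired")) {
    message("study correlation matrix was not positive definite; ",
            "eigenvalue-floor repair applied")
  }
  out
}

check_corr_matrix <- function(R) {
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 1e-10) {
    stop("R must be positive definite (run near_pd repair first)")
  }
  invisible(R)
}

#' Homogeneous-effect cross-phenotype statistic S_hom
#'
#' `S_hom = (w' R^-1 z)^2 / (w' R^-1 w)` with default weights `w = sqrt(n)`;
#' distributed chi-square with 1 df under the null. With `R = I` and
#' inverse-variance weights (`w = 1/se`) it equals the squared
#' inverse-variance-weighted meta-analysis Z — the classical equivalence when
#' no samples are shared.
#'
#' @param z Vector of study Z-scores for one variant.
#' @param n Vector of study sample sizes (used for the default weights).
#' @param R Study correlation matrix.
#' @param w Weights (default `sqrt(n)`).
#' @return List with `statistic` and `p`.
#' @export
s_hom <- function(z, n, R = diag(length(z)), w = sqrt(n)) {
  stopifnot(length(z) == length(w), nrow(R) == length(z))
  check_corr_matrix(R)
  ri_w <- solve(R, w)
  stat <- drop(crossprod(w, solve(R, z)))^2 / drop(crossprod(w, ri_w))
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# S_hom-type statistic restricted to a subset of studies, with cached
# sub-matrix solves. `cache` is an environment keyed by subset bitmask.
subset_stat_factory <- function(R, w) {
  k <- length(w)
  cache <- new.env(parent = emptyenv())
  function(z, mask) {
    if (!any(mask)) return(0)
    key <- paste(which(mask), collapse = ",")
    entry <- cache[[key]]
    if (is.null(entry)) {
      ws <- w[mask]
      v <- solve(R[mask, mask, drop = FALSE], ws)
      entry <- list(v = v, d = drop(crossprod(ws, v)))
      cache[[key]] <- entry
    }
    drop(crossprod(z[mask], entry$v))^2 / entry$d
  }
}

# S_het statistic (max over the truncation grid) for one z-vector.
s_het_stat <- function(z, stat_fn, tau_grid) {
  best <- -Inf
  best_tau <- tau_grid[1]
  for (tau in tau_grid) {
    mask <- if (tau == 0) rep(TRUE, length(z)) else abs(z) > tau
    s <- stat_fn(z, mask)
    if (s > best) {
      best <- s
      best_tau <- tau
    }
  }
  list(statistic = best, tau = best_tau)
}

#' Heterogeneous-effect cross-phenotype statistic S_het
#'
#' For each truncation threshold tau in `tau_grid`, computes the S_hom-type
#' statistic restricted to studies with `|z| > tau` (0 when none qualify);
#' `S_het` is the maximum over the grid (tau = 0 includes all studies, so
#' `S_het >= S_hom`-type floor by construction). Because the maximisation
#' breaks the chi-square null, the p-value is Monte Carlo: `n_mc` null
#' z-vectors are drawn from N(0, R), the max statistic recomputed, and
#' `p = (r + 1) / (n_mc + 1)`.
#'
#' @param z Vector of study Z-scores for one variant.
#' @param n Study sample sizes (weights are `sqrt(n)`).
#' @param R Study correlation matrix.
#' @param tau_grid Ascending truncation grid starting at 0
#'   (default `c(0, 0.5, 1, 1.5, 2, 2.5, 3)`).
#' @param n_mc Monte Carlo null draws (>= 100).
#' @param seed Integer seed for the null draws.
#' @return List with `statistic`, `p`, `tau_argmax`.
#' @export
s_het <- function(z, n, R = diag(length(z)),
                  tau_grid = c(0, 0.5, 1, 1.5, 2, 2.5, 3),
                  n_mc = 5000, seed = 1L) {
  if (n_mc < 100) stop("n_mc must be >= 100")
  if (!length(tau_grid) || tau_grid[1] != 0 || is.unsorted(tau_grid)) {
    stop("tau_grid must be ascending and start at 0")
  }
  check_corr_matrix(R)
  w <- sqrt(n)
  stat_fn <- subset_stat_factory(R, w)
  obs <- s_het_stat(z, stat_fn, tau_grid)
  null_max <- s_het_null(R, w, tau_grid, n_mc, seed)
  p <- (1 + sum(null_max >= obs$statistic)) / (n_mc + 1)
  list(statistic = obs$statistic, p = p, tau_argmax = obs$tau)
}

# Null distribution of the max-over-tau statistic: n_mc draws from N(0, R).
s_het_null <- function(R, w, tau_grid, n_mc, seed) {
  set.seed(seed)
  k <- length(w)
  Z <- matrix(rnorm(n_mc * k), n_mc, k) %*% chol(R)
  s_het_stat_vec(Z, R, w, tau_grid)$statistic
}

# Vectorised S_het over the rows of a Z matrix.
s_het_stat_vec <- function(Z, R, w, tau_grid) {
  k <- ncol(Z)
  nr <- nrow(Z)
  best <- rep(-Inf, nr)
  best_tau <- rep(tau_grid[1], nr)
  pow2 <- 2^(seq_len(k) - 1)
  solves <- list()
  for (tau in tau_grid) {
    mask <- if (tau == 0) matrix(TRUE, nr, k) else abs(Z) > tau
    codes <- as.integer(mask %*% pow2)
    s <- numeric(nr)
    for (code in unique(codes)) {
      rows <- codes == code
      if (code == 0) next
      key <- as.character(code)
      entry <- solves[[key]]
      if (is.null(entry)) {
        sel <- bitwAnd(code, as.integer(pow2)) > 0
        ws <- w[sel]
        v <- solve(R[sel, sel, drop = FALSE], ws)
        entry <- list(sel = sel, v = v, d = drop(crossprod(ws, v)))
        solves[[key]] <- entry
      }
      s[rows] <- drop(Z[rows, entry$sel, drop = FALSE] %*% entry$v)^2 / entry$d
    }
    better <- s > best
    best[better] <- s[better]
    best_tau[better] <- tau
  }
  list(statistic = best, tau_argmax = best_tau)
}

#' Cross-phenotype association scan over a harmonised pair
#'
#' Computes S_hom and S_het per shared variant, with the study correlation
#' matrix estimated from null SNPs unless supplied. The S_het null
#' distribution is drawn once (it depends only on `R`, the weights and the
#' grid) and shared across variants.
#'
#' @param a,b Harmonised `sumstats` tibbles.
#' @param R Study correlation matrix (2x2); `NULL` estimates it via
#'   [z_correlation_overlap()].
#' @param ld,blocks Passed to the correlation estimate when `R` is `NULL`.
#' @param tau_grid,n_mc,seed As in [s_het()].
#' @return A `cpassoc_result` tibble: `variant_id`, `z_1`, `z_2`, `s_hom`,
#'   `p_hom`, `s_het`, `p_het`, `tau_argmax`.
#' @export
cpassoc_scan <- function(a, b, R = NULL, ld = NULL, blocks = NULL,
                         tau_grid = c(0, 0.5, 1, 1.5, 2, 2.5, 3),
                         n_mc = 5000, seed = 1L) {
  common <- intersect(a$variant_id, b$variant_id)
  if (!length(common)) stop("no shared variants")
  aa <- tibble::as_tibble(a)[match(common, a$variant_id), ]
  bb <- tibble::as_tibble(b)[match(common, b$variant_id), ]
  if (is.null(R)) {
    c_hat <- z_correlation_overlap(restamp_sumstats(aa, a),
                                   restamp_sumstats(bb, b),
                                   ld = ld, blocks = blocks)
    R <- matrix(c(1, c_hat, c_hat, 1), 2)
    dimnames(R) <- list(
      c(attr(a, "trait_name") %||% "trait1",
        attr(b, "trait_name") %||% "trait2"),
      c(attr(a, "trait_name") %||% "trait1",
        attr(b, "trait_name") %||% "trait2")
    )
  }
  check_corr_matrix(R)
  n <- c(mean(aa$n), mean(bb$n))
  w <- sqrt(n)
  Z <- cbind(aa$z, bb$z)

  ri_w <- solve(R, w)
  denom <- drop(crossprod(w, ri_w))
  shom <- drop(Z %*% ri_w)^2 / denom
  p_hom <- pchisq(shom, df = 1, lower.tail = FALSE)

  het <- s_het_stat_vec(Z, R, w, tau_grid)
  null_max <- sort(s_het_null(R, w, tau_grid, n_mc, seed))
  # p = (1 + #\{null >= obs\}) / (n_mc + 1) via binary search on sorted null.
  n_ge <- n_mc - findInterval(het$statistic - 1e-12, null_max)
  p_het <- (1 + n_ge) / (n_mc + 1)

  structure(
    tibble::tibble(
      variant_id = aa$variant_id,
      z_1 = aa$z, z_2 = bb$z,
      s_hom = shom, p_hom = p_hom,
      s_het = het$statistic, p_het = p_het, tau_argmax = het$tau_argmax
    ),
    class = c("cpassoc_result", class(tibble::tibble())),
    R = R, n = n, n_mc = n_mc, seed = seed
  )
}

#' Inverse-variance-weighted fixed-effects meta-analysis of one variant
#'
#' `pooled_beta = sum(b_i / se_i^2) / sum(1 / se_i^2)`,
#' `pooled_se = 1 / sqrt(sum(1 / se_i^2))`; two-sided normal p; odds ratio
#' and 95% CI on the exp scale. Studies with missing effect or SE are
#' skipped and recorded as `?` in the direction string (METAL-style, one
#' character per study: `+`, `-`, `?`).
#'
#' @param betas Effect sizes per study (log-odds / per-SD); `NA` = missing.
#' @param ses Standard errors per study, > 0 where present.
#' @param variant_id Optional label.
#' @return A one-row `meta_result` tibble: `pooled_beta`, `pooled_se`, `or_`,
#'   `ci95_lo`, `ci95_hi`, `p_meta`, `direction`, `n_studies`.
#' @export
ivw_meta <- function(betas, ses, variant_id = NA_character_) {
  stopifnot(length(betas) == length(ses))
  ok <- !is.na(betas) & !is.na(ses)
  if (!any(ok)) stop("all studies missing")
  if (any(ses[ok] <= 0)) stop("standard errors must be positive")
  wt <- 1 / ses[ok]^2
  pooled_beta <- sum(betas[ok] * wt) / sum(wt)
  pooled_se <- 1 / sqrt(sum(wt))
  direction <- rep("?", length(betas))
  direction[ok] <- ifelse(betas[ok] >= 0, "+", "-")
  structure(
    tibble::tibble(
      variant_id = variant_id,
      pooled_beta = pooled_beta,
      pooled_se = pooled_se,
      or_ = exp(pooled_beta),
      ci95_lo = exp(pooled_beta - 1.96 * pooled_se),
      ci95_hi = exp(pooled_beta + 1.96 * pooled_se),
      p_meta = two_sided_p(pooled_beta / pooled_se),
      direction = paste(direction, collapse = ""),
      n_studies = sum(ok)
    ),
    class = c("meta_result", class(tibble::tibble()))
  )
}

#' Meta-analyse a candidate list across study cohorts
#'
#' Runs [ivw_meta()] per candidate variant over the supplied cohorts;
#' variants absent from a cohort contribute `?` to the direction string.
#'
#' @param variant_ids Candidate variant ids.
#' @param studies Named list of `sumstats` tibbles (assumed allele-aligned;
#'   harmonise each against the discovery cohort first).
#' @return A `meta_result` tibble with one row per candidate.
#' @export
meta_scan <- function(variant_ids, studies) {
  stopifnot(length(studies) >= 1)
  rows <- purrr::map(variant_ids, function(v) {
    betas <- vapply(studies, function(s) {
      i <- match(v, s$variant_id)
      if (is.na(i)) NA_real_ else s$beta[i]
    }, numeric(1))
    ses <- vapply(studies, function(s) {
      i <- match(v, s$variant_id)
      if (is.na(i)) NA_real_ else s$se[i]
    }, numeric(1))
    ivw_meta(betas, ses, variant_id = v)
  })
  dplyr::bind_rows(rows)
}

#' Binomial direction-of-effect sign test
#'
#' Among independent variants with a non-missing direction in every study,
#' counts those with an identical direction across all studies and tests the
#' count against the null concordance probability `(1/2)^(k - 1)` for `k`
#' studies, by a two-sided exact binomial test (doubled smaller tail, capped
#' at 1).
#'
#' @param direction_strings Character vector of METAL-style direction
#'   strings, one character per study; strings containing `?` are excluded.
#' @return List with `k_concordant`, `n_eligible`, `n_studies`, `null_prob`,
#'   `p`.
#' @export
sign_test <- function(direction_strings) {
  eligible <- direction_strings[!grepl("?", direction_strings, fixed = TRUE)]
  if (!length(eligible)) stop("zero eligible variants")
  ns <- unique(nchar(eligible))
  if (length(ns) != 1) stop("direction strings of unequal length")
  if (ns < 2) stop("need at least two studies")
  concordant <- eligible == strrep("+", ns) | eligible == strrep("-", ns)
  k <- sum(concordant)
  n <- length(eligible)
  p0 <- 0.5^(ns - 1)
  upper <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  lower <- pbinom(k, n, p0)
  list(
    k_concordant = k, n_eligible = n, n_studies = ns, null_prob = p0,
    p = min(1, 2 * min(upper, lower))
  )
}
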