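# Regional Bayesian colocalisation from Z-scores and standard errors.
#
# Per approximately independent LD block, posterior probabilities for five
# hypotheses under the single-causal-variant-per-trait frame:
#   H0 no associated variant; H1/H2 one variant for trait 1/2 only;
#   H3 one shared causal variant; H4 two distinct causal variants.
# Evidence is assembled from per-SNP Wakefield approximate Bayes factors in
# log-sum-exp arithmetic; sample overlap enters the shared-causal (H3) joint
# ABF through the bivariate null covariance [[1, c], [c, 1]].

#' Priors for regional colocalisation
#'
#' @param p1,p2 Prior probability that any one SNP is causal for trait 1/2
#'   only (defaults 1e-4, field standard).
#' @param p12 Prior probability of a shared causal SNP (default 1e-5);
#'   must satisfy `0 < p12 <= min(p1, p2)` and `p1 + p2 + p12 < 1`.
#' @param W1,W2 Prior effect variances on the additive effect scale
#'   (default 0.04, i.e. prior SD 0.2 per log-odds / per-SD unit).
#' @return A `coloc_priors` list.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         W1 = 0.04, W2 = 0.04) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p12 <= min(p1, p2),
            p1 + p2 + p12 < 1, W1 > 0, W2 > 0)
  structure(list(p1 = p1, p2 = p2, p12 = p12, W1 = W1, W2 = W2),
            class = "coloc_priors")
}

#' Wakefield approximate Bayes factor (log scale)
#'
#' For a variant with Z-score `z` and standard error `se` (`V = se^2`), under
#' a normal effect prior of variance `W`:
#' `log ABF = 0.5 log(V / (V + W)) + z^2 W / (2 (V + W))`.
#' Vectorised over all arguments.
#'
#' @param z Z-score(s).
#' @param se Standard error(s), > 0.
#' @param W Prior effect variance, > 0.
#' @return Log approximate Bayes factor(s) in favour of association.
#' @export
wakefield_abf <- function(z, se, W) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(W <= 0)) stop("W must be positive")
  V <- se^2
  0.5 * log(V / (V + W)) + z^2 * W / (2 * (V + W))
}

#' Joint Bayes factor for a shared causal variant under sample overlap
#'
#' Log ratio of bivariate normal densities of `(z1, z2)` under the
#' shared-causal alternative, covariance `[[1 + W1/V1, c], [c, 1 + W2/V2]]`,
#' versus the null, covariance `[[1, c], [c, 1]]`, where `c` is the
#' cross-trait null Z correlation from shared samples. At `c = 0` this
#' factorises exactly into the sum of the two univariate Wakefield log-ABFs.
#' Vectorised.
#'
#' @param z1,z2 Z-scores for the two traits.
#' @param se1,se2 Standard errors, > 0.
#' @param priors A [coloc_priors()] (supplies `W1`, `W2`).
#' @param c Sample-overlap correlation, `|c| < 1`.
#' @return Log Bayes factor(s) for a shared causal variant at this SNP.
#' @export
joint_shared_abf <- function(z1, z2, se1, se2, priors = coloc_priors(),
                             c = 0) {
  if (abs(c) >= 1) stop("|c| must be < 1")
  if (any(se1 <= 0) || any(se2 <= 0)) stop("se must be positive")
  s1 <- 1 + priors$W1 / se1^2
  s2 <- 1 + priors$W2 / se2^2
  det0 <- 1 - c^2
  det1 <- s1 * s2 - c^2
  q0 <- (z1^2 + z2^2 - 2 * c * z1 * z2) / det0
  q1 <- (s2 * z1^2 + s1 * z2^2 - 2 * c * z1 * z2) / det1
  0.5 * (log(det0) - log(det1)) + 0.5 * (q0 - q1)
}

#' Posterior probabilities of the five hypotheses for one region
#'
#' Assembles per-hypothesis evidence from per-SNP log ABFs (priors `p1`,
#' `p2`, `p12` per SNP, H4 summing over ordered distinct pairs through
#' univariate ABFs) in log-sum-exp arithmetic and normalises. With exactly
#' one SNP the H4 posterior is structurally zero.
#'
#' @param region Data frame with columns `variant_id`, `z1`, `se1`, `z2`,
#'   `se2` (aligned across traits).
#' @param priors A [coloc_priors()].
#' @param c Sample-overlap correlation (enters the H3 joint ABF only).
#' @param block_id Optional region label.
#' @return A one-row `coloc_result` tibble: `block_id`, `n_snps`,
#'   `pp_h0`..`pp_h4` (sum to 1), `top_snp_trait1`, `top_snp_trait2`,
#'   `flagged_h3`, `flagged_h4` (posterior >= 0.9).
#' @export
region_posteriors <- function(region, priors = coloc_priors(), c = 0,
                              block_id = NA_character_) {
  region <- tibble::as_tibble(region)
  stopifnot(all(c("variant_id", "z1", "se1", "z2", "se2") %in% names(region)))
  k <- nrow(region)
  if (k < 1) stop("region must contain at least one SNP")

  labf1 <- wakefield_abf(region$z1, region$se1, priors$W1)
  labf2 <- wakefield_abf(region$z2, region$se2, priors$W2)
  labf_joint <- joint_shared_abf(region$z1, region$z2, region$se1,
                                 region$se2, priors, c)

  s1 <- logsumexp(labf1)
  s2 <- logsumexp(labf2)
  s12 <- logsumexp(labf1 + labf2)
  l <- c(
    h0 = 0,
    h1 = log(priors$p1) + s1,
    h2 = log(priors$p2) + s2,
    h3 = log(priors$p12) + logsumexp(labf_joint),
    h4 = if (k < 2) -Inf else {
      log(priors$p1) + log(priors$p2) + logdiffexp(s1 + s2, s12)
    }
  )
  pp <- exp(l - logsumexp(l))
  pp <- pp / sum(pp)

  structure(
    tibble::tibble(
      block_id = block_id,
      n_snps = k,
      pp_h0 = pp[["h0"]], pp_h1 = pp[["h1"]], pp_h2 = pp[["h2"]],
      pp_h3 = pp[["h3"]], pp_h4 = pp[["h4"]],
      top_snp_trait1 = region$variant_id[which.max(abs(region$z1))],
      top_snp_trait2 = region$variant_id[which.max(abs(region$z2))],
      flagged_h3 = pp[["h3"]] >= 0.9,
      flagged_h4 = pp[["h4"]] >= 0.9
    ),
    class = c("coloc_result", class(tibble::tibble()))
  )
}

#' Genome-wide colocalisation scan over LD blocks
#'
#' Runs [region_posteriors()] per approximately independent block and sorts
#' regions by evidence for pleiotropy, `max(pp_h3, pp_h4)`. Regions with a
#' posterior >= 0.9 for H3 or H4 are flagged.
#'
#' @param a,b Harmonised `sumstats` tibbles, aligned on the same variants.
#' @param blocks `ld_blocks` tibble (unused if `a` already carries
#'   `block_id`).
#' @param priors A [coloc_priors()].
#' @param c Sample-overlap correlation, e.g. from
#'   [z_correlation_overlap()].
#' @return A `coloc_scan` tibble, one row per block, sorted by
#'   `max(pp_h3, pp_h4)` descending; also reports the block coordinates.
#' @export
genome_coloc_scan <- function(a, b, blocks = NULL, priors = coloc_priors(),
                              c = 0) {
  common <- intersect(a$variant_id, b$variant_id)
  if (!length(common)) stop("no shared variants")
  aa <- tibble::as_tibble(a)[match(common, a$variant_id), ]
  bb <- tibble::as_tibble(b)[match(common, b$variant_id), ]
  if (!"block_id" %in% names(aa)) {
    if (is.null(blocks)) stop("blocks required when a lacks block_id")
    aa <- assign_blocks(aa, blocks)
  }
  if (anyNA(aa$block_id)) stop("variants without a block assignment")
  if (!length(unique(aa$block_id))) stop("no blocks to scan")

  regions <- split(seq_len(nrow(aa)), aa$block_id)
  res <- purrr::map(names(regions), function(bid) {
    idx <- regions[[bid]]
    region_posteriors(
      tibble::tibble(
        variant_id = aa$variant_id[idx],
        z1 = aa$z[idx], se1 = aa$se[idx],
        z2 = bb$z[idx], se2 = bb$se[idx]
      ),
      priors = priors, c = c, block_id = bid
    )
  })
  out <- dplyr::bind_rows(res)
  if (!is.null(blocks)) {
    out <- dplyr::left_join(
      out,
      tibble::as_tibble(blocks)[c("block_id", "chrom", "start", "stop")],
      by = "block_id"
    )
  }
  out <- dplyr::arrange(out, dplyr::desc(pmax(.data$pp_h3, .data$pp_h4)))
  structure(out, class = c("coloc_scan", class(tibble::tibble())),
            c = c)
}
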