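# SNP-based signal-overlap analysis: p-value-informed LD pruning,
# per-threshold 2x2 chi-square tests, and a permutation null.

#' Configuration for the overlap analysis
#'
#' @param thresholds Descending p-value thresholds (defaults to the ten used
#'   in the overlap analysis the package reproduces).
#' @param prune_r2 LD-pruning r-squared threshold (default 0.05).
#' @param n_perm Number of permutations (default 1e6).
#' @param seed Integer seed for the permutation stream.
#' @return An `overlap_config` list.
#' @export
overlap_config <- function(thresholds = c(0.5, 0.1, 0.05, 0.04, 0.03, 0.02,
                                          0.01, 0.005, 0.001, 5e-4),
                           prune_r2 = 0.05, n_perm = 1e6, seed = 1L) {
  stopifnot(
    all(thresholds > 0), all(thresholds < 1),
    prune_r2 > 0, prune_r2 < 1, n_perm >= 1
  )
  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  structure(
    list(thresholds = thresholds, prune_r2 = prune_r2,
         n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "overlap_config"
  )
}

#' P-value-informed greedy LD pruning
#'
#' Variants are visited in ascending order of the (trait-1) p-value, ties
#' broken by chromosome, position, then variant id; the current variant is
#' retained iff its r-squared with every already-retained variant in the same
#' block is at most `prune_r2`. Cross-block LD is treated as exactly 0.
#'
#' @param s A `sumstats` tibble with a `block_id` column (see
#'   [assign_blocks()]).
#' @param ld Named list of per-block LD matrices.
#' @param prune_r2 r-squared above which a variant is removed (default 0.05).
#' @return Character vector of retained variant ids, in visit order.
#' @export
prune_by_pvalue <- function(s, ld, prune_r2 = 0.05) {
  greedy_prune(s, ld, prune_r2,
               order(s$pvalue, s$chrom, s$pos, s$variant_id))
}

# Greedy pruning in genomic-position order: statistic-independent, used
# where the retained set must not condition on the association signal
# (null-SNP overlap estimation).
prune_by_position <- function(s, ld, prune_r2 = 0.05) {
  greedy_prune(s, ld, prune_r2, order(s$chrom, s$pos, s$variant_id))
}

greedy_prune <- function(s, ld, prune_r2, ord) {
  if (!"block_id" %in% names(s)) stop("s needs a block_id column")
  if (anyNA(s$block_id)) stop("variant missing LD assignment")
  bid <- s$block_id[ord]
  vid <- s$variant_id[ord]

  # Per-block matrix row index of each variant, for O(1) lookups.
  row_in_block <- integer(length(vid))
  for (b in unique(bid)) {
    R <- ld[[b]]
    if (is.null(R)) stop("no LD matrix for block ", b)
    sel <- bid == b
    idx <- match(vid[sel], rownames(R))
    if (anyNA(idx)) stop("variant missing from LD matrix of block ", b)
    row_in_block[sel] <- idx
  }

  kept <- vector("list", length(unique(bid)))
  names(kept) <- unique(bid)
  keep <- logical(length(vid))
  for (i in seq_along(vid)) {
    b <- bid[i]
    held <- kept[[b]]
    if (is.null(held) ||
        all(ld[[b]][row_in_block[i], held]^2 <= prune_r2)) {
      keep[i] <- TRUE
      kept[[b]] <- c(held, row_in_block[i])
    }
  }
  vid[keep]
}

#' 2x2 overlap test at one p-value threshold
#'
#' Cross-classifies aligned pruned variants by strict `p < t` in each trait
#' and computes the Pearson chi-square (1 df, no continuity correction). Any
#' zero margin leaves the chi-square undefined.
#'
#' @param a_p,b_p Equal-length aligned p-value vectors (trait 1, trait 2).
#' @param t Threshold in (0, 1).
#' @return List with `table` (2x2 matrix, below/above in trait 1 by trait 2),
#'   `chi2` and `p_chi2`.
#' @export
threshold_overlap <- function(a_p, b_p, t) {
  stopifnot(length(a_p) == length(b_p), t > 0, t < 1)
  a_below <- a_p < t
  b_below <- b_p < t
  tab <- matrix(
    c(sum(a_below & b_below), sum(!a_below & b_below),
      sum(a_below & !b_below), sum(!a_below & !b_below)),
    nrow = 2,
    dimnames = list(trait1 = c("below", "above"), trait2 = c("below", "above"))
  )
  n <- sum(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(table = tab, chi2 = NA_real_, p_chi2 = NA_real_))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  list(table = tab, chi2 = chi2, p_chi2 = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Number of thresholds (descending) that each p-value falls strictly below.
threshold_levels <- function(p, thresholds) {
  lev <- integer(length(p))
  for (t in thresholds) lev <- lev + (p < t)
  lev
}

#' Permutation-calibrated overlap analysis across thresholds
#'
#' For each threshold the observed 2x2 chi-square is compared against an
#' empirical null obtained by randomly permuting the trait-2 p-values; one
#' shared permutation stream serves all thresholds, preserving their
#' dependence. The permutation p-value is the one-sided
#' enrichment test on the signed statistic `s = sign(overlap - expected) *
#' chi2`, with the add-one estimator `p_perm = (1 + #\{s* >= s_obs\}) /
#' (n_perm + 1)` (never zero, and exactly valid under the null).
#'
#' @param a_p,b_p Aligned pruned p-value vectors; `b_p` is the permuted side.
#' @param config An [overlap_config()].
#' @return An `overlap_result` tibble, one row per threshold: counts of the
#'   2x2 table, `n_overlap` (below threshold in both), `chi2`, `p_chi2`,
#'   `p_perm`.
#' @export
permutation_overlap <- function(a_p, b_p, config = overlap_config()) {
  stopifnot(length(a_p) == length(b_p))
  thr <- config$thresholds
  K <- length(thr)
  N <- length(a_p)
  lev_a <- threshold_levels(a_p, thr)
  lev_b <- threshold_levels(b_p, thr)
  A <- vapply(seq_len(K), function(k) sum(lev_a >= k), numeric(1))
  B <- vapply(seq_len(K), function(k) sum(lev_b >= k), numeric(1))

  # chi2 for fixed margins is N (N n11 - A B)^2 / (A (N-A) B (N-B)).
  denom <- A * (N - A) * B * (N - B)
  denom[denom == 0] <- NA_real_
  L <- matrix(0, K + 1, K + 1)
  L[upper.tri(L, diag = TRUE)] <- 1  # L[i, j] = 1 iff j >= i

  cross_n11 <- function(la, lb) {
    idx <- la * (K + 1L) + lb + 1L
    M <- matrix(tabulate(idx, nbins = (K + 1L)^2), K + 1L, K + 1L)
    # suffix sums: suff[i, j] = #\{a_lev >= i-1 & b_lev >= j-1\}
    suff <- L %*% M %*% t(L)
    diag(suff)[-1]
  }

  n11_obs <- cross_n11(lev_a, lev_b)
  u_obs <- N * n11_obs - A * B
  chi2_obs <- N * u_obs^2 / denom
  s_obs <- sign(u_obs) * chi2_obs

  set.seed(config$seed)
  exceed <- numeric(K)
  valid <- !is.na(s_obs)
  for (r in seq_len(config$n_perm)) {
    lb <- lev_b[sample.int(N)]
    n11 <- cross_n11(lev_a, lb)
    u <- N * n11 - A * B
    s <- sign(u) * N * u^2 / denom
    exceed <- exceed + (valid & s >= s_obs)
  }
  p_perm <- ifelse(valid, (1 + exceed) / (config$n_perm + 1), NA_real_)

  structure(
    tibble::tibble(
      threshold = thr,
      n_total = N,
      n_below_1 = A,
      n_below_2 = B,
      n_overlap = n11_obs,
      n_10 = A - n11_obs,
      n_01 = B - n11_obs,
      n_00 = N - A - B + n11_obs,
      chi2 = as.numeric(chi2_obs),
      p_chi2 = pchisq(as.numeric(chi2_obs), df = 1, lower.tail = FALSE),
      p_perm = as.numeric(p_perm)
    ),
    class = c("overlap_result", class(tibble::tibble())),
    n_perm = config$n_perm,
    seed = config$seed
  )
}

#' Overlap analysis of a harmonised study pair
#'
#' Convenience wrapper: assigns blocks, prunes by the trait-1 p-values at
#' `config$prune_r2`, then runs [permutation_overlap()] on the pruned pair.
#'
#' @param a,b Harmonised `sumstats` tibbles (trait 1 sorts and trait 2 is
#'   permuted, mirroring the OA-vs-BMD roles).
#' @param ld Named list of block LD matrices.
#' @param blocks `ld_blocks` tibble (unused if `a` already has `block_id`).
#' @param config An [overlap_config()].
#' @return An `overlap_result` tibble; attribute `pruned_ids` holds the
#'   retained variant ids.
#' @export
overlap_analysis <- function(a, b, ld, blocks = NULL,
                             config = overlap_config()) {
  common <- intersect(a$variant_id, b$variant_id)
  aa <- tibble::as_tibble(a)[match(common, a$variant_id), ]
  bb <- tibble::as_tibble(b)[match(common, b$variant_id), ]
  ss <- restamp_sumstats(aa, a)
  if (!"block_id" %in% names(ss) && !is.null(blocks)) {
    ss <- assign_blocks(ss, blocks)
  }
  pruned <- prune_by_pvalue(ss, ld, prune_r2 = config$prune_r2)
  sel <- match(pruned, aa$variant_id)
  res <- permutation_overlap(aa$pvalue[sel], bb$pvalue[sel], config)
  attr(res, "pruned_ids") <- pruned
  res
}

#' Select replication candidates from overlap and colocalisation results
#'
#' The candidate set is the union of (i) pruned variants below `p_t` in both
#' traits and (ii) for every colocalisation-flagged region, the top trait-1
#' and top trait-2 variants. Deduplicated, deterministic order (overlap
#' variants in ascending trait-1 p-value, then flagged-region top SNPs in
#' region order).
#'
#' @param pruned_a,pruned_b Aligned `sumstats` rows for the pruned panel.
#' @param coloc A `coloc_scan` tibble (see [genome_coloc_scan()]); `NULL`
#'   skips part (ii).
#' @param p_t Overlap threshold (default 0.005).
#' @return Tibble with `variant_id` and `source`
#'   (`"overlap"`, `"coloc_top"`, or `"both"`).
#' @export
select_candidates <- function(pruned_a, pruned_b, coloc = NULL, p_t = 0.005) {
  stopifnot(nrow(pruned_a) == nrow(pruned_b))
  hit <- pruned_a$pvalue < p_t & pruned_b$pvalue < p_t
  overlap_ids <- pruned_a$variant_id[hit][order(pruned_a$pvalue[hit])]

  top_ids <- character(0)
  if (!is.null(coloc) && nrow(coloc)) {
    flagged <- coloc[coloc$flagged_h3 | coloc$flagged_h4, ]
    top_ids <- as.character(rbind(flagged$top_snp_trait1,
                                  flagged$top_snp_trait2))
  }

  ids <- c(overlap_ids, top_ids)
  src <- c(rep("overlap", length(overlap_ids)),
           rep("coloc_top", length(top_ids)))
  if (!length(ids)) {
    return(tibble::tibble(variant_id = character(0), source = character(0)))
  }
  tibble::tibble(variant_id = ids, source = src, ord = seq_along(ids)) |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      source = if (dplyr::n_distinct(.data$source) > 1) "both"
               else .data$source[1],
      ord = min(.data$ord),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$ord) |>
    dplyr::select("variant_id", "source")
}
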