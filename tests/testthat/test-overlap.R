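make_pruning_instance <- function(df, ld) {
  # df needs variant_id, pvalue, block_id, pos; fill sumstats fields
  df$chrom <- "1"
  df$z <- qnorm(df$pvalue / 2, lower.tail = FALSE)
  df
}

test_that("greedy pruning follows the sorted-greedy rule", {
  # hand-executed example: r2(1,2) = 0.9 removes SNP2; SNP3 untouched
  r <- sqrt(0.9)
  R <- ld_matrix(matrix(c(1, r, 0, r, 1, 0, 0, 0, 1), 3),
                 c("s1", "s2", "s3"))
  df <- tibble::tibble(
    variant_id = c("s1", "s2", "s3"), chrom = "1", pos = 1:3,
    pvalue = c(0.001, 0.01, 0.02), block_id = "b1"
  )
  expect_equal(prune_by_pvalue(df, list(b1 = R)), c("s1", "s3"))

  # identity LD retains everything
  R_id <- ld_matrix(diag(3), c("s1", "s2", "s3"))
  expect_setequal(prune_by_pvalue(df, list(b1 = R_id)), df$variant_id)

  # equal p, r2 = 1: exactly one survives, the earlier by position
  R_dup <- ld_matrix(matrix(1, 2, 2), c("t1", "t2"))
  df2 <- tibble::tibble(
    variant_id = c("t2", "t1"), chrom = "1", pos = c(5, 9),
    pvalue = c(0.5, 0.5), block_id = "b1"
  )
  expect_equal(prune_by_pvalue(df2, list(b1 = R_dup)), "t2")

  df$block_id[2] <- NA
  expect_error(prune_by_pvalue(df, list(b1 = R)), "missing LD assignment")
})

test_that("pruning matches the brute-force oracle on random instances", {
  set.seed(30)
  for (rep in 1:25) {
    n_blocks <- sample(1:3, 1)
    ld <- list()
    rows <- list()
    pos0 <- 0
    for (b in seq_len(n_blocks)) {
      k <- sample(2:7, 1)
      ids <- sprintf("b%d_v%d", b, seq_len(k))
      ld[[paste0("b", b)]] <- ld_matrix(random_corr(k, jitter = 0.3), ids)
      p <- round(runif(k), sample(c(1, 2, 6), 1))  # induce occasional ties
      p[p == 0] <- 0.5
      rows[[b]] <- tibble::tibble(
        variant_id = ids, chrom = "1", pos = pos0 + seq_len(k),
        pvalue = p, block_id = paste0("b", b)
      )
      pos0 <- pos0 + k
    }
    df <- dplyr::bind_rows(rows)
    got <- prune_by_pvalue(df, ld, prune_r2 = 0.05)
    expect_identical(got, oracle_prune(df, ld, 0.05))
    # exhaustive within-block check of the retained set
    for (b in names(ld)) {
      kept <- intersect(got, rownames(ld[[b]]))
      if (length(kept) > 1) {
        sub <- ld[[b]][kept, kept]^2
        diag(sub) <- 0
        expect_lte(max(sub), 0.05)
      }
    }
  }
})

test_that("threshold tables match the direct chi-square computation", {
  # table [[10, 90], [5, 895]]
  a_p <- c(rep(0.01, 100), rep(0.9, 900))
  b_p <- c(rep(0.01, 10), rep(0.9, 90), rep(0.01, 5), rep(0.9, 895))
  res <- threshold_overlap(a_p, b_p, 0.5)
  expect_equal(unname(res$table[1, ]), c(10, 90))
  expect_equal(res$chi2, 54.3, tolerance = 1e-2)
  oracle <- suppressWarnings(
    stats::chisq.test(res$table, correct = FALSE)
  )
  expect_equal(res$chi2, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(res$p_chi2, oracle$p.value, tolerance = 1e-10)

  # exact independence: proportional counts -> chi2 = 0
  a_p2 <- c(rep(0.1, 50), rep(0.9, 50))
  b_p2 <- c(rep(0.1, 25), rep(0.9, 25), rep(0.1, 25), rep(0.9, 25))
  expect_equal(threshold_overlap(a_p2, b_p2, 0.5)$chi2, 0)

  # zero margin -> undefined
  res0 <- threshold_overlap(rep(0.9, 100), runif(100), 0.5)
  expect_true(is.na(res0$chi2) && is.na(res0$p_chi2))
})

test_that("permutation p-values hit the add-one floor for maximal overlap", {
  set.seed(31)
  p <- c(runif(50, 0, 0.04), runif(950, 0.06, 1))
  res <- permutation_overlap(p, p, overlap_config(
    thresholds = c(0.5, 0.05), n_perm = 999, seed = 4
  ))
  expect_equal(res$p_perm[res$threshold == 0.05], 1 / 1000)
  expect_true(all(res$p_perm >= 1 / 1000))
})

test_that("permutation results agree with per-threshold recomputation", {
  set.seed(32)
  a_p <- runif(400)
  b_p <- runif(400)
  res <- permutation_overlap(a_p, b_p,
                             overlap_config(n_perm = 50, seed = 9))
  for (k in seq_len(nrow(res))) {
    direct <- threshold_overlap(a_p, b_p, res$threshold[k])
    expect_equal(res$n_overlap[k], direct$table[1, 1])
    expect_equal(res$chi2[k], direct$chi2, tolerance = 1e-10)
  }
  # monotone nesting as thresholds tighten
  expect_true(all(diff(res$n_overlap) <= 0))
  expect_true(all(diff(res$n_below_1) <= 0))
})

test_that("p_perm converges to the one-sided chi-square tail under the null", {
  # with near-continuous counts and an enrichment-direction observation, the
  # signed permutation p estimates the one-sided tail p_chi2 / 2
  set.seed(33)
  repeat {
    a_p <- runif(4000)
    b_p <- runif(4000)
    obs <- threshold_overlap(a_p, b_p, 0.5)
    enriched <- obs$table[1, 1] > sum(obs$table[1, ]) *
      sum(obs$table[, 1]) / sum(obs$table)
    if (enriched && obs$p_chi2 > 0.1 && obs$p_chi2 < 0.9) break
  }
  res <- permutation_overlap(a_p, b_p, overlap_config(
    thresholds = 0.5, n_perm = 20000, seed = 10
  ))
  expect_equal(res$p_perm, obs$p_chi2 / 2,
               tolerance = 4 * sqrt(0.25 / 20000) / (obs$p_chi2 / 2))
})

test_that("candidate selection unions overlap hits and coloc top SNPs", {
  pr_a <- mk_ss(c(4, 3.5, 0.1, 3.2, 0.2), ids = paste0("v", 1:5))
  pr_b <- mk_ss(c(4.2, 3.6, 0.1, 0.1, 0.3), ids = paste0("v", 1:5))
  # v1, v2 below 0.005 in both; v4 only in trait 1
  coloc <- tibble::tibble(
    block_id = c("b1", "b2"),
    flagged_h3 = c(TRUE, FALSE), flagged_h4 = c(FALSE, FALSE),
    top_snp_trait1 = c("v9", "v5"), top_snp_trait2 = c("v2", "v5")
  )
  out <- select_candidates(pr_a, pr_b, coloc, p_t = 0.005)
  expect_equal(out$variant_id, c("v1", "v2", "v9"))
  expect_equal(out$source[out$variant_id == "v2"], "both")
  expect_equal(out$source[out$variant_id == "v9"], "coloc_top")

  # no hits, no flags -> empty
  none <- select_candidates(mk_ss(c(0.1, 0.2)), mk_ss(c(0.1, 0.2)),
                            coloc[0, ], p_t = 0.005)
  expect_equal(nrow(none), 0L)

  # one flagged region where the same SNP tops both traits -> deduplicated
  coloc1 <- tibble::tibble(
    block_id = "b1", flagged_h3 = TRUE, flagged_h4 = FALSE,
    top_snp_trait1 = "x1", top_snp_trait2 = "x1"
  )
  one <- select_candidates(mk_ss(0.5), mk_ss(0.5), coloc1)
  expect_equal(one$variant_id, "x1")
})
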