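test_that("reading fills Z from beta/SE and p from Z, and drops invalid rows", {
  df <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    chrom = "1", pos = 1:4,
    effect_allele = "A", other_allele = "G",
    beta = c(0.1, NA, 0.2, 0.05),
    se = c(0.05, NA, 0.1, 0),
    z = c(NA, 2.0, NA, NA),
    pvalue = NA_real_
  )
  s <- as_sumstats(df, trait_name = "toy")
  expect_equal(nrow(s), 3L)            # se = 0 row dropped
  expect_equal(attr(s, "dropped")[["bad_se"]], 1L)

  expect_equal(s$z[s$variant_id == "rs1"], 2.0)
  # Independent tail-probability oracle for p(|Z| > 2).
  p_oracle <- 2 * stats::integrate(stats::dnorm, 2, Inf)$value
  expect_equal(s$pvalue[s$variant_id == "rs2"], p_oracle, tolerance = 1e-8)
  expect_equal(s$pvalue[s$variant_id == "rs2"], 0.0455, tolerance = 1e-3)
})

test_that("odds ratios are converted to log-odds at read time", {
  df <- tibble::tibble(
    variant_id = "rs1", chrom = "1", pos = 1,
    effect_allele = "A", other_allele = "G",
    or = 1.5, se = 0.1
  )
  s <- as_sumstats(df, trait_type = "binary", n_cases = 100, n_controls = 200)
  expect_equal(s$beta, log(1.5))
  expect_equal(s$n, effective_n(100, 200))
})

test_that("validation drops inconsistent, duplicated and malformed rows", {
  df <- tibble::tibble(
    variant_id = c("a", "a", "b", "c", "d", "e"),
    chrom = "1", pos = 1:6,
    effect_allele = c("A", "A", "A", "A", "X", "A"),
    other_allele = c("G", "G", "A", "G", "G", "G"),
    z = c(1, 1, 1, 2, 1, 1.5),
    pvalue = c(NA, NA, NA, 0.5, NA, NA),  # p inconsistent with z = 2
    beta = c(0.1, 0.1, 0.1, -0.2, 0.1, 0.15)  # rs c: sign conflict too
  )
  s <- as_sumstats(df)
  tallies <- attr(s, "dropped")
  expect_equal(s$variant_id, c("a", "e"))
  expect_equal(tallies[["duplicate_id"]], 1L)
  expect_equal(tallies[["bad_allele"]], 2L)  # same-allele and non-ACGT
  expect_equal(sum(tallies), 4L)
})

test_that("write/read round-trips identifiers exactly and reals to 1e-12", {
  set.seed(41)
  s <- mk_ss(rnorm(25), n = 12345.6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(s, path)
  expect_equal(length(readLines(path)), 26L)  # header + 25 records
  back <- read_sumstats(path, trait_name = "toy")
  expect_identical(back$variant_id, s$variant_id)
  expect_identical(back$effect_allele, s$effect_allele)
  expect_equal(back$beta, s$beta, tolerance = 1e-12)
  expect_equal(back$pvalue, s$pvalue, tolerance = 1e-12)
  expect_error(write_sumstats(s[0, ], withr::local_tempfile()), "empty")
})

test_that("read_sumstats applies a column map and rejects bad maps", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SNP CHR BP A1 A2 B SE",
               "rs1 1 100 A G 0.1 0.05",
               "rs2 1 200 T C -0.2 0.1"), path)
  cmap <- c(variant_id = "SNP", chrom = "CHR", pos = "BP",
            effect_allele = "A1", other_allele = "A2", beta = "B", se = "SE")
  s <- read_sumstats(path, cmap)
  expect_equal(s$z, c(2, -2))
  expect_error(read_sumstats(path, c(variant_id = "NOPE")), "absent")
  expect_error(read_sumstats(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("harmonisation aligns swaps and strand flips, drops ambiguous", {
  a <- as_sumstats(tibble::tibble(
    variant_id = c("v1", "v2", "v3", "v4"),
    chrom = "1", pos = 1:4,
    effect_allele = c("A", "A", "A", "A"),
    other_allele = c("G", "G", "T", "G"),
    beta = c(0.1, 0.1, 0.1, 0.1), se = 0.05
  ))
  b <- as_sumstats(tibble::tibble(
    variant_id = c("v1", "v2", "v3", "v4"),
    chrom = "1", pos = 1:4,
    effect_allele = c("G", "T", "A", "C"),   # v1 swap, v2 strand flip,
    other_allele = c("A", "C", "T", "A"),    # v3 ambiguous, v4 mismatch
    beta = c(-0.1, 0.1, 0.1, 0.1), se = 0.05
  ))
  h <- harmonize_pair(a, b)
  expect_equal(h$a$variant_id, c("v1", "v2"))
  expect_equal(h$b$effect_allele, c("A", "A"))
  expect_equal(h$b$beta, c(0.1, 0.1))       # swap negated, flip untouched
  expect_equal(attr(h, "harmonization")[["n_ambiguous_dropped"]], 1L)
  expect_equal(attr(h, "harmonization")[["n_mismatch_dropped"]], 1L)

  kept <- harmonize_pair(a, b, drop_ambiguous = FALSE)
  expect_true("v3" %in% kept$a$variant_id)
  expect_error(harmonize_pair(a[0, ], b), "non-empty")
})

test_that("harmonisation is idempotent and orientation-invariant", {
  set.seed(7)
  for (rep in 1:5) {
    z <- rnorm(40)
    pairs <- matrix(c("A", "G", "T", "C", "A", "C", "G", "T"), nrow = 2)
    k <- sample(1:4, 40, replace = TRUE)
    a <- as_sumstats(tibble::tibble(
      variant_id = sprintf("v%02d", 1:40), chrom = "1", pos = 1:40,
      effect_allele = pairs[1, k], other_allele = pairs[2, k],
      beta = z / 100, se = 1 / 100, z = z, n = 1e4
    ))
    # b: random swaps and strand flips of a, with matching sign changes
    swap <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    flip <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    b_df <- tibble::as_tibble(a)
    ea <- ifelse(swap, b_df$other_allele, b_df$effect_allele)
    oa <- ifelse(swap, b_df$effect_allele, b_df$other_allele)
    b_df$effect_allele <- ifelse(flip, chartr("ACGT", "TGCA", ea), ea)
    b_df$other_allele <- ifelse(flip, chartr("ACGT", "TGCA", oa), oa)
    b_df$beta <- ifelse(swap, -b_df$beta, b_df$beta)
    b_df$z <- ifelse(swap, -b_df$z, b_df$z)
    b <- as_sumstats(b_df)

    h1 <- harmonize_pair(a, b)
    h2 <- harmonize_pair(h1$a, h1$b)
    expect_equal(tibble::as_tibble(h2$b), tibble::as_tibble(h1$b))
    # orientation invariance: b re-expressed on the other strand/order gives
    # the same aligned output
    h_ref <- harmonize_pair(a, a)
    expect_equal(h1$b$z, h_ref$b$z[match(h1$b$variant_id,
                                         h_ref$b$variant_id)])
  }
})

test_that("retained records keep p consistent with z", {
  set.seed(8)
  s <- mk_ss(rnorm(200, sd = 2))
  expect_true(all(abs(2 * pnorm(-abs(s$z)) - s$pvalue) <=
                    1e-6 * s$pvalue))
})
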