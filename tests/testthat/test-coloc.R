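test_that("Wakefield ABFs match their closed form", {
  # z = 0, V = 1, W = 0.04: ABF = sqrt(1 / 1.04)
  expect_equal(wakefield_abf(0, 1, 0.04), log(sqrt(1 / 1.04)))
  expect_equal(exp(wakefield_abf(0, 1, 0.04)), 0.9806, tolerance = 1e-4)
  # z = 5, se = 0.1, W = 0.04: ABF = sqrt(0.2) * exp(10)
  expect_equal(exp(wakefield_abf(5, 0.1, 0.04)), sqrt(0.2) * exp(10))
  expect_equal(exp(wakefield_abf(5, 0.1, 0.04)), 9.85e3, tolerance = 1e-3)
  # prior collapsing to the null: W -> 0 gives ABF -> 1
  expect_lt(abs(wakefield_abf(3, 0.5, 1e-12)), 1e-10)
  expect_error(wakefield_abf(1, 0, 0.04), "se")
  expect_error(wakefield_abf(1, 0.1, -1), "W")
})

test_that("the joint ABF factorises at c = 0 and matches the density ratio", {
  pr <- coloc_priors()
  set.seed(70)
  z1 <- rnorm(500, 0, 3); z2 <- rnorm(500, 0, 3)
  se1 <- runif(500, 0.01, 1); se2 <- runif(500, 0.01, 1)
  expect_equal(
    joint_shared_abf(z1, z2, se1, se2, pr, c = 0),
    wakefield_abf(z1, se1, pr$W1) + wakefield_abf(z2, se2, pr$W2),
    tolerance = 1e-13
  )
  # independent oracle at c != 0: explicit bivariate normal log-densities
  ldmvn2 <- function(x, y, v1, v2, cv) {
    det <- v1 * v2 - cv^2
    -log(2 * pi) - 0.5 * log(det) -
      0.5 * (v2 * x^2 + v1 * y^2 - 2 * cv * x * y) / det
  }
  cc <- 0.4
  got <- joint_shared_abf(z1, z2, se1, se2, pr, c = cc)
  want <- ldmvn2(z1, z2, 1 + pr$W1 / se1^2, 1 + pr$W2 / se2^2, cc) -
    ldmvn2(z1, z2, 1, 1, cc)
  expect_equal(got, want, tolerance = 1e-10)
  expect_error(joint_shared_abf(1, 1, 0.1, 0.1, pr, c = 1), "c")
})

test_that("at z = 0 the joint ABF is the negative determinant term", {
  pr <- coloc_priors()
  for (cc in c(0, 0.3, -0.5)) {
    got <- joint_shared_abf(0, 0, 0.2, 0.3, pr, c = cc)
    s1 <- 1 + pr$W1 / 0.04; s2 <- 1 + pr$W2 / 0.09
    expect_equal(got, 0.5 * log((1 - cc^2) / (s1 * s2 - cc^2)))
    expect_lt(got, 0)
  }
})

test_that("the shared-causal BF decreases with overlap at concordant signals", {
  pr <- coloc_priors()
  vals <- vapply(seq(0, 0.8, by = 0.1), function(cc) {
    joint_shared_abf(4, 4, 0.1, 0.1, pr, c = cc)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("regional posteriors behave structurally", {
  pr <- coloc_priors()
  # no evidence anywhere: H0 wins
  reg0 <- tibble::tibble(variant_id = sprintf("v%d", 1:50),
                         z1 = 0, se1 = 0.01, z2 = 0, se2 = 0.01)
  pp0 <- region_posteriors(reg0, pr)
  expect_equal(which.max(unlist(pp0[paste0("pp_h", 0:4)])), c(pp_h0 = 1L))

  # single-SNP region with strong shared signal: H3, and H4 structurally 0
  reg1 <- tibble::tibble(variant_id = "v1", z1 = 8, se1 = 0.1,
                         z2 = 8, se2 = 0.1)
  pp1 <- region_posteriors(reg1, pr)
  expect_identical(pp1$pp_h4, 0)
  expect_gt(pp1$pp_h3, 0.99)
  expect_error(region_posteriors(reg1[0, ], pr), "at least one")

  # posteriors sum to one, even at extreme Z
  set.seed(71)
  for (i in 1:20) {
    k <- sample(1:40, 1)
    reg <- tibble::tibble(
      variant_id = sprintf("v%d", seq_len(k)),
      z1 = rnorm(k, 0, 12), se1 = runif(k, 0.01, 0.5),
      z2 = rnorm(k, 0, 12), se2 = runif(k, 0.01, 0.5)
    )
    pp <- region_posteriors(reg, pr)
    expect_lt(abs(sum(pp[paste0("pp_h", 0:4)]) - 1), 1e-9)
  }
})

test_that("swapping the traits swaps H1 and H2 and fixes H0/H3/H4", {
  pr <- coloc_priors()  # symmetric priors
  set.seed(72)
  reg <- tibble::tibble(
    variant_id = sprintf("v%d", 1:15),
    z1 = rnorm(15, 0, 4), se1 = runif(15, 0.05, 0.3),
    z2 = rnorm(15, 0, 2), se2 = runif(15, 0.05, 0.3)
  )
  fwd <- region_posteriors(reg, pr, c = 0.2)
  swp <- region_posteriors(
    dplyr::rename(reg, z1 = "z2", z2 = "z1", se1 = "se2", se2 = "se1"),
    pr, c = 0.2
  )
  expect_equal(swp$pp_h1, fwd$pp_h2, tolerance = 1e-12)
  expect_equal(swp$pp_h2, fwd$pp_h1, tolerance = 1e-12)
  expect_equal(swp$pp_h0, fwd$pp_h0, tolerance = 1e-12)
  expect_equal(swp$pp_h3, fwd$pp_h3, tolerance = 1e-12)
  expect_equal(swp$pp_h4, fwd$pp_h4, tolerance = 1e-12)
})

test_that("posteriors match brute-force configuration enumeration", {
  pr <- coloc_priors()
  set.seed(73)
  for (i in 1:30) {
    k <- sample(1:5, 1)
    reg <- tibble::tibble(
      variant_id = sprintf("v%d", seq_len(k)),
      z1 = rnorm(k, 0, 3), se1 = runif(k, 0.05, 0.5),
      z2 = rnorm(k, 0, 3), se2 = runif(k, 0.05, 0.5)
    )
    got <- unlist(region_posteriors(reg, pr, c = 0)[paste0("pp_h", 0:4)])
    want <- oracle_coloc_pp(reg$z1, reg$se1, reg$z2, reg$se2, pr)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("the genome scan flags simulated shared-causal regions", {
  sc_h3 <- make_coloc_scenarios("H3", n_regions = 4, n_snps = 30,
                                effect_z = 8, seed = 80)
  sc_h0 <- make_coloc_scenarios("H0", n_regions = 16, n_snps = 30, seed = 81)
  sc_h0$scenarios$block_id <- sub("^r", "q", sc_h0$scenarios$block_id)
  names(sc_h0$ld) <- sub("^r", "q", names(sc_h0$ld))
  for (nm in names(sc_h0$ld)) {
    rownames(sc_h0$ld[[nm]]) <- colnames(sc_h0$ld[[nm]]) <-
      sub("^r", "q", rownames(sc_h0$ld[[nm]]))
  }
  scen <- dplyr::bind_rows(sc_h3$scenarios, sc_h0$scenarios)
  ld <- c(sc_h3$ld, sc_h0$ld)
  sim <- simulate_coloc_regions(scen, ld, seed = 82)
  scan <- genome_coloc_scan(sim$a, sim$b, sim$blocks)
  expect_equal(nrow(scan), 20L)
  flagged <- scan$block_id[scan$flagged_h3]
  expect_setequal(flagged, sc_h3$scenarios$block_id)
  expect_false(any(scan$flagged_h4))
  # sorted by pleiotropy evidence
  key <- pmax(scan$pp_h3, scan$pp_h4)
  expect_true(all(diff(key) <= 1e-12))

  # single-block input gives a single row
  sel <- grepl(paste0("^", scen$block_id[1], "_"), sim$a$variant_id)
  one <- genome_coloc_scan(sim$a[sel, ], sim$b[sel, ], sim$blocks)
  expect_equal(nrow(one), 1L)
})
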