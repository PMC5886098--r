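test_that("the generator is deterministic and validates its config", {
  cfg <- sim_config(m_snps = 500, block_size = 25, seed = 42)
  s1 <- simulate_polygenic_pair(cfg)
  s2 <- simulate_polygenic_pair(cfg)
  expect_identical(s1$a$z, s2$a$z)
  expect_identical(s1$b$z, s2$b$z)
  expect_identical(s1$truth$beta_1, s2$truth$beta_1)

  expect_error(sim_config(m_snps = 0), "m_snps")
  expect_error(sim_config(rg = 1.5))
  expect_error(sim_config(overlap_c = 1))
})

test_that("pure null draws are standard normal with the requested overlap", {
  cfg <- sim_config(
    m_snps = 20000, ld_rho = 0, h2_1 = 0, h2_2 = 0, rg = 0,
    overlap_c = 0, n1 = 20000, n2 = 20000,
    trait_types = c("quantitative", "quantitative"), seed = 3
  )
  sim <- simulate_polygenic_pair(cfg)
  expect_equal(mean(sim$a$z^2), 1, tolerance = 0.05)
  expect_equal(mean(sim$b$z^2), 1, tolerance = 0.05)
  # fraction of p < 0.05 within 3 binomial SEs of 0.05
  for (p in list(sim$a$pvalue, sim$b$pvalue)) {
    expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 20000))
  }
  # cross-trait correlation ~ overlap_c under shared samples
  cfg2 <- sim_config(
    m_snps = 50000, ld_rho = 0, h2_1 = 0, h2_2 = 0, rg = 0,
    overlap_c = 0.3, n1 = 20000, n2 = 20000,
    trait_types = c("quantitative", "quantitative"), seed = 4
  )
  sim2 <- simulate_polygenic_pair(cfg2)
  expect_equal(cor(sim2$a$z, sim2$b$z), 0.3, tolerance = 0.011)
})

test_that("true effect draws recover the target bivariate covariance", {
  cfg <- sim_config(
    m_snps = 50000, ld_rho = 0, h2_1 = 0.4, h2_2 = 0.6, rg = -0.5,
    n1 = 1e4, n2 = 1e4, trait_types = c("quantitative", "quantitative"),
    seed = 9
  )
  sim <- simulate_polygenic_pair(cfg)
  B <- cbind(sim$truth$beta_1, sim$truth$beta_2)
  emp <- crossprod(B)  # m * sample covariance (mean ~ 0)
  expect_equal(emp[1, 1], 0.4, tolerance = 0.02)
  expect_equal(emp[2, 2], 0.6, tolerance = 0.02)
  expect_equal(emp[1, 2], -0.5 * sqrt(0.24), tolerance = 0.02)
})

test_that("null Z covariance within a block converges to the LD matrix", {
  cfg <- function(seed, m) sim_config(
    m_snps = m, block_size = 10, ld_rho = 0.6, h2_1 = 0, h2_2 = 0, rg = 0,
    n1 = 1e4, n2 = 1e4, trait_types = c("quantitative", "quantitative"),
    seed = seed
  )
  frob <- function(m) {
    sim <- simulate_polygenic_pair(cfg(11, m))
    Z <- matrix(sim$a$z, nrow = 10)  # blocks in columns, identical structure
    norm(tcrossprod(Z) / ncol(Z) - ar1_corr(10, 0.6), "F")
  }
  expect_lt(frob(20000), frob(1000))
})

test_that("coloc-region simulation propagates effects through LD", {
  # H3 with identity LD: E[z] = effect_z at the causal SNP for both traits
  sc <- make_coloc_scenarios("H3", n_regions = 200, n_snps = 5,
                             effect_z = 8, rho = 0, seed = 21)
  sim <- simulate_coloc_regions(sc$scenarios, sc$ld, seed = 22)
  at_causal <- match(sc$scenarios$causal1, sim$a$variant_id)
  expect_equal(mean(sim$a$z[at_causal]), 8, tolerance = 3 / sqrt(200))
  expect_equal(mean(sim$b$z[at_causal]), 8, tolerance = 3 / sqrt(200))

  # H0: all Z centred at zero
  sc0 <- make_coloc_scenarios("H0", n_regions = 100, n_snps = 10, seed = 23)
  sim0 <- simulate_coloc_regions(sc0$scenarios, sc0$ld, seed = 24)
  expect_equal(mean(sim0$a$z), 0, tolerance = 4 / sqrt(1000))
  expect_equal(mean(sim0$b$z^2), 1, tolerance = 0.15)

  # H1 with AR(1) rho = 0.5, causal mid-SNP of 3, effect 6:
  # flanking E[z1] = r * 6 = 3, trait 2 stays null
  ld <- lapply(1:300, function(i) {
    ld_matrix(ar1_corr(3, 0.5), sprintf("r%03d_s%d", i, 1:3))
  })
  names(ld) <- sprintf("r%03d", 1:300)
  scen <- tibble::tibble(
    block_id = names(ld), hypothesis = "H1",
    causal1 = sprintf("%s_s2", names(ld)), causal2 = NA_character_,
    effect_z = 6
  )
  sim1 <- simulate_coloc_regions(scen, ld, seed = 25)
  flank <- sim1$a$z[grepl("_s1$|_s3$", sim1$a$variant_id)]
  expect_equal(mean(flank), 3, tolerance = 3 / sqrt(600))
  expect_equal(mean(sim1$b$z), 0, tolerance = 4 / sqrt(900))
})

test_that("scenario validation rejects inconsistent causal configurations", {
  sc <- make_coloc_scenarios("H4", n_regions = 1, n_snps = 4, seed = 1)
  bad <- sc$scenarios
  bad$causal2 <- bad$causal1
  expect_error(simulate_coloc_regions(bad, sc$ld), "distinct")
  bad2 <- sc$scenarios
  bad2$causal1 <- "nonexistent"
  expect_error(simulate_coloc_regions(bad2, sc$ld), "not in block")
  bad3 <- sc$scenarios
  bad3$hypothesis <- "H0"
  expect_error(simulate_coloc_regions(bad3, sc$ld), "H0")
})

test_that("fixtures are complete and digest-stable across identical seeds", {
  cfg <- sim_config(m_snps = 200, block_size = 20, seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- make_fixture(cfg, d1, replication_n = 15000)
  make_fixture(cfg, d2, replication_n = 15000)
  expect_gte(nrow(m1), 5)
  expect_true(all(file.exists(m1$path)))
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("replication cohorts share the truth but not the noise", {
  cfg <- sim_config(m_snps = 2000, block_size = 20, h2_1 = 0.8, rg = 0,
                    n1 = 5e4, n2 = 5e4, seed = 13,
                    trait_types = c("quantitative", "quantitative"))
  sim <- simulate_polygenic_pair(cfg)
  rep1 <- simulate_replication(sim$truth, sim$ld, n = 5e4, seed = 1)
  rep2 <- simulate_replication(sim$truth, sim$ld, n = 5e4, seed = 1)
  rep3 <- simulate_replication(sim$truth, sim$ld, n = 5e4, seed = 2)
  expect_identical(rep1$z, rep2$z)
  expect_false(identical(rep1$z, rep3$z))
  # correlated with the discovery study through the shared true effects
  expect_gt(cor(rep1$z, sim$a$z), 0.5)
})
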