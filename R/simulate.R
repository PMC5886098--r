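# Synthetic paired GWAS summary statistics with known truth.
#
# The generator emulates a case-control ("OA-like") plus quantitative
# ("BMD-like") pair of studies: block-diagonal AR(1) LD, per-SNP true effects
# from a bivariate polygenic model with tunable genetic correlation, and
# correlated null noise standing in for shared samples. Within each block the
# observed Z-vectors are
#   Z_t = R %*% lambda_t + eps_t,   lambda_t = sqrt(n_t) * beta_t,
# where R is the block LD matrix, each trait's noise has covariance R, and the
# cross-trait noise covariance is overlap_c * R. Betas and SEs are back-filled
# on the standardised-genotype scale as beta = z / sqrt(n), se = 1 / sqrt(n).

#' Configuration for the paired-GWAS simulator
#'
#' Defaults mirror the study the package targets: a combined hip/knee OA-like
#' binary trait (7,410 cases, 11,009 controls; effective n about 17,716) paired
#' with a lumbar-spine-BMD-like quantitative trait (n = 31,800), genetic
#' correlation 0.18, modest SNP heritabilities, and AR(1) LD in blocks of 50.
#'
#' @param m_snps Number of variants (>= 1).
#' @param block_size Variants per LD block.
#' @param ld_rho AR(1) correlation within a block; 0 gives identity LD. A
#'   vector is recycled across blocks (the default mixes weak to strong LD,
#'   emulating the heterogeneity of real genomes and giving LD scores enough
#'   spread for the regression estimators to be well conditioned).
#' @param n_cases,n_controls Case/control counts for the binary trait-1.
#' @param n1 Trait-1 sample size; defaults to the effective sample size
#'   implied by `n_cases`/`n_controls` when trait 1 is binary.
#' @param n2 Trait-2 sample size.
#' @param trait_types Pair of `"binary"`/`"quantitative"`.
#' @param h2_1,h2_2 SNP heritabilities in \[0, 1\].
#' @param rg Genetic correlation in \[-1, 1\].
#' @param overlap_c Cross-trait null Z-score correlation induced by shared
#'   samples, in (-1, 1).
#' @param seed Integer seed; all randomness flows from it.
#' @param trait_names Labels for the two traits.
#' @return A `sim_config` list.
#' @export
sim_config <- function(m_snps = 20000, block_size = 50,
                       ld_rho = c(0, 0.3, 0.6, 0.9),
                       n_cases = 7410, n_controls = 11009,
                       n1 = NULL, n2 = 31800,
                       trait_types = c("binary", "quantitative"),
                       h2_1 = 0.25, h2_2 = 0.30, rg = 0.18,
                       overlap_c = 0.05, seed = 1L,
                       trait_names = c("OA_like", "BMD_like")) {
  if (m_snps < 1) stop("m_snps must be >= 1")
  stopifnot(
    block_size >= 1, length(ld_rho) >= 1, all(abs(ld_rho) < 1),
    h2_1 >= 0, h2_1 <= 1, h2_2 >= 0, h2_2 <= 1,
    abs(rg) <= 1, abs(overlap_c) < 1,
    length(trait_types) == 2, all(trait_types %in% c("binary", "quantitative"))
  )
  if (is.null(n1)) {
    n1 <- if (trait_types[1] == "binary") effective_n(n_cases, n_controls)
          else stop("n1 required for a quantitative trait 1")
  }
  stopifnot(n1 > 0, n2 > 0)
  structure(
    list(m_snps = as.integer(m_snps), block_size = as.integer(block_size),
         ld_rho = ld_rho, n_cases = n_cases, n_controls = n_controls,
         n1 = n1, n2 = n2, trait_types = trait_types,
         h2_1 = h2_1, h2_2 = h2_2, rg = rg, overlap_c = overlap_c,
         seed = as.integer(seed), trait_names = trait_names),
    class = "sim_config"
  )
}

# Deterministic variant ids, positions, alleles and block layout for a config.
sim_layout <- function(cfg) {
  m <- cfg$m_snps
  bs <- cfg$block_size
  nb <- ceiling(m / bs)
  block_of <- (seq_len(m) - 1L) %/% bs + 1L
  block_id <- sprintf("b%05d", seq_len(nb))
  blocks <- as_ld_blocks(tibble::tibble(
    chrom = "1",
    start = (seq_len(nb) - 1L) * bs + 1,
    stop = pmin(seq_len(nb) * bs, m) + 1,
    block_id = block_id
  ))
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), nrow = 2)
  k <- (seq_len(m) - 1L) %% 4L + 1L
  tibble::tibble(
    variant_id = sprintf("rs%07d", seq_len(m)),
    chrom = "1",
    pos = seq_len(m),
    effect_allele = pairs[1, k],
    other_allele = pairs[2, k],
    block_id = block_id[block_of]
  )
}

# Per-block LD matrices for a config: AR(1) with the rho values recycled
# across blocks in order.
sim_ld <- function(cfg, layout = sim_layout(cfg)) {
  bids <- unique(layout$block_id)
  split_ids <- split(layout$variant_id, layout$block_id)[bids]
  rho <- rep_len(cfg$ld_rho, length(bids))
  mats <- lapply(seq_along(bids), function(k) {
    ids <- split_ids[[k]]
    ld_matrix(ar1_corr(length(ids), rho[k]), ids)
  })
  names(mats) <- bids
  mats
}

# Draw block-wise Z-scores for two traits given per-variant non-centrality
# vectors lam1, lam2 (already on the Z scale) and the layout/LD of `cfg`-style
# blocks. Noise is jointly normal with per-trait covariance R and cross-trait
# covariance overlap_c * R. Consumes RNG.
draw_block_z <- function(lam1, lam2, block_of, mats, overlap_c) {
  m <- length(lam1)
  z1 <- numeric(m)
  z2 <- numeric(m)
  # Cache the symmetric square roots across structurally identical blocks.
  sqrt_cache <- list()
  for (bid in names(mats)) {
    R <- mats[[bid]]
    key <- ld_sig(R)
    if (is.null(sqrt_cache[[key]])) sqrt_cache[[key]] <- sym_sqrt(R)
    S <- sqrt_cache[[key]]
    idx <- which(block_of == bid)
    a1 <- rnorm(length(idx))
    a2 <- overlap_c * a1 + sqrt(1 - overlap_c^2) * rnorm(length(idx))
    z1[idx] <- R %*% lam1[idx] + S %*% a1
    z2[idx] <- R %*% lam2[idx] + S %*% a2
  }
  list(z1 = z1, z2 = z2)
}

sim_sumstats_from_z <- function(layout, z, n, trait_name, trait_type,
                                n_cases = NULL, n_controls = NULL) {
  df <- layout[c("variant_id", "chrom", "pos", "effect_allele", "other_allele")]
  df$beta <- z / sqrt(n)
  df$se <- 1 / sqrt(n)
  df$z <- z
  df$pvalue <- two_sided_p(z)
  df$n <- n
  as_sumstats(df, trait_name = trait_name, trait_type = trait_type,
              n_cases = n_cases, n_controls = n_controls)
}

#' Simulate a pair of polygenic GWAS with block LD and sample overlap
#'
#' Per-SNP true effects are bivariate normal with variances `h2_i / m` and
#' covariance `rg * sqrt(h2_1 * h2_2) / m`; observed Z-scores propagate
#' through block LD and carry correlated null noise (see the module notes
#' above). Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `gwas_sim` list: `a`, `b` (`sumstats`), `truth` (per-variant true
#'   betas and block assignment), `blocks` (`ld_blocks`), `ld` (named list of
#'   block LD matrices).
#' @export
simulate_polygenic_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- cfg$m_snps
  layout <- sim_layout(cfg)
  mats <- sim_ld(cfg, layout)

  set.seed(cfg$seed)
  cov_b <- matrix(c(cfg$h2_1, cfg$rg * sqrt(cfg$h2_1 * cfg$h2_2),
                    cfg$rg * sqrt(cfg$h2_1 * cfg$h2_2), cfg$h2_2), 2) / m
  B <- matrix(rnorm(2 * m), ncol = 2) %*% sym_sqrt(cov_b)
  lam1 <- sqrt(cfg$n1) * B[, 1]
  lam2 <- sqrt(cfg$n2) * B[, 2]
  zz <- draw_block_z(lam1, lam2, layout$block_id, mats, cfg$overlap_c)

  a <- sim_sumstats_from_z(
    layout, zz$z1, cfg$n1, cfg$trait_names[1], cfg$trait_types[1],
    n_cases = if (cfg$trait_types[1] == "binary") cfg$n_cases,
    n_controls = if (cfg$trait_types[1] == "binary") cfg$n_controls
  )
  b <- sim_sumstats_from_z(layout, zz$z2, cfg$n2, cfg$trait_names[2],
                           cfg$trait_types[2])
  truth <- layout
  truth$beta_1 <- B[, 1]
  truth$beta_2 <- B[, 2]
  attr(truth, "params") <- cfg[c("h2_1", "h2_2", "rg", "overlap_c", "seed",
                                 "n1", "n2", "m_snps")]
  structure(list(a = a, b = b, truth = truth, blocks = sim_layout_blocks(cfg),
                 ld = mats),
            class = "gwas_sim")
}

sim_layout_blocks <- function(cfg) {
  m <- cfg$m_snps
  bs <- cfg$block_size
  nb <- ceiling(m / bs)
  as_ld_blocks(tibble::tibble(
    chrom = "1",
    start = (seq_len(nb) - 1L) * bs + 1,
    stop = pmin(seq_len(nb) * bs, m) + 1,
    block_id = sprintf("b%05d", seq_len(nb))
  ))
}

#' Build regional causal scenarios for the five colocalisation hypotheses
#'
#' Convenience constructor for [simulate_coloc_regions()]: `n_regions` blocks
#' per requested hypothesis, each with `n_snps` variants under AR(1) LD with
#' correlation `rho`, causal variants drawn at random (H4 draws two distinct
#' ones), all with non-centrality `effect_z`.
#'
#' @param hypotheses Subset of `"H0"`..`"H4"`.
#' @param n_regions Regions per hypothesis (recycled along `hypotheses`).
#' @param n_snps Variants per region.
#' @param effect_z Non-centrality (Z scale) at causal variants.
#' @param rho AR(1) LD correlation inside each region.
#' @param seed Integer seed for the causal-variant draws.
#' @return List with `scenarios` (tibble: `block_id`, `hypothesis`,
#'   `causal1`, `causal2`, `effect_z`) and `ld` (named list of LD matrices).
#' @export
make_coloc_scenarios <- function(hypotheses = c("H0", "H1", "H2", "H3", "H4"),
                                 n_regions = 1, n_snps = 50, effect_z = 8,
                                 rho = 0, seed = 1L) {
  stopifnot(all(hypotheses %in% paste0("H", 0:4)), n_snps >= 1)
  if ("H4" %in% hypotheses && n_snps < 2) stop("H4 needs >= 2 SNPs")
  set.seed(seed)
  n_regions <- rep_len(n_regions, length(hypotheses))
  rows <- list()
  mats <- list()
  i <- 0L
  for (hi in seq_along(hypotheses)) {
    h <- hypotheses[hi]
    for (r in seq_len(n_regions[hi])) {
      i <- i + 1L
      bid <- sprintf("r%05d", i)
      ids <- sprintf("%s_s%03d", bid, seq_len(n_snps))
      mats[[bid]] <- ld_matrix(ar1_corr(n_snps, rho), ids)
      causal <- if (h == "H0") c(NA_character_, NA_character_)
        else if (h == "H4") c(sample(ids, 2), recursive = TRUE)
        else c(sample(ids, 1), NA_character_)
      rows[[i]] <- tibble::tibble(
        block_id = bid, hypothesis = h,
        causal1 = causal[1], causal2 = causal[2], effect_z = effect_z
      )
    }
  }
  list(scenarios = dplyr::bind_rows(rows), ld = mats)
}

#' Simulate regional summary statistics under colocalisation scenarios
#'
#' Each region follows one of the five hypotheses: H0 no causal variant; H1/H2
#' one causal variant for trait 1/trait 2 only; H3 one shared causal variant;
#' H4 two distinct causal variants, `causal1` for trait 1 and `causal2` for
#' trait 2. The trait-specific non-centrality vector (value `effect_z` at the
#' causal variant, 0 elsewhere) is propagated through LD as `R %*% lambda`;
#' noise is as in [simulate_polygenic_pair()].
#'
#' @param scenarios Tibble with `block_id`, `hypothesis`, `causal1`,
#'   `causal2`, `effect_z` (see [make_coloc_scenarios()]).
#' @param ld Named list of per-block LD matrices covering every `block_id`.
#' @param overlap_c Cross-trait null Z correlation.
#' @param n1,n2 Nominal sample sizes used to back-fill betas and SEs.
#' @param seed Integer seed.
#' @return A `gwas_sim` list as for [simulate_polygenic_pair()], with `truth`
#'   carrying the scenario labels.
#' @export
simulate_coloc_regions <- function(scenarios, ld, overlap_c = 0,
                                   n1 = 10000, n2 = 10000, seed = 1L) {
  scenarios <- tibble::as_tibble(scenarios)
  stopifnot(all(c("block_id", "hypothesis", "effect_z") %in% names(scenarios)))
  if (!"causal2" %in% names(scenarios)) scenarios$causal2 <- NA_character_
  missing_ld <- setdiff(scenarios$block_id, names(ld))
  if (length(missing_ld)) stop("no LD matrix for block(s): ",
                               paste(missing_ld, collapse = ", "))

  # Validate causal configurations against their hypotheses and blocks.
  for (r in seq_len(nrow(scenarios))) {
    sc <- scenarios[r, ]
    ids <- rownames(ld[[sc$block_id]])
    h <- sc$hypothesis
    c1 <- sc$causal1
    c2 <- sc$causal2
    if (h == "H0" && (!is.na(c1) || !is.na(c2))) stop("H0 takes no causal ids")
    if (h %in% c("H1", "H2", "H3") && (is.na(c1) || !is.na(c2))) {
      stop(h, " takes exactly one causal id")
    }
    if (h == "H4") {
      if (is.na(c1) || is.na(c2)) stop("H4 takes two causal ids")
      if (c1 == c2) stop("H4 causal ids must be distinct")
    }
    for (cc in c(c1, c2)) {
      if (!is.na(cc) && !(cc %in% ids)) stop("causal variant ", cc,
                                             " not in block ", sc$block_id)
    }
  }

  set.seed(seed)
  offset <- 0
  out1 <- list()
  out2 <- list()
  blocks <- list()
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), nrow = 2)
  for (r in seq_len(nrow(scenarios))) {
    sc <- scenarios[r, ]
    R <- ld[[sc$block_id]]
    ids <- rownames(R)
    k <- length(ids)
    lam1 <- lam2 <- numeric(k)
    if (sc$hypothesis %in% c("H1", "H3", "H4")) {
      lam1[match(sc$causal1, ids)] <- sc$effect_z
    }
    if (sc$hypothesis == "H2") lam2[match(sc$causal1, ids)] <- sc$effect_z
    if (sc$hypothesis == "H3") lam2[match(sc$causal1, ids)] <- sc$effect_z
    if (sc$hypothesis == "H4") lam2[match(sc$causal2, ids)] <- sc$effect_z

    S <- sym_sqrt(R)
    a1 <- rnorm(k)
    a2 <- overlap_c * a1 + sqrt(1 - overlap_c^2) * rnorm(k)
    z1 <- drop(R %*% lam1 + S %*% a1)
    z2 <- drop(R %*% lam2 + S %*% a2)

    ai <- (seq_len(k) - 1L) %% 4L + 1L
    layout <- tibble::tibble(
      variant_id = ids, chrom = "1", pos = offset + seq_len(k),
      effect_allele = pairs[1, ai], other_allele = pairs[2, ai],
      block_id = sc$block_id
    )
    blocks[[r]] <- tibble::tibble(chrom = "1", start = offset + 1,
                                  stop = offset + k + 1,
                                  block_id = sc$block_id)
    out1[[r]] <- layout |> dplyr::mutate(z = z1)
    out2[[r]] <- layout |> dplyr::mutate(z = z2)
    offset <- offset + k
  }

  l1 <- dplyr::bind_rows(out1)
  l2 <- dplyr::bind_rows(out2)
  mk <- function(l, n, nm) {
    sim_sumstats_from_z(l, l$z, n, nm, "quantitative")
  }
  structure(
    list(
      a = mk(l1, n1, "trait1"), b = mk(l2, n2, "trait2"),
      truth = scenarios,
      blocks = as_ld_blocks(dplyr::bind_rows(blocks)),
      ld = ld[unique(scenarios$block_id)]
    ),
    class = "gwas_sim"
  )
}

#' Simulate a replication cohort from known true effects
#'
#' Draws an independent study of size `n` for the trait whose true per-SD
#' effects are in `truth` (column `beta_1` or `beta_2`), using the same block
#' LD. Used to emulate in-silico replication cohorts.
#'
#' @param truth Truth table from [simulate_polygenic_pair()].
#' @param ld Named list of block LD matrices.
#' @param n Sample size of the replication cohort.
#' @param trait Which trait's effects to replicate (1 or 2).
#' @param trait_name,trait_type Metadata for the returned table.
#' @param seed Integer seed.
#' @return A `sumstats` tibble.
#' @export
simulate_replication <- function(truth, ld, n, trait = 1,
                                 trait_name = "replication",
                                 trait_type = "binary", seed = 1L) {
  stopifnot(trait %in% c(1, 2), n > 0)
  beta <- truth[[paste0("beta_", trait)]]
  set.seed(seed)
  lam <- sqrt(n) * beta
  z <- numeric(nrow(truth))
  sqrt_cache <- list()
  for (bid in unique(truth$block_id)) {
    R <- ld[[bid]]
    key <- ld_sig(R)
    if (is.null(sqrt_cache[[key]])) sqrt_cache[[key]] <- sym_sqrt(R)
    idx <- which(truth$block_id == bid)
    z[idx] <- R %*% lam[idx] + sqrt_cache[[key]] %*% rnorm(length(idx))
  }
  sim_sumstats_from_z(truth, z, n, trait_name, trait_type)
}

#' Write a complete synthetic fixture to disk
#'
#' Materialises a simulated study pair as the file set the pipeline reads:
#' two summary-statistics tables, a block file, per-block LD matrices, the
#' truth table, optional replication cohorts, and the realised configuration.
#' Identical seeds give identical file digests.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param replication_n Sample sizes of trait-1 replication cohorts to write
#'   (default two cohorts; use `NULL` for none).
#' @return Invisibly, a tibble manifest of the files written.
#' @export
make_fixture <- function(cfg, out_dir, replication_n = c(30000, 50000)) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_polygenic_pair(cfg)

  paths <- c(
    sumstats1 = file.path(out_dir, "trait1.sumstats.tsv"),
    sumstats2 = file.path(out_dir, "trait2.sumstats.tsv"),
    blocks = file.path(out_dir, "blocks.bed"),
    truth = file.path(out_dir, "truth.tsv"),
    config = file.path(out_dir, "sim_config.json")
  )
  write_sumstats(sim$a, paths[["sumstats1"]])
  write_sumstats(sim$b, paths[["sumstats2"]])
  write_blocks(sim$blocks, paths[["blocks"]])
  readr::write_tsv(tibble::as_tibble(sim$truth), paths[["truth"]],
                   progress = FALSE)
  write_ld_collection(sim$ld, file.path(out_dir, "ld"))
  jsonlite::write_json(unclass(cfg), paths[["config"]], auto_unbox = TRUE,
                       digits = NA)

  rep_paths <- character(0)
  for (i in seq_along(replication_n)) {
    p <- file.path(out_dir, sprintf("replication_%d.sumstats.tsv", i))
    rs <- simulate_replication(
      sim$truth, sim$ld, n = replication_n[i], trait = 1,
      trait_name = sprintf("replication_%d", i),
      trait_type = cfg$trait_types[1], seed = derive_seed(cfg$seed, 100 + i)
    )
    write_sumstats(rs, p)
    rep_paths <- c(rep_paths, p)
  }

  manifest <- tibble::tibble(
    role = c(names(paths), rep("replication", length(rep_paths)), "ld_dir"),
    path = c(unname(paths), rep_paths, file.path(out_dir, "ld"))
  )
  invisible(manifest)
}
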