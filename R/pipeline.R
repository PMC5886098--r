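# End-to-end orchestration: harmonise -> genetic correlation -> overlap ->
# colocalisation -> cross-phenotype statistics -> candidate selection ->
# replication meta-analysis and sign test, with per-stage reports, a run
# manifest, and seeded determinism.

#' Pipeline configuration
#'
#' Collects the file paths, per-stage settings and seed for [run_pipeline()].
#' All paths are validated up front; every output records the seed.
#'
#' @param sumstats1,sumstats2 Paths to the two discovery summary-statistics
#'   tables (trait 1 plays the sorting/OA-like role, trait 2 the
#'   permuted/BMD-like role).
#' @param blocks Path to the BED-like LD-block file.
#' @param ld_dir Directory of per-block `.ld` matrices.
#' @param out_dir Output directory for reports.
#' @param replication Character vector of paths to trait-1 replication
#'   cohorts (may be empty; the meta stage then pools the discovery cohort
#'   only).
#' @param trait1_name,trait2_name,trait1_type,trait2_type Trait metadata.
#' @param n_cases,n_controls Case/control counts when trait 1 is binary.
#' @param overlap An [overlap_config()].
#' @param priors A [coloc_priors()].
#' @param tau_grid,n_mc S_het settings (see [s_het()]).
#' @param candidate_p Overlap threshold for candidate selection
#'   (default 0.005).
#' @param n_blocks_jackknife LDSC jackknife blocks.
#' @param stages Character subset of
#'   `c("rg", "overlap", "coloc", "cpassoc", "meta")` to run.
#' @param seed Top-level integer seed; stages draw from derived substreams.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sumstats1, sumstats2, blocks, ld_dir, out_dir,
                            replication = character(0),
                            trait1_name = "trait1", trait2_name = "trait2",
                            trait1_type = "binary",
                            trait2_type = "quantitative",
                            n_cases = NULL, n_controls = NULL,
                            overlap = overlap_config(),
                            priors = coloc_priors(),
                            tau_grid = c(0, 0.5, 1, 1.5, 2, 2.5, 3),
                            n_mc = 5000,
                            candidate_p = 0.005,
                            n_blocks_jackknife = 200,
                            stages = c("rg", "overlap", "coloc", "cpassoc",
                                       "meta"),
                            seed = 1L) {
  paths <- c(sumstats1 = sumstats1, sumstats2 = sumstats2, blocks = blocks,
             ld_dir = ld_dir, replication)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input path(s): ", paste(missing, collapse = ", "))
  }
  stopifnot(all(stages %in% c("rg", "overlap", "coloc", "cpassoc", "meta")))
  structure(
    list(sumstats1 = sumstats1, sumstats2 = sumstats2, blocks = blocks,
         ld_dir = ld_dir, out_dir = out_dir, replication = replication,
         trait1_name = trait1_name, trait2_name = trait2_name,
         trait1_type = trait1_type, trait2_type = trait2_type,
         n_cases = n_cases, n_controls = n_controls,
         overlap = overlap, priors = priors, tau_grid = tau_grid,
         n_mc = n_mc, candidate_p = candidate_p,
         n_blocks_jackknife = n_blocks_jackknife,
         stages = stages, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `overlap` and `priors`
#' may be given as nested maps of their constructor arguments. Relative paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  for (key in c("sumstats1", "sumstats2", "blocks", "ld_dir", "out_dir")) {
    if (!is.null(y[[key]])) y[[key]] <- fix(y[[key]])
  }
  if (!is.null(y$replication)) y$replication <- fix(unlist(y$replication))
  if (!is.null(y$overlap)) y$overlap <- do.call(overlap_config, y$overlap)
  if (!is.null(y$priors)) y$priors <- do.call(coloc_priors, y$priors)
  do.call(pipeline_config, y)
}

stage_seed <- function(cfg, stage) {
  derive_seed(cfg$seed, match(stage, c("rg", "overlap", "coloc", "cpassoc",
                                       "meta")) * 1000L)
}

write_report_tsv <- function(df, path) {
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  path
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full cross-phenotype analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing per-stage TSV/JSON
#' reports, a run manifest (inputs, package version, seed, parameters) and a
#' combined summary to `cfg$out_dir`. Deterministic for a fixed seed: each
#' stage uses a substream derived from the top-level seed, so disabling a
#' downstream stage never changes an upstream report. A stage failure writes a
#' `FAILED` marker naming the stage and re-raises the error; reports already
#' written are retained.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- character(0)
  results <- list()
  current_stage <- "setup"

  run <- function() {
    # -- inputs ------------------------------------------------------------
    a <- read_sumstats(cfg$sumstats1, trait_name = cfg$trait1_name,
                       trait_type = cfg$trait1_type,
                       n_cases = cfg$n_cases, n_controls = cfg$n_controls)
    b <- read_sumstats(cfg$sumstats2, trait_name = cfg$trait2_name,
                       trait_type = cfg$trait2_type)
    blocks <- load_blocks(cfg$blocks)
    ld <- read_ld_collection(cfg$ld_dir)

    hp <- harmonize_pair(a, b)
    ha <- assign_blocks(hp$a, blocks)
    hb <- hp$b
    qq1 <- qq_export(ha)
    qq2 <- qq_export(hb)
    reports <<- c(reports,
      write_report_json(
        list(seed = cfg$seed,
             n_trait1 = nrow(a), n_trait2 = nrow(b),
             harmonization = as.list(attr(hp, "harmonization")),
             lambda_trait1 = attr(qq1, "lambda"),
             lambda_trait2 = attr(qq2, "lambda")),
        file.path(cfg$out_dir, "01_harmonize.json")
      ),
      write_report_tsv(qq1, file.path(cfg$out_dir, "01_qq_trait1.tsv")),
      write_report_tsv(qq2, file.path(cfg$out_dir, "01_qq_trait2.tsv"))
    )
    results$harmonize <<- hp

    c_hat <- NA_real_

    # -- genetic correlation ----------------------------------------------
    if ("rg" %in% cfg$stages) {
      current_stage <<- "rg"
      lsc <- ld_scores(ld)
      rg_fit <- bivariate_ldsc(ha, hb, lsc,
                               n_blocks = min(cfg$n_blocks_jackknife,
                                              floor(nrow(ha) / 2)))
      c_hat <- z_correlation_overlap(ha, hb, ld = ld, blocks = blocks)
      results$rg <<- rg_fit
      reports <<- c(reports,
        write_report_tsv(tidy(rg_fit),
                         file.path(cfg$out_dir, "02_genetic_correlation.tsv")),
        write_report_json(
          c(unclass(rg_fit)[c("h2_1", "h2_1_se", "h2_2", "h2_2_se", "gcov",
                              "gcov_se", "rg", "rg_se", "p_rg", "intercept_1",
                              "intercept_2", "intercept_cross",
                              "intercept_cross_se", "n_snps_used",
                              "n_jackknife_blocks")],
            list(z_correlation_overlap = as.numeric(c_hat), seed = cfg$seed)),
          file.path(cfg$out_dir, "02_genetic_correlation.json")
        )
      )
    }

    # -- overlap -----------------------------------------------------------
    pruned_a <- pruned_b <- NULL
    if ("overlap" %in% cfg$stages) {
      current_stage <<- "overlap"
      ocfg <- cfg$overlap
      ocfg$seed <- stage_seed(cfg, "overlap")
      ores <- overlap_analysis(ha, hb, ld, blocks, config = ocfg)
      pruned_ids <- attr(ores, "pruned_ids")
      pruned_a <- ha[match(pruned_ids, ha$variant_id), ]
      pruned_b <- hb[match(pruned_ids, hb$variant_id), ]
      results$overlap <<- ores
      reports <<- c(reports,
        write_report_tsv(ores, file.path(cfg$out_dir, "03_overlap.tsv")),
        write_report_tsv(tibble::tibble(variant_id = pruned_ids),
                         file.path(cfg$out_dir, "03_pruned_variants.tsv"))
      )
    }

    # -- colocalisation ----------------------------------------------------
    if ("coloc" %in% cfg$stages) {
      current_stage <<- "coloc"
      c_use <- if (is.finite(c_hat)) as.numeric(c_hat) else 0
      cres <- genome_coloc_scan(ha, hb, blocks, priors = cfg$priors,
                                c = c_use)
      results$coloc <<- cres
      reports <<- c(reports,
        write_report_tsv(cres, file.path(cfg$out_dir, "04_coloc.tsv")))
    }

    # -- cross-phenotype statistics ---------------------------------------
    if ("cpassoc" %in% cfg$stages) {
      current_stage <<- "cpassoc"
      R <- if (is.finite(c_hat)) {
        matrix(c(1, as.numeric(c_hat), as.numeric(c_hat), 1), 2)
      } else NULL
      cp <- cpassoc_scan(ha, hb, R = R, ld = ld, blocks = blocks,
                         tau_grid = cfg$tau_grid, n_mc = cfg$n_mc,
                         seed = stage_seed(cfg, "cpassoc"))
      results$cpassoc <<- cp
      reports <<- c(reports,
        write_report_tsv(cp, file.path(cfg$out_dir, "05_cpassoc.tsv")))
    }

    # -- candidate selection, replication meta, sign test ------------------
    if ("meta" %in% cfg$stages) {
      current_stage <<- "meta"
      if (is.null(pruned_a)) stop("meta stage requires the overlap stage")
      cand <- select_candidates(pruned_a, pruned_b, results$coloc,
                                p_t = cfg$candidate_p)
      studies <- c(
        list(discovery = ha),
        setNames(
          lapply(seq_along(cfg$replication), function(i) {
            r <- read_sumstats(cfg$replication[i],
                               trait_name = sprintf("replication_%d", i),
                               trait_type = cfg$trait1_type)
            harmonize_pair(ha, r)$b
          }),
          if (length(cfg$replication)) {
            sprintf("replication_%d", seq_along(cfg$replication))
          } else character(0)
        )
      )
      mres <- if (nrow(cand)) meta_scan(cand$variant_id, studies) else
        tibble::tibble()
      st <- if (nrow(mres) && length(studies) >= 2) {
        sig <- mres$direction[mres$p_meta < 0.05 &
                                !grepl("?", mres$direction, fixed = TRUE)]
        list(
          all = tryCatch(sign_test(mres$direction), error = function(e) NULL),
          p_meta_lt_0.05 = if (length(sig)) {
            tryCatch(sign_test(sig), error = function(e) NULL)
          } else NULL
        )
      } else NULL
      results$candidates <<- cand
      results$meta <<- mres
      results$sign_test <<- st
      reports <<- c(reports,
        write_report_tsv(cand, file.path(cfg$out_dir, "06_candidates.tsv")),
        write_report_tsv(mres, file.path(cfg$out_dir, "06_meta.tsv")),
        write_report_json(st %||% list(),
                          file.path(cfg$out_dir, "06_sign_test.json"))
      )
    }
  }

  tryCatch(run(), error = function(e) {
    writeLines(paste0("stage: ", current_stage, "\n", conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    stop("pipeline stage '", current_stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })

  manifest <- list(
    package = "pleioscan",
    version = as.character(packageVersion("pleioscan")),
    seed = cfg$seed,
    inputs = list(sumstats1 = cfg$sumstats1, sumstats2 = cfg$sumstats2,
                  blocks = cfg$blocks, ld_dir = cfg$ld_dir,
                  replication = cfg$replication),
    parameters = list(
      overlap = unclass(cfg$overlap), priors = unclass(cfg$priors),
      tau_grid = cfg$tau_grid, n_mc = cfg$n_mc,
      candidate_p = cfg$candidate_p,
      n_blocks_jackknife = cfg$n_blocks_jackknife
    ),
    stages = cfg$stages,
    reports = basename(reports)
  )
  write_report_json(manifest, file.path(cfg$out_dir, "manifest.json"))
  invisible(list(results = results, manifest = manifest,
                 reports = c(reports, file.path(cfg$out_dir, "manifest.json"))))
}

#' Observed-vs-expected quantiles and genomic inflation
#'
#' Exports sorted observed and expected `-log10` p-value pairs plus the
#' genomic inflation factor `lambda` (median chi-square over 0.4549, the
#' median of a 1-df chi-square).
#'
#' @param s A `sumstats` tibble (non-empty).
#' @return Tibble with `expected` and `observed` columns (ascending);
#'   attribute `lambda` holds the inflation factor.
#' @export
qq_export <- function(s) {
  if (nrow(s) == 0) stop("empty sumstats")
  m <- nrow(s)
  p <- sort(s$pvalue)
  out <- tibble::tibble(
    expected = -log10((seq_len(m) - 0.5) / m),
    observed = -log10(p)
  )
  out <- dplyr::arrange(out, .data$expected)
  attr(out, "lambda") <- lambda_gc(s$pvalue)
  out
}

#' Genomic inflation factor
#'
#' @param p P-values.
#' @return `median(qchisq(p, 1, lower = FALSE)) / qchisq(0.5, 1)`.
#' @export
lambda_gc <- function(p) {
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}
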