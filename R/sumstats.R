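# GWAS summary-statistics tables: reading, validation, harmonisation.
#
# A sumstats object is a tibble with the canonical columns below plus
# trait-level metadata in attributes (trait_name, trait_type, n_cases,
# n_controls). All effects are on the additive scale: log-odds for binary
# traits, per-SD units for quantitative traits.

SUMSTATS_COLS <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "beta", "se", "pvalue", "z", "n", "eaf", "info"
)

#' Build a summary-statistics object from a data frame
#'
#' Coerces a per-variant association table to the canonical `sumstats` layout,
#' fills derivable fields (Z from beta/SE, Z from p-value plus effect
#' direction, p-value from Z, effective sample size from case/control counts)
#' and drops rows that fail validation, keeping a tally of the reasons.
#'
#' Validation rules: unique variant ids; alleles uppercase A/C/G/T strings
#' with effect != other allele; `se > 0` and `pvalue` in (0, 1] where present;
#' `n > 0` where present; sign consistency `z * beta >= 0`; and, where both
#' were supplied, the stored p-value must match the two-sided normal tail of
#' `z` to within 1e-6 relative tolerance.
#'
#' @param data Data frame with at least `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele` and enough of `beta`/`se`/`z`/`pvalue`
#'   to resolve a Z-score. An `or` column (odds ratio) is converted to
#'   log-odds `beta` on entry.
#' @param trait_name Label used in reports.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param n_cases,n_controls Case/control counts for binary traits; used to
#'   fill missing `n` with the effective sample size.
#' @return A `sumstats` tibble. Attribute `dropped` holds a named integer
#'   tally of removed rows.
#' @export
as_sumstats <- function(data, trait_name = "trait",
                        trait_type = c("quantitative", "binary"),
                        n_cases = NULL, n_controls = NULL) {
  trait_type <- match.arg(trait_type)
  df <- tibble::as_tibble(data)

  required <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("missing required columns: ", paste(miss, collapse = ", "))
  }

  if ("or" %in% names(df) && !("beta" %in% names(df) && any(!is.na(df$beta)))) {
    df$beta <- log(df$or)
  }
  for (col in setdiff(SUMSTATS_COLS, names(df))) df[[col]] <- NA_real_
  df <- df[SUMSTATS_COLS]

  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.numeric(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("beta", "se", "pvalue", "z", "n", "eaf", "info")) {
    df[[col]] <- as.numeric(df[[col]])
  }

  had_z <- !is.na(df$z)
  had_p <- !is.na(df$pvalue)

  # Fill derivable fields.
  fill <- is.na(df$z) & !is.na(df$beta) & !is.na(df$se) & df$se > 0
  df$z[fill] <- df$beta[fill] / df$se[fill]
  fill <- is.na(df$z) & !is.na(df$pvalue) & !is.na(df$beta)
  df$z[fill] <- sign(df$beta[fill]) *
    qnorm(df$pvalue[fill] / 2, lower.tail = FALSE)
  fill <- is.na(df$pvalue) & !is.na(df$z)
  df$pvalue[fill] <- two_sided_p(df$z[fill])

  if (trait_type == "binary" && !is.null(n_cases) && !is.null(n_controls)) {
    df$n[is.na(df$n)] <- effective_n(n_cases, n_controls)
  }

  dropped <- c(
    duplicate_id = 0L, bad_allele = 0L, bad_se = 0L, bad_pvalue = 0L,
    bad_n = 0L, no_z = 0L, sign_conflict = 0L, z_p_mismatch = 0L
  )
  keep <- rep(TRUE, nrow(df))
  mark <- function(bad, reason) {
    bad <- bad & keep
    dropped[reason] <<- dropped[reason] + sum(bad)
    keep <<- keep & !bad
  }

  mark(duplicated(df$variant_id), "duplicate_id")
  allele_ok <- grepl("^[ACGT]+$", df$effect_allele) &
    grepl("^[ACGT]+$", df$other_allele) &
    df$effect_allele != df$other_allele
  mark(!allele_ok, "bad_allele")
  mark(!is.na(df$se) & df$se <= 0, "bad_se")
  mark(!is.na(df$pvalue) & (df$pvalue <= 0 | df$pvalue > 1), "bad_pvalue")
  mark(!is.na(df$n) & df$n <= 0, "bad_n")
  mark(is.na(df$z) | is.na(df$pvalue), "no_z")
  mark(!is.na(df$beta) & df$z * df$beta < 0, "sign_conflict")
  p_implied <- two_sided_p(df$z)
  mismatch <- had_z & had_p &
    abs(p_implied - df$pvalue) > 1e-6 * pmax(df$pvalue, p_implied)
  mark(mismatch, "z_p_mismatch")

  out <- df[keep, ]
  new_sumstats(out, trait_name = trait_name, trait_type = trait_type,
               n_cases = n_cases, n_controls = n_controls, dropped = dropped)
}

new_sumstats <- function(df, trait_name, trait_type, n_cases = NULL,
                         n_controls = NULL, dropped = NULL) {
  structure(
    tibble::as_tibble(df),
    class = c("sumstats", class(tibble::tibble())),
    trait_name = trait_name,
    trait_type = trait_type,
    n_cases = n_cases,
    n_controls = n_controls,
    dropped = dropped
  )
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf(
    "<sumstats> trait '%s' (%s), %d variants\n",
    attr(x, "trait_name") %||% "?", attr(x, "trait_type") %||% "?", nrow(x)
  ))
  NextMethod()
}

trait_meta <- function(s) {
  list(
    trait_name = attr(s, "trait_name") %||% "trait",
    trait_type = attr(s, "trait_type") %||% "quantitative",
    n_cases = attr(s, "n_cases"),
    n_controls = attr(s, "n_controls")
  )
}

# Rebuild a sumstats object around a modified data frame, keeping trait
# metadata from `template`.
restamp_sumstats <- function(df, template, dropped = NULL) {
  m <- trait_meta(template)
  new_sumstats(df, trait_name = m$trait_name, trait_type = m$trait_type,
               n_cases = m$n_cases, n_controls = m$n_controls,
               dropped = dropped)
}

#' Read a GWAS summary-statistics file
#'
#' Reads a whitespace- or tab-delimited association table (gzip transparently
#' supported), renames columns to the canonical layout through `column_map`,
#' and validates it via [as_sumstats()].
#'
#' @param path File path.
#' @param column_map Named character vector mapping canonical names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#'   `or`, `se`, `pvalue`, `z`, `n`, `eaf`, `info`) to the file's column
#'   names, e.g. `c(variant_id = "SNP", pvalue = "P")`. `NULL` assumes the
#'   file already uses canonical names.
#' @inheritParams as_sumstats
#' @return A `sumstats` tibble.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_name = "trait",
                          trait_type = c("quantitative", "binary"),
                          n_cases = NULL, n_controls = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)

  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (!length(first)) stop("empty file: ", path)

  if (grepl("\t", first)) {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    df <- readr::read_table(path, show_col_types = FALSE, progress = FALSE)
  }

  if (!is.null(column_map)) {
    absent <- setdiff(unname(column_map), names(df))
    if (length(absent)) {
      stop("column_map names absent from header: ",
           paste(absent, collapse = ", "))
    }
    for (canon in names(column_map)) {
      df[[canon]] <- df[[column_map[[canon]]]]
    }
    extra <- setdiff(unname(column_map), c(SUMSTATS_COLS, "or"))
    df <- df[setdiff(names(df), extra)]
  }

  out <- as_sumstats(df, trait_name = trait_name, trait_type = trait_type,
                     n_cases = n_cases, n_controls = n_controls)
  if (nrow(out) == 0L) stop("no valid rows in ", path)
  out
}

#' Write a summary-statistics table
#'
#' Writes the canonical tab-delimited layout with a fixed header. A
#' write/read round trip preserves identifiers and alleles exactly and real
#' fields to within 1e-12 relative tolerance.
#'
#' @param s A `sumstats` tibble (non-empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(s, path) {
  if (nrow(s) == 0L) stop("cannot write an empty sumstats table")
  readr::write_tsv(tibble::as_tibble(s)[SUMSTATS_COLS], path, progress = FALSE)
  invisible(path)
}

#' Harmonise two summary-statistics tables to a common allele frame
#'
#' Restricts both tables to shared variant ids and aligns the second table's
#' effect alleles to the first's: allele swaps negate `beta` and `z` and
#' complement `eaf`; strand flips (complement alleles) are reconciled without
#' sign change; strand-ambiguous A/T and C/G variants are dropped when
#' `drop_ambiguous` is set; irreconcilable allele pairs are dropped and
#' tallied.
#'
#' @param a,b `sumstats` tibbles.
#' @param drop_ambiguous Drop strand-ambiguous (A/T, C/G) variants
#'   (default `TRUE`).
#' @return List with elements `a` and `b`, aligned row-for-row. Attribute
#'   `harmonization` on the list records the tally.
#' @export
harmonize_pair <- function(a, b, drop_ambiguous = TRUE) {
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both tables must be non-empty")
  common <- a$variant_id[a$variant_id %in% b$variant_id]
  if (!length(common)) stop("no shared variants between the two tables")

  aa <- tibble::as_tibble(a)[match(common, a$variant_id), ]
  bb <- tibble::as_tibble(b)[match(common, b$variant_id), ]

  snv <- nchar(aa$effect_allele) == 1L & nchar(aa$other_allele) == 1L &
    nchar(bb$effect_allele) == 1L & nchar(bb$other_allele) == 1L

  same <- bb$effect_allele == aa$effect_allele &
    bb$other_allele == aa$other_allele
  swap <- bb$effect_allele == aa$other_allele &
    bb$other_allele == aa$effect_allele
  flip <- snv & !same & !swap &
    complement_alleles(bb$effect_allele) == aa$effect_allele &
    complement_alleles(bb$other_allele) == aa$other_allele
  flip_swap <- snv & !same & !swap &
    complement_alleles(bb$effect_allele) == aa$other_allele &
    complement_alleles(bb$other_allele) == aa$effect_allele

  ambiguous <- snv &
    complement_alleles(aa$effect_allele) == aa$other_allele
  mismatch <- !(same | swap | flip | flip_swap)

  keep <- !mismatch
  if (drop_ambiguous) keep <- keep & !ambiguous
  tally <- c(
    n_shared = length(common),
    n_ambiguous_dropped = if (drop_ambiguous) sum(ambiguous & !mismatch) else 0L,
    n_mismatch_dropped = sum(mismatch),
    n_swapped = sum(swap[keep]),
    n_strand_flipped = sum((flip | flip_swap)[keep])
  )

  negate <- (swap | flip_swap) & keep
  bb$beta[negate] <- -bb$beta[negate]
  bb$z[negate] <- -bb$z[negate]
  bb$eaf[negate] <- 1 - bb$eaf[negate]
  bb$effect_allele <- aa$effect_allele
  bb$other_allele <- aa$other_allele
  bb$chrom <- aa$chrom
  bb$pos <- aa$pos

  if (!any(keep)) stop("no variants left after harmonisation")
  out <- list(
    a = restamp_sumstats(aa[keep, ], a),
    b = restamp_sumstats(bb[keep, ], b)
  )
  attr(out, "harmonization") <- tally
  out
}
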