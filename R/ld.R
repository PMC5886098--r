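# Approximately independent LD blocks, per-block signed LD matrices and
# per-SNP LD scores.
#
# Convention: block files are BED-like 0-based half-open intervals and a
# variant belongs to the block whose [start, stop) interval contains its
# position. Cross-block LD is defined to be exactly 0, which is what
# "approximately independent" blocks license and makes permutation and
# simulation block-separable.

#' Load approximately independent LD-block boundaries
#'
#' Reads a BED-like file (`chrom start stop [block_id]`, whitespace- or
#' tab-delimited, header optional) of 0-based half-open block intervals.
#' Blocks are validated (start < stop, non-overlapping within chromosome) and
#' sorted; missing block ids are synthesised as `chrom_start_stop`.
#'
#' @param path File path.
#' @return An `ld_blocks` tibble with columns `chrom`, `start`, `stop`,
#'   `block_id`.
#' @export
load_blocks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("block file needs at least 3 columns")
  # Drop a header row if the second column is not numeric.
  if (is.na(suppressWarnings(as.numeric(raw[1, 2])))) raw <- raw[-1, ]
  df <- tibble::tibble(
    chrom = as.character(raw[[1]]),
    start = as.numeric(raw[[2]]),
    stop = as.numeric(raw[[3]]),
    block_id = if (ncol(raw) >= 4) as.character(raw[[4]]) else NA_character_
  )
  df$block_id[is.na(df$block_id)] <- paste(
    df$chrom[is.na(df$block_id)], df$start[is.na(df$block_id)],
    df$stop[is.na(df$block_id)], sep = "_"
  )
  as_ld_blocks(df)
}

#' Validate and classify a block table
#'
#' @param df Data frame with `chrom`, `start`, `stop` and optionally
#'   `block_id` (0-based half-open intervals).
#' @return An `ld_blocks` tibble, sorted by chromosome and start.
#' @export
as_ld_blocks <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("chrom", "start", "stop") %in% names(df)))
  if (!"block_id" %in% names(df)) {
    df$block_id <- paste(df$chrom, df$start, df$stop, sep = "_")
  }
  if (anyNA(df$start) || anyNA(df$stop)) stop("non-numeric block bounds")
  if (any(df$start >= df$stop)) stop("block start must be < stop")
  if (anyDuplicated(df$block_id)) stop("duplicate block ids")
  df <- dplyr::arrange(df, .data$chrom, .data$start)
  overlap <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      bad = dplyr::n() > 1 &&
        any(.data$start[-1] < .data$stop[-dplyr::n()]),
      .groups = "drop"
    )
  if (any(overlap$bad)) stop("overlapping blocks within a chromosome")
  structure(df, class = c("ld_blocks", class(tibble::tibble())))
}

#' Write block boundaries as a BED-like file
#'
#' @param blocks An `ld_blocks` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  readr::write_tsv(
    tibble::as_tibble(blocks)[c("chrom", "start", "stop", "block_id")],
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Assign variants to LD blocks
#'
#' Adds a `block_id` column: a variant is assigned to the block whose
#' half-open `[start, stop)` interval contains its position (so a variant
#' sitting exactly on a boundary belongs to the downstream block). Variants
#' outside every block get `NA`.
#'
#' @param s A `sumstats` tibble (or any data frame with `chrom` and `pos`).
#' @param blocks An `ld_blocks` tibble.
#' @return `s` with a `block_id` column.
#' @export
assign_blocks <- function(s, blocks) {
  bid <- rep(NA_character_, nrow(s))
  for (ch in unique(s$chrom)) {
    bl <- blocks[blocks$chrom == ch, ]
    if (!nrow(bl)) next
    rows <- which(s$chrom == ch)
    idx <- findInterval(s$pos[rows], bl$start)
    ok <- idx >= 1L & idx <= nrow(bl)
    ok[ok] <- s$pos[rows][ok] < bl$stop[idx[ok]]
    bid[rows[ok]] <- bl$block_id[idx[ok]]
  }
  s$block_id <- bid
  s
}

#' Construct and validate a signed per-block LD matrix
#'
#' @param r Square matrix of signed correlations.
#' @param variant_ids Variant ids for rows/columns; defaults to the existing
#'   dimnames.
#' @return The validated matrix with variant ids as dimnames.
#' @export
ld_matrix <- function(r, variant_ids = NULL) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  variant_ids <- variant_ids %||% rownames(r)
  if (is.null(variant_ids) || length(variant_ids) != nrow(r)) {
    stop("variant_ids must match the matrix dimension")
  }
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix must have unit diagonal")
  if (max(abs(r)) > 1 + 1e-8) stop("LD entries must lie in [-1, 1]")
  if (nrow(r) > 1 && min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("LD matrix must be positive semi-definite")
  }
  dimnames(r) <- list(variant_ids, variant_ids)
  r
}

#' Squared LD between two variants of one block
#'
#' @param ld A per-block LD matrix (see [ld_matrix()]).
#' @param i,j Variant ids.
#' @return `r^2` in \[0, 1\]; 1 when `i == j`. Cross-block pairs are defined
#'   as 0 by the caller's contract and are not accepted here.
#' @export
r2 <- function(ld, i, j) {
  ids <- rownames(ld)
  if (!(i %in% ids) || !(j %in% ids)) stop("variant not in block")
  unname(ld[i, j]^2)
}

#' LD scores from a collection of per-block LD matrices
#'
#' For each variant, the LD score is the sum of its squared correlations with
#' every variant in the same block, itself included, so `l >= 1` always and
#' `l = 1` exactly for a variant uncorrelated with all others. No
#' finite-sample bias correction is applied: the reference LD is taken as
#' exact (the in-silico setting); for estimated panels this is a documented
#' limitation.
#'
#' @param mats Named list of per-block LD matrices.
#' @return Tibble with columns `variant_id` and `l`.
#' @export
ld_scores <- function(mats) {
  ids <- unlist(lapply(mats, rownames), use.names = FALSE)
  if (anyDuplicated(ids)) stop("duplicate variant across blocks")
  l <- unlist(lapply(mats, function(m) rowSums(m^2)), use.names = FALSE)
  tibble::tibble(variant_id = ids, l = l)
}

#' Write / read one per-block LD matrix as plain text
#'
#' Format: a first line of tab-separated variant ids, then the matrix rows.
#'
#' @param m LD matrix with variant ids as dimnames.
#' @param path File path.
#' @return `write_ld_matrix`: `path` invisibly; `read_ld_matrix`: the matrix.
#' @export
write_ld_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rownames(m), collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  ids <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  m <- as.matrix(utils::read.table(path, skip = 1L, header = FALSE))
  ld_matrix(m, ids)
}

#' Write / read a whole LD collection (one file per block)
#'
#' @param mats Named list of per-block LD matrices.
#' @param dir Directory holding `<block_id>.ld` files.
#' @return `write_ld_collection`: `dir` invisibly; `read_ld_collection`: a
#'   named list of matrices.
#' @export
write_ld_collection <- function(mats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (bid in names(mats)) {
    write_ld_matrix(mats[[bid]], file.path(dir, paste0(bid, ".ld")))
  }
  invisible(dir)
}

#' @rdname write_ld_collection
#' @export
read_ld_collection <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.ld$", full.names = TRUE))
  if (!length(files)) stop("no .ld files in ", dir)
  mats <- lapply(files, read_ld_matrix)
  names(mats) <- sub("\\.ld$", "", basename(files))
  mats
}
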