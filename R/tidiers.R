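# broom-style tidiers for fitted objects.

#' Tidy an LD score regression fit
#'
#' @param x An `ldsc_h2` object.
#' @param ... Unused.
#' @return A tibble with one row per quantity (`h2`, `intercept`):
#'   `term`, `estimate`, `std.error`.
#' @export
tidy.ldsc_h2 <- function(x, ...) {
  tibble::tibble(
    term = c("h2", "intercept"),
    estimate = c(x$h2, x$intercept),
    std.error = c(x$h2_se, x$intercept_se)
  )
}

#' @rdname tidy.ldsc_h2
#' @return `glance`: a one-row tibble with fit-level summaries.
#' @export
glance.ldsc_h2 <- function(x, ...) {
  tibble::tibble(
    h2 = x$h2, h2_se = x$h2_se, intercept = x$intercept,
    intercept_se = x$intercept_se, n_snps = x$n_snps,
    n_blocks = x$n_blocks
  )
}

#' Tidy a bivariate LD score regression fit
#'
#' @param x An `ldsc_rg` object.
#' @param ... Unused.
#' @return A tibble with one row per quantity (`h2_1`, `h2_2`, `gcov`, `rg`,
#'   intercepts): `term`, `estimate`, `std.error`, `p.value`.
#' @export
tidy.ldsc_rg <- function(x, ...) {
  tibble::tibble(
    term = c("h2_1", "h2_2", "gcov", "rg", "intercept_1", "intercept_2",
             "intercept_cross"),
    estimate = c(x$h2_1, x$h2_2, x$gcov, x$rg, x$intercept_1, x$intercept_2,
                 x$intercept_cross),
    std.error = c(x$h2_1_se, x$h2_2_se, x$gcov_se, x$rg_se, NA_real_,
                  NA_real_, x$intercept_cross_se),
    p.value = c(NA_real_, NA_real_, NA_real_, x$p_rg, NA_real_, NA_real_,
                NA_real_)
  )
}

#' @rdname tidy.ldsc_rg
#' @return `glance`: a one-row tibble with the headline estimates.
#' @export
glance.ldsc_rg <- function(x, ...) {
  tibble::tibble(
    rg = x$rg, rg_se = x$rg_se, p_rg = x$p_rg,
    h2_1 = x$h2_1, h2_2 = x$h2_2, gcov = x$gcov,
    intercept_cross = x$intercept_cross,
    n_snps_used = x$n_snps_used,
    n_jackknife_blocks = x$n_jackknife_blocks
  )
}
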