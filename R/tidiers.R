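# broom-style tidiers for the package's result objects.

#' Tidy a bin-fraction result
#'
#' @param x A `bin_fraction_result`.
#' @param ... Unused.
#' @return The per-bin tibble (`bin`, `n_genes`, `fraction`, and the
#'   permutation columns when present).
#' @method tidy bin_fraction_result
#' @export
tidy.bin_fraction_result <- function(x, ...) x$bins

#' @rdname tidy.bin_fraction_result
#' @return `glance()` returns a one-row tibble: `n_genes`, `n_bins`,
#'   `overall_fraction`, and permutation metadata when present.
#' @method glance bin_fraction_result
#' @export
glance.bin_fraction_result <- function(x, ...) {
  out <- tibble::tibble(
    n_genes = x$n_genes,
    n_bins = x$n_bins,
    overall_fraction = x$overall_fraction
  )
  if (!is.null(x$n_permutations)) {
    out$n_permutations <- x$n_permutations
    out$n_significant <- sum(x$bins$significant)
    out$alpha <- x$alpha
  }
  out
}

#' Tidy a CV-distribution comparison
#'
#' @param x A `cv_comparison`.
#' @param ... Unused.
#' @return `tidy()` returns the per-group mean/SD summary;
#'   `glance()` the one-row test result.
#' @method tidy cv_comparison
#' @export
tidy.cv_comparison <- function(x, ...) x$summary

#' @rdname tidy.cv_comparison
#' @method glance cv_comparison
#' @export
glance.cv_comparison <- function(x, ...) {
  tibble::tibble(
    group_x = x$group_x, group_e = x$group_e, n_genes = x$n_genes,
    statistic = x$statistic, p_value = x$p_value
  )
}

#' Tidy a phylostratum enrichment table
#'
#' @param x A `stratum_table`.
#' @param ... Unused.
#' @return `tidy()` returns the long per-list per-stratum tibble (`count`,
#'   `fraction`, `expected`, `std_residual`); `glance()` the chi-square
#'   statistic, df and p-value.
#' @method tidy stratum_table
#' @export
tidy.stratum_table <- function(x, ...) x$table

#' @rdname tidy.stratum_table
#' @method glance stratum_table
#' @export
glance.stratum_table <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = as.integer(x$df), p_value = x$p_value,
    n_lists = nrow(x$contingency), n_strata = ncol(x$contingency)
  )
}

#' Tidy a kinematics summary
#'
#' @param x A `kinematics_summary`.
#' @param ... Unused.
#' @return `tidy()` returns the per-interval tibble; `glance()` a one-row
#'   tibble with `delta_peak`.
#' @method tidy kinematics_summary
#' @export
tidy.kinematics_summary <- function(x, ...) x$intervals

#' @rdname tidy.kinematics_summary
#' @method glance kinematics_summary
#' @export
glance.kinematics_summary <- function(x, ...) {
  tibble::tibble(delta_peak = x$delta_peak)
}
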