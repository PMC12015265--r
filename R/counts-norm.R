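#' Filter low-expression genes by CPM
#'
#' Keeps a gene if and only if its counts-per-million value is strictly
#' greater than `cpm_threshold` in at least `min_samples` samples. CPM is
#' `1e6 * count / library_size` with library size the raw column sum. The
#' defaults (0.6 CPM in at least 3 samples) follow the standard filter used
#' with three replicate pools per group; gene order is preserved.
#'
#' @param x A [pooled_counts()] object.
#' @param cpm_threshold Strict CPM threshold (default 0.6).
#' @param min_samples Minimum number of samples exceeding the threshold
#'   (default 3).
#' @return A filtered [pooled_counts()] object.
#' @export
filter_low_expression <- function(x, cpm_threshold = 0.6, min_samples = 3) {
  stopifnot(inherits(x, "pooled_counts"))
  lib <- library_sizes(x)
  if (any(lib == 0)) {
    abort(sprintf(
      "Library size is zero for sample(s): %s",
      paste(names(lib)[lib == 0], collapse = ", ")
    ))
  }
  m <- counts_matrix(x)
  cpm <- sweep(m, 2, lib, "/") * 1e6
  keep <- rowSums(cpm > cpm_threshold) >= min_samples
  pooled_counts(x$counts[keep, , drop = FALSE], x$design)
}

#' TMM normalization factors
#'
#' Computes weighted trimmed-mean-of-M-values (TMM) scaling factors for
#' each pooled library via [edgeR::calcNormFactors()], with the standard
#' defaults: reference sample chosen as the one whose upper-quartile count
#' fraction is closest to the mean, 30% trimming of M-values, 5% trimming
#' of A-values, and inverse-asymptotic-variance weighting. Factors are
#' renormalized to geometric mean 1.
#'
#' @param x A [pooled_counts()] object with at least two samples.
#' @param ref_sample Optional sample ID used as the reference library.
#' @return A tibble with columns `sample_id`, `norm_factor`.
#' @export
tmm_factors <- function(x, ref_sample = NULL) {
  stopifnot(inherits(x, "pooled_counts"))
  m <- counts_matrix(x)
  if (ncol(m) < 2L) abort("TMM needs at least two samples.")
  zero <- colSums(m) == 0
  if (any(zero)) {
    abort(sprintf(
      "All-zero sample(s): %s", paste(colnames(m)[zero], collapse = ", ")
    ))
  }
  ref <- NULL
  if (!is.null(ref_sample)) {
    ref <- match(ref_sample, colnames(m))
    if (is.na(ref)) abort(sprintf("Unknown reference sample '%s'.", ref_sample))
  }
  f <- edgeR::calcNormFactors(m, method = "TMM", refColumn = ref)
  tibble::tibble(sample_id = colnames(m), norm_factor = as.numeric(f))
}

#' logCPM transform
#'
#' Transforms counts to `log2(1e6 * (count + pseudocount) /
#' (library_size * norm_factor))`. The default `pseudocount = 0` evaluates
#' that formula exactly, so zero counts map to `-Inf` (these are flagged,
#' not an error); `pseudocount = 0.5` gives voom-style behavior.
#'
#' @param x A [pooled_counts()] object.
#' @param factors A data frame with columns `sample_id`, `norm_factor`
#'   (e.g. from [tmm_factors()]); `NULL` means all factors 1.
#' @param pseudocount Added to every count before the log (default 0).
#' @return An object of class `normalized_matrix`: list with `logcpm`
#'   (tibble, `gene_id` + one column per sample), `norm_factors` (tibble)
#'   and `n_neg_inf` (number of `-Inf` cells).
#' @examples
#' # log2(1e6 * 1000 / 1e6) = log2(1000) = 9.9658
#' @export
logcpm_transform <- function(x, factors = NULL, pseudocount = 0) {
  stopifnot(inherits(x, "pooled_counts"))
  m <- counts_matrix(x)
  lib <- library_sizes(x)
  if (is.null(factors)) {
    factors <- tibble::tibble(sample_id = colnames(m), norm_factor = 1)
  }
  factors <- tibble::as_tibble(factors)
  f <- factors$norm_factor[match(colnames(m), factors$sample_id)]
  if (anyNA(f)) abort("`factors` must cover every sample.")
  if (any(f <= 0)) abort("Normalization factors must be positive.")
  logcpm <- log2(sweep(m + pseudocount, 2, lib * f, "/") * 1e6)
  n_neg_inf <- sum(is.infinite(logcpm) & logcpm < 0)
  if (n_neg_inf > 0) {
    inform(sprintf(
      "%d zero-count cells mapped to -Inf (pseudocount = %g).",
      n_neg_inf, pseudocount
    ))
  }
  structure(
    list(
      logcpm = dplyr::bind_cols(
        tibble::tibble(gene_id = rownames(m)),
        tibble::as_tibble(as.data.frame(logcpm))
      ),
      norm_factors = factors,
      n_neg_inf = n_neg_inf
    ),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf(
    "<normalized_matrix> %d genes x %d samples; %d -Inf cells\n",
    nrow(x$logcpm), ncol(x$logcpm) - 1L, x$n_neg_inf
  ))
  print(x$logcpm, n = 5)
  invisible(x)
}
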