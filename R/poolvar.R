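#' Remove genes with any zero pool value
#'
#' Drops every gene that has a count of 0 in any sample. The CV
#' deconvolution divides by pool means, so genes with zeros are excluded
#' from the variability analysis up front.
#'
#' @param x A [pooled_counts()] object.
#' @return A [pooled_counts()] object with strictly positive values.
#' @export
drop_zero_genes <- function(x) {
  stopifnot(inherits(x, "pooled_counts"))
  m <- counts_matrix(x)
  keep <- rowSums(m == 0) == 0
  if (!any(keep)) warn("All genes have a zero value in some sample; result is empty.")
  pooled_counts(x$counts[keep, , drop = FALSE], x$design)
}

#' Deconvolve individual-level CVs from replicate pools
#'
#' Each pooled library's per-gene value is the mean over the `n` individuals
#' in the pool, so the standard deviation of the `r` replicate pool values
#' estimates the standard error of that mean: `SE = sigma / sqrt(n)`.
#' Multiplying the pool SE by `sqrt(n)` therefore recovers the
#' individual-level standard deviation `sigma_hat = SE * sqrt(n)`, and
#' dividing by the mean of the group's pools gives the inter-individual
#' coefficient of variation `CV = sigma_hat / pool_mean`. The SE uses the
#' n-1 sample SD of the replicate pool values. Genes are ranked ascending by
#' their mean count across all samples of all groups.
#'
#' @param x A [pooled_counts()] object with at least two replicate pools
#'   per group.
#' @param drop_zeros Drop genes with any zero value first (default `TRUE`;
#'   see [drop_zero_genes()]).
#' @return A tibble of class `cv_table`, one row per gene per group:
#'   `gene_id`, `overall_mean`, `rank`, `group`, `n_individuals`,
#'   `pool_mean`, `pool_se`, `sigma_hat`, `cv`.
#' @examples
#' # pools (10, 12, 14) with n = 10: SE = 2, sigma_hat = 2 * sqrt(10),
#' # CV = 6.3246 / 12 = 0.5271
#' @export
compute_cv_table <- function(x, drop_zeros = TRUE) {
  stopifnot(inherits(x, "pooled_counts"))
  if (drop_zeros) {
    before <- nrow(x$counts)
    x <- drop_zero_genes(x)
    if (nrow(x$counts) < before) {
      inform(sprintf(
        "Removed %d gene(s) with a zero value in some pool.",
        before - nrow(x$counts)
      ))
    }
  }
  reps <- table(x$design$group)
  if (any(reps < 2)) {
    abort(sprintf(
      "Pool SE is undefined with a single replicate pool (group %s).",
      paste(names(reps)[reps < 2], collapse = ", ")
    ))
  }
  m <- counts_matrix(x)
  overall <- unname(rowMeans(m))
  rank_overall <- rank(overall, ties.method = "first")
  groups <- unique(x$design$group)
  out <- purrr::map(groups, function(g) {
    cols <- x$design$sample_id[x$design$group == g]
    n <- x$design$n_individuals[x$design$group == g][1]
    sub <- m[, cols, drop = FALSE]
    pool_mean <- unname(rowMeans(sub))
    pool_se <- unname(apply(sub, 1, sd))
    sigma_hat <- pool_se * sqrt(n)
    tibble::tibble(
      gene_id = rownames(m),
      overall_mean = overall,
      rank = as.integer(rank_overall),
      group = g,
      n_individuals = n,
      pool_mean = pool_mean,
      pool_se = pool_se,
      sigma_hat = sigma_hat,
      cv = sigma_hat / pool_mean
    )
  })
  out <- dplyr::bind_rows(out)
  class(out) <- unique(c("cv_table", class(out)))
  out
}

# Resolve the (test, reference) group pair of a CV table; defaults to the
# first two groups in order of appearance (test = Xenobot-like group).
cv_group_pair <- function(cv_table, group_x = NULL, group_e = NULL) {
  groups <- unique(cv_table$group)
  if (length(groups) < 2L) abort("Need two groups in the CV table.")
  gx <- group_x %||% groups[1]
  ge <- group_e %||% setdiff(groups, gx)[1]
  if (!all(c(gx, ge) %in% groups)) abort("Unknown group label.")
  c(gx, ge)
}

# Wide per-gene view of a two-group CV table, ordered by rank.
cv_wide <- function(cv_table, group_x = NULL, group_e = NULL) {
  pair <- cv_group_pair(cv_table, group_x, group_e)
  w <- tidyr::pivot_wider(
    dplyr::select(
      tibble::as_tibble(cv_table),
      "gene_id", "overall_mean", "rank", "group", "cv"
    ),
    names_from = "group", values_from = "cv"
  )
  w <- dplyr::arrange(w, .data$rank)
  tibble::tibble(
    gene_id = w$gene_id,
    overall_mean = w$overall_mean,
    rank = w$rank,
    cv_x = w[[pair[1]]],
    cv_e = w[[pair[2]]]
  )
}

#' Compare CV distributions between groups
#'
#' Two-sided Wilcoxon rank-sum test on the per-gene CV values of the test
#' group versus the reference group, plus per-group means and SDs of the CV
#' distributions.
#'
#' @param cv_table A `cv_table` from [compute_cv_table()].
#' @param group_x,group_e Group labels for the test (e.g. Xenobot) and
#'   reference (e.g. embryo) groups; default to the first two groups.
#' @return An object of class `cv_comparison`; see [glance.cv_comparison()].
#' @export
compare_cv_distributions <- function(cv_table, group_x = NULL, group_e = NULL) {
  w <- cv_wide(cv_table, group_x, group_e)
  pair <- cv_group_pair(cv_table, group_x, group_e)
  ht <- wilcox.test(w$cv_x, w$cv_e, alternative = "two.sided", exact = FALSE)
  structure(
    list(
      group_x = pair[1], group_e = pair[2],
      n_genes = nrow(w),
      statistic = unname(ht$statistic),
      p_value = ht$p.value,
      summary = tibble::tibble(
        group = pair,
        mean_cv = c(mean(w$cv_x), mean(w$cv_e)),
        sd_cv = c(sd(w$cv_x), sd(w$cv_e))
      )
    ),
    class = "cv_comparison"
  )
}

#' @export
print.cv_comparison <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank-sum on %d genes: W = %g, p = %g\n",
    x$n_genes, x$statistic, x$p_value
  ))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %s: mean CV %.4f, SD %.4f\n", s$group[i], s$mean_cv[i], s$sd_cv[i]
    ))
  }
  invisible(x)
}

# Bin assignment in rank order: sizes differ by at most one, the first
# (G mod n_bins) bins take the extra gene, and order is preserved.
bin_assignment <- function(n_genes, n_bins) {
  base <- n_genes %/% n_bins
  extra <- n_genes %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  rep(seq_len(n_bins), times = sizes)
}

#' Percentile bin-fraction analysis
#'
#' Genes are assigned, in rank order (lowest to highest overall mean
#' count), to `n_bins` near-equal bins, and each bin's fraction of genes
#' for which the test group's CV strictly exceeds the reference group's
#' (`CVX > CVE`; ties do not count) is computed, along with the overall
#' fraction across all genes.
#'
#' @inheritParams compare_cv_distributions
#' @param n_bins Number of rank-percentile bins (default 100).
#' @return An object of class `bin_fraction_result`; `$bins` is a tibble
#'   with one row per bin (`bin`, `n_genes`, `n_greater`, `fraction`) and
#'   `$overall_fraction` the fraction over all genes. Use
#'   [permutation_test()] to fill in per-bin p-values.
#' @export
bin_fraction_analysis <- function(cv_table, n_bins = 100,
                                  group_x = NULL, group_e = NULL) {
  w <- cv_wide(cv_table, group_x, group_e)
  pair <- cv_group_pair(cv_table, group_x, group_e)
  G <- nrow(w)
  if (n_bins < 1 || n_bins > G) {
    abort(sprintf("`n_bins` must be between 1 and the gene count (%d).", G))
  }
  gt <- w$cv_x > w$cv_e
  bin <- bin_assignment(G, n_bins)
  n_per <- as.integer(tabulate(bin, n_bins))
  n_gt <- as.integer(rowsum(as.integer(gt), bin)[, 1])
  structure(
    list(
      bins = tibble::tibble(
        bin = seq_len(n_bins),
        n_genes = n_per,
        n_greater = n_gt,
        fraction = n_gt / n_per
      ),
      overall_fraction = mean(gt),
      n_bins = as.integer(n_bins),
      n_genes = G,
      group_x = pair[1],
      group_e = pair[2],
      gt = gt,
      bin = bin,
      n_permutations = NULL,
      seed = NULL
    ),
    class = "bin_fraction_result"
  )
}

#' Permutation test for bin fractions
#'
#' Shuffles whole (CVX, CVE) gene pairs across rank positions and
#' recomputes the bin fractions on the shuffled list, using the same bin
#' partition, `n_permutations` times. Each bin's p-value is the proportion
#' of null fractions lying strictly further (in absolute value) from the
#' bin's null mean than the observed fraction does. A bin is significant
#' when `p < alpha`. Degenerate bins -- all null fractions identical and the
#' observed deviation zero -- are assigned `p = 1` and flagged, since the
#' strict-exceedance proportion would read 0 and falsely signal
#' significance.
#'
#' @param result A `bin_fraction_result` from [bin_fraction_analysis()].
#' @param n_permutations Number of shuffles (default 1000).
#' @param seed Integer seed for exact reproducibility of the p-values.
#' @param alpha Significance level (default 0.05).
#' @return The `bin_fraction_result` with `$bins` gaining `null_mean`,
#'   `p_value`, `significant` and `degenerate` columns, and the permutation
#'   metadata (`n_permutations`, `seed`, `alpha`) recorded.
#' @export
permutation_test <- function(result, n_permutations = 1000, seed = NULL,
                             alpha = 0.05) {
  stopifnot(inherits(result, "bin_fraction_result"))
  if (n_permutations < 1) abort("`n_permutations` must be at least 1.")
  gt <- as.integer(result$gt)
  bin <- result$bin
  n_per <- result$bins$n_genes
  G <- result$n_genes
  null_frac <- with_stream(seed, "permutation", {
    vapply(seq_len(n_permutations), function(i) {
      rowsum(gt[sample.int(G)], bin)[, 1] / n_per
    }, numeric(result$n_bins))
  })
  null_frac <- matrix(null_frac, nrow = result$n_bins)
  null_mean <- rowMeans(null_frac)
  true_dev <- abs(result$bins$fraction - null_mean)
  null_dev <- abs(null_frac - null_mean)
  p <- rowMeans(null_dev > true_dev)
  degenerate <- apply(null_frac, 1, function(z) all(z == z[1])) & true_dev == 0
  p[degenerate] <- 1
  result$bins$null_mean <- null_mean
  result$bins$p_value <- p
  result$bins$degenerate <- degenerate
  result$bins$significant <- p < alpha & !degenerate
  result$n_permutations <- as.integer(n_permutations)
  result$seed <- seed
  result$alpha <- alpha
  result
}

#' @export
print.bin_fraction_result <- function(x, ...) {
  cat(sprintf(
    "<bin_fraction_result> %d genes in %d bins; overall fraction %s > %s: %.4f\n",
    x$n_genes, x$n_bins, x$group_x, x$group_e, x$overall_fraction
  ))
  if (!is.null(x$n_permutations)) {
    cat(sprintf(
      "  permutation test: %d shuffles, %d/%d bins significant at alpha = %g\n",
      x$n_permutations, sum(x$bins$significant), x$n_bins, x$alpha
    ))
  }
  print(x$bins, n = 5)
  invisible(x)
}

#' Top most-variable genes in the test group
#'
#' Ranks genes by the test group's CV, descending, after applying the
#' exclusion rules for the top-variable-gene table: genes for which any of
#' the group's replicate pools has a count of 0, and genes for which all of
#' the group's replicate pools are below `min_count`, are excluded. Ties in
#' CV are broken lexicographically by gene ID.
#'
#' @param cv_table A `cv_table` from [compute_cv_table()].
#' @param x The [pooled_counts()] object the table was computed from (used
#'   for the exclusion rules; may contain zeros).
#' @param k Number of genes to return (default 10).
#' @param group Group label; defaults to the first group.
#' @param min_count Exclusion threshold: genes with all replicate values
#'   strictly below this are dropped (default 10).
#' @return A tibble `gene_id`, `cv`, `pool_mean`, ordered by decreasing CV.
#' @export
top_variable_genes <- function(cv_table, x, k = 10, group = NULL,
                               min_count = 10) {
  stopifnot(inherits(x, "pooled_counts"))
  g <- group %||% unique(cv_table$group)[1]
  cols <- x$design$sample_id[x$design$group == g]
  m <- counts_matrix(x)[, cols, drop = FALSE]
  ok <- rowSums(m == 0) == 0 & rowSums(m >= min_count) > 0
  keep_ids <- rownames(m)[ok]
  tab <- dplyr::filter(
    tibble::as_tibble(cv_table),
    .data$group == g, .data$gene_id %in% keep_ids
  )
  tab <- dplyr::arrange(tab, dplyr::desc(.data$cv), .data$gene_id)
  if (k > nrow(tab)) {
    warn(sprintf(
      "Only %d genes remain after exclusions; returning all of them.", nrow(tab)
    ))
    k <- nrow(tab)
  }
  dplyr::select(
    utils::head(tab, k), "gene_id", "cv", "pool_mean", "sigma_hat"
  )
}
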