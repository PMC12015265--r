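#' Overlap percentage between two gene lists
#'
#' Exact-ID intersection of a query list with a reference set, with the
#' percentage expressed relative to the query size
#' (`100 * |intersection| / |query|`), as used for thanatotranscriptome
#' enrichment comparisons.
#'
#' @param query,reference [gene_list()] objects in the same namespace.
#' @return A one-row tibble: `query_size`, `reference_size`,
#'   `intersection_size`, `percentage`, and `intersecting` (list-column of
#'   the shared ids).
#' @export
overlap_percentage <- function(query, reference) {
  stopifnot(inherits(query, "gene_list"), inherits(reference, "gene_list"))
  check_same_namespace(query, reference)
  if (length(query$ids) == 0L) {
    abort("Empty query list: the overlap percentage is undefined.")
  }
  shared <- query$ids[query$ids %in% reference$ids]
  tibble::tibble(
    query_size = length(query$ids),
    reference_size = length(reference$ids),
    intersection_size = length(shared),
    percentage = 100 * length(shared) / length(query$ids),
    intersecting = list(shared)
  )
}

#' Audit a gene list against germ-layer / patterning marker sets
#'
#' Intersects the query list with each named marker set (mesoderm,
#' endoderm, axis patterning, ...) and reports one overlap row per set. The
#' audit is "all clear" only when every intersection is empty -- i.e. none
#' of the critical marker genes appear in the query.
#'
#' @param query A [gene_list()].
#' @param marker_sets A named list of [gene_list()] objects.
#' @return A tibble of class `germ_layer_audit` with one row per marker
#'   set (`set`, overlap columns) plus an `all_clear` attribute; the
#'   `all_clear()` accessor reads it.
#' @export
germ_layer_audit <- function(query, marker_sets) {
  stopifnot(inherits(query, "gene_list"), length(marker_sets) > 0)
  rows <- purrr::imap(marker_sets, function(set, nm) {
    dplyr::bind_cols(tibble::tibble(set = nm), overlap_percentage(query, set))
  })
  out <- dplyr::bind_rows(rows)
  structure(
    out,
    class = unique(c("germ_layer_audit", class(out))),
    all_clear = all(out$intersection_size == 0L)
  )
}

#' @param audit A `germ_layer_audit`.
#' @rdname germ_layer_audit
#' @export
all_clear <- function(audit) {
  isTRUE(attr(audit, "all_clear"))
}

#' Phylostratum enrichment comparison
#'
#' Cross-tabulates two or more gene lists against a phylostratum map (one
#' gene-age stratum per gene, ordered oldest clade first) and tests whether
#' the lists' stratum distributions differ with a Pearson chi-square test
#' on the counts (no continuity correction). Genes absent from the stratum
#' map are excluded from the contingency table but reported, never silently
#' dropped. Standardized residuals are returned so the strata driving the
#' difference are auditable.
#'
#' @param lists A named list of [gene_list()] objects (>= 2).
#' @param strata_map A data frame with columns `gene_id`, `stratum`.
#' @param strata_order Ordered stratum labels, oldest first; defaults to
#'   [phylostrata_default()] filtered to the strata present.
#' @param selected_strata Optional subset of strata to retain in the
#'   contingency table (order preserved).
#' @return An object of class `stratum_table`: per-list per-stratum counts
#'   and fractions, unmapped counts, the chi-square statistic, degrees of
#'   freedom, p-value, expected counts and standardized residuals. See
#'   [tidy.stratum_table()] and [glance.stratum_table()].
#' @export
stratum_enrichment <- function(lists, strata_map, strata_order = NULL,
                               selected_strata = NULL) {
  if (length(lists) < 2L) abort("Need at least two gene lists to compare.")
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    abort("`lists` must be a named list.")
  }
  strata_map <- tibble::as_tibble(strata_map)
  stopifnot(all(c("gene_id", "stratum") %in% names(strata_map)))
  order_all <- strata_order %||% phylostrata_default()
  present <- unique(strata_map$stratum)
  order_all <- c(order_all[order_all %in% present],
                 setdiff(present, order_all))
  if (!is.null(selected_strata)) {
    order_all <- order_all[order_all %in% selected_strata]
  }
  lookup <- setNames(strata_map$stratum, strata_map$gene_id)
  counts <- purrr::imap(lists, function(gl, nm) {
    st <- unname(lookup[gl$ids])
    tibble::tibble(
      list = nm,
      list_size = length(gl$ids),
      n_unmapped = sum(is.na(st)),
      stratum = factor(st[!is.na(st)], levels = order_all)
    )
  })
  tab <- t(vapply(counts, function(d) table(d$stratum),
                  setNames(integer(length(order_all)), order_all)))
  rownames(tab) <- names(lists)
  # drop strata (columns) / lists (rows) that are all-zero: every expected
  # count there is zero and the chi-square statistic is undefined
  drop_col <- colSums(tab) == 0
  drop_row <- rowSums(tab) == 0
  if (any(drop_col)) {
    warn(sprintf(
      "Dropping empty stratum(a): %s",
      paste(colnames(tab)[drop_col], collapse = ", ")
    ))
  }
  if (any(drop_row)) {
    warn(sprintf(
      "Dropping empty list(s): %s",
      paste(rownames(tab)[drop_row], collapse = ", ")
    ))
  }
  tab <- tab[!drop_row, !drop_col, drop = FALSE]
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  unmapped <- dplyr::distinct(
    dplyr::bind_rows(counts), .data$list, .data$list_size, .data$n_unmapped
  )
  long <- tibble::as_tibble(as.data.frame(as.table(tab), stringsAsFactors = FALSE))
  names(long) <- c("list", "stratum", "count")
  long$stratum <- factor(long$stratum, levels = colnames(tab))
  long <- dplyr::group_by(long, .data$list)
  long <- dplyr::mutate(long, fraction = .data$count / sum(.data$count))
  long <- dplyr::ungroup(long)
  # align expected / residuals with the long table by (list, stratum)
  idx <- cbind(match(long$list, rownames(tab)),
               match(as.character(long$stratum), colnames(tab)))
  long$expected <- ht$expected[idx]
  long$std_residual <- ht$stdres[idx]
  structure(
    list(
      table = long,
      contingency = tab,
      unmapped = unmapped,
      strata = colnames(tab),
      statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = ht$p.value
    ),
    class = "stratum_table"
  )
}

#' @export
print.stratum_table <- function(x, ...) {
  cat(sprintf(
    "<stratum_table> %d lists x %d strata; X-squared = %.4g, df = %d, p = %.4g\n",
    nrow(x$contingency), ncol(x$contingency), x$statistic, x$df, x$p_value
  ))
  if (any(x$unmapped$n_unmapped > 0)) {
    cat("  unmapped genes:",
        paste(sprintf("%s: %d", x$unmapped$list, x$unmapped$n_unmapped),
              collapse = ", "), "\n")
  }
  print(x$table, n = 8)
  invisible(x)
}
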