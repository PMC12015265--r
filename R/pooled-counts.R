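#' Pooled count matrix with pool design
#'
#' Container for a gene-by-sample matrix of pooled RNA-seq counts together
#' with its pool design. Each sample (column) is one pooled library whose
#' per-gene value is treated as the mean over the `n_individuals` animals in
#' that pool; the design records, per sample, the group label and the number
#' of individuals pooled. Values may be non-integer (RSEM-style expected
#' counts, or means of integer draws from the simulator).
#'
#' @param counts A data frame whose first column (`gene_id`) holds unique
#'   gene identifiers and whose remaining columns are non-negative numeric
#'   counts, one column per pooled sample.
#' @param design A data frame with columns `sample_id`, `group`,
#'   `n_individuals`, one row per count column.
#'
#' @return An object of class `pooled_counts`: a list with elements
#'   `counts` (tibble) and `design` (tibble).
#' @examples
#' counts <- tibble::tibble(
#'   gene_id = c("g1", "g2"),
#'   X1 = c(5, 0), X2 = c(6, 1), E1 = c(4, 2), E2 = c(5, 3)
#' )
#' design <- tibble::tibble(
#'   sample_id = c("X1", "X2", "E1", "E2"),
#'   group = c("xenobot", "xenobot", "embryo", "embryo"),
#'   n_individuals = c(50, 50, 10, 10)
#' )
#' pooled_counts(counts, design)
#' @export
pooled_counts <- function(counts, design) {
  counts <- tibble::as_tibble(counts)
  design <- tibble::as_tibble(design)
  if (ncol(counts) < 2L) {
    abort("`counts` needs a gene-id column plus at least one sample column.")
  }
  names(counts)[1] <- "gene_id"
  counts$gene_id <- as.character(counts$gene_id)
  dup <- unique(counts$gene_id[duplicated(counts$gene_id)])
  if (length(dup) > 0L) {
    abort(sprintf(
      "Duplicate gene IDs are not allowed: %s",
      paste(head(dup, 5L), collapse = ", ")
    ))
  }
  need <- c("sample_id", "group", "n_individuals")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0L) {
    abort(sprintf("`design` is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  design$sample_id <- as.character(design$sample_id)
  samples <- names(counts)[-1]
  absent <- setdiff(samples, design$sample_id)
  if (length(absent) > 0L) {
    abort(sprintf(
      "Sample(s) present in counts but missing from the design: %s",
      paste(absent, collapse = ", ")
    ))
  }
  design <- design[match(samples, design$sample_id), , drop = FALSE]
  vals <- as.matrix(counts[-1])
  if (!is.numeric(vals)) abort("Count columns must be numeric.")
  if (anyNA(vals)) abort("Counts must not contain missing values.")
  if (any(vals < 0)) abort("Counts must be non-negative.")
  if (any(design$n_individuals < 1)) {
    abort("`n_individuals` must be >= 1 for every sample.")
  }
  structure(
    list(counts = counts, design = design),
    class = "pooled_counts"
  )
}

#' @export
print.pooled_counts <- function(x, ...) {
  cat(sprintf(
    "<pooled_counts> %d genes x %d samples (%s)\n",
    nrow(x$counts), nrow(x$design),
    paste(sprintf(
      "%s: %d pools of n=%g", unique(x$design$group),
      as.integer(table(x$design$group)[unique(x$design$group)]),
      x$design$n_individuals[!duplicated(x$design$group)]
    ), collapse = "; ")
  ))
  print(x$counts, n = 5)
  invisible(x)
}

#' @export
dim.pooled_counts <- function(x) c(nrow(x$counts), nrow(x$design))

#' Extract the numeric count matrix
#'
#' @param x A [pooled_counts()] object.
#' @return A numeric matrix, genes as rows (rownames = gene IDs).
#' @export
counts_matrix <- function(x) {
  stopifnot(inherits(x, "pooled_counts"))
  m <- as.matrix(x$counts[-1])
  rownames(m) <- x$counts$gene_id
  m
}

#' Per-sample library sizes (column sums)
#'
#' @param x A [pooled_counts()] object.
#' @return A named numeric vector of column sums.
#' @export
library_sizes <- function(x) {
  colSums(counts_matrix(x))
}

#' @importFrom tibble as_tibble
#' @method as_tibble pooled_counts
#' @export
as_tibble.pooled_counts <- function(x, ...) {
  long <- tidyr::pivot_longer(
    x$counts, -"gene_id",
    names_to = "sample_id", values_to = "count"
  )
  dplyr::left_join(long, x$design, by = "sample_id")
}

#' Read / write a pooled count matrix
#'
#' The on-disk format is two TSV files: the matrix (first column `gene_id`,
#' one column per sample) and a design sidecar with columns `sample_id`,
#' `group`, `n_individuals`. `read_counts()` and `write_counts()` round-trip
#' losslessly.
#'
#' @param path Path of the count matrix TSV.
#' @param design_path Path of the design TSV.
#' @return `read_counts()` returns a [pooled_counts()] object;
#'   `write_counts()` returns `x` invisibly.
#' @export
read_counts <- function(path, design_path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  design <- readr::read_tsv(design_path, show_col_types = FALSE, progress = FALSE)
  pooled_counts(counts, design)
}

#' @param x A [pooled_counts()] object.
#' @rdname read_counts
#' @export
write_counts <- function(x, path, design_path) {
  stopifnot(inherits(x, "pooled_counts"))
  readr::write_tsv(x$counts, path, progress = FALSE)
  readr::write_tsv(x$design, design_path, progress = FALSE)
  invisible(x)
}
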