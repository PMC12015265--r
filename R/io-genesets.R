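# Plain-text gene-set formats: one-id-per-line lists, GMT collections,
# and two-column TSV maps (ortholog and stratum assignments).

#' Read / write a one-id-per-line gene list
#'
#' @param path File path.
#' @param namespace,provenance Passed to [gene_list()].
#' @return `read_gene_list()` returns a [gene_list()] (duplicates are
#'   removed with a message); `write_gene_list()` returns `x` invisibly.
#' @export
read_gene_list <- function(path, namespace = "xenopus_symbol",
                           provenance = basename(path)) {
  ids <- readr::read_lines(path, progress = FALSE)
  ids <- ids[nzchar(trimws(ids))]
  if (anyDuplicated(ids)) {
    inform(sprintf("Removed %d duplicate id(s) from %s.",
                   sum(duplicated(ids)), basename(path)))
    ids <- ids[!duplicated(ids)]
  }
  gene_list(trimws(ids), namespace = namespace, provenance = provenance)
}

#' @param x A [gene_list()].
#' @rdname read_gene_list
#' @export
write_gene_list <- function(x, path) {
  stopifnot(inherits(x, "gene_list"))
  readr::write_lines(x$ids, path)
  invisible(x)
}

#' Read / write GMT gene-set collections
#'
#' GMT is the tab-separated gene-set format: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path File path.
#' @param namespace Namespace assigned to every set.
#' @return `read_gmt()` returns a named list of [gene_list()] objects;
#'   `write_gmt()` returns `sets` invisibly.
#' @export
read_gmt <- function(path, namespace = "xenopus_symbol") {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      abort(sprintf("Malformed GMT line (fewer than 3 fields): %s",
                    substr(ln, 1, 40)))
    }
    gene_list(unique(parts[-c(1, 2)]), namespace = namespace,
              provenance = parts[2])
  })
  names(sets) <- vapply(lines, function(ln) {
    strsplit(ln, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' @param sets A named list of [gene_list()] objects.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    gl <- sets[[nm]]
    paste(c(nm, if (nzchar(gl$provenance)) gl$provenance else nm, gl$ids),
          collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(sets)
}

#' Read a two-column ortholog map TSV
#'
#' @param path File path of a headerless or headered two-column TSV
#'   (`source`, `target`).
#' @return An [ortholog_map()].
#' @export
read_ortholog_map <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_names = c("source", "target"), skip = 0)
  if (identical(tolower(unlist(d[1, ])), c("source", "target"))) {
    d <- d[-1, , drop = FALSE]
  }
  ortholog_map(d$source, d$target)
}

#' Read a two-column stratum map TSV
#'
#' @param path File path of a two-column TSV (`gene_id`, `stratum`).
#' @return A tibble with columns `gene_id`, `stratum`.
#' @export
read_stratum_map <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_names = c("gene_id", "stratum"))
  if (identical(tolower(unlist(d[1, ])), c("gene_id", "stratum"))) {
    d <- d[-1, , drop = FALSE]
  }
  tibble::as_tibble(d)
}

#' @param map An [ortholog_map()] or stratum map tibble.
#' @rdname read_ortholog_map
#' @export
write_ortholog_map <- function(map, path) {
  readr::write_tsv(tibble::as_tibble(map), path, col_names = FALSE,
                   progress = FALSE)
  invisible(map)
}
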