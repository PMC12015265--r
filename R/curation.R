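#' Gene list with namespace and provenance
#'
#' An ordered, duplicate-free set of gene identifiers together with the
#' identifier namespace (Xenopus symbols or human ortholog symbols) and a
#' free-text provenance label recording which curation stage produced it.
#' Matching throughout the curation pipeline is exact string matching (no
#' case folding): silent case folding corrupts symbol namespaces.
#'
#' @param ids Character vector of identifiers (no duplicates).
#' @param namespace `"xenopus_symbol"` or `"human_symbol"`.
#' @param provenance Free-text stage label.
#' @return An object of class `gene_list`.
#' @examples
#' gene_list(c("sox2.L", "LOC108718123", "krt12.4.S"))
#' @export
gene_list <- function(ids, namespace = c("xenopus_symbol", "human_symbol"),
                      provenance = "") {
  namespace <- match.arg(namespace)
  ids <- as.character(ids)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(sprintf(
      "Duplicate identifiers in gene list: %s",
      paste(head(dup, 5L), collapse = ", ")
    ))
  }
  structure(
    list(ids = ids, namespace = namespace, provenance = provenance),
    class = "gene_list"
  )
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf(
    "<gene_list> %d ids (%s%s)\n", length(x$ids), x$namespace,
    if (nzchar(x$provenance)) paste0("; ", x$provenance) else ""
  ))
  cat(" ", paste(head(x$ids, 8L), collapse = ", "),
      if (length(x$ids) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
length.gene_list <- function(x) length(x$ids)

#' @export
as.character.gene_list <- function(x, ...) x$ids

check_same_namespace <- function(a, b) {
  if (a$namespace != b$namespace) {
    abort(sprintf(
      "Namespace mismatch: %s vs %s.", a$namespace, b$namespace
    ))
  }
}

#' Subtract a gene set
#'
#' Removes from `x` every identifier that occurs in `set` (exact-ID match),
#' preserving order. Both lists must share a namespace.
#'
#' @param x,set [gene_list()] objects.
#' @param label Provenance label for the result.
#' @return A [gene_list()].
#' @export
subtract_gene_set <- function(x, set, label = NULL) {
  stopifnot(inherits(x, "gene_list"), inherits(set, "gene_list"))
  check_same_namespace(x, set)
  gene_list(
    x$ids[!x$ids %in% set$ids],
    namespace = x$namespace,
    provenance = label %||% sprintf("minus %s", set$provenance)
  )
}

#' Ortholog map
#'
#' A many-to-one source-to-target identifier map (each source maps to at
#' most one target), as produced by ortholog lookup services; the map is a
#' consumed input, never computed here.
#'
#' @param source,target Character vectors of equal length.
#' @return A tibble of class `ortholog_map` with columns `source`,
#'   `target`.
#' @export
ortholog_map <- function(source, target) {
  source <- as.character(source)
  target <- as.character(target)
  stopifnot(length(source) == length(target))
  dup <- unique(source[duplicated(source)])
  if (length(dup) > 0L) {
    abort(sprintf(
      "A source id may map to at most one target; duplicated: %s",
      paste(head(dup, 5L), collapse = ", ")
    ))
  }
  out <- tibble::tibble(source = source, target = target)
  class(out) <- unique(c("ortholog_map", class(out)))
  out
}

#' Annotate uncharacterized LOC genes
#'
#' Replaces LOC-style uncharacterized identifiers (default pattern: prefix
#' `LOC` followed by digits) with their mapped symbols; unmapped LOC ids
#' are dropped when `drop_unannotated = TRUE`, and non-LOC ids are left
#' untouched. Replacement can merge ids (two LOC genes annotated to the
#' same symbol, or a symbol already present); duplicates keep their first
#' occurrence.
#'
#' @param x A [gene_list()].
#' @param map An [ortholog_map()] (or data frame with columns `source`,
#'   `target`) taking LOC ids to symbols.
#' @param drop_unannotated Drop LOC ids absent from the map (default
#'   `TRUE`).
#' @param pattern Regular expression identifying LOC-style ids.
#' @return A [gene_list()] with attributes `n_loc`, `n_annotated`,
#'   `n_dropped` recording the bookkeeping.
#' @export
annotate_loc_genes <- function(x, map, drop_unannotated = TRUE,
                               pattern = "^LOC[0-9]+") {
  stopifnot(inherits(x, "gene_list"))
  map <- tibble::as_tibble(map)
  is_loc <- grepl(pattern, x$ids)
  lookup <- setNames(map$target, map$source)
  ids <- x$ids
  mapped <- is_loc & ids %in% names(lookup)
  ids[mapped] <- unname(lookup[ids[mapped]])
  drop <- is_loc & !mapped & drop_unannotated
  ids <- ids[!drop]
  ids <- ids[!duplicated(ids)]
  out <- gene_list(ids, namespace = x$namespace, provenance = "LOC-annotated")
  attr(out, "n_loc") <- sum(is_loc)
  attr(out, "n_annotated") <- sum(mapped)
  attr(out, "n_dropped") <- sum(drop)
  out
}

homeolog_base <- function(ids, suffix_pattern = "\\.(L|S)$") {
  sub(suffix_pattern, "", ids)
}

#' Collapse long/short-chromosome homeolog duplicates
#'
#' Identifiers sharing a base symbol after stripping a terminal `.L` or
#' `.S` (the allotetraploid long/short chromosome convention) collapse to a
#' single entry named by the base symbol. When a count matrix is supplied
#' the copy with the higher mean count survives; otherwise the `.L` copy is
#' preferred; remaining ties break lexicographically. The operation is
#' idempotent and keeps first-occurrence order.
#'
#' @param x A [gene_list()].
#' @param counts Optional [pooled_counts()] used for the
#'   keep-higher-expression survivor rule.
#' @param prefer Survivor rule when no counts are available or means tie:
#'   `"L"` (default) or `"lexicographic"`.
#' @param suffix_pattern Regular expression stripped to obtain the base
#'   symbol.
#' @return A [gene_list()] of base symbols.
#' @export
dedup_homeologs <- function(x, counts = NULL, prefer = c("L", "lexicographic"),
                            suffix_pattern = "\\.(L|S)$") {
  stopifnot(inherits(x, "gene_list"))
  prefer <- match.arg(prefer)
  ids <- x$ids
  base <- homeolog_base(ids, suffix_pattern)
  mean_count <- rep(NA_real_, length(ids))
  if (!is.null(counts)) {
    stopifnot(inherits(counts, "pooled_counts"))
    m <- counts_matrix(counts)
    hit <- match(ids, rownames(m))
    mean_count[!is.na(hit)] <- rowMeans(m)[hit[!is.na(hit)]]
  }
  ord <- seq_along(ids)
  pick <- vapply(split(ord, base)[unique(base)], function(idx) {
    if (length(idx) == 1L) return(idx)
    mc <- mean_count[idx]
    if (any(!is.na(mc))) {
      best <- idx[!is.na(mc) & mc == max(mc, na.rm = TRUE)]
      if (length(best) == 1L) return(best)
      idx <- best
    }
    if (prefer == "L") {
      is_l <- grepl("\\.L$", ids[idx])
      if (any(is_l)) idx <- idx[is_l]
    }
    idx[order(ids[idx])][1]
  }, integer(1))
  # output follows the first occurrence of each base symbol
  gene_list(names(pick), namespace = x$namespace,
            provenance = "homeolog-deduplicated")
}

#' Map a gene list to orthologs
#'
#' Maps every identifier through the ortholog map, dropping unmapped ids
#' and deduplicating targets (the map may be many-to-one), so the output
#' size never exceeds the input size. The output namespace is
#' `human_symbol`.
#'
#' @param x A [gene_list()] in the map's source namespace.
#' @param map An [ortholog_map()] (or data frame with columns `source`,
#'   `target`).
#' @return A [gene_list()] of mapped target symbols.
#' @export
map_to_orthologs <- function(x, map) {
  stopifnot(inherits(x, "gene_list"))
  map <- tibble::as_tibble(map)
  lookup <- setNames(map$target, map$source)
  targets <- unname(lookup[x$ids])
  targets <- targets[!is.na(targets)]
  targets <- targets[!duplicated(targets)]
  gene_list(targets, namespace = "human_symbol", provenance = "ortholog-mapped")
}

#' Run the stringent curation chain
#'
#' Executes an ordered sequence of curation stages -- cell-type gene-set
#' subtraction, LOC annotation, homeolog deduplication, further stringent
#' subtractions, ortholog mapping -- and reports per-stage gene counts. The
#' canonical chain mirrors the stringent curation of uniquely upregulated
#' transcripts: subtract epidermal progenitors, annotate LOC genes,
#' deduplicate homeologs, subtract the remaining epidermal cell-type sets,
#' then map to human orthologs, with monotone non-increasing counts.
#'
#' @param x The starting [gene_list()].
#' @param stages A list of stage descriptions, each a list with element
#'   `stage` (one of `"subtract"`, `"annotate_loc"`, `"dedup_homeologs"`,
#'   `"map_orthologs"`), an optional `label`, plus the stage's inputs:
#'   `set` (a [gene_list()]) for `subtract`, `map` (an [ortholog_map()])
#'   for `annotate_loc` / `map_orthologs`, and any further arguments of the
#'   stage function (e.g. `drop_unannotated`, `prefer`).
#' @param counts Optional [pooled_counts()] forwarded to homeolog
#'   deduplication.
#' @return A list with `genes` (the final [gene_list()]) and `report` (a
#'   tibble: `stage`, `label`, `genes_in`, `genes_out`, `removed` sample of
#'   removed/renamed ids).
#' @export
run_curation <- function(x, stages, counts = NULL) {
  stopifnot(inherits(x, "gene_list"))
  report <- list()
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    kind <- st$stage
    label <- st$label %||% kind
    n_in <- length(x$ids)
    before_ids <- x$ids
    args <- st[!names(st) %in% c("stage", "label", "set", "map")]
    y <- switch(kind,
      subtract = subtract_gene_set(x, st$set, label = label),
      annotate_loc = do.call(annotate_loc_genes, c(list(x, st$map), args)),
      dedup_homeologs = do.call(dedup_homeologs, c(list(x, counts = counts), args)),
      map_orthologs = map_to_orthologs(x, st$map),
      abort(sprintf("Unknown curation stage '%s'.", kind))
    )
    removed <- setdiff(before_ids, y$ids)
    report[[i]] <- tibble::tibble(
      stage = kind,
      label = label,
      genes_in = n_in,
      genes_out = length(y$ids),
      removed = paste(head(removed, 5L), collapse = ",")
    )
    x <- y
  }
  x$provenance <- "curated"
  list(genes = x, report = dplyr::bind_rows(report))
}

#' Read a curation stage configuration
#'
#' Reads an ordered YAML list of stages, each entry a mapping with keys
#' `stage`, optional `label`, optional `file` (a one-id-per-line gene list
#' for `subtract` stages, or a two-column TSV map for `annotate_loc` /
#' `map_orthologs`), and any further stage options.
#'
#' @param path Path to the YAML file.
#' @param namespace Namespace assumed for gene-list files.
#' @return A `stages` list suitable for [run_curation()].
#' @export
read_curation_config <- function(path, namespace = "xenopus_symbol") {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(st) {
    if (!is.null(st$file)) {
      if (st$stage == "subtract") {
        st$set <- read_gene_list(st$file, namespace = namespace,
                                 provenance = st$label %||% st$file)
      } else {
        st$map <- read_ortholog_map(st$file)
      }
      st$file <- NULL
    }
    st
  })
}
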