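#' Simulation configuration for pooled-count experiments
#'
#' Defines the study design the simulator emulates: two (or more) groups,
#' each profiled as `r` replicate pooled libraries where every pool value is
#' the arithmetic mean over `n` individuals, and per-individual counts are
#' negative binomial with mean `mu` and dispersion `phi`
#' (variance `mu + phi * mu^2`; `phi = 0` is the Poisson limit).
#'
#' The default design matches three replicate pools per group with 50
#' individuals per Xenobot pool and 10 per embryo pool. The default mean
#' grid is drawn log-uniformly over \[1, 1e4\] so rank-percentile binning is
#' exercised across expression magnitudes.
#'
#' @param n_genes Number of genes (positive integer).
#' @param groups A data frame with columns `label`, `n` (individuals per
#'   pool, >= 1) and `r` (replicate pools, >= 2).
#' @param mean_grid Optional numeric vector of per-gene expected expression
#'   (positive, length `n_genes`). Drawn log-uniformly over \[1, 1e4\] when
#'   `NULL`.
#' @param dispersion Per-group NB dispersion `phi` (>= 0): a single number,
#'   a named vector/list keyed by group label, or per-gene vectors.
#' @param loc_fraction Fraction of gene IDs named LOC-style, in \[0, 1\].
#' @param homeolog_fraction Fraction of symbol genes duplicated as `.L`/`.S`
#'   homeolog pairs, in \[0, 1\].
#' @param seed Integer seed; one global seed feeds a named sub-stream per
#'   generated artifact.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 100, seed = 1)
#' @export
sim_config <- function(n_genes,
                       groups = tibble::tibble(
                         label = c("xenobot", "embryo"),
                         n = c(50, 10),
                         r = c(3, 3)
                       ),
                       mean_grid = NULL,
                       dispersion = 0.2,
                       loc_fraction = 0.41,
                       homeolog_fraction = 0.3,
                       seed = NULL) {
  check_scalar_number(n_genes, "n_genes", min = 1)
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("label", "n", "r") %in% names(groups)))
  if (any(groups$n < 1)) abort("Each group needs n >= 1 individuals per pool.")
  if (any(groups$r < 2)) {
    abort("Each group needs r >= 2 replicate pools (pool SE is undefined otherwise).")
  }
  if (is.null(mean_grid)) {
    mean_grid <- with_stream(seed %||% 0, "mean_grid",
      exp(runif(n_genes, log(1), log(1e4)))
    )
  }
  if (length(mean_grid) != n_genes) abort("`mean_grid` must have length `n_genes`.")
  if (any(mean_grid <= 0)) abort("All means must be positive.")
  disp <- lapply(setNames(groups$label, groups$label), function(g) {
    d <- if (is.list(dispersion) || !is.null(names(dispersion))) {
      if (!g %in% names(dispersion)) abort(sprintf("No dispersion given for group '%s'.", g))
      dispersion[[g]]
    } else {
      dispersion
    }
    d <- rep_len(as.numeric(d), n_genes)
    if (any(d < 0)) abort("Dispersion phi must be >= 0.")
    d
  })
  if (loc_fraction < 0 || loc_fraction > 1) abort("`loc_fraction` must be in [0, 1].")
  if (homeolog_fraction < 0 || homeolog_fraction > 1) {
    abort("`homeolog_fraction` must be in [0, 1].")
  }
  structure(
    list(
      n_genes = as.integer(n_genes), groups = groups, mean_grid = mean_grid,
      dispersion = disp, loc_fraction = loc_fraction,
      homeolog_fraction = homeolog_fraction, seed = seed
    ),
    class = "sim_config"
  )
}

nb_draws <- function(k, mu, phi) {
  if (phi == 0) rpois(k, mu) else rnbinom(k, mu = mu, size = 1 / phi)
}

# G x r matrix of pool values: each pool is the mean of n NB individual
# draws per gene. Vectorized one replicate at a time; Poisson-limit genes
# (phi = 0) are drawn separately since rnbinom rejects size = Inf.
pool_value_matrix <- function(mu, phi, n, r) {
  G <- length(mu)
  pois <- phi == 0
  out <- matrix(0, G, r)
  for (j in seq_len(r)) {
    m <- matrix(0, G, n)
    if (any(!pois)) {
      m[!pois, ] <- rnbinom(sum(!pois) * n,
        mu = rep(mu[!pois], times = n),
        size = rep(1 / phi[!pois], times = n)
      )
    }
    if (any(pois)) {
      m[pois, ] <- rpois(sum(pois) * n, rep(mu[pois], times = n))
    }
    out[, j] <- rowMeans(m)
  }
  out
}

#' Simulate pooled counts with known ground truth
#'
#' For each group and replicate pool, every gene's pool value is the
#' arithmetic mean of `n` independent negative-binomial individual draws
#' (the pooling model: a pool's count represents the mean over the
#' individuals in that pool). The returned truth table records, per gene and
#' group, the true individual mean, standard deviation
#' `sqrt(mu + phi * mu^2)`, and CV, so deconvolution can be checked against
#' ground truth.
#'
#' @param config A [sim_config()].
#' @param round_pools Round pool values to integers? Defaults to `FALSE`:
#'   keeping the exact means preserves the SE*sqrt(n) algebra (real
#'   RSEM-style counts are non-integer anyway).
#' @return A list with elements `counts` (a [pooled_counts()]) and `truth`
#'   (tibble: `gene_id`, `group`, `mu`, `sigma`, `cv`).
#' @examples
#' sim <- simulate_pooled_counts(sim_config(n_genes = 20, seed = 7))
#' sim$counts
#' @export
simulate_pooled_counts <- function(config, round_pools = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  gene_ids <- sprintf("gene%05d", seq_len(config$n_genes))
  mu <- config$mean_grid
  blocks <- list()
  design <- list()
  truth <- list()
  for (gi in seq_len(nrow(config$groups))) {
    g <- config$groups$label[gi]
    n <- config$groups$n[gi]
    r <- config$groups$r[gi]
    phi <- config$dispersion[[g]]
    pools <- with_stream(config$seed, paste0("counts/", g),
      pool_value_matrix(mu, phi, n, r)
    )
    if (round_pools) pools <- round(pools)
    colnames(pools) <- sprintf("%s_%d", g, seq_len(r))
    blocks[[g]] <- pools
    design[[g]] <- tibble::tibble(
      sample_id = colnames(pools), group = g, n_individuals = n
    )
    sigma <- sqrt(mu + phi * mu^2)
    truth[[g]] <- tibble::tibble(
      gene_id = gene_ids, group = g, mu = mu, sigma = sigma, cv = sigma / mu
    )
  }
  counts <- tibble::as_tibble(as.data.frame(do.call(cbind, blocks)))
  counts <- dplyr::bind_cols(tibble::tibble(gene_id = gene_ids), counts)
  list(
    counts = pooled_counts(counts, dplyr::bind_rows(design)),
    truth = dplyr::bind_rows(truth)
  )
}

#' Simulate a gene universe with annotation fixtures
#'
#' Generates the identifier-level inputs the curation and gene-set modules
#' consume: a gene-ID universe containing LOC-style uncharacterized IDs at
#' the configured fraction and `.L`/`.S` homeolog duplicate pairs (the
#' allotetraploid long/short chromosome convention), an ortholog map
#' covering a configurable fraction of IDs, named cell-type gene sets, and a
#' stratum map assigning exactly one gene-age stratum from an ordered list
#' to every gene.
#'
#' @param config A [sim_config()]; `loc_fraction`, `homeolog_fraction` and
#'   `seed` are used.
#' @param ortholog_coverage Fraction of universe IDs covered by the ortholog
#'   map, in \[0, 1\].
#' @param set_sizes Named integer vector: number of genes sampled into each
#'   cell-type gene set.
#' @param strata Ordered character vector of stratum labels, oldest first.
#' @return A list: `genes` (character universe), `ortholog_map` (tibble
#'   `source`, `target`), `homeolog_pairs` (tibble `base`, `l_id`, `s_id`),
#'   `gene_sets` (named list of character vectors), `stratum_map` (tibble
#'   `gene_id`, `stratum`), `strata` (the ordered labels).
#' @export
simulate_gene_universe <- function(config,
                                   ortholog_coverage = 0.8,
                                   set_sizes = c(
                                     epidermal_progenitor = 60,
                                     multiciliated = 40,
                                     ionocyte = 30,
                                     goblet = 30
                                   ),
                                   strata = phylostrata_default()) {
  stopifnot(inherits(config, "sim_config"))
  if (ortholog_coverage < 0 || ortholog_coverage > 1) {
    abort("`ortholog_coverage` must be in [0, 1].")
  }
  ng <- config$n_genes
  n_loc <- round(config$loc_fraction * ng)
  with_stream(config$seed, "universe", {
    loc_idx <- sort(sample.int(ng, n_loc))
    base <- sprintf("sym%05d", seq_len(ng))
    base[loc_idx] <- sprintf("LOC1%06d", loc_idx)
    sym_idx <- setdiff(seq_len(ng), loc_idx)
    n_pair <- round(config$homeolog_fraction * length(sym_idx))
    pair_idx <- sort(sample(sym_idx, n_pair))
    pair_base <- base[pair_idx]
    homeolog_pairs <- tibble::tibble(
      base = pair_base,
      l_id = paste0(pair_base, ".L"),
      s_id = paste0(pair_base, ".S")
    )
    genes <- base
    if (n_pair > 0L) {
      genes <- c(
        genes[-pair_idx],
        as.vector(rbind(homeolog_pairs$l_id, homeolog_pairs$s_id))
      )
    }
    genes <- sample(genes)
    n_map <- round(ortholog_coverage * length(genes))
    mapped <- sort(sample(seq_along(genes), n_map))
    ortholog_map <- tibble::tibble(
      source = genes[mapped],
      # ~10% of targets collide, so mapping is many-to-one as in real HCOP
      target = sprintf("HUM%05d", ceiling(seq_len(n_map) / 1.1))
    )
    gene_sets <- lapply(set_sizes, function(k) {
      sample(genes, min(k, length(genes)))
    })
    stratum_map <- tibble::tibble(
      gene_id = genes,
      stratum = sample(strata, length(genes), replace = TRUE,
                       prob = seq(length(strata), 1))
    )
    list(
      genes = genes, ortholog_map = ortholog_map,
      homeolog_pairs = homeolog_pairs, gene_sets = gene_sets,
      stratum_map = stratum_map, strata = strata
    )
  })
}

#' Simulate gene lists with planted overlaps
#'
#' Builds a synthetic stand-in for an overlap-enrichment comparison: a
#' reference set plus a query and a control list of given sizes whose
#' intersections with the reference are planted exactly, so overlap
#' percentages have known ground truth. All identifiers are synthetic
#' human-symbol-style ids.
#'
#' @param query_size,control_size,reference_size List sizes.
#' @param query_hits,control_hits Planted intersection sizes with the
#'   reference.
#' @param seed Integer seed.
#' @return A list of three [gene_list()]s: `query`, `control`,
#'   `reference`.
#' @export
simulate_overlap_lists <- function(query_size, control_size, reference_size,
                                   query_hits, control_hits, seed = NULL) {
  stopifnot(query_hits <= min(query_size, reference_size),
            control_hits <= min(control_size, reference_size))
  with_stream(seed, "overlap_lists", {
    reference <- sprintf("REF%05d", seq_len(reference_size))
    query <- c(
      sample(reference, query_hits),
      sprintf("QRY%05d", seq_len(query_size - query_hits))
    )
    control <- c(
      sample(reference, control_hits),
      sprintf("CTL%05d", seq_len(control_size - control_hits))
    )
    list(
      query = gene_list(sample(query), namespace = "human_symbol",
                        provenance = "synthetic query"),
      control = gene_list(sample(control), namespace = "human_symbol",
                          provenance = "synthetic control"),
      reference = gene_list(reference, namespace = "human_symbol",
                            provenance = "synthetic reference")
    )
  })
}

#' Default ordered phylostratum labels
#'
#' The ordered gene-age strata used for Xenopus phylostratigraphy, oldest
#' clade first, ending with the focal species (orphan genes).
#'
#' @return A character vector of stratum labels.
#' @export
phylostrata_default <- function() {
  c(
    "All living organisms", "Eukaryota", "Opisthokonta", "Metazoa",
    "Eumetazoa", "Bilateria", "Deuterostomia", "Chordata", "Vertebrata",
    "Gnathostomata", "Euteleostomi", "Sarcopterygii", "Tetrapoda", "Anura",
    "Xenopus", "Xenopus Laevis"
  )
}

#' Simulate a planar tracking export
#'
#' Generates a time-lapse track in the format produced by video tracking:
#' one row per frame with movie time, x/y in mm, and an interval label.
#' Defaults emulate capture of one frame every 2 s of real time compressed
#' to a 30 fps movie, so 1 s of movie equals 1 min of real time, and three
#' equal 10-min before/during/after segments.
#'
#' @param pattern One of `"stationary"`, `"circular"`, `"linear"`.
#' @param speed Ground-truth speed in mm/min (circular and linear patterns).
#' @param duration Real-time duration in minutes.
#' @param frame_interval Real seconds between captured frames.
#' @param radius Circle radius in mm (circular pattern); the angular rate is
#'   `speed / radius` rad/min.
#' @param jitter_sd SD (mm) of isotropic Gaussian positional jitter.
#' @param time_scale Real minutes per second of movie.
#' @param seed Integer seed (only jitter consumes randomness).
#' @return A `track_series` tibble: `frame`, `t_movie_s`, `t_min`, `x_mm`,
#'   `y_mm`, `interval`, with `time_scale` and `capture_interval`
#'   attributes.
#' @examples
#' tr <- simulate_track("circular", speed = 1, radius = 2, duration = 30)
#' @export
simulate_track <- function(pattern = c("stationary", "circular", "linear"),
                           speed = 1,
                           duration = 30,
                           frame_interval = 2,
                           radius = 2,
                           jitter_sd = 0,
                           time_scale = 1,
                           seed = NULL) {
  pattern <- match.arg(pattern)
  check_scalar_number(duration, "duration", min = 0, strict_min = TRUE)
  check_scalar_number(frame_interval, "frame_interval", min = 0, strict_min = TRUE)
  t_min <- seq(0, duration, by = frame_interval / 60)
  nf <- length(t_min)
  xy <- switch(pattern,
    stationary = cbind(rep(0, nf), rep(0, nf)),
    circular = {
      omega <- speed / radius # rad/min
      cbind(radius * cos(omega * t_min), radius * sin(omega * t_min))
    },
    linear = cbind(speed * t_min, rep(0, nf))
  )
  if (jitter_sd > 0) {
    xy <- xy + with_stream(seed %||% 0, "track_jitter",
      matrix(stats::rnorm(2 * nf, sd = jitter_sd), ncol = 2)
    )
  }
  seg <- pmin(floor(t_min / (duration / 3)), 2)
  out <- tibble::tibble(
    frame = seq_len(nf) - 1L,
    t_movie_s = t_min / time_scale,
    t_min = t_min,
    x_mm = xy[, 1],
    y_mm = xy[, 2],
    interval = c("before", "during", "after")[seg + 1L]
  )
  new_track_series(out, time_scale = time_scale, capture_interval = frame_interval)
}

new_track_series <- function(df, time_scale, capture_interval, gaps = integer()) {
  structure(
    df,
    class = unique(c("track_series", class(df))),
    time_scale = time_scale,
    capture_interval = capture_interval,
    gaps = gaps
  )
}
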