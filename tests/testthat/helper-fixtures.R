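# Fixture builders and independent oracles shared across tests.

# Small pooled_counts object from a plain matrix.
toy_counts <- function(m, groups = NULL, n_individuals = NULL) {
  ns <- ncol(m)
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ns))
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  groups <- groups %||% rep(c("X", "E"), each = ceiling(ns / 2))[seq_len(ns)]
  n_individuals <- n_individuals %||% ifelse(groups == groups[1], 50, 10)
  pooled_counts(
    tibble::tibble(gene_id = rownames(m), !!!as.data.frame(m)),
    tibble::tibble(
      sample_id = colnames(m), group = groups, n_individuals = n_individuals
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force evaluation of the weighted trimmed-mean-of-M-values
# scaling factor: doubly trimmed (30% on M, 5% on A) weighted mean of
# gene-wise log ratios against a reference sample, with
# inverse-asymptotic-variance weights, factors renormalized to geometric
# mean 1. Written directly from the published definition, independent of
# the implementation under test.
tmm_oracle <- function(m, ref) {
  lib <- colSums(m)
  one_factor <- function(j) {
    obs <- m[, j]
    refv <- m[, ref]
    nO <- lib[j]
    nR <- lib[ref]
    M <- log2((obs / nO) / (refv / nR))
    A <- (log2(obs / nO) + log2(refv / nR)) / 2
    w <- (nO - obs) / (nO * obs) + (nR - refv) / (nR * refv)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f <- vapply(seq_len(ncol(m)), one_factor, numeric(1))
  f / exp(mean(log(f)))
}
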