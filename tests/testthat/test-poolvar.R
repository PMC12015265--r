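make_cv_table <- function(cv_x, cv_e, overall = seq_along(cv_x)) {
  # hand-built two-group CV table in rank order
  g <- sprintf("g%03d", seq_along(cv_x))
  out <- dplyr::bind_rows(
    tibble::tibble(
      gene_id = g, overall_mean = overall,
      rank = as.integer(rank(overall, ties.method = "first")),
      group = "X", n_individuals = 50, pool_mean = 1, pool_se = cv_x / sqrt(50),
      sigma_hat = cv_x, cv = cv_x
    ),
    tibble::tibble(
      gene_id = g, overall_mean = overall,
      rank = as.integer(rank(overall, ties.method = "first")),
      group = "E", n_individuals = 10, pool_mean = 1, pool_se = cv_e / sqrt(10),
      sigma_hat = cv_e, cv = cv_e
    )
  )
  class(out) <- unique(c("cv_table", class(out)))
  out
}

test_that("genes with any zero pool value are removed", {
  m <- rbind(
    ok = c(5, 6, 4, 3, 2, 1),
    one_zero = c(5, 0, 4, 3, 2, 1),
    all_pos = c(1, 1, 1, 1, 1, 1)
  )
  x <- toy_counts(m)
  kept <- drop_zero_genes(x)
  expect_identical(kept$counts$gene_id, c("ok", "all_pos"))
  # identity on an all-positive matrix
  expect_equal(drop_zero_genes(kept)$counts, kept$counts)
  # survivor count equals a brute-force row scan
  set.seed(31)
  sim <- simulate_pooled_counts(sim_config(
    n_genes = 500, mean_grid = exp(runif(500, 0, 3)), seed = 31
  ))
  mm <- counts_matrix(sim$counts)
  brute <- sum(apply(mm, 1, function(r) all(r > 0)))
  expect_identical(nrow(drop_zero_genes(sim$counts)$counts), brute)
})

test_that("CV deconvolution follows the SE * sqrt(n) identity", {
  # pools (10, 12, 14) with n = 10: SE = 2, sigma = 2 sqrt(10), CV = 0.5271
  m <- rbind(g1 = c(10, 12, 14, 20, 20, 20))
  x <- toy_counts(m, groups = c("E", "E", "E", "X", "X", "X"),
                  n_individuals = c(10, 10, 10, 50, 50, 50))
  cv <- compute_cv_table(x)
  e <- cv[cv$group == "E", ]
  expect_equal(e$pool_se, 2, tolerance = 1e-12)
  expect_equal(e$sigma_hat, 2 * sqrt(10), tolerance = 1e-12)
  expect_equal(e$cv, 2 * sqrt(10) / 12, tolerance = 1e-12)
  expect_equal(e$cv, 0.527046, tolerance = 1e-6)
  # identical pool values give CV 0
  xx <- cv[cv$group == "X", ]
  expect_equal(xx$pool_se, 0)
  expect_equal(xx$cv, 0)
  expect_equal(e$overall_mean, mean(c(10, 12, 14, 20, 20, 20)))
})

test_that("single-replicate groups are rejected", {
  m <- rbind(g1 = c(10, 12, 14))
  x <- toy_counts(m, groups = c("E", "E", "X"),
                  n_individuals = c(10, 10, 50))
  expect_error(compute_cv_table(x), "single replicate")
})

test_that("CV is invariant to a global count rescaling", {
  sim <- simulate_pooled_counts(sim_config(n_genes = 100, seed = 41))
  cv1 <- suppressMessages(compute_cv_table(sim$counts))
  scaled <- sim$counts
  scaled$counts[-1] <- scaled$counts[-1] * 3.7
  cv2 <- suppressMessages(compute_cv_table(scaled))
  expect_equal(cv2$cv, cv1$cv, tolerance = 1e-12)
  expect_identical(cv2$rank, cv1$rank)
})

test_that("sigma recovery is unbiased with many replicate pools", {
  cfg <- sim_config(
    n_genes = 300,
    groups = tibble::tibble(label = c("X", "E"), n = c(50, 10), r = c(50, 50)),
    dispersion = list(X = 0.2, E = 0.2), seed = 51
  )
  sim <- simulate_pooled_counts(cfg)
  cv <- suppressMessages(compute_cv_table(sim$counts))
  j <- dplyr::inner_join(cv, sim$truth, by = c("gene_id", "group"))
  ratio <- j$sigma_hat / j$sigma
  expect_lt(abs(median(ratio) - 1), 0.05)
})

test_that("rank-sum comparison behaves at the identity and under large shifts", {
  set.seed(123)
  cv_eq <- make_cv_table(cv_x = runif(300, 1, 2), cv_e = runif(300, 1, 2))
  cmp <- compare_cv_distributions(cv_eq, group_x = "X", group_e = "E")
  expect_gt(cmp$p_value, 1e-4) # exchangeable draws: no systematic difference
  base <- runif(1000, 1, 2)
  cv_shift <- make_cv_table(cv_x = base + 2, cv_e = base)
  cmp2 <- compare_cv_distributions(cv_shift, group_x = "X", group_e = "E")
  expect_lt(cmp2$p_value, 1e-6)
  expect_equal(cmp2$summary$mean_cv[1] - cmp2$summary$mean_cv[2], 2,
               tolerance = 1e-12)
})

test_that("bin fractions count strict CVX > CVE per rank bin", {
  gt <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  cv <- make_cv_table(cv_x = ifelse(gt, 2, 1), cv_e = rep(1.5, 10))
  bf <- bin_fraction_analysis(cv, n_bins = 2, group_x = "X", group_e = "E")
  expect_equal(bf$bins$fraction, c(0.8, 0.6))
  expect_equal(bf$overall_fraction, 0.7)
  # ties never count: CVX = CVE contributes nothing
  cv_tie <- make_cv_table(cv_x = rep(1.5, 10), cv_e = rep(1.5, 10))
  bf_tie <- bin_fraction_analysis(cv_tie, n_bins = 2, group_x = "X",
                                  group_e = "E")
  expect_equal(bf_tie$overall_fraction, 0)
  # all greater: every fraction 1
  cv_all <- make_cv_table(cv_x = rep(2, 10), cv_e = rep(1, 10))
  bf_all <- bin_fraction_analysis(cv_all, n_bins = 2, group_x = "X",
                                  group_e = "E")
  expect_equal(bf_all$bins$fraction, c(1, 1))
  expect_equal(bf_all$overall_fraction, 1)
})

test_that("bins partition the ranked gene list into near-equal sizes", {
  G <- 25276
  cv <- make_cv_table(cv_x = rep(2, G), cv_e = rep(1, G))
  bf <- bin_fraction_analysis(cv, n_bins = 100, group_x = "X", group_e = "E")
  expect_equal(sum(bf$bins$n_genes), G)
  expect_lte(diff(range(bf$bins$n_genes)), 1)
  small <- make_cv_table(cv_x = rep(2, 3), cv_e = rep(1, 3))
  expect_error(bin_fraction_analysis(small, n_bins = 100), "between 1 and")
})

test_that("weighted mean of bin fractions equals the overall fraction", {
  set.seed(8)
  for (G in c(101, 1000, 2503)) {
    cv <- make_cv_table(cv_x = runif(G), cv_e = runif(G))
    bf <- bin_fraction_analysis(cv, n_bins = 100, group_x = "X", group_e = "E")
    wm <- sum(bf$bins$fraction * bf$bins$n_genes) / sum(bf$bins$n_genes)
    expect_equal(wm, bf$overall_fraction, tolerance = 1e-12)
  }
})

test_that("permutation p-values are reproducible and sensibly calibrated", {
  set.seed(9)
  cv <- make_cv_table(cv_x = runif(500), cv_e = runif(500))
  bf <- bin_fraction_analysis(cv, n_bins = 20, group_x = "X", group_e = "E")
  p1 <- permutation_test(bf, n_permutations = 300, seed = 99)
  p2 <- permutation_test(bf, n_permutations = 300, seed = 99)
  expect_identical(p1$bins$p_value, p2$bins$p_value)
  p3 <- permutation_test(bf, n_permutations = 300, seed = 100)
  expect_false(identical(p3$bins$p_value, p1$bins$p_value))
  expect_true(all(p1$bins$p_value >= 0 & p1$bins$p_value <= 1))
  expect_error(permutation_test(bf, n_permutations = 0), "at least 1")
})

test_that("degenerate all-equal bins are flagged and non-significant", {
  cv <- make_cv_table(cv_x = rep(2, 40), cv_e = rep(1, 40))
  bf <- bin_fraction_analysis(cv, n_bins = 4, group_x = "X", group_e = "E")
  res <- permutation_test(bf, n_permutations = 100, seed = 1)
  expect_true(all(res$bins$degenerate))
  expect_true(all(res$bins$p_value == 1))
  expect_false(any(res$bins$significant))
})

test_that("top variable genes honour the exclusion rules and sort order", {
  m <- rbind(
    zeroed = c(0, 50, 60, 5, 5, 5),    # a zero X replicate: excluded
    low = c(9, 8, 7, 5, 5, 5),         # all X replicates < 10: excluded
    a_hi = c(10, 30, 50, 5, 5, 5),
    b_hi = c(100, 300, 500, 5, 5, 5),  # same CV as a_hi: tie on CV
    mild = c(20, 21, 22, 5, 5, 5)
  )
  x <- toy_counts(m, groups = c("X", "X", "X", "E", "E", "E"),
                  n_individuals = c(50, 50, 50, 10, 10, 10))
  cv <- compute_cv_table(x, drop_zeros = FALSE)
  expect_warning(
    top <- top_variable_genes(cv, x, k = 10, group = "X"),
    "returning all"
  )
  expect_false(any(c("zeroed", "low") %in% top$gene_id))
  # brute-force sort oracle on the survivors
  survivors <- cv[cv$group == "X" & cv$gene_id %in% c("a_hi", "b_hi", "mild"), ]
  oracle <- survivors$gene_id[order(-survivors$cv, survivors$gene_id)]
  expect_identical(top$gene_id, oracle)
  expect_identical(top$gene_id[1:2], c("a_hi", "b_hi")) # lexicographic tie
})
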