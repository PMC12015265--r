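test_that("gene lists enforce uniqueness and namespace checks", {
  expect_error(gene_list(c("a", "a")), "Duplicate")
  a <- gene_list(c("a", "b", "c"))
  h <- gene_list("TP53", namespace = "human_symbol")
  expect_error(subtract_gene_set(a, h), "Namespace mismatch")
})

test_that("set subtraction removes exact matches and preserves order", {
  a <- gene_list(c("a", "b", "c"))
  expect_identical(as.character(subtract_gene_set(a, gene_list("b"))),
                   c("a", "c"))
  expect_identical(as.character(subtract_gene_set(a, gene_list(c("x", "y")))),
                   c("a", "b", "c"))
  # subtracting twice equals subtracting once
  s <- gene_list(c("b", "c"))
  once <- subtract_gene_set(a, s)
  expect_identical(subtract_gene_set(once, s)$ids, once$ids)
  # planted-overlap fixture against a set-intersection oracle
  set.seed(14)
  big <- gene_list(sprintf("g%04d", 1:500))
  sub <- gene_list(c(sample(big$ids, 150), sprintf("other%d", 1:50)))
  out <- subtract_gene_set(big, sub)
  expect_identical(length(out$ids), 500L - length(intersect(big$ids, sub$ids)))
})

test_that("LOC annotation replaces mapped ids and drops the rest", {
  gl <- gene_list(c("sox2", "LOC123", "LOC999", "krt12"))
  map <- ortholog_map("LOC123", "GENE1")
  out <- annotate_loc_genes(gl, map)
  expect_identical(as.character(out), c("sox2", "GENE1", "krt12"))
  expect_identical(attr(out, "n_loc"), 2L)
  expect_identical(attr(out, "n_annotated"), 1L)
  expect_identical(attr(out, "n_dropped"), 1L)
  # no LOC ids: identity
  clean <- gene_list(c("sox2", "krt12"))
  expect_identical(annotate_loc_genes(clean, map)$ids, clean$ids)
  # keep unannotated when requested
  kept <- annotate_loc_genes(gl, map, drop_unannotated = FALSE)
  expect_true("LOC999" %in% kept$ids)
})

test_that("LOC bookkeeping conserves counts at a realistic LOC fraction", {
  # ~41% LOC ids, as in the upregulated-transcript list
  cfg <- sim_config(n_genes = 1000, loc_fraction = 0.41,
                    homeolog_fraction = 0, seed = 15)
  u <- simulate_gene_universe(cfg, ortholog_coverage = 0.7)
  gl <- gene_list(u$genes)
  out <- annotate_loc_genes(gl, u$ortholog_map)
  n_loc <- sum(grepl("^LOC[0-9]+", u$genes))
  expect_identical(attr(out, "n_loc"), n_loc)
  expect_identical(attr(out, "n_annotated") + attr(out, "n_dropped"), n_loc)
})

test_that("homeolog deduplication collapses L/S pairs deterministically", {
  gl <- gene_list(c("g1.L", "g1.S", "g2.L", "plain"))
  expect_identical(as.character(dedup_homeologs(gl)), c("g1", "g2", "plain"))
  # idempotent
  once <- dedup_homeologs(gl)
  expect_identical(dedup_homeologs(once)$ids, once$ids)
  # no suffixes: identity
  flat <- gene_list(c("a", "b"))
  expect_identical(dedup_homeologs(flat)$ids, c("a", "b"))
  # keep-higher-expression rule matches a per-pair argmax oracle
  m <- rbind(
    `h1.L` = c(10, 10, 10, 10, 10, 10),
    `h1.S` = c(90, 90, 90, 90, 90, 90),
    `h2.L` = c(50, 50, 50, 50, 50, 50),
    `h2.S` = c(5, 5, 5, 5, 5, 5)
  )
  x <- toy_counts(m)
  gl2 <- gene_list(rownames(m))
  out <- dedup_homeologs(gl2, counts = x)
  # oracle: for each base, the surviving copy is the row with larger mean
  expect_identical(out$ids, c("h1", "h2"))
  means <- rowMeans(m)
  for (b in c("h1", "h2")) {
    pair <- paste0(b, c(".L", ".S"))
    expect_identical(
      names(which.max(means[pair])),
      paste0(b, c(".L", ".S"))[which.max(means[pair])]
    )
  }
  # without counts the .L copy wins
  expect_identical(dedup_homeologs(gene_list(c("h9.S", "h9.L")))$ids, "h9")
})

test_that("ortholog mapping drops unmapped ids and deduplicates targets", {
  gl <- gene_list(c("a", "b", "c", "d"))
  expect_identical(map_to_orthologs(gl, ortholog_map(character(), character()))$ids,
                   character())
  bij <- ortholog_map(c("a", "b", "c", "d"), c("A", "B", "C", "D"))
  out <- map_to_orthologs(gl, bij)
  expect_identical(out$ids, c("A", "B", "C", "D"))
  expect_identical(out$namespace, "human_symbol")
  many <- ortholog_map(c("a", "b", "c"), c("T1", "T1", "T2"))
  out2 <- map_to_orthologs(gl, many)
  expect_identical(out2$ids, c("T1", "T2")) # distinct-target count
})

test_that("the full curation chain matches stage-by-stage set algebra", {
  cfg <- sim_config(n_genes = 800, loc_fraction = 0.4,
                    homeolog_fraction = 0.3, seed = 16)
  u <- simulate_gene_universe(cfg, ortholog_coverage = 0.85)
  start <- gene_list(u$genes, provenance = "upregulated")
  sets <- lapply(u$gene_sets, gene_list)
  stages <- list(
    list(stage = "subtract", set = sets$epidermal_progenitor,
         label = "minus epidermal progenitors"),
    list(stage = "annotate_loc", map = u$ortholog_map),
    list(stage = "dedup_homeologs"),
    list(stage = "subtract", set = sets$multiciliated,
         label = "minus multiciliated"),
    list(stage = "map_orthologs", map = u$ortholog_map)
  )
  res <- run_curation(start, stages)
  rep <- res$report
  # independent recomputation with base set algebra
  s1 <- setdiff(u$genes, sets$epidermal_progenitor$ids)
  lookup <- setNames(u$ortholog_map$target, u$ortholog_map$source)
  is_loc <- grepl("^LOC[0-9]+", s1)
  s2 <- ifelse(is_loc & s1 %in% names(lookup), lookup[s1], s1)
  s2 <- s2[!(is_loc & !(s1 %in% names(lookup)))]
  s2 <- s2[!duplicated(s2)]
  s3 <- unique(sub("\\.(L|S)$", "", s2))
  s4 <- setdiff(s3, sets$multiciliated$ids)
  s5 <- unique(unname(lookup[s4][!is.na(lookup[s4])]))
  expect_identical(rep$genes_out, c(length(s1), length(s2), length(s3),
                                    length(s4), length(s5)))
  expect_identical(res$genes$ids, s5)
  # counts are monotone non-increasing and stages appear in configured order
  expect_true(all(diff(c(rep$genes_in[1], rep$genes_out)) <= 0))
  expect_identical(rep$stage, vapply(stages, `[[`, "", "stage"))
  # removing a stage removes its row
  res2 <- run_curation(start, stages[-4])
  expect_false("minus multiciliated" %in% res2$report$label)
})

test_that("an empty starting list flows through all stages as zero", {
  empty <- gene_list(character())
  stages <- list(
    list(stage = "subtract", set = gene_list(c("a", "b"))),
    list(stage = "dedup_homeologs")
  )
  res <- run_curation(empty, stages)
  expect_true(all(res$report$genes_in == 0L))
  expect_true(all(res$report$genes_out == 0L))
})

test_that("gene-set files and curation configs round-trip", {
  tmp <- withr::local_tempdir()
  gl <- gene_list(c("a", "b", "c"))
  write_gene_list(gl, file.path(tmp, "list.txt"))
  expect_identical(read_gene_list(file.path(tmp, "list.txt"))$ids, gl$ids)
  sets <- list(s1 = gene_list(c("a", "b")), s2 = gene_list(c("c")))
  write_gmt(sets, file.path(tmp, "sets.gmt"))
  back <- read_gmt(file.path(tmp, "sets.gmt"))
  expect_identical(lapply(back, `[[`, "ids"), lapply(sets, `[[`, "ids"))
  map <- ortholog_map(c("a", "b"), c("A", "B"))
  write_ortholog_map(map, file.path(tmp, "map.tsv"))
  expect_equal(tibble::as_tibble(read_ortholog_map(file.path(tmp, "map.tsv"))),
               tibble::as_tibble(map))
  yaml::write_yaml(list(
    list(stage = "subtract", label = "sub", file = file.path(tmp, "list.txt")),
    list(stage = "dedup_homeologs")
  ), file.path(tmp, "stages.yaml"))
  st <- read_curation_config(file.path(tmp, "stages.yaml"))
  expect_identical(st[[1]]$set$ids, gl$ids)
  expect_identical(st[[2]]$stage, "dedup_homeologs")
})
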