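# Helpers building tiny enrichment worlds entirely in code ------------------

toy_world <- function(gene_pos, chrom_size = 50000L, chrom = "chr1") {
  regions <- data.frame(gene_id = names(gene_pos), symbol = names(gene_pos),
                        chrom = chrom,
                        region_start = vapply(gene_pos, `[[`, 0L, 1L),
                        region_end = vapply(gene_pos, `[[`, 0L, 2L),
                        strand = "+", stringsAsFactors = FALSE)
  list(regions = regions, chrom_sizes = setNames(chrom_size, chrom))
}

test_that("observed statistic: worked examples and both modes", {
  w <- toy_world(list(g1 = c(100L, 200L), g2 = c(150L, 300L),
                      g3 = c(1000L, 1100L), g4 = c(5000L, 5100L)))
  ann <- gene_annotation(list(T1 = c("g1", "g2", "g3")),
                         c("g1", "g2", "g3", "g4"))
  iv <- genomic_intervals("chr1", c(50L, 900L), c(400L, 1200L), c("A", "B"))
  expect_equal(observed_statistic(iv, w$regions, ann, "T1", "gene"), 3L)
  expect_equal(observed_statistic(iv, w$regions, ann, "T1", "interval"), 2L)
  # no annotated genes anywhere
  iv2 <- genomic_intervals("chr1", 40000L, 41000L, "C")
  expect_equal(observed_statistic(iv2, w$regions, ann, "T1", "gene"), 0L)
  expect_equal(observed_statistic(iv2, w$regions, ann, "T1", "interval"), 0L)
  expect_error(observed_statistic(iv, w$regions, ann, "nope", "gene"),
               "unknown term")
})

test_that("observed statistic equals the nested-loop oracle on random fixtures", {
  set.seed(53)
  for (rep in 1:20) {
    reg <- random_regions(30, chroms = "chr1", size = 200000L)
    bg <- reg$gene_id
    term_genes <- sample(bg, sample(3:10, 1))
    ann <- gene_annotation(list(T1 = term_genes), bg)
    # non-overlapping intervals so distinct-gene counting is comparable
    starts <- seq(1L, 190000L, by = 20000L)[1:8]
    iv <- genomic_intervals("chr1", starts, starts + sample.int(15000L, 8),
                            sprintf("iv%d", 1:8))
    for (mode in c("gene", "interval")) {
      expect_equal(observed_statistic(iv, reg, ann, "T1", mode),
                   oracle_statistic(iv, reg, term_genes, mode))
    }
    # with disjoint intervals, gene-mode count >= interval-mode count
    expect_gte(observed_statistic(iv, reg, ann, "T1", "gene"),
               observed_statistic(iv, reg, ann, "T1", "interval"))
  }
})

test_that("relocation is uniform over the enumerated valid placements", {
  # one dense region (3 clusters) plus scattered singles on a 5 kb toy genome
  w <- toy_world(list(g1 = c(500L, 600L), g2 = c(700L, 800L),
                      g3 = c(950L, 1050L), g4 = c(3000L, 3100L)),
                 chrom_size = 5000L)
  clusters <- collapse_genes(w$regions)
  expect_equal(nrow(clusters), 4L)
  iv <- genomic_intervals("chr1", 450L, 999L, "k3")   # covers 3 clusters
  valid <- oracle_placements(550L, 3L, clusters, w$chrom_sizes)
  expect_gt(nrow(valid), 0L)
  set.seed(61)
  draws <- vapply(1:2000, function(i)
    relocate_interval(iv, w$chrom_sizes, clusters)$start, numeric(1))
  expect_true(all(draws %in% valid$start))
  # chi-squared uniformity over the enumerated placements (pooled bins)
  bins <- cut(match(draws, sort(valid$start)), breaks = 10)
  expect_gt(stats::chisq.test(table(bins))$p.value, 1e-4)
})

test_that("k = 0 intervals relocate into gene deserts; k is matched exactly", {
  w <- toy_world(list(g1 = c(2000L, 2500L), g2 = c(2400L, 3000L)),
                 chrom_size = 20000L)
  clusters <- collapse_genes(w$regions)
  desert <- genomic_intervals("chr1", 10000L, 10499L, "k0")
  dense <- genomic_intervals("chr1", 1900L, 2600L, "k1")
  set.seed(67)
  for (i in 1:50) {
    r0 <- relocate_interval(desert, w$chrom_sizes, clusters)
    expect_equal(mendelprior:::interval_cluster_counts(r0, clusters), 0L)
    r1 <- relocate_interval(dense, w$chrom_sizes, clusters)
    expect_equal(mendelprior:::interval_cluster_counts(r1, clusters), 1L)
    expect_equal(r1$end - r1$start, dense$end - dense$start)
  }
})

test_that("empirical p formula: ties give p = 1; bounds hold", {
  # chromosome exactly the interval's length: the only valid placement is the
  # interval itself, so every replicate ties the observed statistic
  w <- toy_world(list(g1 = c(100L, 200L)), chrom_size = 1000L)
  ann <- gene_annotation(list(T1 = "g1", T2 = "g1"), "g1")
  iv <- genomic_intervals("chr1", 1L, 1000L, "all")
  cfg <- enrichment_config(n_perm = 99L, n_boot = 19L, seed = 2L,
                           min_term_size = 1L)
  fl <- empirical_pvalues(iv, w$regions, ann, w$chrom_sizes, cfg)
  expect_equal(fl$table$empirical_p, c(1, 1))
  expect_equal(corrected_pvalues(fl)$corrected_p, c(1, 1))
})

test_that("empirical p matches its own null matrix and stated bounds", {
  set.seed(71)
  reg <- random_regions(20, chroms = "chr1", size = 100000L)
  ann <- gene_annotation(list(T1 = sample(reg$gene_id, 6),
                              T2 = sample(reg$gene_id, 4)),
                         reg$gene_id)
  iv <- genomic_intervals("chr1", c(1L, 50000L), c(20000L, 70000L),
                          c("a", "b"))
  cfg <- enrichment_config(n_perm = 200L, n_boot = 50L, seed = 5L)
  fl <- empirical_pvalues(iv, reg, ann, setNames(100000L, "chr1"), cfg)
  for (j in seq_len(nrow(fl$table))) {
    expect_equal(fl$table$empirical_p[j],
                 (1 + sum(fl$S[, j] >= fl$table$observed[j])) / 201)
  }
  expect_true(all(fl$table$empirical_p >= 1 / 201 &
                    fl$table$empirical_p <= 1))
})

test_that("Monte-Carlo empirical p agrees with exhaustive-placement exact p", {
  set.seed(73)
  gene_pos <- list()
  s <- cumsum(c(2000L, sample(2000:5000, 9)))
  for (i in 1:10) gene_pos[[sprintf("g%02d", i)]] <- c(s[i], s[i] + 800L)
  w <- toy_world(gene_pos, chrom_size = 50000L)
  bg <- names(gene_pos)
  ann <- gene_annotation(list(T1 = bg[c(1, 2, 3)], T2 = bg[c(5, 9)]), bg)
  iv <- genomic_intervals("chr1", 1500L, 4499L, "probe")   # 3 kb
  clusters <- collapse_genes(w$regions)
  k <- mendelprior:::interval_cluster_counts(iv, clusters)
  valid <- oracle_placements(3000L, k, clusters, w$chrom_sizes)
  cfg <- enrichment_config(n_perm = 2000L, n_boot = 1L, seed = 11L,
                           min_term_size = 2L)
  fl <- empirical_pvalues(iv, w$regions, ann, w$chrom_sizes, cfg)
  for (j in seq_len(nrow(fl$table))) {
    t_id <- fl$table$term_id[j]
    term_genes <- ann$term_to_genes[[t_id]]
    stats_exact <- vapply(seq_len(nrow(valid)), function(r)
      oracle_statistic(genomic_intervals(valid$chrom[r], valid$start[r],
                                         valid$start[r] + 2999L, "x"),
                       w$regions, term_genes, "gene"), numeric(1))
    p_exact <- mean(stats_exact >= fl$table$observed[j])
    se <- sqrt(max(p_exact * (1 - p_exact), 1e-6) / 2000)
    expect_lt(abs(fl$table$empirical_p[j] - p_exact), 3 * se + 1 / 2001)
  }
})

test_that("corrected p: no multiplicity for a single term; p=1 stays 1", {
  set.seed(79)
  reg <- random_regions(20, chroms = "chr1", size = 100000L)
  ann1 <- gene_annotation(list(T1 = sample(reg$gene_id, 6)), reg$gene_id)
  iv <- genomic_intervals("chr1", c(1L, 40000L), c(15000L, 55000L),
                          c("a", "b"))
  cfg <- enrichment_config(n_perm = 400L, n_boot = 400L, seed = 7L)
  res <- run_enrichment(iv, ann1, reg, setNames(100000L, "chr1"), cfg)
  expect_lt(abs(res$corrected_p - res$empirical_p), 0.1)
  if (res$empirical_p == 1) expect_equal(res$corrected_p, 1)
})

test_that("corrected p stochastically dominates empirical p under the null", {
  b <- generate_null_dataset(fixture_spec(seed = 83,
                                          frac_termless_diseases = 0))
  kb <- suppressWarnings(fixture_knowledge_base(b))
  ann <- annotate_genes(kb$associations, b$ontology, "hpo")
  reg <- build_gene_regions(kb$genes)
  cfg <- enrichment_config(n_perm = 300L, n_boot = 300L, seed = 13L)
  res <- run_enrichment(validate_intervals(b$intervals), ann, reg,
                        b$chrom_sizes, cfg)
  expect_true(all(sort(res$corrected_p) >= sort(res$empirical_p) - 1e-9))
})

test_that("results are sorted by (p, gene count desc, term id) and are
           deterministic and order-invariant", {
  b <- generate_fixture(fixture_spec(
    planted_term = list(n_target_loci = 4L, effect = 1), seed = 89))
  kb <- suppressWarnings(fixture_knowledge_base(b))
  ann <- annotate_genes(kb$associations, b$ontology, "hpo")
  reg <- build_gene_regions(kb$genes)
  cfg <- enrichment_config(n_perm = 200L, n_boot = 100L, seed = 17L)
  iv <- validate_intervals(b$intervals)
  res <- run_enrichment(iv, ann, reg, b$chrom_sizes, cfg)
  key <- order(res$empirical_p, -res$n_genes_in_intervals, res$term_id)
  expect_equal(key, seq_len(nrow(res)))

  res2 <- run_enrichment(iv, ann, reg, b$chrom_sizes, cfg)
  expect_identical(res, res2)
  # permuting the interval input order leaves every number unchanged
  res3 <- run_enrichment(iv[rev(seq_len(nrow(iv))), ], ann, reg,
                         b$chrom_sizes, cfg)
  expect_equal(res3, res)
})

test_that("config validation rejects bad replicate counts and term bounds work", {
  expect_error(enrichment_config(n_perm = 0L), "CONFIG_REPLICATES")
  expect_error(enrichment_config(n_boot = -1L), "CONFIG_REPLICATES")
  reg <- data.frame(gene_id = c("g1", "g2", "g3"), symbol = "s",
                    chrom = "chr1",
                    region_start = c(100L, 5000L, 9000L),
                    region_end = c(400L, 5400L, 9400L), strand = "+")
  ann <- gene_annotation(list(big = c("g1", "g2", "g3"), small = "g1"),
                         c("g1", "g2", "g3"))
  iv <- genomic_intervals("chr1", 1L, 1000L, "a")
  cfg <- enrichment_config(n_perm = 50L, n_boot = 10L, seed = 1L,
                           min_term_size = 2L, max_term_size = 2L)
  res <- run_enrichment(iv, ann, reg, c(chr1 = 20000L), cfg)
  expect_equal(res$term_id, character(0))   # both terms outside [2, 2]
})
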