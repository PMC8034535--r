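test_that("integrate_sources merges by (gene, disease) key with source union", {
  omim <- data.frame(gene_id = "g1", disease_id = "D1", disease_name = "d one")
  orpha <- data.frame(gene_id = c("g1", "g2"), disease_id = c("D1", "D2"),
                      disease_name = c("d one alt", "d two"))
  out <- integrate_sources(list(OMIM = omim, ORPHANET = orpha))
  expect_equal(nrow(out), 2L)
  expect_equal(out$sources[[which(out$disease_id == "D1")]],
               c("OMIM", "ORPHANET"))
  # disease_name comes from the highest-priority source
  expect_equal(out$disease_name[out$disease_id == "D1"], "d one")

  empty <- integrate_sources(list(OMIM = NULL, ORPHANET = NULL,
                                  DECIPHER = NULL, GE = NULL))
  expect_equal(nrow(empty), 0L)
})

test_that("integration matches brute-force distinct-pair count and is idempotent", {
  set.seed(11)
  for (rep in 1:20) {
    tables <- lapply(setNames(nm = c("OMIM", "ORPHANET", "DECIPHER", "GE")),
                     function(s) {
      n <- sample(0:25, 1)
      if (n == 0) return(NULL)
      data.frame(gene_id = sprintf("g%d", sample(8, n, replace = TRUE)),
                 disease_id = sprintf("D%d", sample(10, n, replace = TRUE)),
                 disease_name = "x", stringsAsFactors = FALSE)
    })
    out <- integrate_sources(tables)
    all_pairs <- unique(do.call(rbind, lapply(tables, function(t)
      if (is.null(t)) NULL else t[, c("gene_id", "disease_id")])))
    expect_equal(nrow(out), nrow(all_pairs) %||% 0L)
    # idempotence: re-integrating the integrated table changes nothing
    again <- integrate_sources(list(
      OMIM = out[, c("gene_id", "disease_id", "disease_name")]))
    expect_equal(again[, c("gene_id", "disease_id")],
                 out[, c("gene_id", "disease_id")])
  }
})

test_that("unresolvable gene ids are dropped with a warning; aliases merge series", {
  genes <- data.frame(gene_id = c("g1", "g2"))
  tabs <- list(OMIM = data.frame(gene_id = c("g1", "gX"),
                                 disease_id = c("D1", "D2"),
                                 disease_name = "n"))
  expect_warning(out <- integrate_sources(tabs, genes = genes), "dropped")
  expect_equal(out$gene_id, "g1")
  expect_equal(attr(out, "n_unresolved"), 1L)

  alias <- data.frame(disease_id = c("D1", "D2"), series_id = "PS1")
  tabs2 <- list(OMIM = data.frame(gene_id = "g1", disease_id = "D1",
                                  disease_name = "a"),
                ORPHANET = data.frame(gene_id = "g1", disease_id = "D2",
                                      disease_name = "b"))
  merged <- integrate_sources(tabs2, alias = alias)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$sources[[1]], c("OMIM", "ORPHANET"))
})

test_that("description priority is OMIM > Orphanet > Uniprot > DO", {
  assoc <- integrate_sources(list(OMIM = data.frame(
    gene_id = c("g1", "g2", "g3"), disease_id = c("D1", "D2", "D3"),
    disease_name = "n")))
  tables <- list(DO = data.frame(disease_id = c("D1", "D3"),
                                 description = c("do1", "do3")),
                 ORPHANET = data.frame(disease_id = "D1",
                                       description = "orpha1"))
  out <- attach_descriptions(assoc, tables)
  expect_equal(out$description[out$disease_id == "D1"], "orpha1")
  expect_equal(out$description_source[out$disease_id == "D1"], "ORPHANET")
  expect_equal(out$description_source[out$disease_id == "D3"], "DO")
  expect_true(is.na(out$description[out$disease_id == "D2"]))
})

test_that("description winner equals a priority-scan oracle on a random fixture", {
  set.seed(4)
  ids <- sprintf("D%02d", 1:30)
  assoc <- integrate_sources(list(OMIM = data.frame(
    gene_id = "g1", disease_id = ids, disease_name = "n")))
  prio <- c("OMIM", "ORPHANET", "UNIPROT", "DO")
  tables <- lapply(setNames(nm = prio), function(s) {
    has <- ids[runif(30) < 0.4]
    data.frame(disease_id = has, description = paste(s, has))
  })
  out <- attach_descriptions(assoc, tables[sample(prio)])   # shuffled input
  for (i in seq_along(ids)) {
    winner <- NA_character_
    for (s in prio) if (ids[i] %in% tables[[s]]$disease_id) { winner <- s; break }
    row <- which(out$disease_id == ids[i])
    if (is.na(winner)) expect_true(is.na(out$description[row]))
    else expect_equal(out$description[row], paste(winner, ids[i]))
  }
})

test_that("ontology terms are unioned over sources; provenance is logged", {
  ont <- parse_obo(obo_text(c("T:1", "T:2", "T:3"),
                            edges = list(`T:2` = "T:1", `T:3` = "T:1")))
  assoc <- integrate_sources(list(OMIM = data.frame(
    gene_id = c("g1", "g2"), disease_id = c("D1", "D2"), disease_name = "n")))
  tabs <- list(OMIM = data.frame(disease_id = "D1", term_id = "T:2"),
               ORPHANET = data.frame(disease_id = c("D1", "D1", "D2"),
                                     term_id = c("T:2", "T:3", "T:3")))
  out <- attach_ontology_terms(assoc, tabs, ont, "hpo")
  expect_equal(out$hpo_terms[[which(out$disease_id == "D1")]], c("T:2", "T:3"))
  expect_equal(out$hpo_terms[[which(out$disease_id == "D2")]], "T:3")
  # D2 gained terms only from a non-primary source
  expect_equal(attr(out, "n_gained_nonprimary"), 1L)
  # source order cannot change the final sets, only the log
  out2 <- attach_ontology_terms(assoc, rev(tabs), ont, "hpo")
  expect_equal(out$hpo_terms, out2$hpo_terms)
})

test_that("unknown and obsolete term ids are dropped with a warning", {
  ont <- parse_obo(obo_text(c("T:1", "T:old"), obsolete = "T:old"))
  assoc <- integrate_sources(list(OMIM = data.frame(
    gene_id = "g1", disease_id = "D1", disease_name = "n")))
  tabs <- list(OMIM = data.frame(disease_id = "D1",
                                 term_id = c("T:1", "T:old", "T:nope")))
  expect_warning(out <- attach_ontology_terms(assoc, tabs, ont, "hpo"),
                 "dropped")
  expect_equal(out$hpo_terms[[1]], "T:1")
})

test_that("canonical transcript selection follows APPRIS > length > id", {
  tx <- function(id, start, end, principal) {
    data.frame(gene_id = "g1", symbol = "S", chrom = "chr1", tx_start = start,
               tx_end = end, strand = "+", transcript_id = id,
               appris_principal = principal)
  }
  expect_equal(select_canonical_transcript(
    rbind(tx("tA", 1, 1000, TRUE), tx("tB", 1, 5000, FALSE)))$transcript_id, "tA")
  expect_equal(select_canonical_transcript(
    rbind(tx("ENST02", 1, 2000, FALSE), tx("ENST01", 1, 2000, FALSE)))$transcript_id,
    "ENST01")
  expect_error(select_canonical_transcript(tx("t", 1, 10, TRUE)[0, ]),
               "no transcripts")
})

test_that("canonical selection matches argmax oracle and is permutation-invariant", {
  set.seed(9)
  for (rep in 1:10) {
    n <- 50
    df <- data.frame(gene_id = "g", symbol = "s", chrom = "chr1",
                     tx_start = 1L, tx_end = sample.int(10000L, n),
                     strand = "+",
                     transcript_id = sprintf("t%03d", sample.int(999L, n)),
                     appris_principal = runif(n) < 0.05)
    sel <- select_canonical_transcript(df)
    # exhaustive-scan oracle
    pr <- which(df$appris_principal)
    expected <- if (length(pr) == 1L) df$transcript_id[pr] else {
      pool <- if (length(pr) > 1) df[pr, ] else df
      len <- pool$tx_end - pool$tx_start
      cand <- pool[len == max(len), ]
      sort(cand$transcript_id)[1]
    }
    expect_equal(sel$transcript_id, expected)
    perm <- select_canonical_transcript(df[sample(n), ])
    expect_equal(perm$transcript_id, sel$transcript_id)
  }
})

test_that("knowledge base enforces referential integrity", {
  genes <- data.frame(gene_id = "g1", symbol = "S", chrom = "chr1",
                      tx_start = 1L, tx_end = 10L, strand = "+",
                      transcript_id = "t1", appris_principal = TRUE)
  assoc <- integrate_sources(list(OMIM = data.frame(
    gene_id = "g2", disease_id = "D1", disease_name = "n")))
  expect_error(knowledge_base(genes, assoc), "gene_id")
})
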