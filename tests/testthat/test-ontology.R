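test_that("parse_obo reads chains, flags obsolete terms, rejects bad graphs", {
  ont <- parse_obo(obo_text(c("A", "B", "C"),
                            edges = list(B = "A", C = "B")))
  expect_equal(ont$parents[["C"]], "B")
  expect_equal(ont$roots, "A")

  ont2 <- parse_obo(obo_text(c("A", "B"), edges = list(B = "A"),
                             obsolete = "B"))
  expect_true(ont2$obsolete[["B"]])
  expect_error(parse_obo(obo_text(c("A", "B"),
                                  edges = list(A = "B", B = "A"))), "cycle")
  expect_error(parse_obo(obo_text("A", edges = list(A = "Z"))), "not defined")
})

test_that("generated ontology matches the generator's bookkeeping", {
  b <- generate_fixture(fixture_spec(n_terms = 200L, ontology_depth = 4L,
                                     ontology_branching = 8L, seed = 5))
  expect_equal(length(b$ontology$ids), 201L)       # 200 terms + root
  n_edges <- sum(lengths(b$ontology$parents))
  expect_equal(n_edges, sum(grepl("^is_a:", b$obo_lines)))
  expect_equal(b$ontology$roots, "SYN:0000000")
})

test_that("ancestor_closure equals a BFS oracle on random DAGs", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 30
    ids <- sprintf("T:%02d", seq_len(n))
    edges <- list()
    for (i in 2:n)
      edges[[ids[i]]] <- ids[sample(i - 1, min(i - 1, sample(1:2, 1)))]
    ont <- parse_obo(obo_text(ids, edges))
    seed_set <- sample(ids, sample(1:5, 1))
    expect_equal(ancestor_closure(seed_set, ont),
                 oracle_closure(seed_set, ont$parents))
  }
})

test_that("closure handles roots, fixpoints and root exclusion", {
  ont <- parse_obo(obo_text(c("A", "B", "C"), edges = list(B = "A", C = "B")))
  expect_equal(ancestor_closure("C", ont), c("A", "B", "C"))
  expect_equal(ancestor_closure("A", ont), "A")
  expect_equal(ancestor_closure("C", ont, include_roots = FALSE), c("B", "C"))
  expect_error(ancestor_closure("Z", ont), "unknown")
})

test_that("build_slim returns direct non-obsolete children only", {
  ont <- parse_obo(obo_text(c("R", "a", "b", "c", "d", "grand"),
                            edges = list(a = "R", b = "R", c = "R", d = "R",
                                         grand = "a"),
                            obsolete = "d"))
  expect_equal(build_slim(ont, "R"), c("a", "b", "c"))
  expect_error(build_slim(ont, "nope"), "unknown")
})

test_that("map_to_slim equals a closure-intersection oracle", {
  set.seed(31)
  ids <- c("R", sprintf("T:%02d", 1:20))
  edges <- list()
  for (i in 2:length(ids))
    edges[[ids[i]]] <- ids[sample(i - 1, 1)]
  ont <- parse_obo(obo_text(ids, edges))
  slim <- build_slim(ont, "R")
  for (rep in 1:20) {
    terms <- sample(ids[-1], sample(1:6, 1))
    got <- map_to_slim(terms, slim, ont)
    expected <- sort(intersect(oracle_closure(terms, ont$parents), slim))
    expect_equal(got, expected)
    expect_true(all(got %in% slim))
  }
  # a slim term maps to itself
  expect_true(slim[1] %in% map_to_slim(slim[1], slim, ont))
})

test_that("annotate_genes propagates terms and matches a double-loop oracle", {
  ont <- parse_obo(obo_text(c("R", "T:1", "T:2"),
                            edges = list(`T:1` = "R", `T:2` = "R")))
  assoc <- integrate_sources(list(OMIM = data.frame(
    gene_id = c("g1", "g1", "g2"), disease_id = c("D1", "D2", "D3"),
    disease_name = "n")))
  tabs <- list(OMIM = data.frame(disease_id = c("D1", "D2"),
                                 term_id = c("T:1", "T:2")))
  assoc <- attach_ontology_terms(assoc, tabs, ont, "hpo")
  ann <- annotate_genes(assoc, ont, "hpo")
  expect_equal(ann$term_to_genes[["T:1"]], "g1")
  expect_equal(ann$term_to_genes[["T:2"]], "g1")
  expect_equal(ann$term_to_genes[["R"]], "g1")
  # termless gene stays in background, absent from all term sets
  expect_true("g2" %in% ann$genome_background)
  expect_false("g2" %in% unlist(ann$term_to_genes))
})

test_that("inverted index equals brute force on a 100-gene fixture; invariants", {
  set.seed(41)
  ids <- c("R", sprintf("T:%02d", 1:15))
  edges <- list()
  for (i in 2:length(ids)) edges[[ids[i]]] <- ids[sample(i - 1, 1)]
  ont <- parse_obo(obo_text(ids, edges))
  genes <- sprintf("g%03d", 1:100)
  assoc <- integrate_sources(list(OMIM = data.frame(
    gene_id = genes, disease_id = sprintf("D%03d", 1:100),
    disease_name = "n")))
  direct <- lapply(seq_len(100), function(i)
    if (runif(1) < 0.2) character(0) else sample(ids[-1], sample(1:3, 1)))
  pairs <- data.frame(
    disease_id = rep(assoc$disease_id, lengths(direct)),
    term_id = unlist(direct))
  assoc <- attach_ontology_terms(assoc, list(OMIM = pairs), ont, "hpo")
  ann <- annotate_genes(assoc, ont, "hpo")

  # O(G*T) brute-force oracle over the direct annotations
  for (t in ids) {
    expected <- sort(genes[vapply(seq_len(100), function(i)
      t %in% oracle_closure(direct[[i]], ont$parents), logical(1))])
    got <- ann$term_to_genes[[t]] %||% character(0)
    expect_equal(got, expected)
  }
  # closure invariant: term set is a subset of each parent's set
  for (t in names(ann$term_to_genes)) for (p in ont$parents[[t]])
    expect_true(all(ann$term_to_genes[[t]] %in% ann$term_to_genes[[p]]))
  # idempotence: re-annotating an already-propagated table is a no-op
  assoc2 <- assoc
  assoc2$hpo_terms <- lapply(assoc$hpo_terms, function(t)
    if (length(t)) ancestor_closure(t, ont) else t)
  ann2 <- annotate_genes(assoc2, ont, "hpo")
  expect_equal(ann2$term_to_genes, ann$term_to_genes)
})
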