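# Seeded synthetic fixture generator: toy genome, transcripts, gene-disease
# associations split over four sources, an is_a ontology with per-source term
# tables, ClinVar-like variants, LD proxy tables, recombination map and test
# intervals — optionally with a planted enrichment signal. Everything the
# other modules read can be produced here, so the whole pipeline is testable
# offline. Same seed, same bundle, byte for byte.

#' Specification of a synthetic fixture
#'
#' Defaults describe the standard small calibration genome: one 10 Mbp
#' chromosome, 60 genes, 10 terms of 4-8 genes each under a single root, and
#' 8 test intervals of 100 kbp.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param n_genes number of genes.
#' @param n_diseases number of diseases (>= n_genes recommended so every gene
#'   has at least one association).
#' @param n_terms number of non-root ontology terms.
#' @param ontology_depth depth of the is_a DAG below the root (1 = flat).
#' @param ontology_branching children per internal term when depth > 1.
#' @param frac_termless_diseases fraction of diseases with no ontology terms.
#' @param term_size_range genome-wide gene-count range per term.
#' @param planted_term optional list `(n_target_loci, effect)`: the first
#'   term is planted by centring `effect * n_target_loci` of the test
#'   intervals on its member genes.
#' @param ld_decay_bp exponential decay scale of r-squared with distance.
#' @param hotspot_spacing_bp spacing of recombination hotspots (rate > 3).
#' @param n_intervals number of test intervals in the bundle.
#' @param interval_length length of each test interval (bp).
#' @param seed RNG seed; identical seeds give byte-identical bundles.
#' @return list of class `mv_fixture_spec`.
#' @export
fixture_spec <- function(n_chrom = 1L, chrom_length = 10000000L, n_genes = 60L,
                         n_diseases = 60L, n_terms = 10L, ontology_depth = 1L,
                         ontology_branching = 5L,
                         frac_termless_diseases = 0.1,
                         term_size_range = c(4L, 8L), planted_term = NULL,
                         ld_decay_bp = 50000L, hotspot_spacing_bp = 1000000L,
                         n_intervals = 8L, interval_length = 100000L,
                         seed = 1L) {
  spec <- list(n_chrom = n_chrom, chrom_length = chrom_length,
               n_genes = n_genes, n_diseases = n_diseases, n_terms = n_terms,
               ontology_depth = ontology_depth,
               ontology_branching = ontology_branching,
               frac_termless_diseases = frac_termless_diseases,
               term_size_range = term_size_range,
               planted_term = planted_term, ld_decay_bp = ld_decay_bp,
               hotspot_spacing_bp = hotspot_spacing_bp,
               n_intervals = n_intervals, interval_length = interval_length,
               seed = seed)
  counts <- c("n_chrom", "chrom_length", "n_genes", "n_diseases", "n_terms",
              "ontology_depth", "n_intervals", "interval_length")
  for (f in counts) if (!is_count(spec[[f]]))
    mv_stop("SPEC_COUNT", paste(f, "must be a positive integer"))
  if (frac_termless_diseases < 0 || frac_termless_diseases > 1)
    mv_stop("SPEC_FRACTION", "frac_termless_diseases must be in [0, 1]")
  if (!is.null(planted_term)) {
    if (planted_term$n_target_loci > n_intervals)
      mv_stop("SPEC_PLANTED", "more planted loci than test intervals")
    if (planted_term$n_target_loci > n_genes)
      mv_stop("SPEC_PLANTED", "more planted loci than genes")
  }
  structure(spec, class = "mv_fixture_spec")
}

#' Generate an LD proxy table around an index variant
#'
#' Proxies are placed within the 1 Mbp window centred on the index position;
#' r-squared decays exponentially with distance (times multiplicative noise,
#' clipped to [0, 1]) and D-prime is drawn row-wise at or above r-squared.
#' The index variant appears in its own table with both statistics equal 1.
#' Uses the current RNG state.
#'
#' @param index_id,index_chrom,index_pos identity of the index variant.
#' @param chrom_size chromosome size for clipping.
#' @param ld_decay_bp decay scale (> 0).
#' @param n_proxies number of proxies to draw.
#' @return LD proxy data.frame sorted by position.
#' @export
generate_ld_table <- function(index_id, index_chrom, index_pos, chrom_size,
                              ld_decay_bp, n_proxies = 40L) {
  if (ld_decay_bp <= 0) mv_stop("SPEC_LD_DECAY", "ld_decay_bp must be > 0")
  lo <- max(1L, index_pos - LD_WINDOW_BP)
  hi <- min(chrom_size, index_pos + LD_WINDOW_BP)
  pos <- sort(unique(round(stats::runif(n_proxies, lo, hi))))
  pos <- setdiff(pos, index_pos)
  d <- abs(pos - index_pos)
  r2 <- pmin(1, pmax(0, exp(-d / ld_decay_bp) * stats::runif(length(pos), 0.7, 1.05)))
  dprime <- pmin(1, r2 + stats::runif(length(pos)) * (1 - r2))
  df <- data.frame(
    variant_id = sprintf("%s_prox%03d", index_id, seq_along(pos)),
    chrom = index_chrom, pos = as.integer(pos),
    r2 = round(r2, 6), dprime = round(dprime, 6), stringsAsFactors = FALSE)
  df <- rbind(df, data.frame(variant_id = index_id, chrom = index_chrom,
                             pos = as.integer(index_pos), r2 = 1, dprime = 1))
  df <- df[radix_order(df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Generate a complete synthetic input bundle
#'
#' Returns an in-memory bundle (all tables plus a ground-truth manifest);
#' when `out_dir` is given, every external-interface file of the pipeline is
#' also written there in its documented plain-text format, plus
#' `manifest.json`.
#'
#' @param spec an [fixture_spec()].
#' @param out_dir optional output directory.
#' @return list of class `mv_fixture` with elements `chrom_sizes,
#'   transcripts, genes` (canonical), `assoc_tables, desc_tables,
#'   term_tables, obo_lines, ontology, variants, recomb_map, intervals,
#'   positions, ld_tables, manifest`.
#' @export
generate_fixture <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "mv_fixture_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  chroms <- sprintf("chr%d", seq_len(spec$n_chrom))
  chrom_sizes <- stats::setNames(rep(as.integer(spec$chrom_length),
                                     spec$n_chrom), chroms)

  ## -- genes and transcripts ------------------------------------------------
  gene_chrom <- chroms[((seq_len(spec$n_genes) - 1L) %% spec$n_chrom) + 1L]
  gene_len <- as.integer(round(stats::runif(spec$n_genes, 5000, 30000)))
  gene_start <- as.integer(round(stats::runif(
    spec$n_genes, 1, spec$chrom_length - max(gene_len) - 20000)))
  gene_id <- sprintf("G%04d", seq_len(spec$n_genes))
  transcripts <- list()
  for (i in seq_len(spec$n_genes)) {
    n_tx <- sample(1:3, 1L)
    has_principal <- stats::runif(1) < 0.8
    tx_start <- gene_start[i] + as.integer(round(stats::runif(n_tx, 0, 2000)))
    tx_end <- gene_start[i] + gene_len[i] -
      as.integer(round(stats::runif(n_tx, 0, 2000)))
    tx_end <- pmax(tx_end, tx_start + 100L)
    transcripts[[i]] <- data.frame(
      gene_id = gene_id[i], symbol = sprintf("SYG%04d", i),
      chrom = gene_chrom[i], tx_start = tx_start, tx_end = tx_end,
      strand = sample(c("+", "-"), 1L),
      transcript_id = sprintf("%s.t%02d", gene_id[i], seq_len(n_tx)),
      appris_principal = if (has_principal)
        seq_len(n_tx) == sample(n_tx, 1L) else rep(FALSE, n_tx),
      stringsAsFactors = FALSE)
  }
  transcripts <- do.call(rbind, transcripts)
  genes <- canonical_transcripts(transcripts)

  ## -- ontology -------------------------------------------------------------
  root_id <- "SYN:0000000"
  term_ids <- sprintf("SYN:%07d", seq_len(spec$n_terms))
  parents <- vector("list", spec$n_terms)
  level <- integer(spec$n_terms)
  for (j in seq_len(spec$n_terms)) {
    if (spec$ontology_depth == 1L || j <= spec$ontology_branching) {
      parents[[j]] <- root_id; level[j] <- 1L
    } else {
      cand <- which(level[seq_len(j - 1L)] < spec$ontology_depth)
      p <- sample(cand, min(length(cand), sample(1:2, 1L)))
      parents[[j]] <- term_ids[p]
      level[j] <- max(level[p]) + 1L
    }
  }
  obo_lines <- c("format-version: 1.2", "ontology: synthetic-phenotype", "",
                 "[Term]", paste0("id: ", root_id),
                 "name: synthetic phenotypic abnormality (root)")
  for (j in seq_len(spec$n_terms)) {
    obo_lines <- c(obo_lines, "", "[Term]", paste0("id: ", term_ids[j]),
                   sprintf("name: synthetic phenotype term %d", j),
                   paste0("is_a: ", parents[[j]]))
  }
  ontology <- parse_obo(obo_lines)

  ## -- term -> gene assignment (null by construction: independent of
  ##    gene position) ------------------------------------------------------
  sz <- spec$term_size_range
  term_genes <- lapply(seq_len(spec$n_terms), function(j)
    radix_sort(gene_id[sample(spec$n_genes,
                              sample(seq(sz[1L], min(sz[2L], spec$n_genes)), 1L))]))
  names(term_genes) <- term_ids

  ## -- diseases and associations -------------------------------------------
  disease_id <- sprintf("OMIM:%06d", 600000L + seq_len(spec$n_diseases))
  disease_gene <- gene_id[((seq_len(spec$n_diseases) - 1L) %% spec$n_genes) + 1L]
  termless <- stats::runif(spec$n_diseases) < spec$frac_termless_diseases
  # Multi-gene diseases are drawn from the termless pool only, so ontology
  # terms never spill onto genes outside their generated membership and the
  # manifest ground truth equals what annotate_genes() recomputes.
  extra <- termless & stats::runif(spec$n_diseases) < 0.5
  assoc <- data.frame(gene_id = disease_gene, disease_id = disease_id,
                      stringsAsFactors = FALSE)
  for (d in which(extra)) {
    g2 <- sample(setdiff(gene_id, disease_gene[d]), 1L)
    assoc <- rbind(assoc, data.frame(gene_id = g2, disease_id = disease_id[d]))
  }
  assoc$disease_name <- sprintf("synthetic disease %s",
                                sub("^OMIM:", "", assoc$disease_id))
  # split across sources: always >= 1 source per association
  in_src <- cbind(OMIM = stats::runif(nrow(assoc)) < 0.7,
                  ORPHANET = stats::runif(nrow(assoc)) < 0.5,
                  DECIPHER = stats::runif(nrow(assoc)) < 0.3,
                  GE = stats::runif(nrow(assoc)) < 0.3)
  in_src[rowSums(in_src) == 0L, "OMIM"] <- TRUE
  assoc_tables <- lapply(colnames(in_src), function(s)
    assoc[in_src[, s], c("gene_id", "disease_id", "disease_name")])
  names(assoc_tables) <- colnames(in_src)

  ## -- disease term sets (terms of a gene = union over its diseases) --------
  disease_terms <- stats::setNames(rep(list(character(0)), spec$n_diseases),
                                   disease_id)
  first_disease_of_gene <- disease_id[match(gene_id, disease_gene)]
  for (t in term_ids) for (g in term_genes[[t]]) {
    d <- first_disease_of_gene[match(g, gene_id)]
    if (!is.na(d) && !termless[match(d, disease_id)])
      disease_terms[[d]] <- c(disease_terms[[d]], t)
  }
  # realized (post-termless-filter) membership; equals what the annotation
  # pipeline recomputes because term-bearing diseases are single-gene
  realized <- stats::setNames(rep(list(character(0)), spec$n_terms), term_ids)
  for (d in disease_id) for (t in disease_terms[[d]]) {
    g <- assoc$gene_id[assoc$disease_id == d]
    realized[[t]] <- radix_sort(unique(c(realized[[t]], g)))
  }
  dt_pairs <- data.frame(
    disease_id = rep(names(disease_terms), lengths(disease_terms)),
    term_id = unlist(disease_terms, use.names = FALSE),
    stringsAsFactors = FALSE)
  term_src <- cbind(OMIM = stats::runif(nrow(dt_pairs)) < 0.6,
                    ORPHANET = stats::runif(nrow(dt_pairs)) < 0.4,
                    DECIPHER = stats::runif(nrow(dt_pairs)) < 0.2,
                    OFFICIAL = stats::runif(nrow(dt_pairs)) < 0.3)
  if (nrow(dt_pairs)) term_src[rowSums(term_src) == 0L, "OMIM"] <- TRUE
  term_tables <- lapply(colnames(term_src), function(s)
    dt_pairs[term_src[, s], , drop = FALSE])
  names(term_tables) <- colnames(term_src)

  ## -- descriptions ----------------------------------------------------------
  desc_prob <- c(OMIM = 0.5, ORPHANET = 0.4, UNIPROT = 0.3, DO = 0.3)
  desc_tables <- lapply(names(desc_prob), function(s) {
    has <- stats::runif(spec$n_diseases) < desc_prob[[s]]
    data.frame(disease_id = disease_id[has],
               description = sprintf("Synthetic %s description of %s.",
                                     s, disease_id[has]),
               stringsAsFactors = FALSE)
  })
  names(desc_tables) <- names(desc_prob)

  ## -- variants --------------------------------------------------------------
  n_var_per_gene <- sample(0:2, spec$n_genes, replace = TRUE)
  variants <- list()
  for (i in which(n_var_per_gene > 0L)) {
    vp <- as.integer(round(stats::runif(n_var_per_gene[i], genes$tx_start[i],
                                        genes$tx_end[i])))
    variants[[length(variants) + 1L]] <- data.frame(
      variant_id = sprintf("%s_v%d", gene_id[i], seq_along(vp)),
      chrom = genes$chrom[i], pos = vp,
      ref = sample(c("A", "C", "G", "T"), length(vp), replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), length(vp), replace = TRUE),
      clinical_significance = sample(CLINSIG_LEVELS, length(vp),
                                     replace = TRUE,
                                     prob = c(0.35, 0.25, 0.2, 0.1, 0.1)),
      gene_id = gene_id[i],
      disease_name = sprintf("synthetic disease %06d", 600000L + i),
      stringsAsFactors = FALSE)
  }
  variants <- if (length(variants)) do.call(rbind, variants) else
    utils::head(data.frame(variant_id = "", chrom = "", pos = 1L, ref = "",
                           alt = "", clinical_significance = "pathogenic",
                           gene_id = "", disease_name = ""), 0L)

  ## -- recombination map ------------------------------------------------------
  recomb <- list()
  for (ch in chroms) {
    pos <- seq(50000L, spec$chrom_length, by = 50000L)
    rate <- round(stats::runif(length(pos), 0.2, 2.5), 4)
    hs <- pos %% spec$hotspot_spacing_bp == 0L
    rate[hs] <- round(stats::runif(sum(hs), 5, 30), 4)
    recomb[[ch]] <- data.frame(chrom = ch, pos = pos, rate_cM_per_Mb = rate,
                               stringsAsFactors = FALSE)
  }
  recomb_map <- do.call(rbind, recomb)
  rownames(recomb_map) <- NULL

  ## -- test intervals (planted loci centred on member genes) -----------------
  L <- as.integer(spec$interval_length)
  n_planted <- 0L
  planted_id <- NA_character_
  iv_chrom <- character(0); iv_start <- integer(0)
  if (!is.null(spec$planted_term)) {
    planted_id <- term_ids[1L]
    eff <- spec$planted_term$effect %||% 1
    n_planted <- as.integer(round(spec$planted_term$n_target_loci * eff))
    members <- realized[[planted_id]]
    if (n_planted > 0L) {
      tgt <- sample(members, min(n_planted, length(members)),
                    replace = n_planted > length(members))
      gi <- match(tgt, genes$gene_id)
      mid <- as.integer((genes$tx_start[gi] + genes$tx_end[gi]) / 2)
      iv_chrom <- genes$chrom[gi]
      iv_start <- pmax(1L, pmin(as.integer(mid - L %/% 2L),
                                as.integer(spec$chrom_length) - L + 1L))
      n_planted <- length(tgt)
    }
  }
  n_rand <- spec$n_intervals - n_planted
  if (n_rand > 0L) {
    iv_chrom <- c(iv_chrom, sample(chroms, n_rand, replace = TRUE))
    iv_start <- c(iv_start, as.integer(floor(
      stats::runif(n_rand, 1, spec$chrom_length - L + 1))))
  }
  intervals <- genomic_intervals(iv_chrom, iv_start, iv_start + L - 1L,
                                 label = sprintf("locus%02d",
                                                 seq_len(spec$n_intervals)),
                                 origin = "user")
  positions <- data.frame(chrom = intervals$chrom,
                          pos = as.integer((intervals$start + intervals$end) / 2),
                          label = sprintf("rsSYN%04d", seq_len(spec$n_intervals)),
                          stringsAsFactors = FALSE)

  ## -- LD tables around the lead positions -----------------------------------
  ld_tables <- lapply(seq_len(nrow(positions)), function(i)
    generate_ld_table(positions$label[i], positions$chrom[i], positions$pos[i],
                      chrom_sizes[[positions$chrom[i]]], spec$ld_decay_bp))
  names(ld_tables) <- positions$label

  manifest <- list(
    spec = unclass(spec)[!vapply(unclass(spec), is.null, logical(1))],
    n_associations = nrow(unique(assoc[, c("gene_id", "disease_id")])),
    term_genes = term_genes, realized_term_genes = realized,
    disease_terms = disease_terms,
    planted_term = planted_id, n_planted_intervals = n_planted,
    gene_positions = genes[, c("gene_id", "chrom", "tx_start", "tx_end")])

  bundle <- structure(list(
    chrom_sizes = chrom_sizes, transcripts = transcripts, genes = genes,
    assoc_tables = assoc_tables, desc_tables = desc_tables,
    term_tables = term_tables, obo_lines = obo_lines, ontology = ontology,
    variants = variants, recomb_map = recomb_map, intervals = intervals,
    positions = positions, ld_tables = ld_tables, manifest = manifest),
    class = "mv_fixture")
  if (!is.null(out_dir)) write_fixture(bundle, out_dir)
  bundle
}

#' Generate a null bundle (no planted signal)
#'
#' Term labels are assigned to genes independently of gene position and of
#' the test intervals, so every term's enrichment null hypothesis holds by
#' construction. Used for type-I-error calibration.
#'
#' @param spec an [fixture_spec()]; any `planted_term` is removed.
#' @param out_dir optional output directory.
#' @return `mv_fixture` bundle.
#' @export
generate_null_dataset <- function(spec, out_dir = NULL) {
  spec$planted_term <- NULL
  generate_fixture(spec, out_dir = out_dir)
}

#' Write a fixture bundle to disk in the pipeline's input formats
#'
#' @param bundle `mv_fixture`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_tsv(data.frame(chrom = names(bundle$chrom_sizes),
                       size = unname(bundle$chrom_sizes)), p("chrom_sizes.tsv"))
  tx <- bundle$transcripts
  tx$appris_principal <- as.integer(tx$appris_principal)
  write_tsv(tx[, c("gene_id", "symbol", "chrom", "tx_start", "tx_end",
                   "strand", "transcript_id", "appris_principal")],
            p("transcripts.tsv"))
  for (s in names(bundle$assoc_tables))
    write_tsv(bundle$assoc_tables[[s]], p(sprintf("assoc_%s.tsv", s)))
  for (s in names(bundle$desc_tables))
    write_tsv(bundle$desc_tables[[s]], p(sprintf("desc_%s.tsv", s)))
  for (s in names(bundle$term_tables))
    write_tsv(bundle$term_tables[[s]], p(sprintf("terms_%s.tsv", s)))
  writeLines(bundle$obo_lines, p("ontology.obo"))
  write_tsv(bundle$variants, p("variants.tsv"))
  write_tsv(bundle$recomb_map, p("recomb_map.tsv"))
  write_tsv(bundle$intervals[, c("chrom", "start", "end", "label")],
            p("intervals.tsv"))
  write_tsv(bundle$positions, p("positions.tsv"))
  dir.create(p("ld"), showWarnings = FALSE)
  for (id in names(bundle$ld_tables))
    write_tsv(bundle$ld_tables[[id]], p("ld", sprintf("%s.tsv", id)))
  jsonlite::write_json(bundle$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Assemble a knowledge base directly from an in-memory fixture bundle
#'
#' Runs the standard integration steps (source merging, description priority,
#' term attachment) on the bundle's tables.
#'
#' @param bundle `mv_fixture`.
#' @return `mv_knowledge_base` with HPO-kind terms attached.
#' @export
fixture_knowledge_base <- function(bundle) {
  assoc <- integrate_sources(bundle$assoc_tables, genes = bundle$genes)
  assoc <- attach_descriptions(assoc, bundle$desc_tables)
  assoc <- suppressWarnings(
    attach_ontology_terms(assoc, bundle$term_tables, bundle$ontology, "hpo"))
  knowledge_base(bundle$genes, assoc, bundle$variants, "GRCh38")
}
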