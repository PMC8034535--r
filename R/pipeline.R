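# Single-command pipeline driver: config, logging, standard output files and
# the ranked-term summary report; plus the type-I-error calibration
# experiment used for acceptance.

#' Read a pipeline run configuration (JSON)
#'
#' The configuration holds the input route, knowledge-base file paths,
#' interval/overlap settings and the enrichment parameters. Exactly one input
#' route must be active: `positions` + `flank_left/flank_right`,
#' `positions` + `ld_dir` + `ld_threshold`, or `intervals`.
#'
#' @param path JSON file path.
#' @return config list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  route <- cfg$route %||% NULL
  if (is.null(route) || !route %in% c("flank", "ld", "intervals"))
    mv_stop("CONFIG_ROUTE", "route must be one of 'flank', 'ld', 'intervals'")
  path_keys <- c("genes", "variants", "ontology_obo", "chrom_sizes",
                 "positions", "intervals", "recomb_map", "ld_dir")
  for (k in intersect(path_keys, names(cfg))) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      mv_stop("CONFIG_PATH", sprintf("configured path '%s' does not exist: %s",
                                     k, cfg[[k]]))
  }
  cfg
}

config_flat <- function(cfg, prefix = "") {
  out <- character(0)
  for (k in names(cfg)) {
    v <- cfg[[k]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    if (is.list(v)) out <- c(out, config_flat(v, key))
    else out <- c(out, sprintf("%s = %s", key, paste(v, collapse = ",")))
  }
  out
}

#' Run the full pipeline from a configuration
#'
#' Builds test intervals by the configured route, validates them, intersects
#' them with the knowledge base, runs enrichment for each configured ontology
#' and writes the standard output inventory to `out_dir`: `mendelprior.log`,
#' `input_file.bed`, `disease_overlap.txt`, `variant_overlap.txt`, and per
#' ontology `<label>.out.inrich`, `<label>.out.inrich.parsed`,
#' `<label>.top_terms.tsv` plus a best-effort `<label>.top_terms.png`.
#'
#' @param config list (see [read_run_config()]) or a JSON path.
#' @return invisibly, a list with the intervals, overlap tables and
#'   enrichment results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  out_dir <- config$out_dir %||% mv_stop("CONFIG_OUT", "out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("# mendelprior run log", config_flat(config))
  log_note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  withCallingHandlers({
    ## knowledge base ---------------------------------------------------------
    chrom_sizes_df <- read_tsv(config$chrom_sizes,
                               colClasses = c(chrom = "character"))
    chrom_sizes <- stats::setNames(as.integer(chrom_sizes_df$size),
                                   chrom_sizes_df$chrom)
    transcripts <- read_gene_table(config$genes)
    genes <- canonical_transcripts(transcripts)
    assoc_tables <- lapply(config$associations, read_tsv)
    assoc <- integrate_sources(assoc_tables, genes = genes)
    if (!is.null(config$descriptions))
      assoc <- attach_descriptions(assoc, lapply(config$descriptions, read_tsv))
    ontology <- parse_obo(config$ontology_obo)
    if (!is.null(config$term_tables))
      assoc <- attach_ontology_terms(assoc, lapply(config$term_tables, read_tsv),
                                     ontology, config$ontology_kind %||% "hpo")
    variants <- if (!is.null(config$variants)) read_variant_table(config$variants)
    kb <- knowledge_base(genes, assoc, variants,
                         config$build_label %||% "GRCh38")
    log_note("knowledge base: %d genes, %d associations, %d variants",
             nrow(kb$genes), nrow(kb$associations),
             if (is.null(variants)) 0L else nrow(variants))

    ## intervals ---------------------------------------------------------------
    intervals <- switch(config$route,
      flank = make_flank_intervals(read_positions(config$positions),
                                   config$flank_left %||% 0L,
                                   config$flank_right %||% 0L, chrom_sizes),
      ld = {
        pos <- read_positions(config$positions)
        rows <- lapply(seq_len(nrow(pos)), function(i) {
          f <- file.path(config$ld_dir, paste0(pos$label[i], ".tsv"))
          ld <- if (file.exists(f)) read_ld_table(f) else NULL
          make_ld_interval(pos[i, ], ld, config$ld_stat %||% "r2",
                           config$ld_threshold %||% 0.8)
        })
        do.call(rbind, rows)
      },
      intervals = read_intervals(config$intervals))
    if (isTRUE(config$extend_to_hotspot)) {
      recomb <- read_recomb_map(config$recomb_map)
      intervals <- extend_to_hotspot(intervals, recomb,
                                     config$hotspot_rate %||% 3)
      log_note("hotspot extension applied (rate > %s cM/Mb)",
               config$hotspot_rate %||% 3)
    }
    intervals <- validate_intervals(intervals)
    for (i in seq_len(nrow(intervals)))
      log_note("interval %s: %s:%d-%d (%s)", intervals$label[i],
               intervals$chrom[i], intervals$start[i], intervals$end[i],
               intervals$origin[i])
    write_bed(intervals, file.path(out_dir, "input_file.bed"))

    ## overlap -----------------------------------------------------------------
    regions <- build_gene_regions(genes,
                                  config$upstream %||% 0L,
                                  config$downstream %||% 0L,
                                  config$strand_aware %||% TRUE)
    disease_overlap <- find_gene_overlaps(intervals, regions, kb)
    write_tsv(disease_overlap, file.path(out_dir, "disease_overlap.txt"))
    variant_overlap <- if (!is.null(variants))
      find_variant_overlaps(intervals, variants)
    else data.frame()
    write_tsv(variant_overlap, file.path(out_dir, "variant_overlap.txt"))
    log_note("overlap: %d disease rows, %d variant rows",
             nrow(disease_overlap), nrow(variant_overlap))

    ## enrichment --------------------------------------------------------------
    ec <- config$enrichment %||% list()
    e_config <- enrichment_config(
      mode = ec$mode %||% "gene", n_perm = ec$n_perm %||% 5000L,
      n_boot = ec$n_boot %||% 1000L, seed = ec$seed %||% 1L,
      min_term_size = ec$min_term_size %||% 2L,
      max_term_size = ec$max_term_size %||% 2000L,
      match_tolerance = ec$match_tolerance %||% 0L)
    annotation <- annotate_genes(kb$associations, ontology,
                                 config$ontology_kind %||% "hpo",
                                 label = config$ontology_label %||% "HPO")
    bg_regions <- regions[regions$gene_id %in% annotation$genome_background, ,
                          drop = FALSE]
    results <- run_enrichment(intervals, annotation, bg_regions, chrom_sizes,
                              e_config)
    write_enrichment_outputs(results, annotation$label, out_dir)
    render_top_terms(results, k = config$top_k %||% 50L,
                     path_prefix = file.path(out_dir, annotation$label))
    log_note("enrichment: %d terms tested (mode=%s, R1=%d, R2=%d, seed=%d)",
             nrow(results), e_config$mode, e_config$n_perm, e_config$n_boot,
             e_config$seed)
  }, warning = function(w) {
    log_note("warning: %s", conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  writeLines(log_lines, file.path(out_dir, "mendelprior.log"))
  invisible(list(intervals = intervals, disease_overlap = disease_overlap,
                 variant_overlap = variant_overlap, results = results,
                 log = log_lines))
}

write_enrichment_outputs <- function(results, label, out_dir) {
  raw <- results[, c("term_id", "observed", "empirical_p", "corrected_p")]
  raw$genes <- vapply(results$overlap_genes, collapse_set, character(1))
  write_tsv(raw, file.path(out_dir, paste0(label, ".out.inrich")))
  parsed <- results
  parsed$overlap_genes <- vapply(results$overlap_genes, collapse_set,
                                 character(1))
  write_tsv(parsed, file.path(out_dir, paste0(label, ".out.inrich.parsed")))
  invisible(NULL)
}

#' Ranked top-term summary (table + best-effort figure)
#'
#' Takes the top `k` results in the fixed report order (empirical p, then
#' number of overlapping genes, then term id) and writes a table twin of the
#' summary figure: term names on the y axis in rank order, number of genes in
#' the tested intervals on the x axis, point size proportional to the gene
#' ratio, point colour by empirical p-value. Figure rendering never fails the
#' run.
#'
#' @param results enrichment result table from [run_enrichment()].
#' @param k number of top terms (default 50).
#' @param path_prefix when given, writes `<prefix>.top_terms.tsv` and
#'   attempts `<prefix>.top_terms.png`.
#' @return the top-k data.frame, invisibly when writing.
#' @export
render_top_terms <- function(results, k = 50L, path_prefix = NULL) {
  if (!is_count(k)) mv_stop("REPORT_K", "k must be a positive integer")
  top <- utils::head(results, k)
  top$overlap_genes <- vapply(top$overlap_genes %||% list(), collapse_set,
                              character(1))
  if (is.null(path_prefix)) return(top)
  write_tsv(top, paste0(path_prefix, ".top_terms.tsv"))
  tryCatch({
    grDevices::png(paste0(path_prefix, ".top_terms.png"),
                   width = 900, height = 200 + 18 * nrow(top), res = 96)
    on.exit(grDevices::dev.off(), add = TRUE)
    n <- nrow(top)
    y <- rev(seq_len(n))
    pal <- grDevices::colorRampPalette(c("#b2182b", "#fddbc7", "#2166ac"))(100)
    col <- pal[pmax(1L, ceiling(top$empirical_p * 100))]
    graphics::par(mar = c(4, 18, 2, 6))
    graphics::plot(top$n_genes_in_intervals, y, pch = 16,
                   cex = 0.8 + 2.5 * top$gene_ratio, col = col,
                   xlab = "genes in tested intervals", ylab = "", yaxt = "n",
                   main = "top enriched terms")
    graphics::axis(2, at = y, labels = substr(top$term_name, 1, 45), las = 2,
                   cex.axis = 0.7)
  }, error = function(e) {
    mv_warn(sprintf("figure rendering skipped: %s", conditionMessage(e)))
  })
  invisible(top)
}

#' Family-wise type-I-error calibration experiment
#'
#' Generates `n_bundles` independent null bundles (term labels assigned to
#' genes independently of position; no planted signal), runs the full
#' annotation + enrichment pipeline on each, and reports the fraction of
#' bundles in which any term reaches `corrected_p < alpha`. The stated world
#' of the calibration: one 10 Mbp chromosome, 60 genes, 10 terms of 4 to 8
#' genes each (no termless diseases so term sizes are exact), 8 test
#' intervals of 100 kbp.
#'
#' @param n_bundles number of simulated null datasets (default 200).
#' @param seed master seed; bundle seeds and enrichment seeds are derived
#'   from it.
#' @param n_perm,n_boot enrichment replicates per bundle.
#' @param alpha nominal family-wise level.
#' @param mode enrichment mode.
#' @return list with `fraction` (proportion of bundles with any
#'   `corrected_p < alpha`), `min_corrected_p` per bundle, `n_bundles`.
#' @export
null_calibration_experiment <- function(n_bundles = 200L, seed = 1L,
                                        n_perm = 500L, n_boot = 200L,
                                        alpha = 0.05, mode = "gene") {
  min_p <- numeric(n_bundles)
  for (b in seq_len(n_bundles)) {
    spec <- fixture_spec(n_chrom = 1L, chrom_length = 10000000L,
                         n_genes = 60L, n_diseases = 60L, n_terms = 10L,
                         term_size_range = c(4L, 8L),
                         frac_termless_diseases = 0,
                         n_intervals = 8L, interval_length = 100000L,
                         seed = derive_seed(seed, b))
    bundle <- generate_null_dataset(spec)
    kb <- suppressWarnings(fixture_knowledge_base(bundle))
    annotation <- annotate_genes(kb$associations, bundle$ontology, "hpo")
    regions <- build_gene_regions(kb$genes)
    cfg <- enrichment_config(mode = mode, n_perm = n_perm, n_boot = n_boot,
                             seed = derive_seed(seed, 1000000L + b))
    res <- run_enrichment(validate_intervals(bundle$intervals), annotation,
                          regions, bundle$chrom_sizes, cfg)
    min_p[b] <- if (nrow(res)) min(res$corrected_p) else 1
  }
  list(fraction = mean(min_p < alpha), min_corrected_p = min_p,
       n_bundles = n_bundles, alpha = alpha)
}

#' Command-line entry point
#'
#' Subcommands: `run --config cfg.json`, `synth --spec spec.json --out dir`.
#' Exit status: 0 success, 2 validation error, 3 data error, 4 internal
#' error.
#'
#' @param args character vector of CLI arguments.
#' @return integer exit status, invisibly.
#' @export
mendelprior_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  arg_val <- function(flag) {
    i <- which(args == flag)
    if (length(i) != 1L || i == length(args)) NULL else args[i + 1L]
  }
  status <- tryCatch({
    cmd <- if (length(args)) args[[1L]] else ""
    switch(cmd,
      run = {
        cfg <- arg_val("--config") %||%
          mv_stop("CLI_ARGS", "run requires --config <file>")
        run_pipeline(cfg)
        0L
      },
      synth = {
        spec_path <- arg_val("--spec")
        out <- arg_val("--out") %||%
          mv_stop("CLI_ARGS", "synth requires --out <dir>")
        spec_args <- if (is.null(spec_path)) list() else
          jsonlite::read_json(spec_path, simplifyVector = TRUE)
        generate_fixture(do.call(fixture_spec, spec_args), out_dir = out)
        0L
      },
      {
        message("usage: mendelprior <run|synth> [--config cfg.json] [--spec spec.json] [--out dir]")
        2L
      })
  },
  mv_validation_error = function(e) { message(conditionMessage(e)); 2L },
  mv_data_error = function(e) { message(conditionMessage(e)); 3L },
  error = function(e) { message(conditionMessage(e)); 4L })
  invisible(status)
}
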