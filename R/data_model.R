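# Knowledge-base schema: gene/transcript records, multi-source gene-disease
# associations with provenance, descriptions and ontology annotations.

SOURCE_LEVELS <- c("OMIM", "ORPHANET", "DECIPHER", "GE")
DESCRIPTION_PRIORITY <- c("OMIM", "ORPHANET", "UNIPROT", "DO")
CLINSIG_LEVELS <- c("pathogenic", "likely pathogenic", "benign",
                    "likely benign", "uncertain significance")

#' Read a gene/transcript coordinate table
#'
#' Tab-delimited with header columns `gene_id, symbol, chrom, tx_start,
#' tx_end, strand, transcript_id, appris_principal` (0/1). Coordinates are
#' 1-based inclusive.
#'
#' @param path file path.
#' @return data.frame of transcript records with `appris_principal` logical
#'   and `transcript_length` (bp) added.
#' @export
read_gene_table <- function(path) {
  df <- read_tsv(path, colClasses = c(chrom = "character"))
  validate_transcripts(df)
}

validate_transcripts <- function(df) {
  need <- c("gene_id", "symbol", "chrom", "tx_start", "tx_end", "strand",
            "transcript_id", "appris_principal")
  miss <- setdiff(need, names(df))
  if (length(miss))
    mv_stop("GENE_TABLE_COLUMNS", paste("missing columns:", paste(miss, collapse = ", ")),
            "mv_data_error")
  df$appris_principal <- as.logical(as.integer(df$appris_principal))
  if (any(df$tx_start > df$tx_end))
    mv_stop("GENE_COORDS", "tx_start > tx_end for some transcripts", "mv_data_error")
  if (!all(df$strand %in% c("+", "-")))
    mv_stop("GENE_STRAND", "strand must be '+' or '-'", "mv_data_error")
  df$transcript_length <- df$tx_end - df$tx_start + 1L
  df
}

#' Select the canonical transcript of one gene
#'
#' The unique APPRIS-principal isoform wins if exactly one exists; otherwise
#' the longest transcript, with ties broken by lexicographically smallest
#' `transcript_id` (C collation).
#'
#' @param transcripts data.frame of transcript records for a single gene.
#' @return the selected single-row data.frame.
#' @export
select_canonical_transcript <- function(transcripts) {
  if (is.null(transcripts) || nrow(transcripts) == 0L)
    mv_stop("NO_TRANSCRIPTS", "gene has no transcripts", "mv_data_error")
  if (length(unique(transcripts$gene_id)) != 1L)
    mv_stop("MIXED_GENES", "transcripts belong to more than one gene", "mv_data_error")
  principal <- which(transcripts$appris_principal)
  if (length(principal) == 1L) return(transcripts[principal, , drop = FALSE])
  pool <- if (length(principal) > 1L) transcripts[principal, , drop = FALSE] else transcripts
  len <- pool$tx_end - pool$tx_start + 1L
  best <- which(len == max(len))
  if (length(best) > 1L)
    best <- best[radix_order(pool$transcript_id[best])[1L]]
  pool[best, , drop = FALSE]
}

#' Canonical transcript per gene for a whole transcript table
#'
#' @param transcripts data.frame as returned by [read_gene_table()].
#' @return one row per gene, ordered by gene_id (C collation).
#' @export
canonical_transcripts <- function(transcripts) {
  transcripts <- validate_transcripts(transcripts)
  parts <- split(transcripts, transcripts$gene_id)
  out <- do.call(rbind, lapply(parts, select_canonical_transcript))
  out <- out[radix_order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read one per-source association table
#'
#' Tab-delimited with header `gene_id, disease_id, disease_name`.
#'
#' @param path file path.
#' @param source source label the table is tagged with.
#' @return data.frame with a `source` column attached.
#' @export
read_association_table <- function(path, source) {
  df <- read_tsv(path)
  need <- c("gene_id", "disease_id", "disease_name")
  if (!all(need %in% names(df)))
    mv_stop("ASSOC_COLUMNS", "association table needs gene_id, disease_id, disease_name",
            "mv_data_error")
  df$source <- source
  df
}

disease_link_url <- function(disease_id) {
  ns <- sub(":.*$", "", disease_id)
  acc <- sub("^[^:]*:", "", disease_id)
  ifelse(ns == "OMIM", paste0("https://www.omim.org/entry/", acc),
  ifelse(ns == "ORPHA", paste0("https://www.orpha.net/ORDO/Orphanet_", acc),
  ifelse(ns == "DECIPHER", paste0("https://www.deciphergenomics.org/ddd/ddgene/", acc),
  ifelse(ns == "GE", paste0("https://panelapp.genomicsengland.co.uk/panels/entities/", acc),
         ""))))
}

#' Integrate per-source gene-disease tables into one association table
#'
#' Rows sharing a `(gene_id, disease_id)` key across sources are merged into a
#' single association whose `sources` is the union of contributing labels;
#' duplicates within one source are silently dropped. When an alias table is
#' supplied (phenotypic-series style grouping), merging happens on the aliased
#' disease id.
#'
#' @param tables named list of data.frames (`gene_id, disease_id,
#'   disease_name`); each name is the source label of that table.
#' @param genes optional canonical gene table; associations whose `gene_id`
#'   does not resolve are dropped with a warning (count kept in
#'   `attr(,"n_unresolved")`).
#' @param alias optional data.frame `disease_id, series_id` mapping member
#'   disease ids to a shared series id used as the merge key.
#' @return data.frame with columns `gene_id, disease_id, disease_name,
#'   sources` (list), `description, description_source` (NA), `hpo_terms,
#'   do_terms` (empty lists), `link_url`. The winning `disease_name` and
#'   retained `disease_id` come from the highest-priority source
#'   (OMIM > ORPHANET > DECIPHER > GE, then input order for other labels).
#' @export
integrate_sources <- function(tables, genes = NULL, alias = NULL) {
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables)))
    mv_stop("SOURCE_LABELS", "each table must be named with its source label")
  src_rank <- function(s) {
    r <- match(s, SOURCE_LEVELS)
    extra <- match(s, names(tables)) + length(SOURCE_LEVELS)
    ifelse(is.na(r), extra, r)
  }
  rows <- list()
  for (src in names(tables)) {
    tb <- tables[[src]]
    if (is.null(tb) || nrow(tb) == 0L) next
    tb <- unique(tb[, c("gene_id", "disease_id", "disease_name")])
    tb$source <- src
    rows[[src]] <- tb
  }
  n_unresolved <- 0L
  if (length(rows) == 0L) {
    out <- empty_associations()
    attr(out, "n_unresolved") <- 0L
    return(out)
  }
  all_rows <- do.call(rbind, rows)
  if (!is.null(genes)) {
    ok <- all_rows$gene_id %in% genes$gene_id
    n_unresolved <- sum(!ok)
    if (n_unresolved > 0L) {
      mv_warn(sprintf("%d association rows dropped: gene_id not in gene table (%s)",
                      n_unresolved,
                      paste(utils::head(unique(all_rows$gene_id[!ok]), 5L), collapse = ", ")))
      all_rows <- all_rows[ok, , drop = FALSE]
    }
  }
  key_disease <- all_rows$disease_id
  if (!is.null(alias)) {
    m <- match(key_disease, alias$disease_id)
    key_disease <- ifelse(is.na(m), key_disease, alias$series_id[m])
  }
  key <- paste(all_rows$gene_id, key_disease, sep = "\r")
  ord <- radix_order(key, src_rank(all_rows$source))
  all_rows <- all_rows[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  out <- all_rows[first, c("gene_id", "disease_id", "disease_name"), drop = FALSE]
  out$sources <- lapply(split(all_rows$source, factor(key, levels = unique(key))),
                        function(s) SOURCE_LEVELS[SOURCE_LEVELS %in% s] |>
                          c(setdiff(unique(s), SOURCE_LEVELS)))
  out$description <- NA_character_
  out$description_source <- NA_character_
  out$hpo_terms <- rep(list(character(0)), nrow(out))
  out$do_terms <- rep(list(character(0)), nrow(out))
  out$link_url <- disease_link_url(out$disease_id)
  out <- out[radix_order(out$gene_id, out$disease_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unresolved") <- n_unresolved
  out
}

empty_associations <- function() {
  data.frame(gene_id = character(0), disease_id = character(0),
             disease_name = character(0), sources = I(list()),
             description = character(0), description_source = character(0),
             hpo_terms = I(list()), do_terms = I(list()),
             link_url = character(0), stringsAsFactors = FALSE)
}

#' Attach disease descriptions by source priority
#'
#' Each association receives the first available description in the order
#' OMIM > Orphanet > Uniprot > DO; `description_source` records the winner.
#' Diseases absent from every table keep `description = NA`.
#'
#' @param associations integrated association table.
#' @param description_tables named list of data.frames `disease_id,
#'   description`; names are the four description sources. Tables may be
#'   supplied in any order — priority is fixed.
#' @return the association table with `description`/`description_source` set.
#' @export
attach_descriptions <- function(associations, description_tables) {
  order_use <- intersect(DESCRIPTION_PRIORITY, names(description_tables))
  extra <- setdiff(names(description_tables), DESCRIPTION_PRIORITY)
  for (src in c(order_use, extra)) {
    tb <- description_tables[[src]]
    if (is.null(tb) || nrow(tb) == 0L) next
    open <- is.na(associations$description)
    m <- match(associations$disease_id[open], tb$disease_id)
    hit <- !is.na(m)
    idx <- which(open)[hit]
    associations$description[idx] <- tb$description[m[hit]]
    associations$description_source[idx] <- src
  }
  associations
}

#' Attach ontology terms to associations from prioritized sources
#'
#' Per disease, the attached set is the union over all sources; sources are
#' applied in the given order only so the run log can report how many diseases
#' gained terms exclusively from non-primary sources
#' (`attr(,"n_gained_nonprimary")`). Term ids unknown to the ontology, or
#' obsolete, are dropped with one summary warning.
#'
#' @param associations integrated association table.
#' @param term_tables named, ordered list of data.frames `disease_id,
#'   term_id`; the first name is the primary source.
#' @param ontology an [parse_obo()] ontology used to validate ids.
#' @param kind `"hpo"` or `"do"` — which term column to fill.
#' @return association table with the term list-column populated.
#' @export
attach_ontology_terms <- function(associations, term_tables, ontology,
                                  kind = c("hpo", "do")) {
  kind <- match.arg(kind)
  col <- paste0(kind, "_terms")
  if (length(term_tables) == 0L) return(associations)
  if (is.null(names(term_tables)))
    mv_stop("TERM_SOURCE_LABELS", "term tables must be a named list")
  all_tb <- do.call(rbind, lapply(names(term_tables), function(src) {
    tb <- term_tables[[src]]
    if (is.null(tb) || nrow(tb) == 0L) return(NULL)
    data.frame(disease_id = tb$disease_id, term_id = tb$term_id,
               source = src, rank = match(src, names(term_tables)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(all_tb)) return(associations)
  known <- all_tb$term_id %in% ontology$ids
  obsolete <- known & ontology$obsolete[all_tb$term_id]
  drop <- !known | obsolete
  if (any(drop)) {
    mv_warn(sprintf("%d term annotations dropped (%d unknown, %d obsolete ids)",
                    sum(drop), sum(!known), sum(obsolete, na.rm = TRUE)))
    all_tb <- all_tb[!drop, , drop = FALSE]
  }
  per_disease <- split(all_tb, all_tb$disease_id)
  sets <- lapply(per_disease, function(d) radix_sort(unique(d$term_id)))
  nonprimary_only <- vapply(per_disease, function(d) all(d$rank > 1L), logical(1))
  m <- match(associations$disease_id, names(sets))
  filled <- !is.na(m)
  associations[[col]][filled] <- sets[m[filled]]
  gained <- names(sets)[nonprimary_only]
  attr(associations, "n_gained_nonprimary") <-
    sum(unique(associations$disease_id) %in% gained)
  associations
}

#' Read a ClinVar-like variant table
#'
#' Tab-delimited with header `variant_id, chrom, pos, ref, alt,
#' clinical_significance, gene_id, disease_name`.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_variant_table <- function(path) {
  df <- read_tsv(path, colClasses = c(chrom = "character"))
  need <- c("variant_id", "chrom", "pos", "ref", "alt", "clinical_significance")
  if (!all(need %in% names(df)))
    mv_stop("VARIANT_COLUMNS", "variant table missing required columns", "mv_data_error")
  if (any(df$pos < 1L))
    mv_stop("VARIANT_POS", "variant pos must be >= 1", "mv_data_error")
  bad <- !(df$clinical_significance %in% CLINSIG_LEVELS)
  if (any(bad))
    mv_stop("VARIANT_CLINSIG",
            paste("unknown clinical_significance:",
                  paste(unique(df$clinical_significance[bad]), collapse = ", ")),
            "mv_data_error")
  df
}

#' Assemble a knowledge base
#'
#' Bundles canonical genes, integrated associations and variants, checking
#' referential integrity: every association and every gene-linked variant must
#' resolve to a gene record.
#'
#' @param genes canonical gene table (one row per gene).
#' @param associations integrated association table.
#' @param variants variant table (optional).
#' @param build_label `"GRCh37"` or `"GRCh38"` pass-through label.
#' @return an object of class `mv_knowledge_base`.
#' @export
knowledge_base <- function(genes, associations, variants = NULL,
                           build_label = c("GRCh38", "GRCh37")) {
  build_label <- match.arg(build_label)
  if (anyDuplicated(genes$gene_id))
    mv_stop("KB_DUP_GENES", "gene table must have one canonical row per gene", "mv_data_error")
  if (!all(associations$gene_id %in% genes$gene_id))
    mv_stop("KB_ASSOC_GENE", "association gene_id not present in gene table", "mv_data_error")
  if (!is.null(variants)) {
    linked <- !is.na(variants$gene_id) & nzchar(variants$gene_id)
    if (!all(variants$gene_id[linked] %in% genes$gene_id))
      mv_stop("KB_VARIANT_GENE", "variant gene_id not present in gene table", "mv_data_error")
  }
  structure(list(genes = genes, associations = associations,
                 variants = variants, build_label = build_label),
            class = "mv_knowledge_base")
}

#' @export
print.mv_knowledge_base <- function(x, ...) {
  cat(sprintf("<mv_knowledge_base> %d genes, %d associations, %d variants [%s]\n",
              nrow(x$genes), nrow(x$associations),
              if (is.null(x$variants)) 0L else nrow(x$variants), x$build_label))
  invisible(x)
}
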