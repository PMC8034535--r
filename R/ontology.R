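# OBO ontologies as is_a DAGs: parsing, ancestor closure, slim mapping, and
# propagation of disease terms onto genes for enrichment.

#' Parse an OBO 1.2 ontology
#'
#' Reads `[Term]` stanzas (`id`, `name`, `is_a`, `is_obsolete`); only `is_a`
#' edges are kept — `part_of` and other relationships are ignored, matching
#' standard enrichment practice for HPO/DO. Obsolete terms are retained but
#' flagged and excluded from closures and slims. The is_a graph must be
#' acyclic and closed (no dangling parent ids).
#'
#' @param x path to an OBO file, or a character vector of OBO lines.
#' @return an object of class `mv_ontology`: list with `ids`, `names`
#'   (named character), `parents` (named list of character), `obsolete`
#'   (named logical), `roots` (non-obsolete terms with no parents).
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  term_starts <- which(lines == "[Term]")
  stanza_starts <- grep("^\\[", lines)
  ids <- character(0); nms <- character(0)
  parents <- list(); obsolete <- logical(0)
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1L):end]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": *"), "", grep(paste0("^", key, ":"), block, value = TRUE))
      if (length(v)) v[1L] else NA_character_
    }
    id <- get1("id")
    if (is.na(id)) mv_stop("OBO_NO_ID", "Term stanza without id", "mv_data_error")
    isa <- grep("^is_a:", block, value = TRUE)
    isa <- sub("^is_a: *", "", isa)
    isa <- trimws(sub("!.*$", "", isa))        # strip trailing "! name" comment
    obs <- identical(tolower(get1("is_obsolete")), "true")
    ids <- c(ids, id)
    nms <- c(nms, get1("name"))
    parents[[id]] <- isa
    obsolete <- c(obsolete, obs)
  }
  names(nms) <- ids
  names(obsolete) <- ids
  dangling <- setdiff(unique(unlist(parents)), ids)
  if (length(dangling))
    mv_stop("OBO_DANGLING",
            paste("is_a parent id(s) not defined:", paste(dangling, collapse = ", ")),
            "mv_data_error")
  ont <- structure(list(ids = ids, names = nms, parents = parents,
                        obsolete = obsolete,
                        roots = ids[!obsolete &
                                      vapply(parents[ids], length, 1L) == 0L]),
                   class = "mv_ontology")
  cyc <- find_cycle_member(ont)
  if (!is.na(cyc))
    mv_stop("OBO_CYCLE", paste("is_a graph contains a cycle through", cyc),
            "mv_data_error")
  ont
}

# Kahn's algorithm; returns NA if acyclic, else one cycle member id.
find_cycle_member <- function(ont) {
  if (length(unlist(ont$parents)) == 0L) return(NA_character_)
  indeg <- vapply(ont$parents, length, 1L)        # edges point child -> parent
  children <- split(rep(names(ont$parents), lengths(ont$parents)),
                    unlist(ont$parents))
  q <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(q)) {
    v <- q[[1L]]; q <- q[-1L]; seen <- seen + 1L
    for (ch in children[[v]] %||% character(0)) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) q <- c(q, ch)
    }
  }
  if (seen == length(ont$ids)) NA_character_ else names(indeg)[indeg > 0L][1L]
}

#' @export
print.mv_ontology <- function(x, ...) {
  cat(sprintf("<mv_ontology> %d terms (%d obsolete), %d roots\n",
              length(x$ids), sum(x$obsolete), length(x$roots)))
  invisible(x)
}

#' Ancestor closure of a term set
#'
#' Returns the input terms plus all is_a ancestors, walking only through
#' non-obsolete terms. Root terms are included by default; set
#' `include_roots = FALSE` to drop them (they are uninformative for
#' enrichment).
#'
#' @param term_ids character vector of term ids.
#' @param ontology an `mv_ontology`.
#' @param include_roots keep root terms in the result?
#' @return sorted character vector of term ids.
#' @export
ancestor_closure <- function(term_ids, ontology, include_roots = TRUE) {
  term_ids <- unique(term_ids)
  unknown <- setdiff(term_ids, ontology$ids)
  if (length(unknown))
    mv_stop("TERM_UNKNOWN", paste("unknown term id(s):", paste(unknown, collapse = ", ")),
            "mv_data_error")
  obs <- term_ids[ontology$obsolete[term_ids]]
  if (length(obs))
    mv_stop("TERM_OBSOLETE", paste("obsolete term id(s):", paste(obs, collapse = ", ")),
            "mv_data_error")
  out <- character(0)
  frontier <- term_ids
  while (length(frontier)) {
    out <- c(out, frontier)
    up <- unique(unlist(ontology$parents[frontier], use.names = FALSE))
    up <- up[!ontology$obsolete[up]]
    frontier <- setdiff(up, out)
  }
  if (!include_roots) out <- setdiff(out, ontology$roots)
  radix_sort(unique(out))
}

#' Build a slim from the direct children of a root term
#'
#' Mirrors the custom high-level slim construction: the slim is the set of
#' direct (distance-1) non-obsolete descendants of the given root term.
#'
#' @param ontology an `mv_ontology`.
#' @param root_term_id the term whose children form the slim.
#' @return sorted character vector of slim term ids.
#' @export
build_slim <- function(ontology, root_term_id) {
  if (!root_term_id %in% ontology$ids)
    mv_stop("SLIM_ROOT_UNKNOWN", paste("unknown root term:", root_term_id),
            "mv_data_error")
  kids <- names(ontology$parents)[vapply(ontology$parents,
                                         function(p) root_term_id %in% p, logical(1))]
  radix_sort(kids[!ontology$obsolete[kids]])
}

#' Map a term set onto a slim
#'
#' A slim term is hit when it lies in the ancestor closure of at least one
#' input term (a term that is itself a slim term maps to itself).
#'
#' @param term_ids character vector of annotated term ids.
#' @param slim character vector of slim term ids (must exist in the ontology).
#' @param ontology an `mv_ontology`.
#' @return sorted character vector, always a subset of `slim`.
#' @export
map_to_slim <- function(term_ids, slim, ontology) {
  bad <- setdiff(slim, ontology$ids)
  if (length(bad))
    mv_stop("SLIM_UNKNOWN", paste("slim ids not in ontology:", paste(bad, collapse = ", ")),
            "mv_data_error")
  if (length(term_ids) == 0L) return(character(0))
  radix_sort(intersect(ancestor_closure(term_ids, ontology), slim))
}

#' Propagate disease ontology terms to genes and invert to term -> gene sets
#'
#' Each gene is annotated with the ancestor closure of the union of the direct
#' terms of all its diseases; the inverted index (`term_to_genes`) is the
#' input to enrichment. The genome background is every gene with at least one
#' association, terms or not.
#'
#' @param associations integrated association table with the term list-column
#'   of `kind` filled (see [attach_ontology_terms()]).
#' @param ontology an `mv_ontology`.
#' @param kind `"hpo"` or `"do"`.
#' @param label annotation label used in reports (defaults to `kind`).
#' @return object of class `mv_gene_annotation`: list with `label`,
#'   `term_to_genes` (named list of sorted gene ids), `genome_background`,
#'   `root_ids`, `term_names`.
#' @export
annotate_genes <- function(associations, ontology, kind = c("hpo", "do"),
                           label = NULL) {
  kind <- match.arg(kind)
  col <- paste0(kind, "_terms")
  background <- radix_sort(unique(associations$gene_id))
  direct <- tapply(associations[[col]], associations$gene_id,
                   function(sets) unique(unlist(sets)), simplify = FALSE)
  term_to_genes <- list()
  for (g in names(direct)) {
    terms <- direct[[g]]
    if (is.null(terms) || length(terms) == 0L) next
    for (t in ancestor_closure(terms, ontology))
      term_to_genes[[t]] <- c(term_to_genes[[t]], g)
  }
  term_to_genes <- lapply(term_to_genes, function(g) radix_sort(unique(g)))
  term_to_genes <- term_to_genes[radix_sort(names(term_to_genes))]
  gene_annotation(term_to_genes, background,
                  label = label %||% toupper(kind),
                  root_ids = ontology$roots,
                  term_names = ontology$names)
}

#' Build a gene annotation from explicit term -> gene sets
#'
#' Generic entry point for pathway-style term/gene mappings (GMT files and
#' similar); no closure is applied.
#'
#' @param term_to_genes named list mapping term id to character vector of
#'   gene ids.
#' @param genome_background character vector of all background gene ids.
#' @param label annotation label.
#' @param root_ids terms to exclude from enrichment reporting (e.g. DAG root).
#' @param term_names optional named character vector of term names.
#' @return object of class `mv_gene_annotation`.
#' @export
gene_annotation <- function(term_to_genes, genome_background, label = "custom",
                            root_ids = character(0), term_names = NULL) {
  term_to_genes <- lapply(term_to_genes, function(g) radix_sort(unique(g)))
  out_of_bg <- setdiff(unique(unlist(term_to_genes)), genome_background)
  if (length(out_of_bg))
    mv_stop("ANNOT_BACKGROUND",
            paste("annotated genes missing from background:",
                  paste(utils::head(out_of_bg, 5L), collapse = ", ")),
            "mv_data_error")
  structure(list(label = label, term_to_genes = term_to_genes,
                 genome_background = radix_sort(unique(genome_background)),
                 root_ids = root_ids,
                 term_names = term_names %||%
                   stats::setNames(names(term_to_genes), names(term_to_genes))),
            class = "mv_gene_annotation")
}

#' @export
print.mv_gene_annotation <- function(x, ...) {
  cat(sprintf("<mv_gene_annotation> '%s': %d terms over %d background genes\n",
              x$label, length(x$term_to_genes), length(x$genome_background)))
  invisible(x)
}

#' Read a GMT-style term -> gene set file
#'
#' One line per term: `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @param genome_background optional explicit background; defaults to the
#'   union of all listed genes.
#' @param label annotation label.
#' @return `mv_gene_annotation`.
#' @export
read_gmt <- function(path, genome_background = NULL, label = "custom") {
  lines <- readLines(path)
  parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  nms <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  gene_annotation(sets, genome_background %||% unique(unlist(sets)),
                  label = label, term_names = stats::setNames(nms, ids))
}
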