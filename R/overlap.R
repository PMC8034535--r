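# Intersection of test intervals with extended canonical gene regions and
# pathogenic variants; gene collapsing into overlap clusters for enrichment.
# Overlap arithmetic is 1-based inclusive throughout (IRanges semantics).

MAX_GENE_EXTENSION_BP <- 20000L

#' Build (optionally extended) gene regions from canonical transcripts
#'
#' Extends each canonical transcript span by up to 20 kbp per side. By
#' default the extension is strand-aware ("upstream" is transcription-
#' relative): on the minus strand the upstream extension is applied to the
#' transcript end. `strand_aware = FALSE` applies `upstream` to the left and
#' `downstream` to the right on both strands. Starts are clipped at 1.
#'
#' @param genes canonical gene table (one row per gene).
#' @param upstream,downstream extensions in bp (0..20,000).
#' @param strand_aware logical.
#' @return data.frame `gene_id, symbol, chrom, region_start, region_end, strand`.
#' @export
build_gene_regions <- function(genes, upstream = 0L, downstream = 0L,
                               strand_aware = TRUE) {
  if (upstream < 0 || downstream < 0 ||
      upstream > MAX_GENE_EXTENSION_BP || downstream > MAX_GENE_EXTENSION_BP)
    mv_stop("GENE_EXTENSION_LIMIT",
            sprintf("gene extensions must be within [0, %d] bp", MAX_GENE_EXTENSION_BP))
  minus <- strand_aware & genes$strand == "-"
  left <- ifelse(minus, downstream, upstream)
  right <- ifelse(minus, upstream, downstream)
  data.frame(gene_id = genes$gene_id,
             symbol = genes$symbol,
             chrom = genes$chrom,
             region_start = pmax(1L, as.integer(genes$tx_start - left)),
             region_end = as.integer(genes$tx_end + right),
             strand = genes$strand,
             stringsAsFactors = FALSE)
}

check_chrom_conventions <- function(a, b) {
  pa <- any(startsWith(unique(a), "chr")); pb <- any(startsWith(unique(b), "chr"))
  if (length(a) && length(b) && length(intersect(unique(a), unique(b))) == 0L &&
      pa != pb)
    mv_stop("CHROM_NAMING",
            "no shared chromosome names between intervals and annotation; one side uses a 'chr' prefix and the other does not - harmonize naming",
            "mv_data_error")
  invisible(TRUE)
}

# Core 1-based inclusive overlap of two interval sets split by chromosome.
# Returns data.frame(query = i, subject = j) index pairs.
overlap_pairs <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  out <- list()
  for (ch in intersect(unique(q_chrom), unique(s_chrom))) {
    qi <- which(q_chrom == ch); si <- which(s_chrom == ch)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(q_start[qi], q_end[qi]),
      IRanges::IRanges(s_start[si], s_end[si]))
    out[[ch]] <- data.frame(query = qi[S4Vectors::queryHits(hits)],
                            subject = si[S4Vectors::subjectHits(hits)])
  }
  if (length(out) == 0L) return(data.frame(query = integer(0), subject = integer(0)))
  res <- do.call(rbind, out)
  res <- res[radix_order(res$query, res$subject), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Genes overlapping the test intervals
#'
#' A `(interval, gene)` row exists iff the interval and the gene region share
#' at least one base (touching end-to-start in inclusive coordinates is not
#' overlap). When a knowledge base is supplied, each gene row is joined with
#' all of that gene's disease associations.
#'
#' @param intervals validated `mv_intervals`.
#' @param regions gene regions from [build_gene_regions()].
#' @param kb optional `mv_knowledge_base` used to join disease rows.
#' @return data.frame with one row per (interval, gene[, disease]).
#' @export
find_gene_overlaps <- function(intervals, regions, kb = NULL) {
  check_chrom_conventions(intervals$chrom, regions$chrom)
  pairs <- overlap_pairs(intervals$chrom, intervals$start, intervals$end,
                         regions$chrom, regions$region_start, regions$region_end)
  hits <- data.frame(
    interval_label = intervals$label[pairs$query],
    interval = sprintf("%s:%d-%d", intervals$chrom[pairs$query],
                       intervals$start[pairs$query], intervals$end[pairs$query]),
    gene_id = regions$gene_id[pairs$subject],
    symbol = regions$symbol[pairs$subject],
    chrom = regions$chrom[pairs$subject],
    region_start = regions$region_start[pairs$subject],
    region_end = regions$region_end[pairs$subject],
    strand = regions$strand[pairs$subject],
    stringsAsFactors = FALSE)
  if (is.null(kb)) return(hits)
  assoc <- kb$associations
  idx <- lapply(hits$gene_id, function(g) which(assoc$gene_id == g))
  reps <- lengths(idx)
  reps[reps == 0L] <- 1L                       # keep genes with no disease rows
  out <- hits[rep(seq_len(nrow(hits)), reps), , drop = FALSE]
  a_idx <- unlist(lapply(idx, function(i) if (length(i)) i else NA_integer_))
  pick <- function(col) ifelse(is.na(a_idx), NA, assoc[[col]][a_idx])
  out$disease_id <- pick("disease_id")
  out$disease_name <- pick("disease_name")
  out$link_url <- pick("link_url")
  out$sources <- vapply(a_idx, function(i)
    if (is.na(i)) "" else collapse_set(assoc$sources[[i]]), character(1))
  out$description <- pick("description")
  out$description_source <- pick("description_source")
  out$hpo_terms <- vapply(a_idx, function(i)
    if (is.na(i)) "" else collapse_set(assoc$hpo_terms[[i]]), character(1))
  out$do_terms <- vapply(a_idx, function(i)
    if (is.na(i)) "" else collapse_set(assoc$do_terms[[i]]), character(1))
  rownames(out) <- NULL
  out
}

#' Pathogenic variants inside the test intervals
#'
#' A variant row is kept iff its position lies within an interval and its
#' clinical significance is in the filter set (default: pathogenic and likely
#' pathogenic). Variants are anchored at their single `pos` even for indels.
#'
#' @param intervals validated `mv_intervals`.
#' @param variants variant table.
#' @param significance_filter significance classes to keep.
#' @return data.frame, one row per (interval, variant).
#' @export
find_variant_overlaps <- function(intervals, variants,
                                  significance_filter = c("pathogenic",
                                                          "likely pathogenic")) {
  keep <- variants$clinical_significance %in% significance_filter
  v <- variants[keep, , drop = FALSE]
  pairs <- overlap_pairs(intervals$chrom, intervals$start, intervals$end,
                         v$chrom, v$pos, v$pos)
  out <- data.frame(
    interval_label = intervals$label[pairs$query],
    interval = sprintf("%s:%d-%d", intervals$chrom[pairs$query],
                       intervals$start[pairs$query], intervals$end[pairs$query]),
    v[pairs$subject, , drop = FALSE],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Collapse overlapping gene regions into clusters
#'
#' Maximal chains of pairwise-overlapping regions become one cluster (the
#' counting unit for the permutation null, so clustered paralogs are not
#' double-counted); genes overlapping nothing are singleton clusters.
#'
#' @param regions gene regions restricted to the enrichment background.
#' @return data.frame `cluster_id, chrom, span_start, span_end, n_members`
#'   with a `members` list-column of gene ids.
#' @export
collapse_genes <- function(regions) {
  if (nrow(regions) == 0L)
    return(data.frame(cluster_id = character(0), chrom = character(0),
                      span_start = integer(0), span_end = integer(0),
                      n_members = integer(0), members = I(list())))
  out <- list()
  for (ch in radix_sort(unique(regions$chrom))) {
    ri <- which(regions$chrom == ch)
    ir <- IRanges::IRanges(regions$region_start[ri], regions$region_end[ri])
    # min.gapwidth = 0: merge only genuinely overlapping regions; regions
    # that merely touch end-to-start are distinct clusters (inclusive coords).
    merged <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, merged)
    members <- split(regions$gene_id[ri[S4Vectors::queryHits(hit)]],
                     S4Vectors::subjectHits(hit))
    out[[ch]] <- data.frame(chrom = ch,
                            span_start = IRanges::start(merged),
                            span_end = IRanges::end(merged),
                            n_members = lengths(members),
                            stringsAsFactors = FALSE)
    out[[ch]]$members <- lapply(members, radix_sort)
  }
  res <- do.call(rbind, out)
  res <- res[radix_order(res$chrom, res$span_start), , drop = FALSE]
  res <- cbind(cluster_id = sprintf("CL%04d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
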