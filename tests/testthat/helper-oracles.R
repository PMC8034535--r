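# Independent brute-force oracles. These deliberately re-derive each result
# by the most naive correct method (double loops, BFS, union-find,
# exhaustive enumeration) and never call the code paths they check.

# All-pairs interval/region overlap under 1-based inclusive arithmetic.
oracle_overlap_pairs <- function(intervals, regions) {
  out <- list()
  for (i in seq_len(nrow(intervals))) for (j in seq_len(nrow(regions))) {
    if (intervals$chrom[i] == regions$chrom[j] &&
        intervals$start[i] <= regions$region_end[j] &&
        intervals$end[i] >= regions$region_start[j])
      out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(query = integer(0), subject = integer(0)))
  m <- do.call(rbind, out)
  df <- data.frame(query = m[, 1], subject = m[, 2])
  df[order(df$query, df$subject), ]
}

# Union-find clustering of pairwise-overlapping regions.
oracle_clusters <- function(regions) {
  n <- nrow(regions)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && regions$chrom[i] == regions$chrom[j] &&
        regions$region_start[i] <= regions$region_end[j] &&
        regions$region_end[i] >= regions$region_start[j])
      parent[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(lapply(split(regions$gene_id, roots), function(g) sort(g)))
}

# BFS ancestor closure over an is_a parent map (skips obsolete terms).
oracle_closure <- function(ids, parents, obsolete = character(0)) {
  seen <- character(0)
  frontier <- ids
  while (length(frontier)) {
    seen <- union(seen, frontier)
    nxt <- unique(unlist(parents[frontier]))
    nxt <- setdiff(nxt, c(seen, obsolete))
    frontier <- nxt
  }
  sort(seen)
}

# Nested-loop observed statistic over intervals x genes.
oracle_statistic <- function(intervals, regions, term_genes, mode) {
  hit_genes <- character(0)
  hit_intervals <- 0L
  for (i in seq_len(nrow(intervals))) {
    genes_i <- character(0)
    for (j in seq_len(nrow(regions))) {
      if (intervals$chrom[i] == regions$chrom[j] &&
          intervals$start[i] <= regions$region_end[j] &&
          intervals$end[i] >= regions$region_start[j] &&
          regions$gene_id[j] %in% term_genes)
        genes_i <- c(genes_i, regions$gene_id[j])
    }
    if (length(genes_i)) hit_intervals <- hit_intervals + 1L
    hit_genes <- union(hit_genes, genes_i)
  }
  if (mode == "gene") length(hit_genes) else hit_intervals
}

# Exhaustive enumeration of every valid same-length placement on a genome
# small enough to scan: returns, per start position with matching cluster
# count, the per-term statistic of the single relocated interval.
oracle_placements <- function(len, k, clusters, chrom_sizes) {
  out <- list()
  for (ch in names(chrom_sizes)) {
    smax <- chrom_sizes[[ch]] - len + 1
    if (smax < 1) next
    cl <- clusters[clusters$chrom == ch, , drop = FALSE]
    for (s in seq_len(smax)) {
      cnt <- sum(cl$span_start <= s + len - 1 & cl$span_end >= s)
      if (cnt == k) out[[length(out) + 1L]] <- data.frame(chrom = ch, start = s)
    }
  }
  if (!length(out)) return(data.frame(chrom = character(0), start = integer(0)))
  do.call(rbind, out)
}

# Small random fixture pieces -------------------------------------------------

random_intervals <- function(n, chroms = c("chr1", "chr2"), size = 100000L) {
  start <- sample.int(size - 2000L, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start,
                    start + sample.int(2000L, n, replace = TRUE),
                    label = sprintf("iv%03d", seq_len(n)))
}

random_regions <- function(n, chroms = c("chr1", "chr2"), size = 100000L) {
  start <- sample.int(size - 3000L, n, replace = TRUE)
  data.frame(gene_id = sprintf("G%03d", seq_len(n)),
             symbol = sprintf("S%03d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             region_start = start,
             region_end = start + sample.int(3000L, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Minimal OBO text builder: edges is a list child -> character vector of
# parents; obsolete a character vector of term ids.
obo_text <- function(terms, edges = list(), obsolete = character(0)) {
  lines <- c("format-version: 1.2", "")
  for (t in terms) {
    lines <- c(lines, "[Term]", paste0("id: ", t), paste0("name: name of ", t))
    for (p in edges[[t]] %||% character(0))
      lines <- c(lines, paste0("is_a: ", p, " ! ", p))
    if (t %in% obsolete) lines <- c(lines, "is_obsolete: true")
    lines <- c(lines, "")
  }
  lines
}

`%||%` <- function(a, b) if (is.null(a)) b else a
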