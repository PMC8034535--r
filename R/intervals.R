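# Test-interval construction: fixed flanks around lead positions, LD-proxy
# boundaries with optional recombination-hotspot extension, or user intervals.
# Internal coordinates are 1-based inclusive; BED I/O converts at the boundary.

MAX_FLANK_BP <- 10000000L
MAX_INTERVAL_BP <- 20000000L
MAX_INPUT_N <- 10000L
LD_WINDOW_BP <- 500000L   # half-width of the 1 Mbp window centred on the SNP

#' Construct a genomic interval table
#'
#' @param chrom,start,end vectors of equal length; 1-based inclusive.
#' @param label interval labels (input variant id or "chrom:start-end").
#' @param origin one of `"flank"`, `"ld"`, `"user"` per interval.
#' @return data.frame of class `mv_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, label = NULL, origin = "user") {
  label <- label %||% sprintf("%s:%d-%d", chrom, start, end)
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), label = label,
                   origin = origin, stringsAsFactors = FALSE)
  class(df) <- c("mv_intervals", "data.frame")
  df
}

#' Fixed-flank intervals around input positions
#'
#' Builds `[pos - flank_left, pos + flank_right]` around each position,
#' clipped to `[1, chrom_size]` (clipping is logged via warning attribute, not
#' an error). Flanks may be at most 10 Mbp each.
#'
#' @param positions data.frame `chrom, pos, label`.
#' @param flank_left,flank_right flank sizes in bp (0..10e6).
#' @param chrom_sizes named integer vector of chromosome sizes.
#' @return `mv_intervals`, one per input row, order preserved.
#' @export
make_flank_intervals <- function(positions, flank_left, flank_right, chrom_sizes) {
  if (flank_left < 0 || flank_right < 0 ||
      flank_left > MAX_FLANK_BP || flank_right > MAX_FLANK_BP)
    mv_stop("FLANK_LIMIT",
            sprintf("flanks must be within [0, %d] bp", MAX_FLANK_BP))
  bad_chrom <- !(positions$chrom %in% names(chrom_sizes))
  if (any(bad_chrom))
    mv_stop("POSITION_CHROM",
            paste("unknown chromosome for record(s):",
                  paste(positions$label[bad_chrom], collapse = ", ")))
  size <- chrom_sizes[positions$chrom]
  outside <- positions$pos < 1 | positions$pos > size
  if (any(outside))
    mv_stop("POSITION_RANGE",
            paste("position outside chromosome for record(s):",
                  paste(positions$label[outside], collapse = ", ")))
  genomic_intervals(positions$chrom,
                    pmax(1, positions$pos - flank_left),
                    pmin(size, positions$pos + flank_right),
                    positions$label, origin = "flank")
}

#' Read an LD proxy table for one index variant
#'
#' Tab-delimited columns `variant_id, chrom, pos, r2, dprime` (LDproxy-style
#' export). The index variant is expected to appear in its own table with
#' `r2 = dprime = 1`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_ld_table <- function(path) {
  df <- read_tsv(path, colClasses = c(chrom = "character"))
  need <- c("variant_id", "chrom", "pos", "r2", "dprime")
  if (!all(need %in% names(df)))
    mv_stop("LD_COLUMNS", "LD table needs variant_id, chrom, pos, r2, dprime",
            "mv_data_error")
  df
}

#' LD-based interval around an index variant
#'
#' The interval runs from the most distant upstream to the most distant
#' downstream proxy meeting the LD threshold; the index variant always
#' qualifies, so the interval always contains its position. A missing or
#' empty proxy table degrades to the 1-bp interval `[pos, pos]` with a
#' warning rather than aborting a multi-locus run.
#'
#' @param index list or one-row data.frame with `chrom, pos, label`.
#' @param ld LD proxy table (see [read_ld_table()]), or NULL.
#' @param stat `"r2"` or `"dprime"`.
#' @param threshold minimum LD statistic in `[0, 1]`.
#' @return single-row `mv_intervals` with `origin = "ld"`.
#' @export
make_ld_interval <- function(index, ld, stat = c("r2", "dprime"), threshold) {
  stat <- match.arg(stat)
  if (threshold < 0 || threshold > 1)
    mv_stop("LD_THRESHOLD", "LD threshold must be in [0, 1]")
  pos <- as.integer(index$pos)
  if (is.null(ld) || nrow(ld) == 0L) {
    mv_warn(sprintf("no LD proxies for %s; falling back to 1-bp interval", index$label))
    return(genomic_intervals(index$chrom, pos, pos, index$label, origin = "ld"))
  }
  far <- abs(ld$pos - pos) > LD_WINDOW_BP
  if (any(far)) {
    mv_warn(sprintf("%d proxies outside the 1 Mbp window dropped for %s",
                    sum(far), index$label))
    ld <- ld[!far, , drop = FALSE]
  }
  qual <- ld$pos[ld[[stat]] >= threshold]
  qual <- c(qual, pos)                       # index always qualifies
  genomic_intervals(index$chrom, min(qual), max(qual), index$label, origin = "ld")
}

#' Read a recombination map
#'
#' Tab-delimited `chrom, pos, rate_cM_per_Mb` (HapMap-style); positions must
#' be strictly increasing within each chromosome and rates non-negative.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_recomb_map <- function(path) {
  df <- read_tsv(path, colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "rate_cM_per_Mb")
  if (!all(need %in% names(df)))
    mv_stop("RECOMB_COLUMNS", "recombination map needs chrom, pos, rate_cM_per_Mb",
            "mv_data_error")
  if (any(df$rate_cM_per_Mb < 0))
    mv_stop("RECOMB_RATE", "recombination rates must be >= 0", "mv_data_error")
  inc <- tapply(df$pos, df$chrom, function(p) all(diff(p) > 0))
  if (!all(unlist(inc)))
    mv_stop("RECOMB_SORTED", "map positions must be strictly increasing per chromosome",
            "mv_data_error")
  df
}

#' Extend intervals to the nearest flanking recombination hotspots
#'
#' A hotspot is a map entry with rate strictly greater than `rate_threshold`
#' (default 3 cM/Mb). The new start is the nearest qualifying entry at or left
#' of the current start (unchanged if none); the end is extended
#' symmetrically to the right. Never shrinks; idempotent.
#'
#' @param intervals `mv_intervals`.
#' @param recomb_map data.frame from [read_recomb_map()].
#' @param rate_threshold hotspot rate cut-off, cM/Mb (strict `>`).
#' @return `mv_intervals` with possibly widened boundaries.
#' @export
extend_to_hotspot <- function(intervals, recomb_map, rate_threshold = 3) {
  hot <- recomb_map[recomb_map$rate_cM_per_Mb > rate_threshold, , drop = FALSE]
  for (i in seq_len(nrow(intervals))) {
    h <- hot$pos[hot$chrom == intervals$chrom[i]]
    left <- h[h <= intervals$start[i]]
    right <- h[h >= intervals$end[i]]
    if (length(left)) intervals$start[i] <- max(left)
    if (length(right)) intervals$end[i] <- min(right)
  }
  intervals
}

#' Validate a set of test intervals
#'
#' Enforces the pipeline input limits: at most 10,000 intervals, each at most
#' 20 Mbp long, coordinates well-formed (`1 <= start <= end`). Violations
#' raise structured validation errors naming the offending record numbers.
#'
#' @param intervals `mv_intervals`.
#' @return the intervals, unchanged, when valid.
#' @export
validate_intervals <- function(intervals) {
  if (nrow(intervals) > MAX_INPUT_N)
    mv_stop("INPUT_COUNT_LIMIT",
            sprintf("%d intervals exceed the maximum input of %d",
                    nrow(intervals), MAX_INPUT_N))
  bad <- which(is.na(intervals$start) | is.na(intervals$end) |
                 intervals$start < 1 | intervals$start > intervals$end)
  if (length(bad))
    mv_stop("INTERVAL_COORDS",
            paste("malformed coordinates at line(s):", paste(bad, collapse = ", ")))
  len <- intervals$end - intervals$start + 1
  too_long <- which(len > MAX_INTERVAL_BP)
  if (length(too_long))
    mv_stop("INTERVAL_SIZE_LIMIT",
            sprintf("interval(s) %s exceed the maximum size of %d bp",
                    paste(too_long, collapse = ", "), MAX_INTERVAL_BP))
  intervals
}

#' Read input positions (3-column text)
#'
#' Tab-delimited `chrom, pos, label` with header.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_positions <- function(path) {
  df <- read_tsv(path, colClasses = c(chrom = "character"))
  if (!all(c("chrom", "pos", "label") %in% names(df)))
    mv_stop("POSITIONS_COLUMNS", "positions file needs chrom, pos, label",
            "mv_data_error")
  df
}

#' Read user intervals (TSV `chrom start end label` or "chrom:start-end" lines)
#'
#' @param path file path.
#' @return `mv_intervals` with `origin = "user"`.
#' @export
read_intervals <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(":", first, fixed = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    m <- regmatches(lines, regexec("^([^:]+):([0-9]+)-([0-9]+)$", lines))
    bad <- which(lengths(m) != 4L)
    if (length(bad))
      mv_stop("INTERVAL_PARSE",
              paste("cannot parse interval line(s):", paste(bad, collapse = ", ")))
    genomic_intervals(vapply(m, `[[`, "", 2L),
                      as.integer(vapply(m, `[[`, "", 3L)),
                      as.integer(vapply(m, `[[`, "", 4L)),
                      label = lines, origin = "user")
  } else {
    df <- read_tsv(path, colClasses = c(chrom = "character"))
    if (!all(c("chrom", "start", "end") %in% names(df)))
      mv_stop("INTERVAL_COLUMNS", "interval file needs chrom, start, end[, label]",
              "mv_data_error")
    genomic_intervals(df$chrom, df$start, df$end, df$label, origin = "user")
  }
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals `mv_intervals`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  bed <- data.frame(chrom = intervals$chrom,
                    start = intervals$start - 1L,
                    end = intervals$end,
                    name = intervals$label)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a BED3+name file into 1-based inclusive intervals
#'
#' @param path BED file path.
#' @return `mv_intervals` with `origin = "user"`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = c(V1 = "character"))
  genomic_intervals(df[[1L]], df[[2L]] + 1L, df[[3L]],
                    label = if (ncol(df) >= 4L) df[[4L]] else NULL,
                    origin = "user")
}
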