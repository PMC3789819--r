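# Internal interval helpers. All user-facing coordinates in this package are
# 0-based half-open [start, end); IRanges is 1-based closed, so conversion
# happens only inside these wrappers.

# 0-based half-open -> IRanges. Zero-width intervals are not representable and
# are rejected.
.ir <- function(start, end) {
  stopifnot(all(end > start))
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

# findOverlaps on half-open intervals grouped by chromosome; returns a
# data.frame of (query_idx, subject_idx) pairs over the original row indices.
.overlap_pairs <- function(q, s) {
  stopifnot(all(c("chrom", "start", "end") %in% names(q)),
            all(c("chrom", "start", "end") %in% names(s)))
  if (nrow(q) == 0L || nrow(s) == 0L)
    return(data.frame(query_idx = integer(0), subject_idx = integer(0)))
  out <- vector("list", 0L)
  for (ch in intersect(unique(q$chrom), unique(s$chrom))) {
    qi <- which(q$chrom == ch)
    si <- which(s$chrom == ch)
    hits <- IRanges::findOverlaps(.ir(q$start[qi], q$end[qi]),
                                  .ir(s$start[si], s$end[si]))
    out[[length(out) + 1L]] <- data.frame(
      query_idx = qi[S4Vectors::queryHits(hits)],
      subject_idx = si[S4Vectors::subjectHits(hits)])
  }
  if (length(out) == 0L)
    return(data.frame(query_idx = integer(0), subject_idx = integer(0)))
  do.call(rbind, out)
}

# TRUE for each row of `q` that overlaps any row of `s` by >= 1 base.
.overlaps_any <- function(q, s) {
  hit <- logical(nrow(q))
  p <- .overlap_pairs(q, s)
  hit[unique(p$query_idx)] <- TRUE
  hit
}

# Single-linkage merge of half-open intervals: a gap of <= gap merges
# (< gap when strict = TRUE). Returns list(start, end, n) sorted along the
# genome, n counting merged members.
.gap_merge <- function(start, end, gap, strict = FALSE) {
  stopifnot(length(start) == length(end))
  n <- length(start)
  if (n == 0L)
    return(list(start = integer(0), end = integer(0), n = integer(0)))
  o <- order(start, end)
  start <- start[o]; end <- cummax(end[o])
  g <- start[-1L] - end[-n]
  brk <- if (strict) g >= gap else g > gap
  last <- c(which(brk), n)
  first <- c(1L, which(brk) + 1L)
  list(start = start[first], end = end[last], n = last - first + 1L)
}

.reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Longest run of a single base in a nucleotide string; 0 when absent.
.max_run <- function(seq, base) {
  m <- gregexpr(paste0(base, "+"), seq)[[1L]]
  if (m[1L] == -1L) return(0L)
  max(attr(m, "match.length"))
}
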