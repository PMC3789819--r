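#' Assemble intronic read contigs
#'
#' Single-linkage clustering of intronic fragment footprints within each
#' intron: two footprints merge when the gap between them is no more than
#' \code{gap} nt (a gap of exactly \code{gap} merges). A contig spans from the
#' first footprint start to the last footprint end. A contig gets
#' \code{has_exon_junction_end = TRUE} when an exon-intron junction fragment
#' of the same intron overlaps or abuts either contig end, evidence that the
#' retained sequence is contiguous with spliced mRNA.
#'
#' @param assignments fragment table from [classify_fragments()] (categories
#'   \code{intronic} and \code{exon_intron_junction} are used; others are
#'   ignored).
#' @param gap maximum inter-footprint gap to merge, in nt (default 500).
#' @return data.frame: \code{gene_id}, \code{intron_index}, \code{chrom},
#'   \code{start}, \code{end}, \code{length}, \code{n_fragments},
#'   \code{has_exon_junction_end}; contigs of one intron are disjoint and
#'   sorted.
#' @export
assemble_contigs <- function(assignments, gap = 500L) {
  a <- assignments[assignments$category == "intronic", , drop = FALSE]
  jx <- assignments[assignments$category == "exon_intron_junction", ,
                    drop = FALSE]
  empty <- data.frame(gene_id = character(0), intron_index = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      n_fragments = integer(0),
                      has_exon_junction_end = logical(0))
  if (nrow(a) == 0L) return(empty)
  key <- paste(a$gene_id, a$intron_index)
  jkey <- paste(jx$gene_id, jx$intron_index)
  groups <- split(seq_len(nrow(a)), key)
  parts <- lapply(groups, function(idx) {
    m <- .gap_merge(a$start[idx], a$end[idx], gap = gap)
    js <- jx$start[jkey == key[idx[1L]]]
    je <- jx$end[jkey == key[idx[1L]]]
    # overlap or half-open adjacency with either contig end
    jend <- vapply(seq_along(m$start), function(i)
      any(js <= m$end[i] & je >= m$start[i]), logical(1L))
    list(i = idx[1L], m = m, jend = jend)
  })
  nper <- vapply(parts, function(p) length(p$m$start), integer(1L))
  first <- vapply(parts, `[[`, integer(1L), "i")
  rep1 <- rep(seq_along(parts), nper)
  out <- data.frame(
    gene_id = a$gene_id[first][rep1],
    intron_index = a$intron_index[first][rep1],
    chrom = a$chrom[first][rep1],
    start = unlist(lapply(parts, function(p) p$m$start)),
    end = unlist(lapply(parts, function(p) p$m$end)),
    n_fragments = unlist(lapply(parts, function(p) p$m$n)),
    has_exon_junction_end = unlist(lapply(parts, `[[`, "jend")),
    stringsAsFactors = FALSE)
  out$length <- out$end - out$start
  out <- out[, c("gene_id", "intron_index", "chrom", "start", "end",
                 "length", "n_fragments", "has_exon_junction_end")]
  rownames(out) <- NULL
  out[order(out$gene_id, out$intron_index, out$start), ]
}

#' Test contig lengths against an exponential null
#'
#' Kolmogorov-Smirnov test of the observed lengths against an exponential
#' distribution with rate 1/mean(lengths) — the null expected if retained
#' sequences arose from uniformly random breakpoints. Because the rate is
#' estimated from the same data the nominal p-value is conservative; tied
#' integer lengths also make it approximate.
#'
#' @param lengths numeric vector of contig lengths (n >= 8).
#' @return list: \code{statistic} (KS D), \code{p_value}.
#' @export
length_null_test <- function(lengths) {
  if (length(lengths) < 8L) stop("need at least 8 lengths")
  kt <- suppressWarnings(
    stats::ks.test(lengths, "pexp", rate = 1 / mean(lengths)))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Sense-strand sequence of an intron
#'
#' @param intron one row of [derive_introns()] output.
#' @param genome named \code{DNAStringSet}.
#' @return character string; reverse complement of the reference for
#'   minus-strand genes.
#' @export
intron_sense_sequence <- function(intron, genome) {
  s <- as.character(Biostrings::subseq(genome[[intron$chrom]],
                                       start = intron$start + 1L,
                                       end = intron$end))
  if (intron$strand == "-") s <- .reverse_complement(s)
  s
}

#' Poly(A)-tract contigs within an intron sequence
#'
#' Finds pure-A runs of at least \code{min_len} nt on the supplied
#' sense-strand sequence and clusters runs separated by strictly less than
#' \code{gap} nt, mirroring the read-contig construction. Used to ask whether
#' read-contig lengths merely track the spacing of amplification-primable pA
#' tracts.
#'
#' @param seq sense-strand nucleotide string.
#' @param min_len minimum tract length (default 9 nt).
#' @param gap tracts closer than this merge (strict; default 500 nt).
#' @return data.frame: \code{start}, \code{end}, \code{length},
#'   \code{n_tracts}, coordinates 0-based half-open within \code{seq}.
#' @export
pa_tract_contigs <- function(seq, min_len = 9L, gap = 500L) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), n_tracts = integer(0))
  m <- gregexpr(sprintf("A{%d,}", min_len), seq)[[1L]]
  if (m[1L] == -1L) return(empty)
  s <- as.integer(m) - 1L
  e <- s + attr(m, "match.length")
  g <- .gap_merge(s, e, gap = gap, strict = TRUE)
  data.frame(start = g$start, end = g$end, length = g$end - g$start,
             n_tracts = g$n)
}

.CODON_STOPS <- c("TAA", "TAG", "TGA")

# codon-wise ORF scan of one frame; codons containing anything but A/C/G/T
# are neither start nor stop
.frame_orf <- function(codons) {
  is_start <- codons == "ATG"
  is_stop <- codons %in% .CODON_STOPS
  starts <- which(is_start)
  stops <- which(is_stop)
  max_aa <- 0L
  if (length(starts) > 0L) {
    # next stop at or after each start (none -> open 3' end)
    nxt <- stops[findInterval(starts, stops) + 1L]
    aa <- ifelse(is.na(nxt), length(codons) - starts + 1L, nxt - starts)
    max_aa <- max(aa)
  }
  list(max_orf_aa = as.integer(max_aa), has_stop = length(stops) > 0L)
}

#' Six-frame ORF and stop-codon screen
#'
#' For each of the six reading frames (three sense, three antisense) reports
#' the longest ATG-initiated open reading frame in amino acids — terminated at
#' the first in-frame stop (excluded from the count) or, when no stop follows,
#' running open to the sequence end — and whether the frame contains any stop
#' codon at all. Contigs unlikely to code have short ORFs and a stop in all
#' six frames.
#'
#' @param seq nucleotide string, length >= 3.
#' @return list: \code{max_orf_aa} (named length-6 integer vector, frames
#'   \code{F1..F3}, \code{R1..R3}), \code{max_orf_aa_overall},
#'   \code{has_stop_all_six_frames}.
#' @export
orf_screen <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) < 3L) stop("sequence must be at least 3 nt")
  rc <- .reverse_complement(seq)
  frames <- c(F1 = 0L, F2 = 1L, F3 = 2L, R1 = 0L, R2 = 1L, R3 = 2L)
  src <- c(seq, seq, seq, rc, rc, rc)
  res <- lapply(seq_along(frames), function(i) {
    s <- substring(src[i], frames[i] + 1L)
    n <- nchar(s) %/% 3L
    if (n == 0L) return(list(max_orf_aa = 0L, has_stop = FALSE))
    codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    .frame_orf(codons)
  })
  aa <- vapply(res, `[[`, integer(1L), "max_orf_aa")
  names(aa) <- names(frames)
  list(max_orf_aa = aa,
       max_orf_aa_overall = max(aa),
       has_stop_all_six_frames = all(vapply(res, `[[`, logical(1L),
                                            "has_stop")))
}

#' Assign a contig to an intron third
#'
#' The intron is split into three parts at floor(L/3) and floor(2L/3) of its
#' length; the contig is binned by its 5' start position on the transcribed
#' strand (half-open thirds: a start exactly at L/3 falls in bin 2).
#'
#' @param contig_start,contig_end contig interval (genomic).
#' @param intron_start,intron_end,strand host intron interval and gene strand.
#' @return integer bin in 1:3 (1 = 5'-most third).
#' @export
contig_position_thirds <- function(contig_start, contig_end,
                                   intron_start, intron_end, strand) {
  stopifnot(all(contig_start >= intron_start), all(contig_end <= intron_end))
  len <- intron_end - intron_start
  rel <- ifelse(strand == "+", contig_start - intron_start,
                intron_end - contig_end)
  b1 <- len %/% 3L
  b2 <- (2L * len) %/% 3L
  ifelse(rel < b1, 1L, ifelse(rel < b2, 2L, 3L))
}

#' 5' vs 3' half placement of retained introns
#'
#' Pools genes with at least \code{min_introns} introns and asks whether
#' retained introns sit preferentially in the 5' or 3' half of the gene model.
#' For a gene with n introns, indices <= floor(n/2) are the 5' half and
#' indices > ceiling(n/2) the 3' half; the middle intron of an odd-n gene
#' belongs to neither and is excluded.
#'
#' @param calls data.frame of retained-intron calls with \code{gene_id},
#'   \code{intron_index}.
#' @param introns [derive_introns()] output (supplies per-gene intron counts).
#' @param min_introns minimum introns per gene to include (default 5).
#' @return list: \code{n_5prime}, \code{n_3prime}, \code{n_excluded_middle},
#'   \code{fraction_5prime}, \code{fraction_3prime}.
#' @export
halves_analysis <- function(calls, introns, min_introns = 5L) {
  nint <- tapply(introns$n_introns, introns$gene_id, function(x) x[1L])
  n <- nint[calls$gene_id]
  keep <- !is.na(n) & n >= min_introns
  idx <- calls$intron_index[keep]
  n <- n[keep]
  five <- idx <= n %/% 2L
  three <- idx > ceiling(n / 2)
  n5 <- sum(five); n3 <- sum(three)
  tot <- n5 + n3
  list(n_5prime = n5, n_3prime = n3,
       n_excluded_middle = sum(!five & !three),
       fraction_5prime = if (tot > 0) n5 / tot else NA_real_,
       fraction_3prime = if (tot > 0) n3 / tot else NA_real_)
}

#' Length cutoff for whole-cell samples
#'
#' Whole-cell (soma / single-cell) samples contain the nucleus, so long
#' contigs may reflect unspliced hnRNA; only contigs of at most \code{max_len}
#' nt are retained in that mode.
#'
#' @param contigs [assemble_contigs()] output.
#' @param max_len maximum contig length kept, inclusive (default 400 nt).
#' @return filtered contig data.frame.
#' @export
apply_length_cutoff <- function(contigs, max_len = 400L) {
  contigs[contigs$length <= max_len, , drop = FALSE]
}

#' Split contigs by repeat overlap
#'
#' A contig sharing even a single base with any repeat interval counts as
#' overlapping; half-open adjacency does not.
#'
#' @param contigs [assemble_contigs()] output.
#' @param repeats data.frame of repeat intervals (\code{chrom}, \code{start},
#'   \code{end}), or NULL to skip with a warning.
#' @return list: \code{overlapping}, \code{clean} (both contig data.frames).
#' @export
repeat_overlap_filter <- function(contigs, repeats) {
  if (is.null(repeats)) {
    warning("no repeat annotation supplied; repeat filter skipped")
    return(list(overlapping = contigs[0, , drop = FALSE], clean = contigs))
  }
  hit <- .overlaps_any(contigs, repeats)
  list(overlapping = contigs[hit, , drop = FALSE],
       clean = contigs[!hit, , drop = FALSE])
}
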