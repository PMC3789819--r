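.CANONICAL_SIGNALS <- c("GT-AG", "GC-AG", "AT-AC")

# a signal is accepted as given or as the reverse complement pair read from
# the other strand (GT-AG <-> CT-AC, etc.)
.signal_set <- function(signals = .CANONICAL_SIGNALS) {
  rc_pair <- function(sig) {
    p <- strsplit(sig, "-", fixed = TRUE)[[1L]]
    paste(.reverse_complement(p[2L]), .reverse_complement(p[1L]), sep = "-")
  }
  unique(c(signals, vapply(signals, rc_pair, "")))
}

#' Read a de-novo junction table
#'
#' Tab-separated with header: \code{chrom}, \code{start}, \code{end} (0-based
#' half-open; start = first intronic base of the spliced-out segment),
#' \code{signal} (e.g. \code{GT-AG}), \code{unique_reads},
#' \code{overhang_left}, \code{overhang_right}.
#'
#' @param path TSV file.
#' @return data.frame of raw junctions.
#' @export
read_junction_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "signal", "unique_reads",
            "overhang_left", "overhang_right")
  if (!all(need %in% names(x)))
    stop("junction table must have columns: ", paste(need, collapse = ", "))
  x
}

#' Call intron-internal splice junctions
#'
#' Keeps de-novo junctions that (a) carry a known splice signal (canonical
#' GT-AG plus GC-AG and AT-AC, or their reverse complements), (b) are crossed
#' by at least one uniquely mapping read, (c) have at least \code{min_overhang}
#' nt aligned on each side, and (d) lie strictly inside a single annotated
#' intron — both ends inside the intron, implying processing within the
#' intron rather than annotated splicing. Junctions touching an annotated
#' exon boundary are ordinary splicing and counted separately.
#'
#' @param junctions raw junction table (see [read_junction_table()]).
#' @param introns [derive_introns()] output.
#' @param min_overhang minimum aligned overhang on each side (default 8 nt).
#' @param min_unique_reads minimum uniquely mapping crossing reads (default 1).
#' @param signals accepted splice-signal pairs (reverse complements added
#'   automatically).
#' @return data.frame of accepted calls: junction columns plus
#'   \code{host_gene_id}, \code{host_intron_index}, \code{host_intron_length},
#'   \code{spliced_length}; attribute \code{n_annotated_splicing} counts
#'   quality-passing junctions rejected only for touching exon boundaries.
#' @export
call_intron_intron_junctions <- function(junctions, introns,
                                         min_overhang = 8L,
                                         min_unique_reads = 1L,
                                         signals = .CANONICAL_SIGNALS) {
  ok <- junctions$signal %in% .signal_set(signals) &
    junctions$unique_reads >= min_unique_reads &
    junctions$overhang_left >= min_overhang &
    junctions$overhang_right >= min_overhang &
    junctions$end > junctions$start
  j <- junctions[ok, , drop = FALSE]
  host_gene <- rep(NA_character_, nrow(j))
  host_idx <- rep(NA_integer_, nrow(j))
  host_len <- rep(NA_integer_, nrow(j))
  p <- .overlap_pairs(j, introns)
  # strict containment: both ends inside the intron, not at its boundaries
  strict <- j$start[p$query_idx] > introns$start[p$subject_idx] &
    j$end[p$query_idx] < introns$end[p$subject_idx]
  p <- p[strict, , drop = FALSE]
  host_gene[p$query_idx] <- introns$gene_id[p$subject_idx]
  host_idx[p$query_idx] <- introns$intron_index[p$subject_idx]
  host_len[p$query_idx] <- introns$length[p$subject_idx]
  inside <- !is.na(host_gene)
  out <- j[inside, , drop = FALSE]
  out$host_gene_id <- host_gene[inside]
  out$host_intron_index <- host_idx[inside]
  out$host_intron_length <- host_len[inside]
  out$spliced_length <- out$end - out$start
  rownames(out) <- NULL
  attr(out, "n_annotated_splicing") <- sum(!inside)
  out
}

# longest single-base homopolymer within `flank` nt of either junction end;
# a simple low-complexity proxy for primer design feasibility
.flank_max_run <- function(call, genome, flank = 50L) {
  chrom_len <- length(genome[[call$chrom]])
  region <- function(s, e) as.character(Biostrings::subseq(
    genome[[call$chrom]], start = max(1L, s + 1L), end = min(chrom_len, e)))
  left <- region(call$start - flank, call$start + flank)
  right <- region(call$end - flank, call$end + flank)
  max(vapply(c("A", "C", "G", "T"), function(b)
    max(.max_run(left, b), .max_run(right, b)), integer(1L)))
}

#' Select junctions suitable for validation
#'
#' Applies the four candidate criteria: host intron shorter than
#' \code{max_intron_len}; spliced-out length at least \code{min_spliced};
#' host-gene expression above the sample median; and flanking sequence
#' complexity adequate for primer design, operationalized as no single-base
#' homopolymer run of \code{max_homopolymer} nt or more within \code{flank} nt
#' of either junction end (skipped when no genome is supplied).
#'
#' @param calls [call_intron_intron_junctions()] output.
#' @param expression named numeric vector of per-gene expression.
#' @param genome optional named \code{DNAStringSet} for the complexity screen.
#' @param max_intron_len exclusive upper bound on host intron length
#'   (default 20000 nt).
#' @param min_spliced minimum spliced-out length (default 100 nt).
#' @param max_homopolymer run length that disqualifies a flank (default 10).
#' @param flank flank width scanned on each side (default 50 nt).
#' @return subset of \code{calls} meeting all criteria.
#' @export
junction_selection_criteria <- function(calls, expression, genome = NULL,
                                        max_intron_len = 20000L,
                                        min_spliced = 100L,
                                        max_homopolymer = 10L,
                                        flank = 50L) {
  if (nrow(calls) == 0L) return(calls)
  expr <- expression[calls$host_gene_id]
  keep <- calls$host_intron_length < max_intron_len &
    calls$spliced_length >= min_spliced &
    !is.na(expr) & expr > stats::median(expression)
  if (!is.null(genome)) {
    runs <- vapply(seq_len(nrow(calls)), function(i)
      .flank_max_run(calls[i, ], genome, flank), integer(1L))
    keep <- keep & runs < max_homopolymer
  }
  calls[keep, , drop = FALSE]
}
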