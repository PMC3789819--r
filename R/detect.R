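#' Detect cytoplasmic intron-sequence retaining transcripts
#'
#' The main entry point: classifies uniquely mapped fragments against the gene
#' models, assembles intronic contigs with the gap rule, applies the filter
#' cascade, and summarizes retention per gene. Modes differ in how whole-cell
#' (nucleus-containing) contamination is handled:
#' \describe{
#'   \item{dendrite}{mechanically isolated cytoplasm; no length cutoff, all
#'     filters.}
#'   \item{soma}{whole single cells; contigs longer than
#'     \code{max_contig_len} nt are discarded as likely hnRNA.}
#'   \item{tissue}{bulk total RNA; no length cutoff and no junction-only
#'     exclusion (descriptive contig survey).}
#' }
#'
#' @param blocks alignment-block table (see [read_alignment_blocks()]).
#' @param models a [gene_models()] object.
#' @param genome optional named \code{DNAStringSet}; enables intron sequence
#'   features on the result.
#' @param mode \code{"dendrite"}, \code{"soma"} or \code{"tissue"}.
#' @param annotations optional list for [apply_cirt_filters()]
#'   (\code{predicted_genes}, \code{polya_sites}, \code{ncrna},
#'   \code{antisense}); absent stages are skipped.
#' @param gap contig gap threshold in nt (default 500).
#' @param max_contig_len soma-mode contig length cutoff (default 400 nt).
#' @param chrom_lengths optional named vector; enables the intronic-vs-
#'   intergenic enrichment test.
#' @param intergenic_pad padding around gene spans excluded from intergenic
#'   space (default 1000 nt).
#' @return object of class \code{cirt_scan}: list with \code{assignments},
#'   \code{contigs}, \code{calls}, \code{gene_summary}, \code{introns},
#'   \code{enrichment} (NULL without \code{chrom_lengths}), \code{mode},
#'   \code{params}.
#' @seealso [summary.cirt_scan()], [assemble_contigs()],
#'   [apply_cirt_filters()]
#' @export
detect_cirts <- function(blocks, models, genome = NULL,
                         mode = c("dendrite", "soma", "tissue"),
                         annotations = list(), gap = 500L,
                         max_contig_len = 400L, chrom_lengths = NULL,
                         intergenic_pad = 1000L) {
  mode <- match.arg(mode)
  introns <- derive_introns(models)
  if (!is.null(genome)) introns <- intron_features(introns, genome)
  assignments <- classify_fragments(blocks, models, introns)
  contigs <- assemble_contigs(assignments, gap = gap)
  if (mode == "soma") contigs <- apply_length_cutoff(contigs, max_contig_len)
  calls <- build_retained_calls(contigs, assignments, introns)
  calls <- apply_cirt_filters(calls, contigs, annotations, quiet = TRUE)
  if (mode == "tissue") {
    # tissue mode keeps junction-only introns: the survey is descriptive
    calls$flag_junction_only <- FALSE
    calls <- .update_passed(calls)
  }
  gene_summary <- summarize_genes(assignments, calls, introns)
  enrichment <- NULL
  if (!is.null(chrom_lengths)) {
    ig <- intergenic_space(models, chrom_lengths, pad = intergenic_pad)
    inter <- assignments$category == "intergenic"
    # count only fragments fully outside the padded spans
    far <- inter & !.overlaps_any(
      assignments,
      data.frame(chrom = models$spans$chrom,
                 start = pmax(0L, models$spans$start - intergenic_pad),
                 end = models$spans$end + intergenic_pad))
    enrichment <- enrichment_test(
      intronic_reads = sum(assignments$category == "intronic"),
      intronic_nt = sum(introns$length),
      intergenic_reads = sum(far),
      intergenic_nt = sum(ig$end - ig$start))
  }
  structure(list(assignments = assignments, contigs = contigs, calls = calls,
                 gene_summary = gene_summary, introns = introns,
                 enrichment = enrichment, mode = mode,
                 params = list(gap = gap, max_contig_len = max_contig_len,
                               intergenic_pad = intergenic_pad)),
            class = "cirt_scan")
}

#' @export
print.cirt_scan <- function(x, ...) {
  p <- x$calls[x$calls$passed, , drop = FALSE]
  cat("CIRT scan (", x$mode, " mode)\n", sep = "")
  cat("  fragments classified: ", nrow(x$assignments), "\n", sep = "")
  cat("  intronic contigs:     ", nrow(x$contigs), "\n", sep = "")
  cat("  retained introns:     ", nrow(p), " passed / ", nrow(x$calls),
      " candidate\n", sep = "")
  cat("  CIRT genes:           ", length(unique(p$gene_id)), "\n", sep = "")
  invisible(x)
}

#' Summarize a CIRT scan
#'
#' @param object a \code{cirt_scan}.
#' @param ... unused.
#' @return object of class \code{summary.cirt_scan} with fragment category
#'   counts, gene category counts, filter-flag counts, contig length summary
#'   and the enrichment test (when computed).
#' @export
summary.cirt_scan <- function(object, ...) {
  p <- object$calls[object$calls$passed, , drop = FALSE]
  pk <- paste(p$gene_id, p$intron_index)
  ck <- paste(object$contigs$gene_id, object$contigs$intron_index)
  passed_contigs <- object$contigs[ck %in% pk, , drop = FALSE]
  fl <- grep("^flag_", names(object$calls), value = TRUE)
  structure(list(
    mode = object$mode,
    fragment_categories = table(object$assignments$category),
    gene_categories = table(object$gene_summary$category),
    n_candidate_introns = nrow(object$calls),
    n_passed_introns = nrow(p),
    n_cirt_genes = length(unique(p$gene_id)),
    filter_flags = vapply(fl, function(f) sum(object$calls[[f]]),
                          integer(1L)),
    contig_lengths = if (nrow(passed_contigs) > 0L)
      summary(passed_contigs$length) else NULL,
    mean_contig_length = if (nrow(passed_contigs) > 0L)
      mean(passed_contigs$length) else NA_real_,
    enrichment = object$enrichment),
    class = "summary.cirt_scan")
}

#' @export
print.summary.cirt_scan <- function(x, ...) {
  cat("CIRT scan summary (", x$mode, " mode)\n", sep = "")
  cat("\nFragment categories:\n")
  print(x$fragment_categories)
  cat("\nGene categories:\n")
  print(x$gene_categories)
  cat("\nRetained introns: ", x$n_passed_introns, " passed / ",
      x$n_candidate_introns, " candidate in ", x$n_cirt_genes,
      " genes\n", sep = "")
  cat("Filter flags set:\n")
  print(x$filter_flags)
  if (!is.null(x$contig_lengths)) {
    cat("\nPassed-contig lengths (mean ",
        round(x$mean_contig_length, 1), " nt):\n", sep = "")
    print(x$contig_lengths)
  }
  if (!is.null(x$enrichment))
    cat("\nIntronic vs intergenic enrichment: p = ",
        format.pval(x$enrichment$p_value), " (",
        x$enrichment$method, ")\n", sep = "")
  invisible(x)
}

#' Plot contig length distribution of a scan
#'
#' Histogram of contig lengths for introns passing the filter cascade.
#'
#' @param x a \code{cirt_scan}.
#' @param breaks passed to [graphics::hist()].
#' @param ... further arguments to [graphics::hist()].
#' @return the histogram object, invisibly.
#' @export
plot.cirt_scan <- function(x, breaks = 30, ...) {
  p <- x$calls[x$calls$passed, , drop = FALSE]
  ck <- paste(x$contigs$gene_id, x$contigs$intron_index)
  keep <- ck %in% paste(p$gene_id, p$intron_index)
  if (!any(keep)) stop("no passed contigs to plot")
  h <- graphics::hist(x$contigs$length[keep], breaks = breaks,
                      main = sprintf("Intronic contig lengths (%s)", x$mode),
                      xlab = "contig length (nt)", ...)
  invisible(h)
}
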