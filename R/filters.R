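#' Build candidate retained-intron calls
#'
#' One candidate call per intron with at least one supporting fragment
#' (intronic or exon-intron junction). Filter flags start empty; the filter
#' cascade ([apply_cirt_filters()]) sets them and \code{passed} is TRUE iff no
#' flag is set.
#'
#' @param contigs [assemble_contigs()] output.
#' @param assignments [classify_fragments()] output (for junction-only
#'   detection).
#' @param introns [derive_introns()] output (supplies intron intervals).
#' @return data.frame: \code{gene_id}, \code{intron_index}, \code{chrom},
#'   \code{start}, \code{end} (intron interval), \code{n_contigs},
#'   \code{total_intronic_fragments}, \code{n_junction_fragments}, one logical
#'   \code{flag_*} column per filter stage, \code{passed}.
#' @export
build_retained_calls <- function(contigs, assignments, introns) {
  jx <- assignments[assignments$category == "exon_intron_junction", ,
                    drop = FALSE]
  keys <- unique(rbind(contigs[, c("gene_id", "intron_index")],
                       jx[, c("gene_id", "intron_index")]))
  if (nrow(keys) == 0L) {
    n0 <- integer(0); l0 <- logical(0)
    return(data.frame(gene_id = character(0), intron_index = n0,
                      chrom = character(0), start = n0, end = n0,
                      n_contigs = n0, total_intronic_fragments = n0,
                      n_junction_fragments = n0,
                      flag_predicted_gene = l0, flag_polyA_site = l0,
                      flag_ncRNA = l0, flag_antisense = l0,
                      flag_junction_only = l0, passed = l0,
                      stringsAsFactors = FALSE))
  }
  ik <- paste(introns$gene_id, introns$intron_index)
  m <- match(paste(keys$gene_id, keys$intron_index), ik)
  if (anyNA(m)) stop("call references an intron absent from the annotation")
  ck <- paste(contigs$gene_id, contigs$intron_index)
  jk <- paste(jx$gene_id, jx$intron_index)
  kk <- paste(keys$gene_id, keys$intron_index)
  nc <- as.integer(table(factor(ck, levels = kk))[kk])
  nfrag <- vapply(kk, function(k)
    sum(contigs$n_fragments[ck == k]), integer(1L), USE.NAMES = FALSE)
  njx <- as.integer(table(factor(jk, levels = kk))[kk])
  out <- data.frame(gene_id = keys$gene_id,
                    intron_index = keys$intron_index,
                    chrom = introns$chrom[m],
                    start = introns$start[m], end = introns$end[m],
                    n_contigs = nc,
                    total_intronic_fragments = nfrag,
                    n_junction_fragments = njx,
                    flag_predicted_gene = FALSE,
                    flag_polyA_site = FALSE,
                    flag_ncRNA = FALSE,
                    flag_antisense = FALSE,
                    flag_junction_only = FALSE,
                    passed = TRUE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_id, out$intron_index), ]
}

.update_passed <- function(calls) {
  fl <- grep("^flag_", names(calls))
  calls$passed <- rowSums(as.matrix(calls[, fl, drop = FALSE])) == 0L
  calls
}

#' Flag introns overlapping predicted genes
#'
#' Operates at intron level: a single base of overlap between the intron
#' interval and any predicted-gene interval sets the flag (outputs of ab
#' initio gene predictors are consumed as plain intervals).
#'
#' @param calls [build_retained_calls()] output.
#' @param predicted data.frame of predicted-gene intervals (\code{chrom},
#'   \code{start}, \code{end}); NULL skips the stage with a warning.
#' @return updated calls.
#' @export
filter_predicted_genes <- function(calls, predicted) {
  if (is.null(predicted)) {
    warning("no predicted-gene annotation; stage skipped")
    return(calls)
  }
  calls$flag_predicted_gene <- calls$flag_predicted_gene |
    .overlaps_any(calls, predicted)
  .update_passed(calls)
}

#' Flag introns containing a poly(A) site
#'
#' A site is a point coordinate; it falls inside the intron when
#' \code{start <= site < end} (half-open containment).
#'
#' @param calls [build_retained_calls()] output.
#' @param sites data.frame with \code{chrom}, \code{pos} (0-based point
#'   coordinates); NULL skips the stage with a warning.
#' @return updated calls.
#' @export
filter_polya_sites <- function(calls, sites) {
  if (is.null(sites)) {
    warning("no poly(A)-site annotation; stage skipped")
    return(calls)
  }
  hit <- logical(nrow(calls))
  for (ch in intersect(unique(calls$chrom), unique(sites$chrom))) {
    ci <- which(calls$chrom == ch)
    p <- sites$pos[sites$chrom == ch]
    hit[ci] <- hit[ci] | vapply(ci, function(i)
      any(p >= calls$start[i] & p < calls$end[i]), logical(1L))
  }
  calls$flag_polyA_site <- calls$flag_polyA_site | hit
  .update_passed(calls)
}

# contig-level single-base overlap, propagated to the intron call; when the
# annotation has a `class` column the overlapping classes are recorded per
# call (comma-separated) for the class-breakdown report
.flag_by_contig_overlap <- function(calls, contigs, intervals,
                                    class_col = NULL) {
  hit_contig <- .overlaps_any(contigs, intervals)
  hk <- unique(paste(contigs$gene_id[hit_contig],
                     contigs$intron_index[hit_contig]))
  hit <- paste(calls$gene_id, calls$intron_index) %in% hk
  if (!is.null(class_col) && class_col %in% names(intervals)) {
    p <- .overlap_pairs(contigs, intervals)
    cls <- tapply(intervals[[class_col]][p$subject_idx],
                  paste(contigs$gene_id, contigs$intron_index)[p$query_idx],
                  function(x) paste(sort(unique(x)), collapse = ","))
    attr(hit, "classes") <-
      unname(cls[paste(calls$gene_id, calls$intron_index)])
  }
  hit
}

#' Flag calls whose contigs overlap annotated ncRNAs
#'
#' Conservative single-base rule at contig level: any contig of the call
#' sharing at least one base with an ncRNA interval flags the intron.
#'
#' @param calls [build_retained_calls()] output.
#' @param contigs [assemble_contigs()] output.
#' @param ncrna data.frame of ncRNA intervals; an optional \code{class}
#'   column (snRNA, snoRNA, miRNA, ...) is recorded on the flagged calls as
#'   \code{ncRNA_classes} for the class breakdown; NULL skips with a warning.
#' @return updated calls.
#' @export
filter_ncrna <- function(calls, contigs, ncrna) {
  if (is.null(ncrna)) {
    warning("no ncRNA annotation; stage skipped")
    return(calls)
  }
  hit <- .flag_by_contig_overlap(calls, contigs, ncrna, class_col = "class")
  calls$flag_ncRNA <- calls$flag_ncRNA | hit
  if (!is.null(attr(hit, "classes")))
    calls$ncRNA_classes <- attr(hit, "classes")
  .update_passed(calls)
}

#' Breakdown of ncRNA classes embedded in flagged calls
#'
#' Tabulates the annotation classes recorded by [filter_ncrna()] on the
#' ncRNA-flagged calls (which functional RNAs live inside the filtered-out
#' introns).
#'
#' @param calls calls processed by [filter_ncrna()] with a classed
#'   annotation.
#' @return table of class counts over flagged calls.
#' @export
ncrna_class_breakdown <- function(calls) {
  if (is.null(calls$ncRNA_classes))
    stop("calls carry no ncRNA class records; run filter_ncrna with a ",
         "'class' column in the annotation")
  cls <- calls$ncRNA_classes[calls$flag_ncRNA & !is.na(calls$ncRNA_classes)]
  table(unlist(strsplit(cls, ",", fixed = TRUE)))
}

#' Flag calls whose contigs overlap antisense transcripts
#'
#' Partial (single-base) overlap suffices; strand is ignored because the
#' sequencing protocol is not strand specific.
#'
#' @param calls [build_retained_calls()] output.
#' @param contigs [assemble_contigs()] output.
#' @param antisense data.frame of antisense transcript intervals; NULL skips
#'   with a warning.
#' @return updated calls.
#' @export
filter_antisense <- function(calls, contigs, antisense) {
  if (is.null(antisense)) {
    warning("no antisense annotation; stage skipped")
    return(calls)
  }
  calls$flag_antisense <- calls$flag_antisense |
    .flag_by_contig_overlap(calls, contigs, antisense)
  .update_passed(calls)
}

#' Flag introns supported only by exon-intron junction reads
#'
#' Such reads may be unannotated exon extensions rather than retained intronic
#' sequence, so introns whose every supporting fragment straddles a boundary
#' are excluded.
#'
#' @param calls [build_retained_calls()] output.
#' @return updated calls.
#' @export
filter_junction_only <- function(calls) {
  calls$flag_junction_only <- calls$flag_junction_only |
    (calls$n_junction_fragments > 0L & calls$total_intronic_fragments == 0L)
  .update_passed(calls)
}

#' Run the full filter cascade
#'
#' Applies, in order: predicted-gene, poly(A)-site, ncRNA, antisense and
#' junction-only filters. The filters are pure interval predicates, so the
#' order does not affect the result. Annotation stages with NULL input are
#' skipped (with a warning) because those resources are external.
#'
#' @param calls [build_retained_calls()] output.
#' @param contigs [assemble_contigs()] output.
#' @param annotations list with optional elements \code{predicted_genes},
#'   \code{polya_sites}, \code{ncrna}, \code{antisense} (interval/site
#'   data.frames as the individual filters expect).
#' @param quiet suppress skip warnings for absent annotation stages.
#' @return calls with all flags set and \code{passed} updated.
#' @export
apply_cirt_filters <- function(calls, contigs, annotations = list(),
                               quiet = FALSE) {
  run <- function(expr) if (quiet) suppressWarnings(expr) else expr
  calls <- run(filter_predicted_genes(calls, annotations$predicted_genes))
  calls <- run(filter_polya_sites(calls, annotations$polya_sites))
  calls <- run(filter_ncrna(calls, contigs, annotations$ncrna))
  calls <- run(filter_antisense(calls, contigs, annotations$antisense))
  calls <- filter_junction_only(calls)
  calls
}
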