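#' Read an alignment-block table
#'
#' The text-table alignment format used throughout the package: one row per
#' aligned block, tab-separated with a header line, columns \code{fragment_id},
#' \code{chrom}, \code{start}, \code{end} (0-based half-open), \code{unique}
#' (logical / 0-1). A paired-end fragment contributes one row per aligned
#' block of either mate, so the fragment is the counting unit.
#'
#' @param path TSV file.
#' @return data.frame of blocks.
#' @export
read_alignment_blocks <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("fragment_id", "chrom", "start", "end", "unique")
  if (!all(need %in% names(x)))
    stop("alignment table must have columns: ", paste(need, collapse = ", "))
  x$unique <- as.logical(x$unique)
  x
}

#' Read alignment blocks from a BAM file
#'
#' Converts a coordinate-sorted BAM into the package's alignment-block table.
#' Uniqueness defaults to MAPQ >= \code{min_mapq} and no \code{XS}-style
#' multi-hit evidence beyond the primary record. Mates sharing a query name
#' form one fragment.
#'
#' @param path indexed BAM file.
#' @param min_mapq MAPQ threshold for the "uniquely mappable" flag.
#' @return data.frame of blocks as in [read_alignment_blocks()].
#' @export
read_alignment_blocks_bam <- function(path, min_mapq = 10L) {
  if (!requireNamespace("GenomicAlignments", quietly = TRUE) ||
      !requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM input requires the GenomicAlignments and Rsamtools packages")
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "mapq"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE))
  aln <- GenomicAlignments::readGAlignments(path, param = param)
  grl <- GenomicAlignments::grglist(aln)  # spliced blocks per record
  bl <- unlist(grl)
  rec <- rep(seq_along(aln), lengths(grl))
  mq <- S4Vectors::mcols(aln)$mapq
  data.frame(fragment_id = S4Vectors::mcols(aln)$qname[rec],
             chrom = as.character(GenomicRanges::seqnames(bl)),
             start = GenomicRanges::start(bl) - 1L,
             end = GenomicRanges::end(bl),
             unique = (!is.na(mq) & mq >= min_mapq)[rec],
             stringsAsFactors = FALSE)
}

#' Classify uniquely mapped fragments against gene models
#'
#' Each fragment (all blocks of both mates) is assigned one category:
#' \describe{
#'   \item{exonic}{every block contained in the exon union of one gene}
#'   \item{intronic}{every block contained in a single intron of one gene}
#'   \item{exon_intron_junction}{blocks lie within one gene's span and touch
#'     both exonic and intronic sequence, i.e. straddle a boundary}
#'   \item{intergenic}{no overlap with any gene span}
#'   \item{ambiguous}{overlaps gene(s) but no single consistent assignment,
#'     or several genes admit conflicting assignments}
#' }
#' Non-unique fragments are dropped up front; their count is attached as
#' attribute \code{n_nonunique}.
#'
#' @param blocks alignment-block table (see [read_alignment_blocks()]).
#' @param models a [gene_models()] object.
#' @param introns output of [derive_introns()] for the same models (computed
#'   if NULL).
#' @return data.frame with one row per unique fragment: \code{fragment_id},
#'   \code{chrom}, \code{start}, \code{end} (fragment footprint span),
#'   \code{category}, \code{gene_id}, \code{intron_index}.
#' @export
classify_fragments <- function(blocks, models, introns = NULL) {
  if (is.null(introns)) introns <- derive_introns(models)
  n_nonunique <- length(unique(blocks$fragment_id[!blocks$unique]))
  blocks <- blocks[blocks$unique, , drop = FALSE]
  fid <- factor(blocks$fragment_id, levels = unique(blocks$fragment_id))
  nfrag <- nlevels(fid)
  fi <- as.integer(fid)
  nb <- tabulate(fi, nfrag)
  span_start <- as.integer(tapply(blocks$start, fi, min))
  span_end <- as.integer(tapply(blocks$end, fi, max))
  chrom <- as.character(tapply(blocks$chrom, fi, function(x) x[1L]))

  out <- data.frame(fragment_id = levels(fid), chrom = chrom,
                    start = span_start, end = span_end,
                    category = "intergenic", gene_id = NA_character_,
                    intron_index = NA_integer_, stringsAsFactors = FALSE)

  ex <- models$exons
  sp <- models$spans
  genes <- sp$gene_id

  # block-level overlap pairs against exons, introns and spans of each gene
  pe <- .overlap_pairs(blocks, ex)
  pe$gene <- ex$gene_id[pe$subject_idx]
  pe$contained <- blocks$start[pe$query_idx] >= ex$start[pe$subject_idx] &
    blocks$end[pe$query_idx] <= ex$end[pe$subject_idx]
  pin <- if (nrow(introns) > 0L) .overlap_pairs(blocks, introns) else
    data.frame(query_idx = integer(0), subject_idx = integer(0))
  pin$gene <- introns$gene_id[pin$subject_idx]
  pin$intron_index <- introns$intron_index[pin$subject_idx]
  pin$contained <- blocks$start[pin$query_idx] >= introns$start[pin$subject_idx] &
    blocks$end[pin$query_idx] <= introns$end[pin$subject_idx]
  ps <- .overlap_pairs(blocks, sp)
  ps$gene <- sp$gene_id[ps$subject_idx]
  ps$contained <- blocks$start[ps$query_idx] >= sp$start[ps$subject_idx] &
    blocks$end[ps$query_idx] <= sp$end[ps$subject_idx]

  # per (fragment, gene) tallies keyed on integer codes
  gk <- function(f, g) (as.numeric(match(g, genes)) - 1) * nfrag + f
  key_e <- gk(fi[pe$query_idx], pe$gene)
  key_i <- gk(fi[pin$query_idx], pin$gene)
  key_s <- gk(fi[ps$query_idx], ps$gene)
  cand_keys <- sort(unique(c(key_e, key_i, key_s)))
  if (length(cand_keys) > 0L) {
    cand_f <- as.integer((cand_keys - 1) %% nfrag) + 1L
    cand_g <- as.integer((cand_keys - 1) %/% nfrag) + 1L
    tally <- function(keys, w) {
      if (length(keys) == 0L) return(integer(length(cand_keys)))
      t <- rowsum(as.integer(w), keys)
      v <- integer(length(cand_keys))
      m <- match(as.numeric(rownames(t)), cand_keys)
      v[m] <- t[, 1L]
      v
    }
    # distinct blocks contained in exons of the gene (an exon union is
    # disjoint, so each block is contained in at most one exon)
    ne_cont <- tally(key_e, pe$contained)
    ov_exon <- tally(key_e, rep(1L, length(key_e))) > 0L
    ov_intron <- tally(key_i, rep(1L, length(key_i))) > 0L
    ns_cont <- tally(key_s, ps$contained)

    # intronic: some single intron contains all blocks of the fragment
    intr_ok <- rep(NA_integer_, length(cand_keys))
    if (nrow(pin) > 0L) {
      key_ii <- paste(gk(fi[pin$query_idx], pin$gene), pin$intron_index)
      cont_by_intron <- rowsum(as.integer(pin$contained), key_ii)
      parts <- strsplit(rownames(cont_by_intron), " ", fixed = TRUE)
      ii_key <- as.numeric(vapply(parts, `[`, "", 1L))
      ii_idx <- as.integer(vapply(parts, `[`, "", 2L))
      full <- cont_by_intron[, 1L] == nb[as.integer((ii_key - 1) %% nfrag) + 1L]
      m <- match(ii_key[full], cand_keys)
      intr_ok[m] <- ii_idx[full]
      # junction intron index: the intron with most overlapping blocks
      ov_by_intron <- rowsum(rep(1L, nrow(pin)), key_ii)
      o <- order(-ov_by_intron[, 1L], ii_idx)
      junc_idx <- rep(NA_integer_, length(cand_keys))
      first <- !duplicated(ii_key[o])
      m2 <- match(ii_key[o][first], cand_keys)
      junc_idx[m2] <- ii_idx[o][first]
    } else junc_idx <- rep(NA_integer_, length(cand_keys))

    nb_c <- nb[cand_f]
    cat_cand <- ifelse(ne_cont == nb_c, "exonic",
                ifelse(!is.na(intr_ok), "intronic",
                ifelse(ns_cont == nb_c & ov_exon & ov_intron,
                       "exon_intron_junction", "inconsistent")))

    # resolve per fragment
    consistent <- cat_cand != "inconsistent"
    n_consistent <- tabulate(cand_f[consistent], nfrag)
    has_cand <- tabulate(cand_f, nfrag) > 0L
    pick <- which(consistent)[!duplicated(cand_f[consistent])]
    one <- pick[n_consistent[cand_f[pick]] == 1L]
    out$category[has_cand] <- "ambiguous"
    out$category[cand_f[one]] <- cat_cand[one]
    out$gene_id[cand_f[one]] <- genes[cand_g[one]]
    ii <- ifelse(cat_cand[one] == "intronic", intr_ok[one],
          ifelse(cat_cand[one] == "exon_intron_junction", junc_idx[one],
                 NA_integer_))
    out$intron_index[cand_f[one]] <- ii
  }
  unknown <- !(out$chrom %in% sp$chrom) & out$category == "intergenic"
  if (any(unknown))
    warning(sum(unknown),
            " fragment(s) on chromosomes absent from the annotation",
            " classified intergenic")
  attr(out, "n_nonunique") <- n_nonunique
  out
}

#' Windowed read-density profile over a feature
#'
#' Tiles the feature with fixed windows (the last window may be shorter; a
#' feature shorter than one window is a single window) and counts the
#' fragments overlapping each window.
#'
#' @param starts,ends fragment footprint spans (0-based half-open) already
#'   assigned to the feature.
#' @param feature_start,feature_end feature interval.
#' @param window window size in nt (default 50).
#' @return list with \code{counts} (per window), \code{windows} (data.frame of
#'   window intervals), \code{median_density}, \code{max_density}.
#' @export
density_profile <- function(starts, ends, feature_start, feature_end,
                            window = 50L) {
  stopifnot(feature_end > feature_start)
  ws <- seq.int(feature_start, feature_end - 1L, by = window)
  we <- pmin(ws + window, feature_end)
  counts <- vapply(seq_along(ws), function(i)
    sum(starts < we[i] & ends > ws[i]), integer(1L))
  list(counts = counts,
       windows = data.frame(start = ws, end = we),
       median_density = stats::median(counts),
       max_density = max(counts))
}

#' Intronic vs intergenic enrichment test
#'
#' One-sided test of H1: the per-base fragment rate in intronic space exceeds
#' the rate in intergenic space. Conditional on the total fragment count, the
#' intronic count is Binomial with success probability given by the intronic
#' share of sequence under H0; the exact tail is summed directly for totals up
#' to \code{exact_max}, above which a pooled two-proportion z approximation is
#' used.
#'
#' @param intronic_reads,intronic_nt fragment count and sequence length of the
#'   intronic space.
#' @param intergenic_reads,intergenic_nt same for the intergenic space.
#' @param exact_max largest total read count for the exact path.
#' @return list: \code{p_value}, \code{method}, \code{rate_intronic},
#'   \code{rate_intergenic} (per-base rates).
#' @export
enrichment_test <- function(intronic_reads, intronic_nt,
                            intergenic_reads, intergenic_nt,
                            exact_max = 10000L) {
  stopifnot(intronic_nt > 0, intergenic_nt > 0,
            intronic_reads >= 0, intergenic_reads >= 0)
  x1 <- intronic_reads; x2 <- intergenic_reads
  n <- x1 + x2
  r1 <- x1 / intronic_nt; r2 <- x2 / intergenic_nt
  if (n == 0)
    return(list(p_value = 1, method = "degenerate",
                rate_intronic = 0, rate_intergenic = 0))
  if (n <= exact_max) {
    p0 <- intronic_nt / (intronic_nt + intergenic_nt)
    p <- sum(stats::dbinom(seq.int(x1, n), n, p0))
    method <- "exact conditional binomial"
  } else {
    pp <- n / (intronic_nt + intergenic_nt)
    se <- sqrt(pp * (1 - pp) * (1 / intronic_nt + 1 / intergenic_nt))
    z <- (r1 - r2) / se
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "two-proportion z"
  }
  list(p_value = min(1, p), method = method,
       rate_intronic = r1, rate_intergenic = r2)
}

#' Intergenic space complement of padded gene spans
#'
#' The intergenic space used for enrichment statistics is the complement of
#' all gene spans padded by \code{pad} nt on each side (to keep unannotated
#' UTR sequence out of the intergenic denominator).
#'
#' @param models a [gene_models()] object.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param pad padding in nt (default 1000).
#' @return data.frame of intergenic intervals (\code{chrom}, \code{start},
#'   \code{end}).
#' @export
intergenic_space <- function(models, chrom_lengths, pad = 1000L) {
  sp <- models$spans
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    g <- sp[sp$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L)
      return(data.frame(chrom = ch, start = 0L, end = as.integer(len)))
    m <- .gap_merge(pmax(0L, g$start - pad), pmin(len, g$end + pad), gap = 0L)
    s <- c(0L, m$end); e <- c(m$start, as.integer(len))
    keep <- e > s
    data.frame(chrom = ch, start = s[keep], end = e[keep])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
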