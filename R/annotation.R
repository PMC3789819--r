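#' Gene model container
#'
#' Builds a \code{gene_models} object from a table of exons. All coordinates
#' in this package are 0-based half-open genomic intervals; converters from
#' GTF (1-based inclusive) live in [read_gene_models()].
#'
#' @param exons data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand} (\code{"+"} or \code{"-"}), \code{start}, \code{end}
#'   (0-based half-open). Exons of one gene must be non-overlapping; they are
#'   sorted and unioned on construction.
#' @return An object of class \code{gene_models}: a list with element
#'   \code{exons} (normalized exon table) and \code{spans} (one row per gene:
#'   \code{gene_id}, \code{chrom}, \code{strand}, \code{start}, \code{end},
#'   \code{n_exons}).
#' @export
gene_models <- function(exons) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(exons)))
    stop("exons must have columns: ", paste(need, collapse = ", "))
  if (nrow(exons) == 0L) stop("no exons supplied")
  if (!all(exons$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(exons$end <= exons$start))
    stop("exon end must exceed start (0-based half-open)")
  exons <- exons[order(exons$gene_id, exons$start), need, drop = FALSE]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  # union touching/overlapping exons within a gene so invariants hold
  parts <- split(seq_len(nrow(exons)), exons$gene_id)
  merged <- lapply(parts, function(idx) {
    m <- .gap_merge(exons$start[idx], exons$end[idx], gap = 0L)
    data.frame(gene_id = exons$gene_id[idx[1L]],
               chrom = exons$chrom[idx[1L]],
               strand = exons$strand[idx[1L]],
               start = m$start, end = m$end,
               stringsAsFactors = FALSE)
  })
  exons <- do.call(rbind, merged)
  rownames(exons) <- NULL
  spans <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e)
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               strand = e$strand[1L], start = min(e$start), end = max(e$end),
               n_exons = nrow(e), stringsAsFactors = FALSE)))
  rownames(spans) <- NULL
  structure(list(exons = exons, spans = spans), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$spans), "genes,", nrow(x$exons), "exons on",
      length(unique(x$spans$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read gene models from BED12 or GTF
#'
#' One model per transcript by default; \code{collapse = TRUE} unions the
#' exons of all transcripts sharing a \code{gene_id} into one model.
#' GTF exon records (1-based inclusive) are converted to the internal 0-based
#' half-open convention at this boundary.
#'
#' @param path BED12 or GTF file.
#' @param format \code{"auto"} (by extension), \code{"bed12"} or \code{"gtf"}.
#' @param collapse union transcripts of a gene into a single model.
#' @param genome optional [read_genome()] result; models on chromosomes absent
#'   from it are skipped with a warning (or an error when \code{strict}).
#' @param strict error instead of warn-and-skip on unknown chromosomes.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path, format = c("auto", "bed12", "gtf"),
                             collapse = FALSE, genome = NULL,
                             strict = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff2?)$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  }
  if (format == "bed12") {
    gr <- rtracklayer::import(path, format = "bed")
    bl <- rtracklayer::blocks(gr)  # absolute 1-based exon ranges
    ex <- as.data.frame(unlist(bl))
    ex$gene_id <- rep(gr$name, lengths(bl))
    exons <- data.frame(gene_id = ex$gene_id,
                        chrom = as.character(ex$seqnames),
                        strand = as.character(ex$strand),
                        start = ex$start - 1L, end = ex$end,
                        stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L) stop("no exon records in ", path)
    id <- if (!is.null(gr$transcript_id)) gr$transcript_id else gr$gene_id
    if (is.null(id)) stop("GTF exons carry neither transcript_id nor gene_id")
    exons <- data.frame(gene_id = id,
                        chrom = as.character(GenomicRanges::seqnames(gr)),
                        strand = as.character(GenomicRanges::strand(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr),
                        stringsAsFactors = FALSE)
    if (collapse && !is.null(gr$gene_id)) exons$gene_id <- gr$gene_id
  }
  if (collapse && format == "bed12")
    warning("collapse for BED12 unions models sharing a name")
  if (!is.null(genome)) {
    bad <- !(exons$chrom %in% names(genome))
    if (any(bad)) {
      msg <- paste("models on unknown chromosome(s):",
                   paste(unique(exons$chrom[bad]), collapse = ", "))
      if (strict) stop(msg)
      warning(msg, "; skipped")
      exons <- exons[!bad, , drop = FALSE]
    }
  }
  gene_models(exons)
}

#' Write gene models as BED12
#'
#' @param models a [gene_models()] object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_gene_models_bed12 <- function(models, path) {
  ex <- models$exons
  gr <- GenomicRanges::GRanges(ex$chrom,
                               IRanges::IRanges(ex$start + 1L, ex$end),
                               strand = ex$strand)
  grl <- GenomicRanges::split(gr, ex$gene_id)
  bed <- rtracklayer::asBED(grl)
  rtracklayer::export(bed, path, format = "bed")
  invisible(path)
}

#' Derive introns from gene models
#'
#' Introns are the gaps between consecutive exons. \code{intron_index} counts
#' 5' to 3' in transcription order, so for a minus-strand gene index 1 is the
#' rightmost gap in genome coordinates.
#'
#' @param models a [gene_models()] object.
#' @return data.frame: \code{gene_id}, \code{chrom}, \code{strand},
#'   \code{intron_index}, \code{start}, \code{end}, \code{length},
#'   \code{n_introns} (per gene).
#' @export
derive_introns <- function(models) {
  ex <- models$exons
  out <- lapply(split(ex, ex$gene_id), function(e) {
    if (nrow(e) < 2L) return(NULL)
    s <- e$end[-nrow(e)]
    en <- e$start[-1L]
    k <- length(s)
    idx <- if (e$strand[1L] == "+") seq_len(k) else rev(seq_len(k))
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               strand = e$strand[1L], intron_index = idx,
               start = s, end = en, length = en - s, n_introns = k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), intron_index = integer(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), n_introns = integer(0)))
  rownames(out) <- NULL
  out[order(out$gene_id, out$intron_index), ]
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A named \code{DNAStringSet}; names are truncated at the first
#'   whitespace so they match annotation chromosome names.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Per-intron sequence features
#'
#' Computes GC fraction (Ns excluded from numerator and denominator) and the
#' longest internal poly(A) tract on the transcribed strand: A-runs on the
#' reference for plus-strand genes, T-runs for minus-strand genes. Runs
#' shorter than \code{min_pa_len} are reported as 0 ("no tract"), matching the
#' convention used for background matching.
#'
#' @param introns output of [derive_introns()].
#' @param genome a named \code{DNAStringSet} (see [read_genome()]).
#' @param min_pa_len minimum tract length to count (default 10 nt).
#' @return \code{introns} with added columns \code{gc_fraction} (NA when the
#'   sequence is all N) and \code{max_pa_tract}.
#' @export
intron_features <- function(introns, genome, min_pa_len = 10L) {
  if (nrow(introns) == 0L) {
    introns$gc_fraction <- numeric(0)
    introns$max_pa_tract <- integer(0)
    return(introns)
  }
  missing_chrom <- setdiff(unique(introns$chrom), names(genome))
  if (length(missing_chrom) > 0L)
    stop("chromosome(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "))
  seqs <- as.character(Biostrings::subseq(
    genome[introns$chrom], start = introns$start + 1L, end = introns$end))
  counts <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                        c("G", "C", "A", "T"))
  acgt <- rowSums(counts)
  gc <- ifelse(acgt > 0, (counts[, "G"] + counts[, "C"]) / acgt, NA_real_)
  # sense-strand A-run: A on reference for '+', T on reference for '-'
  base <- ifelse(introns$strand == "+", "A", "T")
  run <- mapply(.max_run, seqs, base, USE.NAMES = FALSE)
  introns$gc_fraction <- gc
  introns$max_pa_tract <- ifelse(run >= min_pa_len, run, 0L)
  introns
}

#' Read an annotation BED as an interval table
#'
#' Generic reader for the interval annotations consumed by the filter cascade
#' and overlap reports (predicted genes, ncRNAs, antisense transcripts,
#' repeats, ESTs). The BED name field, when present, is kept as \code{class}
#' so the ncRNA breakdown can use it.
#'
#' @param path BED file (3+ columns).
#' @return data.frame: \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open) and optionally \code{class}.
#' @export
read_bed_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$class <- gr$name
  out
}

#' Write introns as BED6
#'
#' Names follow \code{gene_id|i<index>}.
#'
#' @param introns output of [derive_introns()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_introns_bed <- function(introns, path) {
  bed <- data.frame(introns$chrom, introns$start, introns$end,
                    paste0(introns$gene_id, "|i", introns$intron_index),
                    0L, introns$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
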