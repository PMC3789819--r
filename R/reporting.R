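#' Per-gene CIRT summary
#'
#' Classifies every gene with read evidence into \code{exonic_only} (exonic
#' reads, no passed retained-intron call), \code{exonic_and_intronic} (both),
#' or \code{intron_only} (passed call(s), zero exonic reads). "Total genes"
#' means genes with at least one uniquely mapped fragment of any gene-assigned
#' category.
#'
#' @param assignments [classify_fragments()] output.
#' @param calls filtered calls ([apply_cirt_filters()] output); only
#'   \code{passed} rows count as retention.
#' @param introns [derive_introns()] output (per-gene intron totals).
#' @param models optional [gene_models()] object; when supplied, a per-gene
#'   \code{intron_exon_density_ratio} column is added (intronic fragments per
#'   intronic nt over exonic fragments per exonic nt; NA when either side has
#'   no fragments).
#' @return data.frame: \code{gene_id}, \code{category},
#'   \code{n_retained_introns}, \code{n_introns}, \code{n_exonic_fragments},
#'   \code{n_intronic_fragments}, \code{max_intron_fragments}, and optionally
#'   \code{intron_exon_density_ratio}.
#' @export
summarize_genes <- function(assignments, calls, introns, models = NULL) {
  a <- assignments[!is.na(assignments$gene_id), , drop = FALSE]
  genes <- sort(unique(a$gene_id))
  nex <- table(factor(a$gene_id[a$category == "exonic"], levels = genes))
  nin <- table(factor(a$gene_id[a$category == "intronic"], levels = genes))
  p <- calls[calls$passed, , drop = FALSE]
  nret <- table(factor(p$gene_id, levels = genes))
  maxfrag <- rep(0L, length(genes))
  if (nrow(p) > 0L) {
    mx <- tapply(p$total_intronic_fragments, p$gene_id, max)
    maxfrag[match(names(mx), genes)] <- as.integer(mx)
  }
  nint <- tapply(introns$n_introns, introns$gene_id, function(x) x[1L])
  category <- ifelse(nret > 0L & nex > 0L, "exonic_and_intronic",
              ifelse(nret > 0L, "intron_only",
              ifelse(nex > 0L, "exonic_only", "none")))
  out <- data.frame(gene_id = genes, category = as.character(category),
                    n_retained_introns = as.integer(nret),
                    n_introns = as.integer(nint[genes]),
                    n_exonic_fragments = as.integer(nex),
                    n_intronic_fragments = as.integer(nin),
                    max_intron_fragments = maxfrag,
                    stringsAsFactors = FALSE)
  out$n_introns[is.na(out$n_introns)] <- 0L
  if (!is.null(models)) {
    ex_nt <- tapply(models$exons$end - models$exons$start,
                    models$exons$gene_id, sum)
    in_nt <- tapply(introns$length, introns$gene_id, sum)
    ed <- out$n_exonic_fragments / as.numeric(ex_nt[out$gene_id])
    id <- out$n_intronic_fragments / as.numeric(in_nt[out$gene_id])
    out$intron_exon_density_ratio <- ifelse(
      !is.na(ed) & !is.na(id) & ed > 0, id / ed, NA_real_)
  }
  rownames(out) <- NULL
  out
}

.call_keys <- function(calls) {
  p <- calls[calls$passed, , drop = FALSE]
  list(genes = unique(p$gene_id),
       introns = unique(paste(p$gene_id, p$intron_index)))
}

#' Overlap of CIRT calls between two samples
#'
#' Gene overlap is the shared-gene count divided by the smaller per-sample
#' gene set (min denominator; the Jaccard variant is also reported). Intron
#' overlap is computed over shared genes only, as matching (gene, intron)
#' pairs over the smaller of the two restricted sets.
#'
#' @param calls_a,calls_b filtered call tables of the two samples.
#' @return list: \code{gene_overlap}, \code{gene_jaccard},
#'   \code{intron_overlap}, \code{intron_jaccard}, plus the underlying counts.
#' @export
replicate_overlap <- function(calls_a, calls_b) {
  a <- .call_keys(calls_a); b <- .call_keys(calls_b)
  if (length(a$genes) == 0L || length(b$genes) == 0L) {
    warning("a sample has no passed calls; overlap reported as 0")
    return(list(gene_overlap = 0, gene_jaccard = 0,
                intron_overlap = 0, intron_jaccard = 0,
                n_shared_genes = 0L, n_shared_introns = 0L))
  }
  shared_genes <- intersect(a$genes, b$genes)
  gmin <- min(length(a$genes), length(b$genes))
  guni <- length(union(a$genes, b$genes))
  restrict <- function(keys) keys[sub(" .*$", "", keys) %in% shared_genes]
  ia <- restrict(a$introns); ib <- restrict(b$introns)
  shared_introns <- intersect(ia, ib)
  imin <- min(length(ia), length(ib))
  list(gene_overlap = length(shared_genes) / gmin,
       gene_jaccard = length(shared_genes) / guni,
       intron_overlap = if (imin > 0L)
         length(shared_introns) / imin else 0,
       intron_jaccard = if (length(union(ia, ib)) > 0L)
         length(shared_introns) / length(union(ia, ib)) else 0,
       n_shared_genes = length(shared_genes),
       n_shared_introns = length(shared_introns))
}

#' Introns retained in every sample
#'
#' The most confident retention set: (gene, intron) pairs passing the filter
#' cascade in all supplied samples.
#'
#' @param call_list list (length >= 2) of filtered call tables.
#' @return data.frame: \code{gene_id}, \code{intron_index}, one row per
#'   shared pair.
#' @export
shared_intron_set <- function(call_list) {
  stopifnot(length(call_list) >= 2L)
  keys <- lapply(call_list, function(x) .call_keys(x)$introns)
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0L)
    return(data.frame(gene_id = character(0), intron_index = integer(0)))
  parts <- strsplit(shared, " ", fixed = TRUE)
  out <- data.frame(gene_id = vapply(parts, `[`, "", 1L),
                    intron_index = as.integer(vapply(parts, `[`, "", 2L)),
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$intron_index), ]
}

#' Fragment-count threshold sweep over CIRT genes
#'
#' For each cutoff, the fraction of CIRT genes (genes with any passed call)
#' having at least that many fragments in at least one retained intron.
#' Optionally reports the gene list at the highest cutoff and, when per-gene
#' intron/exon density ratios are supplied, their median ratio — the class
#' used for downstream functional (GO) export.
#'
#' @param calls filtered call table.
#' @param cutoffs integer fragment cutoffs (default \code{c(1, 32, 256)}).
#' @param density_ratio optional named vector of per-gene intron/exon density
#'   ratios.
#' @return list: \code{fractions} (named by cutoff, monotone non-increasing),
#'   \code{n_cirt_genes}, \code{top_genes} (gene list at the highest cutoff),
#'   \code{top_median_density_ratio} (NA unless ratios supplied).
#' @export
threshold_sweep <- function(calls, cutoffs = c(1L, 32L, 256L),
                            density_ratio = NULL) {
  p <- calls[calls$passed, , drop = FALSE]
  if (nrow(p) == 0L)
    return(list(fractions = stats::setNames(rep(0, length(cutoffs)),
                                            cutoffs),
                n_cirt_genes = 0L, top_genes = character(0),
                top_median_density_ratio = NA_real_))
  gmax <- tapply(p$total_intronic_fragments, p$gene_id, max)
  fr <- vapply(cutoffs, function(ct) mean(gmax >= ct), numeric(1L))
  top <- names(gmax)[gmax >= max(cutoffs)]
  list(fractions = stats::setNames(fr, cutoffs),
       n_cirt_genes = length(gmax),
       top_genes = top,
       top_median_density_ratio = if (is.null(density_ratio)) NA_real_
       else stats::median(density_ratio[top], na.rm = TRUE))
}

#' Correlation between exonic and intronic read density
#'
#' Pearson by default (the working hypothesis is that retention evidence is
#' not a simple function of expression); Spearman available.
#'
#' @param exon_density,intron_density per-gene densities, equal length.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return list: \code{r}, \code{p_value}, \code{n}; \code{r} is NA with a
#'   warning for n < 3 or zero-variance input.
#' @export
density_correlation <- function(exon_density, intron_density,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(exon_density, intron_density)
  x <- exon_density[ok]; y <- intron_density[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined (n < 3 or constant input)")
    return(list(r = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Frequency of retention along normalized intron position
#'
#' Retained introns are placed at normalized position
#' \code{(intron_index - 0.5) / n_introns} (a single-intron gene falls at 0.5
#' by this convention), histogrammed into equal bins, with a chi-square test
#' against uniformity.
#'
#' @param calls filtered call table.
#' @param introns [derive_introns()] output.
#' @param n_bins histogram bins (default 10).
#' @return list: \code{positions}, \code{counts} (per bin),
#'   \code{breaks}, \code{chisq_p}.
#' @export
intron_position_frequency <- function(calls, introns, n_bins = 10L) {
  p <- calls[calls$passed, , drop = FALSE]
  nint <- tapply(introns$n_introns, introns$gene_id, function(x) x[1L])
  pos <- (p$intron_index - 0.5) / as.numeric(nint[p$gene_id])
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  counts <- as.integer(table(cut(pos, breaks, include.lowest = TRUE)))
  chisq_p <- if (sum(counts) > 0L)
    suppressWarnings(stats::chisq.test(counts)$p.value) else NA_real_
  list(positions = pos, counts = counts, breaks = breaks, chisq_p = chisq_p)
}

#' Classify contig/EST overlaps
#'
#' Each contig is assigned to at most one class with precedence
#' contained-in-EST > EST-contained-in-contig (proper) > partial overlap;
#' contigs touching no EST are uncounted.
#'
#' @param contigs [assemble_contigs()] output.
#' @param ests data.frame of EST alignment intervals (\code{chrom},
#'   \code{start}, \code{end}).
#' @return list of counts: \code{contig_within_est}, \code{est_within_contig},
#'   \code{partial}, \code{no_overlap}, \code{n_contigs}.
#' @export
est_overlap <- function(contigs, ests) {
  n <- nrow(contigs)
  cls <- rep("no_overlap", n)
  p <- .overlap_pairs(contigs, ests)
  if (nrow(p) > 0L) {
    cs <- contigs$start[p$query_idx]; ce <- contigs$end[p$query_idx]
    es <- ests$start[p$subject_idx]; ee <- ests$end[p$subject_idx]
    contained <- cs >= es & ce <= ee
    containing <- es >= cs & ee <= ce & (es > cs | ee < ce)
    for (i in unique(p$query_idx)) {
      rows <- p$query_idx == i
      cls[i] <- if (any(contained[rows])) "contig_within_est"
      else if (any(containing[rows])) "est_within_contig"
      else "partial"
    }
  }
  list(contig_within_est = sum(cls == "contig_within_est"),
       est_within_contig = sum(cls == "est_within_contig"),
       partial = sum(cls == "partial"),
       no_overlap = sum(cls == "no_overlap"),
       n_contigs = n)
}
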