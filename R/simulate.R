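#' Simulation configuration
#'
#' Defaults emulate the structure of subcellular neuronal RNA-seq: genes with
#' a handful of exons, intron lengths lognormal with median ~1300 nt, retained
#' segments of ~360 nt (sd 60) planted in one intron of a minority of genes,
#' ~47% of retained introns carrying an internal pA tract of >= 10 nt, ~30% of
#' retained segments abutting an exon boundary (emitting exon-intron junction
#' reads), optional full-intron hnRNA contamination (whole-cell modes) and
#' uniform intergenic noise. Decoy genes carry the same retained-read signal
#' plus an overlapping annotation interval of one decoy class each, so the
#' filter cascade is exercised with known truth.
#'
#' @param seed RNG seed (mandatory; the whole simulation is deterministic
#'   given it).
#' @param n_genes number of genes.
#' @param cirt_gene_fraction fraction of genes with a clean planted retained
#'   intron.
#' @param introns_per_gene_range inclusive range of intron counts per gene.
#' @param exon_length_range inclusive range of exon lengths (nt).
#' @param intron_meanlog,intron_sdlog lognormal intron-length parameters
#'   (defaults give median ~1300 nt).
#' @param min_intron minimum intron length (nt).
#' @param segment_mean,segment_sd retained-segment length distribution
#'   (Normal, truncated above \code{read_length}).
#' @param read_length aligned block length per mate (nt).
#' @param exonic_depth,intronic_depth fold coverage of exon unions and of
#'   retained segments.
#' @param hnrna_rate fold coverage of full introns of every expressed gene
#'   (0 = dendrite mode; > 0 emulates nuclear contamination in soma/tissue).
#' @param noise_rate fold coverage of intergenic space.
#' @param pa_fraction fraction of introns given a planted internal pA tract
#'   (length 10-14 nt on the sense strand).
#' @param junction_end_fraction fraction of retained segments abutting an
#'   exon boundary, with junction reads emitted.
#' @param decoys_per_class clean-signal genes per decoy annotation class
#'   (ncRNA, poly(A) site, predicted gene, antisense).
#' @param n_planted_junctions intron-internal splice junctions planted in
#'   retained introns (plus fixed quality-failing negatives).
#' @param nonunique_fraction fraction of exonic fragments emitted with
#'   \code{unique = FALSE}.
#' @param bias_3prime 3' positional bias of the retained-intron choice, to
#'   probe poly(A)-primed amplification artifacts: 0 (default) picks the
#'   retained intron uniformly; larger values weight intron k of n by
#'   \code{1 + bias_3prime * (k - 1) / (n - 1)} in transcription order.
#' @param gc_mean,gc_sd per-intron GC content distribution (clipped to
#'   \code{[0.25, 0.65]}).
#' @param n_chroms chromosomes the genes are laid out on.
#' @return object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(seed,
                       n_genes = 200L,
                       cirt_gene_fraction = 0.30,
                       introns_per_gene_range = c(2L, 10L),
                       exon_length_range = c(120L, 300L),
                       intron_meanlog = log(1300),
                       intron_sdlog = 0.5,
                       min_intron = 300L,
                       segment_mean = 360,
                       segment_sd = 60,
                       read_length = 100L,
                       exonic_depth = 20,
                       intronic_depth = 20,
                       hnrna_rate = 0,
                       noise_rate = 0.02,
                       pa_fraction = 0.47,
                       junction_end_fraction = 0.30,
                       decoys_per_class = 2L,
                       n_planted_junctions = 5L,
                       nonunique_fraction = 0.02,
                       bias_3prime = 0,
                       gc_mean = 0.45,
                       gc_sd = 0.07,
                       n_chroms = 4L) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 1, cfg$cirt_gene_fraction >= 0,
            cfg$cirt_gene_fraction <= 1, cfg$exonic_depth >= 0,
            cfg$intronic_depth >= 0, cfg$hnrna_rate >= 0,
            cfg$noise_rate >= 0, cfg$pa_fraction >= 0, cfg$pa_fraction <= 1,
            cfg$junction_end_fraction >= 0, cfg$junction_end_fraction <= 1,
            cfg$nonunique_fraction >= 0, cfg$nonunique_fraction <= 1,
            cfg$bias_3prime >= 0)
  structure(cfg, class = "sim_config")
}

.rand_seq <- function(n, gc = 0.45) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)  # A C G T
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE,
                                             prob = p)])
}

# map an interval on the concatenated exon union (left-to-right genomic
# order) back to genomic blocks; returns a 2-column (start, end) matrix
.map_to_genome <- function(ts, te, ex_start, ex_end) {
  w <- ex_end - ex_start
  off <- c(0L, cumsum(w)[-length(w)])
  hit <- which(ts < off + w & te > off)
  cbind(ex_start[hit] + pmax(0L, ts - off[hit]),
        ex_start[hit] + pmin(w[hit], te - off[hit]))
}

# vectorized paired-end blocks over unspliced regions: fragment i spans
# [s_i, s_i + span_i) with two read_length mates, merged into one block when
# the mates overlap; returns parallel vectors with `frag` indexing into s
.pe_blocks <- function(s, span, read_length) {
  single <- span <= 2L * read_length
  i1 <- which(single); i2 <- which(!single)
  list(start = c(s[i1], s[i2], s[i2] + span[i2] - read_length),
       end = c(s[i1] + span[i1], s[i2] + read_length, s[i2] + span[i2]),
       frag = c(i1, i2, i2))
}

#' Generate a synthetic CIRT experiment
#'
#' Builds a genome, gene models, aligned fragments, decoy annotations, a
#' de-novo junction table and a machine-readable truth table, all
#' deterministically from \code{config$seed}. Reads are emitted as aligned
#' blocks (the pipeline's contract starts at alignments; no sequencing-error
#' or aligner model).
#'
#' @param config a [sim_config()] object.
#' @return list: \code{genome} (DNAStringSet), \code{models}
#'   ([gene_models()]), \code{introns} (with sequence features),
#'   \code{blocks} (alignment-block table), \code{annotations} (decoy
#'   interval/site tables for the filter cascade), \code{junction_table},
#'   \code{truth} (list: \code{genes}, \code{retained}, \code{junctions}),
#'   \code{chrom_lengths}, \code{config}.
#' @export
simulate_cirt_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config
  R <- cf$read_length

  n_cirt <- round(cf$n_genes * cf$cirt_gene_fraction)
  decoy_classes <- c("decoy_ncrna", "decoy_polya", "decoy_predicted",
                     "decoy_antisense")
  n_decoy <- min(cf$decoys_per_class * length(decoy_classes),
                 max(0L, cf$n_genes - n_cirt))
  role <- rep("background", cf$n_genes)
  if (n_cirt > 0L) role[seq_len(n_cirt)] <- "cirt"
  if (n_decoy > 0L)
    role[n_cirt + seq_len(n_decoy)] <-
      rep(decoy_classes, length.out = n_decoy)
  role <- sample(role)  # shuffle placement along the genome
  gene_ids <- sprintf("gene%03d", seq_len(cf$n_genes))

  # --- gene structures -----------------------------------------------------
  seg_draw <- function() {
    repeat {
      L <- round(stats::rnorm(1L, cf$segment_mean, cf$segment_sd))
      if (L > R) return(as.integer(L))
    }
  }
  planted <- role %in% c("cirt", decoy_classes)
  structures <- vector("list", cf$n_genes)
  for (g in seq_len(cf$n_genes)) {
    ni <- sample(seq.int(cf$introns_per_gene_range[1L],
                         cf$introns_per_gene_range[2L]), 1L)
    ex_len <- sample(seq.int(cf$exon_length_range[1L],
                             cf$exon_length_range[2L]), ni + 1L,
                     replace = TRUE)
    in_len <- pmax(cf$min_intron,
                   as.integer(round(stats::rlnorm(ni, cf$intron_meanlog,
                                                  cf$intron_sdlog))))
    strand <- sample(c("+", "-"), 1L)
    seg <- NA_integer_; seg_intron <- NA_integer_
    if (planted[g]) {
      seg <- seg_draw()
      if (cf$bias_3prime > 0 && ni > 1L) {
        # transcription-order index of each genomic gap
        tx_idx <- if (strand == "+") seq_len(ni) else rev(seq_len(ni))
        w <- 1 + cf$bias_3prime * (tx_idx - 1) / (ni - 1)
        seg_intron <- sample.int(ni, 1L, prob = w)
      } else {
        seg_intron <- sample.int(ni, 1L)
      }
      tries <- 0L
      while (in_len[seg_intron] < seg + 20L && tries < 50L) {
        seg <- seg_draw(); tries <- tries + 1L
      }
      if (in_len[seg_intron] < seg + 20L)
        in_len[seg_intron] <- seg + 20L  # widen the intron as a last resort
    }
    structures[[g]] <- list(n_introns = ni, ex_len = ex_len, in_len = in_len,
                            seg_len = seg, seg_intron = seg_intron,
                            strand = strand)
  }

  # --- genome layout -------------------------------------------------------
  chrom_of <- rep(seq_len(cf$n_chroms), length.out = cf$n_genes)
  chroms <- sprintf("chr%d", seq_len(cf$n_chroms))
  cursor <- stats::setNames(rep(0L, cf$n_chroms), chroms)
  exons <- vector("list", cf$n_genes)
  seq_parts <- stats::setNames(vector("list", cf$n_chroms), chroms)
  retained <- list()
  gc_of_intron <- list()
  for (g in seq_len(cf$n_genes)) {
    st <- structures[[g]]
    ch <- chroms[chrom_of[g]]
    gap <- as.integer(round(stats::runif(1L, 2000, 6000)))
    seq_parts[[ch]] <- c(seq_parts[[ch]], .rand_seq(gap, cf$gc_mean))
    pos <- cursor[ch] + gap
    ex_start <- integer(0); ex_end <- integer(0)
    intron_iv <- matrix(0L, nrow = st$n_introns, ncol = 2L)
    gcs <- numeric(st$n_introns)
    for (k in seq_len(st$n_introns + 1L)) {
      ex_start <- c(ex_start, pos)
      seq_parts[[ch]] <- c(seq_parts[[ch]],
                           .rand_seq(st$ex_len[k], cf$gc_mean))
      pos <- pos + st$ex_len[k]
      ex_end <- c(ex_end, pos)
      if (k <= st$n_introns) {
        gci <- min(0.65, max(0.25, stats::rnorm(1L, cf$gc_mean, cf$gc_sd)))
        gcs[k] <- gci
        seq_parts[[ch]] <- c(seq_parts[[ch]], .rand_seq(st$in_len[k], gci))
        intron_iv[k, ] <- c(pos, pos + st$in_len[k])
        pos <- pos + st$in_len[k]
      }
    }
    cursor[ch] <- pos
    exons[[g]] <- data.frame(gene_id = gene_ids[g], chrom = ch,
                             strand = st$strand, start = ex_start,
                             end = ex_end, stringsAsFactors = FALSE)
    if (planted[g]) {
      k <- st$seg_intron  # genomic (left-to-right) gap index
      iv <- intron_iv[k, ]
      # intron_index is transcription-order; convert from the genomic gap
      idx <- if (st$strand == "+") k else st$n_introns - k + 1L
      abut <- stats::runif(1L) < cf$junction_end_fraction
      if (abut) {
        side <- sample(c("left", "right"), 1L)
        ss <- if (side == "left") iv[1L] else iv[2L] - st$seg_len
      } else {
        side <- "none"
        ss <- iv[1L] + sample.int(iv[2L] - iv[1L] - st$seg_len - 1L, 1L)
      }
      retained[[length(retained) + 1L]] <- data.frame(
        gene_id = gene_ids[g], chrom = ch, strand = st$strand,
        intron_index = idx, intron_start = iv[1L], intron_end = iv[2L],
        segment_start = ss, segment_end = ss + st$seg_len,
        abut_side = side, role = role[g], stringsAsFactors = FALSE)
    }
    gc_of_intron[[g]] <- gcs
  }
  tail_gap <- as.integer(round(stats::runif(cf$n_chroms, 2000, 4000)))
  for (i in seq_len(cf$n_chroms))
    seq_parts[[chroms[i]]] <- c(seq_parts[[chroms[i]]],
                                .rand_seq(tail_gap[i], cf$gc_mean))
  genome_chr <- vapply(seq_parts, paste, "", collapse = "")
  retained <- if (length(retained)) do.call(rbind, retained) else
    data.frame(gene_id = character(0), chrom = character(0),
               strand = character(0), intron_index = integer(0),
               intron_start = integer(0), intron_end = integer(0),
               segment_start = integer(0), segment_end = integer(0),
               abut_side = character(0), role = character(0))

  models <- gene_models(do.call(rbind, exons))
  introns <- derive_introns(models)

  # --- plant internal pA tracts (sense strand) -----------------------------
  pa_pick <- stats::runif(nrow(introns)) < cf$pa_fraction
  pa_planted <- integer(nrow(introns))
  pa_at <- integer(nrow(introns))
  for (i in which(pa_pick)) {
    len <- sample(10:14, 1L)
    if (introns$length[i] < len + 40L) next
    pa_at[i] <- introns$start[i] + 20L +
      sample.int(introns$length[i] - len - 40L, 1L)
    pa_planted[i] <- len
  }
  for (ch in chroms) {  # patch each chromosome once, at byte level
    idx <- which(pa_planted > 0L & introns$chrom == ch)
    if (length(idx) == 0L) next
    r <- charToRaw(genome_chr[ch])
    for (i in idx) {
      b <- charToRaw(if (introns$strand[i] == "+") "A" else "T")
      r[(pa_at[i] + 1L):(pa_at[i] + pa_planted[i])] <- b
    }
    genome_chr[ch] <- rawToChar(r)
  }
  genome <- Biostrings::DNAStringSet(genome_chr)
  names(genome) <- chroms
  introns <- intron_features(introns, genome)

  # --- fragments -----------------------------------------------------------
  blocks <- list()
  frag_n <- 0L
  # register one batch of fragments: bl = list(start, end, frag) from
  # .pe_blocks (frag indexes fragments within the batch)
  add_batch <- function(bl, chrom, n, unique = rep(TRUE, n)) {
    if (n == 0L) return(invisible(NULL))
    ids <- sprintf("frag%06d", frag_n + seq_len(n))
    frag_n <<- frag_n + n
    blocks[[length(blocks) + 1L]] <<- data.frame(
      fragment_id = ids[bl$frag], chrom = chrom,
      start = as.integer(bl$start), end = as.integer(bl$end),
      unique = unique[bl$frag], stringsAsFactors = FALSE)
    invisible(NULL)
  }
  frag_spans <- function(n, limit) {
    pmin(limit,
         2L * R + pmax(0L, as.integer(round(stats::rnorm(n, 50, 20)))))
  }
  upos <- function(n, lo, width) lo + floor(stats::runif(n) * width)

  for (g in seq_len(cf$n_genes)) {
    ex <- exons[[g]]
    tx_len <- sum(ex$end - ex$start)
    n_ex <- as.integer(ceiling(cf$exonic_depth * tx_len / (2L * R)))
    if (n_ex > 0L) {
      span <- frag_spans(n_ex, tx_len)
      ts <- upos(n_ex, 0L, tx_len - span + 1L)
      mate <- .pe_blocks(ts, span, R)
      # map each transcript-coordinate mate block to genomic exon blocks
      w <- ex$end - ex$start
      off <- c(0L, cumsum(w)[-length(w)])
      gb <- lapply(seq_along(mate$start), function(q) {
        m <- .map_to_genome(mate$start[q], mate$end[q], ex$start, ex$end)
        cbind(m, mate$frag[q])
      })
      gb <- do.call(rbind, gb)
      add_batch(list(start = gb[, 1L], end = gb[, 2L], frag = gb[, 3L]),
                ex$chrom[1L], n_ex,
                unique = stats::runif(n_ex) >= cf$nonunique_fraction)
    }
    if (cf$hnrna_rate > 0 && structures[[g]]$n_introns > 0L) {
      gi <- introns[introns$gene_id == gene_ids[g], , drop = FALSE]
      for (k in seq_len(nrow(gi))) {
        n_hn <- as.integer(ceiling(cf$hnrna_rate * gi$length[k] / (2L * R)))
        if (n_hn == 0L) next
        span <- frag_spans(n_hn, gi$length[k])
        s <- upos(n_hn, gi$start[k], gi$length[k] - span + 1L)
        add_batch(.pe_blocks(s, span, R), gi$chrom[k], n_hn)
      }
    }
  }
  if (nrow(retained) > 0L) {
    for (i in seq_len(nrow(retained))) {
      seg <- retained[i, ]
      L <- seg$segment_end - seg$segment_start
      n_in <- as.integer(ceiling(cf$intronic_depth * L / (2L * R)))
      if (n_in > 0L) {
        span <- frag_spans(n_in, L)
        s <- upos(n_in, seg$segment_start, L - span + 1L)
        add_batch(.pe_blocks(s, span, R), seg$chrom, n_in)
      }
      if (seg$abut_side != "none") {
        bnd <- if (seg$abut_side == "left") seg$intron_start else
          seg$intron_end
        n_jx <- max(2L, as.integer(round(0.1 * n_in)))
        off <- 10L + floor(stats::runif(n_jx) * (R - 20L))  # intronic nt
        s <- if (seg$abut_side == "left") bnd - (R - off) else bnd - off
        add_batch(list(start = s, end = s + R, frag = seq_len(n_jx)),
                  seg$chrom, n_jx)
      }
    }
  }
  chrom_lengths <- stats::setNames(nchar(genome_chr), chroms)
  if (cf$noise_rate > 0) {
    ig <- intergenic_space(models, chrom_lengths, pad = 0L)
    ig <- ig[ig$end - ig$start > 2L * R + 100L, , drop = FALSE]
    ig_nt <- sum(ig$end - ig$start)
    n_noise <- as.integer(round(cf$noise_rate * ig_nt / (2L * R)))
    if (n_noise > 0L && nrow(ig) > 0L) {
      pick <- sample.int(nrow(ig), n_noise, replace = TRUE,
                         prob = ig$end - ig$start)
      for (ch in unique(ig$chrom[pick])) {
        idx <- pick[ig$chrom[pick] == ch]
        n_ch <- length(idx)
        lim <- ig$end[idx] - ig$start[idx]
        span <- frag_spans(n_ch, lim)
        s <- upos(n_ch, ig$start[idx], lim - span + 1L)
        add_batch(.pe_blocks(s, span, R), ch, n_ch)
      }
    }
  }
  blocks <- do.call(rbind, blocks)
  rownames(blocks) <- NULL

  # --- decoy annotations ---------------------------------------------------
  ann <- list(predicted_genes = NULL, polya_sites = NULL, ncrna = NULL,
              antisense = NULL)
  mkiv <- function(rows) data.frame(
    chrom = rows$chrom,
    start = rows$segment_start + 5L,
    end = pmin(rows$segment_end, rows$segment_start + 80L),
    stringsAsFactors = FALSE)
  dn <- retained[retained$role == "decoy_ncrna", , drop = FALSE]
  if (nrow(dn) > 0L) ann$ncrna <- mkiv(dn)
  da <- retained[retained$role == "decoy_antisense", , drop = FALSE]
  if (nrow(da) > 0L) ann$antisense <- mkiv(da)
  dp <- retained[retained$role == "decoy_predicted", , drop = FALSE]
  if (nrow(dp) > 0L)
    ann$predicted_genes <- data.frame(chrom = dp$chrom,
                                      start = dp$intron_start + 1L,
                                      end = dp$intron_end - 1L,
                                      stringsAsFactors = FALSE)
  ds <- retained[retained$role == "decoy_polya", , drop = FALSE]
  if (nrow(ds) > 0L)
    ann$polya_sites <- data.frame(
      chrom = ds$chrom,
      pos = (ds$segment_start + ds$segment_end) %/% 2L,
      stringsAsFactors = FALSE)

  # --- de-novo junction table with planted truth ---------------------------
  jt <- list(); jtruth <- list()
  clean <- retained[retained$role == "cirt" &
                    retained$intron_end - retained$intron_start >= 400L, ,
                    drop = FALSE]
  n_j <- min(cf$n_planted_junctions, nrow(clean))
  if (n_j > 0L) {
    rows <- clean[sample.int(nrow(clean), n_j), , drop = FALSE]
    for (i in seq_len(n_j)) {
      r <- rows[i, ]
      ilen <- r$intron_end - r$intron_start
      spl <- min(ilen - 60L, 100L + sample.int(200L, 1L))
      donor <- r$intron_start + 20L
      jt[[length(jt) + 1L]] <- data.frame(
        chrom = r$chrom, start = donor, end = donor + spl,
        signal = "GT-AG", unique_reads = 1L + sample.int(3L, 1L),
        overhang_left = 8L + sample.int(10L, 1L),
        overhang_right = 8L + sample.int(10L, 1L),
        stringsAsFactors = FALSE)
      jtruth[[length(jtruth) + 1L]] <- data.frame(
        gene_id = r$gene_id, intron_index = r$intron_index,
        chrom = r$chrom, start = donor, end = donor + spl,
        expected_accept = TRUE, reason = "planted",
        stringsAsFactors = FALSE)
    }
    # quality-failing negatives anchored on the first planted junction
    r <- rows[1L, ]
    neg <- data.frame(
      chrom = r$chrom,
      start = c(r$intron_start + 40L, r$intron_start + 45L, r$intron_start),
      end = c(r$intron_start + 180L, r$intron_start + 200L, r$intron_end),
      signal = c("GT-AG", "AA-TT", "GT-AG"),
      unique_reads = c(2L, 2L, 2L),
      overhang_left = c(7L, 12L, 12L),
      overhang_right = c(12L, 12L, 12L),
      stringsAsFactors = FALSE)
    jt[[length(jt) + 1L]] <- neg
    jtruth[[length(jtruth) + 1L]] <- data.frame(
      gene_id = r$gene_id, intron_index = r$intron_index,
      chrom = neg$chrom, start = neg$start, end = neg$end,
      expected_accept = FALSE,
      reason = c("overhang_below_8", "unknown_signal", "not_strictly_inside"),
      stringsAsFactors = FALSE)
  }
  junction_table <- if (length(jt)) do.call(rbind, jt) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               signal = character(0), unique_reads = integer(0),
               overhang_left = integer(0), overhang_right = integer(0))
  rownames(junction_table) <- NULL

  truth_genes <- data.frame(gene_id = gene_ids, role = role,
                            stringsAsFactors = FALSE)
  ik <- paste(introns$gene_id, introns$intron_index)
  retained$pa_planted <- if (nrow(retained) > 0L)
    pa_planted[match(paste(retained$gene_id, retained$intron_index), ik)]
  else integer(0)
  list(genome = genome, models = models, introns = introns, blocks = blocks,
       annotations = ann, junction_table = junction_table,
       truth = list(genes = truth_genes, retained = retained,
                    junctions = if (length(jtruth)) do.call(rbind, jtruth)
                    else NULL),
       chrom_lengths = chrom_lengths, config = config)
}

#' Write a simulated experiment to a directory
#'
#' Standard plain-text formats: genome FASTA, gene models BED12, alignment
#' blocks TSV, decoy annotation BEDs / site table, junction table TSV and
#' truth tables TSV.
#'
#' @param sim [simulate_cirt_data()] output.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_gene_models_bed12(sim$models, file.path(dir, "genes.bed"))
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(sim$blocks, "alignments.tsv")
  wt(sim$junction_table, "junctions.tsv")
  wt(sim$truth$genes, "truth_genes.tsv")
  wt(sim$truth$retained, "truth_retained.tsv")
  if (!is.null(sim$truth$junctions)) wt(sim$truth$junctions,
                                        "truth_junctions.tsv")
  for (nm in names(sim$annotations)) {
    x <- sim$annotations[[nm]]
    if (is.null(x)) next
    wt(x, paste0(nm, ".tsv"))
  }
  invisible(dir)
}
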