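# Shared fixtures and independent oracles, all built in code.

# two toy 3-exon genes on chr1: G1 plus strand, G2 minus strand
toy_models <- function() {
  gene_models(data.frame(
    gene_id = rep(c("G1", "G2"), each = 3L),
    chrom = "chr1",
    strand = rep(c("+", "-"), each = 3L),
    start = c(0L, 200L, 400L, 1000L, 1200L, 1400L),
    end = c(100L, 300L, 500L, 1100L, 1300L, 1500L)))
}

blk <- function(id, s, e, chrom = "chr1", unique = TRUE) {
  data.frame(fragment_id = id, chrom = chrom, start = as.integer(s),
             end = as.integer(e), unique = unique, stringsAsFactors = FALSE)
}

# the default simulated experiment, computed once per test run
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(.sim_cache$sim))
    .sim_cache$sim <- simulate_cirt_data(sim_config(seed = 1))
  .sim_cache$sim
}
default_scan <- function() {
  if (is.null(.sim_cache$scan)) {
    sim <- default_sim()
    .sim_cache$scan <- detect_cirts(sim$blocks, sim$models,
                                    mode = "dendrite",
                                    annotations = sim$annotations,
                                    chrom_lengths = sim$chrom_lengths)
  }
  .sim_cache$scan
}

# brute-force single-linkage oracle: repeatedly merge any pair of footprints
# whose gap is <= gap, until no pair merges; order-free by construction
bf_contigs <- function(start, end, gap = 500L) {
  iv <- Map(c, start, end)
  repeat {
    merged <- FALSE
    for (i in seq_along(iv)) {
      for (j in seq_along(iv)) {
        if (j <= i) next
        a <- iv[[i]]; b <- iv[[j]]
        if (max(a[1L], b[1L]) - min(a[2L], b[2L]) <= gap) {
          iv[[i]] <- c(min(a[1L], b[1L]), max(a[2L], b[2L]))
          iv <- iv[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  m <- do.call(rbind, iv)
  m[order(m[, 1L]), , drop = FALSE]
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# independent six-frame translation oracle built on Biostrings::translate,
# vectorized over sequences; ORF = "M" up to (excluding) the next "*" or the
# peptide end. Returns max_orf_aa as an N x 6 matrix (3 sense then 3
# antisense frames) and has_stop_all_six_frames as a length-N logical.
orf_oracle <- function(seqs) {
  dna <- Biostrings::DNAStringSet(seqs)
  rc <- Biostrings::reverseComplement(dna)
  frame_prot <- function(src, off) {
    n <- (Biostrings::width(src) - off) %/% 3L
    as.character(Biostrings::translate(
      Biostrings::subseq(src, off + 1L, off + 3L * n),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  prots <- c(lapply(0:2, function(o) frame_prot(dna, o)),
             lapply(0:2, function(o) frame_prot(rc, o)))
  max_aa <- vapply(prots, function(p)
    vapply(regmatches(p, gregexpr("M[^*]*", p)), function(m)
      if (length(m)) max(nchar(m)) else 0L, integer(1L)),
    integer(length(seqs)))
  has_stop <- vapply(prots, function(p) grepl("*", p, fixed = TRUE),
                     logical(length(seqs)))
  list(max_orf_aa = matrix(max_aa, ncol = 6L),
       has_stop_all_six_frames = rowSums(matrix(has_stop, ncol = 6L)) == 6L)
}

# random intron feature tables for background-matching tests
random_intron_features <- function(n, prefix) {
  data.frame(gene_id = paste0(prefix, seq_len(n)),
             intron_index = 1L,
             length = as.integer(round(stats::rlnorm(n, log(1300), 0.4))),
             gc_fraction = stats::runif(n, 0.30, 0.60),
             max_pa_tract = ifelse(stats::runif(n) < 0.5, 0L,
                                   sample(10:14, n, replace = TRUE)),
             stringsAsFactors = FALSE)
}
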