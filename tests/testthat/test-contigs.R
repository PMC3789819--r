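intronic_frags <- function(starts, ends, gene = "g", intron = 1L) {
  n <- length(starts)
  data.frame(fragment_id = sprintf("f%03d", seq_len(n)),
             chrom = rep("chr1", n), start = as.integer(starts),
             end = as.integer(ends), category = rep("intronic", n),
             gene_id = rep(gene, n), intron_index = rep(intron, n),
             stringsAsFactors = FALSE)
}

test_that("contigs merge at the 500-bp gap rule boundary", {
  # gaps of 150 and 550: first two footprints merge, third stands alone
  cg <- assemble_contigs(intronic_frags(c(100, 300, 900),
                                        c(150, 350, 950)))
  expect_equal(cg$start, c(100L, 900L))
  expect_equal(cg$end, c(350L, 950L))
  expect_equal(cg$n_fragments, c(2L, 1L))
  # a single fragment is its own contig
  cg <- assemble_contigs(intronic_frags(100, 150))
  expect_equal(cg$start, 100L)
  expect_equal(cg$end, 150L)
  # "no more than 500 bp": a gap of exactly 500 merges
  cg <- assemble_contigs(intronic_frags(c(0, 550), c(50, 600)))
  expect_equal(nrow(cg), 1L)
  # 501 does not
  cg <- assemble_contigs(intronic_frags(c(0, 551), c(50, 601)))
  expect_equal(nrow(cg), 2L)
  # empty input gives an empty table
  expect_equal(nrow(assemble_contigs(intronic_frags(integer(0),
                                                    integer(0)))), 0L)
})

test_that("contig limits: gap 0 gives overlap components, gap Inf one contig", {
  set.seed(11)
  s <- sample(0:5000, 20)
  f <- intronic_frags(s, s + 80)
  one <- assemble_contigs(f, gap = .Machine$integer.max)
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_fragments, 20L)
  zero <- assemble_contigs(f, gap = 0L)
  # with gap 0 adjacent/overlapping footprints form connected components:
  # contigs are separated by at least one empty base
  expect_true(all(zero$start[-1L] > zero$end[-nrow(zero)]))
  expect_equal(sum(zero$n_fragments), 20L)
})

test_that("contigs are disjoint, sorted and conserve fragment counts", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(2:30, 1L)
    s <- sample(0:20000, n)
    f <- intronic_frags(s, s + sample(30:150, n, replace = TRUE))
    cg <- assemble_contigs(f)
    expect_equal(sum(cg$n_fragments), n)
    if (nrow(cg) > 1L)
      expect_true(all(cg$start[-1L] - cg$end[-nrow(cg)] > 500L))
  }
})

test_that("exon-junction fragments abutting a contig end set the evidence flag", {
  f <- intronic_frags(c(1000, 1200), c(1100, 1300))
  j <- data.frame(fragment_id = "j1", chrom = "chr1", start = 950L,
                  end = 1010L, category = "exon_intron_junction",
                  gene_id = "g", intron_index = 1L)
  cg <- assemble_contigs(rbind(f, j))
  expect_true(cg$has_exon_junction_end)
  # junction evidence for a different intron does not count
  j$intron_index <- 2L
  cg <- assemble_contigs(rbind(f, j))
  expect_false(cg$has_exon_junction_end)
})

test_that("exponential-null KS test rejects non-exponential lengths", {
  set.seed(21)
  # identical lengths: strong rejection
  expect_lt(length_null_test(rep(360, 100))$p_value, 1e-10)
  # truncated-normal lengths: strong rejection at n = 1000
  x <- stats::rnorm(1000, 360, 40); x <- x[x > 0]
  expect_lt(length_null_test(x)$p_value, 0.01)
  # genuinely exponential lengths are typically not rejected
  expect_gt(length_null_test(stats::rexp(1000, 1 / 360))$p_value, 0.001)
  expect_error(length_null_test(1:5), "at least 8")
})

test_that("pA-tract contigs follow the >=9 nt / <500 bp clustering rule", {
  pad <- function(...) paste0(...)
  # 8-A run is below threshold
  expect_equal(nrow(pa_tract_contigs(pad(strrep("C", 50), strrep("A", 8),
                                         strrep("C", 50)))), 0L)
  # a single 9-A run makes one tract contig of length 9
  tc <- pa_tract_contigs(pad(strrep("C", 50), strrep("A", 9),
                             strrep("C", 50)))
  expect_equal(tc$length, 9L)
  expect_equal(tc$start, 50L)
  # two 10-A runs 600 nt apart stay separate
  tc <- pa_tract_contigs(pad(strrep("A", 10), strrep("C", 600),
                             strrep("A", 10)))
  expect_equal(nrow(tc), 2L)
  # 400 nt apart they merge (strictly less than 500)
  tc <- pa_tract_contigs(pad(strrep("A", 10), strrep("C", 400),
                             strrep("A", 10)))
  expect_equal(nrow(tc), 1L)
  expect_equal(tc$n_tracts, 1L + 1L)
  # exactly 500 apart they do not (strict rule)
  tc <- pa_tract_contigs(pad(strrep("A", 10), strrep("C", 500),
                             strrep("A", 10)))
  expect_equal(nrow(tc), 2L)
})

test_that("ORF screen handles starts, stops and N codons", {
  r <- orf_screen("ATGTAA")
  expect_equal(unname(r$max_orf_aa["F1"]), 1L)
  expect_equal(r$max_orf_aa_overall, 1L)
  # no ATG anywhere: zero in all frames
  r <- orf_screen(strrep("C", 60))
  expect_true(all(r$max_orf_aa == 0L))
  # open 3' end: ATG with no following stop runs to the sequence end
  r <- orf_screen("ATGAAACCC")
  expect_equal(unname(r$max_orf_aa["F1"]), 3L)
  # N codons are neither start nor stop
  r <- orf_screen("ATGNNNTAA")
  expect_equal(unname(r$max_orf_aa["F1"]), 2L)
  r2 <- orf_screen("ANGCCCCCC")
  expect_equal(unname(r2$max_orf_aa["F1"]), 0L)
  # stop-in-all-six-frames flag
  expect_false(orf_screen(strrep("C", 60))$has_stop_all_six_frames)
})

test_that("contig thirds are assigned from the transcribed-strand 5' start", {
  # plus strand, intron [0, 900): thirds split at 300 and 600
  expect_equal(contig_position_thirds(0L, 50L, 0L, 900L, "+"), 1L)
  expect_equal(contig_position_thirds(300L, 350L, 0L, 900L, "+"), 2L)
  expect_equal(contig_position_thirds(899L, 900L, 0L, 900L, "+"), 3L)
  # minus strand: the genomic right end is the 5' end
  expect_equal(contig_position_thirds(850L, 900L, 0L, 900L, "-"), 1L)
  expect_equal(contig_position_thirds(0L, 50L, 0L, 900L, "-"), 3L)
})

test_that("halves analysis places retained introns by index and skips odd middles", {
  introns <- data.frame(gene_id = rep(c("a", "b"), c(5L, 6L)),
                        intron_index = c(1:5, 1:6),
                        n_introns = rep(c(5L, 6L), c(5L, 6L)))
  calls <- data.frame(gene_id = c("a", "a", "a", "b"),
                      intron_index = c(1L, 2L, 3L, 4L))
  h <- halves_analysis(calls, introns)
  # a:i1, a:i2 are 5'; a:i3 is the excluded middle of 5; b:i4 is 3' of 6
  expect_equal(h$n_5prime, 2L)
  expect_equal(h$n_3prime, 1L)
  expect_equal(h$n_excluded_middle, 1L)
  expect_equal(h$fraction_5prime, 2 / 3)
})

test_that("uniform retention gives balanced halves on a synthetic cohort", {
  set.seed(31)
  n_genes <- 300L
  ni <- sample(5:9, n_genes, replace = TRUE)
  introns <- data.frame(gene_id = rep(sprintf("g%03d", seq_len(n_genes)), ni),
                        intron_index = unlist(lapply(ni, seq_len)),
                        n_introns = rep(ni, ni))
  pick <- sample(nrow(introns), 600L, replace = FALSE)
  h <- halves_analysis(introns[pick, c("gene_id", "intron_index")], introns)
  tot <- h$n_5prime + h$n_3prime
  expect_lt(abs(h$fraction_5prime - 0.5), 3 * sqrt(0.25 / tot))
})

test_that("soma length cutoff keeps 400 and drops 401", {
  cg <- data.frame(gene_id = "g", intron_index = 1L, chrom = "chr1",
                   start = 0L, end = 0L, length = c(400L, 401L, 100L),
                   n_fragments = 1L, has_exon_junction_end = FALSE)
  kept <- apply_length_cutoff(cg)
  expect_equal(kept$length, c(400L, 100L))
  expect_equal(nrow(apply_length_cutoff(cg[0, ])), 0L)
})

test_that("repeat filter uses single-base overlap with half-open adjacency", {
  cg <- data.frame(gene_id = "g", intron_index = 1L, chrom = "chr1",
                   start = 100L, end = 200L, length = 100L,
                   n_fragments = 1L, has_exon_junction_end = FALSE)
  r1 <- repeat_overlap_filter(cg, data.frame(chrom = "chr1", start = 199L,
                                             end = 250L))
  expect_equal(nrow(r1$overlapping), 1L)
  r2 <- repeat_overlap_filter(cg, data.frame(chrom = "chr1", start = 200L,
                                             end = 250L))
  expect_equal(nrow(r2$clean), 1L)
  expect_warning(r3 <- repeat_overlap_filter(cg, NULL), "skipped")
  expect_equal(nrow(r3$clean), 1L)
})
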