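mk_call <- function(gene, intron, frags = 10L, passed = TRUE) {
  data.frame(gene_id = gene, intron_index = intron,
             total_intronic_fragments = frags, passed = passed,
             stringsAsFactors = FALSE)
}

test_that("gene summaries recover a known cohort composition", {
  # 6 exonic-only, 3 exonic+intronic, 1 intron-only gene
  genes <- sprintf("g%02d", 1:10)
  a <- do.call(rbind, c(
    lapply(genes[1:9], function(g)
      data.frame(fragment_id = paste0(g, "_e"), chrom = "chr1", start = 0L,
                 end = 50L, category = "exonic", gene_id = g,
                 intron_index = NA_integer_)),
    lapply(genes[7:10], function(g)
      data.frame(fragment_id = paste0(g, "_i"), chrom = "chr1", start = 0L,
                 end = 50L, category = "intronic", gene_id = g,
                 intron_index = 1L))))
  calls <- do.call(rbind, lapply(genes[7:10], mk_call, intron = 1L))
  introns <- data.frame(gene_id = genes, intron_index = 1L, n_introns = 4L)
  s <- summarize_genes(a, calls, introns)
  expect_equal(sum(s$category == "exonic_only"), 6L)
  expect_equal(sum(s$category == "exonic_and_intronic"), 3L)
  expect_equal(sum(s$category == "intron_only"), 1L)
  expect_equal(nrow(s), 10L)
  # column consistency: genes with retention split between the two classes
  expect_equal(sum(s$category %in% c("exonic_and_intronic", "intron_only")),
               4L)
  # a failed call does not make a CIRT gene
  calls$passed[calls$gene_id == "g10"] <- FALSE
  s2 <- summarize_genes(a, calls, introns)
  expect_equal(sum(s2$category == "intron_only"), 0L)
})

test_that("replicate overlap uses the min denominator over genes and introns", {
  a <- rbind(mk_call("g1", 1L), mk_call("g2", 2L), mk_call("g3", 1L))
  expect_equal(replicate_overlap(a, a)$gene_overlap, 1)
  expect_equal(replicate_overlap(a, a)$intron_overlap, 1)
  b <- rbind(mk_call("g4", 1L), mk_call("g5", 1L))
  expect_equal(replicate_overlap(a, b)$gene_overlap, 0)
  # superset: min denominator gives 1
  ab <- rbind(a, mk_call("g9", 1L), mk_call("g8", 1L))
  expect_equal(replicate_overlap(a, ab)$gene_overlap, 1)
  expect_lt(replicate_overlap(a, ab)$gene_jaccard, 1)
  # intron overlap is conditioned on shared genes
  c1 <- rbind(mk_call("g1", 1L), mk_call("g2", 5L))
  c2 <- rbind(mk_call("g1", 1L), mk_call("g2", 6L), mk_call("g7", 1L))
  ov <- replicate_overlap(c1, c2)
  expect_equal(ov$intron_overlap, 1 / 2)
  expect_warning(replicate_overlap(a, a[0, ]), "no passed calls")
})

test_that("shared intron set is the across-sample intersection", {
  s1 <- rbind(mk_call("g1", 1L), mk_call("g2", 2L), mk_call("g3", 3L))
  s2 <- rbind(mk_call("g1", 1L), mk_call("g2", 2L))
  s3 <- rbind(mk_call("g1", 1L), mk_call("g2", 9L), mk_call("g4", 1L))
  sh <- shared_intron_set(list(s1, s2, s3))
  expect_equal(sh$gene_id, "g1")
  expect_equal(sh$intron_index, 1L)
})

test_that("threshold sweep fractions are exact and monotone", {
  calls <- rbind(mk_call("g1", 1L, 10L), mk_call("g2", 1L, 40L),
                 mk_call("g3", 1L, 300L))
  sw <- threshold_sweep(calls)
  expect_equal(unname(sw$fractions), c(1, 2 / 3, 1 / 3))
  expect_true(all(diff(sw$fractions) <= 0))
  expect_equal(sw$top_genes, "g3")
  # a cutoff beyond every count gives zero
  expect_equal(unname(threshold_sweep(calls, cutoffs = 1000L)$fractions), 0)
  # density ratios for the top class
  sw2 <- threshold_sweep(calls, density_ratio = c(g1 = 0.1, g3 = 0.8))
  expect_equal(sw2$top_median_density_ratio, 0.8)
})

test_that("density correlation matches known cases and flags degeneracy", {
  x <- 1:50
  r <- density_correlation(x, x)
  expect_equal(r$r, 1)
  expect_warning(rc <- density_correlation(rep(1, 10), 1:10), "undefined")
  expect_true(is.na(rc$r))
  set.seed(61)
  ind <- density_correlation(stats::rnorm(5000), stats::rnorm(5000))
  expect_lt(abs(ind$r), 0.05)
  # rank correlation is available
  s <- density_correlation(x, x^3, method = "spearman")
  expect_equal(s$r, 1)
})

test_that("intron position frequency localizes retention along the model", {
  introns <- data.frame(gene_id = rep(sprintf("g%02d", 1:30), each = 10L),
                        intron_index = rep(1:10, 30L),
                        n_introns = 10L)
  first_only <- mk_call(sprintf("g%02d", 1:30), 1L)
  f <- intron_position_frequency(first_only, introns)
  expect_equal(sum(f$counts), 30L)
  expect_equal(f$counts[1L], 30L)   # all mass in the 5'-most bin
  expect_lt(f$chisq_p, 0.01)
  # single-intron genes sit at 0.5 by convention
  one <- data.frame(gene_id = "solo", intron_index = 1L, n_introns = 1L)
  f1 <- intron_position_frequency(mk_call("solo", 1L), one)
  expect_equal(f1$positions, 0.5)
  # uniform planting is flat within sampling error
  set.seed(62)
  unif <- mk_call(rep(sprintf("g%02d", 1:30), each = 6L),
                  as.integer(replicate(180, sample(10L, 1L))))
  fu <- intron_position_frequency(unif, introns)
  expect_gt(fu$chisq_p, 0.001)
})

test_that("EST overlap classes follow the containment precedence", {
  cg <- function(s, e) data.frame(gene_id = "g", intron_index = 1L,
                                  chrom = "chr1", start = s, end = e,
                                  length = e - s, n_fragments = 1L,
                                  has_exon_junction_end = FALSE)
  ests <- data.frame(chrom = "chr1", start = c(100L, 700L, 1200L),
                     end = c(400L, 720L, 1300L))
  res <- est_overlap(rbind(cg(150L, 300L),   # inside the first EST
                           cg(650L, 800L),   # contains the second EST
                           cg(1250L, 1400L), # staggered with the third
                           cg(5000L, 5100L)),# touches nothing
                     ests)
  expect_equal(res$contig_within_est, 1L)
  expect_equal(res$est_within_contig, 1L)
  expect_equal(res$partial, 1L)
  expect_equal(res$no_overlap, 1L)
  # equal intervals count as contained (contig within EST)
  res2 <- est_overlap(cg(100L, 400L), ests)
  expect_equal(res2$contig_within_est, 1L)
})
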