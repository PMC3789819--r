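# minimal candidate set: one call on intron [1000, 2000) with one contig
mk_calls <- function(n_junction = 0L, n_internal = 3L) {
  data.frame(gene_id = "g", intron_index = 1L, chrom = "chr1",
             start = 1000L, end = 2000L, n_contigs = 1L,
             total_intronic_fragments = n_internal,
             n_junction_fragments = n_junction,
             flag_predicted_gene = FALSE, flag_polyA_site = FALSE,
             flag_ncRNA = FALSE, flag_antisense = FALSE,
             flag_junction_only = FALSE, passed = TRUE,
             stringsAsFactors = FALSE)
}
mk_contig <- function(start = 1200L, end = 1500L) {
  data.frame(gene_id = "g", intron_index = 1L, chrom = "chr1",
             start = start, end = end, length = end - start,
             n_fragments = 3L, has_exon_junction_end = FALSE,
             stringsAsFactors = FALSE)
}

test_that("predicted-gene filter flags single-base intron overlap", {
  iv <- function(s, e) data.frame(chrom = rep("chr1", length(s)),
                                  start = s, end = e)
  expect_true(filter_predicted_genes(mk_calls(), iv(1999L, 2100L))$
                flag_predicted_gene)
  expect_false(filter_predicted_genes(mk_calls(), iv(2000L, 2100L))$
                 flag_predicted_gene)
  expect_false(filter_predicted_genes(mk_calls(),
                                      iv(integer(0), integer(0)))$
                 flag_predicted_gene)
  expect_warning(filter_predicted_genes(mk_calls(), NULL), "skipped")
})

test_that("poly(A)-site filter uses half-open point containment", {
  st <- function(p) data.frame(chrom = "chr1", pos = p)
  expect_true(filter_polya_sites(mk_calls(), st(1000L))$flag_polyA_site)
  expect_false(filter_polya_sites(mk_calls(), st(2000L))$flag_polyA_site)
  expect_false(filter_polya_sites(mk_calls(), st(500L))$flag_polyA_site)
  # two sites in the intron flag it once
  f <- filter_polya_sites(mk_calls(), st(c(1100L, 1900L)))
  expect_equal(sum(f$flag_polyA_site), 1L)
})

test_that("ncRNA and antisense filters act at contig level with single-base rule", {
  iv <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  cg <- mk_contig(1200L, 1500L)
  expect_true(filter_ncrna(mk_calls(), cg, iv(1499L, 1600L))$flag_ncRNA)
  # adjacent (half-open) does not flag
  expect_false(filter_ncrna(mk_calls(), cg, iv(1500L, 1600L))$flag_ncRNA)
  # contig containing the whole ncRNA flags
  expect_true(filter_ncrna(mk_calls(), cg, iv(1300L, 1320L))$flag_ncRNA)
  # an interval in the intron but outside every contig does not flag
  expect_false(filter_ncrna(mk_calls(), cg, iv(1700L, 1800L))$flag_ncRNA)
  expect_true(filter_antisense(mk_calls(), cg,
                               iv(1499L, 1600L))$flag_antisense)
  expect_false(filter_antisense(mk_calls(), cg,
                                iv(1500L, 1600L))$flag_antisense)
})

test_that("junction-only introns are excluded, mixed support passes", {
  expect_true(filter_junction_only(mk_calls(n_junction = 3L,
                                            n_internal = 0L))$
                flag_junction_only)
  expect_false(filter_junction_only(mk_calls(n_junction = 1L,
                                             n_internal = 1L))$
                 flag_junction_only)
})

test_that("filters commute and are monotone in annotation input", {
  iv <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  cg <- mk_contig()
  ann <- list(predicted_genes = iv(1999L, 2100L),
              polya_sites = data.frame(chrom = "chr1", pos = 1100L),
              ncrna = iv(1499L, 1600L),
              antisense = iv(1210L, 1220L))
  base <- mk_calls()
  a <- filter_junction_only(
    filter_antisense(
      filter_ncrna(
        filter_polya_sites(
          filter_predicted_genes(base, ann$predicted_genes),
          ann$polya_sites), cg, ann$ncrna), cg, ann$antisense))
  b <- filter_predicted_genes(
    filter_polya_sites(
      filter_junction_only(
        filter_antisense(
          filter_ncrna(base, cg, ann$ncrna), cg, ann$antisense)),
      ann$polya_sites), ann$predicted_genes)
  expect_equal(a, b)
  expect_false(a$passed)
  # monotone: adding intervals can only add flags
  fewer <- suppressWarnings(apply_cirt_filters(base, cg,
                                               ann[c("ncrna")]))
  more <- suppressWarnings(apply_cirt_filters(base, cg, ann))
  fl <- grep("^flag_", names(fewer), value = TRUE)
  expect_true(all(as.matrix(more[fl]) >= as.matrix(fewer[fl])))
})

test_that("ncRNA classes are recorded and tabulated for flagged calls", {
  cg <- mk_contig(1200L, 1500L)
  ann <- data.frame(chrom = "chr1", start = c(1250L, 1300L, 5000L),
                    end = c(1260L, 1310L, 5100L),
                    class = c("snRNA", "snoRNA", "miRNA"))
  calls <- filter_ncrna(mk_calls(), cg, ann)
  expect_true(calls$flag_ncRNA)
  expect_equal(calls$ncRNA_classes, "snRNA,snoRNA")
  bd <- ncrna_class_breakdown(calls)
  expect_equal(as.integer(bd[c("snRNA", "snoRNA")]), c(1L, 1L))
  expect_false("miRNA" %in% names(bd))
})

test_that("gene summaries report intron/exon density ratios when models are given", {
  m <- toy_models()
  introns <- derive_introns(m)
  a <- rbind(blk("e1", 0, 50), blk("e2", 210, 260), blk("i1", 110, 160))
  a <- classify_fragments(a, m)
  calls <- data.frame(gene_id = "G1", intron_index = 1L,
                      total_intronic_fragments = 1L, passed = TRUE)
  s <- summarize_genes(a, calls, introns, models = m)
  g1 <- s[s$gene_id == "G1", ]
  # exon union 300 nt / 2 fragments; introns 200 nt / 1 fragment
  expect_equal(g1$intron_exon_density_ratio, (1 / 200) / (2 / 300))
})

test_that("annotation BED files load as interval tables", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tsnRNA", "chr2\t0\t50\tmiRNA"), bed)
  iv <- read_bed_intervals(bed)
  expect_equal(iv$start, c(100L, 0L))
  expect_equal(iv$end, c(200L, 50L))
  expect_equal(iv$class, c("snRNA", "miRNA"))
})

test_that("passed is true exactly when no flag is set", {
  cg <- mk_contig()
  calls <- suppressWarnings(apply_cirt_filters(mk_calls(), cg, list()))
  fl <- grep("^flag_", names(calls))
  expect_equal(calls$passed, rowSums(as.matrix(calls[, fl])) == 0L)
  expect_true(calls$passed)
})
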