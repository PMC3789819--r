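---
title: "Detecting cytoplasmic intron-sequence retaining transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cytoplasmic intron-sequence retaining transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cirtseq)
```

## The problem

Mature cytoplasmic mRNAs are expected to be fully spliced. Subcellular
RNA-seq of neuronal compartments, however, shows reads mapping inside
annotated introns of expressed genes — not spread across whole introns as
nuclear pre-mRNA (hnRNA) would produce, but concentrated in short islands of
a few hundred nucleotides within a minority of introns. Transcripts carrying
such retained intronic sub-sequences in the cytoplasm are called CIRTs
(cytoplasmic intron-sequence retaining transcripts). Distinguishing genuine
cytoplasmic retention from the many look-alikes — unannotated genes inside
introns, intronic poly(A) isoforms, independently transcribed ncRNAs,
antisense transcription, unannotated exon extensions, plain hnRNA
contamination — is the analytical problem this package addresses.

`cirtseq` implements the full detection pipeline for users working from
aligned reads: fragment classification against gene models, island ("contig")
assembly of intronic reads, a five-stage annotation filter cascade, novel
intron-internal junction discovery, matched background construction, and the
summary statistics used to characterize retention. A seeded generator plants
ground-truth retention in synthetic genomes so every stage is verifiable
without external data.

## Pipeline and assumptions

1. **Classification.** Only uniquely mapped fragments are used; the fragment
   (paired mates, all aligned blocks) is the counting unit. A fragment is
   *exonic* when every block lies in one gene's exon union, *intronic* when
   every block lies inside a single intron, an *exon–intron junction*
   fragment when its blocks straddle a boundary of one gene, *intergenic*
   when it touches no gene span, and *ambiguous* otherwise (counted,
   excluded). The protocol modelled is not strand-specific, so strand never
   enters any overlap test.
2. **Contig assembly.** Within each intron, fragment footprints merge when
   separated by at most 500 bp ("no more than 500 bp" — a gap of exactly
   500 merges). The threshold is deliberately generous: it bridges
   unmappable repeat patches inside introns and is conservative about the
   number of independent retention events. Contigs record fragment support
   and whether a junction fragment abuts an end (evidence the retained
   sequence is contiguous with spliced mRNA).
3. **Filter cascade.** An intron with read evidence is flagged when (i) it
   overlaps a predicted gene by one base or more, (ii) it contains an
   intronic poly(A) site, (iii) any of its contigs overlaps an annotated
   ncRNA by one base or more, (iv) any contig partially overlaps an
   antisense transcript, or (v) its only supporting fragments are
   exon–intron junction reads (possible unannotated exon extensions). A call
   passes iff no flag is set. The filters are pure interval predicates, so
   their order is irrelevant; absent annotation files skip a stage with a
   warning, because these resources are external.
4. **Modes.** *dendrite* (mechanically isolated cytoplasm) applies no length
   cutoff. *soma* (whole single cells, nucleus present) keeps only contigs
   of at most 400 nt, since hnRNA inflates contig length; this mirrors the
   observation that whole-cell contigs are systematically longer.
   *tissue* keeps everything including junction-only introns — it is a
   descriptive survey of bulk RNA, where the ~300-nt contig mode can be
   compared with the retention signal seen in dendrites.

## Key statistics

- **Intronic enrichment.** One-sided test that the per-base fragment rate in
  intronic space exceeds the intergenic rate (complement of gene spans
  padded by 1 kb to keep unannotated UTRs out of the denominator).
  Conditional on the total count the intronic count is binomial under the
  null, so the exact tail is summed directly for totals up to 10,000; a
  pooled two-proportion z approximation takes over above that.
- **Length null.** If retained intervals arose from uniformly random breaks,
  contig lengths would be exponential. We test with Kolmogorov–Smirnov
  against an exponential with rate 1/mean; estimating the rate from the
  data makes the nominal p conservative (the test under-rejects a true
  exponential), which is the safe direction for claiming non-randomness.
- **ORF screen.** Six-frame scan; an ORF is ATG-initiated and ends at the
  first in-frame stop (excluded from the length) or runs open to the
  sequence end. Codons containing N are neither start nor stop. A
  stop-to-stop mode is deliberately not the default: with no evidence of
  translation initiation inside a contig, the ATG-anchored reading is the
  conservative choice. Coding potential is summarized as the maximal ORF
  length and whether all six frames contain a stop.
- **Positional analyses.** Contigs are assigned to intron thirds by their
  transcribed-strand 5' start (boundaries at floor(L/3) and floor(2L/3),
  half-open); retained introns are assigned to gene halves by intron index
  (the middle intron of an odd count belongs to neither half and is
  excluded); the retention frequency along the gene uses normalized position
  (index − 0.5)/n, placing a single-intron gene at 0.5.
- **pA-tract analyses.** The amplification chemistry can prime on internal
  adenosine runs, so introns record their longest sense-strand A-run
  (A on the reference for plus-strand genes, T for minus-strand). Two
  thresholds coexist deliberately: tract *contigs* are built from runs of
  ≥ 9 nt clustered at gaps strictly under 500 bp, while the per-intron
  reporting and background matching use ≥ 10 nt (below which the tract
  length is recorded as 0, "no tract"). Each operation defaults to its own
  quoted threshold and both are configurable.
- **Matched background.** Each retained intron is paired, uniformly at
  random without replacement, with an intron of a retention-free gene whose
  GC differs by at most 5 percentage points, whose length is within ±5%
  (the "within a range of 5%" phrase is ambiguous; we apply it as absolute
  percentage points for GC and relative for length, both configurable), and
  whose pA-tract length is identical. Unmatched introns are reported, never
  dropped silently.
- **Junction discovery.** De-novo junction calls are kept when the splice
  signal is GT-AG, GC-AG or AT-AC (or a reverse complement), at least one
  uniquely mapping read crosses with ≥ 8 nt aligned on each side, and both
  ends fall strictly inside one annotated intron. Junctions touching
  annotated exon boundaries are ordinary splicing and only counted.
  Validation candidates additionally require host intron < 20,000 nt,
  spliced-out length ≥ 100 nt, above-median host-gene expression, and
  flanks usable for primer design — operationalized as no homopolymer run of
  ≥ 10 nt within 50 nt of either end, a simple stand-in for a sequence
  complexity screen.

## Coordinates and conventions

All intervals are 0-based half-open; GTF input (1-based inclusive) is
converted at the boundary. Intron indices count 5'→3' in transcription
order, so index 1 of a minus-strand gene is the genomic-rightmost gap.
Overlap always means ≥ 1 shared base; half-open adjacency is not overlap.
Replicate overlap uses the smaller set as denominator (the Jaccard variant
is emitted alongside); intron-level overlap is conditioned on shared genes.
Gene models are analyzed per transcript by default, with a collapse-to-gene
union mode available, and retention is rolled up per gene as the union of
its models' calls.

## The synthetic generator

`sim_config()` / `simulate_cirt_data()` emulate the structure of the data the
pipeline targets, with defaults chosen as the study conditions:

- 200 genes on 4 chromosomes, 2–10 introns each, exons 120–300 nt, intron
  lengths lognormal with median ~1300 nt;
- 30% of genes carry one retained intron; retained segments are
  Normal(360, 60) nt truncated above the 100-nt read length, placed
  uniformly within the intron — except for the 30% of segments that abut an
  exon boundary and additionally emit junction-straddling reads;
- 47% of introns receive a planted internal pA tract of 10–14 nt on the
  sense strand;
- exonic coverage 20×, retained-segment coverage 20×, intergenic noise
  0.02×, hnRNA 0 (dendrite conditions; whole-cell simulations set
  `hnrna_rate > 0` and recover the longer-contig signature);
- two genes per decoy class carry the same retained-read signal plus an
  overlapping ncRNA / poly(A)-site / predicted-gene / antisense interval, so
  the cascade's sensitivity and specificity are measurable against truth;
- five intron-internal junctions are planted with passing quality, plus
  fixed negatives (7-nt overhang, unknown signal, boundary-touching).

Reads are emitted as already-aligned blocks: the pipeline's contract starts
at alignments, so no sequencing-error or aligner model is included. What the
generator does **not** emulate: mappability structure and repeats, GC or
3'-coverage bias of amplification (a positional-bias knob exists but is off),
overlapping gene models, PCR duplicates, and realistic transcript-abundance
dispersion. Passing tests therefore demonstrate the correctness of the
interval logic, the filters and the statistics under clean conditions — not
robustness to alignment artifacts on real genomes.

Problem sizes used in the shipped tests (200 genes, ~33,000 fragments;
500 oracle cases for contig assembly; 1,000 random 400-mers for the ORF
screen; 1,000 × n = 500 null simulations for the KS size check) were chosen
to give tight Monte-Carlo error on every property while keeping a full run
comfortably interactive.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_cirt_data(sim_config(seed = 1))
scan <- detect_cirts(sim$blocks, sim$models, genome = sim$genome,
                     mode = "dendrite", annotations = sim$annotations,
                     chrom_lengths = sim$chrom_lengths)
summary(scan)
plot(scan)

# matched background over the non-retained genes
pool <- scan$introns[!(scan$introns$gene_id %in%
                         scan$calls$gene_id), ]
ret <- scan$introns[paste(scan$introns$gene_id,
                          scan$introns$intron_index) %in%
                    with(scan$calls[scan$calls$passed, ],
                         paste(gene_id, intron_index)), ]
bg <- sample_matched_background(ret, pool, seed = 1)
```

## Known limitations

- Fragments whose blocks span two different introns of one gene without
  touching an exon (possible with very long inserts) are classified
  ambiguous rather than intronic; at realistic insert sizes this is rare.
- Contigs are clipped to introns by construction; junction evidence is kept
  as a flag rather than extending contigs across boundaries.
- The ncRNA/antisense filters operate on contig intervals and propagate to
  the intron; the predicted-gene and poly(A) filters operate on the intron
  interval itself. Mixed granularity is intentional (a poly(A) site anywhere
  in the intron compromises the whole intron, while an ncRNA only
  contaminates the overlapping island).
- Whether annotation filtering should precede contig assembly is an open
  design point; here assembly always happens first and flags annotate the
  calls, so downstream statistics can be recomputed under any flag subset.
- The exact enrichment test conditions on the total fragment count; for
  very unequal interval sizes with tiny counts the conditional test is
  conservative.
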