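# cirtseq

Detection and characterization of **cytoplasmic intron-sequence retaining
transcripts (CIRTs)** from subcellular RNA-seq alignments.

Fully spliced mRNA should carry no intronic sequence, yet RNA-seq of
nucleus-free neuronal compartments (dissected dendrites, single-cell soma)
shows uniquely mapping read islands inside annotated introns of expressed
genes — short (~360 nt) segments within a specific minority of introns,
rather than the full-intron coverage nuclear pre-mRNA would give. `cirtseq`
is for transcriptomics researchers who want to detect such retention from
their own aligned data and separate it from the look-alikes: unannotated
intronic genes, intronic poly(A) isoforms, embedded ncRNAs, antisense
transcription, unannotated exon extensions and hnRNA contamination.

## Method

Given gene models and uniquely mapped paired-end fragments, each fragment is
classified as exonic, intronic, exon–intron junction, intergenic or
ambiguous. Intronic fragments in each intron are clustered into **contigs**
(islands) by single linkage with a gap threshold *g* = 500 bp: footprints
separated by ≤ *g* merge. An intron with read evidence becomes a retained
intron call iff it survives a five-stage filter cascade (predicted-gene
overlap, intronic poly(A) site, ncRNA contig overlap, antisense contig
overlap — all at the ≥ 1 base rule — and junction-only support). Intronic
enrichment over intergenic background is tested with an exact conditional
binomial: with x intronic and y intergenic fragments over L_in and L_ig
bases, under H₀ x | (x+y) ~ Bin(x+y, L_in/(L_in+L_ig)), one-sided. Contig
lengths are tested against the exponential null Exp(1/mean) by
Kolmogorov–Smirnov (random-breakpoint model); coding potential by a
six-frame ATG-initiated ORF scan; amplification artifacts by poly(A)-tract
contigs (A-runs ≥ 9 nt clustered at gaps < 500 bp). Each retained intron is
matched to a background intron of equal pA-tract length, GC within 5
percentage points and length within ±5% from retention-free genes. Novel
intron-internal junctions are called from de-novo junction tables (known
splice signals, ≥ 1 unique crossing read, ≥ 8 nt overhang each side, both
ends strictly inside one intron).

A seeded generator (`simulate_cirt_data`) builds genomes, gene models,
aligned fragments, decoy annotations and a truth table so the whole pipeline
is verifiable offline; see the vignette in `vignettes/cirt-detection.Rmd`.

## Worked example

```r
library(cirtseq)

sim  <- simulate_cirt_data(sim_config(seed = 1))   # 200 genes, 30% CIRT
scan <- detect_cirts(sim$blocks, sim$models, genome = sim$genome,
                     mode = "dendrite", annotations = sim$annotations,
                     chrom_lengths = sim$chrom_lengths)
scan
#> CIRT scan (dendrite mode)
#>   fragments classified: 30726
#>   intronic contigs:     68
#>   retained introns:     60 passed / 68 candidate
#>   CIRT genes:           60
```

60 introns pass the cascade (the 8 flagged candidates are the generator's
planted decoys: each overlaps a predicted gene, poly(A) site, ncRNA or
antisense interval). `summary(scan)` breaks down fragment categories, gene
categories (`exonic_and_intronic` = 60, `exonic_only` = 140 here), filter
flags and passed-contig lengths (mean 341 nt against a planted segment
mean of 360 nt — contigs slightly undershoot their segment because the
outermost read starts fall inside it), and reports the intronic-vs-intergenic
enrichment test (p = 5.4e-170 on this data). `plot(scan)` draws the contig
length histogram.

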