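# hairpinseq

Genome-based microRNA discovery and expression profiling from plant small
RNA sequencing libraries, for a two-genotype x two-developmental-stage
design (an early-flowering mutant, MT, against its wild type, WT, each
sampled at a juvenile and an adult stage: libraries WT1, WT2, MT1, MT2).

The package is aimed at analysts who want a transparent, fully testable
re-implementation of the classic small-RNA discovery workflow: every stage
is an ordinary R function, the folding engine and validation rules are
documented and deterministic, and a built-in simulator generates genomes
and read sets with known truth so the whole pipeline can be validated end
to end without any external data or tools.

## What it computes

1. **Read cleanup and collapsing.** 3' adapter trimming (longest suffix
   matching an adapter prefix with >= 7 nt overlap and <= 1 mismatch per
   7 nt), 5' contaminant removal, quality and length filtering to the
   18-30 nt window, and collapsing to unique tags with per-library read
   counts.
2. **Mapping and classification.** Ungapped genomic alignment with at
   most one substitution (seed-and-verify, exactly equivalent to a
   brute-force scan of all offsets), then classification against
   structural-RNA/repeat annotation with the precedence
   rRNA > tRNA > snRNA > snoRNA > other ncRNA > repeat > unannotated and a
   50%-overlap inheritance rule. Tags mapping to more than 20 loci are
   flagged hyper-repetitive and excluded from discovery.
3. **miRNA discovery.** Conserved miRNAs by homology to a mature
   reference set (<= 3 mismatches over the aligned overlap); novel miRNAs
   by excising candidate precursor windows around expressed tag clusters,
   folding them, and applying the community annotation criteria: the
   mature tag on one arm, a sequenced star tag on the opposite arm, a
   mature/star duplex with 2-nt 3' overhangs (+/- 1 nt), at most 4
   unpaired mature bases, at most 2 nt bulge asymmetry, and folding
   energy at or below -18 kcal/mol.
4. **Folding.** A built-in nested-structure (pseudoknot-free)
   minimum-energy engine with a compact stacking model (G-C -3, A-U -2,
   G-U -1 kcal/mol per stacked pair; +3 per hairpin loop; minimum loop
   3 nt), verified in the test suite against exhaustive enumeration of
   all nested structures. External folding engines can be plugged in
   behind the same contract.
5. **Expression profiling.** Reads-per-million normalization, stage-wise
   regulation calls (up/down/unchanged/stage-only/absent, with a 2-fold
   differential flag on the stage2/stage1 ratio), genotype
   presence/absence partitions and inverse-pattern detection.
6. **Target prediction.** Complementarity scanning with the plant
   positional rules: penalty = mismatches + 0.5 per G:U wobble, accepted
   iff penalty <= 2, at most one mismatch at miRNA positions 2-11, none
   at the cleavage site (10-11), at most three mismatches at 12-21 with
   no more than two consecutive, at most four mismatches in total, no
   gaps. Sites carry region labels (5'UTR/ORF/3'UTR) and duplex energy
   ratios.
7. **RA-PCR cleavage evidence.** Region ratios (middle/3', 5'/3') of
   relative amplicon quantities and a cleavage-support call (middle/3'
   below 0.6 in every sample).

A packaged catalog of 75 novel miRNAs (precursor coordinates, folding
energies, arm sequences and four-library read counts) supports worked
examples and census statistics.

## Worked example

Census of the packaged novel miRNA catalog:

```r
library(hairpinseq)
cat75 <- load_novel_catalog()
summarize_precursors(cat75)
#> $count
#> [1] 75
#> $length
#>      min      max     mean
#>  74.0000 343.0000 132.2267
#> $mfe
#>        min        max       mean
#> -140.20000  -18.00000  -52.84027
counts <- setNames(cat75[, c("wt1", "wt2", "mt1", "mt2")],
                   c("WT1", "WT2", "MT1", "MT2"))
table(presence_pattern(counts))
#> MT-only WT-only  shared  absent
#>      18      23      34       0
```

The 75 precursors run from 74 to 343 bp (mean 132 bp) with folding
energies from -18 down to -140.2 kcal/mol; 18 of the miRNAs were read
only in the two mutant libraries and 23 only in the two wild-type
libraries, the rest in both genotypes.

Designing and folding a hairpin precursor:

```r
hp <- build_hairpin_precursor("UGGAGUGUGACAAUGGUGUUUG", loop_len = 15)
fold(hp$precursor)
#> TGGAGTGTGACAATGGTGTTTGCACAACCCAACCACCAACACCATTGTCACACTCCAGG
#> ((((((((((((((((((((((...........))..))))))))))))))))))))..
#> MFE: -46.00 kcal/mol (22 base pairs)
```

The 59-nt precursor (2 x 22 + 15) folds into the designed stem-loop: the
mature occupies the 5' arm, the star arm is its reverse complement offset
so that the excised duplex carries 2-nt 3' overhangs on both strands.

For an end-to-end run on simulated data, see `?run_pipeline` and the
methods vignette (`vignettes/hairpinseq-methods.Rmd`).

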