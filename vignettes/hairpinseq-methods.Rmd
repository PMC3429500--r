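---
title: "Methods: small RNA miRNA discovery, profiling and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA miRNA discovery, profiling and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpinseq)
```

# The analysis

hairpinseq re-implements the classic genome-based small-RNA discovery
workflow for a four-library design: two genotypes (an early-flowering
mutant, MT, and its wild type, WT) each sequenced at a juvenile and an
adult stage. The stages are deliberately simple, deterministic functions
rather than wrappers around external tools, so every decision the
pipeline makes can be recomputed and tested.

The flow is: raw reads are cleaned and collapsed into unique tags with
per-library counts; tags are mapped to the genome (ungapped, at most one
substitution) and classified against structural-RNA/repeat annotation;
unclassified expressed tags seed hairpin excision and validation for
novel miRNA discovery, while homology against a mature reference calls
conserved miRNAs; per-library counts are normalized to reads per million
(RPM) for stage-wise regulation and presence/absence calls; miRNA/target
complementarity is scored under plant positional rules; and
regional-amplification qPCR (RA-PCR) quantities provide orthogonal
cleavage evidence for predicted targets.

# The folding engine

Secondary structures are pseudoknot-free pairings with hairpin loops of
at least 3 nt. The energy of a structure is

* a stacking term for every base pair whose immediately inner neighbour
  is also paired: G-C/C-G -3.0, A-U/U-A -2.0, G-U/U-G -1.0 kcal/mol,
  attributed to the outer pair of each stack, plus
* +3.0 kcal/mol for every hairpin-loop closure.

Interior loops, bulges and multiloops carry no explicit penalty, and the
empty structure (energy 0) is always admissible, so the minimum free
energy (MFE) is never positive. The optimum is found by dynamic
programming over closed (`C`), paired (`Wp`) and end-unpaired (`Wx`)
interval states in C++ (O(n^3) time, O(n^2) memory), with a traceback
that reconstructs one optimal structure deterministically.

Two properties justify trusting it for hairpin geometry. First, the test
suite checks the engine against exhaustive enumeration of *all* nested
structures for short sequences: energies agree exactly. Second, for every
folded sequence the returned MFE equals the independent score of the
returned structure. What the model does *not* attempt is thermodynamic
fidelity: its absolute energies are not comparable to full
nearest-neighbour (Turner) energies, which is why the packaged catalog's
catalogued MFE values are consumed as data and never recomputed. Any
external engine honouring the same return contract (structure, MFE,
partner vector) can be passed as `fold_fun` to the validation functions.

A consequence of the stacking-only model is that an isolated base pair
flanked by mismatches contributes zero energy, so the engine is
indifferent to forming it. The synthetic generator therefore spaces
designed star-arm mismatches at least 3 nt apart, keeping designed
structures well defined (see below).

# Hairpin validation

A candidate window is accepted as a novel miRNA when:

* the most abundant expressed 20-24 nt tag in the window (the mature) has
  at most 4 bases unpaired in its duplex with a second expressed tag on
  the opposite arm (the star);
* the duplex inferred from the predicted pairing shows 2-nt 3' overhangs
  on both strands, with +/- 1 nt tolerance for folding ambiguity at duplex
  ends;
* bulge asymmetry across the duplex is at most 2 nt;
* the precursor folds at or below `mfe_max` (default -18 kcal/mol, the
  least stable value in the packaged catalog; configurable) and is at most
  400 nt long.

Duplex membership is evaluated against each candidate star tag directly:
a mature base counts as paired into the duplex when its partner falls
within the star tag's interval extended by 2 nt on either side. The 2-nt
slack tolerates duplex-end breathing (the folding engine occasionally
shifts the terminal pairs of a stem by one or two positions into an
adjacent bulge); the overhang test still pins the geometry, so a register
shift larger than the +/- 1 nt tolerance is rejected. Stray pairs from
the mature into flanking sequence simply count as unpaired rather than
corrupting the arm inference.

Windows are excised around clusters of candidate-tag alignments (merge
gap 30 nt): per cluster, one window extending `flank = 250` nt upstream
and one extending 250 nt downstream, each emitted for both strands,
clipped to [50, 400] nt. The flank covers precursors up to ~300 nt with
the mature on either arm, consistent with the 74-343 bp precursor range
in the packaged catalog. The reported precursor is the hairpin span
(mature plus star), grown symmetrically into the window to a 50-nt
minimum so that very short designed stems still yield a plausible
precursor with flanking stem context.

Because the star arm is the near-reverse-complement of the mature, every
hairpin locus has a "mirror" image on the opposite genomic strand, and
sequencing-error variants of the mature/star tags can map there within
the one-mismatch budget, producing a duplicate opposite-strand call.
Calls whose precursor intervals overlap on the genome (either strand) are
therefore collapsed to the single call whose mature tag has the strongest
read support. Deduplication by mature sequence (keeping the most stable
precursor) happens first; novel ids are assigned in genomic order.

# Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| adapter overlap | 7 nt, <= 1 mismatch / 7 nt | nt | deterministic, enumerable trimming rule |
| quality floor | Q10 per base | Phred | drops clearly bad reads; configurable |
| length window | 18-30 | nt | the gel-purified small-RNA range; 20-24 nt is a reporting view, not a filter |
| mapping mismatches | <= 1 | nt | substitution-only contract; matches the simulator's error model |
| multiplicity cap | 20 loci | count | hyper-repetitive tags are poor miRNA evidence |
| overlap rule | >= 50% of tag | fraction | partial-feature overlaps inherit the feature's class |
| homology threshold | <= 3 mismatches | nt | conserved-miRNA assignment rule |
| `mfe_max` | -18 | kcal/mol | least-stable precursor in the packaged catalog |
| overhang tolerance | +/- 1 | nt | folding-engine ambiguity at duplex ends |
| fold threshold | 2 | ratio | two-fold differential expression flag |
| penalty cap | 2 | penalty | target-site acceptance (mismatch 1.0, G:U 0.5) |
| RA-PCR threshold | 0.6 | ratio | above observed cleaved-target ratios (<= 0.51), below 1 |

Open choices resolved as package defaults: the up/down regulation census
uses strict count comparison while the two-fold rule is a separate flag
(both framings are in common use); expression ratios use RPM with no
pseudocount, with zero denominators reported as stage-only classes rather
than infinite ratios; mature-arm selection takes the tag with the highest
summed count across libraries, ties to the 5' arm; target-rule position
12 is counted in the 12-21 regime only, so the seed window is positions
2-11; the penalty cap and the positional mismatch rules are applied
conjointly (the strictest reading); repeats are excluded from miRNA
candidacy by default (`include_repeats` flips this); RA-PCR support
requires the ratio criterion in every provided sample.

# The synthetic generator

`generate_genome()` embeds designed loci in uniform-random scaffolds;
`simulate_libraries()` draws per-library locus counts from a multinomial
over the loci's expected abundances, so each library sums exactly to its
requested total. miRNA loci emit their mature sequence and, at
`star_fraction` (default 0.1), their star; structural-RNA, repeat and
random loci shed uniformly placed 18-30 nt fragments, mimicking
degradation products. Every read carries the 3' adapter (truncated at the
read length, default 40 nt) and i.i.d. substitution errors. A convenience
sampler draws log-normal(mu = 3, sigma = 1.5) abundance expectations.

Designed hairpins place the mature on the 5' arm and a star arm
positioned for exact 2-nt 3' overhangs; star mismatches are spaced >= 3 nt
apart within the stem interior, and loop/overhang bases are chosen not to
pair with the stem ends, so that the designed structure is the unique
optimum under the energy model. Every designed hairpin with at most 2
mismatches and loop up to 20 nt passes `validate_hairpin()` at defaults
(a tested property).

What the generator does **not** emulate: realistic quality-score
distributions, indels, ligation and PCR biases, isomiR 5'/3' end
heterogeneity, multi-locus miRNA families, or genome-scale repeat
structure. Passing the recovery benchmark therefore demonstrates the
pipeline's internal consistency — the stages compose correctly and the
validation rules recover exactly the planted signal at the stated error
rate — not its performance on real sequencing runs.

# Problem sizes and determinism

The default validation benchmark uses 20 miRNA loci and 15 decoy loci on
three 25-kb scaffolds, four libraries of 20,000 reads at 0.1% error; at
these sizes the full pipeline runs in well under a minute and reaches
sensitivity >= 0.95 with no false calls at fixed seeds. The
enumeration cross-check of the folding engine uses random sequences up to
25 nt (the enumeration, not the engine, is the limiting factor). All
stochastic steps run under locally-scoped seeds (`with_seed`), so equal
seeds give byte-identical FASTA/FASTQ/GFF3 outputs and identical reports,
and the caller's RNG state is never disturbed.

# Known limitations

* The energy model ignores loop-size dependence and dangling ends;
  structures with long interior loops are penalized only implicitly.
* Mapping is substitution-only; an indel-bearing read is simply unmapped.
* Conserved-miRNA calling requires a perfect-or-near genome match and a
  folding precursor, so reference miRNAs absent from the genome are not
  called.
* The census of the packaged catalog reports what the printed table
  contains; its accompanying summary statistics are reproduced except where
  the table itself disagrees with them (the catalog yields 18 mutant-only
  miRNAs and a mean MFE of -52.84 kcal/mol).
* No statistical differential-expression testing is attempted: the design
  has no biological replicates, so only descriptive ratio-based calls are
  reported.
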