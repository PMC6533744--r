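---
title: "Subtractive ddRAD discovery of sex-limited markers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtractive ddRAD discovery of sex-limited markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsub)
```

## The problem

In a female-heterogametic (ZW) species, sequences confined to the W
chromosome are present in every female genome and absent from every male
genome. When the genome is very large (tens of gigabases, as in the giant
salamander this workflow was built around), whole-genome assembly and
SNP-based association are impractical; reduced-representation sequencing at
well below 1x coverage is still informative, because a W-limited locus shows
a clean presence/absence signal across sexes. `radsub` implements that
subtractive logic end to end: double-digest RAD (ddRAD) tags are stacked per
individual, one sex's tags are screened against the other sex's reads and
then against the other sex's genome, and the surviving sequences are
sex-specific marker candidates. A validated marker panel is then applied by
(in-silico) PCR to call genetic sex, and disagreement with gonadal phenotype
identifies environmentally induced sex reversal.

## The library model

A ddRAD library is modelled as the set of genomic fragments flanked by one
cut of each of two enzymes. Defaults follow EcoRI (`GAATTC`, cutting
`G^AATTC`, offset 1) and NlaIII (`CATG`, cutting `CATG^`, offset 4); the
offsets are the enzymes' canonical cut positions and are configurable
(`enzyme_a_cut`, `enzyme_b_cut`). Fragments between two cuts of the same
enzyme, or bounded by a contig end, never receive both adapters and are
excluded from the library (the exhaustive-scan oracles in the test suite do
generate them, and verify they are exactly the ones excluded). When cuts of
both enzymes would fall at the same coordinate the A-enzyme label wins; this
tie is essentially impossible in real data and only matters for adversarial
inputs.

Size selection keeps fragments whose *gel* size — insert length plus
`adapter_length` (default 75 bp) — lies in the inclusive window
`[select_min, select_max]` (defaults 400–600 bp, hence a 325–525 bp insert
window). Whether a published gel window includes one or both adapters is
often ambiguous; we therefore expose `adapter_length` as a single additive
parameter rather than modelling adapter chemistry.

Read 1 starts at the enzyme-A end: inline barcode (MID), then the
restriction residue (`AATTC`), then the insert. For fragments whose A cut
lies at the right end the template is read off the bottom strand; because
the EcoRI site is palindromic this regains the `AATT` overhang across the
cut, so every read 1 carries the residue. Read 2 (from the B end) is
emitted for format fidelity but ignored downstream, since the screened unit
is a single fixed-length tag.

Per-fragment, per-individual read counts are Poisson(`mean_depth`).
Published run tables report only realised mean depths, so Poisson is the
simplest defensible sampling law; it also makes the power behaviour
transparent (a fragment is missed by one individual with probability
`exp(-mean_depth)`). Sequencing error is i.i.d. base substitution at
`error_rate`; indels, quality miscalibration, PCR duplicates and insert-size
distributions are deliberately out of scope. Base qualities are constant
(Phred 37), so quality summaries exercise arithmetic, not an error model.

## What the generator emulates — and what it does not

`build_genomes()` plants `n_w_regions` female-limited insertions into a
random shared genome. Each region is built around one *guaranteed*
ddRAD-valid fragment (A site, clean core, B site, insert length drawn
uniformly from the selection window), with all spurious enzyme sites inside
the planted fragment scrubbed, so every planted region survives digestion
and size selection. This gives tests planted truth with known coordinates.
Consequences to keep in mind: real W regions carry no such guarantee (many
W loci fall outside the size window); the simulated genomes are single
haplotypes with no heterozygosity, repeats or shared W/Z paralogy; and the
shared background is i.i.d. random sequence, so cut-site density is
Poisson-like rather than clustered. Passing tests therefore demonstrate the
correctness of the subtraction machinery, not the discovery rate to expect
from real data.

Default study conditions (and the sizes used throughout the test suite):
100 kb shared genome, 3 planted W regions of 2 kb, 4 females + 4 males,
mean depth 5, error rate 0, 150 bp reads, 110 nt tags. These mirror the
original experiment's structure (4 + 4 individuals, PE150, 110 nt trimmed
tags) at desk scale.

## Cleaning and stacking rules

Demultiplexing is exact-prefix matching with variable-length MIDs
(longest match wins, which the 4–6 nt barcodes of the original study
require); assigned plus unassigned reads always partition the input.
Cleaning removes reads missing the restriction residue at position one,
trims to `tag_length` (110 nt), and removes tags with strictly more than
10% N — the strict inequality follows the original rule's wording, and the
fraction is computed on the trimmed tag, which is the unit every later
exact comparison uses. By default the 5 nt residue is *retained* inside the
110 nt tag (standard RAD-tag convention); `keep_residual = FALSE` is
available since published descriptions are ambiguous on this point. No
sliding-window quality trimming is performed: the fixed-length trim plus
the Q20/Q30 report reproduces the published contract, in which quality is a
reporting check rather than a filter.

Stacking is exact: identical tags collapse with depth conservation. By
default tags are canonicalised to the lexicographic minimum of the sequence
and its reverse complement, making presence/absence strand-safe (library
orientation is arbitrary); `canonicalize = FALSE` reproduces naive
single-strand behaviour. Mean tag depth is defined as raw reads divided by
distinct tags — the definition that reproduces the published per-individual
table — and coverage as raw base pairs over the genome size (default
5e10). Full precision is kept internally; `format_run_table()` rounds
half-up (1 dp / 2 dp) at report time only. The published table's own
last-digit rounding is not fully self-consistent (a few printed depth and
coverage cells differ by one unit in the last digit from any single
rounding rule applied to its own counts, and its printed sub-average
coverages are not the means of its per-row values); we reproduce every cell
to within one unit in the last printed digit and compute aggregates from
first principles.

## The subtractive screen

`cross_sex_screen()` takes per-individual catalogs of the source sex and
marks each tag *matched* if it occurs in any opposite-sex individual.
Unmatched tags present in at least `min_source_individuals` source
individuals (default: all of them) at depth at least `min_depth` (default
1) are candidates. The all-individuals default is strict on purpose: a true
sex-limited marker is carried by every source-sex sample, and the
strictness is what suppresses false positives from opposite-sex coverage
gaps. The screened universe defaults to the union of source catalogs; a
`reference` individual can be designated instead, mirroring workflows that
screen one reference individual's assembly per sex — under the
all-individuals presence rule both choices give the same candidate set, so
the union default simply avoids an arbitrary reference choice.

`genome_filter()` then checks candidates against the opposite sex's genome:
a candidate is *mapped* if it aligns, on either strand, over its full
length with at most `max_mismatch_fraction` mismatches (default 0.10, i.e.
11 on a 110 nt tag — roughly BLASTn-like sensitivity for queries of this
size), found by exact seed-and-extend with `seed_length` 20. Seeding is a
heuristic: an alignment with its mismatches spread so evenly that no exact
20-mer survives can be missed, exactly as with any seeded aligner; the test
suite checks agreement with a full Hamming scan in the regimes that matter
(exact substrings, clustered mismatches, unrelated sequence). Unmapped
candidates are the final markers, and `select_candidates()` draws a
seed-logged uniform subset for validation, as one would pick markers for
wet-lab PCR.

Candidates are fixed at tag length: the original workflow screened
assembled sequences, but reports candidates as tag-like units, and at
sub-1x coverage assemblies are dominated by single-tag contigs, so the
unique-tag representative is the honest desk-scale stand-in.

## Marker application

`insilico_pcr()` reports every interval where the forward primer matches
one strand and the reverse primer's reverse complement matches the same
strand downstream within `max_product_bp`, allowing
`max_primer_mismatches` per primer except at the 3'-terminal base, which
must match exactly (polymerase extension requires a paired 3' end; the
default mismatch budget is 0). Both strands are scanned and coordinates are
reported on the plus strand. Single-primer (F/F or R/R) amplicons are not
modelled. A *band* is a product within `size_tolerance_bp` (default 5 bp,
a gel-resolution analogue) of the expected size. Genetic sex follows the
marker system (band = female under `ZW_female_marker`) with majority vote
across a panel and ties called `indeterminate`; the published experiments
used one marker per exposure group, which corresponds to a one-column
panel. Negative controls are modelled as template-free (always no band).
`detect_reversals()` cross-tabulates genetic against phenotypic sex; a
genetic female with male phenotype is a `female_to_male` reversal and vice
versa, the direction naming used for temperature-masculinised and
estradiol-feminised groups.

## Numerical and degenerate-input choices

* All coordinates are 0-based half-open internally, converted only at file
  boundaries (FASTA/FASTQ/TSV are 1-line-per-record text formats; catalogs
  are TSV with optional gzip).
* Empty inputs: an empty read set gives a zero quality summary with a
  warning; a catalog with zero tags reports mean depth 0 with a warning;
  an empty panel genotypes to a zero-column matrix; an all-`NA` genotype
  row is `indeterminate`.
* Determinism: every stochastic step (genomes, barcodes, read counts,
  errors, candidate selection) derives from the configuration seed through
  scoped RNG, so identical configurations give byte-identical outputs and
  the pipeline's rerun-equality is testable.
* Pipeline intermediates are plain text with the configuration hash and
  seed in `#` comment headers; FASTA/FASTQ cannot carry comments in-format,
  so their provenance lives in the run manifest written alongside.

## Known limitations

Subtraction at low coverage is one-sided: completeness of the *opposite*
sex's data bounds the false-positive rate, while depth in the *source* sex
bounds recall; with Poisson depth 5 and the all-individuals presence rule,
each true marker is lost with probability about
`1 - (1 - exp(-5))^4` ≈ 2.7% per source individual quartet, which is why
recall properties are stated at fixed seeds. The genome filter is ungapped:
an indel between a candidate and the opposite genome makes the candidate
look unmapped. Diploidy, W/Z gametologs with high identity, and
population-level presence/absence polymorphism are not modelled, and are
the main reasons wet-lab validation remains necessary for real candidates.
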