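---
title: "Guide design and edit simulation for wheat gliadin families: models and choices"
author: "gliadinCRISPR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide design and edit simulation for wheat gliadin families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliadinCRISPR)
```

This vignette explains the models behind `gliadinCRISPR` — what each
stage computes, which parameters matter and why their defaults were
chosen, what the synthetic generator does and does not emulate, and
where the design was genuinely open. It states no empirical result that
the package's tests and acceptance script do not themselves compute.

## The biological setting

Bread wheat is allohexaploid: every locus exists on the A, B and D
subgenomes. The gliadin storage proteins that carry most coeliac-disease
(CD) epitopes are encoded by large tandem arrays of intronless genes —
on the order of 60–150 α-gliadin copies, ~40 γ-gliadins and ~16
ω-gliadins per genome complement — with many pseudogene copies
(about 90% for α-gliadins) distinguished by in-frame premature stop
codons. A gliadin protein is, schematically, a signal peptide followed
by a Gln/Pro-rich repetitive region that houses the CD epitopes, then a
more conserved C-terminal part. Multiplexed Cas9 cutting of such arrays
can produce small indels, in-frame excision of the epitope region, or —
when two cuts co-occur in non-consecutive genes — deletion of all
intervening gene copies.

## Annotation

Coding sequences are translated in frame 0 with the standard genetic
code (`translateCds`; stop codons are kept as `*`, the first codon is
*not* treated as an initiator, and a trailing incomplete codon is
dropped with a warning). No ORF search is performed: inputs are assumed
ATG-anchored CDS, which is how gliadin genes are deposited and cloned.
A gene is called a pseudogene iff `*` occurs before the final codon; a
missing terminal stop is flagged but is not a pseudogene call.

Epitope scanning (`scanEpitopes`) is an exact 9-mer window comparison
against an editable catalogue (`inst/extdata/epitopes.tsv`), reporting
*all* matches including mutual overlaps — canonical CD epitopes overlap
one another, so a single repeat can carry several. Matching is done on
the genomically encoded Q-form by default; T-cell assays use the
deamidated (Q→E) forms, so a `qeEquivalence` flag treats Q and E as
equal when a deamidated catalogue is supplied. The shipped catalogue
holds canonical Q-form peptides from the CD epitope registry
literature; it is input data, not package constants, and should be
extended or replaced as the registry evolves.

Domain segmentation (`segmentDomains`) uses three rules: the signal
peptide is the first `signalLength` residues (default 20 — typical for
cereal storage-protein signal peptides; the exact value only shifts the
`post_signal_peptide` anchor), the epitope region spans from the first
to the last epitope hit, and the remainder is downstream. Because the
epitope region usually starts after the signal peptide ends, the gap is
labelled `epitope_upstream` so that segments remain contiguous and
cover the protein up to its first stop.

Coordinate conventions, used everywhere: DNA intervals in files are
0-based half-open; in-memory ranges are 1-based closed `IRanges`;
protein positions are 1-based inclusive; cut sites are between-base
indices counted as the number of bases 5′ of the cut.

## Subgroup classification

Genes are grouped by their *epitope signature*: the exact multiset of
catalogue epitopes found within the epitope region, serialised in
catalogue order. Signature equality is exact (name and count).
Pseudogenes are excluded by default — guide design focuses on
full-length genes — but an `includePseudogenes` flag restores them,
since whether pseudogenes should inform grouping is genuinely
ambiguous and both modes are useful.

Subgenome assignment is a majority vote over the subgroup members whose
genome is known (in practice, sequences from the diploid relatives
*T. monococcum*/*T. urartu* (A), *Ae. speltoides* (B) and *Ae.
tauschii* (D)). The majority share must reach a threshold, default 0.6:
there is no published rule, and `ambiguous` is a safer answer than a
wrong genome. Subgroups with no labelled member are `ambiguous` with
support 0 — the expected outcome for γ-gliadin groups, where epitope
combinations correlate poorly with subgenome.

## Guide evaluation

* **Matching** (`matchGuide`): both strands, IUPAC degenerate codes in
  the query (so degenerate cloning primers use the same machinery), a
  mandatory NGG PAM immediately 3′ of the protospacer on the matched
  strand (SpCas9; the PAM is never counted as mismatch), and
  protospacer lengths 17–23 nt (the published guides mix 19 and 20).
  Published gliadin guides target the antisense strand, so their
  reverse complement, preceded by the CCN PAM complement, is what
  appears in coding sequences.
* **Cut sites** (`predictCutSites`): perfect matches only; one blunt
  cut per match, 3 bp 5′ of the PAM, irrespective of protospacer
  length. A gene with k copies of the target motif yields exactly k
  cuts — the design expectation for the guide targeting the repeated
  DQ2.5-glia-g4c motif, whose copy number varies from 1 to 6 across
  γ subgroups.
* **Coverage** (`coverageMatrix`): perfect-match, PAM-required counts
  of member genes per subgroup. 100% identity is deliberate — coverage
  claims for guide sets are made at exact match, even though Cas9
  tolerates some mismatches in practice.
* **Off-targets** (`offTargetScan`): Hamming matches up to a
  configurable mismatch budget (default 3, a BLAST-like sensitivity)
  with a flag for a mismatch-free PAM-proximal 12-nt seed, the region
  that dominates Cas9 specificity.
* **Oligo heuristics**: `hairpinFlag` reports the longest exact
  self-complementary stem separated by a loop of ≥ `minLoop` (default
  3, the minimal sterically plausible loop; default stem threshold 8),
  and `crossDimerFlag` the longest contiguous antiparallel
  complementary run between two oligos (default threshold 10). These
  are fast screening heuristics for secondary structure and
  multiplexing compatibility, not thermodynamic folding models; no
  folding energies are computed, and borderline oligos should go to a
  dedicated folding tool.

`findConservedWindows` enumerates protospacer-sized windows (k ≥ 20;
k = 23 for protospacer+PAM) on both strands and reports those present
in at least a configurable fraction of genes, optionally restricted to
a domain region — the "relatively conserved stretch near the epitope
region" strategy for placing family-wide guides.

## Edit simulation

A `LocusModel` is a tandem array on one strand. `applyCuts` processes
sorted cuts left to right under a `repairPolicy`:

* each *adjacent pair* of cuts excises the intervening segment with
  probability `pSegmentDeletion`; genes fully inside the excision are
  `deleted`, and when the cuts lie in different genes the flanking
  genes become a `fusion`;
* remaining cuts resolve independently: perfect re-ligation with
  probability `pPerfectRepair` (default 0.2), else a deletion of
  1–10 nt immediately 5′ of the cut (probability 0.7, uniform sizes)
  or an insertion of 1–3 random bases. These indel defaults are
  pragmatic, config-exposed stand-ins for NHEJ outcome spectra — no
  microhomology modelling is attempted.

Consequences are called by comparing each gene before and after:
length change not divisible by 3 → `frameshift_ko`; in-frame with a
new internal stop → `nonsense_ko`; in-frame otherwise →
`inframe_edit`. The calls are, by construction, verifiable by
re-running the annotation stage on the edited allele, and the test
suite does exactly that.

The Acid-PAGE readout is emulated by a deliberately coarse mass proxy:
every intact protein (non-pseudogene, not knocked out) is binned at
110 Da per residue into 0.5 kDa bins per family. Any monotone proxy
suffices for presence/absence logic: a *clear change* is a bin gained
or lost, a *potential change* is a bin-count (intensity-like) change
only. Band *position shifts* within a bin and subtler intensity
effects are not representable — a known limitation shared with the
one-dimensional gel the proxy imitates.

`simulateScreen` runs the screen design — plants × 8 grains, each
allele of each locus edited independently per grain, every predicted
cut site firing with a per-site efficiency — and tallies plants and
grains with clear/any changes. One genotype per grain: chimerism and
post-meiotic Cas9 activity are not modelled, since a gel-based screen
cannot resolve them either. The default genotype template is 3
subgenomes × 2 alleles × 1 locus per family. When the repair policy is
deterministic (single deletion size, no insertions, degenerate
probabilities), per-allele outcomes are memoised by fired-cut subset,
which makes replicate calibration runs cheap without bypassing the
simulator. With a knockout-only policy the per-grain change
probability has the closed form 1 − (1 − e)^S (S = total cut sites per
grain), which the acceptance tests use for calibration and for
method-of-moments recovery of e (`estimateEfficiency`).

## Screening statistics

`percentageTable` derives the summary percentages from raw counts,
rounding half-up for display (half-even rounding would alter printed
values such as 9.375 → 9.4) while returning unrounded values
alongside; zero denominators give `NA`, never 0. "Any changes" is
defined as clear ∪ potential.

`heterogeneityChi2` is the Pearson chi-square on the 2×k
successes/failures table *without* continuity correction, df = k−1 —
the default convention for 2×k heterogeneity. On the shipped grain
counts it reproduces the published significant/non-significant
dichotomy (any changes significant at 0.05, clear changes not), but
not the exact printed P values: the source does not state whether the
plants or the grains table was tested, nor the correction used. The
package reports its exact method and leaves the small discrepancy in
place rather than tuning to printed values. A `small_expected` flag
warns when any expected cell is below 1.

## The synthetic generator

`generateFamily` emulates the statistical structure the analysis
relies on: subgroup templates (signal peptide, Q/P-free scaffolds, an
epitope block of repeated catalogue peptides separated by an `AS`
spacer so no spurious epitope windows arise at junctions, and in-frame
protospacer+PAM cassettes), synonymous-codon jitter so DNA copies
differ while proteins are identical within a subgroup, per-copy
stop-codon pseudogenisation at a configurable rate, and a labelled
fraction of members standing in for diploid-relative sequences (30%
by default, at least one per subgroup, so genome assignment is
testable).

The study-condition defaults are: α — 100 copies, 90% pseudogenes,
five subgroups (two A, two B, one D); γ — 40 copies, six subgroups
(two A, one B, three B/D) with the DQ2.5-glia-g4c copy number rising
from 1 to 6; ω — 16 copies, one subgroup per genome. The γ and ω
pseudogene fractions (0.5) and the intergenic spacer range are
assumptions, exposed as parameters, because no published values exist.
Guide cassettes are embedded per the reported coverage pattern (e.g.
the column-213 guide in all five α subgroups, the column-324 guide
withheld from both B subgroups), which is what makes the coverage
matrix a testable ground-truth quantity.

What the generator does **not** emulate: real wheat codon usage,
chromosome-scale context, sequence divergence *within* a subgroup
beyond synonymous sites, ω-gliadin/LMW-glutenin realism beyond motif
structure, and length variation of the repetitive region within a
subgroup. Tests passing on generator output therefore demonstrate the
correctness of the algorithms under the assumed family structure, not
performance on noisy database sequences — in particular, real families
will produce more, finer subgroups and partial coverage fractions
rather than the crisp all-or-none cells of the synthetic design.

## Problem sizes used by tests and the acceptance script

Chosen as the package's own balance of resolution against runtime:
families of 10–100 genes; screen calibration on a 10-gene α family
arranged as 6 alleles (2 genes per locus) with 117 plants × 8 grains
per replicate, 200 replicates in the test suite and 50 in the
acceptance script; 1000-case randomised oracle comparisons for
matching and scanning, 100–200 for the oligo heuristics. The
generator's binomial pseudogenisation makes an all-pseudogene draw
possible at 90% and small n; the pipeline driver then falls back to
classifying pseudogenes rather than failing.

## Known limitations

* Epitope presence/absence only — no HLA-binding or immunogenicity
  scoring, and no alignment-based inference for diverged epitope
  variants.
* No genome-wide indexed off-target search; `offTargetScan` is meant
  for gene-family-sized backgrounds.
* The repair model has no microhomology, base-editing or expression
  compensation; outcome frequencies are as configured, not learned.
* The chi-square printed-P discrepancy discussed above is inherent to
  the underspecified source and is documented, not resolved.
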