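---
title: "Methods: building and validating a gut virome catalogue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating a gut virome catalogue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(virocat)
```

## The problem

Virus-like-particle sequencing of the human gut yields assemblies whose
contigs mix genuine phage genomes, bacterial fragments, and fragments too
short to interpret. Turning them into a catalogue involves a chain of
thresholded decisions, each simple on its own but easy to get subtly wrong
in aggregate: which contigs are viral, which are complete circular
genomes, which are redundant with one another, which are new relative to
existing catalogues, how they group into genus-like clusters, where they
occur and how abundantly, and which bacteria they infect. `virocat` makes
every one of those decisions an explicit, tested function with its
thresholds collected in a single configuration object
(`pipeline_config()`).

## The decision rules and their parameters

**Viral calling.** Five binary criteria are evaluated per contig from a
detector-evidence table: VirSorter score >= 0.7 (inclusive), VirFinder
score > 0.6 (strict), PPR-Meta phage score > 0.7 (strict), a viral RefSeq
hit at > 50% identity and > 90% coverage, and >= 3 phage-orthologous-group
ORF hits at a rate >= 2 per 10 kb. A contig is called viral when circular,
when >= 2 criteria hold, or when exactly one holds and CheckV completeness
is >= 90%. The comparators follow the printed protocol exactly; a missing
detector value never satisfies a criterion, since each detector ran
independently and silence is informative. The decision is monotone: adding
evidence can never turn a virus into a non-virus (a property test asserts
this on random evidence).

**Decontamination.** Bacterial reference genomes are first masked for
prophages (intervals excised after merging overlaps; coordinates are
0-based half-open everywhere in the package). A viral-called contig is
removed when its merged >= 90%-identity alignment regions against the
masked set cover >= 50% of its length — merged regions, so the decision is
invariant to how an aligned region happens to be split into segments. Both
comparators are read inclusively: for a removal rule, the inclusive
reading is the conservative one against contamination. The length filter
keeps contigs strictly longer than 5 kb.

**Circularity.** An assembler traversing a circular genome emits the
origin twice, leaving an exact terminal repeat; the detector reports the
maximal L >= 30 for which the length-L prefix equals the length-L suffix.
Identity must be 100%, which is why no alignment statistics are needed —
exact string equality over all candidate overlap lengths is both the
definition and the implementation (`N` never matches). The second route
counts junction-spanning reads: >= 2 reads each having a >= 50 bp segment
ending within 100 bp of the contig end and a distinct >= 50 bp segment
starting within 100 bp of the start, on the same strand. The 100-bp
terminal window is our choice — the smallest window consistent with
requiring 50-bp hits — and it is configurable (`circ_end_window`).
Requiring the same strand, and two distinct segments rather than one long
alignment spanning the whole contig, reflects what a wrapped read actually
looks like; a single full-length alignment is evidence of coverage, not
circularity.

**The alignment engine.** All nucleotide comparisons go through one
seed-and-extend engine (Rcpp): exact 15-mer anchors on both strands,
ungapped X-drop extension (drop 20, match +1, mismatch -2), merging of
overlapping segments per diagonal, and filtering by identity and length.
Ungapped extension is sufficient because every identity threshold in the
pipeline (>= 90%) sits far above the regime where gaps dominate, and it
makes the reported identity exact rather than alignment-dependent. On
score-tie plateaus the extension prefers the longer endpoint, matching
the Smith-Waterman convention; the test suite checks recovered region
boundaries against a Smith-Waterman oracle (Biostrings, same scoring,
prohibitive gap penalties since the synthetic generator is
substitution-only) within +/- 5 bp. E-values are not computed: every
search in scope carries identity/length thresholds that dominate the
printed E-value cutoffs, so Karlin-Altschul calibration would add nothing
but a second source of numerical disagreement.

**ANI and novelty.** "Overall ANI" is operationalized as the percentage
of the query covered by merged alignment regions at >= 95% identity and
>= 500 bp. This coverage reading is the only one consistent with class
cuts at 95/70: a mosaic genome sharing 75% of its length at near-perfect
identity should be "partial", which an identity-weighted average would
not deliver. ANI is query-normalized and therefore asymmetric; novelty
always uses the catalogue sequence as query. An identity-weighted variant
sits behind `ani_identity_weighted` for sensitivity analyses. Class
boundaries are inclusive at 95 and 70.

**Dereplication.** CD-HIT-style greedy clustering: contigs visited by
descending length (ties by id), each joining the first representative
with global identity >= 95%, where global identity is matching bases of
the best compatible segment chain divided by the shorter sequence length.
The printed protocol's phrasing ("100% sequence consistency for 95% of
the shorter genome") conflicts with the `-c 0.95` parameter it quotes; we
implement the `-c 0.95` semantics (95% identity over the shorter), the
reading consistent with the tool actually cited. Source-group
attribution consults all contigs in the workspace, including those
discarded during dereplication, from all samples.

**Viral clusters.** The homology graph uses merged coverage at >= 90%
identity with no minimum segment length, and keeps edges covering > 70%
of the larger and > 90% of the smaller genome. Markov clustering is
implemented from scratch: unit edge weights and unit self-loops, column
normalization, expansion/inflation cycles (inflation 4.0 by default) with
pruning at 1e-6, convergence when the maximum entry change falls below
1e-8, capped at 200 iterations (non-convergence warns and interprets the
current state). Clusters are read off as connected components of the
converged matrix's nonzero structure, so the result is a true partition;
node order is fixed lexicographically, making clustering deterministic.
Unit weights match a protocol that feeds filtered, unweighted pairs to
MCL; coverage-weighted edges would be a one-line change and are
deliberately not the default.

**Quantification.** Presence demands breadth > 0.5 and mean depth > 4,
both strict, with depth averaged over the whole contig (not only covered
positions). RPKM is reads/(kb)/(millions mapped); relative abundance
zeroes absent vOTUs *before* renormalizing, so present vOTUs sum to one
per sample. Shannon diversity uses natural log (the protocol is silent;
nats are stated so values are comparable). Rarefaction resamples the
sample pool 10 times and reports mean unique-vOTU counts over prefix
unions, which makes each resample's curve — and hence the mean curve —
non-decreasing by construction.

**Clades and lifestyle.** crAssphage requires length > 70 kb plus either
a significant hit to the prototypical polymerase/terminase (consumed as a
significance-flagged table; the protein route is recorded when both fire)
or >= 95% nucleotide identity over >= 80% of the contig. Gubaphage-like
labels propagate by co-clustering with labelled reference genomes.
Lifestyle scores bin at 0.3/0.5/0.7 with inclusive upper boundaries; the
virulent-to-temperate ratio pools each uncertain bin with its side by
default (`vt_strict_bins` switches to unambiguous bins only — the source
protocol is ambiguous, and both variants are provided rather than
guessed). A zero temperate-side denominator is flagged undefined, never
infinity. COG enrichment is a per-category 2x2 Pearson chi-squared test
without continuity correction at p < 0.001, requiring the novel
proportion to actually exceed the comparison proportion.

**Hosts.** Spacer matching is exact full-length substring search on both
strands; exactness gives a clean false-positive bound (a chance 25-bp
match has probability about 4^-25 per position) and a <=1-mismatch mode
exists behind `spacer_max_mismatch` since the original aligner settings
are unstated. Spacers shorter than 20 bp match but can never support high
confidence. tRNA links require >= 95% identity across 100% of the viral
gene. Evidence is counted per (virus, host species) as distinct spacer
sequences and distinct host tRNA genes; >= 2 spacers, >= 2 tRNAs, or 1+1
give high confidence. Host ranges are LCAs over a rank-labelled taxonomy
table; the interaction network keeps high-confidence evidence only,
collapsed to (viral cluster, host genus) edges.

## The synthetic-data generator

Real studies of this kind rest on terabytes of reads and a dozen external
tools; the package instead validates against data it constructs with
known truth. The generator emulates: clustered viral genomes (founders
6-12 kb, members at 1-3% substitution-only divergence and slightly
shorter, so each planted cluster's representative is its founder);
planted terminal repeats and junction reads; five founder/member
assembly-source patterns covering the long-read/short-read/both groups;
reference catalogues containing exact copies, 75% mosaics, or nothing
(the three novelty classes); lognormal(0,1) per-sample abundances with
placements giving present genomes comfortable margins above the
presence thresholds and absent genomes breadth under a third; detector
scores that sit clearly above or below each threshold (flip probability
`noise`, 0 in the validation suites); a >70 kb crAss-like genome with a
marker-protein hit; a bacterial contaminant that detectors "mistake" for
a virus and decontamination must remove; sub-5-kb fragments; and host
genomes with planted prophages, exact spacers (25-45 bp; deliberately
short ones for the low-confidence path) and copied tRNA genes, under a
balanced seven-rank taxonomy.

Substitution-only mutation is the default so realized identity is
analytically known, which is what makes exact oracles possible. What the
generator does *not* emulate: sequencing error, gapped divergence,
repeat-rich genomes, chimeric contigs, abundance-dependent assembly
quality. Passing the recovery suites therefore demonstrates that the
decision rules are implemented correctly, not that the upstream detectors
would perform equally well on real data — those tools are consumed, not
modelled.

## Problem sizes and numerical choices

The standard validation study uses 60 genomes across 5 samples (about 20
clusters), the dereplication suite 20 planted clusters, the circularity
suite 200 circular plus 1000 linear genomes, and the alignment-oracle
suite 50 pairs under 300 bp; these sizes give every rule multiple planted
positives and negatives while keeping the full suite comfortably fast on
a single core. Ties are always broken deterministically (descending
length then id; descending cluster size then smallest member id; fixed
lexicographic node order in MCL), so reruns with the same seed are
byte-identical — asserted end to end in the test suite. Degenerate inputs
are defined rather than accidental: empty placement tables give zero
coverage, an all-zero abundance pair makes Bray-Curtis an error rather
than a NaN, a zero temperate side makes the V/T ratio undefined rather
than infinite, and zero-margin enrichment categories are skipped with a
warning.

## Known limitations

The alignment engine is ungapped; genuinely gappy homology (large indels
within otherwise-identical regions) fragments into multiple segments,
which merged-coverage statistics absorb but per-segment identity does
not. The from-scratch MCL is dense and intended for catalogue-scale
graphs (thousands of nodes), not millions. Protein-space searches,
detector internals, taxonomy assignment of the viruses themselves, and
read mapping are out of scope by design: their outputs are inputs here.
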