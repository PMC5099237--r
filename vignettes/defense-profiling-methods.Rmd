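---
title: "Methods: defense-feature profiling of assembled metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: defense-feature profiling of assembled metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defenseprofiler)
```

## Scientific setting

Dense microbial communities, such as those hosted by marine sponges, are
continuously exposed to foreign DNA from phages, viruses and plasmids.
Prokaryotes defend themselves with, among other systems, CRISPR-Cas loci
(arrays of near-identical direct repeats separated by variable spacers
acquired from past invaders, flanked by *cas* genes) and
restriction-modification systems (RMS: a restriction endonuclease, REase,
paired with a methyltransferase, MTase, of the same type, plus a
specificity subunit for type I). Comparative metagenomics asks whether
such defense features are *enriched* in one habitat over another, which
requires (i) detecting the features on assembled contigs, (ii)
normalizing counts by sequencing effort, and (iii) comparing normalized
abundances across samples.

`defenseprofiler` implements that workflow as a reusable, fully tested
pipeline over standard tabular/FASTA inputs, together with a synthetic
metagenome generator that plants features with known coordinates so every
stage can be benchmarked against ground truth.

## CRISPR array detection

The detector is a seed-and-extend algorithm run under multiple parameter
*profiles*. Within one contig, every exact `seed_k`-mer occurring at least
twice is examined; occurrences whose consecutive periods lie in
`[repeat_len_min + spacer_len_min, repeat_len_max + spacer_len_max]` form
a chain, and each chain is extended left and right while **all** copies
agree exactly, bounded by `repeat_len_max` and by the minimum spacer
length. Chains whose extended repeat is shorter than `repeat_len_min`, or
whose gaps fall outside the spacer range, are discarded or split.
Overlapping candidates are resolved in favor of more repeat copies, then
longer repeats, then leftmost start — so the full chain of a locus always
beats fragmentary sub-chains.

Validation is separate from detection: an array is retained only if it
has at least `min_spacers = 2` spacers, every repeat copy is within
`max_repeat_divergence = 0.2` of the per-column majority consensus (ties
broken alphabetically), adjacent spacers have positional identity at most
`max_spacer_pair_identity = 0.6` (higher means a tandem repeat, not a
CRISPR), and all segment lengths lie in the configured ranges.

Published protocols of this kind run several independent detectors and
keep arrays confirmed by more than one, or arrays on contigs that also
carry *cas* genes. We reproduce the *logic* of that consensus without
shipping third-party binaries: one detector, run under a `strict` profile
(seed 8, repeat 19–48 nt, spacer 19–72 nt) and a `lenient` profile (seed
7, repeat 17–50 nt, spacer 15–80 nt, looser divergence). An array is
retained when hit by both profiles, or by one profile on a *cas*-carrying
contig. Arrays from different profiles overlapping by at least one base
are merged: union coordinates, structure of the hit with more repeat
copies. Because no published rule fixes which profile's parameters govern
validation of a merged array, we validate under each detecting profile
and keep the array if it passes at least one — the permissive reading,
consistent with treating profile agreement as confirmation.

The default length bounds span the defaults of the widely used detectors
(CRT, PILER-CR, CRISPRFinder); all are configurable through
`detection_params()`.

## cas typing and adjacency

*cas* genes are identified by mapping domain-annotation accessions
(COG/Pfam/TIGRFAM) through an editable table shipped in `extdata`; among
a gene's mapped hits the best e-value names it. Consecutive cas genes
(index gap ≤ 5) form a locus. Signature genes define the CRISPR-Cas type:
*cas3* → type I, *cas9* → type II, *cas10* → type III; conflicting or
missing signatures give "unknown" — the conservative choice, matching
the large unknown fractions such surveys report. An array is
*cas-adjacent* when a locus on its contig lies within
`max_gene_gap = 5` gene ordinals of the genes flanking the array; the
field's protocols never quantify "adjacent", so the window is explicit
and configurable.

## Spacer-target search

Protospacer search uses the published scoring exactly: match +1,
mismatch −1, gap open −5, gap extend −2, word size 7, E ≤ 0.1. A hit
requires an exact shared 7-mer on the examined strand (both strands of
each target are scanned); given a seed, the score is computed by a full
local (Smith–Waterman/Gotoh) dynamic program in C++, so whenever a seed
exists the reported score equals the exhaustive-DP optimum — the test
suite verifies this against an independent aligner on random pairs.

E-values use the Karlin–Altschul form `E = K·m·n·exp(−λS)`. λ is solved
numerically for the match/mismatch scheme under uniform base composition
(λ = ln 3 for +1/−1); gapped parameters are approximated by the ungapped
pair. K is a fixed default (0.35) documented as an approximate
calibration constant rather than derived from the lattice renewal
series: the published protocol delegates E-values to an external web
tool without stating its model, all score-level checks in this package
use raw scores, and K only shifts the reporting threshold
logarithmically (a factor of 3 in K moves the score cutoff by one
match). Both λ and K are configurable in `scoring_scheme()`.

A spacer with no hit is categorized "unknown"; a spacer with hits in
several target categories is counted once per category, which is why
per-category tallies may exceed the number of spacers with a target —
mirroring how published summary tables overlap. "Unique spacers" are
reported as *both* distinct-sequence and singleton counts, because the
printed tallies in the literature are ambiguous between the two
definitions.

## RMS completeness and clustering

REBASE-role hits are kept at query coverage ≥ 70 % (inclusive). A
complete system is an REase and an MTase of the same type within
`max_gene_distance = 4` gene ordinals; each REase pairs with its nearest
qualifying MTase (leftmost on tie), and type I records a specificity
gene in the window when present without requiring it. Same-type systems
whose index spans overlap or lie within 4 gene ordinals merge
transitively into one cluster; cluster counts are the reported RMS
counts.

Two readings deserve note. First, the source protocol's phrase "at least
four genes apart" contradicts its own proximity-based completeness
intent and its cited convention; we read it as *at most* four genes
apart and expose the threshold as a config default rather than silently
fixing it. Second, when one gene carries both REase and MTase domains
above threshold, the best e-value defines its single role (the
documented tie rule); a fused architecture can still be declared
explicitly by annotating the gene with the combined role token
`REase+MTase`, which counts as a complete system of span zero.

## Normalization, enrichment, and community profiles

Contig coverage is the zero-included mean of per-position depth; cpm
(copies per megabase) is coverage divided by the sample's total mapped
basepairs times 10^6. This gives the conservation identity
`sum(cpm_c · len_c) = 10^6` whenever depth and the total come from the
same mapping — checked at relative tolerance 1e−9 on every simulated
mapping. A feature instance contributes its *host contig's* cpm (not
per-gene depth), and feature cpm is the sum over instances.

Enrichment compares the arithmetic mean over sponge-role samples with
the seawater value and flags a side only when strictly greater than 1.5×
the other; a zero denominator with a positive numerator is enriched on
the positive side, both-zero is "none". The mean (not median) is used
for the sponge average — the published figure captions say "on average"
without further detail, and the mean is the convention in comparable
heatmap analyses.

Community profiles use a re-implemented lowest-common-ancestor
assignment: hits within the top 10 % of the best bit score are retained
(the common default of LCA classifiers; the protocol we follow says only
"default parameters") and the answer is the LCA of the retained taxids.
Bray–Curtis dissimilarity (`1 − 2·Σmin/(Σa+Σb)`) and complete-linkage
clustering (`stats::hclust`, deterministic for fixed input order)
summarize between-sample structure; dendrograms export as Newick via
`ape`. GC content excludes N from numerator and denominator, avoiding
deflated GC on gappy sequences. Reported percentages round half-up at
two decimals — matching printed tables, unlike R's banker's rounding.

## The synthetic world

`simulation_config()` states the benchmark world once: 20 contigs of
20–50 kb at GC 0.60 (sponge-like; a seawater-like sample uses GC 0.41
and zero planted features), 10 planted arrays (repeat 32 nt, spacer
36 nt, 3–6 spacers, mutation rate 0), half with an adjacent 3-gene cas
operon, 5 single-spacer decoy loci, 8 complete RMS pairs (3/3/2 across
types I/II/III, REase–MTase distance ≤ 4) plus 6 isolated decoy
singletons and a few sub-threshold-coverage hits, and per-position
Poisson depth around per-contig targets of 5–50×. Sizes are desk-scale
stand-ins for multi-gigabase assemblies; coverage and feature densities
are in the range such surveys report, and the seed is mandatory —
identical config and seed give byte-identical outputs.

Three construction details matter for interpreting green tests. Planted
spacers are regenerated until pairwise positional identity is ≤ 0.6, so
decoy rejection tests the tandem-repeat gate, not luck. The flanking
bases around each planted block are adjusted so the block is *maximal*
(no accidental one-base seed extension), making truth coordinates equal
the detector's maximal extension — otherwise "exact boundary" recovery
would be ill-posed. RMS features keep > 4 gene ordinals between each
other so planted systems never merge and decoys never acquire partners;
decoys are therefore rejected by the distance rule, not by chance.

What the generator does **not** emulate: real assemblies' repeat-induced
fragmentation, chimeric contigs, strain mixtures, non-uniform base
composition, HMM-scan noise in domain hits (hit tables are generated
directly, since the pipeline consumes annotations), and read-level
sequencing error. A green recovery test establishes correctness of the
detection and bookkeeping logic under the stated world, not performance
on real sponge metagenomes.

## Degenerate inputs and numerical choices

Readers reject non-ACGTN characters, duplicate ids and empty sequences
at load time (fail early). Depth tables are 1-based; absent positions
are depth 0 when the contig length is known. The contig filter keeps
length ≥ 1000 — the source protocol states both "≤ 1000 discarded" and
"≥ 1000 used", and we follow the reading consistent with its summary
table's "contigs > 1000 bp" label; the boundary is configurable.
Consensus ties break alphabetically; overlapping candidate resolution
and cluster merging are deterministic and order-invariant (tested).
Zero-variance vectors, all-zero profiles, empty references and empty
catalogues raise explicit errors or warnings rather than NaN.

## Known limitations

The detector's exact-extension step shortens repeats at high mutation
rates instead of modeling indels; arrays with diverged repeat copies are
found only insofar as a mutation-free seed chain survives (the truth
ledger carries an `expected_detectable` flag computed from exactly that
criterion). Subtype assignment is a thin accession lookup, not a
phylogenetic classification. E-values are approximate (see above).
Alignment *start* coordinates follow a per-cell traceback that is exact
for score and end position but may begin a gap run one cell off in rare
affine-gap geometries; scores and end coordinates are exact.
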