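---
title: "Methods: reconstructing the history of a hybrid yeast genome"
author: "hybridarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing the history of a hybrid yeast genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridarch)
```

# The problem

An allopolyploid yeast genome is a mosaic of two parental subgenomes:
one nearly identical to an extant reference species (subgenome A), one
from a related but unidentified parent (subgenome B, here ~7% diverged,
synonymous divergence peak *K*~S~ ≈ 0.16). After hybridization the genome
keeps evolving: homogenization (loss of heterozygosity, LOH) overwrites
one homeolog with the other, reciprocal crossovers join A and B
chromosome arms, break-induced replication (BIR) copies one chromosome
end over another, individual genes acquire disabling mutations, and —
decisively for the life cycle — one of the two mating-type (MAT) loci can
be destroyed by the very endonuclease (HO) that normally drives
mating-type switching, leaving a functionally haploid genome that can
switch, mate with itself and sporulate.

`hybridarch` infers each of these events from sequence alone, and ships a
simulator that generates hybrid genomes with complete ground truth so
that every inference step is testable by recovery.

# Subgenome assignment

## Synonymous divergence (NG86 + Jukes–Cantor)

For each hybrid gene, the best reference homolog is found by a
shared-k-mer prefilter (k = 5 amino acids, ≥ 3 shared) followed by local
alignment (BLOSUM62, gap open 11 / extend 1); the top scorer is the
homolog, ties broken by identity then subject name, and hits covering
< 50% of the shorter protein are discarded (community-standard scoring;
the coverage rule guards against domain-level spurious pairs). The CDS
pair is then aligned codon-wise by projecting a global protein alignment
back onto the nucleotides, so gaps only ever occur in multiples of 3 and
gapped columns are excluded from counting. Equal-length protein pairs
above 70% identity skip the dynamic program — their optimal global
alignment is gapless.

Divergence is counted in the Nei–Gojobori (1986) framework: each codon
position contributes synonymous "site" mass equal to the fraction of its
three possible single-nucleotide changes that preserve the amino acid
(changes to stop codons count as nonsynonymous); codons differing at
several positions are resolved by averaging the synonymous/nonsynonymous
step counts over all minimal mutational pathways, excluding pathways
through stop codons unless all are blocked. Proportions are corrected
with Jukes–Cantor, *K* = −(3/4)·log(1 − (4/3)·*p*); *p*~S~ ≥ 3/4 is
saturation and *K*~S~ is undefined there. We deliberately do not use a
maximum-likelihood codon model: at the divergences that matter for the
classifier (*K*~S~ ≤ 0.25) the counting estimator and ML agree closely,
and the classification thresholds, not the estimator family, carry the
scientific weight. Alignments under 30 codons are flagged low-confidence
and yield no label.

## Labels, pairs, categories

Labels: A if *K*~S~ ≤ 0.05, B if 0.05 < *K*~S~ ≤ 0.25, N otherwise or if
no homolog was found. Boundary values go to the lower class (the
thresholds are inclusive "≤"). Homeolog pairs *within* the hybrid are
reciprocal best hits of the hybrid proteome against itself (self-hits
excluded) — reciprocity prevents one gene from anchoring two pairs, and
pairing is deliberately independent of the reference-based labelling.
Every gene then falls in exactly one of 7 categories: `A-in-A:B`,
`B-in-A:B`, `A-in-A:A`, `B-in-B:B`, `A-unpaired`, `B-unpaired`, `N`
(a labelled gene paired with an N gene counts as effectively unpaired).

# Chromosome archaeology

## Breakpoints and events

An adjacency is a pair of genes consecutive on a chromosome (up to
`max_gap` unmapped genes between them; default 2, and 0 in all oracle
tests). It is broken in the other genome if the homologs are on
different chromosomes, not adjacent, or inconsistent in relative
orientation (an inversion-internal adjacency — reversed order, both
strands flipped — is intact). Because every inversion or reciprocal
translocation creates exactly two breakpoints, the event estimate is
⌊*b*/2⌋, with a warning on odd *b*. The simulator enforces
no-breakpoint-reuse by construction (each accepted event must raise the
breakpoint count by exactly 2), so recovery is exact: *b* = 2 × events.

## LOH tracts

LOH converts A:B pairs into A:A or B:B pairs, and both members of the
homogenised pair show up as runs of same-label-pair genes. Tracts are
maximal runs (per category) of at least `min_run` genes (default 3 — the
multi-gene stretches reported for real hybrids are unquantified, and 3
suppresses single-gene conversion noise); N genes are transparent. The
background class of a tract is the majority label of its *local* flanks
(up to 10 A/B genes per side) rather than a whole-chromosome majority: on
chromosomes that recombination has turned into part-A/part-B mosaics the
chromosome-wide vote misstates the local background, while flank voting
remains deterministic and correct. Note that the donor-side run of a
pair sits in its own subgenome's territory, so `tract_class ==
background` there — the overwritten-side run is the one carrying the
usual "A island in B" appearance.

## Recombination junctions

Crossover junctions are persistent background switches among genes in
A:B pairs only (LOH-pair, unpaired and N genes are transparent), with at
least `min_run` genes of each class on their own side. LOH tracts cannot
masquerade as junctions because their genes are not in A:B pairs. The
HO-catalysed MAT translocation produces two bona fide A|B junctions and
is counted as such.

## BIR ends

BIR copies a donor chromosome end over a recipient end, making the two
ends identical from the initiation point to the telomere. In a complete
assembly both copies are present, pair with each other, and appear as
*terminal runs of same-label pairs*; in a collapsed assembly one copy is
missing and the survivors appear *unpaired*. The detector accepts both
appearances as candidate ends (terminal runs of ≥ `min_bir_genes`
same-label genes, default 5) but only *flags* a candidate once a partner
end with ≥ 95% sequence identity over the shorter terminal span is
found — BIR is, by definition, a two-ended signature; candidate runs
without partners (e.g. homeologs widowed by the event) are reported
separately. Each homogenised end pair yields one flag.

## Telomere consensus

Each chromosome end contributes a terminal window (left ends
reverse-complemented); the shortest tandem period at the terminus is
detected by suffix periodicity, reduced to its primitive unit, and units
are normalised to the lexicographically minimal rotation before the
majority vote. Both the canonical and the as-found orientation are
reported, with minority units listed.

# MAT locus forensics

## Cassette discovery

The X and Z repeats flanking MAT/HML/HMR are found de novo: 16-mer
multi-copy intervals (≥ 3 copies genome-wide), filtered for simple
tandem arrays (telomeres) and for *diffuse* intervals — diverged
homeologous duplications (e.g. a BIR donor + copy + their homeolog)
share only a fraction of their k-mers and fail a 90% density test,
whereas true repeat copies are contiguous. An HMR-type cluster, where
the short a-specific Y region stays below the copy-number threshold,
yields clean seed probes for the two flanks; each probe is then refined
by anchor-k-mer consensus extension (extend while ≥ 80% of the anchor's
exact occurrences agree per column), which clips linker contamination
and tolerates truncated fragment copies. The longer refined repeat is X
(654 bp here), the shorter is Z (266 bp). A locus with both flanks and a
Y region between them is intact; a lone flank is a fragment, and
complementary X-side and Z-side fragments are paired into one broken
locus. Idiomorphs are called from the Y region (two gene stubs — alpha1
and alpha2 — make an α cassette; the single-stub a cassette carries only
a2; there is deliberately no a1 gene anywhere). Telomere-proximal loci
(within min(30 kb, 12% of the median chromosome length)) are silent
cassettes (HML if α, HMR if a); internal loci are MAT.

## HO cleavage registration

The cleavage core `cgcagca` always forms the first nucleotides of the Z
region. The enzyme leaves a 4-nt 3′ overhang, but the exact
phosphodiester positions are not biochemically established for this
genus, so the registration is a single documented constant: the **top
strand is cut after the 4th core nucleotide and the bottom strand at the
5′ core boundary**, giving a 3′ overhang whose sequence is the first 4
core nucleotides (`cgca`). (The mirrored registration — top cut at the
boundary, bottom cut 4 nt in — yields a 5′ overhang and is therefore not
usable.) Cleavage and re-ligation are exactly inverse, which every test
asserts.

## NHEJ junctions

A repair junction is decomposed against its two donors as left prefix +
insert + right suffix, anchored at the known cut positions when
available (inferred by maximal prefix/suffix matching otherwise). A
negative insert is microhomology; a positive insert is classified as a
duplication of right-donor sequence immediately 5′ of the right cut, a
tandem duplication of the left prefix end, a combination, or an
untemplated insertion. The simulator's MAT breakage plants the
documented pattern — a 5-bp duplication (`acaac`) from the intergenic
side, a 2-bp duplication (`ca`) from the MAT side (the 2 bp fall inside
the cleavage core, positions 3–4), zero microhomology — and the analyzer
recovers it exactly; a 1,000-trial property test covers duplication
lengths 0–10 and microhomologies 0–6.

## Splice-site shifts

Given an intron-bearing gene model, any non-AG acceptor triggers a scan
for the nearest downstream AG (window 50 nt); the transcript is
re-spliced with the shifted acceptor and translated. The frame is
preserved iff the shift is a multiple of 3. The simulator's B-subgenome
alpha2 genes carry the AG→AC acceptor mutation in intron 2 with the next
AG exactly 2 nt downstream; re-splicing truncates the 211-residue
protein to 57 residues, which the analysis reproduces.

# Gene integrity

Pairs in which one predicted protein is shorter than 90% of the other
(strict inequality; proteins, not nucleotides, because indels and stops
act on the product) are flagged and the mechanism typed from the CDS: a
length difference that is not a multiple of 3 is a frameshift indel,
localised at the first divergence; otherwise an in-frame premature stop
is sought. Cross-strain comparison partitions calls into shared (same
gene, same mechanism class) and strain-unique sets. In-frame introns
(length ≡ 0 mod 3, no stop in the retained frame, checked by translating
the unspliced transcript) and +1 frameshift sites (`CTT-A-GTT` /
`CTT-A-GGC` at codon boundaries, zero-frame stop within 30 codons, +1
frame open for ≥ 30 codons — a reference-free stand-in for the
homology-based identification used on real genes) complete the screen.

# The simulator

The generator replays the inferred history: a parent A with random valid
genes (start codon, no internal stop, stop codon; default 1,000 genes of
500 codons on 8 chromosomes, 200-bp spacers, telomeres of 20 ×
`tgtgggtgggg` at every end, reverse-complemented on left ends); a parent
B derived by codon-wise divergence; 17 inversions/reciprocal
translocations at intergenic midpoints with no breakpoint reuse;
hybridization into 16 chromosomes with `_A`/`_B` suffixes and a truth
table; then LOH → recombination → BIR → disablements (a fixed order, for
reproducibility only) and finally the MAT architecture and breakage.

Divergence model: each internal codon receives Poisson(3·*K*~S~)
proposed single-base changes, uniform over the nine neighbours;
synonymous proposals are always accepted, nonsynonymous with probability
ω (default 0.05), stop-creating proposals rejected. A uniform proposal
is synonymous with probability *s*~c~/3, so accepted synonymous events
per synonymous site have expectation exactly *K*~S~ for every codon —
the quantity the downstream estimator is built to recover (calibration:
mean estimate within 3 SE of 0.16 at 200 genes × 500 codons). Intergenic
spacers substitute at the same per-site event rate; telomeres and
start/stop codons are untouched.

Default event numbers mirror the observed genome: ten LOH tracts of 1–8
genes including one 8-gene tract (the A:A / (A:A+B:B) proportion of
0.78 sets the donor direction), 3 crossovers, 3 BIR events of 8 genes,
10 disablements per subgenome (alternating 1-bp indels and premature
stops, redrawn until actually disabling, i.e. protein ratio < 0.9).

Placement constraints exist so that ground truth stays well-defined, not
to make detection easier than reality: tracts are buffered by one gene
(adjacent tracts would merge into one run), crossovers require three
clean A:B genes on each flank of both cut points (a junction without
flanks is undefined, and unflanked events are excluded from the
recovery criteria anyway), the cassette chromosomes are excluded from
LOH/crossovers/BIR (the MAT breakage must not bisect another event),
and the breakage's intergenic cut lands in bona fide A territory —
mirroring the real event, which joined A-subgenome intergenic sequence
to the B MAT locus.

What the simulator does **not** emulate: realistic intergenic sequence
composition, gene families and paralogy (every gene is unique, which
makes homology search unambiguous), gene length variation, introns in
ordinary genes, rDNA, mitochondria, assembly collapse (both BIR copies
are emitted), and meiosis. Recovery rates on simulated data are
therefore upper bounds for real genomes, where paralogy and annotation
error add noise the tests do not model.

# Numerical and reproducibility choices

Internal coordinates are 1-based inclusive (GFF3); BED exports are
0-based half-open with a round-trip test. All randomness flows from a
single integer seed; equal configurations give byte-identical FASTA/GFF3
and JSON summaries. Ties in best-hit scoring break by identity then
lexicographic subject id; category boundaries, threshold boundaries, and
the HO registration are all inclusive/fixed constants documented above.
Desk-scale test problems use 120–240 genes of 100 codons (estimator
noise at that length moves a few percent of B genes over the N
threshold, which the tests budget for); calibration and acceptance
checks use the default 1,000-gene, 500-codon configuration where label
accuracy exceeds 99%.

# Known limitations

* The subgenome labeller needs a reference parent; no reference-free
  (k-mer phasing) mode is provided.
* NG86+JC saturates near *K*~S~ ≈ 0.75 and the classifier is only
  meaningful well below that.
* The MAT cataloguer assumes cassettes share near-identical X/Z flanks
  in a consistent orientation and needs at least one HMR-type locus to
  seed probe derivation; genomes with fewer than 3 repeat copies fall
  back to an empty catalog (probe mode can be driven with explicit
  `x_repeat`/`z_repeat` sequences through the simulator spec).
* Rearrangement-scenario reconstruction (which events, in which order)
  is out of scope; only the breakpoint count and the two-breakpoints-
  per-event estimate are computed.
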