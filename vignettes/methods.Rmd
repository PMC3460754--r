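---
title: "Detecting host-to-parasite horizontal gene transfer: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting host-to-parasite horizontal gene transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloHGT)
```

## The inference problem

A holoparasitic plant lives embedded in its host's tissue, creating an
unusually permissive interface for the exchange of nucleic acids. Given
transcriptomes of the parasite (*Rafflesia*-like, a Malpighiales) and
its obligate host (*Tetrastigma*-like, a Vitaceae), plus reference
genomes spanning the angiosperm tree, the question is: which parasite
transcripts were acquired horizontally from the host lineage rather
than inherited vertically? The operational signal is gene-tree/species-
tree discordance: a parasite transcript whose gene-tree sister is the
host clade, with adequate bootstrap support, is a horizontal gene
transfer (HGT) candidate; one placed with the parasite's closest
organismal relatives is vertical (VGT); everything else is left
unassigned.

phyloHGT implements this classification together with the three
supporting analyses that make it credible: control-taxon background
rates (how often does non-HGT discordance mimic the signal?), genomic
integration verification from genomic-DNA reads (is the "transferred"
transcript really in the parasite's genome, i.e. not host
contamination?), and coding-property convergence (do parasite genes
drift toward host-like codon usage?).

## Classification model and its assumptions

Each homolog cluster contributes one gene tree with per-edge bootstrap
supports (the RAxML convention: the integer label of an internal node
is the support of the edge subtending it). Clusters are retained only
when they contain the outgroup (*Oryza*), the focal taxon, at least one
close relative (*Manihot*/*Populus*/*Ricinus* for the parasite) and the
host-side genome (*Vitis*) — otherwise the VGT/HGT dichotomy is not
testable in that tree. Trees are rooted on the outgroup.

`classifyTip()` ascends from the focal tip to the first ancestor whose
other descendants include a non-focal tip. Other tips of the focal
genome encountered on the way (in-paralogs from the assembler) are
treated as part of the focal lineage and skipped, because transcripts,
not clusters, are classified. The sister set is evaluated as a whole —
for a polytomy every genome in it must fall inside one rule set — and
the support used is that of the edge subtending the (focal ∪ sister)
clade. When that edge is the root edge there is no support to quote and
the transcript is conservatively unassigned. Sister sets containing any
other reference taxon (*Aquilegia*, *Arabidopsis*, *Carica*,
*Medicago*, *Mimulus*, *Oryza*) are unassigned as well.

Assumptions worth stating: orthology assessment is taken as given (the
cluster map is input); incomplete lineage sorting and hidden paralogy
are not modelled but are *measured* collectively by the control-taxon
background rate; and a transfer is only detectable if the donor lineage
is represented in the cluster.

The bootstrap threshold τ defaults to 50 (percent of bootstrap
replicates). `sweepThresholds()` re-evaluates the calls at τ = 50, 55,
60, 65, 70 and reports HGT% among resolved transcripts
(#HGT/(#HGT+#VGT)); because clusters are classified once and
thresholded post hoc, the resolved set at a higher τ is a subset of the
resolved set at a lower τ by construction. An empty resolved set yields
an undefined percentage (NA), never zero.

Control runs (`controlConfig()`) re-run the identical machinery with
*Manihot* or *Ricinus* as the focal taxon and *Vitis* still as the
"transfer" side. Neither control is a parasite, so its host-sister rate
estimates the combined contribution of every non-HGT source of
discordance at the same τ.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study
conditions under which the pipeline's claims are checked.

Per cluster it (1) restricts the accepted 12-taxon species topology to
a random subset that always satisfies the retention filter (optional
taxa kept with probability `taxonKeepProb` = 0.5); (2) with probability
`hgtFraction` detaches the parasite tip and re-attaches it as sister to
*Vitis* — HGT is simulated at the tree level by regrafting because the
classifier consumes trees, and regrafting is exactly the operational
definition of the signal; (3) with probability `noiseFraction` applies
one random NNI rearrangement, emulating gene-tree estimation error; (4)
draws branch lengths i.i.d. exponential (rate `branchRate` = 10, i.e.
mean 0.1 substitutions/site, a typical interspecific depth); and (5)
draws integer supports per internal edge — uniform on 85–100 for edges
present in the noise-free tree, 30–70 for edges created by the NNI —
because tree inference itself is out of scope and the classifier
consumes only the support numbers.

Defaults: 200 clusters; `hgtFraction` = 0.05 (the same order as the
empirical parasite-side rate, but high enough that a desk-scale run
contains tens of events); `noiseFraction` = 0.1.

Sequences: codon-usage conservation within clades is emulated
hierarchically — one 61-codon profile per clade from a symmetric
Dirichlet (`cladeConcentration` = 3; smaller = clades more distinct),
then one profile per genome from a Dirichlet centred on the clade
profile with concentration `codonProfileDivergence` = 200 (larger =
genomes within a clade more alike; in the limit they coincide with the
clade mean). Transcripts are i.i.d. codon strings from the genome
profile, 100–300 codons, so lengths are multiples of 3 and contain no
internal stop codons. Parasite transcripts get a genomic copy that with
probability `intronRate` = 0.5 (about half of verified transfers showed
an intron) carries one inserted GT..AG intron of 60–200 bp, placed so
that at least one fragment length (25 bp) of exon flanks each side.
cDNA reads are exact substrings of transcripts with per-transcript
counts from `expressionModel` (Poisson with log-normal mean, meanlog =
log 50, sdlog = 1 — a heavy-tailed expression distribution); gDNA reads
are exact substrings of the genomic copies at `gdnaCoverage` = 2-fold.
Reads are error-free: the verification contract is zero-mismatch
matching, so planted errors would only exercise the rejection path,
which unit tests cover directly.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: sequencing error and quality
variation, indels and alignment uncertainty, assembly chimerism and
fragmentation, paralog misassignment in the cluster map, rate variation
across sites and lineages, biased (non-uniform) read coverage, and any
selective process generating codon convergence (profiles are drawn, not
evolved). The pipeline's statistical behaviour under those features
must be judged on real data.

All randomness flows from the single `seed`; identical configurations
reproduce byte-identical studies (tested).

## Verification, introns, divergence

Zero-mismatch alignment of 25 bp fragments is mathematically exact
substring search, so `mapFragments()` is specified (and property-tested)
as equivalent to a naive scan; the implementation concatenates the
transcripts with an N spacer and uses Aho–Corasick matching
(`Biostrings::matchPDict`) for large fragment sets. N-containing
fragments can never match exactly and are skipped. Verification
requires ≥ 1 gDNA fragment hit by default (`minHits` configurable): the
most permissive reading of "positively mapped", stated in the output
rather than hidden.

Intron detection anchors on the two colinear fragment blocks of a split
read, extends each anchor base-by-base to the exact junction, and
requires the blocks to be adjacent in cDNA coordinates. When the
junction is ambiguous (the intron's first bases equal the next exon
bases, the classic splice-placement ambiguity), the placement whose gap
starts with GT and ends with AG is preferred; otherwise the maximal
left extension is reported. Reads with a single anchor and an unmapped
overhang of ≥ 8 bp (shorter overhangs are indistinguishable from
chance) yield partial calls whose unobserved motif flag is NA rather
than FALSE. With the default read length a multiple of the fragment
size, every intron fully spanned by a read with ≥ 25 bp in each
flanking exon is guaranteed to contain fully-exonic anchor fragments on
both sides, which is why the recall property holds at 100%.

Divergence uses a global Needleman–Wunsch alignment with match +1,
mismatch −1, gap −2 per position (no alignment method is canonical for
this summary; the scores are fixed defaults reported in metadata) and
counts mismatched columns over aligned non-gap columns.

## Expression

The overlap-window normalization R = N/(L − k + 1 + l − k) is evaluated
with the denominator grouped as written: the number of distinct
placements at which a read of length l can overlap a transcript of
length L by at least k bases. With k = l = 25 the boundary case L = 25
gives denominator 1. The flat rendering of this formula is ambiguous;
this grouping is the only one that matches the minimum-overlap counting
logic and keeps R finite and positive, so the package fixes it and
exposes the components (N, L) alongside. A read counts toward every
transcript at least one of its fragments matches — no fractional
assignment, the simplest deterministic rule, recorded in the output.
RPKM is computed from the raw counts N (whether the original
normalization chain applied RPKM to N or to R is unknowable from the
formula alone, so both columns are emitted and either convention is
inspectable).

## Coding properties

Profiles concatenate three independently normalized blocks (4
nucleotide, 16 overlapping dinucleotide, 61 in-frame sense-codon
frequencies; stop codons excluded from numerator and denominator; a
trailing partial codon dropped; N-containing windows excluded). Per-
block normalization makes the blocks contribute comparably to the χ²
distance; joint normalization (a single division by total count) is
available via `jointNormalize = TRUE` and recorded where used. The χ²
distance Σ(pᵢ−qᵢ)²/(pᵢ+qᵢ) skips features with pᵢ+qᵢ = 0 — the standard
symmetric histogram form.

Affinity calls compare the smallest distance to the relative side
(*Manihot*/*Ricinus* by default; *Populus*, not named in the two-way
comparison this mirrors, is excluded by default and can be added) with
the smallest distance to the host side (*Vitis*). Exact ties classify
as relative-like — the direction biased *against* the convergence
claim. A cluster lacking a homologue on either side excludes the
transcript with a log message instead of defaulting.

The excess of host-like calls is tested with an exact upper-tail
binomial test. The null proportion is deliberately explicit: it
defaults to the larger of the two control-genome host-like rates
(`p0` configurable), because a symmetric-choice null of 1/3 would
conflate clade-level codon conservation with convergence. The
expression–affinity association uses Spearman rank correlation on RPKM
versus the affinity margin: expression is heavy-tailed, so a rank
method is the robust default.

## Numerical and degenerate-input choices

- Welch's t test: two constant equal samples give t = 0, p = 1; two
  constant unequal samples are an error (infinite t), not a silent 0.
  Two-sided p-values throughout, since the comparisons are reported as
  non-directional.
- The substitution-rate proxy is the focal tip's terminal branch length
  (substitutions/site) — the minimal tree-derived proxy requiring no
  extra inference; root-to-tip distance is available behind
  `rootToTip = TRUE`, and every report names the proxy used. Whether a
  different rate measure underlies the original boxplots is unknowable
  from the figures, so the choice is flagged, not guessed.
- Outgroup conflicts: when outgroup tips are non-monophyletic the tree
  is rooted at the edge maximizing (outgroup tips − non-outgroup tips)
  on one side and flagged `outgroupConflict` instead of being dropped.
- Percentages with empty denominators are NA ("undefined"), never 0.
- The binomial tail is computed via `pbinom(..., lower.tail = FALSE)`,
  which is exact in double precision down to the underflow limit
  (~1e-308), far below any threshold used here.
- The species panel: the accepted relationships are stated for twelve
  taxa, but only eleven genomes are enumerated in the source material;
  the panel is completed with *Carica* (a sequenced Brassicales of the
  same era, role "other"). Nothing downstream depends on the twelfth
  taxon; it only widens the "unassigned" sister vocabulary.

## Problem sizes

The test suite and the acceptance script run the generator at the sizes
the analyses need, chosen once: 1000 clusters for parameter recovery
and background rates (binomial intervals at h = 0.05 are informative at
that n), 150 clusters with 0.8-fold gDNA coverage for verification
parity (coverage low enough that parity is a non-trivial statement), 60
clusters at intron rate 1 and 4-fold coverage for split-read recall,
100 + 300 draws for affinity recovery and its chance baseline, and 400
replicates for the 5%-level calibration of the Welch and Spearman
tests.

## Known limitations

Placement-based HGT inference cannot see transfers from donors missing
from the cluster, and reconciliation-based methods (which model
duplication/loss explicitly) are out of scope. The intron caller
requires exact cDNA adjacency of the flanking blocks, so genomic copies
with small deletions near the junction escape it. The divergence
aligner is a fixed-score global alignment, not a model-based distance.
And all power statements derive from the generator's idealized
conditions listed above.
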