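---
title: "Methods: discovering and characterizing complete phage genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and characterizing complete phage genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagering)
```

phagering recovers likely-complete phage genomes from whole-community
metagenome assemblies and characterizes them: host prediction from CRISPR
spacers, anti-CRISPR candidate screening, detection of
diversity-generating retroelements (DGRs), marker-based clustering, and
abundance profiling from virome reads. This vignette explains the models
and procedures, the parameters that matter, the numerical choices, and
what the synthetic-data tests do and do not demonstrate.

## Circularity screening

Short-read assemblers emit a contig assembled from a circular template
with an exact duplicate of its first *k*-mer-scale bases at the end.
`find_terminal_repeat()` reports the longest `r` with
`prefix(r) == suffix(r)` and calls the contig circular when
`r` lies in 50–200 bp, the range of typical assembly *k*-mers. Choices:

* **Exact matching.** Terminal overlaps are assembler artifacts — exact
  *k*-mer copies — so no mismatch tolerance is allowed, and `N` never
  matches.
* **Longest qualifying repeat.** Nested exact repeats make shorter ones
  redundant.
* **Over-long repeats** (`r` above the window, up to `L/2`) are reported
  as non-circular with reason `repeat_exceeds_max`: the window is an
  artifact filter, not a claim about repeat biology.

`canonicalize()` trims the duplicate and returns the lexicographically
least rotation, so every rotation of the same circle maps to one string;
all downstream stages operate on canonical sequences, which makes the
pipeline rotation-invariant by construction.

## Gene calling and amber reassignment

ORFs are called deterministically: maximal start(ATG/GTG/TTG)-to-stop
reading frames of at least `min_aa = 30` residues, both strands, with
origin wrap on circular contigs (`end` may exceed the contig length).
Coordinates are 0-based half-open and include the stop codon, so the
protein length is `(end - start)/3 - 1`. A trained gene caller would
refine boundaries, but no downstream decision here depends on boundary
accuracy — only on whether a marker-matching ORF exists.

Some gut phages read the amber stop TAG as glutamine. The
`amber-gln` code differs from the standard code only at TAG.
`assess_code_reassignment()` prefers an external amber-suppressor tRNA
annotation when provided (annotation dominates); otherwise it falls back
to a coding-density heuristic: re-call ORFs under both codes and switch
to `amber-gln` when coding density (fraction of bases covered by at
least one ORF) gains at least 10 percentage points. TAG read-through can
only lengthen ORFs, so the gain is never negative; a genuine
reassignment restores whole genes that the standard code shatters into
sub-threshold fragments, while a standard-code gene-dense genome gains
only marginally. The threshold is deliberately conservative and assumes
gene-dense input; on mostly non-coding sequence the density gap between
the two codes is noisier.

## Marker profiles and the two-round decision rule

A contig is called **phage** when it exceeds 3 kb (strictly) and one of
its ORFs matches a hallmark-gene profile — terminase large subunit
(TerL), major capsid protein (MCP), or portal — below the round-2
e-value cutoff.

Profiles are fixed-width position-specific log-odds matrices built from
aligned protein families (`build_profile()`): columns with more than 50%
gaps are dropped, residue counts get a pseudocount of 0.5, and scores
are `log(freq/background)`. The background is the amino-acid
distribution induced by uniform random codons (61 sense codons), which
is the right null for ORFs called on random metagenomic DNA — not the
uniform distribution over 20 residues. Full profile-HMM machinery
(insert/delete states) is not reimplemented: hits here are best
**ungapped local** alignments (a min-length-constrained best-segment
scan over all diagonals, at least 25 aligned columns so hits are
domain-scale). The contract preserved is hit/no-hit at an e-value.

Significance is empirical: each profile is calibrated once against 500
decoy proteins sampled from the background composition (lengths 0.5–2x
the profile width), a Gumbel location/scale is fitted by the method of
moments, and the e-value of a score is its Gumbel tail probability times
the number of proteins searched. By construction the expected number of
false hits at threshold `t` is `t` per profile, which the decoy tests
verify.

Classification is two-round, mirroring how reassigned codes are handled:
round 1 searches all ORFs called under the standard code at `e1 = 0.05`
(a wide net, including non-marker phage profiles such as a reverse
transcriptase); contigs with any round-1 hit are re-assessed for amber
reassignment and re-translated; round 2 re-searches everything at
`e2 = 0.01`, and only round-2 TerL/MCP/portal hits make a contig phage.
A configuration with `e2 > e1` is rejected. The packaged marker
alignments are synthetic families (generated once, with conserved and
variable columns and a gap fraction) — stand-ins for curated marker
collections, labelled `*_synthetic` accordingly; real analyses should
load curated alignments through the same `load_marker_profiles()`
surface.

## Dereplication

Genomes are dereplicated at **95% ANI over 80% of the genome length**.
`estimate_ani()` anchors exact 16-mer seeds shared by the two genomes,
groups them into syntenic blocks by diagonal (gap tolerance 2 kb),
counts identity base-by-base over each block, and reports the
length-weighted identity plus the fraction of the *shorter* genome
covered (the convention of the common ANI tools; the coverage
denominator is otherwise ambiguous). Both orientations are tried;
argument order is canonicalized internally so the estimate is exactly
symmetric. Clustering is greedy longest-first first-fit
(`dereplicate_genomes()`), which is deterministic and reproduces the
stated thresholds at desk scale; an all-pairs brute-force oracle in the
test suite confirms the greedy result on 30-genome inputs. Rotated
relatives are handled naturally: a rotation splits the alignment into
two diagonals whose blocks jointly cover the genome.

Protein clustering (`cluster_proteins()`) is greedy centroid clustering
with ends-free pairwise alignment (BLOSUM62): identity over aligned
columns, coverage over the member's own length; 95%/50% for genome-wide
protein dereplication and 50% identity for marker clustering.

## Host prediction and the anti-CRISPR screen

`match_spacers()` is ungapped seed-and-extend from exact 8-mer seeds on
both strands with no complexity filtering; a match is accepted when the
spacer is at least 95% identical over at least 95% of its length
(identity over the aligned span, coverage over the full spacer — on a
32-nt spacer one substitution passes at 96.9%, two fail at 93.8%).
Circular genomes are searched across the origin. Host taxonomy
propagates from matching spacers; phages targeted by two or more genera
are flagged, as are protospacers shared verbatim between phages.

The anti-CRISPR screen (`screen_acr()`) is a four-criterion conjunction
over an externally supplied per-protein score in [0, 1]: (1) mean score
of the protein's 50%-identity cluster at least 0.9, (2) directon of at
most 5 genes, (3) an HTH-domain protein somewhere in the same directon,
(4) no strong database hit anywhere in the cluster. A **directon** is a
maximal run of adjacent co-oriented ORFs with intergenic gaps of at most
250 bp (configurable; the unit is not standardized in the literature).
The HTH criterion is satisfied by any member of the protein's own
directon; a flag to widen to neighboring directons is deliberately not
offered until a use case demands it. The scoring model itself is an
input — `acr_standin_scores()` is a transparent fixture heuristic
(short, lysine-rich, charged), not a validated predictor.

## DGR detection and the adenine-bias hallmark

DGRs diversify a variable repeat (VR) by copying a template repeat (TR)
through an error-prone reverse transcriptase that mutates specifically
at template adenines. Detection is two-stage
(`find_repeat_pairs()`):

1. **Stage 1** scans a 10-kb window centered on the annotated RT for
   near-exact repeat pairs: at least 80 bp at 85% identity or better
   (typical DGR repeats are 50–150 bp). The RT locus is an input — RT
   annotation is upstream of this module.
2. **Stage 2** re-searches each stage-1 template genome-wide, both
   strands, ungapped, at 75% identity or better over at least 50% of the
   template — catching VRs far from the cassette.

Repeat extension scores +1/−2 (match/mismatch), the scheme that sustains
ungapped extension above ~67% identity, and candidate segments are then
filtered by the stated identity and length; the member of a pair closer
to the RT is designated the template. Because each reported pair is an
independently trimmed segment, `dgr_adenine_report()` projects every VR
onto the columns of the longest template in its group through its own
template offsets (padding with `N`, which never counts as substituted)
before testing.

The hallmark statistic formalizes "substitutions confined to template
adenines": a TR column counts as substituted when **any** VR differs
there; with `n` substituted columns total and `p` the fraction of
template positions that are adenine, the p-value is the binomial tail
`P(X >= n_A_substituted | n, p)`. A repeat is hypervariable when
`p < 0.01` and at least 3 adenine columns are substituted (the count
floor guards against trivially small alignments). The test is exact, so
type-I error is at most alpha by construction; the suite confirms this
empirically under a uniform-substitution null. Known limitation: a
repeat diversified below the stage-1 identity floor (for example an
adenine-rich template with a high mutation fraction) is missed unless a
better-conserved sibling VR anchors the template first.

## Marker clustering, guide dendrogram, and gene sharing

Marker families are compared as frequency profiles: the column score of
two alignment columns is `log(20 * sum_a fA(a) fB(a))` (the log-odds of
drawing the same residue from both columns against a uniform
background), and `S_AB` is the best ungapped diagonal segment sum.
Column frequencies are smoothed by mixing with a uniform background
(weight 0.05) rather than by additive pseudocounts, so duplicating every
sequence in a cluster leaves its profile — and all distances —
unchanged. Similarities convert to distances as
`-ln(S_AB / min(S_AA, S_BB))`, clamped at zero; a non-positive `S_AB`
maps to `Inf`, which the dendrogram builder caps at 1.05x the largest
finite distance.

The guide dendrogram is UPGMA (average-linkage agglomeration; node
height is half the merge distance, hence ultrametric), with ties broken
by lexicographic label order. Tips whose subtree root sits at depth
strictly below 1.5 are grouped for progressive alignment merging; depth
is measured as leaf-to-subtree-root height (the alternative,
root-relative depth, is not what a merge threshold needs). Merged
alignments are filtered (`filter_alignment()`): columns with more than
50% gaps go, as do columns with homogeneity below 0.1, where homogeneity
is normalized BLOSUM62 conservation — `(mean pairwise score − expected
random-pair score) / (mean same-residue score − expected random-pair
score)`, clipped to [0, 1], with the same-residue term computed from the
column's own residues so an identical column scores exactly 1. The exact
homogeneity formula is pinned here because the filtering tradition it
follows does not print one; it is configurable through the substitution
matrix. Maximum-likelihood tree building is out of scope: the module
exports filtered alignments for external tree builders and provides the
internal UPGMA for tests. Equal-length marker emissions stack directly
(`stack_alignment()`); genuinely diverged families should be aligned
externally and read back in.

`gene_sharing_network()` weights a genome pair by `-log10` of the
hypergeometric tail probability of sharing at least the observed number
of protein clusters given each genome's cluster count and the cluster
universe; edges below weight 1 are dropped and self-edges never occur.
The tail is computed in log space, so weights do not saturate.

## Read recruitment and fractional abundance

Reads are first decontaminated: any read with at least half of its
31-mers present in the decoy database (either strand) is removed.
Survivors are assigned by exact-seed ungapped extension (seeds at the
read's start, middle, and end; both strands; circular genomes matched
across the origin) to the genome with the most matching bases, requiring
at least 90% identity; ties split fractionally (1/t to each of t
genomes), since a winner-take-all or discard rule would bias abundances
in repeat-bearing families. This deterministic mapper is adequate for
the error-free or low-error reads the generator produces; alignments
from an external mapper can be supplied as SAM text instead
(`read_sam_counts()`). Per-100-bp window coverage is tracked for
detection plots.

Fractional abundance is reads-per-base, normalized:
`F_i = (c_i / L_i) / sum_j (c_j / L_j)`, zeros when nothing maps. A
genome is detected when it recruits at least one (whole) read. The read
generator draws genome `i` with probability proportional to
`abundance_i x length_i`, exactly the inverse of this normalization, so
recovered abundances are unbiased for the input vector — the suite
checks recovery within three binomial standard deviations at 50,000
reads.

## The synthetic-data generator: scope and limits

`generate_community()` plants everything downstream stages must find:
circular phage genomes (terminal repeats 50–200 bp; markers emitted from
the packaged profiles so detection is guaranteed-possible, planted in
1–3 copies), gene-dense plasmid decoys with terminal repeats but no
markers, linear fragments, TAG-recoded genomes (read-through TAGs in
filler genes and in the distal half of one marker, leaving a
standard-code prefix for round 1), DGR cassettes with adenine-restricted
VR mutations, spacer tables targeting planted protospacers, and reads
from a known abundance vector. Defaults, chosen once: 20 phages of 5–15
kb (compact-phage scale keeps desk-scale runs meaningful; genome size
does not enter any decision rule except the 3-kb floor), 5 plasmids of
3–8 kb, 10 linear fragments of 2–6 kb, uniform base composition with
configurable GC, ~70% coding density, error-free reads with an optional
uniform substitution rate. Everything is deterministic given the seed.

What passing tests show: the decision rules, thresholds, statistics and
bookkeeping are implemented correctly, and each stage recovers planted
truth under its stated conditions. What they do not show: performance on
real data — real assemblies have chimeras, uneven coverage, strain
mixtures and repeat-induced misassemblies; real markers diverge beyond
the packaged families; real reads carry structured error. The generator
deliberately omits all of these (non-goals), so sensitivity and
false-positive figures from synthetic runs are upper bounds on
real-data behavior.

## Numerical choices and problem sizes

Tie-breaking is lexicographic by identifier everywhere a tie is
possible (clustering order, dendrogram joins). Distances are clamped at
zero before `-ln`; Gumbel p-values are floored above zero so e-values
stay positive; hypergeometric tails are computed in log space. Degenerate
inputs fail fast with typed messages: all-N genomes, ragged alignments,
scores outside [0, 1], abundance vectors not summing to one, templates
with fewer than five adenines (the hallmark test would be underpowered).

The shipped test suite and acceptance script run at sizes chosen to keep
a laptop run comfortable while leaving no statistic degenerate: 1,000
contigs for the repeat-detector oracle, 20 seeded communities of 35
contigs for the discovery funnel, 30 genomes for dereplication, 200
replicates for the hallmark null, 40 planted cassettes for its power,
100 random matrices for ultrametricity, and 50,000 reads over 10 genomes
for abundance recovery.
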