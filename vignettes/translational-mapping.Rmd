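---
title: "Translational comparative mapping with legumap: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translational comparative mapping with legumap: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A crop species with a dense genetic map but no assembled genome (pea is
the motivating case) can borrow positional information from a sequenced
relative (*Medicago truncatula*, *Lotus japonicus*, soybean, poplar).
The chain of inference is:

1. build a non-redundant **Unigene** set from the crop's transcript and
   EST sequences;
2. find, for each Unigene, its **best reciprocal homolog** (RBH) among
   the relative's predicted genes, transcript contigs (TCs) and genomic
   sequences, and resolve each homolog to a pseudo-chromosome position;
3. use genetic-map markers whose homologs are positioned — **anchors**
   that carry both a (linkage group, cM) and a (chromosome, bp)
   coordinate — to interpolate a cM position for every other positioned
   Unigene (*in silico* placement);
4. detect **synteny blocks** from the anchor dot-plot and use them to
   restrict interpolation to collinear segments;
5. answer two queries: sequence → putative map position (forward), and
   genetic locus → candidate genes nearby (reverse).

`legumap` implements this chain end to end, plus a synthetic genome-pair
simulator with full ground truth so that every step can be validated
without external data.

## Sequence cleaning and Unigene construction

Cleaning applies, in order: terminal vector trimming (library matches
within `vector_terminal_margin` = 50 bp of an end are cut off together
with everything outward; internal vector hits are flagged, not cut),
repeat masking (library alignments at ≥ 80% identity over ≥ 20 bp are
replaced by N, lengths unchanged), strict-homopolymer poly-A/poly-T
trimming (terminal runs ≥ 12 bp; a single interrupting base ends a run —
strictness keeps the operator deterministic and idempotent), a Shannon-
entropy end trim (terminal 20 bp windows under 0.5 bits), and finally
the length filter: sequences under 100 bp are removed, 100 bp exactly is
kept. The whole pipeline is idempotent, which the tests verify directly.

Clustering is single-linkage over the pairwise overlap graph: two
sequences join when they share a local alignment (either strand) with
identity ≥ 95% over ≥ 40 aligned columns. 95% is the overlap-identity
setting of the EST-assembly tools this stage stands in for; 40 bp is a
conventional minimum overlap from the same tool family, exposed in
`cluster_config()`. Each connected component is one Unigene; the
representative is the longest member (ties: lexicographically smallest
id). Consensus base-calling is deliberately not performed — the
representative suffices for homology search, and components remain
auditable. Depths therefore sum exactly to the number of input
sequences, a partition invariant the property tests exercise on a
thousand random instances.

Annotation searches an ordered database list and accepts the first hit
with E ≤ 1e-15 and identity ≥ 70%; tiers are `highly_similar` (E <
1e-50), `very_similar` (E < 1e-20), `similar` otherwise. The identity
floor applies to acceptance only, not to the tier labels. Databases can
be nucleotide or protein ("translated" mode: six-frame query translation
against BLOSUM62).

## The built-in aligner and its E-values

All homology steps run on one seed-and-extend local aligner:

* exact k-mer seeds (word size 11) located via a database word index;
* seeds grouped into diagonal bands (band width 32, split at subject
  gaps > 5 kb); a cheap ungapped extension from each band's central seed
  must reach a trigger score of 2k = 22 before the band is extended —
  the same role as BLAST's two-hit and X-drop rules. Chance 12–16 bp
  word matches, which are common against hundreds of kilobases, are
  rejected here for the cost of a string comparison;
* qualifying bands are merged into subject windows and aligned exactly
  with affine-gap Smith–Waterman (`Biostrings::pairwiseAlignment`);
  small problems skip seeding and run full Smith–Waterman directly.
* per query, only the 8 best-seeded subjects per database and 8
  best-seeded bands per subject are extended.

Scoring is BLASTN-like: match +1, mismatch −2, gap open 5, gap extend 2
(a gap of length L costs 5 + 2L). Identity is computed over aligned
columns with gap columns counted as mismatches. Raw scores map to
E-values through the ungapped Karlin–Altschul form `E = K·m·n·e^(−λS)`
with λ = 1.28, K = 0.46, `m` the query length and `n` the total database
length, which makes the thresholds 1e-20 (reciprocal search), 1e-15
(annotation) and 1e-50 (tier boundary) operational. The tests pin the
aligner to an independent, plain-R affine-gap dynamic program on random
and homologous pairs.

Two consequences of the heuristics are worth knowing. A genuine hit
whose best ungapped segment scores below 22 (indels more often than
every ~20 bp) can be missed; at the divergences this toolkit targets
(≤ 15%) such hits are far below the 1e-20 threshold anyway. And identity
at score ties is traceback-dependent, so only scores — not identities —
are meaningful for borderline chance hits.

## Reciprocal best homologs

The forward best hit is taken over the union of the three target
databases; exact (E, bit score) ties across databases resolve predicted
gene > transcript contig > genomic, so a gene embedded verbatim in its
own pseudo-chromosome is reported as the gene. The reverse query is the
full subject for gene and TC subjects; for genomic subjects it is the
matched interval widened by 2 kb on each side, clamped to the sequence.
A pair is reciprocal only when the unique best reverse hit at 1e-20 is
the original Unigene; an exact reverse tie between the original Unigene
and another sequence is rejected as ambiguous (strict-best rule), which
is what makes identical duplicated sequences come out non-reciprocal
rather than arbitrarily assigned.

Positions: predicted genes take their interval midpoint (`direct`);
genomic subjects take the hit-interval midpoint when the subject is a
pseudo-chromosome (`window`), else stay unplaced; TC subjects relay
through their best predicted-gene homolog at 1e-20 (`tc_relay`).
Midpoints are used because the published procedure refers to a gene
"position" without an endpoint convention and the midpoint is symmetric.

Summary rates are integer percentages rounded half-up; the estimated
hit rate at full genome coverage divides the *unrounded* hit ratio by
the covered fraction before rounding. One published table cell (the
*L. japonicus* estimate) is consistent only with rounding the ratio
first; the unrounded convention reproduces every other cell and is the
one implemented.

## Map placement

Anchors are markers with a resolved homolog position, sorted by
(chromosome, bp). For a query position the flanking anchors left and
right are located; if they share a linkage group, cM is linearly
interpolated; outside the anchor span the nearest interval's local
cM/bp rate continues the line, clamped to [0, LG length] and flagged
`extrapolated`; flanking anchors from different linkage groups (a
chromosome syntenic to two LGs) give `chromosome_only` with both
candidates reported. Anchors sharing one bp average their cM, which
also makes the scheme exact at every anchor — the round-trip identity
is asserted at machine precision. When synteny blocks are supplied, the
candidate anchors are first restricted to the block containing the
position (narrowest wins), which is what rescues placements inside
inverted segments. Piecewise-linear interpolation was chosen as the
simplest scheme that is exact at anchors and monotone within collinear
runs; the published web tool's exact rule is not recoverable, so this
is a declared reconstruction, not a claim of bit-compatibility.

The forward query BLASTs a sequence against the Unigene set at 1e-20
and reports the five best hits with their placements; the reverse query
returns placements within the closed cM interval between two same-LG
markers, or within ±5 cM (configurable) of a marker or explicit
position. Exported tables round cM to 0.1; in-memory values keep full
precision.

## Synteny blocks

Dot-plot points (LG, cM) × (chromosome, bp) are scanned per chromosome
in bp order. For each linkage group, a run tolerates at most 2
consecutive intruding points from other groups (intruders are never
members — so an isolated translocated gene does not shatter a block);
runs are further broken at optional bp/cM gap limits and at changes of
cM direction, giving consistently oriented blocks: `plus` when cM rises
with bp, `minus` when it falls (ties tolerated within either), `mixed`
only for all-tied runs. Blocks under 3 points are discarded — the
"at least three homologs" convention of the source maps. Orientation
splitting is required for inversions to surface as their own blocks;
the greedy segmentation assigns a direction-flip boundary point to the
earlier segment, so an inversion spanning s anchors yields a block of
s − 1 to s points. No significance test is attached to blocks.

## The simulator

`simulate_bundle()` builds an ancestral multi-chromosome genome (random
gene sequences of 900–1100 bp separated by 2–10 kb intergenic spacers),
evolves two lineages independently at half the configured divergence
each (substitutions plus rare 1–3 bp indels), and applies losses,
tandem duplications, inversions (reversing gene order and strand) and
translocations to the target lineage only, all logged in truth tables.
The query lineage gets a genetic map — true cM is the integral of a
(piecewise-constant) cM/Mb rate to the gene midpoint, default 3.3
cM/Mb, the pea–Medicago genome-wide ratio — plus marker sequences
(default 20% of genes) and EST reads with configurable error, poly-A
tails and a fixed 40-mer vector contaminant. Every draw is fixed by the
seed; stages reseed deterministically from it.

What the simulator does *not* emulate: codon structure, introns
(transcripts equal gene sequences), repeat families, paralogous gene
families beyond tandem duplications, heterogeneous gene spacing, or
EST quality-score artifacts. Passing the validation suite therefore
shows the algorithms are correct under clean, known-truth conditions —
not that real EST corpora will reach the same recall.

## Validation scale and numerical choices

The validation suite runs at desk scale, chosen to keep the full test
run in minutes on one CPU: reciprocal-search recovery on 2 chromosomes
× 50 genes at 10% divergence (recall and precision ≥ 0.95 against
truth, plus exact equivalence with an all-pairs DP score matrix on
10 × 10 sets); placement recovery with markers on 20% of genes (mean
absolute error below the mean inter-anchor spacing; exact at anchors);
block recovery under k = 1, 2, 3 adjacent tail inversions of ≥ 4
anchors each (exactly k + 1 blocks, correct orientations — adjacent
spans tiling a terminal segment are the configuration in which k
inversions produce k + 1 alternating monotone segments); byte-identical
pipeline reruns; and clustering partition/monotonicity invariants over
1000 random instances.

Degenerate inputs are defined rather than rejected: empty FASTA files
read as empty sets; an all-N query aligns to nothing; a chromosome with
one anchor yields `chromosome_only`; equal-bp anchor pairs average; an
empty repeat library is the identity. Ties everywhere break
lexicographically by id so every run of every stage is reproducible
file-for-file, which the determinism test asserts by checksum.

## Limitations

* The aligner is a desk-scale reconstruction of a BLASTN-like search,
  not a BLAST replacement; for genome-scale runs, import external
  12-column tabular hits via `read_blast_tsv()` / `rbh_from_hits()`.
* Karlin–Altschul parameters are fixed defaults, not fitted to the
  scoring matrix; E-values are internally consistent thresholds rather
  than calibrated significance estimates.
* Placement assumes local collinearity; within an undetected
  rearrangement the interpolated cM can be badly wrong, which is the
  reason block-restricted placement exists and is the default in the
  pipeline.
* Protein-level forward RBH (BLASTX-style) and multi-genome orthology
  are out of scope.
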