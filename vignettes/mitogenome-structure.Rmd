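---
title: "Structural characterization of mitochondrial genomes with mitocr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural characterization of mitochondrial genomes with mitocr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocr)
```

## The problem

Vertebrate mitochondrial genomes are circular molecules of roughly 16–17 kb
carrying 13 protein-coding genes, two rRNAs, 22 tRNAs, a light-strand
replication origin (O~L~) and one large non-coding control region (CR).
Although gene content is strongly conserved, two structural layers vary
between lineages and carry phylogenetic and functional signal:

* **gene order** — most gecko lizards retain the canonical vertebrate
  arrangement, but a minority carry characteristic edits (tRNA
  duplications, extra O~L~ copies, tRNA translocation or loss, large block
  duplications);
* **control-region architecture** — the CR decomposes into the ETAS domain
  (extended termination-associated sequences, usually embedded in a
  variable-number tandem-repeat array), the central conserved region
  (CCR, marked by the CSB-F block) and the CSB domain (CSB-1/2/3, often
  with microsatellite runs). In *Cyrtodactylus* geckos the ETAS repeat is
  a ~75 bp unit (the "75-bp box"); one species instead carries a 225 bp
  unit that decomposes into three 75 bp sub-units.

`mitocr` makes both layers computable from annotated mitogenomes: it
classifies gene orders into the six recognized rearrangement types,
partitions the CR into its three domains from degenerate consensus motifs,
detects and decomposes tandem-repeat arrays, scans microsatellites and
inverted-repeat stems, and computes composition skews and uncorrected
p-distances. A synthetic-genome generator with exact ground truth makes
the whole pipeline testable without downloading sequence data.

## Gene-order typing

Orders are linearized on the heavy strand and rotation-canonicalized to
start at tRNA-Phe (`trnF`); classification is therefore invariant under
any rotation of the circle. The canonical (Type I) template is the 39-token
vertebrate order (37 genes + O~L~ + CR) with nine minority-strand genes:

```{r}
canonical_type1_order()
```

`classify_rearrangement()` compares a canonicalized order against this
template and matches event signatures in a fixed precedence:

| Type | signature |
|------|-----------|
| I    | identical to the template |
| II   | `trnQ` and `ND4` each duplicated in place |
| III  | more than one O~L~ between `trnN` and `trnC` (WANCY cluster) |
| IV   | `trnE` moved from 3' of `ND6` to immediately 5' of `trnP` |
| V    | `trnE` absent |
| VI   | a contiguous duplicated block intersecting the `ND4`..`trnI` span |

Anything else — including compound edits such as an extra O~L~ *plus* a
deletion — is reported as `"novel"` together with the raw multiset
differences. O~L~ multiplicity is tested before the `trnE` signatures so
that compound artifacts cannot be silently absorbed into Types IV/V; each
type is treated as a single event class. Pseudogenized duplicate copies
count as copies whenever the annotation labels them with a vocabulary
token: typing is order- and content-based, not functional. Because the
reported extent of the large Type VI duplication is ambiguous at its
endpoints, the classifier accepts any contiguous duplicated block whose
span intersects the circular `ND4`..`trnI` region and records the observed
block.

```{r}
tmpl <- canonical_type1_order()
classify_rearrangement(apply_event(tmpl, list(kind = "deletion", labels = "trnE")))
```

## Control-region partitioning

The CR is the heavy-strand subsequence strictly between the end of `trnP`
and the start of `trnF`, wrapping across the circular origin when needed.
Partitioning uses degenerate consensus motifs matched by an IUPAC-aware
Hamming scan (`iupac_scan()`):

* TAS `TACAT` (exact),
* CSB-F `CHCGRGAAACCAKCRACCCS` (up to 3 mismatches),
* CSB-1 `KTTMATGCTCGAWRGACATAY` (3), CSB-2 `AAACCCCCCTTACCCCCC` (2),
  CSB-3 `CGCCAAACCCCTAAAACG` (2).

Mismatch budgets are looser for CSB-1 because its sequence is the least
conserved of the three CSB blocks; all budgets are configurable
per-motif. An `N` in the sequence never matches exactly and always
consumes mismatch budget.

The exact boundary rule used to produce published domain sizes is not
recoverable from domain-size tables alone, so the module defines its own
deterministic, configurable rule and enforces the *partition invariant*
instead of exact boundary reproduction: the ETAS/CCR boundary is the end
of the last TAS-bearing tandem array (fallback: last TAS hit in the 5'
half; fallback: a configurable default fraction of the CR), the CCR/CSB
boundary is the start of the best CSB-1 hit (fewest mismatches, leftmost
on ties; fallback CSB-2), and every successful partition satisfies
ETAS + CCR + CSB = CR with no gaps or overlaps. Published domain sizes
obey the same sum identity, which is what the package's checks conserve.
Degenerate evidence (no CSB hit, or a CSB hit at position 0 implying an
empty ETAS) is a hard error, not a silent guess.

## Tandem-repeat detection

`find_tandem_repeats()` is a seed-and-extend detector. Exact 8-mer
recurrence distances propose candidate periods; each candidate is extended
copy-by-copy while consecutive period-sized windows match at the identity
threshold (default 0.7). Identity is edit-distance based
(`1 - edits / unit length`) because real VNTR copies differ in length.
Three numerical choices matter and were validated on planted arrays:

* **Period selection by seed-distance mode.** Overlapping extensions are
  merged into a region and the region's period is the mode of the exact
  k-mer recurrence distances inside it. A 75 bp array also chains at 150
  or 225 bp, and identity alone cannot reliably distinguish a period from
  its harmonics or from ±1 bp jitter; the recurrence-distance mode is
  robust to both.
* **Consensus chaining.** A window also chains if it matches the running
  majority consensus of accepted copies. Copies diverge independently
  from a common ancestral unit, so adjacent copies differ at roughly
  twice the per-copy divergence while the consensus stays close to every
  copy; without this, short (25 bp) units at 10% divergence break their
  chains too often.
* **Boundary polish and tolerant copy counting.** Stride extension from an
  arbitrary seed phase can leave partial copies outside the detected
  span; flanking fragments that still match the terminal copy are
  reclaimed, and a trailing copy shortened by at most 20% (small indels)
  counts as complete. Truth comparisons are phase-insensitive: the array
  is anchored at its leftmost start rather than at a canonical rotation
  of the unit.

Under these rules, planted arrays (units 25/75/225 bp, 2–8 copies, up to
10% per-copy substitution divergence) are recovered — exact unit length
and copy number — in ≥ 95% of cases, the acceptance bar enforced by the
test suite. Note that a 1–3 bp indel in a copy genuinely changes the
maximal-repeat period (a 3 bp deletion at a copy edge makes the true
maximal tandem repeat 72 bp), so exact unit-length recovery is only
defined for substitution divergence.

`decompose_unit()` cuts a long unit into base-length sub-units plus a
remainder and classifies each sub-unit by its best edit-identity against
the others: `member` (≥ 0.65 by default), `box-like` (below the member
threshold but above 0.52) or `unrelated`. The 0.52 floor is the empirical
random expectation: unrelated random DNA has edit-distance identity near
0.5, not near the 0.25 a Hamming intuition would suggest. This reproduces
the composite-unit analysis in which a 225 bp unit contains two closely
related 75 bp boxes plus one diverged "box-like" third sub-unit.

`microsat_scan()` reports maximal, non-extendable perfect runs (default
motifs TA and CA, minimum four copies). `find_stems()` enumerates all
arm/loop placements whose arms reverse-complement-match at a configurable
identity (default 0.8, minimum arm 6 bp, loop 3–30 bp); it is a purely
sequence-based stem detector standing in for thermodynamic folding, which
is out of scope.

## Composition and distances

`compute_composition()` tallies bases on the heavy strand and derives
AT-skew = (A − T)/(A + T) and GC-skew = (G − C)/(G + C); ambiguity codes
count as `other` and never enter the skews, and a skew with a zero
denominator is `NA` rather than a number. Because the skews are ratios of
percentages, `composition_from_counts()` accepts published per-base
percentages directly, which is how the package reproduces reported skew
values from printed composition tables. `cohort_summary()` reports the
mean, the sample SD and the standard error per metric: published
"mean ± x" summaries are ambiguous between SD and SE, and across the five
*Cyrtodactylus* A+T values the reported ±0.61 matches the SE (0.61), not
the SD (1.36), so both are always shown. One published composition row
has an internal rounding slip (A% + T% = 50.9 vs a printed A+T of 50.8);
the package always reports recomputed values rather than matching
printed rounding.

`p_distance()` implements uncorrected distances (mismatches over compared
sites) with pairwise deletion by default — sites with a gap or ambiguity
in either member of a pair are excluded — and complete deletion as an
option, matching the two published alignment treatments (with and without
gap-containing sites). `divergence_summary()` averages within-group pairs
and estimates the SE by a seeded site bootstrap (default 500 replicates),
since the method behind published ±SE values is unstated; singleton
groups report `NA`, mirroring the dash entries in published tables.

## The synthetic generator

`build_mock_mitogenome()` emulates the study conditions: a circular
~16.8 kb genome laid out in the canonical order (or edited into Types
II–VI by pure event operators), gene placeholders at realistic lengths
(ND5 the longest protein-coding gene, ATP8 the shortest; no codon
structure), and a CR assembled as

```
[ETAS: tandem array, TACAT inside every copy][CCR: one CSB-F]
[CSB: CSB-1 .. microsat .. CSB-2 CSB-3 .. microsat]
```

Defaults mirror the observed structures: a 75 bp unit × 6 copies at 5%
per-copy divergence (about the conservation reported for the 75-bp box
family), a ~310 bp CCR and ~650 bp CSB domain (mid-range of the reported
domain sizes), background composition A 30 / T 22 / G 15.5 / C 32.5%
(the reported genome-wide means), and (TA)~6~/(CA)~5~ microsatellites.
Each diverged copy receives substitutions at the requested rate plus,
with probability 0.1, a single 1–3 bp indel, so the edit-distance
identity metric is genuinely exercised. Output is deterministic given the
seed, and the truth record (feature coordinates, array unit/copies,
motif placements, applied events) matches the emitted annotation exactly.

What the generator does *not* emulate — codon structure, transfer-RNA
secondary structure, phylogenetically correlated divergence, composition
heterogeneity along the molecule — bounds what passing tests show:
recovery on synthetic genomes demonstrates the pipeline's arithmetic and
decision rules, not annotation quality on real submissions, where gene
naming and boundary conventions vary (hence the controlled-vocabulary
normalizer and the treatment of input annotations as authoritative).

## Problem sizes and reproducibility

The shipped test suite and the acceptance script use desk-scale problem
sizes chosen to exercise every decision rule: 1,000 randomized
motif-scan cases checked against an exhaustive IUPAC-expansion oracle,
classifier round-trips over randomized instances of all six types under
every rotation, 200 planted tandem arrays, and five-sequence alignments
for the distance checks. All randomness is seeded; the acceptance script
(`scripts/acceptance.R`) recomputes every headline number from scratch at
run time.

## Known limitations

* GenBank parsing targets the feature types relevant here (gene, tRNA,
  rRNA, CDS, D-loop, rep_origin, misc_feature) and common location forms
  (ranges, `complement`, `join`); it is not a general GenBank reader.
* Serine/leucine tRNAs without codon-family or anticodon information
  normalize to ambiguous tokens (`trnS`/`trnL`) rather than guessing.
* Exact reproduction of published ETAS/CCR/CSB boundary positions is out
  of scope (the generating rule is not recoverable); the domain-sum
  invariant is conserved instead.
* Similarity percentages quoted for repeat families elsewhere depend on
  unstated alignment choices; the package reports its own edit-distance
  identity and does not claim to reproduce those exact figures.
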