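---
title: "Structural annotation of CACTA elements: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural annotation of CACTA elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cactascan)
```

## The annotation model

CACTA (EnSpm/CMC) elements are Class 2 cut-and-paste DNA transposons with a
characteristic terminal architecture: a short terminal inverted repeat (TIR)
at each end anchored by the conserved `CACTA` pentamer, a subterminal region
(subTIR) of closely spaced 10--20 bp units repeated in direct orientation at
the 5' end and inverted orientation at the 3' end, and a 3-bp target-site
duplication (TSD) created on insertion. The internal region carries one or
two open reading frames; ORF1 holds the conserved-domain backbone
TAD--Transposase_21--DUF4218--DUF4216, and ORF2, when present, carries
Transposase_24 and/or Peptidase_C48. In the *Chenopodium* Jozin family these
elements additionally capture host-gene fragments in the 5' region upstream
of TAD and, in one lineage, a multi-kilobase tandem satellite-DNA array near
the 3' end (171-bp monomer family).

`cactascan` implements this model as a domain-anchored annotation pipeline:
quality-filtered protein-domain hits provide transposase (tnp2) anchors, and
terminal structure is searched in the flanking sequence
(`call_element()`). The conserved domain architecture (CDA) is typed from
the ordered domain list (`classify_cda()`: the basic ORF1 set is type 1;
plus Peptidase_C48, type 2; plus Transposase_24, type 3; plus both, with
Transposase_24 first, type 4). Satellite arrays and captured fragments are
annotated relative to element landmarks. A transposase comparative module
computes p and Tamura (1992) distances, neighbor-joining trees and
nearest-reference clade assignments.

## Coordinates

All positions are reported 1-based; intervals are half-open on the right, so
an interval's length is `end - start` and the printed arithmetic of
published array intervals (e.g. `15648 - 10098 = 5550`) holds by plain
subtraction. The GFF3 writer converts to 1-based inclusive coordinates
(`end - 1`), the BED writer to 0-based half-open.

## Detection parameters

| parameter | default | units | rationale |
|---|---|---|---|
| TIR anchor motif | `CACTA` | -- | superfamily-defining terminal pentamer |
| TIR length range | 25--40 | bp | described TIRs are 28 bp; the cap guards against degenerate extension |
| TIR pair identity | 0.70 | fraction | published cross-species TIR identities bottom out at 0.75 |
| subTIR end window | 600 | bp | subTIR regions span several hundred bp; covers 23 units x 12 bp with margin |
| subTIR unit range | 10--20 | bp | the defining unit-size band |
| subTIR copy identity | 0.80 | fraction | published copy similarities bottom out at 83.3% (10/12); 0.80 admits all of them for 12-bp units without admitting 9/12 copies |
| TSD length | 3 | bp | canonical CACTA target-site duplication |
| hit filter | id 0.35, sim 0.45, aln 0.8, 0 interruptions, len prop 1.2 | -- | DANTE-style transposase-domain filtering |
| full-length tnp2 | 630 +/- 10% | bp | complete tnp2 domain size; the tolerance makes "about 630 bp" operational (closed interval, so 567 bp is kept) |
| satellite monomer range | 30--400 | bp | 30 bp excludes subTIR units from satellite calls; 400 bp covers common plant satDNA monomers |
| satellite copy identity | 0.70 | fraction | diverged satellite copies are common |
| anchor search flank | 15000 | bp | upper bound on element half-length plus slack |

Every threshold is echoed verbatim into the scan run report
(`scan_config()` rejects unknown keys).

## Algorithmic choices that required a decision

**TIR extent.** Among lengths whose inverted pair identity reaches the
threshold, `find_tir()` reports the one maximizing matches minus
mismatches, not the longest passing length. A perfect 28-bp TIR extended by
12 random bases still clears 0.70 (28 guaranteed matches of 40), so
"longest passing" would saturate at the cap for every real TIR; the score
criterion stops at the true extent because extension into unrelated flank
always lowers it. In elements whose subTIR arrays mirror each other
perfectly, the reported TIR legitimately extends into the subTIR region --
the terminal inverted repeat is genuinely longer there.

**Unit-length estimation.** `estimate_unit_length()` implements the plain
shifted-self-identity curve (mean match at each lag, ties to the smaller
period so harmonics resolve to the fundamental). Inside `detect_subtir()`
the period is instead estimated from the best rolling window of the lag
profile: a 4-copy array contributes ~48 bp of signal to a 600-bp window,
which a global mean cannot resolve (the bump is ~2.5 standard deviations)
while a localized maximum detects it reliably.

**Copy phase.** A tandem unit is only defined up to rotation, and a rotated
copy grid turns *n* true copies into *n - 1* full copies plus two
straddlers. The phase is chosen per array as the offset maximizing the
summed identity margin of its copies over the counting threshold; each
element end derives its own phase, because a rotation chosen at one end
need not tile the other end's array (its junction-straddling copy would
depend on flanking bases).

**Copy counting.** Greedy left-to-right non-overlapping scanning at the
copy-identity threshold, with two qualifications: only full-length units
are counted (partial units at array edges are not), and counted copies must
form a contiguous chain with gaps of at most one unit length. The chain
rule is what makes counts reproducible: at a 0.80 identity threshold, a
600-bp window of random sequence produces a chance 10-bp-unit match with
probability about 0.25 per window, so unrestricted whole-window counting
would inflate counts in a substantial fraction of elements. A single
diverged (uncounted) copy inside an array leaves a gap of exactly one unit,
so it does not break the chain.

**Satellite-array boundaries.** Boundaries are phase-independent: starting
from the most confident copy, the sequence is compared base-by-base to the
periodic continuation of the consensus, and each boundary is placed at the
maximum of matches minus twice mismatches. Inside the array the score
rises; in unrelated flank it falls steeply, so a mid-copy truncation point
is found exactly on clean arrays and fractional copy numbers (reported to
one decimal, half-up, as length/monomer) are well-defined. Harmonic periods
are reduced to the smallest divisor scoring within 0.05 of the best, and
candidate regions whose consensus is itself periodic below the minimum
monomer length (subTIR-unit harmonics) are rejected and masked so the
search can continue elsewhere.

**Completeness classes.** `complete` requires a CACTA-intact TIR pair plus
at least 3 subTIR units per end; `subtir_only` requires the unit arrays
without an intact TIR pair; anything else around an anchor is
`incomplete`. The 3-unit minimum keeps chance periodicity in random flanks
from producing spurious terminal structure.

**Alignment identity.** `global_align_identity()` scores a global
Needleman--Wunsch alignment (defaults: match 1, mismatch -1, gap -2) and
divides matched columns by total alignment columns, gaps included. When
several alignments are optimal, the high-road traceback (diagonal preferred
over up, up over left) fixes the reported identity deterministically. `N`
counts as a mismatch everywhere, including against `N`.

**Distances.** The Tamura (1992) distance is computed from transition and
transversion proportions with the GC-content correction; the
rate-heterogeneity variant uses the continuous-gamma closed form rather
than a small number of discrete categories -- at desk scale the difference
is well below the divergences of interest. Saturated pairs (non-positive
logarithm arguments) are flagged, not clipped; `nj_tree()` excludes flagged
taxa with a warning. Tree inference is neighbor joining over these
distances: the claim this package supports is the separation of transposase
clades, which NJ resolves whenever between-clade distances exceed
within-clade spread; it makes no claim about deep-branch resolution, for
which likelihood methods with bootstrap support would be required.
Alignment is an input -- the package does not bundle a multiple aligner.

## The synthetic-element generator

`build_element()` realizes the structural grammar generatively: TIR, n5
direct unit copies, 5' spacer (with captured fragments written at exact
offsets upstream of TAD), ORF1 with fixed sentinel domain segments (ATG +
TAD + Transposase_21 + DUF4218 + DUF4216 + stop, 3294 bp), an optional ORF2
(Transposase_24 / Peptidase_C48), an optional tandem satellite array placed
close to the 3' terminal structure, n3 inverted copies, and the
reverse-complement TIR -- then applies i.i.d. substitution noise (a
substituted base always changes). `embed_in_background()` inserts elements
at random points of an i.i.d. background of chosen GC content, duplicating
the 3-bp TSD on both flanks, and lifts all ground-truth coordinates to
contig space.

The family presets (`jozin_element_spec()`) encode the published
descriptions: TIRs and unit motifs as printed, per-end copy counts
(9+10, 11+8, 10+13, 10+11), total element lengths (8380, 8258, 9210,
10109, 9486 bp), CDA types, the two Neprosin-superfamily fragments of the
longest element (113 and 203 bp, ending 1204 and 754 bp upstream of TAD),
and the satellite-bearing 16523-bp element with a 32.5-copy array of the
171-bp monomer and subTIR-only ends. Where the published record does not
fix a value (spacer lengths, the unit counts of the two *C. quinoa*
elements, placeholder domain sizes other than the 630-bp tnp2), the presets
use one fixed realistic choice and the 3' spacer absorbs the slack so the
total length is exact.

Two deliberate generator properties: substitution-only noise (no indels) is
the default, consistent with fixed-length unit copies whose published
similarities are multiples of 1/12; and the two bases flanking a satellite
array never continue the monomer periodicity, so the array's annotated
extent is well-defined -- a flanking base that coincidentally continues the
periodicity is indistinguishable from array sequence for any detector.

What the generator deliberately does not emulate: nested or fragmented
element insertions, indels and segmental duplications, GC heterogeneity and
repeat families in the background, and sequencing or assembly artifacts.
Passing round-trip tests therefore demonstrates correctness of the
detectors under the structural model, not performance on raw assemblies.

## Validation design and problem sizes

The test suite checks, among others: exact recovery of element spans, unit
counts, TSDs, CDA types and array metrics on 50 random noise-free
generator specifications (units 10--20 bp, 3--15 copies per end, elements
embedded in backgrounds twice their length); subTIR count recovery at 5%
per-base substitution over 100 seeded replicates with 4 units per end --
a 12-bp copy drops below the 0.80 threshold only with three or more
substitutions (probability ~0.02), so about 85% exact recovery is the
binomial expectation and at least 80% is asserted; exact neighbor-joining
recovery of 100 random additive 4- and 5-taxon metrics; per-column
majority-vote consensus against brute-force tallies; and perfect two-family
clade assignment when between-family divergence exceeds three times the
within-family spread. Oracle implementations (brute-force alignment
enumeration, per-frame ORF scanning, closed-form distance evaluation,
`ape`'s distance and tree machinery) are independent of the package code
paths they check.

These sizes keep the default test run within a few minutes on one CPU while
leaving the statistical assertions well-powered.

## Known limitations

* Nested elements are not deconvolved; one anchor yields one element model.
* Terminal-structure detection assumes the anchor's strand; elements on the
  minus strand should be scanned on the reverse complement of the contig.
* Copy counts at low identity thresholds depend on the chain rule described
  above; isolated distal unit copies are deliberately not counted.
* The comparative module requires pre-aligned input and does not estimate
  alignment uncertainty or bootstrap support.
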