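---
title: "Methods: numbering, classes, profiles and rendering in collier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: numbering, classes, profiles and rendering in collier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collier)
```

This vignette documents the models, conventions and numerical choices
behind the package: what is computed, under which assumptions, and where
a design was genuinely open, why the shipped convention was chosen.

## The IMGT unique numbering for V domains

A V domain is mapped onto 128 standardized positions: FR1 1–26, CDR1
27–38, FR2 39–55, CDR2 56–65, FR3 66–104, CDR3 105–117, FR4 118–128.
Five positions are conserved across IG and TR V domains — 1st-CYS 23,
CONSERVED-TRP 41, a hydrophobic residue at 89, 2nd-CYS 104 and
J-PHE/J-TRP 118 — and six framework anchors (26, 39, 55, 66, 104, 118)
flank the three CDR loops. `scheme_constants()` exposes these as data;
all position labels in the package are 1-based.

### Gap placement

A CDR shorter than its region capacity is gapped "at the top of the
loop". Normatively the package uses the closed form: a CDR of observed
length $L$ occupies the first $\lceil L/2 \rceil$ and last
$\lfloor L/2 \rfloor$ positions of its region. This is equivalent to
removing positions middle-out in a fixed order — for the odd-capacity
CDR3 starting at the single middle position and alternating outward
upward-first (111, 112, 110, 113, …), for the even-capacity CDR1/CDR2
starting at the upper middle and alternating downward-first (CDR1: 33,
32, 34, 31, …; CDR2: 61, 60, 62, 59, …). The even-capacity tie-break
(upper-middle-first) is a documented package convention; the test suite
proves the closed form and the removal order agree exhaustively for
every admissible length. CDR3 loops longer than 13 take insertion
positions labelled 112.1, 111.1, 112.2, … in order of addition, displayed
as 111, 111.1, …, 112.1, 112.

### Anchor detection and germline indels

`detect_anchors()` numbers an ungapped sequence by motif: C at position
23, W at 41, C at 104 and F/W at 118 must be placeable such that the
framework lengths are standard and the implied CDR lengths are within
capacity. Frameworks are assumed at full capacity, with two deliberate
exceptions — the common IG germline indels FR1 = 25 (gap at position 10)
and FR3 = 38 (gap at 73). Candidate assignments are searched in a fixed
order so the result is deterministic:

* full FR1 before the 10-gap variant;
* given a full FR1, full FR3 before the 73-gap variant;
* given a 25-residue FR1, the 73-gap variant first — in expressed IG
  heavy chains the two indels co-occur almost always, and a sequence
  showing one is overwhelmingly likely to show the other. The
  trastuzumab VH is the canonical example: 120 residues, gaps at 10 and
  73, CDR-IMGT lengths [8.8.13].

This coupling is a heuristic, not an alignment: a motif-only numberer
cannot distinguish `(FR3 = 39, CDR2 = L)` from `(FR3 = 38, CDR2 = L+1)`
when both place the cysteines and tryptophans consistently, because the
discriminating information lives in the germline reference, which is
exactly what the pre-gapped input path and the reference-directory
functions (`read_gapped_fasta()`, `pick_closest_reference()`) are for.
Sequences with other germline gaps (e.g. the short FR3 of kappa light
chains) must be supplied pre-gapped.

Conserved-position mismatches (e.g. a non-hydrophobic residue at 89) are
*warnings*, not errors: engineered and humanized domains are precisely
the use case in which one wants to render unusual content. A
`strict = TRUE` flag upgrades them to errors.

## The synthetic-domain generator

`synthesize_domain(c(a, b, c), seed)` builds a fixture with chosen CDR
lengths: full-capacity frameworks (93 residues), uniformly random
residues, and the conserved motif placed at the implied offsets (C23,
W41, a hydrophobic residue at 89, C104, W118); total length
$93 + a + b + c$. Two windows are resampled away from decoy motifs: no W
where it could mimic CONSERVED-TRP at a smaller CDR1 length, no C where
it could mimic 2nd-CYS at a smaller CDR2 length. This makes motif-based
numbering provably unambiguous on generator output, which is what lets
the round-trip property (`ungap(gap_sequence(s)) == s`, with the CDR
lengths recovered exactly) hold across all 2002 admissible CDR-length
triples in the tests.

What the generator emulates is the *shape* of a V domain — lengths,
conserved motif, gap structure. What it does not emulate: realistic
amino-acid composition, germline framework indels (it always emits full
frameworks), somatic-hypermutation structure, or any correlation between
positions. Passing tests therefore validate the numbering and rendering
machinery, not biological plausibility of inputs; real expressed
sequences exercise the germline-indel paths instead (the packaged
trastuzumab VH covers those in the tests).

## Amino acid classes

The three classifications — hydropathy (hydrophobic / neutral /
hydrophilic), volume (5 classes from very small to very large) and the
11 physicochemical classes — are shipped as a single plain-text table
(`inst/extdata/imgt_aa_classes.tsv`), not as code, so there is exactly
one place where memberships live. `load_class_tables()` validates that
each dimension partitions the 20 standard residues into 3/5/11 classes
and names any offending entry. Unknown residues (X, B, Z, gaps) yield a
recoverable "unclassifiable" assignment so imperfect sequences still
render, with a default bead style.

Change characterization (`compare_residues()`) reduces a residue pair to
three booleans — same hydropathy / volume / physicochemical class — and
maps the triple to a label. The default map tiers by how many dimensions
are conserved (very similar / similar / dissimilar / very dissimilar,
with identical residues always "identical"); the map is an argument
because different workflows want different vocabularies.

## Position profiles

`build_profile()` counts, per position, occupancy and class occurrences
over a set of gapped domains. Frequencies are computed **over the
sequences occupying a position with a classifiable residue**, not over
all sequences: a position gapped in half the set is described by the
residues that are actually there, and short CDRs do not dilute class
frequencies. This denominator choice is the package's own (the display
convention does not pin it down) and is visible in the profile TSV,
which stores both `occupancy` and `n_classifiable` per position.

Both display thresholds are *inclusive*: the 50%-hydrophobic display
colors a position when the hydrophobic frequency is ≥ 0.5 ("50% or
more"), and the 80%-class display uses ≥ 0.8 with the same comparison
for consistency. At any threshold above 0.5 at most one class can
qualify, so `dominant_class()` is well-defined without a tie-break.

## Hydrogen bonds

The two-layer display can overlay backbone hydrogen bonds from a 3D
structure. The bond criterion is geometric: donor backbone nitrogen to
acceptor carbonyl oxygen distance ≤ 3.5 Å with a chain separation of at
least 2 residues. It needs no hydrogen atoms, is deterministic, and is
testable on synthetic coordinates; a DSSP-style energy criterion would
be a drop-in alternative but is deliberately not required. Residues with
a missing N or O atom simply lose the corresponding role. The detector
is checked against a brute-force $O(n^2)$ distance scan and for
invariance under rigid-body motion; bond sets from experimentally
curated databases will differ in detail, since those pipelines use their
own (undisclosed) assignment methods.

`synthesize_sheet_structure()` writes a backbone-only PDB-format file
with idealized antiparallel-strand coordinates (3.5 Å residue spacing,
4.8 Å strand separation, carbonyl oxygens pointing at the next strand,
giving 2.9 Å N···O contacts). Its coordinates are synthetic — only the
sequence carried in it is meaningful — and it exists so that structure
handling and bond detection are fully testable offline.

## Layout

Coordinates are abstract bead units; aesthetics are explicitly not part
of correctness. The nine strands (A, B, C, C′, C″, D, E, F, G) are
vertical columns with serpentine (alternating up/down) direction, CDR
loops are arcs above the junctions, and gap slots receive coordinates
like any other slot (they render as empty beads). Per-strand position
ranges are a packaged table (`inst/extdata/v_strands.tsv`), not code:
they are the package's standard approximation (A 1–15, B 16–26, C 39–46,
C′ 47–55, C″ 66–74, D 75–84, E 85–96, F 97–104, G 118–128), and the
two-layer sheet split defaults to back A–B–E–D, front G–F–C–C′–C″,
matching the V-domain sandwich. Both are replaceable files.

The geometry guarantees two invariants that the tests enforce: every
slot has unique coordinates, and consecutive slots are within the
`max_step` constant (default 1.6 × spacing) of each other — in the
two-layer view, for consecutive slots on the same layer; the backbone's
physical crossing between sheets has no meaningful 2D distance. Arc
height grows with loop length (0.3 × spacing per slot) so that bead
spacing along the arc never exceeds `max_step`. Layouts are pure
functions of the domain's slot structure and the geometry config:
domains with the same gap pattern get identical coordinates.

## Rendering

SVG output is byte-deterministic: fixed element order, fixed attribute
order, coordinates at 2 decimal places, no timestamps or generator
metadata — so golden-file and re-render-identity testing are exact. The
conventions fixed by the display standard are defaults in
`render_style()` and are test-asserted: hydrophobic beads blue, CDR1/2/3
accents red/orange/purple, conserved letters red and bold, anchors drawn
as squares, difference borders pink, hydrogen bonds green. Every other
color (volume classes, the 11 physicochemical classes, backbone, gaps)
is a documented package palette with no claim to match any other
rendering.

## Parameters at a glance

| parameter | default | unit | where |
|---|---|---|---|
| hydrophobic display threshold | 0.5 (inclusive) | fraction | `hydrophobic_positions()` |
| dominant-class threshold | 0.8 (inclusive) | fraction | `dominant_class()` |
| hydrogen-bond cutoff | 3.5 | Å (N···O) | `detect_hbonds()` |
| minimum bond separation | 2 | residues | `detect_hbonds()` |
| V-domain length bounds | 85–140 | residues | `detect_anchors()` |
| max CDR3 insertions | 20 | positions | `extra_positions()` |
| bead spacing / radius | 1.0 / 0.35 | bead units | `cdp_geometry()` |
| arc height per loop slot | 0.3 | bead units | `cdp_geometry()` |
| max consecutive-bead step | 1.6 | bead units | `cdp_geometry()` |

## Problem sizes used in the test suite

The exhaustive checks are small by construction: the gap-rule oracle
comparison covers all 38 (region, length) pairs; the round-trip sweep
covers all 13 × 11 × 14 = 2002 admissible CDR-length triples with one
generated sequence each; structure tests run on ~122-residue synthetic
sheets; profile boundary tests use hand-built 4- and 5-domain sets where
the expected frequencies are obvious. The whole suite runs in well under
a minute on one core.

## Known limitations

* Motif-based numbering handles only the 10- and 73-position germline
  indels; other framework gaps require pre-gapped input.
* Closest-reference selection is position-wise identity over co-occupied
  slots with first-wins tie-breaking — a documented stand-in for
  reference-directory alignment, not a reimplementation of any hosted
  service; no germline gene/allele nomenclature is assigned.
* C domains and G domains (constant and MH groove domains) are out of
  scope; the numbering here is V-domain only.
* Hydrogen bonds are backbone N···O only; sidechain bonds are not
  reported.
* The layout approximates the canonical wall-chart appearance; it does
  not reproduce any particular rendering pixel-for-pixel.
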