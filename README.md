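# collier

IMGT Colliers de Perles — standardized two-dimensional "beads-on-a-string"
representations of immunoglobulin (IG) and T cell receptor (TR) variable
(V) domains — for antibody engineers, immunoinformaticians and anyone who
needs to compare V domains position by position across sequences, species
or against a reference repertoire (e.g. during antibody humanization).

## What it computes

A V domain is numbered with the **IMGT unique numbering**: 128 positions
tiled into framework and complementarity determining regions

| region | positions | capacity |
|---|---|---|
| FR1-IMGT | 1–26 | 26 |
| CDR1-IMGT | 27–38 | 12 |
| FR2-IMGT | 39–55 | 17 |
| CDR2-IMGT | 56–65 | 10 |
| FR3-IMGT | 66–104 | 39 |
| CDR3-IMGT | 105–117 | 13 (+ insertions 111.x/112.x) |
| FR4-IMGT | 118–128 | 11 |

with five conserved positions (1st-CYS 23, CONSERVED-TRP 41, hydrophobic
89, 2nd-CYS 104, J-PHE/J-TRP 118) and six anchors (26, 39, 55, 66, 104,
118) flanking the CDR loops. A sequence of CDR lengths `[a.b.c]` is
gapped "at the top of the loop": a CDR of length *L* occupies the first
⌈L/2⌉ and last ⌊L/2⌋ positions of its region, the middle stays empty.

On top of the numbering the package provides:

* the **IMGT amino acid classes** — hydropathy (3 classes), volume (5),
  physicochemical (11) — as a packaged data table, with per-pair change
  characterization for difference highlighting;
* **statistical profiles** over sets of gapped domains (per-position class
  frequencies) with the inclusive 50%-hydrophobic and 80%-dominant-class
  display rules;
* **backbone hydrogen bonds** from PDB structures (N···O ≤ 3.5 Å,
  sequence separation ≥ 2) for the two-layer overlay;
* deterministic **SVG rendering** of one-layer and two-layer Colliers de
  Perles: anchors as squares, conserved letters red and bold, CDR1/2/3
  accents red/orange/purple, differences with a pink border, hydrogen
  bonds as green lines.

## Worked example

The VH domain of trastuzumab (the heavy chain of the 1n8z Fab) ships as a
plain-text fixture:

```r
library(collier)
vh <- read_fasta(system.file("extdata", "trastuzumab_vh.fasta",
                             package = "collier"))[[1]]
g <- gap_sequence(vh)
g
#> <gapped_domain> CDR-IMGT lengths [8.8.13]
#>   framework gaps at: 10, 73
```

The CDR-IMGT lengths are `[8.8.13]` — 8, 8 and 13 residues in CDR1, CDR2
and CDR3 — and the sequence shows the two common IG germline indels
(framework gaps at positions 10 and 73). Rendering it:

```r
lay <- layout_two_layers(g)
render_svg(lay, g, render_style("physicochemical"), path = "vh.svg")
table(lay$blocks$kind)
#> loop strand
#>    3      9
```

Nine strand columns (the beta sandwich: back sheet A–B–E–D, front sheet
G–F–C–C′–C″) and the three CDR loops. With a structure, hydrogen bonds
can be overlaid:

```r
d  <- read_structure("structure.pdb", chain = "B")
hb <- detect_hbonds(d, cutoff = 3.5)
render_svg(lay, g, render_style("physicochemical"), hbonds = hb,
           path = "vh_bonds.svg")
```

A thin command-line wrapper covers the same workflow
(`inst/cli/collier gap|draw|profile|compare|hbonds|synth`), e.g.:

```sh
inst/cli/collier gap --input my_domains.fasta --out gapped.fasta
#> seq1    [8.8.13]
```

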