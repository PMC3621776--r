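Package: collier
Title: IMGT Colliers de Perles for Immunoglobulin and T Cell Receptor V Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Numbering, gapping and two-dimensional rendering of
    immunoglobulin (IG) and T cell receptor (TR) variable (V) domains.
    Implements the IMGT unique numbering for V domains (128 positions,
    standardized FR-IMGT/CDR-IMGT delimitations, conserved positions and
    anchors), gap placement at the top of the CDR loops, the IMGT amino
    acid classes (3 hydropathy, 5 volume, 11 physicochemical), per-position
    statistical profiles over sets of gapped domains, backbone hydrogen
    bond detection from PDB structures, and deterministic SVG output of
    one-layer and two-layer Collier de Perles bead diagrams with optional
    difference and hydrogen-bond overlays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
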