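Package: pappadyn
Title: Active-Site Annotation, Interaction-Network and Domain-Dynamics
    Analysis for Pappalysin Metalloproteases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural analysis of pappalysin
    metalloproteases (PAPP-A/PAPP-A2) and related metzincins: residue
    numbering conversion between precursor and mature sequences,
    HEXXHXXGXXH zinc-binding motif detection with geometric validation of
    the zinc coordination sphere, catalytic water and Met-turn, typed
    residue interaction networks (hydrogen bond, hydrophobic, pi-pi,
    metal) with deterministic shortest-path analysis from distal mutation
    sites to the catalytic zinc, Kabsch superposition and domain RMSD,
    and molecular-dynamics trajectory statistics (inter-domain
    center-of-mass distance series, exponential moving averages, block
    averaging, fixed-bandwidth Gaussian kernel density estimation and
    open/closed conformational state classification). Includes synthetic
    structure and trajectory generators with known ground truth so every
    stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
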