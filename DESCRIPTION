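Package: emval
Title: Model-Against-Map Validation for Cryo-EM Structures
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Validation of atomic models against cryo-EM density maps:
    MRC2014/CCP4 map and PDB/mmCIF model input and output, simulation of
    theoretical maps from models, Fourier shell correlation (FSC) and the
    FSCavg global fit score, per-residue SMOC local fit scores, false
    discovery rate (FDR) confidence maps and FDR-backbone scores,
    MolProbity-style geometry validation (clashscore, Ramachandran,
    rotamers, CaBLAM, composite score), amplitude-scaled difference maps
    and model-based local sharpening, and a collation step that flags
    low-scoring residues and clusters them by spatial proximity.
    Includes a synthetic fixture generator (ideal helices, simulated
    noisy maps, controlled defects) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
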