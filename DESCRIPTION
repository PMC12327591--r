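Package: sphereMotif
Title: High-Fluctuation 3D Motif Detection in Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies high-fluctuation three-dimensional motifs in molecular
    dynamics trajectories of proteins. A trajectory supplied as a multi-model
    PDB file is validated (non-protein chains, ligands, ions and waters are
    discarded; residues with missing heavy atoms are rejected, with a full
    validation log), a spatial sphere of radius d is built around every
    residue's C-alpha on a target frame, and a root-mean-square deviation
    score is computed for each sphere between every pair of consecutive
    frames, either raw or after optimal Kabsch superposition. The top
    percentage of (residue, frame transition) cells by score are reported as
    high-fluctuation motifs, exported as a CSV score matrix, a motif report,
    B-factor-annotated PDB frames for viewer coloring, and viewer selection
    strings. A deterministic synthetic-trajectory generator with rigid-body
    motion and localized Gaussian perturbations supports testing, and a
    command-line front-end ties the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
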