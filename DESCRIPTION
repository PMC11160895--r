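Package: pmhcdyn
Title: Conformational Dynamics and Biophysics of Peptide-MHC Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for studying conformational dynamics of
    peptides bound in class I MHC binding grooves. Reads structures and
    trajectories (PDB, multi-model PDB, XYZ frames), computes superposition-
    based RMSD series and pairwise RMSD matrices, mass-weighted RMSF
    profiles, backbone and side-chain torsions, the D-score backbone
    divergence metric, voxel occupancy grids, agglomerative conformational
    clustering with Calinski-Harabasz model selection, solvent accessible
    surface areas, contacts and hydrogen bonds, van der Waals overlap, and
    under-peptide cavity volumetrics. Companion fitting routines cover SPR
    steady-state affinity and dissociation kinetics, electrostatic
    destabilization from pKa shifts, differential scanning fluorimetry melt
    derivatives, and 1D NMR Lorentzian line-shape deconvolution with slow
    conformational exchange models (saturation transfer and EXSY). A
    synthetic-data module generates groove/peptide fixtures and instrument
    data with planted ground truth so the whole pipeline is testable
    without molecular dynamics engines or instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    Matrix,
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
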