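Package: campfep
Title: Alchemical Binding Free-Energy Analysis for cAMP-CNBD Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis of alchemical free-energy perturbation
    (FEP) calculations of cyclic-AMP binding to the cyclic-nucleotide-binding
    domains (CNBDs) of HCN channel isoforms. Parses per-window energy-difference
    records and pair-interaction energy logs, estimates window and total free
    energies by exponential averaging and the Bennett Acceptance Ratio,
    computes a per-residue interaction free-energy decomposition, evaluates
    trajectory quality-control metrics (ligand center-of-mass displacement,
    ligand RMSD after Kabsch superposition, lid distance, inter-helix angle,
    hydrogen-bond geometry) for replicate selection, and aggregates pose-level
    estimates into isoform binding free energies. A synthetic-data module
    generates Crooks-consistent Gaussian work samples, per-residue energy
    streams, and toy CNBD-like trajectories with known ground truth so the
    whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
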