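Package: quadhop
Title: Hole-Transport Analysis for Tryptophan Quadruplexes at Protein Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis toolkit for hole (electron-vacancy)
    transport through tryptophan clusters, centred on the four-indole
    quadruplex at the protein-protein interface of a dimeric azurin
    photosensitizer construct (PDB accession 6MJS). Provides parsers for
    PDB/mmCIF structures and multi-model coordinate trajectories;
    distance-based conformer statistics and 2D structural maps; exclusive
    water coordination numbers, 3D water-oxygen density grids and
    difference-density maps that quantify sub-Angstrom hydration shifts upon
    forced hole transfer; localization and delocalization statistics for
    per-fragment charge/spin time series; point-charge electrostatic
    potentials with component partitioning; linear-response reaction free
    energies and reorganization energies from vertical energy-gap ensembles;
    Marcus-theory hopping networks with feasibility screening, master-equation
    population dynamics and adiabaticity diagnostics; and a PDB-wide
    tryptophan-cluster miner. A synthetic-data module generates every input
    class with planted ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
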