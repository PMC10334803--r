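Package: wlcgating
Title: Worm-Like-Chain Mechanics of Ion-Channel Gating from Tetramer Structures
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the entropic-spring forces, elastic energies and gating
    thermodynamics exerted by unfolded peptide linkers in tetrameric
    ligand-gated channels such as MthK. Reads channel structures from PDB or
    mmCIF files, superposes them on the pore domain, aligns the fourfold pore
    axis to z, measures per-subunit linker end-to-end extensions and their
    vertical and radial components, and converts them to forces, energies and
    spring constants with the Marko-Siggia worm-like-chain interpolation.
    Includes transition-state chimera construction, signed path works around
    the gating cycle, robust outlier detection, open-probability and
    ligand-affinity free-energy conversions, and a synthetic C4-tetramer
    generator with exact ground truth for end-to-end pipeline validation.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
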