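# wlcgating

Worm-like-chain (WLC) mechanics of ion-channel gating, computed from
tetrameric channel structures.

In ligand-gated channels of the MthK family, calcium binding to the
intracellular RCK gating ring spreads the ring outward; short peptide
linkers connecting the ring (Ser115) to the pore-lining helices (Ile99) are
unfolded in the open state and act as *entropic springs* that pull the
bundle-crossing gate open. Because an unfolded polypeptide's
force–extension behaviour is quantitatively described by the Marko–Siggia
WLC interpolation, the pulling force of each linker can be read directly
off its Cα-to-Cα end-to-end distance in a cryo-EM structure — an "ideal
pulling experiment" performed by the protein itself. This package turns
that idea into a reproducible pipeline for structural biologists and
biophysicists working on mechanical coupling in channel gating.

## The model

For a linker of `n` residues with per-residue persistence length
`l_p = 0.38 nm`, contour length `L_C = n·l_p`, and thermal energy
`k_BT = 4.114 pN·nm`, the restoring force at end-to-end extension `x` is

    F(x) = (k_BT / l_p) · [ 1/4·(1 − x/L_C)^−2 + x/L_C − 1/4 ]

The stored elastic energy is the closed-form integral of `F` from 0 to `x`
(reported in units of `k_BT`), and the local spring constant is `dF/dx`.
On an axis-aligned tetramer the force decomposes into a vertical component
`F_z = F·L_z/L` along the pore axis and a radial component
`F_xy = F·L_xy/L` that pulls the gate open. Hypothetical transition states
are built as chimeras (open-ring/closed-pore and closed-ring/open-pore
anchors), and signed path works around the closed → TS1 → open → TS2 →
closed cycle follow from the energy as a state function. Two-state gating
thermodynamics (`ΔG = −k_BT·ln(P_O/(1−P_O))`) and standard-state binding
energies (`|ΔG⁰| = k_BT·ln(1/K_D)`) connect the mechanics to
electrophysiology.

## Worked example

Pure spring numerics need no structures:

```r
library(wlcgating)
p <- wlc_params()                       # 16-residue linker defaults
wlc_force(29.4, p)                      # 12.7 pN at the mean open-state extension
wlc_energy(0, 29.4, p)                  # 3.7 kT stored in that linker
wlc_stiffness(29.1, p)                  # 8.1 pN/nm local spring constant
delta_g_from_open_probability(0.994)    # -5.1 kT, strongly open-favouring
```

A full ensemble analysis, here on synthetic structures with exact ground
truth (replace the list with your own PDB/mmCIF file paths to analyze real
structures; the closed state is auto-detected from its resolved linkers):

```r
opens <- lapply(1:6, function(i)
  generate_tetramer(synthetic_spec(tilt_angle = 25 * (i - 1) / 5,
                                   azimuthal_offset = 3 * (i - 1),
                                   noise_sd = 0.7, seed = 100 + i),
                    id = sprintf("open%02d", i), state_label = "open")$structure)
fit <- gating_analysis(c(opens, list(closed_state_fixture()$structure)))
fit
#> Entropic-spring gating analysis
#>   closed state : synthetic-closed (inferred)
#>   open states  : open01, open02, open03, open04, open05, open06
#>   linkers      : 24 unfolded (0 excluded as folded)
#>   extension    : 30.0 +/- 2.5 Angstrom (pooled, n = 24)
#>   force        : 13.4 +/- 2.5 pN; radial 9.7 +/- 1.3 pN
#>   energy       : 3.9 +/- 0.9 kT per linker
#>   outliers     : 4 flagged, max excess energy 2.6 kT
fit$paths$pooled$path1
#> path1: 4.85 +/- 0.53 kT per subunit (19.41 kT per tetramer)
```

The pooled extension (30.0 ± 2.5 Å) recovers the generator's calibrated
29.4 Å mean (rigid-ring tilt inflates the most tumbled member slightly);
each linker's ~13 pN pull stores ~3.9 kT, and loading the springs from the
closed geometry to transition state 1 costs ~4.9 kT per subunit, released
again as the gate opens (path 2) and the ring relaxes (path 3).
`write_gating_report(fit, "out/")` serializes per-linker and per-structure
CSVs plus a unit-tagged JSON report, and `summary(fit)`/`plot(fit)` give
the full table and the force–extension figure. A command-line wrapper with
`wlc`, `thermo`, `analyze`, `paths` and `simulate` subcommands ships in
`inst/scripts/wlc-gating`.

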