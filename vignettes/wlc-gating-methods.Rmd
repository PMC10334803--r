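---
title: "Entropic-spring analysis of channel gating: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropic-spring analysis of channel gating: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wlcgating)
```

## The physical model

An unfolded polypeptide of $n$ residues behaves as a worm-like chain: a
semiflexible polymer whose restoring force at end-to-end extension $x$ is
purely entropic. With per-residue persistence length $l_p$ and contour
length $L_C = n\,l_p$, the Marko–Siggia interpolation gives

$$F(x) = \frac{k_BT}{l_p}\left[\frac{1}{4}\left(1-\frac{x}{L_C}\right)^{-2}
  + \frac{x}{L_C} - \frac{1}{4}\right],$$

zero at zero extension, strictly increasing, divergent as $x \to L_C$.
The stored elastic energy between two extensions is its closed-form
integral,

$$\frac{U}{k_BT} = \frac{L_C}{l_p}\left[\frac{1}{4}\left(
  \frac{1}{1-x_2/L_C}-\frac{1}{1-x_1/L_C}\right)
  + \frac{x_2^2-x_1^2}{2L_C^2} - \frac{1}{4}\frac{x_2-x_1}{L_C}\right],$$

and the local spring constant is $k = dF/dx$. In MthK-like channels the
16-residue Ile99–Ser115 linker is unfolded (and crystallographically
unresolved) in open states, so the Cα–Cα anchor distance *is* the spring
extension, and every structure is a calibrated force measurement.

**Sign convention.** Stored stretching energy is reported positive; path
works are signed, negative meaning energy released. The textbook
work-integral convention would attach a leading minus to the loading
integral; we deliberately report the spring's stored energy instead, which
matches the positive energies and signed path prose a reader expects
(loading cost positive, release negative). Energy is a state function, so
the four path works close to zero around the gating cycle to numerical
precision — a bookkeeping identity the test suite asserts at $10^{-9}\,k_BT$.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `persistence_length` | 0.38 | nm | consensus per-residue value from polypeptide force spectroscopy |
| `thermal_energy` | 4.114 | pN·nm | $k_BT$ near room temperature; configurable via `temperature` (K) as $0.0138065\,T$ |
| `n_units` | 16 | residues | the Ile99→Ser115 Cα span; this count reproduces the published 20.3 pN / 8.1 pN·nm⁻¹ spot values, 15 or 17 do not |
| `pore_anchor`, `ring_anchor` | 99, 115 | residue | last/first resolved residues flanking the unfolded linker |
| `selection` | 20–83 | residue | pore domain from the first transmembrane helix to the glycine hinge: the conformationally constant core used for superposition and axis determination |
| `mad_multiplier` | 2.5 | raw MADs | length-outlier fence (below) |

Interfaces accept Ångström by default (the structural convention) and nm
on request; internally everything is nm, pN, pN·nm, with energies in
$k_BT$ multiples. Extensions beyond 98 % of $L_C$ raise a warning rather
than an error: physiological linkers reach at most ~60 % of contour, so
the guard only fires on pathological input while still letting a user
explore the divergence.

## Geometry pipeline

Each tetramer is superposed on its pore-domain Cα (Kabsch least squares
over all four chains, uniform weights) and rotated so the fourfold
pseudo-symmetry axis coincides with $z$. The axis is found by superposing
chains (1,2,3,4) onto (2,3,4,1): for a near-C4 assembly that cyclic
permutation is a ~90° rotation whose axis is the symmetry axis. A
principal-axis alternative (the gyration-tensor eigenvector with the most
distinct eigenvalue) is available behind `method = "principal"`; both
agree to well under half a degree on near-symmetric input, and all length
and force magnitudes are rigid-motion invariant anyway — only the
$L_z$/$L_{xy}$ split depends on the frame. The $z$ sign is fixed by
requiring the selectivity-filter end of the pore domain to sit above the
linker anchors. Inputs that fail the permutation fit (RMSD above 3 Å, or a
rotation far from 90°) are rejected as non-tetrameric rather than silently
analyzed.

Anchor rings are summarized by their mean distance from the axis (radius)
and the mean azimuthally-adjacent spacing (interresidue distance); for an
exact C4 square the latter equals radius·√2, which pins down the
adjacent-pair reading of "interresidue distance" against the published
closed-state values (7.9 Å and 43.4 Å from radii 5.6 Å and 30.7 Å).

**Transition-state chimeras.** TS1 joins open-state ring anchors to
closed-state pore anchors (activated ring, still-closed gate); TS2 the
reverse. Chains are paired by minimal azimuthal offset of the pore
anchors; because the closed state is C4-symmetric its coordinates are
pairing-invariant, which the tests assert under chain relabeling. The
extension at the start of path 1 is the closed-state anchor separation
itself, i.e. the springs are treated as always unfolded along the cycle;
no alternative start point is computed.

## Statistics and outliers

Two pooled statistic sets are reported, mirroring the dual bookkeeping a
mixed ensemble needs: `pooled` over every unfolded linker (the headline
means), and `normal` excluding robust length outliers. A linker is flagged
when its length deviates from the pooled median by more than 2.5 raw
median absolute deviations. The *raw* MAD (no 1.4826 normal-consistency
factor) is a deliberate choice: the scientifically interesting outlier — a
single highly stretched linker paying for a neighbour's folded one — sits
near 2.5 sample standard deviations, exactly where a normal-scaled fence
would flip on sampling noise; the raw fence flags it decisively. The cost
is a conservative fence (~1.7σ) that can clip the tails of a well-behaved
pool, which is why the pooled set, not the normal set, carries the primary
means. Each flagged linker is priced by its excess energy relative to the
mean length of the unflagged pool. Folded-linker subunits (≥ 80 % of
linker residues resolved) are excluded *before* pooling — an unfolded
chain is a model precondition, not an outlier — and logged per subunit so
the n-bookkeeping stays auditable.

Mean force is the mean of per-linker forces, not the force at the mean
length; with a convex force–extension curve the two differ, and the
per-linker convention is the one consistent with pooled-ensemble
arithmetic.

## The synthetic generator

`generate_tetramer()` builds C4 tetramers with exact ground truth: pore
anchors on a ring of radius 17.0 Å, ring anchors on a rigid ring of radius
39.3 Å below them (the measured open-state radii), with the vertical drop
solved so the untilted linker is 29.4 Å — the calibrated open-state mean.
The closed fixture uses the measured closed radii (5.6 / 30.7 Å) with an
11.2 Å drop, chosen so the closed anchor separation (~27.5 Å) stores
~3.1 $k_BT$, the value consistent with the gating cycle's energy
bookkeeping; the published record fixes the closed radii but not the
vertical offset, so this is the package's own calibration.

**Tilt pivot.** Ring tumbling is a rigid-body rotation of the intact ring
— never independent per-subunit displacement — about an in-plane axis
through the *dome center*: the point on the symmetry axis at the
pore-anchor level from which the tethered ring hangs. Pivoting about the
ring's own center would shrink both diagonal partners' radial positions by
the same cos θ and destroy the characteristic compensation; with the dome
pivot, the subunit rising toward the membrane plane swings radially
outward while its diagonal partner drops and narrows, reproducing the real
tumbling-ring geometry. This pivot also leaves per-structure mean forces
nearly tilt-invariant (< 1.5 pN spread across 0–25°), the stability the
ensemble analysis relies on. The pivot height is configurable
(`tilt_pivot_height`) for users who want a different dome.

The test ensemble fixes the study conditions once: six open structures,
tilts 0–25° (one markedly tumbled member), ring twists up to 15°, 0.7 Å
iid coordinate noise — spreading linker lengths ~2–3 Å about the 29.4 Å
mean, like a real cryo-EM family. What the generator does *not* emulate:
real side chains, correlated domain motions, resolution-dependent
coordinate error, or partially ordered linkers; passing tests therefore
validate the pipeline's geometry, bookkeeping and spring mathematics, not
the biological accuracy of any particular deposited structure.

## Numerical choices

- The energy closed form is used everywhere; adaptive quadrature of the
  force is the independent cross-check (10⁻⁹ relative over 1000 random
  intervals in the acceptance tests), never the implementation.
- `wlc_inverse_force()` uses bracketed root finding (`uniroot`, tolerance
  10⁻¹³ on extension); monotonicity guarantees uniqueness.
- Kabsch superposition handles the reflection case via the SVD determinant
  sign; fits with fewer than 3 common atoms are refused.
- Zero-length linkers exert zero force with a well-defined (0, 0)
  decomposition; ties in altloc occupancy resolve lexicographically;
  insertion codes are rejected loudly rather than renumbered.
- File fixtures round-trip at PDB field precision (10⁻³ Å), which bounds
  every file-based comparison tolerance in the tests.

## Problem sizes

The shipped tests run entirely on generated data: ensembles of six
4-chain tetramers with ~81 Cα per chain, 1000-case property sweeps for the
energy/stiffness oracles, and 100-seed Monte-Carlo checks for the noisy
superposition law. These sizes make the whole suite run in seconds while
leaving every statistical assertion comfortably powered; they are the
package's chosen desk-scale defaults, and all of them scale up by passing
larger `n`/`angles`/`noise_sd` to the generator.

## Known limitations

- The WLC treatment applies only to *unfolded* linkers; structurally
  resolved linkers (as in BK channels) need a different elastic model, and
  the package deliberately refuses to force-fit them.
- The energy of linker folding and of four-helix coiling at the closed
  gate is not computable from this geometry; path 4 is reported as its
  elastic component only, annotated with the folding-gain lower bound from
  the outlier analysis.
- Deposited-structure reproduction requires the user to supply the
  coordinate files; the package ships no third-party coordinates and the
  synthetic fixtures are labelled as such.
- Chimera transition states are geometric constructs, not observed
  intermediates; their forces are only as meaningful as the
  always-unfolded-linker assumption behind them.
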