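# Shared fixture builders for the test suite. Everything is generated in
# code; no files ship with the package.

# a standard open-state synthetic tetramer (exact C4, no noise)
fix_open <- function(tilt = 0, noise = 0, seed = 1, offset = 0, ...) {
  generate_tetramer(
    synthetic_spec(tilt_angle = tilt, noise_sd = noise, seed = seed,
                   azimuthal_offset = offset, ...),
    id = sprintf("open-t%g-s%d", tilt, seed), state_label = "open")
}

# a small ensemble of open structures emulating a cryo-EM family: rigid
# ring tilts up to a markedly tumbled member and sub-Angstrom coordinate
# noise, spreading linker lengths a few Angstrom about the calibrated mean
fix_ensemble <- function(n = 6, max_tilt = 25, noise = 0.7, seed0 = 100) {
  lapply(seq_len(n), function(i) {
    generate_tetramer(
      synthetic_spec(tilt_angle = max_tilt * (i - 1) / max(1, n - 1),
                     azimuthal_offset = 3 * (i - 1),
                     noise_sd = noise, seed = seed0 + i),
      id = sprintf("ens%02d", i), state_label = "open")
  })
}

# apply a rigid motion (rotation about given axis by deg, then translation)
# to every chain of a structure model
rigid_move <- function(structure, deg = 30, axis = c(0, 0, 1),
                       translation = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  a <- deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
  out <- structure
  out$chains <- lapply(structure$chains, function(ch) {
    ch$ca <- ch$ca %*% t(R) + matrix(translation, nrow(ch$ca), 3, byrow = TRUE)
    ch
  })
  attr(out, "aligned") <- NULL
  out
}

# build an anchor_set directly from coordinate matrices (rows = chains)
make_anchors <- function(pore, ring, id = "manual", aligned = TRUE) {
  chains <- LETTERS[seq_len(nrow(pore))]
  rownames(pore) <- rownames(ring) <- chains
  structure(list(structure_id = id, chain_ids = chains,
                 pore = pore, ring = ring, aligned = aligned),
            class = "anchor_set")
}

# deterministic sample of n lengths with given mean and sd: scaled normal
# quantiles, symmetric, exact first two moments
lengths_with_moments <- function(n, mean, sd) {
  q <- stats::qnorm(stats::ppoints(n))
  mean + sd * q / stats::sd(q)
}
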