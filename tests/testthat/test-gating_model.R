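# Linker mechanics, chimeras, path works, outliers and thermodynamics.

test_that("force decomposition follows the linker direction", {
  # 45-degree linker: equal vertical and radial components
  L <- 29.4
  geo <- data.frame(chain_id = "A", L = L, L_z = L / sqrt(2),
                    L_xy = L / sqrt(2))
  m <- linker_mechanics(geo)
  expect_equal(m$F_z, m$F_xy)
  expect_equal(m$F_z, m$F / sqrt(2), tolerance = 1e-12)
  # purely radial stretched outlier
  geo2 <- data.frame(chain_id = "A", L = 36.2, L_z = 0, L_xy = 36.2)
  m2 <- linker_mechanics(geo2)
  expect_equal(round(m2$F_xy, 1), 20.3)
  expect_equal(m2$F_z, 0)
  # zero-length linker exerts no force
  m0 <- linker_mechanics(data.frame(chain_id = "A", L = 0, L_z = 0, L_xy = 0))
  expect_equal(m0$F, 0)
  expect_equal(m0$U, 0)
})

test_that("force components close Pythagoreanly over random directions", {
  set.seed(101)
  n <- 1000
  L <- runif(n, 5, 45)
  theta <- runif(n, 0, pi / 2)
  geo <- data.frame(chain_id = as.character(seq_len(n)), L = L,
                    L_z = L * cos(theta), L_xy = L * sin(theta))
  m <- linker_mechanics(geo)
  expect_equal(m$F^2, m$F_z^2 + m$F_xy^2, tolerance = 1e-6)
  expect_true(all(m$U >= 0))
})

test_that("structure summaries compute means and sample SDs", {
  geo <- data.frame(chain_id = LETTERS[1:4], L = rep(29.4, 4),
                    L_z = rep(19.16, 4), L_xy = rep(22.3, 4))
  s <- structure_summary(linker_mechanics(geo), "ideal")
  expect_equal(s$n_linkers, 4)
  expect_equal(s$F_sd, 0)
  expect_equal(s$L_mean, 29.4)
  expect_error(structure_summary(geo[0, ]), "at least one")
})

test_that("the identity chimera reproduces native linker lengths", {
  g <- fix_open(tilt = 10)
  a <- extract_anchors(g$structure)
  ts1 <- build_transition_chimera(a, a, "TS1")
  expect_equal(sort(linker_lengths(ts1)$L), sort(linker_lengths(a)$L),
               tolerance = 1e-9)
})

test_that("chimera lengths match direct coordinate arithmetic", {
  op <- extract_anchors(fix_open(tilt = 15, offset = 10)$structure)
  cl <- extract_anchors(closed_state_fixture()$structure)
  ts1 <- build_transition_chimera(op, cl, "TS1")
  ts2 <- build_transition_chimera(op, cl, "TS2")
  # oracle: both generators emit chains at matching azimuths (A at 0,
  # B at 90, ...), so the subunit pairing is the identity and the chimera
  # length is a direct distance between the swapped endpoint coordinates
  exp_ts1 <- unname(sqrt(rowSums((op$ring - cl$pore)^2)))
  exp_ts2 <- unname(sqrt(rowSums((cl$ring - op$pore)^2)))
  expect_equal(sort(linker_lengths(ts1)$L), sort(exp_ts1), tolerance = 1e-9)
  expect_equal(sort(linker_lengths(ts2)$L), sort(exp_ts2), tolerance = 1e-9)
})

test_that("chimera statistics are invariant to closed-state chain relabeling", {
  op <- extract_anchors(fix_open(tilt = 12, offset = 30)$structure)
  cl <- extract_anchors(closed_state_fixture()$structure)
  cl_rot <- cl
  perm <- c(3, 4, 1, 2)
  cl_rot$pore <- cl$pore[perm, ]
  cl_rot$ring <- cl$ring[perm, ]
  rownames(cl_rot$pore) <- rownames(cl_rot$ring) <- cl$chain_ids
  for (w in c("TS1", "TS2")) {
    L1 <- sort(linker_lengths(build_transition_chimera(op, cl, w))$L)
    L2 <- sort(linker_lengths(build_transition_chimera(op, cl_rot, w))$L)
    expect_equal(L1, L2, tolerance = 1e-9)
  }
})

test_that("chimeras demand aligned anchor sets", {
  op <- extract_anchors(fix_open()$structure)
  cl <- extract_anchors(closed_state_fixture()$structure)
  op$aligned <- FALSE
  expect_error(build_transition_chimera(op, cl, "TS1"), "aligned")
})

test_that("path work is the signed elastic energy difference", {
  a <- make_anchors(matrix(0, 4, 3),
                    cbind(29.1, 0, 0)[rep(1, 4), , drop = FALSE])
  b <- make_anchors(matrix(0, 4, 3),
                    cbind(36.2, 0, 0)[rep(1, 4), , drop = FALSE])
  expect_equal(path_work(a, a)$per_subunit, rep(0, 4))
  pw <- path_work(a, b)
  expect_equal(pw$per_subunit, rep(wlc_energy(29.1, 36.2), 4))
  expect_equal(pw$mean, 2.75, tolerance = 0.01 / 2.75)
  expect_equal(pw$per_tetramer, 4 * pw$mean)
  # releasing work is negative
  expect_lt(path_work(b, a)$mean, 0)
})

test_that("the four gating paths close the cycle exactly", {
  cl <- extract_anchors(closed_state_fixture()$structure)
  for (tilt in c(0, 10, 20)) {
    op <- extract_anchors(fix_open(tilt = tilt, noise = 0.4,
                                   seed = 50 + tilt)$structure)
    paths <- gating_paths(cl, op)
    total <- paths$path1$per_subunit + paths$path2$per_subunit +
      paths$path3$per_subunit + paths$path4_elastic$per_subunit
    expect_equal(total, rep(0, 4), tolerance = 1e-9)
    # telescoping: loading then opening equals the signed closed->open
    # energy step (closed lengths are C4-identical scalars)
    L_closed <- mean(linker_lengths(cl)$L)
    L_open <- sort(linker_lengths(op)$L)
    direct <- wlc_energy(rep(0, 4), L_open) -
      wlc_energy(0, L_closed)
    expect_equal(sort(paths$path1$per_subunit + paths$path2$per_subunit),
                 sort(direct), tolerance = 1e-9)
    # canonical signs: loading positive, the two release paths negative
    expect_gt(paths$path1$mean, 0)
    expect_lt(paths$path2$mean, 0)
    expect_lt(paths$path3$mean, 0)
  }
})

test_that("outlier detection flags the stretched linker and prices its excess", {
  L <- c(lengths_with_moments(22, 29.1, 2.8), 36.2)
  mech <- data.frame(chain_id = as.character(seq_along(L)), L = L,
                     L_z = L / sqrt(2), L_xy = L / sqrt(2))
  rep <- detect_outliers(linker_mechanics(mech))
  expect_true(rep$table$outlier[23])
  expect_equal(rep$normal_mean_L, 29.1, tolerance = 0.5 / 29.1)
  expect_equal(unname(rep$excess_energy[["23"]]), 2.7, tolerance = 0.1 / 2.7)
  # all-equal lengths: nothing to flag
  same <- data.frame(chain_id = LETTERS[1:4], L = rep(29, 4),
                     L_z = rep(29, 4) / sqrt(2), L_xy = rep(29, 4) / sqrt(2))
  expect_equal(sum(detect_outliers(linker_mechanics(same))$table$outlier), 0)
})

test_that("a linker spiked beyond the MAD threshold is the only flag", {
  # evenly spread pool: its extremes sit at 2 raw MADs, inside the fence
  L <- seq(27, 31, length.out = 23)
  med <- median(L)
  mad_raw <- median(abs(L - med))
  L <- c(L, med + 4 * mad_raw)  # spike 4 raw MADs above the median
  mech <- data.frame(chain_id = as.character(seq_along(L)), L = L,
                     L_z = L, L_xy = 0)
  rep <- detect_outliers(linker_mechanics(mech))
  expect_equal(which(rep$table$outlier), length(L))
})

test_that("length-perturbed linkers reproduce the published predictions", {
  short <- perturbed_linker_prediction(-3, 29.1)
  expect_equal(short$F, 19.7, tolerance = 0.05 / 19.7)   # printed "~20 pN"
  expect_equal(short$U, 5.0, tolerance = 0.1 / 5)
  long <- perturbed_linker_prediction(+3, 29.1)
  expect_equal(long$F, 9.3, tolerance = 0.05 / 9.3)      # printed "~9 pN"
  expect_equal(long$U, 2.8, tolerance = 0.1 / 2.8)
  ident <- perturbed_linker_prediction(0, 29.1)
  expect_equal(ident$F, as.numeric(wlc_force(29.1)))
  expect_equal(ident$U, wlc_energy(0, 29.1))
  # shortening below the extension is infeasible
  expect_error(perturbed_linker_prediction(-9, 29.1), "contour")
  expect_error(perturbed_linker_prediction(-16, 29.1), "chain unit")
})

test_that("open probabilities convert to gating free energies and back", {
  expect_equal(delta_g_from_open_probability(0.994)$delta_g, -5.1,
               tolerance = 0.05 / 5.1)
  expect_equal(delta_g_from_open_probability(0.5)$delta_g, 0)
  expect_equal(delta_g_from_open_probability(0.0001)$delta_g, 9.2,
               tolerance = 0.05 / 9.2)
  expect_equal(delta_g_from_open_probability(0.0003)$delta_g, 8.1,
               tolerance = 0.05 / 8.1)
  # conversion and inverse are mutual identities
  for (p in c(1e-5, 1e-3, 0.2, 0.5, 0.9, 0.994, 1 - 1e-6)) {
    dg <- delta_g_from_open_probability(p)$delta_g
    expect_equal(open_probability_from_delta_g(dg), p, tolerance = 1e-12)
  }
  expect_error(delta_g_from_open_probability(0))
  expect_error(delta_g_from_open_probability(1))
})

test_that("dissociation constants convert to binding free energies", {
  one <- binding_energy_from_kd(1e-3, 1)
  expect_equal(one$per_site, 6.9, tolerance = 0.05 / 6.9)
  expect_equal(binding_energy_from_kd(1, 1)$total, 0)
  six <- binding_energy_from_kd(1e-3, 6)
  expect_equal(six$total, 41.4, tolerance = 0.05 / 41.4)
  expect_equal(six$delta_g, -six$total)
  expect_error(binding_energy_from_kd(0))
  expect_error(binding_energy_from_kd(1e-3, 0))
})
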