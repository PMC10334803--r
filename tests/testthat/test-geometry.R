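# Superposition, axis alignment, linker lengths and ring spread metrics.

test_that("superposing a structure onto itself is the identity", {
  g <- fix_open(tilt = 5)
  res <- superpose_on_pore(g$structure, g$structure)
  expect_equal(res$rmsd, 0, tolerance = 1e-9)
  expect_equal(res$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(res$transform$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("superposition recovers a known rigid motion", {
  g <- fix_open(tilt = 10, noise = 0.2, seed = 11)
  moved <- rigid_move(g$structure, deg = 30, axis = c(0, 0, 1),
                      translation = c(5, -3, 12))
  res <- superpose_on_pore(moved, g$structure)
  expect_lt(res$rmsd, 1e-6)
  a_ref <- extract_anchors(g$structure)
  a_fit <- extract_anchors(res$structure)
  expect_equal(a_fit$pore, a_ref$pore, tolerance = 1e-6)
  # determinant +1, orthonormal
  R <- res$transform$rotation
  expect_equal(det(R), 1, tolerance = 1e-9)
  expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
})

test_that("fit RMSD of a noisy copy matches the expected Gaussian level", {
  g <- fix_open()
  sigma <- 0.5
  rmsds <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    pert <- g$structure
    pert$chains <- lapply(pert$chains, function(ch) {
      ch$ca <- ch$ca + matrix(rnorm(length(ch$ca), 0, sigma), nrow(ch$ca), 3)
      ch
    })
    superpose_on_pore(pert, g$structure)$rmsd
  }, numeric(1))
  # iid sigma per coordinate gives RMSD ~ sigma * sqrt(3), slightly reduced
  # by the 6 fitted rigid degrees of freedom
  expect_equal(mean(rmsds), sigma * sqrt(3), tolerance = 0.03)
})

test_that("superposition RMSD is symmetric under role swap", {
  a <- fix_open(tilt = 6, noise = 0.4, seed = 21)
  b <- fix_open(tilt = 14, noise = 0.4, seed = 22)
  r1 <- superpose_on_pore(a$structure, b$structure)$rmsd
  r2 <- superpose_on_pore(b$structure, a$structure)$rmsd
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("too-sparse selections refuse to superpose", {
  g <- fix_open()
  expect_error(superpose_on_pore(g$structure, g$structure, selection = 300),
               "common selection atoms")
})

test_that("axis alignment restores a tilted ideal C4 tetramer", {
  g <- fix_open()
  moved <- rigid_move(g$structure, deg = 37, axis = c(1, 2, 0.5),
                      translation = c(10, 20, -5))
  back <- align_pore_axis_to_z(moved)
  a <- extract_anchors(back)
  centroid <- colMeans(a$pore)
  expect_lt(sqrt(centroid[1]^2 + centroid[2]^2), 1e-6)
  # exact C4: equal radial distances per chain
  radii <- sqrt(a$pore[, 1]^2 + a$pore[, 2]^2)
  expect_lt(max(radii) - min(radii), 1e-6)
  # z sign convention: pore body (selectivity-filter side) above the anchors
  sel_z <- mean(back$chains$A$ca[as.character(20:83), 3])
  expect_gt(sel_z, mean(a$pore[, 3]))
})

test_that("aligning an already-aligned structure changes nothing", {
  g <- fix_open()
  once <- align_pore_axis_to_z(g$structure)
  twice <- align_pore_axis_to_z(once)
  expect_equal(extract_anchors(twice)$ring, extract_anchors(once)$ring,
               tolerance = 1e-6)
})

test_that("permutation and principal-axis methods agree on near-C4 input", {
  g <- fix_open(tilt = 10, noise = 0.15, seed = 5)
  moved <- rigid_move(g$structure, deg = 25, axis = c(1, 0, 1),
                      translation = c(3, 4, 5))
  a1 <- extract_anchors(align_pore_axis_to_z(moved, method = "permutation"))
  a2 <- extract_anchors(align_pore_axis_to_z(moved, method = "principal"))
  # both frames put the same radial and vertical anchor coordinates (the
  # frames may differ by a rotation about z); agreement well under 0.5
  # degrees of axis tilt over ~40 Angstrom lever arms
  expect_equal(sort(unname(sqrt(a1$ring[, 1]^2 + a1$ring[, 2]^2))),
               sort(unname(sqrt(a2$ring[, 1]^2 + a2$ring[, 2]^2))),
               tolerance = 0.05)
  expect_equal(sort(unname(a1$ring[, 3])), sort(unname(a2$ring[, 3])),
               tolerance = 0.35)
  expect_equal(linker_lengths(a1)$L, linker_lengths(a2)$L, tolerance = 1e-6)
})

test_that("non-tetrameric point sets are rejected by the axis fit", {
  g <- fix_open()
  s <- g$structure
  set.seed(9)
  s$chains <- lapply(s$chains, function(ch) {
    ch$ca <- matrix(rnorm(length(ch$ca), 0, 20), nrow(ch$ca), 3,
                    dimnames = dimnames(ch$ca))
    ch
  })
  expect_error(align_pore_axis_to_z(s), "C4")
  s3 <- g$structure
  s3$chains <- s3$chains[1:3]
  expect_error(align_pore_axis_to_z(s3), "tetramer")
})

test_that("linker lengths decompose Pythagoreanly in the aligned frame", {
  # closed-form example: ring at (10, 0, -10) from pore at origin
  a <- make_anchors(pore = matrix(0, 4, 3),
                    ring = matrix(rep(c(10, 0, -10), each = 4), 4, 3))
  geo <- linker_lengths(a)
  expect_equal(geo$L, rep(sqrt(200), 4))
  expect_equal(geo$L_z, rep(10, 4))
  expect_equal(geo$L_xy, rep(10, 4))
  # coincident anchors
  a0 <- make_anchors(matrix(1, 4, 3), matrix(1, 4, 3))
  expect_equal(linker_lengths(a0)$L, rep(0, 4))
  # property: L^2 = L_z^2 + L_xy^2 on random geometries
  set.seed(31)
  for (i in 1:25) {
    a <- make_anchors(matrix(rnorm(12, 0, 10), 4, 3),
                      matrix(rnorm(12, 0, 10), 4, 3))
    geo <- linker_lengths(a)
    expect_equal(geo$L^2, geo$L_z^2 + geo$L_xy^2, tolerance = 1e-6)
  }
  # unaligned input carries no components
  g <- fix_open()
  an <- extract_anchors(g$structure)
  an$aligned <- FALSE
  expect_true(all(is.na(linker_lengths(an)$L_z)))
})

test_that("linker lengths are invariant under rigid motions", {
  g <- fix_open(tilt = 12, noise = 0.5, seed = 8)
  L0 <- linker_lengths(extract_anchors(g$structure))$L
  set.seed(77)
  for (i in 1:20) {
    moved <- rigid_move(g$structure, deg = runif(1, 0, 180),
                        axis = rnorm(3), translation = rnorm(3, 0, 30))
    an <- extract_anchors(moved)
    an$aligned <- TRUE  # components differ, L must not
    L1 <- linker_lengths(an)$L
    expect_equal(L1, L0, tolerance = 1e-9)
  }
})

test_that("spread metrics reproduce the square geometry closed forms", {
  sq <- function(r, z = 0) cbind(c(r, 0, -r, 0), c(0, r, 0, -r), z)
  m <- spread_metrics(sq(30.7))
  expect_equal(m$radius, 30.7)
  expect_equal(round(m$interresidue_distance, 1), 43.4)
  expect_equal(spread_metrics(sq(1))$interresidue_distance, sqrt(2))
  # C4 identity: interresidue = radius * sqrt(2)
  expect_equal(m$interresidue_distance, m$radius * sqrt(2), tolerance = 1e-9)
  # invariance under rotation about z
  set.seed(13)
  base <- sq(17, z = 3)
  for (i in 1:100) {
    a <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
    m2 <- spread_metrics(base %*% t(R))
    expect_equal(m2$radius, 17, tolerance = 1e-9)
    expect_equal(m2$interresidue_distance, 17 * sqrt(2), tolerance = 1e-9)
  }
  expect_error(spread_metrics(matrix(0, 3, 3)), "exactly 4")
})
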