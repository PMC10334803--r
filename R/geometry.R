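#' Rigid transforms and pore-frame geometry
#'
#' Internal helpers plus the exported geometry operations: least-squares
#' superposition on the pore domain, alignment of the fourfold pore axis to
#' z, per-linker end-to-end lengths with vertical/radial components, and the
#' ring spread metrics.
#'
#' @name geometry
NULL

# Kabsch least-squares superposition of point set P (n x 3) onto Q (n x 3).
# Returns rotation R (3 x 3, det +1) and translation t such that
# P %*% t(R) + t approximates Q; plus the residual rmsd.
.kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  if (nrow(P) < 3) stop("superposition needs at least 3 common atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cq - as.numeric(R %*% cp)
  moved <- P %*% t(R) + matrix(t, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

# apply a rigid transform (rotation R then translation t) to every CA of a
# structure model
.transform_structure <- function(structure, rotation, translation) {
  out <- structure
  out$chains <- lapply(structure$chains, function(ch) {
    ch$ca <- ch$ca %*% t(rotation) +
      matrix(translation, nrow(ch$ca), 3, byrow = TRUE)
    ch
  })
  out
}

# stack the CA of `selection` residues over all chains, using only residues
# present in every listed structure's corresponding chain (per chain index)
.common_selection <- function(a, b, selection) {
  if (length(a$chains) != length(b$chains))
    stop("structures have different chain counts")
  pa <- list(); pb <- list()
  for (i in seq_along(a$chains)) {
    ra <- intersect(as.character(selection), rownames(a$chains[[i]]$ca))
    rb <- intersect(as.character(selection), rownames(b$chains[[i]]$ca))
    common <- intersect(ra, rb)
    pa[[i]] <- a$chains[[i]]$ca[common, , drop = FALSE]
    pb[[i]] <- b$chains[[i]]$ca[common, , drop = FALSE]
  }
  list(a = do.call(rbind, pa), b = do.call(rbind, pb))
}

#' Superpose a structure onto a reference over the pore domain
#'
#' Least-squares (Kabsch) superposition of the mobile structure onto the
#' reference using the CA atoms of the pore-domain selection in all chains
#' (default residues 20-83: from the start of the first transmembrane helix
#' to the glycine hinge, the region that is conformationally constant across
#' gating states). Only residues resolved in both structures enter the fit.
#'
#' @param mobile,reference [read_structure()] models with equal chain counts.
#' @param selection integer vector of residue numbers to fit on.
#' @return A list with `structure` (the transformed mobile copy), `rmsd`
#'   (Angstrom) and `transform` (list with `rotation`, `translation`).
#' @export
superpose_on_pore <- function(mobile, reference, selection = 20:83) {
  stopifnot(inherits(mobile, "structure_model"),
            inherits(reference, "structure_model"))
  pts <- .common_selection(mobile, reference, selection)
  if (is.null(pts$a) || nrow(pts$a) < 3)
    stop("fewer than 3 common selection atoms; cannot superpose")
  fit <- .kabsch(pts$a, pts$b)
  out <- .transform_structure(mobile, fit$rotation, fit$translation)
  attr(out, "aligned") <- isTRUE(attr(reference, "aligned"))
  list(structure = out, rmsd = fit$rmsd,
       transform = fit[c("rotation", "translation")])
}

# axis (unit vector) and angle of a rotation matrix
.rotation_axis <- function(R) {
  e <- eigen(R)
  i <- which.min(abs(e$values - 1))
  axis <- Re(e$vectors[, i])
  axis <- axis / sqrt(sum(axis^2))
  angle <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  # fix the sign of the axis so that the rotation about +axis by +angle
  # reproduces R (compare the skew-symmetric part)
  skew <- (R - t(R)) / 2
  v <- c(skew[3, 2], skew[1, 3], skew[2, 1])  # = axis * sin(angle)
  if (sum(v * axis) < 0) axis <- -axis
  list(axis = axis, angle = angle)
}

# rotation matrix taking unit vector `from` to unit vector `to`
.rotation_between <- function(from, to) {
  from <- from / sqrt(sum(from^2)); to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c_ <- sum(from * to)
  if (abs(c_ + 1) < 1e-12) {
    # antiparallel: rotate pi about any axis orthogonal to `from`
    ortho <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ortho - sum(ortho * from) * from
    v <- v / sqrt(sum(v^2))
    return(2 * tcrossprod(v) - diag(3))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Align the fourfold pore axis of a tetramer to the z axis
#'
#' Determines the C4 pseudo-symmetry axis of the pore-domain CA set and
#' rigidly moves the structure so that this axis coincides with z and passes
#' through the origin in x, y. The default method superposes the selection
#' CA of chains (1,2,3,4) onto chains (2,3,4,1); for a (near-)C4 tetramer
#' that cyclic-permutation fit is a ~90-degree rotation whose axis is the
#' symmetry axis. A principal-axis alternative (the gyration-tensor
#' eigenvector with the most distinct eigenvalue) is available. The z sign
#' is chosen so that the selectivity-filter end of the pore domain (the
#' lower-numbered selection residues) sits above the linker anchor residues.
#'
#' @param structure a [read_structure()] model with 4 chains.
#' @param selection pore-domain residue numbers used for the axis fit.
#' @param method `"permutation"` (default) or `"principal"`.
#' @param anchor_residues residue numbers defining the "down" side for the z
#'   sign convention (default `c(99, 115)`).
#' @param max_symmetry_rmsd permutation-fit RMSD (Angstrom) above which the
#'   input is rejected as not C4-symmetric.
#' @return The transformed structure, with attribute `aligned = TRUE`.
#' @export
align_pore_axis_to_z <- function(structure, selection = 20:83,
                                 method = c("permutation", "principal"),
                                 anchor_residues = c(99, 115),
                                 max_symmetry_rmsd = 3) {
  stopifnot(inherits(structure, "structure_model"))
  method <- match.arg(method)
  if (length(structure$chains) != 4L)
    stop("axis alignment expects a 4-chain tetramer")

  sel <- lapply(structure$chains, .chain_ca, residues = selection)
  if (any(vapply(sel, nrow, integer(1)) < 3))
    stop("selection too sparse for axis determination")
  pts <- do.call(rbind, sel)
  centroid <- colMeans(pts)

  if (method == "permutation") {
    # residues common to all four chains, so chain i maps onto chain i+1
    common <- Reduce(intersect, lapply(sel, rownames))
    if (length(common) < 3) stop("selection too sparse for axis determination")
    P <- do.call(rbind, lapply(sel, function(m) m[common, , drop = FALSE]))
    Q <- do.call(rbind, lapply(sel[c(2, 3, 4, 1)],
                               function(m) m[common, , drop = FALSE]))
    fit <- .kabsch(P, Q)
    if (fit$rmsd > max_symmetry_rmsd)
      stop(sprintf(
        "structure is not C4-symmetric (permutation fit RMSD %.2f Angstrom)",
        fit$rmsd))
    ax <- .rotation_axis(fit$rotation)
    if (abs(ax$angle - pi / 2) > pi / 9)
      stop("cyclic-permutation rotation is not close to 90 degrees; not C4")
    axis <- ax$axis
  } else {
    cov <- crossprod(sweep(pts, 2, centroid)) / nrow(pts)
    e <- eigen(cov, symmetric = TRUE)
    # C4 symmetry forces two (near-)equal in-plane eigenvalues; the axis is
    # the eigenvector whose eigenvalue is farthest from the other two
    gaps <- vapply(1:3, function(i) min(abs(e$values[i] - e$values[-i])),
                   numeric(1))
    axis <- e$vectors[, which.max(gaps)]
  }

  R <- .rotation_between(axis, c(0, 0, 1))
  out <- .transform_structure(structure, R, -as.numeric(R %*% centroid))

  # z sign: lower-numbered pore residues (selectivity-filter side) must sit
  # above the linker anchors
  sel_z <- mean(do.call(rbind, lapply(out$chains, .chain_ca,
                                      residues = selection))[, 3])
  anch <- do.call(rbind, lapply(out$chains, .chain_ca,
                                residues = anchor_residues))
  if (nrow(anch) > 0 && mean(anch[, 3]) > sel_z) {
    flip <- diag(c(1, -1, -1))  # rotate pi about x
    out <- .transform_structure(out, flip, c(0, 0, 0))
  }
  # re-zero x,y of the selection centroid after any flip
  cen2 <- colMeans(do.call(rbind, lapply(out$chains, .chain_ca,
                                         residues = selection)))
  out <- .transform_structure(out, diag(3), c(-cen2[1], -cen2[2], 0))
  attr(out, "aligned") <- TRUE
  out
}

#' Per-subunit linker end-to-end lengths and components
#'
#' For each chain, computes the Euclidean distance L between the ring and
#' pore anchors, and — when the anchor set comes from an axis-aligned
#' structure — its vertical component `L_z = |dz|` and radial component
#' `L_xy = sqrt(dx^2 + dy^2)`, so that `L^2 = L_z^2 + L_xy^2`.
#'
#' @param anchors an [extract_anchors()] anchor set.
#' @return A data.frame with columns `chain_id`, `L`, `L_z`, `L_xy`
#'   (Angstrom); the components are `NA` for unaligned input.
#' @export
linker_lengths <- function(anchors) {
  stopifnot(inherits(anchors, "anchor_set"))
  d <- anchors$ring - anchors$pore
  L <- sqrt(rowSums(d^2))
  if (isTRUE(anchors$aligned)) {
    L_z <- abs(d[, 3])
    L_xy <- sqrt(d[, 1]^2 + d[, 2]^2)
  } else {
    L_z <- L_xy <- rep(NA_real_, length(L))
  }
  data.frame(chain_id = anchors$chain_ids, L = L, L_z = L_z, L_xy = L_xy,
             row.names = NULL)
}

#' Ring spread metrics of four symmetry-related CA positions
#'
#' Summarizes how far a ring of four equivalent residues has spread: the
#' mean distance of the points from the z axis (radius) and the mean
#' distance between azimuthally adjacent points (interresidue distance).
#' For an exact C4 square the interresidue distance equals radius * sqrt(2).
#'
#' @param points a 4 x 3 coordinate matrix (Angstrom), axis-aligned.
#' @param aligned logical; the radius is only meaningful for points in the
#'   aligned frame.
#' @return A list with `interresidue_distance` and `radius` (Angstrom; the
#'   radius is `NA` when `aligned` is `FALSE`).
#' @export
spread_metrics <- function(points, aligned = TRUE) {
  points <- as.matrix(points)
  if (nrow(points) != 4L || ncol(points) != 3L)
    stop("spread_metrics expects exactly 4 points in 3D")
  radius <- if (aligned) mean(sqrt(points[, 1]^2 + points[, 2]^2)) else NA_real_
  ord <- order(atan2(points[, 2], points[, 1]))
  p <- points[ord, , drop = FALSE]
  nb <- p[c(2, 3, 4, 1), , drop = FALSE]
  interresidue <- mean(sqrt(rowSums((p - nb)^2)))
  list(interresidue_distance = interresidue, radius = radius)
}
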