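#' Entropic-spring mechanics of one set of linkers
#'
#' Converts per-subunit linker geometry into worm-like-chain mechanics: the
#' total pulling force F at extension L, its vertical and radial components
#' (`F_z = F * L_z / L`, `F_xy = F * L_xy / L`, so that
#' `F^2 = F_z^2 + F_xy^2`), the stored elastic energy `U = wlc_energy(0, L)`
#' and the local spring constant.
#'
#' @param geometry a data.frame from [linker_lengths()] (columns `chain_id`,
#'   `L`, `L_z`, `L_xy`, Angstrom).
#' @param params a [wlc_params()] object.
#' @return A data.frame with columns `chain_id`, `L`, `L_z`, `L_xy`
#'   (Angstrom), `F`, `F_z`, `F_xy` (pN), `U` (kT), `k` (pN/nm) and
#'   `near_contour` (logical warning flag).
#' @export
linker_mechanics <- function(geometry, params = wlc_params()) {
  stopifnot(is.data.frame(geometry), all(c("chain_id", "L") %in% names(geometry)))
  L <- geometry$L
  F <- wlc_force(L, params, unit = "A")
  near <- attr(F, "near_contour")
  F <- as.numeric(F)
  ratio_z <- ifelse(L > 0, geometry$L_z / L, 0)
  ratio_xy <- ifelse(L > 0, geometry$L_xy / L, 0)
  data.frame(
    chain_id = geometry$chain_id,
    L = L, L_z = geometry$L_z, L_xy = geometry$L_xy,
    F = F, F_z = F * ratio_z, F_xy = F * ratio_xy,
    U = wlc_energy(rep(0, length(L)), L, params, unit = "A"),
    k = as.numeric(wlc_stiffness(L, params, unit = "A")),
    near_contour = near,
    row.names = NULL)
}

#' Per-structure summary of linker mechanics
#'
#' Arithmetic mean and sample standard deviation of length, force, force
#' components and energy over the (unfolded) linkers of one structure.
#' Folded-linker subunits must be excluded upstream.
#'
#' @param mechanics a [linker_mechanics()] data.frame.
#' @param structure_id identifier carried into the summary row.
#' @return A one-row data.frame: `structure_id`, `n_linkers`, then
#'   `<field>_mean` and `<field>_sd` for L, F, F_z, F_xy and U.
#' @export
structure_summary <- function(mechanics, structure_id = "structure") {
  if (!is.data.frame(mechanics) || nrow(mechanics) == 0L)
    stop("structure_summary needs at least one linker")
  fields <- c("L", "F", "F_z", "F_xy", "U")
  out <- data.frame(structure_id = structure_id, n_linkers = nrow(mechanics))
  for (f in fields) {
    out[[paste0(f, "_mean")]] <- mean(mechanics[[f]])
    out[[paste0(f, "_sd")]] <- if (nrow(mechanics) > 1) stats::sd(mechanics[[f]]) else 0
  }
  out
}

#' Build a transition-state chimera anchor set
#'
#' Hypothetical gating intermediates are modelled as chimeras of the two
#' end-state structures, both in the common aligned frame: transition state
#' 1 ("TS1") joins the spread ring anchors of the open state to the closed
#' pore-side anchors (an activated ring pulling on a still-closed gate);
#' transition state 2 ("TS2") joins the narrow closed ring anchors to the
#' open pore-side anchors (a relaxed ring tethered to a still-open gate).
#' Chains are paired by minimal azimuthal offset of the pore anchors; for a
#' C4-symmetric closed state the per-structure statistics do not depend on
#' the pairing.
#'
#' @param open_anchors,closed_anchors aligned [extract_anchors()] sets.
#' @param which `"TS1"` or `"TS2"`.
#' @return An `"anchor_set"` for the chimera, aligned, with a composite
#'   `structure_id`.
#' @export
build_transition_chimera <- function(open_anchors, closed_anchors,
                                     which = c("TS1", "TS2")) {
  which <- match.arg(which)
  stopifnot(inherits(open_anchors, "anchor_set"),
            inherits(closed_anchors, "anchor_set"))
  if (!isTRUE(open_anchors$aligned) || !isTRUE(closed_anchors$aligned))
    stop("both anchor sets must come from axis-aligned structures")
  if (length(open_anchors$chain_ids) != length(closed_anchors$chain_ids))
    stop("anchor sets have different chain counts")

  # pair closed chain j to each open chain i by pore-anchor azimuth: cyclic
  # shift minimizing the total angular offset
  az <- function(m) atan2(m[, 2], m[, 1])
  ao <- az(open_anchors$pore); ac <- az(closed_anchors$pore)
  n <- length(ao)
  wrap <- function(x) atan2(sin(x), cos(x))
  shift_cost <- vapply(0:(n - 1), function(s) {
    idx <- ((seq_len(n) - 1 + s) %% n) + 1
    sum(abs(wrap(ao - ac[idx])))
  }, numeric(1))
  idx <- ((seq_len(n) - 1 + (which.min(shift_cost) - 1)) %% n) + 1

  if (which == "TS1") {
    ring <- open_anchors$ring
    pore <- closed_anchors$pore[idx, , drop = FALSE]
  } else {
    ring <- closed_anchors$ring[idx, , drop = FALSE]
    pore <- open_anchors$pore
  }
  rownames(pore) <- rownames(ring) <- open_anchors$chain_ids
  structure(list(
    structure_id = sprintf("%s(%s|%s)", which, open_anchors$structure_id,
                           closed_anchors$structure_id),
    chain_ids = open_anchors$chain_ids,
    pore = pore, ring = ring, aligned = TRUE),
    class = "anchor_set")
}

#' Signed elastic work of one gating path
#'
#' The work loading (positive) or releasing (negative) the linker springs
#' when the anchor geometry moves from one state to another: per subunit,
#' `wlc_energy(0, L_to) - wlc_energy(0, L_from)`. Elastic energy is a state
#' function, so works computed this way close exactly around any cycle.
#'
#' @param from_anchors,to_anchors [extract_anchors()] sets with matched
#'   chain pairing.
#' @param params a [wlc_params()] object.
#' @param path_id label carried in the result.
#' @return An object of class `"path_work"`: list with `path_id`,
#'   `per_subunit` (kT, in chain order), `mean`, `sd` and `per_tetramer`
#'   (= 4 * mean).
#' @export
path_work <- function(from_anchors, to_anchors, params = wlc_params(),
                      path_id = "path") {
  L_from <- linker_lengths(from_anchors)$L
  L_to <- linker_lengths(to_anchors)$L
  if (length(L_from) != length(L_to))
    stop("path_work: mismatched subunit counts")
  w <- wlc_energy(rep(0, length(L_to)), L_to, params, unit = "A") -
       wlc_energy(rep(0, length(L_from)), L_from, params, unit = "A")
  structure(list(path_id = path_id, per_subunit = w, mean = mean(w),
                 sd = if (length(w) > 1) stats::sd(w) else 0,
                 per_tetramer = 4 * mean(w)),
            class = "path_work")
}

#' @export
print.path_work <- function(x, ...) {
  cat(sprintf("%s: %.2f +/- %.2f kT per subunit (%.2f kT per tetramer)\n",
              x$path_id, x$mean, x$sd, x$per_tetramer))
  invisible(x)
}

#' Four-path gating cycle works
#'
#' Convenience wrapper computing the four canonical path works of the
#' gating cycle between a closed and an open structure:
#' closed -> TS1 (loading the springs by ring activation), TS1 -> open
#' (release as the gate opens), open -> TS2 (release as the ring relaxes)
#' and TS2 -> closed (elastic component of gate closure and linker
#' refolding). Path 4 is reported as its elastic component only; the
#' additional energy of linker folding and helix coiling is annotated, not
#' computed.
#'
#' @param closed_anchors,open_anchors aligned anchor sets.
#' @param params a [wlc_params()] object.
#' @param folding_gain_threshold annotation attached to path 4: the minimum
#'   energy gain of folding one linker, taken from the outlier excess energy
#'   (kT).
#' @return A list of four `"path_work"` objects named `path1`, `path2`,
#'   `path3`, `path4_elastic`; `path4_elastic` carries the annotation in
#'   attribute `folding_gain_threshold`.
#' @export
gating_paths <- function(closed_anchors, open_anchors, params = wlc_params(),
                         folding_gain_threshold = NULL) {
  ts1 <- build_transition_chimera(open_anchors, closed_anchors, "TS1")
  ts2 <- build_transition_chimera(open_anchors, closed_anchors, "TS2")
  # express the closed state in the open set's chain pairing so every path
  # uses one consistent subunit correspondence
  closed_paired <- build_transition_chimera(open_anchors, closed_anchors, "TS1")
  closed_paired$ring <- build_transition_chimera(open_anchors, closed_anchors,
                                                 "TS2")$ring
  closed_paired$structure_id <- closed_anchors$structure_id
  p4 <- path_work(ts2, closed_paired, params, "path4_elastic")
  if (!is.null(folding_gain_threshold))
    attr(p4, "folding_gain_threshold") <- folding_gain_threshold
  list(path1 = path_work(closed_paired, ts1, params, "path1"),
       path2 = path_work(ts1, open_anchors, params, "path2"),
       path3 = path_work(open_anchors, ts2, params, "path3"),
       path4_elastic = p4)
}

#' Flag anomalously stretched linkers in a pooled set
#'
#' Robust length-outlier detection over linkers pooled across structures:
#' a linker is flagged when its length deviates from the pooled median by
#' more than `mad_multiplier` times the (unscaled) median absolute
#' deviation. For each flagged linker the excess elastic energy relative to
#' the mean length of the unflagged linkers is reported. Folded-linker
#' subunits must be excluded before pooling and are reported separately by
#' the pipeline.
#'
#' @param mechanics a pooled [linker_mechanics()] data.frame (optionally
#'   with a `structure_id` column).
#' @param params a [wlc_params()] object.
#' @param mad_multiplier flagging threshold in MAD units.
#' @return A list with `table` (the input plus `deviation` and `outlier`
#'   columns), `normal_mean_L` (Angstrom), and `excess_energy` (named kT
#'   vector, one entry per flagged linker).
#' @export
detect_outliers <- function(mechanics, params = wlc_params(),
                            mad_multiplier = 2.5) {
  stopifnot(is.data.frame(mechanics), "L" %in% names(mechanics))
  L <- mechanics$L
  med <- stats::median(L)
  mad_raw <- stats::median(abs(L - med))
  dev <- abs(L - med)
  out <- if (mad_raw > 0) dev > mad_multiplier * mad_raw else rep(FALSE, length(L))
  tab <- mechanics
  tab$deviation <- dev
  tab$outlier <- out
  normal_mean <- mean(L[!out])
  excess <- numeric(0)
  if (any(out)) {
    lab <- if ("structure_id" %in% names(tab))
      paste(tab$structure_id[out], tab$chain_id[out], sep = ":")
    else as.character(tab$chain_id[out])
    excess <- vapply(L[out], function(l)
      if (l > normal_mean) wlc_energy(normal_mean, l, params, unit = "A")
      else -wlc_energy(l, normal_mean, params, unit = "A"),
      numeric(1))
    names(excess) <- lab
  }
  list(table = tab, normal_mean_L = normal_mean, excess_energy = excess)
}

#' Force and energy of a length-perturbed linker
#'
#' Predicts the mechanics of a linker shortened or lengthened by
#' `delta_residues` chain units while the geometric end-to-end extension is
#' held fixed (the anchors do not move). Shortening raises, lengthening
#' lowers, both the force and the stored energy.
#'
#' @param delta_residues signed integer change in chain-unit count.
#' @param extension end-to-end extension, Angstrom by default.
#' @param params the unperturbed [wlc_params()].
#' @param unit unit of `extension`.
#' @return A list with `F` (pN), `U` (kT) and `params` (the perturbed
#'   parameter set).
#' @examples
#' perturbed_linker_prediction(-3, 29.1)  # ~20 pN, 5.0 kT
#' perturbed_linker_prediction(+3, 29.1)  # ~9 pN, 2.8 kT
#' @export
perturbed_linker_prediction <- function(delta_residues, extension,
                                        params = wlc_params(),
                                        unit = c("A", "nm")) {
  n_new <- params$n_units + delta_residues
  if (n_new < 1) stop("perturbation leaves fewer than one chain unit")
  p_new <- wlc_params(n_units = n_new,
                      persistence_length = params$persistence_length,
                      thermal_energy = params$thermal_energy)
  x_nm <- .ext_to_nm(extension, match.arg(unit))
  if (x_nm >= p_new$contour_length)
    stop(sprintf(
      "extension %.2f nm exceeds the perturbed contour length %.2f nm",
      x_nm, p_new$contour_length))
  list(F = as.numeric(wlc_force(x_nm, p_new, unit = "nm")),
       U = wlc_energy(0, x_nm, p_new, unit = "nm"),
       params = p_new)
}
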