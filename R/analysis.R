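#' End-to-end entropic-spring gating analysis of a structure ensemble
#'
#' Runs the full pipeline on one closed-state and one or more open-state
#' tetramer structures: axis alignment of each structure, folded-linker
#' detection, anchor extraction, per-linker worm-like-chain mechanics,
#' per-structure summaries, pooled and outlier-robust statistics, the two
#' transition-state chimeras and the four signed gating path works.
#'
#' The closed state may be named explicitly; otherwise it is inferred as
#' the structure whose linker range is resolved (folded) in all four
#' chains, and the inference is recorded in the result metadata.
#' Folded-linker subunits of open structures are excluded from spring
#' statistics (an unfolded chain is a precondition of the model) and
#' listed in the exclusion log. Two pooled statistic sets are reported:
#' `pooled` over all unfolded linkers, and `normal` excluding robust
#' length outliers.
#'
#' @param structures a list of `"structure_model"` objects and/or file
#'   paths understood by [read_structure()].
#' @param closed_id id of the closed-state structure, or `NULL` to infer.
#' @param params a [wlc_params()] object.
#' @param pore_anchor,ring_anchor anchor residue numbers.
#' @param selection pore-domain residues for axis alignment.
#' @param linker_range linker residue numbers for folded-linker detection.
#' @param mad_multiplier outlier threshold in raw-MAD units.
#' @return An object of class `"gating_analysis"` with components
#'   `per_linker` (data.frame over all unfolded open-state linkers),
#'   `per_structure` (summary data.frame), `pooled` and `normal` statistic
#'   sets, `outliers`, `paths` (per open structure and aggregated),
#'   `exclusions` (log data.frame), `params` and `meta`.
#' @export
gating_analysis <- function(structures, closed_id = NULL,
                            params = wlc_params(),
                            pore_anchor = 99, ring_anchor = 115,
                            selection = 20:83, linker_range = 100:114,
                            mad_multiplier = 2.5) {
  if (inherits(structures, "structure_model")) structures <- list(structures)
  if (length(structures) == 0L) stop("no input structures")
  models <- lapply(structures, function(s) {
    if (inherits(s, "structure_model")) s
    else read_structure(s)
  })
  ids <- vapply(models, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate structure ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(models) <- ids

  folded <- lapply(models, detect_resolved_linker, linker_range = linker_range)

  closed_inferred <- FALSE
  if (is.null(closed_id)) {
    all_folded <- vapply(folded, all, logical(1))
    if (sum(all_folded) != 1L)
      stop("cannot infer the closed state: ", sum(all_folded),
           " structure(s) have all four linkers resolved; pass `closed_id`")
    closed_id <- ids[all_folded]
    closed_inferred <- TRUE
  }
  if (!closed_id %in% ids) stop("closed_id '", closed_id, "' not among inputs")
  open_ids <- setdiff(ids, closed_id)
  if (length(open_ids) == 0L) stop("no open-state structures supplied")

  aligned <- lapply(models, align_pore_axis_to_z, selection = selection)
  anchors <- lapply(aligned, extract_anchors, pore_anchor = pore_anchor,
                    ring_anchor = ring_anchor)

  exclusions <- data.frame(structure_id = character(0), chain_id = character(0),
                           reason = character(0))
  per_linker <- NULL
  per_structure <- NULL
  for (sid in open_ids) {
    geo <- linker_lengths(anchors[[sid]])
    keep <- !folded[[sid]][geo$chain_id]
    if (any(!keep))
      exclusions <- rbind(exclusions, data.frame(
        structure_id = sid, chain_id = geo$chain_id[!keep],
        reason = "folded linker (resolved in coordinates)"))
    if (!any(keep)) next
    mech <- linker_mechanics(geo[keep, , drop = FALSE], params)
    mech <- cbind(structure_id = sid, mech)
    per_linker <- rbind(per_linker, mech)
    per_structure <- rbind(per_structure,
                           structure_summary(mech, structure_id = sid))
  }
  if (is.null(per_linker) || nrow(per_linker) == 0L)
    stop("no unfolded linkers found in the open-state structures")

  out_rep <- detect_outliers(per_linker, params, mad_multiplier)
  pool_stats <- function(df) {
    fields <- c("L", "F", "F_z", "F_xy", "U")
    st <- list(n = nrow(df))
    for (f in fields) {
      st[[paste0(f, "_mean")]] <- mean(df[[f]])
      st[[paste0(f, "_sd")]] <- if (nrow(df) > 1) stats::sd(df[[f]]) else 0
    }
    st
  }
  pooled <- pool_stats(per_linker)
  normal <- pool_stats(per_linker[!out_rep$table$outlier, , drop = FALSE])

  fold_gain <- if (length(out_rep$excess_energy))
    max(out_rep$excess_energy) else NULL
  paths_by_structure <- lapply(open_ids, function(sid)
    gating_paths(anchors[[closed_id]], anchors[[sid]], params,
                 folding_gain_threshold = fold_gain))
  names(paths_by_structure) <- open_ids
  path_ids <- c("path1", "path2", "path3", "path4_elastic")
  paths_pooled <- lapply(path_ids, function(p) {
    w <- unlist(lapply(paths_by_structure, function(g) g[[p]]$per_subunit))
    structure(list(path_id = p, per_subunit = as.numeric(w), mean = mean(w),
                   sd = if (length(w) > 1) stats::sd(w) else 0,
                   per_tetramer = 4 * mean(w)),
              class = "path_work")
  })
  names(paths_pooled) <- path_ids
  if (!is.null(fold_gain))
    attr(paths_pooled$path4_elastic, "folding_gain_threshold") <- fold_gain

  structure(list(
    per_linker = per_linker,
    per_structure = per_structure,
    pooled = pooled,
    normal = normal,
    outliers = out_rep,
    paths = list(by_structure = paths_by_structure, pooled = paths_pooled),
    exclusions = exclusions,
    anchors = anchors,
    params = params,
    meta = list(closed_id = closed_id, closed_inferred = closed_inferred,
                open_ids = open_ids, pore_anchor = pore_anchor,
                ring_anchor = ring_anchor, selection = range(selection),
                linker_range = range(linker_range),
                mad_multiplier = mad_multiplier)
  ), class = "gating_analysis")
}

#' @export
print.gating_analysis <- function(x, ...) {
  cat("Entropic-spring gating analysis\n")
  cat(sprintf("  closed state : %s%s\n", x$meta$closed_id,
              if (x$meta$closed_inferred) " (inferred)" else ""))
  cat(sprintf("  open states  : %s\n", paste(x$meta$open_ids, collapse = ", ")))
  cat(sprintf("  linkers      : %d unfolded (%d excluded as folded)\n",
              x$pooled$n, nrow(x$exclusions)))
  cat(sprintf("  extension    : %.1f +/- %.1f Angstrom (pooled, n = %d)\n",
              x$pooled$L_mean, x$pooled$L_sd, x$pooled$n))
  cat(sprintf("  force        : %.1f +/- %.1f pN; radial %.1f +/- %.1f pN\n",
              x$pooled$F_mean, x$pooled$F_sd,
              x$pooled$F_xy_mean, x$pooled$F_xy_sd))
  cat(sprintf("  energy       : %.1f +/- %.1f kT per linker\n",
              x$pooled$U_mean, x$pooled$U_sd))
  n_out <- sum(x$outliers$table$outlier)
  if (n_out > 0)
    cat(sprintf("  outliers     : %d flagged, max excess energy %.1f kT\n",
                n_out, max(x$outliers$excess_energy)))
  invisible(x)
}

#' @export
summary.gating_analysis <- function(object, ...) {
  print(object)
  cat("\nPer-structure summaries:\n")
  df <- object$per_structure
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = 2)
  print(df, row.names = FALSE)
  cat("\nGating path works (kT per subunit, pooled over open structures):\n")
  for (p in object$paths$pooled) print(p)
  if (nrow(object$exclusions)) {
    cat("\nExcluded subunits:\n")
    print(object$exclusions, row.names = FALSE)
  }
  invisible(object)
}

#' Force-extension plot of the analyzed linkers
#'
#' Draws the Marko-Siggia force-extension curve for the analysis parameter
#' set and marks each unfolded linker at its measured extension; flagged
#' outliers are highlighted.
#'
#' @param x a [gating_analysis()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gating_analysis <- function(x, ...) {
  lc_A <- 10 * x$params$contour_length
  xs <- seq(0, 0.9 * lc_A, length.out = 300)
  fs <- as.numeric(wlc_force(xs, x$params, unit = "A"))
  graphics::plot(xs, fs, type = "l", xlab = "extension (Angstrom)",
                 ylab = "force (pN)", ...)
  out <- x$outliers$table$outlier
  graphics::points(x$per_linker$L[!out], x$per_linker$F[!out], pch = 19)
  if (any(out))
    graphics::points(x$per_linker$L[out], x$per_linker$F[out], pch = 17,
                     col = "red")
  invisible(x)
}

# a number with an explicit unit, for the JSON report
.qty <- function(value, unit) list(value = as.numeric(value), unit = unit)

.stats_with_units <- function(st) {
  units <- c(L = "Angstrom", F = "pN", F_z = "pN", F_xy = "pN", U = "kT")
  out <- list(n = st$n)
  for (f in names(units)) {
    out[[f]] <- list(mean = .qty(st[[paste0(f, "_mean")]], units[[f]]),
                     sd = .qty(st[[paste0(f, "_sd")]], units[[f]]))
  }
  out
}

#' Write CSV and JSON reports of a gating analysis
#'
#' Emits `per_linker.csv` (one row per unfolded linker, unit-suffixed
#' column names), `per_structure.csv` (one summary row per structure) and
#' `report.json` (pooled statistics, path works, outlier report and
#' metadata; every number carries a unit field). Output is fully
#' deterministic for identical input.
#'
#' @param x a [gating_analysis()] object.
#' @param dir output directory, created if needed.
#' @return Named character vector of the files written, invisibly.
#' @export
write_gating_report <- function(x, dir) {
  stopifnot(inherits(x, "gating_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  pl <- x$per_linker
  pl$outlier <- x$outliers$table$outlier
  names(pl) <- c("structure_id", "chain_id", "L_A", "L_z_A", "L_xy_A",
                 "F_pN", "F_z_pN", "F_xy_pN", "U_kT", "k_pN_per_nm",
                 "near_contour", "outlier")
  f_linker <- file.path(dir, "per_linker.csv")
  utils::write.csv(pl, f_linker, row.names = FALSE)

  ps <- x$per_structure
  names(ps) <- sub("^(L)_(mean|sd)$", "\\1_\\2_A", names(ps))
  names(ps) <- sub("^(F|F_z|F_xy)_(mean|sd)$", "\\1_\\2_pN", names(ps))
  names(ps) <- sub("^(U)_(mean|sd)$", "\\1_\\2_kT", names(ps))
  f_struct <- file.path(dir, "per_structure.csv")
  utils::write.csv(ps, f_struct, row.names = FALSE)

  report <- list(
    schema = "wlcgating-report/1",
    parameters = list(
      n_units = x$params$n_units,
      persistence_length = .qty(x$params$persistence_length, "nm"),
      thermal_energy = .qty(x$params$thermal_energy, "pN nm"),
      contour_length = .qty(x$params$contour_length, "nm")),
    closed_state = list(id = x$meta$closed_id,
                        inferred = x$meta$closed_inferred),
    pooled = .stats_with_units(x$pooled),
    normal = .stats_with_units(x$normal),
    paths = lapply(x$paths$pooled, function(p) {
      out <- list(mean = .qty(p$mean, "kT"), sd = .qty(p$sd, "kT"),
                  per_tetramer = .qty(p$per_tetramer, "kT"))
      thr <- attr(p, "folding_gain_threshold")
      if (!is.null(thr))
        out$folding_gain_threshold <- .qty(thr, "kT")
      out
    }),
    outliers = list(
      n_flagged = sum(x$outliers$table$outlier),
      normal_mean_L = .qty(x$outliers$normal_mean_L, "Angstrom"),
      excess_energy = lapply(x$outliers$excess_energy, .qty, unit = "kT")),
    exclusions = x$exclusions)
  f_json <- file.path(dir, "report.json")
  jsonlite::write_json(report, f_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(per_linker = f_linker, per_structure = f_struct,
              report = f_json))
}
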