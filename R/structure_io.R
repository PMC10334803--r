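#' Read a tetrameric channel structure from PDB or mmCIF
#'
#' Parses a coordinate file and extracts per-chain alpha-carbon (CA)
#' coordinates for protein residues. Only the first model is used; alternate
#' locations are resolved by highest occupancy, then lexicographically by
#' altloc identifier; hetero and water records are ignored. Residue numbers
#' are the author-assigned numbers. When the file holds more than four
#' protein chains, the four longest are analyzed unless an explicit chain
#' list is given; insertion codes are rejected.
#'
#' @param path path to a PDB or mmCIF file.
#' @param format `"auto"` (by file extension), `"pdb"` or `"mmcif"`.
#' @param state_label one of `"closed"`, `"open"`, `"chimera"`,
#'   `"synthetic"`, or `"unknown"`; carried as metadata.
#' @param chains optional character vector of chain identifiers to keep (in
#'   the given order), overriding the four-longest rule.
#' @param id structure identifier; defaults to the file name without
#'   extension.
#' @return An object of class `"structure_model"`: a list with `id`,
#'   `state_label`, `chains` (a named list; each chain holds `chain_id` and
#'   `ca`, an n x 3 coordinate matrix in Angstrom whose rownames are residue
#'   numbers) and `provenance`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           state_label = "unknown", chains = NULL, id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb")
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                          verbose = FALSE)),
    error = function(e) stop("could not parse '", path, "' as ", format,
                             ": ", conditionMessage(e)))
  atoms <- parsed$atom
  atoms <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no protein CA atoms in ", path)
  if (any(!is.na(atoms$insert) & atoms$insert != ""))
    stop("insertion codes are not supported (found in ", path, ")")

  # resolve altlocs: keep, per chain+residue, the highest occupancy, ties
  # broken by lexicographic altloc id
  alt <- ifelse(is.na(atoms$alt), "", atoms$alt)
  occ <- ifelse(is.na(atoms$o), 1, atoms$o)
  ord <- order(atoms$chain, atoms$resno, -occ, alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(atoms[, c("chain", "resno")]), , drop = FALSE]

  chain_ids <- unique(atoms$chain)
  if (!is.null(chains)) {
    missing <- setdiff(chains, chain_ids)
    if (length(missing))
      stop("requested chain(s) not in file: ", paste(missing, collapse = ", "))
    chain_ids <- chains
  } else if (length(chain_ids) > 4L) {
    sizes <- vapply(chain_ids, function(ch) sum(atoms$chain == ch), integer(1))
    chain_ids <- chain_ids[order(-sizes)][1:4]
    chain_ids <- chain_ids[order(match(chain_ids, unique(atoms$chain)))]
  }

  chain_list <- lapply(chain_ids, function(ch) {
    a <- atoms[atoms$chain == ch, , drop = FALSE]
    a <- a[order(a$resno), , drop = FALSE]
    ca <- as.matrix(a[, c("x", "y", "z")])
    rownames(ca) <- a$resno
    list(chain_id = ch, ca = ca)
  })
  names(chain_list) <- chain_ids

  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(id = id, state_label = state_label, chains = chain_list,
                 provenance = list(path = path, format = format)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  nres <- vapply(x$chains, function(ch) nrow(ch$ca), integer(1))
  cat(sprintf("Structure model '%s' (%s), %d chain(s)\n",
              x$id, x$state_label, length(x$chains)))
  for (i in seq_along(x$chains)) {
    rn <- as.integer(rownames(x$chains[[i]]$ca))
    cat(sprintf("  chain %s: %d CA, residues %d-%d\n",
                names(x$chains)[i], nres[i], min(rn), max(rn)))
  }
  invisible(x)
}

# all CA coordinates of one structure as a single matrix; rows named
# "<chain>:<resno>"
.all_ca <- function(structure) {
  do.call(rbind, lapply(structure$chains, function(ch) {
    m <- ch$ca
    rownames(m) <- paste0(ch$chain_id, ":", rownames(ch$ca))
    m
  }))
}

# CA coordinates of `residues` (in order) for one chain; NULL rows dropped;
# returns matrix with resno rownames
.chain_ca <- function(chain, residues) {
  keep <- intersect(as.character(residues), rownames(chain$ca))
  chain$ca[keep, , drop = FALSE]
}

#' Extract linker anchor coordinates from a structure
#'
#' Pulls the CA coordinates of the two linker endpoints from each analyzed
#' chain: the pore-side anchor (last pore-domain residue, Ile99 in MthK) and
#' the ring-side anchor (first gating-ring residue, Ser115 in MthK).
#'
#' @param structure a [read_structure()] model.
#' @param pore_anchor author residue number of the pore-side anchor.
#' @param ring_anchor author residue number of the ring-side anchor.
#' @return An object of class `"anchor_set"`: a list with `structure_id`,
#'   `chain_ids`, `pore` and `ring` (n x 4 chains x 3 coordinate matrices,
#'   Angstrom, rows in chain order) and `aligned` (FALSE until the parent
#'   structure has been axis-aligned).
#' @export
extract_anchors <- function(structure, pore_anchor = 99, ring_anchor = 115) {
  stopifnot(inherits(structure, "structure_model"))
  get1 <- function(chain, resno) {
    key <- as.character(resno)
    if (!key %in% rownames(chain$ca))
      stop(sprintf("chain %s lacks a CA at anchor residue %d",
                   chain$chain_id, resno))
    chain$ca[key, ]
  }
  pore <- t(vapply(structure$chains, get1, numeric(3), resno = pore_anchor))
  ring <- t(vapply(structure$chains, get1, numeric(3), resno = ring_anchor))
  rownames(pore) <- rownames(ring) <- names(structure$chains)
  structure(list(structure_id = structure$id,
                 chain_ids = names(structure$chains),
                 pore = pore, ring = ring,
                 aligned = isTRUE(attr(structure, "aligned"))),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("Anchor set for '%s' (%d chains, %saligned)\n", x$structure_id,
              length(x$chain_ids), if (x$aligned) "" else "un"))
  invisible(x)
}

#' Flag chains whose linker segment is structurally resolved
#'
#' A folded, ordered linker is resolved in the deposited coordinates, while
#' an unfolded linker is disordered and absent. A chain is flagged as having
#' a resolved (folded) linker when at least 80% of the residues in the linker
#' range carry a CA coordinate. Such chains are excluded from entropic-spring
#' analysis, where the linker must be unfolded.
#'
#' @param structure a [read_structure()] model.
#' @param linker_range integer vector of linker residue numbers
#'   (default 100:114, the MthK linker).
#' @return Named logical vector, one entry per chain.
#' @export
detect_resolved_linker <- function(structure, linker_range = 100:114) {
  stopifnot(inherits(structure, "structure_model"))
  vapply(structure$chains, function(ch) {
    mean(as.character(linker_range) %in% rownames(ch$ca)) >= 0.8
  }, logical(1))
}

#' Write a structure model as a minimal CA-only PDB file
#'
#' Emits fixed-column ATOM records (one CA per residue, occupancy 1, B 0)
#' suitable as a test fixture or for visualization. Coordinates are rounded
#' to the PDB field precision of 0.001 Angstrom.
#'
#' @param structure a [read_structure()] or [generate_tetramer()] model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "structure_model"))
  xyz <- .all_ca(structure)
  resno <- as.integer(sub("^.*:", "", rownames(xyz)))
  chain <- sub(":.*$", "", rownames(xyz))
  n <- nrow(xyz)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)), resno = resno,
                   chain = chain, resid = rep("ALA", n),
                   elety = rep("CA", n), o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Write a structure model as a minimal mmCIF file
#'
#' Emits a single `atom_site` loop with one CA per residue, mirroring
#' [write_fixture_pdb()] in mmCIF encoding.
#'
#' @inheritParams write_fixture_pdb
#' @return `path`, invisibly.
#' @export
write_fixture_cif <- function(structure, path) {
  stopifnot(inherits(structure, "structure_model"))
  xyz <- .all_ca(structure)
  resno <- as.integer(sub("^.*:", "", rownames(xyz)))
  chain <- sub(":.*$", "", rownames(xyz))
  hdr <- c(
    paste0("data_", gsub("[^A-Za-z0-9_]", "_", structure$id)),
    "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "auth_seq_id", "auth_comp_id", "auth_asym_id",
      "auth_atom_id", "pdbx_PDB_model_num")))
  rows <- sprintf(
    "ATOM %d C CA . ALA %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d ALA %s CA 1",
    seq_along(resno), chain, resno, xyz[, 1], xyz[, 2], xyz[, 3],
    resno, chain)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
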