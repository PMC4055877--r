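# Receptor preparation and pocket definition.

# Coarse element-based partial charges for receptor atoms (polarity proxy;
# the toy fixtures use uncharged carbon shells, real use can supply charges).
.RECEPTOR_CHARGE <- c(O = -0.3, N = 0.3, S = -0.1)

receptor_object <- function(structure, pdb_id = "") {
  structure(list(structure = structure, pdb_id = pdb_id), class = "receptor")
}

#' @export
print.receptor <- function(x, ...) {
  cat(sprintf("<receptor> %s: %d atoms\n", x$pdb_id, n_atoms(x$structure)))
  invisible(x)
}

#' Pocket specification
#'
#' The docking pocket is the axis-aligned box around the reference ligand:
#' center at the ligand centroid, half-widths equal to half the ligand
#' extent plus a margin.
#'
#' @param center numeric(3), box center (Angstrom).
#' @param box_half_widths numeric(3), half-widths (Angstrom), all > 0.
#' @return a `pocket_spec` object.
#' @export
pocket_spec <- function(center, box_half_widths) {
  stopifnot(length(center) == 3, length(box_half_widths) == 3,
            all(box_half_widths > 0))
  structure(list(center = as.numeric(center),
                 box_half_widths = as.numeric(box_half_widths)),
            class = "pocket_spec")
}

pocket_from_ligand <- function(lig_xyz, margin = 4.0) {
  center <- colMeans(lig_xyz)
  ext <- apply(lig_xyz, 2, function(v) diff(range(v))) / 2
  pocket_spec(center, ext + margin)
}

#' Prepare a receptor and define its pocket from the bound reference ligand
#'
#' Extracts the named het group to define the pocket box, then removes it
#' (and all waters/other het groups) from the receptor. Receptor coordinates
#' stay fixed throughout docking; coarse element-based partial charges are
#' assigned (override via `charges`).
#'
#' @param pdb path to a PDB file.
#' @param reference_ligand_selector list with `resname` (required) and
#'   optionally `chain` identifying exactly one het group.
#' @param margin pocket box margin beyond the ligand extent (Angstrom).
#' @param charges optional numeric vector of per-atom partial charges for
#'   the retained receptor atoms.
#' @return list with elements `receptor` (a `receptor`), `pocket`
#'   (a `pocket_spec`) and `reference_ligand` (a `molecule`).
#' @export
prepare_receptor <- function(pdb, reference_ligand_selector, margin = 4.0,
                             charges = NULL) {
  sel <- as.list(reference_ligand_selector)
  if (is.null(sel$resname)) stop("selection error: selector needs a 'resname'")
  mol <- read_pdb_molecule(pdb)
  meta <- mol$pdb_meta
  is_lig <- meta$resid == sel$resname
  if (!is.null(sel$chain)) is_lig <- is_lig & meta$chain %in% sel$chain
  if (!any(is_lig)) {
    stop("selection error: no het group '", sel$resname, "' in ", pdb)
  }
  groups <- unique(paste(meta$chain[is_lig], meta$resno[is_lig]))
  if (length(groups) > 1) {
    stop("selection error: selector matches ", length(groups),
         " groups (", paste(groups, collapse = "; "), "); disambiguate with chain")
  }
  lig_idx <- which(is_lig)
  lig <- molecule(mol$atoms[lig_idx, , drop = FALSE], NULL,
                  name = sel$resname,
                  provenance = list(source = pdb, format = "PDB"))
  water <- meta$resid %in% c("HOH", "WAT", "TIP", "TIP3", "SOL")
  keep <- which(!is_lig & !water & meta$type == "ATOM")
  rec_atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(rec_atoms) <- NULL
  if (is.null(charges)) {
    q <- .RECEPTOR_CHARGE[rec_atoms$element]
    q[is.na(q)] <- 0
  } else {
    if (length(charges) != nrow(rec_atoms)) {
      stop("charges must have one value per retained receptor atom")
    }
    q <- charges
  }
  rec_atoms$partial_charge <- as.numeric(q)
  rec <- receptor_object(
    molecule(rec_atoms, NULL, name = basename(pdb),
             provenance = list(source = pdb, format = "PDB")),
    pdb_id = sub("\\.pdb$", "", basename(pdb), ignore.case = TRUE)
  )
  pocket <- pocket_from_ligand(coords_matrix(lig), margin = margin)
  list(receptor = rec, pocket = pocket, reference_ligand = lig)
}
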