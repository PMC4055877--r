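# Partial charges (Gasteiger PEOE, via OpenBabel) and replaceable-site
# enumeration.

# Parse per-record charge columns out of a (possibly multi-record) MOL2 text.
mol2_charge_records <- function(mol2) {
  lines <- strsplit(mol2, "\n")[[1]]
  starts <- grep("^@<TRIPOS>ATOM", lines)
  ends <- grep("^@<TRIPOS>", lines)
  lapply(starts, function(a0) {
    nxt <- ends[ends > a0]
    stop_at <- if (length(nxt)) min(nxt) else length(lines) + 1
    rest <- lines[(a0 + 1):(stop_at - 1)]
    rest <- rest[nzchar(trimws(rest))]
    vapply(strsplit(trimws(rest), "\\s+"), function(f) as.numeric(f[9]),
           numeric(1))
  })
}

# Batched Gasteiger assignment: one OpenBabel conversion for many molecules
# (the per-call conversion overhead dominates otherwise).
assign_gasteiger_charges_batch <- function(mols) {
  if (!length(mols)) return(mols)
  for (mol in mols) {
    bad <- !mol$atoms$element %in% .GASTEIGER_ELEMENTS
    if (any(bad)) {
      stop(sprintf("Gasteiger parameterization does not cover element '%s' (atom %d)",
                   mol$atoms$element[which(bad)[1]], which(bad)[1]))
    }
  }
  sdf <- paste(unlist(lapply(mols, molecule_to_sdf_text)), collapse = "\n")
  mol2 <- ChemmineOB::convertFormat("SDF", "MOL2", sdf)
  recs <- mol2_charge_records(mol2)
  if (length(recs) != length(mols)) {
    stop("charge assignment failed: record count mismatch")
  }
  for (i in seq_along(mols)) {
    q <- recs[[i]]
    if (length(q) != n_atoms(mols[[i]]) || any(!is.finite(q))) {
      stop("charge assignment failed for molecule ", i)
    }
    if (abs(sum(q) - sum(mols[[i]]$atoms$formal_charge)) > 1e-3) {
      stop(sprintf("charge conservation violated for molecule %d: sum(q) = %.4f",
                   i, sum(q)))
    }
    mols[[i]]$atoms$partial_charge <- q
  }
  mols
}

#' Assign Gasteiger partial charges
#'
#' Computes Gasteiger-Marsili (PEOE) partial charges for every atom via
#' OpenBabel. The total partial charge equals the total formal charge to
#' within 1e-3 e. Attachment dummies (`*`) receive charge 0.
#'
#' @param mol a `molecule` with complete valences (explicit hydrogens).
#' @return the molecule with `partial_charge` filled in.
#' @export
assign_gasteiger_charges <- function(mol) {
  bad <- !mol$atoms$element %in% .GASTEIGER_ELEMENTS
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("Gasteiger parameterization does not cover element '%s' (atom %d)",
                 mol$atoms$element[i], i))
  }
  sdf <- paste(molecule_to_sdf_text(mol), collapse = "\n")
  mol2 <- ChemmineOB::convertFormat("SDF", "MOL2", sdf)
  recs <- mol2_charge_records(mol2)
  if (length(recs) != 1) stop("charge assignment failed: no MOL2 atom block")
  q <- recs[[1]]
  if (length(q) != n_atoms(mol)) {
    stop("charge assignment failed: atom count mismatch")
  }
  if (any(!is.finite(q))) stop("charge assignment failed: non-finite charge")
  mol$atoms$partial_charge <- q
  total_formal <- sum(mol$atoms$formal_charge)
  if (abs(sum(q) - total_formal) > 1e-3) {
    # OpenBabel zeroes charges it cannot assign; surface that as an error
    stop(sprintf("charge conservation violated: sum(q) = %.4f, formal = %d",
                 sum(q), total_formal))
  }
  mol
}

#' Enumerate replaceable (H/F) sites of a seed fragment
#'
#' Every hydrogen and fluorine atom of the fragment is a candidate position
#' for side-chain growth. Sites are returned in ascending atom-index order.
#'
#' @param mol a `molecule` with explicit hydrogens.
#' @return data.frame with columns `atom_index`, `anchor_index`, `label`.
#'   Labels are human-readable and 1-based, e.g. `"H7@C3"`.
#' @export
enumerate_replaceable_sites <- function(mol) {
  idx <- which(mol$atoms$element %in% c("H", "F"))
  rows <- lapply(idx, function(i) {
    nb <- neighbors_of(mol, i)
    if (length(nb) != 1) {
      stop(sprintf("replaceable atom %d (%s) must have exactly one bond, found %d",
                   i, mol$atoms$element[i], length(nb)))
    }
    data.frame(
      atom_index = i, anchor_index = nb,
      label = sprintf("%s%d@%s%d", mol$atoms$element[i], i,
                      mol$atoms$element[nb], nb),
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(atom_index = integer(), anchor_index = integer(),
                      label = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
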