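# Deterministic conformer generation by systematic torsion driving with
# RMSD deduplication.

# Rotatable bonds: acyclic single bonds whose both ends carry at least one
# other heavy neighbor (terminal methyl/H rotations do not change the heavy
# skeleton and are skipped).
rotatable_bonds <- function(mol) {
  el <- mol$atoms$element
  out <- list()
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 1) next
    i <- b$from[k]; j <- b$to[k]
    if (el[i] == "H" || el[j] == "H") next
    hv_i <- setdiff(neighbors_of(mol, i), j)
    hv_i <- hv_i[el[hv_i] != "H"]
    hv_j <- setdiff(neighbors_of(mol, j), i)
    hv_j <- hv_j[el[hv_j] != "H"]
    if (!length(hv_i) || !length(hv_j)) next
    if (bond_in_ring(mol, i, j)) next
    out[[length(out) + 1]] <- c(i, j)
  }
  if (!length(out)) return(matrix(integer(), 0, 2))
  do.call(rbind, out)
}

# Atoms on the j-side branch of bond i-j (excluding travel through i).
branch_atoms <- function(mol, i, j) {
  adj <- adjacency(mol)
  seen <- logical(n_atoms(mol))
  seen[i] <- TRUE
  queue <- j; seen[j] <- TRUE
  res <- j
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    for (nb in adj[[a]]) if (!seen[nb]) {
      seen[nb] <- TRUE; queue <- c(queue, nb); res <- c(res, nb)
    }
  }
  res
}

# Kabsch-aligned RMSD between coordinate matrices (same atom order).
aligned_rmsd <- function(A, B) {
  Ac <- A - matrix(colMeans(A), nrow(A), 3, byrow = TRUE)
  Bc <- B - matrix(colMeans(B), nrow(B), 3, byrow = TRUE)
  s <- svd(t(Bc) %*% Ac)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diffm <- Ac - Bc %*% R
  sqrt(mean(rowSums(diffm^2)))
}

#' Generate conformers by systematic torsion driving
#'
#' Rotatable bonds are driven over staggered offsets (0/120/240 degrees for
#' sp3-sp3 bonds, 0/180 otherwise); the Cartesian product is enumerated (or
#' deterministically subsampled from the configured seed when it exceeds
#' `max_conformers`) and deduplicated at 0.5 Angstrom heavy-atom RMSD. The
#' input geometry is always conformer 1. Rigid molecules yield exactly one
#' conformer.
#'
#' @param vc a `virtual_compound` or `molecule` with 3D coordinates.
#' @param cfg a [docking_config()] (uses `max_conformers`, `conformer_seed`).
#' @param rmsd_threshold dedup threshold (Angstrom, heavy atoms).
#' @return list of coordinate matrices (n_atoms x 3), all atoms.
#' @export
generate_conformers <- function(vc, cfg = docking_config(),
                                rmsd_threshold = 0.5) {
  mol <- if (inherits(vc, "virtual_compound")) vc$molecule else vc
  xyz0 <- coords_matrix(mol)
  if (any(!is.finite(xyz0))) {
    stop("conformer error: compound '", mol$name, "' has invalid coordinates")
  }
  rb <- rotatable_bonds(mol)
  if (nrow(rb) == 0) return(list(xyz0))
  hyb <- hybridization(mol)
  offsets <- lapply(seq_len(nrow(rb)), function(k) {
    if (hyb[rb[k, 1]] == "sp3" && hyb[rb[k, 2]] == "sp3") c(0, 120, 240) * pi / 180
    else c(0, pi)
  })
  n_comb <- prod(vapply(offsets, length, numeric(1)))
  if (n_comb <= cfg$max_conformers * 8) {
    combos <- as.matrix(expand.grid(lapply(offsets, seq_along)))
    if (nrow(combos) > cfg$max_conformers) {
      # deterministic subsample; always keep the identity combination first
      set.seed(cfg$conformer_seed)
      keep <- sample.int(nrow(combos) - 1, cfg$max_conformers - 1) + 1L
      combos <- combos[c(1L, sort(keep)), , drop = FALSE]
    }
  } else {
    # combinatorial torsion space too large to materialize: draw torsion
    # choices per bond, deterministically, keeping the identity first
    set.seed(cfg$conformer_seed)
    combos <- rbind(
      rep(1L, length(offsets)),
      vapply(offsets, function(o) sample.int(length(o), cfg$max_conformers - 1,
                                             replace = TRUE),
             integer(cfg$max_conformers - 1))
    )
    combos <- unique(combos)
  }
  branches <- lapply(seq_len(nrow(rb)), function(k) branch_atoms(mol, rb[k, 1], rb[k, 2]))
  heavy <- which(!mol$atoms$element %in% c("H", "*"))
  confs <- list()
  for (r in seq_len(nrow(combos))) {
    xyz <- xyz0
    for (k in seq_len(nrow(rb))) {
      delta <- offsets[[k]][combos[r, k]]
      if (abs(delta) < 1e-12) next
      i <- rb[k, 1]; j <- rb[k, 2]
      axis <- xyz[j, ] - xyz[i, ]
      Rm <- rotation_about_axis(axis, delta)
      br <- branches[[k]]
      pivot <- xyz[j, ]
      xyz[br, ] <- t(Rm %*% t(xyz[br, , drop = FALSE] -
                                matrix(pivot, length(br), 3, byrow = TRUE))) +
        matrix(pivot, length(br), 3, byrow = TRUE)
    }
    dup <- FALSE
    for (prev in confs) {
      if (length(heavy) >= 3 &&
          aligned_rmsd(xyz[heavy, , drop = FALSE], prev[heavy, , drop = FALSE]) <
            rmsd_threshold) { dup <- TRUE; break }
    }
    if (!dup) confs[[length(confs) + 1]] <- xyz
    if (length(confs) >= cfg$max_conformers) break
  }
  confs
}
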