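# Rule-based protonation: dominant ionization states at pH 7.
#
# The rules are deliberately simple graph patterns (not pKa prediction):
# carboxylic acids lose their acidic proton, aliphatic amines and
# amidines/guanidines gain one. Applying a rule twice changes nothing.

#' Protonation configuration
#'
#' @param target_pH target pH (informational; the default rule table encodes
#'   the dominant forms at pH 7).
#' @param rule_set ordered named list of rules; each rule has a `pattern`
#'   (one of the built-in graph patterns: "carboxylic_acid",
#'   "aliphatic_amine", "amidine") and an `action` ("deprotonate" or
#'   "protonate"). Rules are applied in list order.
#' @return a `protonation_config` object.
#' @export
protonation_config <- function(target_pH = 7,
                               rule_set = default_protonation_rules()) {
  for (r in rule_set) {
    if (!is.list(r) || is.null(r$pattern) || is.null(r$action)) {
      stop("protonation config error: each rule needs 'pattern' and 'action'")
    }
    if (!r$pattern %in% names(.PROTONATION_PATTERNS)) {
      stop("protonation config error: unknown pattern '", r$pattern, "'")
    }
    if (!r$action %in% c("deprotonate", "protonate")) {
      stop("protonation config error: unknown action '", r$action, "'")
    }
  }
  structure(list(target_pH = target_pH, rule_set = rule_set),
            class = "protonation_config")
}

#' @export
default_protonation_rules <- function() {
  list(
    carboxylate = list(pattern = "carboxylic_acid", action = "deprotonate"),
    ammonium = list(pattern = "aliphatic_amine", action = "protonate"),
    amidinium = list(pattern = "amidine", action = "protonate")
  )
}

# Each pattern returns, for a molecule, a list of match sites:
# for deprotonation: list(h = index of acidic H, heavy = its heavy atom)
# for protonation:   list(heavy = atom to protonate)
.PROTONATION_PATTERNS <- list(
  carboxylic_acid = function(mol) {
    hyb <- hybridization(mol)
    out <- list()
    for (o in which(mol$atoms$element == "O")) {
      nb <- neighbors_of(mol, o)
      hs <- nb[mol$atoms$element[nb] == "H"]
      cs <- nb[mol$atoms$element[nb] == "C"]
      if (length(hs) != 1 || length(cs) != 1) next
      c_nb <- neighbors_of(mol, cs)
      carbonyl <- any(mol$atoms$element[c_nb] == "O" & c_nb != o &
                        vapply(c_nb, function(j) bond_order_between(mol, cs, j) == 2, logical(1)))
      if (carbonyl) out[[length(out) + 1]] <- list(h = hs, heavy = o)
    }
    out
  },
  aliphatic_amine = function(mol) {
    hyb <- hybridization(mol)
    out <- list()
    for (nn in which(mol$atoms$element == "N")) {
      if (mol$atoms$formal_charge[nn] != 0) next
      if (hyb[nn] != "sp3") next
      nb <- neighbors_of(mol, nn)
      if (length(nb) != 3) next
      heavy_nb <- nb[mol$atoms$element[nb] != "H"]
      if (!all(mol$atoms$element[heavy_nb] == "C")) next
      # exclude amides and anilines: no sp2 carbon neighbor
      if (any(hyb[heavy_nb] == "sp2")) next
      out[[length(out) + 1]] <- list(heavy = nn)
    }
    out
  },
  amidine = function(mol) {
    out <- list()
    for (nn in which(mol$atoms$element == "N")) {
      if (mol$atoms$formal_charge[nn] != 0) next
      nb <- neighbors_of(mol, nn)
      dbl_c <- nb[mol$atoms$element[nb] == "C" &
                    vapply(nb, function(j) bond_order_between(mol, nn, j) == 2, logical(1))]
      if (!length(dbl_c)) next
      c_nb <- neighbors_of(mol, dbl_c[1])
      other_n <- c_nb[mol$atoms$element[c_nb] == "N" & c_nb != nn]
      if (length(other_n) >= 1) out[[length(out) + 1]] <- list(heavy = nn)
    }
    out
  }
)

#' Apply protonation rules for the dominant ionization state at pH 7
#'
#' @param mol a `molecule` with explicit hydrogens.
#' @param cfg a [protonation_config()].
#' @return the adjusted molecule (hydrogens added/removed, formal charges
#'   updated). Idempotent: applying twice equals applying once.
#' @export
prepare_protonation <- function(mol, cfg = protonation_config()) {
  if (!inherits(cfg, "protonation_config")) stop("cfg must be a protonation_config")
  for (r in cfg$rule_set) {
    matches <- .PROTONATION_PATTERNS[[r$pattern]](mol)
    if (r$action == "deprotonate") {
      # remove the matched hydrogens (highest index first to keep indices valid)
      hs <- sort(vapply(matches, function(m) m$h, integer(1)), decreasing = TRUE)
      heavies <- vapply(matches, function(m) m$heavy, integer(1))
      for (m in matches) {
        mol$atoms$formal_charge[m$heavy] <- mol$atoms$formal_charge[m$heavy] - 1L
      }
      for (h in hs) mol <- remove_atom(mol, h)
    } else {
      for (m in matches) {
        mol <- add_hydrogen_at(mol, m$heavy)
        mol$atoms$formal_charge[m$heavy] <- mol$atoms$formal_charge[m$heavy] + 1L
      }
    }
  }
  mol
}

# Remove atom i, reindexing bonds.
remove_atom <- function(mol, i) {
  keep <- setdiff(seq_len(n_atoms(mol)), i)
  remap <- integer(n_atoms(mol))
  remap[keep] <- seq_along(keep)
  b <- mol$bonds
  b <- b[b$from != i & b$to != i, , drop = FALSE]
  b$from <- remap[b$from]
  b$to <- remap[b$to]
  mol$atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(mol$atoms) <- NULL
  mol$bonds <- b
  mol
}

# Add one hydrogen bonded to heavy atom i, placed along the direction that
# points away from the existing neighbors.
add_hydrogen_at <- function(mol, i) {
  xyz <- coords_matrix(mol)
  nb <- neighbors_of(mol, i)
  pos <- xyz[i, ]
  if (length(nb)) {
    away <- pos - colMeans(xyz[nb, , drop = FALSE])
    if (vnorm(away) < 1e-6) away <- c(0, 0, 1)
  } else {
    away <- c(0, 0, 1)
  }
  L <- covalent_radius(mol$atoms$element[i]) + covalent_radius("H")
  hpos <- pos + unit(away) * L
  mol$atoms <- rbind(mol$atoms, data.frame(
    element = "H", x = hpos[1], y = hpos[2], z = hpos[3],
    formal_charge = 0L, partial_charge = NA_real_, stringsAsFactors = FALSE
  ))
  rownames(mol$atoms) <- NULL
  mol$bonds <- rbind(mol$bonds,
                     data.frame(from = i, to = n_atoms(mol), order = 1L))
  mol
}
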