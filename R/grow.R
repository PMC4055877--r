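# Fragment growth: attach side-chain templates at replaceable sites, reject
# intramolecular clashes, and minimize survivors.

#' Clash detection configuration
#'
#' A contact between a side-chain atom and a seed atom counts as an
#' intramolecular clash when the distance falls below a fraction of the sum
#' of the two van der Waals radii. Bonded (1-2) and geminal (1-3) pairs
#' across the new bond are exempt.
#'
#' @param heavy_scale clash threshold fraction for heavy-heavy contacts.
#' @param h_scale threshold fraction for pairs involving hydrogen.
#' @return a `clash_config` object.
#' @export
clash_config <- function(heavy_scale = 0.7, h_scale = 0.6) {
  stopifnot(heavy_scale > 0, heavy_scale < 1, h_scale > 0, h_scale < 1)
  structure(list(heavy_scale = heavy_scale, h_scale = h_scale),
            class = "clash_config")
}

# Clash pairs between seed-part atoms and sidechain-part atoms of a merged
# molecule; `exempt` is a 2-column matrix of exempt index pairs.
find_clash_pairs <- function(xyz, elements, seed_idx, chain_idx, exempt, cfg) {
  if (!length(chain_idx)) return(matrix(integer(), 0, 2))
  out <- list()
  vr <- vdw_radius(elements)
  for (i in seed_idx) {
    d <- sqrt(colSums((t(xyz[chain_idx, , drop = FALSE]) - xyz[i, ])^2))
    scl <- ifelse(elements[i] == "H" | elements[chain_idx] == "H",
                  cfg$h_scale, cfg$heavy_scale)
    thr <- scl * (vr[i] + vr[chain_idx])
    hit <- which(d < thr)
    for (h in hit) {
      j <- chain_idx[h]
      if (nrow(exempt) &&
          any((exempt[, 1] == i & exempt[, 2] == j) |
              (exempt[, 1] == j & exempt[, 2] == i))) next
      out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (!length(out)) return(matrix(integer(), 0, 2))
  do.call(rbind, out)
}

#' Attach a side-chain template at a replaceable site
#'
#' Removes the H or F atom at the site, bonds the template's attachment atom
#' to the anchor along the former bond vector (new bond length from covalent
#' radii), scans the side-chain torsion about the new bond in 30-degree
#' steps, and keeps the rotamer with the fewest clash contacts. If the best
#' rotamer still clashes, the growth is rejected.
#'
#' @param seed prepared seed `molecule`.
#' @param site one row of [enumerate_replaceable_sites()] (or a list with
#'   `atom_index`, `anchor_index`, `label`).
#' @param template one template row of a `sidechain_set`, or a template
#'   `molecule` containing exactly one `*` dummy.
#' @param clash a [clash_config()].
#' @param template_mol optional pre-embedded template molecule (cache).
#' @return a `virtual_compound` (class extends `molecule` metadata), or a
#'   `growth_rejection` object listing the offending atom pairs.
#' @export
attach_sidechain <- function(seed, site, template, clash = clash_config(),
                             template_mol = NULL) {
  site <- as.list(site)
  s_i <- site$atom_index; a_i <- site$anchor_index
  if (!mol_elements_ok(seed, s_i, a_i)) {
    stop("precondition error: site atom must be H or F bonded to the anchor")
  }
  if (is.null(template_mol)) template_mol <- embed_template(template)
  tname <- if (!is.null(template$name)) template$name else template_mol$name
  dummy <- which(template_mol$atoms$element == "*")
  if (length(dummy) != 1) {
    stop("library error: template must contain exactly one attachment dummy")
  }
  t_i <- neighbors_of(template_mol, dummy)
  if (length(t_i) != 1) stop("library error: dummy atom must have one bond")

  seed_xyz <- coords_matrix(seed)
  tpl_xyz <- coords_matrix(template_mol)
  d_vec <- unit(seed_xyz[s_i, ] - seed_xyz[a_i, ])
  bond_len <- covalent_radius(seed$atoms$element[a_i]) +
    covalent_radius(template_mol$atoms$element[t_i])

  # orient template: (t -> dummy) direction becomes -d (dummy toward anchor)
  u <- unit(tpl_xyz[dummy, ] - tpl_xyz[t_i, ])
  R <- rotation_between(u, -d_vec)
  tpl_rot <- t(R %*% t(tpl_xyz - matrix(tpl_xyz[t_i, ], nrow(tpl_xyz), 3, byrow = TRUE)))
  t_pos <- seed_xyz[a_i, ] + bond_len * d_vec
  tpl_rot <- tpl_rot + matrix(t_pos, nrow(tpl_rot), 3, byrow = TRUE)

  # indices after merge: seed atoms minus the site atom, then template atoms
  # minus its dummy
  keep_seed <- setdiff(seq_len(n_atoms(seed)), s_i)
  keep_tpl <- setdiff(seq_len(n_atoms(template_mol)), dummy)
  n_s <- length(keep_seed)
  map_seed <- integer(n_atoms(seed)); map_seed[keep_seed] <- seq_len(n_s)
  map_tpl <- integer(n_atoms(template_mol)); map_tpl[keep_tpl] <- n_s + seq_along(keep_tpl)
  a_new <- map_seed[a_i]; t_new <- map_tpl[t_i]

  elements <- c(seed$atoms$element[keep_seed], template_mol$atoms$element[keep_tpl])
  seed_part <- seq_len(n_s)
  chain_part <- n_s + seq_along(keep_tpl)

  # exclusions across the junction: the new bond and its 1-3 pairs
  nb_a <- map_seed[setdiff(neighbors_of(seed, a_i), s_i)]
  nb_t <- map_tpl[setdiff(neighbors_of(template_mol, t_i), dummy)]
  exempt <- rbind(
    cbind(a_new, t_new),
    if (length(nb_a)) cbind(nb_a, t_new) else NULL,
    if (length(nb_t)) cbind(a_new, nb_t) else NULL
  )

  # torsion scan about anchor->t axis, 30-degree steps
  best <- NULL
  axis <- d_vec
  for (k in 0:11) {
    Rk <- rotation_about_axis(axis, k * pi / 6)
    chain_xyz <- t(Rk %*% t(tpl_rot - matrix(t_pos, nrow(tpl_rot), 3, byrow = TRUE))) +
      matrix(t_pos, nrow(tpl_rot), 3, byrow = TRUE)
    xyz <- rbind(seed_xyz[keep_seed, , drop = FALSE],
                 chain_xyz[keep_tpl, , drop = FALSE])
    pairs <- find_clash_pairs(xyz, elements, seed_part, chain_part, exempt, clash)
    if (is.null(best) || nrow(pairs) < nrow(best$pairs)) {
      best <- list(k = k, xyz = xyz, pairs = pairs)
      if (nrow(pairs) == 0) break
    }
  }

  if (nrow(best$pairs) > 0) {
    return(structure(list(
      seed_name = seed$name, site = site, template_name = tname,
      reason = "intramolecular clash",
      clash_pairs = data.frame(
        seed_atom = best$pairs[, 1], chain_atom = best$pairs[, 2],
        seed_element = elements[best$pairs[, 1]],
        chain_element = elements[best$pairs[, 2]]
      )
    ), class = "growth_rejection"))
  }

  atoms <- data.frame(
    element = elements,
    x = best$xyz[, 1], y = best$xyz[, 2], z = best$xyz[, 3],
    formal_charge = c(seed$atoms$formal_charge[keep_seed],
                      template_mol$atoms$formal_charge[keep_tpl]),
    partial_charge = NA_real_,
    stringsAsFactors = FALSE
  )
  b_s <- seed$bonds[seed$bonds$from != s_i & seed$bonds$to != s_i, , drop = FALSE]
  b_s$from <- map_seed[b_s$from]; b_s$to <- map_seed[b_s$to]
  b_t <- template_mol$bonds[template_mol$bonds$from != dummy &
                              template_mol$bonds$to != dummy, , drop = FALSE]
  b_t$from <- map_tpl[b_t$from]; b_t$to <- map_tpl[b_t$to]
  bonds <- rbind(b_s, b_t, data.frame(from = a_new, to = t_new, order = 1L))
  mol <- molecule(atoms, bonds,
                  name = paste0(seed$name, "+", tname, "@", site$label),
                  provenance = list(seed = seed$name, template = tname,
                                    site = site$label))
  structure(list(
    molecule = mol, seed_name = seed$name, site = site,
    site_label = site$label, template_name = tname,
    generation_index = NA_integer_
  ), class = "virtual_compound")
}

mol_elements_ok <- function(seed, s_i, a_i) {
  s_i >= 1 && s_i <= n_atoms(seed) &&
    seed$atoms$element[s_i] %in% c("H", "F") &&
    a_i %in% neighbors_of(seed, s_i)
}

#' @export
print.virtual_compound <- function(x, ...) {
  cat(sprintf("<virtual_compound> %s: %s at %s (%d atoms)\n",
              x$seed_name, x$template_name, x$site_label, n_atoms(x$molecule)))
  invisible(x)
}

#' @export
print.growth_rejection <- function(x, ...) {
  cat(sprintf("<growth_rejection> %s at %s: %s (%d pair(s))\n",
              x$template_name, x$site$label, x$reason, nrow(x$clash_pairs)))
  invisible(x)
}

# Deterministic 3D embedding of a template row (or SMILES) with the dummy
# kept in place; light minimization so rotamer scans see sane geometry.
embed_template <- function(template) {
  if (inherits(template, "molecule")) return(template)
  smi <- if (is.list(template) || is.data.frame(template)) template$smiles else template
  nm <- if (!is.null(template$name)) template$name else smi
  mol <- smiles_to_molecule_raw(smi, name = nm)
  mol$atoms$partial_charge <- 0
  minimize_molecule(mol, minimization_config(max_iterations = 200L))
}

#' Enumerate the virtual-compound library for one seed
#'
#' Iterates replaceable sites (ascending atom index) x side-chain templates
#' (library order), attaching, clash-screening, and energy-minimizing each
#' candidate. Gasteiger charges are recomputed on every accepted compound
#' before minimization. Accepted + rejected always equals sites x templates.
#'
#' @param seed prepared seed `molecule` (protonation and charges assigned).
#' @param set a `sidechain_set`.
#' @param clash a [clash_config()].
#' @param min_cfg a [minimization_config()].
#' @param minimize logical; minimize accepted compounds (default TRUE).
#' @param charges logical; assign Gasteiger charges to accepted compounds
#'   (default TRUE; turn off for bookkeeping-only enumeration).
#' @return a `virtual_library`: list with `compounds` (list of
#'   `virtual_compound`, dense deterministic `generation_index`) and
#'   `rejections` (data.frame of site/template/reason).
#' @export
enumerate_virtual_library <- function(seed, set, clash = clash_config(),
                                      min_cfg = minimization_config(),
                                      minimize = TRUE, charges = TRUE) {
  stopifnot(inherits(set, "sidechain_set"))
  sites <- enumerate_replaceable_sites(seed)
  if (nrow(sites) == 0) {
    warning("seed has no replaceable (H/F) sites; empty library")
  }
  tpl_cache <- new.env(parent = emptyenv())
  compounds <- list()
  rej <- list()
  gen <- 0L
  for (si in seq_len(nrow(sites))) {
    for (ti in seq_len(nrow(set$templates))) {
      tpl_row <- set$templates[ti, ]
      key <- tpl_row$canonical
      if (is.null(tpl_cache[[key]])) tpl_cache[[key]] <- embed_template(tpl_row)
      res <- attach_sidechain(seed, sites[si, ], tpl_row, clash,
                              template_mol = tpl_cache[[key]])
      if (inherits(res, "growth_rejection")) {
        rej[[length(rej) + 1]] <- data.frame(
          site_label = sites$label[si], template_name = tpl_row$name,
          reason = res$reason, n_clash_pairs = nrow(res$clash_pairs),
          stringsAsFactors = FALSE
        )
      } else {
        gen <- gen + 1L
        res$generation_index <- gen
        compounds[[gen]] <- res
      }
    }
  }
  if (length(compounds) && (charges || minimize)) {
    # batched charge assignment (one conversion), then per-compound minimization
    mols <- if (charges)
      assign_gasteiger_charges_batch(lapply(compounds, `[[`, "molecule"))
    else lapply(compounds, `[[`, "molecule")
    for (i in seq_along(compounds)) {
      compounds[[i]]$molecule <-
        if (minimize) minimize_molecule(mols[[i]], min_cfg) else mols[[i]]
    }
  }
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(site_label = character(), template_name = character(),
               reason = character(), n_clash_pairs = integer())
  structure(list(
    compounds = compounds, rejections = rejections,
    seed_name = seed$name, set_id = set$set_id,
    n_sites = nrow(sites), n_templates = nrow(set$templates)
  ), class = "virtual_library")
}

#' @export
print.virtual_library <- function(x, ...) {
  cat(sprintf("<virtual_library> %s x set %s: %d accepted, %d rejected (%d sites x %d templates)\n",
              x$seed_name, x$set_id, length(x$compounds), nrow(x$rejections),
              x$n_sites, x$n_templates))
  invisible(x)
}

#' Write a virtual library to SDF with annotation tags
#'
#' @param lib a `virtual_library`.
#' @param path output SDF path.
#' @param rejection_log optional CSV path for the rejection log.
#' @return `path`, invisibly.
#' @export
write_virtual_library <- function(lib, path, rejection_log = NULL) {
  mols <- lapply(lib$compounds, function(vc) vc$molecule)
  tags <- lapply(lib$compounds, function(vc) list(
    seed = vc$seed_name, site = vc$site_label,
    template = vc$template_name, generation_index = vc$generation_index
  ))
  write_molecules_sdf(mols, path, tags = tags)
  if (!is.null(rejection_log)) {
    utils::write.csv(lib$rejections, rejection_log, row.names = FALSE)
  }
  invisible(path)
}
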