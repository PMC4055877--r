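# Deterministic synthetic receptor/seed fixtures.
#
# The toy receptor is a shell of uncharged carbon pseudo-atoms on a jittered
# cubic lattice, carved around a posed seed fragment so the cavity is snugly
# complementary to the seed, plus one hydrophobic subpocket tube that
# adjoins exactly one replaceable site of the seed. A copy of the seed is
# written as the reference ligand defining the pocket. Everything is
# bit-reproducible from the spec's RNG seed.

#' Synthetic pocket specification
#'
#' @param n_shell_atoms maximum number of shell pseudo-atoms (nearest to the
#'   cavity are kept first).
#' @param pocket_radius cavity clearance around each seed atom (Angstrom).
#' @param subpocket_direction unit vector from the cavity center toward the
#'   subpocket; the seed is posed with its designated site along it.
#' @param subpocket_depth tube extension beyond the cavity clearance
#'   (Angstrom); must not exceed `pocket_radius`.
#' @param subpocket_radius lateral tube radius (Angstrom).
#' @param charge_pattern optional numeric vector of shell-atom charges
#'   (recycled); default uncharged (hydrophobic pocket).
#' @param seed_kind which toy seed the cavity is carved around (see
#'   [make_toy_seed()]).
#' @param rng_seed integer; controls the small lattice jitter.
#' @return a `synthetic_pocket_spec`.
#' @export
synthetic_pocket_spec <- function(n_shell_atoms = 4000L, pocket_radius = 2.8,
                                  subpocket_direction = c(1, 0, 0),
                                  subpocket_depth = 2.8,
                                  subpocket_radius = 2.8,
                                  charge_pattern = NULL,
                                  seed_kind = "branched",
                                  rng_seed = 42L) {
  if (pocket_radius <= 0 || subpocket_depth <= 0) {
    stop("geometry error: pocket_radius and subpocket_depth must be positive")
  }
  if (subpocket_depth > pocket_radius) {
    stop("geometry error: subpocket_depth (", subpocket_depth,
         ") exceeds pocket_radius (", pocket_radius, ")")
  }
  structure(list(
    n_shell_atoms = as.integer(n_shell_atoms),
    pocket_radius = pocket_radius,
    subpocket_direction = unit(subpocket_direction),
    subpocket_depth = subpocket_depth,
    subpocket_radius = subpocket_radius,
    charge_pattern = charge_pattern,
    seed_kind = seed_kind,
    rng_seed = as.integer(rng_seed)
  ), class = "synthetic_pocket_spec")
}

.TOY_SEED_SMILES <- c(
  "benzene-like" = "c1ccccc1",
  "branched" = "Cc1cccc(C)c1",     # m-xylene: the ring H between the methyls
                                    # is the unique subpocket-facing site
  "with-F" = "Cc1cc(C)cc(F)c1"      # 5-fluoro-m-xylene: one F site
)

# The designated subpocket-facing site: for the branched seeds the ring H
# whose anchor carbon sits between the two substituted ring carbons; for
# benzene the lowest-index H.
toy_seed_site <- function(mol) {
  sites <- enumerate_replaceable_sites(mol)
  hyb <- hybridization(mol)
  ring_c <- which(mol$atoms$element == "C" & hyb == "sp2")
  pick <- NA_integer_
  for (r in seq_len(nrow(sites))) {
    if (sites$atom_index[r] %in% which(mol$atoms$element == "F")) next
    anchor <- sites$anchor_index[r]
    if (!(anchor %in% ring_c)) next
    ring_nb <- intersect(neighbors_of(mol, anchor), ring_c)
    if (length(ring_nb) != 2) next
    substituted <- vapply(ring_nb, function(j) {
      any(!neighbors_of(mol, j) %in% c(anchor) &
            mol$atoms$element[neighbors_of(mol, j)] == "C" &
            !neighbors_of(mol, j) %in% ring_c)
    }, logical(1))
    if (all(substituted)) { pick <- r; break }
  }
  if (is.na(pick)) pick <- 1L
  sites[pick, ]
}

#' Build a toy seed fragment posed for the synthetic pocket
#'
#' Returns a small prepared fragment (protonated, Gasteiger charges,
#' minimized) rigidly posed with its ring in the xy-plane, centroid at the
#' origin, and its designated replaceable site pointing along
#' `direction`. `"benzene-like"` is a symmetric 6-site fragment,
#' `"branched"` an m-xylene-like fragment whose unique inter-methyl ring H
#' faces the subpocket, `"with-F"` the same with a fluorine site on the
#' ring.
#'
#' @param kind one of "benzene-like", "branched", "with-F".
#' @param direction unit vector for the designated site.
#' @return a `molecule` with attribute `subpocket_site` (the site row).
#' @export
make_toy_seed <- function(kind = c("branched", "benzene-like", "with-F"),
                          direction = c(1, 0, 0)) {
  kind <- match.arg(kind)
  mol <- smiles_to_molecule_raw(.TOY_SEED_SMILES[[kind]], name = paste0("toy-", kind))
  mol$atoms$partial_charge <- 0
  mol <- minimize_molecule(mol, minimization_config(max_iterations = 500L))
  mol <- assign_gasteiger_charges(mol)

  xyz <- coords_matrix(mol)
  hyb <- hybridization(mol)
  ring_c <- which(mol$atoms$element == "C" & hyb == "sp2")
  ctr <- colMeans(xyz[ring_c, , drop = FALSE])
  xyz <- xyz - matrix(ctr, nrow(xyz), 3, byrow = TRUE)
  # ring plane -> xy
  sv <- svd(xyz[ring_c, , drop = FALSE])
  normal <- sv$v[, 3]
  R1 <- rotation_between(normal, c(0, 0, 1))
  xyz <- t(R1 %*% t(xyz))
  mol <- set_coords(mol, xyz)
  # designated site direction -> `direction`
  site <- toy_seed_site(mol)
  v <- xyz[site$atom_index, ] - xyz[site$anchor_index, ]
  v[3] <- 0 # keep the ring in plane
  R2 <- rotation_between(unit(v), unit(direction))
  xyz <- t(R2 %*% t(xyz))
  mol <- set_coords(mol, xyz)
  attr(mol, "subpocket_site") <- toy_seed_site(mol)
  mol
}

#' Generate the deterministic toy receptor
#'
#' Carves a snug cavity (clearance `pocket_radius` around every atom of the
#' posed seed) plus one hydrophobic subpocket tube along
#' `subpocket_direction`, out of a jittered carbon lattice; keeps a shell of
#' pseudo-protein atoms around the cavity; writes the receptor and a
#' reference ligand (a copy of the seed, residue `LIG`) to a PDB file.
#'
#' @param spec a [synthetic_pocket_spec()].
#' @param pdb_path output PDB path (default: tempfile).
#' @return list with `pdb` (path), `receptor`, `pocket`, `seed` (the posed
#'   seed molecule), `site` (the subpocket-facing site row), `spec`.
#' @export
make_toy_receptor <- function(spec = synthetic_pocket_spec(),
                              pdb_path = tempfile(fileext = ".pdb")) {
  stopifnot(inherits(spec, "synthetic_pocket_spec"))
  seed <- make_toy_seed(spec$seed_kind, spec$subpocket_direction)
  site <- attr(seed, "subpocket_site")
  seed_xyz <- coords_matrix(seed)
  site_pos <- seed_xyz[site$atom_index, ]
  d <- spec$subpocket_direction

  shell_thick <- 3.5
  spacing <- 1.8
  lo <- apply(seed_xyz, 2, min) - spec$pocket_radius - shell_thick - 1
  hi <- apply(seed_xyz, 2, max) + spec$pocket_radius + shell_thick + 1
  tube_tip <- site_pos + (spec$pocket_radius + spec$subpocket_depth) * d
  lo <- pmin(lo, tube_tip - spec$subpocket_radius - shell_thick - 1)
  hi <- pmax(hi, tube_tip + spec$subpocket_radius + shell_thick + 1)

  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  set.seed(spec$rng_seed)
  pts <- pts + matrix(stats::runif(length(pts), -0.15, 0.15), nrow(pts), 3)

  # clearance-weighted distance to the seed: heavy atoms get the full
  # pocket_radius, hydrogens a smaller ball (just outside the repulsion
  # range), so the cavity is snugly complementary to the posed seed
  h_clear <- min(spec$pocket_radius, 2.2)
  clear_r <- ifelse(seed$atoms$element == "H", h_clear, spec$pocket_radius)
  dmin <- rep(Inf, nrow(pts))   # distance margin: d_atom - clearance_atom
  for (a in seq_len(nrow(seed_xyz))) {
    da <- sqrt((pts[, 1] - seed_xyz[a, 1])^2 + (pts[, 2] - seed_xyz[a, 2])^2 +
                 (pts[, 3] - seed_xyz[a, 3])^2) - clear_r[a]
    dmin <- pmin(dmin, da)
  }
  rel <- sweep(pts, 2, site_pos)
  t_ <- as.numeric(rel %*% d)
  lat <- sqrt(pmax(0, rowSums(rel^2) - t_^2))
  tube_len <- spec$pocket_radius + spec$subpocket_depth
  in_tube <- t_ >= 0 & t_ <= tube_len & lat < spec$subpocket_radius
  in_cav <- dmin < 0 | in_tube
  near_tube <- t_ >= -shell_thick & t_ <= tube_len + shell_thick &
    lat < spec$subpocket_radius + shell_thick
  near_cav <- dmin < shell_thick | near_tube
  keep <- which(!in_cav & near_cav)
  if (length(keep) > spec$n_shell_atoms) {
    keep <- keep[order(dmin[keep])][seq_len(spec$n_shell_atoms)]
    keep <- sort(keep)
  }
  wall <- pts[keep, , drop = FALSE]

  q <- if (is.null(spec$charge_pattern)) rep(0, nrow(wall)) else
    rep_len(spec$charge_pattern, nrow(wall))
  rec_atoms <- data.frame(
    element = "C", x = wall[, 1], y = wall[, 2], z = wall[, 3],
    formal_charge = 0L, partial_charge = q, stringsAsFactors = FALSE
  )
  receptor <- receptor_object(
    molecule(rec_atoms, NULL, name = "toy-receptor",
             provenance = list(source = "synthetic", rng_seed = spec$rng_seed)),
    pdb_id = "TOY"
  )

  # PDB: shell as ATOM/PKT, reference ligand (seed copy) as HETATM/LIG
  n_w <- nrow(wall); n_l <- nrow(seed_xyz)
  bio3d::write.pdb(
    file = pdb_path,
    xyz = as.numeric(t(rbind(wall, seed_xyz))),
    type = c(rep("ATOM", n_w), rep("HETATM", n_l)),
    resno = c(seq_len(n_w), rep(n_w + 1L, n_l)),
    resid = c(rep("PKT", n_w), rep("LIG", n_l)),
    eleno = seq_len(n_w + n_l),
    elety = c(rep("C", n_w), paste0(seed$atoms$element, seq_len(n_l))),
    chain = rep("A", n_w + n_l),
    elesy = c(rep("C", n_w), seed$atoms$element)
  )
  # pocket box: ligand extent + margin, stretched to cover the subpocket tube
  blo <- apply(seed_xyz, 2, min) - 2.5
  bhi <- pmax(apply(seed_xyz, 2, max) + 2.5, tube_tip + spec$subpocket_radius * d)
  pocket <- pocket_spec((blo + bhi) / 2, (bhi - blo) / 2)
  list(pdb = pdb_path, receptor = receptor, pocket = pocket, seed = seed,
       site = site, spec = spec)
}
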