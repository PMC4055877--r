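# Grid scorer and exhaustive rigid-pose docking over pre-generated
# conformers.

#' Docking configuration
#'
#' @param max_conformers cap on conformers per compound (default 100).
#' @param rotation_samples number of rigid-body orientations; the default 60
#'   is the icosahedral rotation group (exhaustive within sampling, no
#'   stochastic optimizer).
#' @param translation_step lattice step of the translation scan (Angstrom).
#' @param weights named vector: `w_surf` (buried-surface), `w_elec`
#'   (electrostatic), `w_rep` (soft repulsion). Lower score = better.
#' @param conformer_seed seed for deterministic conformer subsampling.
#' @return a `docking_config`.
#' @export
docking_config <- function(max_conformers = 100L, rotation_samples = 60L,
                           translation_step = 1.0,
                           weights = c(w_surf = 1.0, w_elec = 0.3, w_rep = 1.0),
                           conformer_seed = 1L) {
  stopifnot(max_conformers >= 1, all(is.finite(weights)),
            translation_step > 0)
  structure(list(
    max_conformers = as.integer(max_conformers),
    rotation_samples = as.integer(rotation_samples),
    translation_step = translation_step,
    weights = weights, score_sign = "lower",
    conformer_seed = as.integer(conformer_seed)
  ), class = "docking_config")
}

# The 60 rotations of the icosahedral group, generated by closure from two
# adjacent 5-fold axes. Deterministic; cached after first call.
.rotation_cache <- new.env(parent = emptyenv())

icosahedral_rotations <- function() {
  if (!is.null(.rotation_cache$R60)) return(.rotation_cache$R60)
  phi <- (1 + sqrt(5)) / 2
  g1 <- rotation_about_axis(c(0, 1, phi), 2 * pi / 5)
  g2 <- rotation_about_axis(c(0, 1, -phi), 2 * pi / 5)
  els <- list(diag(3))
  keys <- paste(round(diag(3), 6), collapse = ",")
  repeat {
    n0 <- length(els)
    for (E in els) for (G in list(g1, g2)) {
      M <- G %*% E
      k <- paste(round(M, 6), collapse = ",")
      if (!(k %in% keys)) { keys <- c(keys, k); els <- c(els, list(M)) }
    }
    if (length(els) == n0) break
  }
  stopifnot(length(els) == 60)
  .rotation_cache$R60 <- els
  els
}

# Rotation set as an nrot x 9 matrix (row-major 3x3 per row).
rotation_matrix_stack <- function(n) {
  R60 <- icosahedral_rotations()
  if (n == 1) R60 <- R60[1]
  else if (n < 60) R60 <- R60[seq_len(n)]
  do.call(rbind, lapply(R60, function(M) as.numeric(t(M))))
}

#' Build the three-channel scoring grid over the pocket box
#'
#' Precomputes, on a `dims^3` lattice spanning the pocket box: a
#' buried-surface channel (negative Gaussian shell at contact distance from
#' every receptor atom, rewarding contact without penetration), an
#' electrostatic channel (receptor Coulomb potential under the
#' distance-dependent dielectric eps = 4R), and a soft-core repulsion
#' channel inside the receptor vdW envelope.
#'
#' @param receptor a `receptor`.
#' @param pocket a `pocket_spec`.
#' @param dims lattice points per axis (default 120).
#' @param probe contact-probe radius added to atom vdW radii (Angstrom).
#' @param shell_width Gaussian width of the contact shell (Angstrom).
#' @param rep_range range of the soft-core penalty beyond the vdW radius.
#' @param rep_k height scale of the repulsion penalty.
#' @param surf_cap saturation of the buried-surface reward per grid point
#'   (a surface patch can only be buried once); 0 disables clamping.
#' @return a `score_grid`.
#' @export
build_score_grid <- function(receptor, pocket, dims = 120L, probe = 1.4,
                             shell_width = 0.45, rep_range = 1.0, rep_k = 15.0,
                             surf_cap = 10.0) {
  stopifnot(inherits(receptor, "receptor"), inherits(pocket, "pocket_spec"))
  dims <- rep(as.integer(dims), length.out = 3)
  lo <- pocket$center - pocket$box_half_widths
  hi <- pocket$center + pocket$box_half_widths
  spacing <- (hi - lo) / (dims - 1)
  xyz <- coords_matrix(receptor$structure)
  q <- receptor$structure$atoms$partial_charge
  q[is.na(q)] <- 0
  vr <- vdw_radius(receptor$structure$atoms$element)
  if (nrow(xyz) > 0) {
    rec_lo <- apply(xyz, 2, min); rec_hi <- apply(xyz, 2, max)
    if (any(hi < rec_lo - 10) || any(lo > rec_hi + 10)) {
      warning("geometry warning: pocket box lies far outside the receptor")
    }
  }
  ch <- .grid_build(xyz, q, vr, lo, spacing, dims, probe, shell_width,
                    rep_range, rep_k, surf_cap)
  structure(list(
    dims = dims, origin = lo, spacing = spacing,
    surf = ch$surf, elec = ch$elec, rep = ch$rep,
    pocket = pocket, receptor_ref = receptor$pdb_id
  ), class = "score_grid")
}

#' @export
print.score_grid <- function(x, ...) {
  cat(sprintf("<score_grid> %s: %dx%dx%d, spacing %.3f/%.3f/%.3f A\n",
              x$receptor_ref, x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# Interpolate one channel at arbitrary points (R-side mirror of the C++
# trilinear kernel; used by tests and probes).
grid_value_at <- function(grid, channel, xyz) {
  g <- grid[[channel]]
  vapply(seq_len(nrow(xyz)), function(i) {
    f <- (xyz[i, ] - grid$origin) / grid$spacing
    if (any(f < 0) || any(f > grid$dims - 1)) return(NA_real_)
    i0 <- pmin(floor(f), grid$dims - 2)
    t <- f - i0
    acc <- 0
    for (c in 0:7) {
      o <- c(bitwAnd(c, 1), bitwAnd(bitwShiftR(c, 1), 1), bitwAnd(bitwShiftR(c, 2), 1))
      w <- prod(ifelse(o == 1, t, 1 - t))
      idx <- (i0[1] + o[1]) + grid$dims[1] * ((i0[2] + o[2]) + grid$dims[2] * (i0[3] + o[3]))
      acc <- acc + w * g[idx + 1]
    }
    acc
  }, numeric(1))
}

#' Dock one compound against a scoring grid
#'
#' Exhaustive, deterministic search over pre-generated conformers x sampled
#' rigid rotations x a translation lattice inside the pocket box. Poses
#' with any atom outside the box are discarded. The score of a pose is the
#' weighted sum of the three channels interpolated trilinearly at every
#' atom position; the best (lowest) score wins, ties going to the earlier
#' pose in enumeration order.
#'
#' @param vc a `virtual_compound` or `molecule` (charges assigned).
#' @param grid a `score_grid`.
#' @param cfg a [docking_config()].
#' @param conformers optional pre-computed conformer list (as from
#'   [generate_conformers()]).
#' @return a `dock_result`: list with `score`, `compound_ref`, `site_label`,
#'   `template_name`, `receptor_ref`, `best_pose`.
#' @export
dock_compound <- function(vc, grid, cfg = docking_config(), conformers = NULL) {
  stopifnot(inherits(grid, "score_grid"))
  mol <- if (inherits(vc, "virtual_compound")) vc$molecule else vc
  if (is.null(conformers)) conformers <- generate_conformers(mol, cfg)
  q <- mol$atoms$partial_charge
  q[is.na(q)] <- 0
  rot <- rotation_matrix_stack(cfg$rotation_samples)
  lo <- grid$pocket$center - grid$pocket$box_half_widths
  hi <- grid$pocket$center + grid$pocket$box_half_widths
  best <- NULL
  for (ci in seq_along(conformers)) {
    xyz <- conformers[[ci]]
    centered <- xyz - matrix(colMeans(xyz), nrow(xyz), 3, byrow = TRUE)
    # score outermost atoms first: wall clashes surface early, so the
    # branch-and-bound cutoff triggers sooner (order does not affect the sum)
    ord <- order(-rowSums(centered^2))
    centered <- centered[ord, , drop = FALSE]
    qo <- q[ord]
    res <- .dock_scan(centered, qo, rot, grid$origin, grid$spacing, grid$dims,
                      grid$surf, grid$elec, grid$rep, lo, hi,
                      cfg$translation_step,
                      cfg$weights[["w_surf"]], cfg$weights[["w_elec"]],
                      cfg$weights[["w_rep"]])
    if (res$n_valid_poses > 0 && (is.null(best) || res$score < best$score)) {
      best <- res
      best$conformer <- ci
    }
  }
  if (is.null(best)) {
    stop("no-pose error: compound '", mol$name,
         "' has no pose inside the pocket box (too large for the box?)")
  }
  structure(list(
    score = best$score,
    compound_ref = if (inherits(vc, "virtual_compound")) vc$generation_index else NA_integer_,
    compound_name = mol$name,
    site_label = if (inherits(vc, "virtual_compound")) vc$site_label else NA_character_,
    template_name = if (inherits(vc, "virtual_compound")) vc$template_name else NA_character_,
    receptor_ref = grid$receptor_ref,
    best_pose = list(rotation_index = best$rotation_index,
                     translation = best$translation,
                     conformer = best$conformer),
    n_valid_poses = best$n_valid_poses
  ), class = "dock_result")
}

#' @export
print.dock_result <- function(x, ...) {
  cat(sprintf("<dock_result> %s vs %s: score %.4f (conformer %d, rotation %d)\n",
              x$compound_name, x$receptor_ref, x$score,
              x$best_pose$conformer, x$best_pose$rotation_index))
  invisible(x)
}

#' Dock every compound of a virtual library
#'
#' Compounds that fit no pose inside the box are kept with score `NA` (they
#' rank last).
#'
#' @param lib a `virtual_library`.
#' @param grid a `score_grid`.
#' @param cfg a [docking_config()].
#' @return data.frame with one row per compound: `generation_index`,
#'   `site_label`, `template_name`, `score`, `receptor_ref`.
#' @export
dock_library <- function(lib, grid, cfg = docking_config()) {
  stopifnot(inherits(lib, "virtual_library"))
  rows <- lapply(lib$compounds, function(vc) {
    res <- tryCatch(dock_compound(vc, grid, cfg), error = function(e) NULL)
    data.frame(
      generation_index = vc$generation_index,
      site_label = vc$site_label,
      template_name = vc$template_name,
      score = if (is.null(res)) NA_real_ else res$score,
      receptor_ref = grid$receptor_ref,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Import docking scores computed by an external engine
#'
#' Accepts a CSV with columns `compound_id`, `receptor_id`, `score` and
#' matches every library member exactly once per receptor.
#'
#' @param csv path to the score table.
#' @param library a `virtual_library` or list of `virtual_compound`s.
#' @param negate flip score signs for engines where higher = better.
#' @return data.frame in the same shape as [dock_library()].
#' @export
import_external_scores <- function(csv, library, negate = FALSE) {
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  need <- c("compound_id", "receptor_id", "score")
  if (!all(need %in% names(tab))) {
    stop("input error: score CSV needs columns ", paste(need, collapse = ", "))
  }
  compounds <- if (inherits(library, "virtual_library")) library$compounds else library
  ids <- vapply(compounds, function(vc) vc$generation_index, integer(1))
  dup <- duplicated(tab[, c("compound_id", "receptor_id")])
  if (any(dup)) {
    stop("input error: duplicate (compound, receptor) rows: ",
         paste(utils::head(tab$compound_id[dup], 5), collapse = ", "))
  }
  out <- list()
  for (rec in unique(tab$receptor_id)) {
    sub <- tab[tab$receptor_id == rec, ]
    missing <- setdiff(ids, sub$compound_id)
    if (length(missing)) {
      stop("input error: no score for compound id(s) ",
           paste(utils::head(missing, 10), collapse = ", "),
           " against receptor ", rec)
    }
    extra <- setdiff(sub$compound_id, ids)
    if (length(extra)) {
      stop("input error: unknown compound id(s) ",
           paste(utils::head(extra, 10), collapse = ", "),
           " for receptor ", rec)
    }
    m <- match(ids, sub$compound_id)
    out[[rec]] <- data.frame(
      generation_index = ids,
      site_label = vapply(compounds, function(vc) vc$site_label, character(1)),
      template_name = vapply(compounds, function(vc) vc$template_name, character(1)),
      score = if (negate) -sub$score[m] else sub$score[m],
      receptor_ref = rec,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
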