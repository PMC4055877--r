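# Term construction and minimization driver for the built-in force field.

.LJ_EPS <- c(H = 0.022, C = 0.086, N = 0.17, O = 0.21, F = 0.061, P = 0.2,
             S = 0.25, Cl = 0.265, Br = 0.32, I = 0.4, "*" = 0.05)

lj_epsilon <- function(element) {
  e <- .LJ_EPS[element]
  e[is.na(e)] <- 0.1
  unname(e)
}

# Equilibrium bond length by order (aromatic rings are kekulized; order 2
# shortens, order 3 more so).
equilibrium_bond_length <- function(el_i, el_j, order) {
  base <- covalent_radius(el_i) + covalent_radius(el_j)
  shrink <- c(`1` = 1.0, `2` = 0.89, `3` = 0.81)
  base * unname(shrink[as.character(pmin(order, 3))])
}

#' Minimization configuration
#'
#' The electrostatic term always uses the distance-dependent dielectric
#' eps = 4R (R = interatomic distance in Angstrom), i.e.
#' E = 332.0637 q_i q_j / (4 R^2) kcal/mol.
#'
#' @param max_iterations maximum L-BFGS iterations.
#' @param gradient_tol convergence tolerance on the projected gradient,
#'   kcal/mol/Angstrom.
#' @return a `minimization_config` object.
#' @export
minimization_config <- function(max_iterations = 500L, gradient_tol = 1e-3) {
  stopifnot(gradient_tol > 0, max_iterations >= 1)
  structure(list(
    dielectric_model = "4R",
    force_field = "fraggrow-lite",
    max_iterations = as.integer(max_iterations),
    gradient_tol = gradient_tol
  ), class = "minimization_config")
}

# Build bonded/nonbonded term tables for a molecule. Partial charges must be
# assigned (NA treated as 0).
build_ff_terms <- function(mol) {
  n <- n_atoms(mol)
  el <- mol$atoms$element
  hyb <- hybridization(mol)
  adj <- adjacency(mol)
  b <- mol$bonds

  bond_idx <- as.matrix(b[, c("from", "to")])
  storage.mode(bond_idx) <- "integer"
  bond_r0 <- equilibrium_bond_length(el[b$from], el[b$to], b$order)
  bond_k <- rep(300, nrow(b))

  # angles: center j over all neighbor pairs
  ang <- list()
  theta0_of <- c(sp3 = 109.47, sp2 = 120, sp = 180, s = 109.47) * pi / 180
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    prs <- utils::combn(nb, 2)
    for (p in seq_len(ncol(prs))) {
      ang[[length(ang) + 1]] <- c(prs[1, p], j, prs[2, p])
    }
  }
  if (length(ang)) {
    angles <- do.call(rbind, ang)
    angle_t0 <- theta0_of[hyb[angles[, 2]]]
    angle_k <- rep(60, nrow(angles))
    # drop angles centered on sp atoms near-linear terms keep small k
    storage.mode(angles) <- "integer"
  } else {
    angles <- matrix(integer(), 0, 3)
    angle_t0 <- numeric(0); angle_k <- numeric(0)
  }

  # torsions over each central bond j-k
  tor <- list(); tor_n <- integer(0); tor_phi0 <- numeric(0); tor_v <- numeric(0)
  for (kbond in seq_len(nrow(b))) {
    j <- b$from[kbond]; k <- b$to[kbond]
    if (hyb[j] == "sp" || hyb[k] == "sp") next
    js <- setdiff(adj[[j]], k); ks <- setdiff(adj[[k]], j)
    if (!length(js) || !length(ks)) next
    ord <- b$order[kbond]
    if (ord >= 2) {
      nper <- 2L; phi0 <- pi; V <- 15
    } else if (hyb[j] == "sp2" && hyb[k] == "sp2") {
      nper <- 2L; phi0 <- pi; V <- 2
    } else if (hyb[j] == "sp3" && hyb[k] == "sp3") {
      nper <- 3L; phi0 <- 0; V <- 0.3
    } else {
      next # sp2-sp3 single bonds rotate freely
    }
    for (i in js) for (l in ks) {
      if (i == l) next
      tor[[length(tor) + 1]] <- c(i, j, k, l)
      tor_n <- c(tor_n, nper); tor_phi0 <- c(tor_phi0, phi0); tor_v <- c(tor_v, V)
    }
  }
  torsions <- if (length(tor)) do.call(rbind, tor) else matrix(integer(), 0, 4)
  storage.mode(torsions) <- "integer"

  # nonbonded pairs with 1-2/1-3 exclusion and 1-4 scaling
  excl <- matrix(FALSE, n, n)
  scale14 <- matrix(FALSE, n, n)
  for (kbond in seq_len(nrow(b))) excl[b$from[kbond], b$to[kbond]] <- excl[b$to[kbond], b$from[kbond]] <- TRUE
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      prs <- utils::combn(nb, 2)
      for (p in seq_len(ncol(prs))) excl[prs[1, p], prs[2, p]] <- excl[prs[2, p], prs[1, p]] <- TRUE
    }
  }
  if (nrow(torsions) > 0) {
    for (t in seq_len(nrow(torsions))) {
      scale14[torsions[t, 1], torsions[t, 4]] <- scale14[torsions[t, 4], torsions[t, 1]] <- TRUE
    }
  }
  q <- mol$atoms$partial_charge
  q[is.na(q)] <- 0
  nbp <- list(); qfac <- numeric(0); eps <- numeric(0); rmin <- numeric(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (excl[i, j]) next
      s_lj <- if (scale14[i, j]) 0.5 else 1.0
      s_el <- if (scale14[i, j]) 0.8333 else 1.0
      nbp[[length(nbp) + 1]] <- c(i, j)
      qfac <- c(qfac, 332.0637 * q[i] * q[j] * s_el / 4)
      eps <- c(eps, sqrt(lj_epsilon(el[i]) * lj_epsilon(el[j])) * s_lj)
      rmin <- c(rmin, vdw_radius(el[i]) + vdw_radius(el[j]))
    }
  }
  nbm <- if (length(nbp)) do.call(rbind, nbp) else matrix(integer(), 0, 2)
  storage.mode(nbm) <- "integer"

  list(bonds = bond_idx, bond_r0 = bond_r0, bond_k = bond_k,
       angles = angles, angle_t0 = unname(angle_t0), angle_k = angle_k,
       torsions = torsions, tor_n = tor_n, tor_phi0 = tor_phi0, tor_v = tor_v,
       nb = nbm, nb_qfac = qfac, nb_eps = eps, nb_rmin = rmin)
}

ff_energy <- function(coords, terms) {
  .ff_energy_gradient(as.numeric(t(coords)), terms$bonds, terms$bond_r0,
                      terms$bond_k, terms$angles, terms$angle_t0, terms$angle_k,
                      terms$torsions, terms$tor_n, terms$tor_phi0, terms$tor_v,
                      terms$nb, terms$nb_qfac, terms$nb_eps, terms$nb_rmin,
                      FALSE)$energy
}

ff_gradient <- function(coords, terms) {
  out <- .ff_energy_gradient(as.numeric(t(coords)), terms$bonds, terms$bond_r0,
                             terms$bond_k, terms$angles, terms$angle_t0, terms$angle_k,
                             terms$torsions, terms$tor_n, terms$tor_phi0, terms$tor_v,
                             terms$nb, terms$nb_qfac, terms$nb_eps, terms$nb_rmin,
                             TRUE)
  matrix(out$gradient, ncol = 3, byrow = TRUE)
}

#' Energy-minimize a molecule in vacuum
#'
#' Minimizes the built-in force-field energy (distance-dependent dielectric
#' eps = 4R) with L-BFGS-B. The connectivity is untouched; the returned
#' energy never exceeds the starting energy.
#'
#' @param mol a `molecule` with 3D coordinates.
#' @param cfg a [minimization_config()].
#' @return the molecule with optimized coordinates; attributes
#'   `initial_energy`, `final_energy`, `iterations`, `converged` record the
#'   minimization trace.
#' @export
minimize_molecule <- function(mol, cfg = minimization_config()) {
  if (!inherits(cfg, "minimization_config")) stop("cfg must be a minimization_config")
  terms <- build_ff_terms(mol)
  x0 <- as.numeric(t(coords_matrix(mol)))
  fn <- function(p) {
    e <- .ff_energy_gradient(p, terms$bonds, terms$bond_r0, terms$bond_k,
                             terms$angles, terms$angle_t0, terms$angle_k,
                             terms$torsions, terms$tor_n, terms$tor_phi0,
                             terms$tor_v, terms$nb, terms$nb_qfac, terms$nb_eps,
                             terms$nb_rmin, FALSE)$energy
    if (!is.finite(e)) stop("minimization error: non-finite energy encountered")
    e
  }
  gr <- function(p) {
    .ff_energy_gradient(p, terms$bonds, terms$bond_r0, terms$bond_k,
                        terms$angles, terms$angle_t0, terms$angle_k,
                        terms$torsions, terms$tor_n, terms$tor_phi0,
                        terms$tor_v, terms$nb, terms$nb_qfac, terms$nb_eps,
                        terms$nb_rmin, TRUE)$gradient
  }
  e0 <- fn(x0)
  res <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = cfg$max_iterations,
                                     pgtol = cfg$gradient_tol, factr = 1e3))
  if (!is.finite(res$value)) stop("minimization error: diverged (energy not finite)")
  xf <- if (res$value <= e0) res$par else x0
  out <- set_coords(mol, matrix(xf, ncol = 3, byrow = TRUE))
  attr(out, "initial_energy") <- e0
  attr(out, "final_energy") <- min(res$value, e0)
  attr(out, "iterations") <- res$counts[["function"]]
  attr(out, "converged") <- res$convergence == 0
  out
}
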