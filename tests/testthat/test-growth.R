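test_that("attachment does correct graph arithmetic", {
  benz <- fix_benzene()
  sites <- enumerate_replaceable_sites(benz)
  vc <- attach_sidechain(benz, sites[1, ], singleton_set()$templates[1, ])
  expect_s3_class(vc, "virtual_compound")
  expect_equal(n_heavy_atoms(vc$molecule), 7) # toluene
  expect_true(fraggrow:::is_connected(vc$molecule))

  meth <- load_molecule("C", format = "SMILES")
  meth$name <- "methane"
  vc2 <- attach_sidechain(meth, enumerate_replaceable_sites(meth)[1, ],
                          singleton_set()$templates[1, ])
  expect_equal(n_heavy_atoms(vc2$molecule), 2) # ethane
  # heavy-atom bookkeeping: seed heavy + template heavy
  expect_equal(nrow(vc2$molecule$bonds), 7)
})

test_that("fluorine replacement removes F and bonds to its anchor", {
  fb <- assign_gasteiger_charges(load_molecule("Fc1ccccc1", format = "SMILES"))
  fb$name <- "fluorobenzene"
  s <- enumerate_replaceable_sites(fb)
  fsite <- s[fb$atoms$element[s$atom_index] == "F", ]
  vc <- attach_sidechain(fb, fsite, singleton_set()$templates[1, ])
  expect_equal(sum(vc$molecule$atoms$element == "F"), 0)
  expect_equal(n_heavy_atoms(vc$molecule), 7) # toluene again
})

test_that("a site buried between ortho tert-butyl groups rejects phenyl", {
  seed <- assign_gasteiger_charges(
    load_molecule("CC(C)(C)c1cccc(C(C)(C)C)c1", format = "SMILES"))
  seed$name <- "1,3-di-tert-butylbenzene"
  sites <- enumerate_replaceable_sites(seed)
  # the ring H between the two substituted carbons
  hyb <- fraggrow:::hybridization(seed)
  buried <- NULL
  for (r in seq_len(nrow(sites))) {
    a <- sites$anchor_index[r]
    if (hyb[a] != "sp2") next
    ring_nb <- Filter(function(j) hyb[j] == "sp2", fraggrow:::neighbors_of(seed, a))
    subst <- vapply(ring_nb, function(j) {
      any(vapply(fraggrow:::neighbors_of(seed, j), function(k) {
        seed$atoms$element[k] == "C" && hyb[k] == "sp3"
      }, logical(1)))
    }, logical(1))
    if (length(ring_nb) == 2 && all(subst)) { buried <- sites[r, ]; break }
  }
  expect_false(is.null(buried))
  tpl <- data.frame(name = "phenyl", smiles = "*c1ccccc1",
                    canonical = "*c1ccccc1", linker = "direct",
                    scaffold_id = 8L, variant_id = 1L)
  res <- attach_sidechain(seed, buried, tpl)
  expect_s3_class(res, "growth_rejection")
  expect_gt(nrow(res$clash_pairs), 0)

  # independent oracle: brute-force the 12 rotamers with plain distance math
  tmol <- fraggrow:::embed_template(tpl)
  dummy <- which(tmol$atoms$element == "*")
  t_i <- fraggrow:::neighbors_of(tmol, dummy)
  sx <- as.matrix(seed$atoms[, c("x", "y", "z")])
  tx <- as.matrix(tmol$atoms[, c("x", "y", "z")])
  d <- (sx[buried$atom_index, ] - sx[buried$anchor_index, ])
  d <- d / sqrt(sum(d^2))
  u <- (tx[dummy, ] - tx[t_i, ]); u <- u / sqrt(sum(u^2))
  R <- fraggrow:::rotation_between(u, -d)
  L <- fraggrow:::covalent_radius("C") * 2
  tpos <- sx[buried$anchor_index, ] + L * d
  tal <- t(R %*% t(tx - matrix(tx[t_i, ], nrow(tx), 3, byrow = TRUE))) +
    matrix(tpos, nrow(tx), 3, byrow = TRUE)
  seed_keep <- setdiff(seq_len(nrow(sx)), buried$atom_index)
  vr <- fraggrow:::vdw_radius
  any_clash_every_rotamer <- TRUE
  for (k in 0:11) {
    Rk <- fraggrow:::rotation_about_axis(d, k * pi / 6)
    rot <- t(Rk %*% t(tal - matrix(tpos, nrow(tal), 3, byrow = TRUE))) +
      matrix(tpos, nrow(tal), 3, byrow = TRUE)
    clash <- FALSE
    for (i in seed_keep) {
      if (i == buried$anchor_index) next
      for (j in setdiff(seq_len(nrow(rot)), c(dummy, t_i))) {
        dist <- sqrt(sum((sx[i, ] - rot[j, ])^2))
        sc <- if (seed$atoms$element[i] == "H" || tmol$atoms$element[j] == "H") 0.6 else 0.7
        if (dist < sc * (vr(seed$atoms$element[i]) + vr(tmol$atoms$element[j]))) {
          clash <- TRUE; break
        }
      }
      if (clash) break
    }
    if (!clash) any_clash_every_rotamer <- FALSE
  }
  expect_true(any_clash_every_rotamer)
})

test_that("library enumeration conserves sites x templates and is deterministic", {
  benz <- fix_benzene()
  lib <- enumerate_virtual_library(benz, singleton_set(), minimize = FALSE, charges = FALSE)
  expect_equal(length(lib$compounds), 6) # six toluene copies, distinct sites
  expect_equal(length(unique(vapply(lib$compounds, function(v) v$site_label,
                                    character(1)))), 6)
  expect_equal(vapply(lib$compounds, function(v) v$generation_index, integer(1)),
               1:6)

  seed <- assign_gasteiger_charges(
    load_molecule("CC(C)(C)c1cccc(C(C)(C)C)c1", format = "SMILES"))
  seed$name <- "crowded"
  set <- fix_set("C")
  lib2 <- enumerate_virtual_library(seed, set, minimize = FALSE, charges = FALSE)
  n_sites <- nrow(enumerate_replaceable_sites(seed))
  expect_equal(length(lib2$compounds) + nrow(lib2$rejections),
               n_sites * length(set))
  expect_lte(length(lib2$compounds), n_sites * length(set))
  expect_gt(nrow(lib2$rejections), 0) # the buried site rejects bulky groups

  lib3 <- enumerate_virtual_library(seed, set, minimize = FALSE, charges = FALSE)
  expect_equal(length(lib3$compounds), length(lib2$compounds))
  expect_lt(max(abs(as.matrix(lib3$compounds[[5]]$molecule$atoms[, c("x", "y", "z")]) -
                      as.matrix(lib2$compounds[[5]]$molecule$atoms[, c("x", "y", "z")]))),
            1e-6)
})

test_that("raising the clash threshold never increases the accepted count", {
  seed <- assign_gasteiger_charges(
    load_molecule("CC(C)(C)c1cccc(C(C)(C)C)c1", format = "SMILES"))
  seed$name <- "crowded"
  set <- singleton_set("phenyl", "*c1ccccc1")
  accepted <- vapply(c(0.5, 0.6, 0.7, 0.8), function(s) {
    lib <- enumerate_virtual_library(seed, set,
                                     clash = clash_config(heavy_scale = s,
                                                          h_scale = s - 0.1),
                                     minimize = FALSE, charges = FALSE)
    length(lib$compounds)
  }, numeric(1))
  expect_true(all(diff(accepted) <= 0))
})

test_that("a seed without replaceable sites yields an empty library with a warning", {
  # perfluorinated? no: F is replaceable. Use a bare carbon cluster instead.
  at <- data.frame(element = c("C", "C"), x = c(0, 1.5), y = 0, z = 0)
  m <- molecule(at, data.frame(from = 1L, to = 2L, order = 3L), name = "C2")
  m$atoms$partial_charge <- 0
  expect_warning(lib <- enumerate_virtual_library(m, singleton_set(),
                                                  minimize = FALSE, charges = FALSE),
                 "no replaceable")
  expect_equal(length(lib$compounds), 0)
})

test_that("minimization lowers energy and keeps connectivity", {
  eth <- fix_eclipsed_ethane()
  out <- minimize_molecule(eth, minimization_config(max_iterations = 2000,
                                                    gradient_tol = 1e-5))
  expect_lte(attr(out, "final_energy"), attr(out, "initial_energy"))
  expect_identical(out$bonds, eth$bonds)
  # staggered torsions: every H-C-C-H dihedral near +-60 or 180
  for (h2 in 6:8) {
    tau <- dihedral_deg(out, 3, 1, 2, h2)
    expect_lt(min(abs(abs(tau) - 60), abs(abs(tau) - 180)), 10)
  }
  # torsion-scan oracle on a 1-degree grid: the minimizer's torsion matches
  # the grid minimum of the same energy function
  terms <- fraggrow:::build_ff_terms(eth)
  xyz <- as.matrix(eth$atoms[, c("x", "y", "z")])
  energies <- vapply(0:359, function(deg) {
    R <- fraggrow:::rotation_about_axis(xyz[2, ] - xyz[1, ], deg * pi / 180)
    x2 <- xyz
    piv <- xyz[2, ]
    x2[6:8, ] <- t(R %*% t(xyz[6:8, ] - matrix(piv, 3, 3, byrow = TRUE))) +
      matrix(piv, 3, 3, byrow = TRUE)
    fraggrow:::ff_energy(x2, terms)
  }, numeric(1))
  grid_min_tau <- (which.min(energies) - 1)
  start_tau <- dihedral_deg(eth, 3, 1, 2, 6)
  best_tau <- (start_tau + grid_min_tau) %% 360
  min_tau <- dihedral_deg(out, 3, 1, 2, 6) %% 360
  diff_tau <- min(abs(best_tau - min_tau), 360 - abs(best_tau - min_tau))
  expect_lt(diff_tau, 10)
})

test_that("an already-minimized structure is a fixed point", {
  eth <- minimize_molecule(fix_eclipsed_ethane(),
                           minimization_config(max_iterations = 2000,
                                               gradient_tol = 1e-6))
  again <- minimize_molecule(eth, minimization_config(max_iterations = 2000,
                                                      gradient_tol = 1e-6))
  expect_lt(attr(again, "initial_energy") - attr(again, "final_energy"), 1e-3)
})
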