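test_that("receptor preparation defines the pocket from the reference ligand", {
  toy <- fix_toy()
  prep <- prepare_receptor(toy$pdb, list(resname = "LIG"))
  lig_xyz <- as.matrix(toy$seed$atoms[, c("x", "y", "z")])
  expect_lt(max(abs(prep$pocket$center - colMeans(lig_xyz))), 1e-3)
  ext <- apply(lig_xyz, 2, function(v) diff(range(v))) / 2
  expect_true(all(prep$pocket$box_half_widths >= ext - 1e-6))
  expect_equal(n_atoms(prep$receptor$structure),
               n_atoms(toy$receptor$structure))
  expect_error(prepare_receptor(toy$pdb, list(resname = "XYZ")),
               "selection error")
})

test_that("grid channels behave physically", {
  # empty receptor -> all channels zero
  empty <- fraggrow:::receptor_object(
    molecule(data.frame(element = character(), x = numeric(), y = numeric(),
                        z = numeric())), "EMPTY")
  g0 <- build_score_grid(empty, pocket_spec(c(0, 0, 0), c(5, 5, 5)), dims = 12)
  expect_true(all(g0$surf == 0) && all(g0$elec == 0) && all(g0$rep == 0))

  # single charged atom: electrostatic channel flips sign with the charge,
  # repulsion decays away from the atom center
  at <- data.frame(element = "C", x = 0, y = 0, z = 0, formal_charge = 0L,
                   partial_charge = 0.5)
  rec_pos <- fraggrow:::receptor_object(molecule(at), "ONE")
  at$partial_charge <- -0.5
  rec_neg <- fraggrow:::receptor_object(molecule(at), "ONE")
  pk <- pocket_spec(c(0, 0, 0), c(6, 6, 6))
  gp <- build_score_grid(rec_pos, pk, dims = 25)
  gn <- build_score_grid(rec_neg, pk, dims = 25)
  expect_equal(gp$elec, -gn$elec, tolerance = 1e-12)
  at_center <- fraggrow:::grid_value_at(gp, "rep", matrix(c(0, 0, 0), 1))
  at_far <- fraggrow:::grid_value_at(gp, "rep", matrix(c(5, 0, 0), 1))
  expect_gt(at_center, at_far)
  expect_equal(at_far, 0)
})

test_that("a single uncharged probe scores the interpolated channel values", {
  grid <- fix_toy_grid()
  # probe on an exact lattice point: score = w_surf*surf + w_rep*rep there
  ij <- c(30, 60, 60)
  pos <- grid$origin + (ij - 1) * grid$spacing
  idx <- (ij[1] - 1) + grid$dims[1] * ((ij[2] - 1) + grid$dims[2] * (ij[3] - 1)) + 1
  at <- data.frame(element = "C", x = pos[1], y = pos[2], z = pos[3],
                   formal_charge = 0L, partial_charge = 0)
  probe <- molecule(at, name = "probe")
  cfg <- docking_config(max_conformers = 1, rotation_samples = 1,
                        translation_step = 1000) # only one translation evaluated
  # place the box so the single translation lands exactly on the lattice point
  g2 <- grid
  g2$pocket <- pocket_spec(pos, c(1e-6, 1e-6, 1e-6) + 1e-9)
  res <- dock_compound(probe, g2, cfg)
  expect_equal(res$score, grid$surf[idx] + grid$rep[idx], tolerance = 1e-5)
})

test_that("docking is deterministic and invariant to atom order", {
  toy <- fix_toy()
  grid <- fix_toy_grid()
  cfg <- docking_config(max_conformers = 2, translation_step = 1.0)
  r1 <- dock_compound(toy$seed, grid, cfg)
  r2 <- dock_compound(toy$seed, grid, cfg)
  expect_identical(r1$score, r2$score)

  m <- toy$seed
  n <- n_atoms(m)
  perm <- rev(seq_len(n))
  inv <- integer(n); inv[perm] <- seq_len(n)
  pm <- molecule(m$atoms[perm, ],
                 data.frame(from = inv[m$bonds$from], to = inv[m$bonds$to],
                            order = m$bonds$order), name = "perm")
  r3 <- dock_compound(pm, grid, cfg)
  expect_equal(r3$score, r1$score, tolerance = 1e-9)
})

test_that("translating receptor and pocket together leaves scores unchanged", {
  toy <- fix_toy()
  shift <- c(13.7, -8.1, 5.5)
  rec2 <- toy$receptor
  rec2$structure$atoms$x <- rec2$structure$atoms$x + shift[1]
  rec2$structure$atoms$y <- rec2$structure$atoms$y + shift[2]
  rec2$structure$atoms$z <- rec2$structure$atoms$z + shift[3]
  pk2 <- pocket_spec(toy$pocket$center + shift, toy$pocket$box_half_widths)
  g1 <- build_score_grid(toy$receptor, toy$pocket, dims = 40)
  g2 <- build_score_grid(rec2, pk2, dims = 40)
  cfg <- docking_config(max_conformers = 1, translation_step = 1.2)
  r1 <- dock_compound(toy$seed, g1, cfg)
  r2 <- dock_compound(toy$seed, g2, cfg)
  expect_equal(r1$score, r2$score, tolerance = 1e-6)
})

test_that("best pose matches brute-force enumeration on a coarse grid", {
  toy <- fix_toy()
  grid <- build_score_grid(toy$receptor, toy$pocket, dims = 20)
  cfg <- docking_config(max_conformers = 1, rotation_samples = 12,
                        translation_step = 1.5)
  mol <- toy$seed
  res <- dock_compound(mol, grid, cfg)

  # independent brute force in R over the same pose set
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  q <- mol$atoms$partial_charge
  centered <- xyz - matrix(colMeans(xyz), nrow(xyz), 3, byrow = TRUE)
  rots <- fraggrow:::icosahedral_rotations()[1:12]
  lo <- grid$pocket$center - grid$pocket$box_half_widths
  hi <- grid$pocket$center + grid$pocket$box_half_widths
  ts <- lapply(1:3, function(d) lo[d] + 1.5 * 0:floor((hi[d] - lo[d]) / 1.5))
  best <- Inf
  for (R in rots) {
    rx <- t(R %*% t(centered))
    for (tz in ts[[3]]) for (ty in ts[[2]]) for (tx in ts[[1]]) {
      posed <- rx + matrix(c(tx, ty, tz), nrow(rx), 3, byrow = TRUE)
      s <- fraggrow:::grid_value_at(grid, "surf", posed)
      e <- fraggrow:::grid_value_at(grid, "elec", posed)
      r <- fraggrow:::grid_value_at(grid, "rep", posed)
      if (any(is.na(s))) next
      sc <- sum(s + 0.3 * q * e + r)
      if (sc < best) best <- sc
    }
  }
  expect_equal(res$score, best, tolerance = 1e-9)
})

test_that("compounds larger than the box raise a no-pose error", {
  toy <- fix_toy()
  grid <- fix_toy_grid()
  long <- load_molecule("CCCCCCCCCCCCCCCCCCCCCCCC", format = "SMILES",
                        minimize = FALSE)
  long$atoms$partial_charge <- 0
  # stretch it flat to be sure it exceeds the box
  long$atoms$x <- seq(0, by = 1.4, length.out = n_atoms(long))
  expect_error(dock_compound(long, grid,
                             docking_config(max_conformers = 1,
                                            rotation_samples = 1,
                                            translation_step = 2)),
               "no-pose")
})

test_that("conformer generation respects bounds, determinism and rigidity", {
  benz <- fix_benzene()
  expect_length(generate_conformers(benz, docking_config()), 1)

  hex <- load_molecule("CCCCCC", format = "SMILES")
  hex$atoms$partial_charge <- 0
  cfg <- docking_config(max_conformers = 10)
  confs <- generate_conformers(hex, cfg)
  expect_gte(length(confs), 1)
  expect_lte(length(confs), 10)
  confs2 <- generate_conformers(hex, cfg)
  expect_identical(confs, confs2)
  # dedup: pairwise heavy-atom RMSD >= 0.5
  heavy <- which(hex$atoms$element != "H")
  if (length(confs) > 1) {
    for (i in 1:(length(confs) - 1)) for (j in (i + 1):length(confs)) {
      expect_gte(fraggrow:::aligned_rmsd(confs[[i]][heavy, ], confs[[j]][heavy, ]),
                 0.5)
    }
  }
})

test_that("external score import matches library members exactly", {
  benz <- fix_benzene()
  lib <- enumerate_virtual_library(benz, singleton_set(), minimize = FALSE)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(compound_id = 1:6, receptor_id = "R1",
                              score = c(-5, -7, -6, -1, -2, -3)), csv,
                   row.names = FALSE)
  res <- import_external_scores(csv, lib)
  expect_equal(nrow(res), 6)
  expect_equal(res$score[res$generation_index == 2], -7)

  utils::write.csv(data.frame(compound_id = 1:5, receptor_id = "R1",
                              score = 1:5), csv, row.names = FALSE)
  expect_error(import_external_scores(csv, lib), "no score for compound")

  utils::write.csv(data.frame(compound_id = 1:7, receptor_id = "R1",
                              score = 1:7), csv, row.names = FALSE)
  expect_error(import_external_scores(csv, lib), "unknown compound")

  utils::write.csv(data.frame(compound_id = c(1:6, 3), receptor_id = "R1",
                              score = 1:7), csv, row.names = FALSE)
  expect_error(import_external_scores(csv, lib), "duplicate")
})
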