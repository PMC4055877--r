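test_that("SMILES loading yields explicit hydrogens and sane composition", {
  m <- load_molecule("C", format = "SMILES")
  expect_equal(sum(m$atoms$element == "C"), 1)
  expect_equal(sum(m$atoms$element == "H"), 4)
  b <- fix_benzene()
  expect_equal(sum(b$atoms$element == "C"), 6)
  expect_equal(sum(b$atoms$element == "H"), 6)
  expect_true(all(is.finite(as.matrix(b$atoms[, c("x", "y", "z")]))))
})

test_that("SMILES embedding is deterministic and records its seed", {
  m1 <- load_molecule("CCO", format = "SMILES", embed_seed = 7L)
  m2 <- load_molecule("CCO", format = "SMILES", embed_seed = 7L)
  expect_identical(m1$atoms, m2$atoms)
  expect_equal(m1$provenance$embed_seed, 7L)
})

test_that("multi-record SDF round-trips graph and coordinates", {
  mols <- list(load_molecule("CCO", format = "SMILES"),
               load_molecule("c1ccccc1C", format = "SMILES"))
  mols[[1]]$name <- "ethanol"; mols[[2]]$name <- "toluene"
  path <- tempfile(fileext = ".sdf")
  write_molecules_sdf(mols, path)
  back <- load_molecule(path, format = "SDF")
  expect_length(back, 2)
  expect_equal(back[[1]]$name, "ethanol")
  expect_equal(back[[2]]$name, "toluene")
  for (i in 1:2) {
    expect_identical(back[[i]]$atoms$element, mols[[i]]$atoms$element)
    expect_equal(back[[i]]$bonds, mols[[i]]$bonds)
    expect_lt(max(abs(as.matrix(back[[i]]$atoms[, c("x", "y", "z")]) -
                        as.matrix(mols[[i]]$atoms[, c("x", "y", "z")]))), 1e-4)
  }
})

test_that("formal charges survive the SDF round trip", {
  m <- load_molecule("CC(=O)[O-]", format = "SMILES", minimize = FALSE)
  path <- tempfile(fileext = ".sdf")
  write_molecules_sdf(m, path)
  back <- load_molecule(path, format = "SDF")
  expect_equal(sum(back$atoms$formal_charge), -1)
})

test_that("unparseable input raises a format error", {
  expect_error(load_molecule("not_a_smiles((", format = "SMILES"),
               "parse failure")
  bad <- tempfile(fileext = ".sdf")
  writeLines(c("junk", "no molecule here"), bad)
  expect_error(load_molecule(bad, format = "SDF"), "parse error")
})

test_that("replaceable sites are exactly the H and F atoms, ascending", {
  expect_equal(nrow(enumerate_replaceable_sites(load_molecule("C", format = "SMILES"))), 4)
  expect_equal(nrow(enumerate_replaceable_sites(fix_benzene())), 6)
  fb <- load_molecule("Fc1ccccc1", format = "SMILES", minimize = FALSE)
  s <- enumerate_replaceable_sites(fb)
  expect_equal(nrow(s), 6) # 5 H + 1 F
  expect_equal(sum(fb$atoms$element[s$atom_index] == "F"), 1)
  expect_true(all(diff(s$atom_index) > 0))
  # property: |sites| = #H + #F on a spread of molecules
  for (smi in c("CC", "CCO", "FC(F)(F)c1ccccc1", "C1CCCCC1", "N", "O=C=O")) {
    m <- load_molecule(smi, format = "SMILES", minimize = FALSE)
    expect_equal(nrow(enumerate_replaceable_sites(m)),
                 sum(m$atoms$element %in% c("H", "F")),
                 info = smi)
  }
})

test_that("site labels name the replaced atom and its anchor, 1-based", {
  m <- load_molecule("C", format = "SMILES")
  s <- enumerate_replaceable_sites(m)
  expect_match(s$label, "^H[2-5]@C1$")
})

test_that("Gasteiger charges conserve total charge and ignore atom order", {
  m <- assign_gasteiger_charges(load_molecule("C", format = "SMILES"))
  cq <- m$atoms$partial_charge[m$atoms$element == "C"]
  expect_lt(cq, 0)
  expect_true(all(m$atoms$partial_charge[m$atoms$element == "H"] > 0))
  expect_lt(abs(sum(m$atoms$partial_charge)), 1e-3)

  for (smi in c("CCO", "CC(=O)[O-]", "C[NH3+]", "c1ccccc1", "CC(C)CC(=O)N")) {
    mol <- assign_gasteiger_charges(load_molecule(smi, format = "SMILES",
                                                  minimize = FALSE))
    expect_lt(abs(sum(mol$atoms$partial_charge) - sum(mol$atoms$formal_charge)),
              1e-3, label = smi)
  }

  # permutation invariance: reverse atom order, recompute, compare multisets
  mol <- assign_gasteiger_charges(load_molecule("CCCO", format = "SMILES",
                                                minimize = FALSE))
  n <- nrow(mol$atoms)
  perm <- rev(seq_len(n))
  inv <- integer(n); inv[perm] <- seq_len(n)
  pm <- molecule(mol$atoms[perm, ],
                 data.frame(from = inv[mol$bonds$from], to = inv[mol$bonds$to],
                            order = mol$bonds$order), name = "perm")
  pm <- assign_gasteiger_charges(pm)
  expect_equal(sort(round(pm$atoms$partial_charge, 6)),
               sort(round(mol$atoms$partial_charge, 6)))
})

test_that("elements outside the charge parameterization are rejected", {
  at <- data.frame(element = c("Se", "H"), x = c(0, 1), y = 0, z = 0)
  bd <- data.frame(from = 1L, to = 2L, order = 1L)
  expect_error(assign_gasteiger_charges(molecule(at, bd)), "Se.*atom 1")
})

test_that("PDB reading keeps first-model ATOM/HETATM with altloc A", {
  toy <- fix_toy()
  mol <- load_molecule(toy$pdb, format = "PDB")
  expect_s3_class(mol, "molecule")
  expect_true(all(c("PKT", "LIG") %in% mol$pdb_meta$resid))
})
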