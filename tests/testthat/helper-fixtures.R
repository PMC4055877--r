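# Shared lazily-built fixtures (cached for the whole test session).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

fix_set <- function(id) cached(paste0("set", id), build_set(id))

fix_benzene <- function() cached("benzene", {
  m <- load_molecule("c1ccccc1", format = "SMILES")
  m$name <- "benzene"
  assign_gasteiger_charges(m)
})

fix_toy <- function() cached("toy", make_toy_receptor())

fix_toy_grid <- function() cached("toy_grid", {
  toy <- fix_toy()
  build_score_grid(toy$receptor, toy$pocket)
})

# An eclipsed-ethane starting structure (slightly perturbed off the exact
# saddle so the minimizer can leave it).
fix_eclipsed_ethane <- function(perturb = 5 * pi / 180) {
  r_cc <- 1.54; r_ch <- 1.09; ang <- 110.9 * pi / 180
  c1 <- c(0, 0, 0); c2 <- c(0, 0, r_cc)
  ph1 <- c(0, 2 * pi / 3, 4 * pi / 3)
  ph2 <- ph1 + perturb # near-eclipsed
  h1 <- t(vapply(ph1, function(p) {
    c1 + r_ch * c(cos(p) * sin(pi - ang), sin(p) * sin(pi - ang), cos(pi - ang))
  }, numeric(3)))
  h2 <- t(vapply(ph2, function(p) {
    c2 + r_ch * c(cos(p) * sin(ang), sin(p) * sin(ang), r_cc * 0 + cos(ang))
  }, numeric(3)))
  atoms <- data.frame(
    element = c("C", "C", rep("H", 6)),
    x = c(c1[1], c2[1], h1[, 1], h2[, 1]),
    y = c(c1[2], c2[2], h1[, 2], h2[, 2]),
    z = c(c1[3], c2[3], h1[, 3], h2[, 3])
  )
  bonds <- data.frame(from = c(1L, 1L, 1L, 1L, 2L, 2L, 2L),
                      to = c(2L, 3L, 4L, 5L, 6L, 7L, 8L), order = 1L)
  m <- molecule(atoms, bonds, name = "ethane-eclipsed")
  m$atoms$partial_charge <- 0
  m
}

# Dihedral angle (degrees) between atoms i-j-k-l.
dihedral_deg <- function(mol, i, j, k, l) {
  x <- as.matrix(mol$atoms[, c("x", "y", "z")])
  b1 <- x[j, ] - x[i, ]; b2 <- x[k, ] - x[j, ]; b3 <- x[l, ] - x[k, ]
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  atan2(sum(cr(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
}

# A tiny single-template sidechain set for growth tests.
singleton_set <- function(name = "methyl", smiles = "*C") {
  tpl <- data.frame(name = name, smiles = smiles, linker = "direct",
                    scaffold_id = 1L, variant_id = 1L,
                    canonical = smiles, stringsAsFactors = FALSE)
  tpl$generation_order <- 1L
  structure(list(set_id = "custom", templates = tpl), class = "sidechain_set")
}
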