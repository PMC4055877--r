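#' @useDynLib fraggrow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Covalent radii (Angstrom), Cordero et al. consensus values.
.COV_RADII <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07, S = 1.05,
  Cl = 1.02, Br = 1.20, I = 1.39, "*" = 0.76
)

# van der Waals radii (Angstrom), Bondi.
.VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  Cl = 1.75, Br = 1.85, I = 1.98, "*" = 1.20
)

# Elements the Gasteiger (PEOE) parameterization covers.
.GASTEIGER_ELEMENTS <- c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "*")

covalent_radius <- function(element) {
  r <- .COV_RADII[element]
  r[is.na(r)] <- 1.0
  unname(r)
}

vdw_radius <- function(element) {
  r <- .VDW_RADII[element]
  r[is.na(r)] <- 1.7
  unname(r)
}

#' Construct a molecule object
#'
#' A `molecule` is the package's light-weight container for a small molecule
#' or a receptor: an atom table (element, Cartesian coordinates in Angstrom,
#' formal and partial charges) and a bond table (1-based atom indices and
#' integer bond order). Atom indices are stable and 1-based; site labels in
#' reports use the same numbering.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `formal_charge`, `partial_charge`.
#' @param bonds data.frame with columns `from`, `to`, `order` (may have zero
#'   rows, e.g. for receptors where connectivity is not needed).
#' @param name molecule name.
#' @param provenance free-form list recording source file, format and any
#'   embedding seed.
#' @return an object of class `molecule`.
#' @export
molecule <- function(atoms, bonds = NULL, name = "", provenance = list()) {
  stopifnot(is.data.frame(atoms), all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(bonds)) {
    bonds <- data.frame(from = integer(), to = integer(), order = integer())
  }
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- rep(0L, nrow(atoms))
  if (is.null(atoms$partial_charge)) atoms$partial_charge <- rep(NA_real_, nrow(atoms))
  atoms <- atoms[, c("element", "x", "y", "z", "formal_charge", "partial_charge")]
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("molecule: non-finite coordinates")
  n <- nrow(atoms)
  if (nrow(bonds) > 0) {
    if (any(bonds$from < 1 | bonds$from > n | bonds$to < 1 | bonds$to > n)) {
      stop("molecule: bond indices out of range")
    }
  }
  structure(
    list(atoms = atoms, bonds = bonds, name = name, provenance = provenance),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf(
    "<molecule> %s: %d atoms (%d heavy), %d bonds\n",
    if (nzchar(x$name)) x$name else "(unnamed)",
    nrow(x$atoms), sum(x$atoms$element != "H"), nrow(x$bonds)
  ))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `molecule`.
#' @return integer count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Number of heavy (non-hydrogen, non-dummy) atoms
#' @param mol a `molecule`.
#' @return integer count.
#' @export
n_heavy_atoms <- function(mol) sum(!mol$atoms$element %in% c("H", "*"))

coords_matrix <- function(mol) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

set_coords <- function(mol, xyz) {
  mol$atoms$x <- xyz[, 1]
  mol$atoms$y <- xyz[, 2]
  mol$atoms$z <- xyz[, 3]
  mol
}

# Adjacency list (list of integer vectors, 1-based).
adjacency <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

neighbors_of <- function(mol, i) {
  b <- mol$bonds
  c(b$to[b$from == i], b$from[b$to == i])
}

bond_order_between <- function(mol, i, j) {
  b <- mol$bonds
  hit <- (b$from == i & b$to == j) | (b$from == j & b$to == i)
  if (!any(hit)) return(0L)
  b$order[which(hit)[1]]
}

# Is the molecule a single connected component? (Isolated molecules only;
# receptors skip this check.)
is_connected <- function(mol) {
  n <- n_atoms(mol)
  if (n <= 1) return(TRUE)
  adj <- adjacency(mol)
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (j in adj[[i]]) if (!seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
  }
  all(seen)
}

# A bond is in a ring iff its endpoints stay connected after removing it.
bond_in_ring <- function(mol, from, to) {
  b <- mol$bonds
  keep <- !((b$from == from & b$to == to) | (b$from == to & b$to == from))
  sub <- b[keep, , drop = FALSE]
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(sub))) {
    i <- sub$from[k]; j <- sub$to[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n); queue <- from; seen[from] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    if (i == to) return(TRUE)
    for (j in adj[[i]]) if (!seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
  }
  FALSE
}

# Hybridization by bond orders: "sp" (triple bond or two doubles),
# "sp2" (any double bond), else "sp3". Hydrogens get "s".
hybridization <- function(mol) {
  n <- n_atoms(mol)
  ndouble <- integer(n); ntriple <- integer(n)
  for (k in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[k]
    ij <- c(mol$bonds$from[k], mol$bonds$to[k])
    if (o == 2) ndouble[ij] <- ndouble[ij] + 1L
    if (o == 3) ntriple[ij] <- ntriple[ij] + 1L
  }
  out <- rep("sp3", n)
  out[ndouble >= 1] <- "sp2"
  out[ntriple >= 1 | ndouble >= 2] <- "sp"
  out[mol$atoms$element == "H"] <- "s"
  out
}

#' Count aromatic rings of a hydrocarbon
#'
#' Number of independent rings among sp2 carbons: for kekulized
#' hydrocarbons this equals the number of aromatic (benzenoid) rings.
#' Counted as the cyclomatic number of the subgraph induced on sp2 carbon
#' atoms.
#'
#' @param mol a `molecule`.
#' @return integer ring count.
#' @export
count_aromatic_rings <- function(mol) {
  hyb <- hybridization(mol)
  keep <- which(mol$atoms$element == "C" & hyb == "sp2")
  if (length(keep) < 6) return(0L)
  inset <- logical(n_atoms(mol)); inset[keep] <- TRUE
  b <- mol$bonds
  sel <- inset[b$from] & inset[b$to]
  n_edges <- sum(sel)
  # connected components of the induced subgraph
  idx <- match(seq_len(n_atoms(mol)), keep)
  adj <- vector("list", length(keep))
  for (k in which(sel)) {
    i <- idx[b$from[k]]; j <- idx[b$to[k]]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(length(keep)); ncomp <- 0L
  for (s in seq_along(keep)) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (j in adj[[i]]) if (!seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
    }
  }
  max(0L, n_edges - length(keep) + ncomp)
}

# Deterministic unit vector helpers -----------------------------------------

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

# Rodrigues rotation matrix about `axis` by `angle` (radians).
rotation_about_axis <- function(axis, angle) {
  a <- unit(axis)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Rotation matrix taking unit vector u onto unit vector v.
rotation_between <- function(u, v) {
  u <- unit(u); v <- unit(v)
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # pick any perpendicular axis
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unit(cross3(u, ref))
    return(rotation_about_axis(axis, pi))
  }
  axis <- cross3(u, v)
  s <- vnorm(axis)
  rotation_about_axis(axis, atan2(s, c_))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
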