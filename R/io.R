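# Molecule I/O: SDF (V2000) via ChemmineR, SMILES/MOL2 via OpenBabel
# (ChemmineOB), PDB via bio3d.

# SDF atom-block charge codes (ctab): 1..7 -> +3..-3, 0/4 -> 0.
.SDF_CHARGE_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                      `5` = -1L, `6` = -2L, `7` = -3L)

ob_options <- function(...) {
  nm <- c(...)
  data.frame(names = nm, args = rep("", length(nm)), stringsAsFactors = FALSE)
}

# One parsed SDF record text -> molecule. Formal charges from M CHG lines
# (authoritative) falling back to atom-block charge codes.
sdf_record_to_molecule <- function(sdf, record_text, name = NULL,
                                   provenance = list()) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_\\d+$", "", rownames(ab))
  n <- nrow(ab)
  fc <- .SDF_CHARGE_CODE[as.character(ab[, "C5"])]
  fc[is.na(fc)] <- 0L
  chg_lines <- grep("^M  CHG", record_text, value = TRUE)
  if (length(chg_lines)) {
    fc <- rep(0L, n)
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
      npairs <- f[1]
      for (p in seq_len(npairs)) {
        fc[f[2 * p]] <- f[2 * p + 1]
      }
    }
  }
  atoms <- data.frame(
    element = element,
    x = unname(ab[, "C1"]), y = unname(ab[, "C2"]), z = unname(ab[, "C3"]),
    formal_charge = as.integer(fc),
    partial_charge = NA_real_,
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(
    from = as.integer(bb[, "C1"]),
    to = as.integer(bb[, "C2"]),
    order = as.integer(bb[, "C3"])
  )
  if (is.null(name)) name <- ChemmineR::sdfid(sdf)
  if (is.na(name) || !nzchar(name)) name <- ""
  molecule(atoms, bonds, name = name, provenance = provenance)
}

split_sdf_records <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, head(ends, -1) + 1L)
  mapply(function(s, e) lines[s:e], starts, ends, SIMPLIFY = FALSE)
}

read_sdf_text <- function(lines, source = "<text>") {
  lines <- lines[!is.na(lines)]
  recs <- split_sdf_records(lines)
  recs <- recs[vapply(recs, function(r) any(grepl("V2000", r)), logical(1))]
  if (!length(recs)) stop("SDF parse error in ", source, ": no V2000 records found")
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    sdfset <- tryCatch(
      ChemmineR::read.SDFset(ChemmineR::read.SDFstr(recs[[i]])),
      error = function(e) stop("SDF parse error in ", source, ", record ", i,
                               ": ", conditionMessage(e))
    )
    title <- trimws(recs[[i]][1])
    out[[i]] <- sdf_record_to_molecule(
      sdfset[[1]], recs[[i]],
      name = if (nzchar(title)) title else sprintf("mol_%d", i),
      provenance = list(source = source, format = "SDF", record = i)
    )
  }
  out
}

# molecule -> SDF (V2000) record text (character vector of lines).
molecule_to_sdf_text <- function(mol) {
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  lines <- c(
    if (nzchar(mol$name)) mol$name else "unnamed",
    "  fraggrow",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  )
  at <- mol$atoms
  lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                            at$x, at$y, at$z, at$element))
  if (nb > 0) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              mol$bonds$from, mol$bonds$to, mol$bonds$order))
  }
  chg <- which(at$formal_charge != 0)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0(
        sprintf("M  CHG%3d", length(grp)),
        paste0(sprintf("%4d%4d", grp, at$formal_charge[grp]), collapse = "")
      ))
    }
  }
  c(lines, "M  END", "$$$$")
}

#' Write molecules to an SDF file
#'
#' @param mols a `molecule` or list of molecules.
#' @param path output file path.
#' @param tags optional named list (or list of named lists, one per molecule)
#'   of SD data tags to append to each record.
#' @return `path`, invisibly.
#' @export
write_molecules_sdf <- function(mols, path, tags = NULL) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  all_lines <- character()
  for (i in seq_along(mols)) {
    rec <- molecule_to_sdf_text(mols[[i]])
    if (!is.null(tags)) {
      tg <- if (is.null(names(tags))) tags[[i]] else tags
      tag_lines <- unlist(lapply(names(tg), function(k) {
        c(sprintf("> <%s>", k), as.character(tg[[k]]), "")
      }))
      rec <- c(rec[-length(rec)], tag_lines, "$$$$")
    }
    all_lines <- c(all_lines, rec)
  }
  writeLines(all_lines, path)
  invisible(path)
}

# Canonical SMILES (OpenBabel), dummy atoms allowed.
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- ChemmineOB::convertFormat("SMILES", "CAN", s)
    out <- strsplit(out, "[\t\n ]")[[1]][1]
    if (is.na(out) || !nzchar(out)) stop("SMILES parse failure: '", s, "'")
    out
  }, character(1), USE.NAMES = FALSE)
}

# SMILES -> molecule graph with explicit hydrogens and a deterministic
# initial embedding: OpenBabel 2D layout lifted with a seed-derived
# out-of-plane jitter. Callers refine with minimize_molecule().
smiles_to_molecule_raw <- function(smiles, name = smiles, seed = 1L) {
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMILES", "SDF", smiles,
                              options = ob_options("gen2D", "h")),
    error = function(e) stop("SMILES parse failure: '", smiles, "': ",
                             conditionMessage(e))
  )
  if (!nzchar(txt) || !grepl("V2000", txt)) {
    stop("SMILES parse failure: '", smiles, "'")
  }
  mol <- read_sdf_text(strsplit(txt, "\n")[[1]], source = smiles)[[1]]
  mol$name <- name
  mol$provenance <- list(source = smiles, format = "SMILES", embed_seed = seed)
  xyz <- coords_matrix(mol)
  # deterministic jitter lifts the planar layout so minimization can reach
  # tetrahedral geometry
  k <- seq_len(nrow(xyz))
  xyz[, 3] <- xyz[, 3] + 0.25 * sin(k * 2.399963 + seed) # golden-angle phase
  xyz[, 1] <- xyz[, 1] + 0.05 * sin(k * 1.324718 + 2 * seed)
  set_coords(mol, xyz)
}

#' Load a molecule (or molecules) from file or SMILES
#'
#' Reads SDF (V2000), MOL2 (SYBYL), PDB, or a SMILES string. SMILES inputs
#' get explicit hydrogens and a deterministic 3D embedding (2D layout +
#' seeded out-of-plane displacement + force-field minimization); the seed is
#' recorded in the provenance. For multi-record SDF files a list of
#' molecules is returned; otherwise a single `molecule`.
#'
#' @param path file path, or the SMILES string itself for `format = "SMILES"`.
#' @param format one of "SDF", "MOL2", "PDB", "SMILES". Guessed from the file
#'   extension when `NULL`.
#' @param embed_seed integer seed for the deterministic SMILES embedding.
#' @param minimize logical; minimize SMILES-derived coordinates (default TRUE).
#' @return a `molecule`, or a list of molecules for multi-record SDF input.
#' @export
load_molecule <- function(path, format = NULL, embed_seed = 1L, minimize = TRUE) {
  if (is.null(format)) {
    ext <- toupper(tools::file_ext(path))
    format <- switch(ext, SDF = "SDF", MOL = "SDF", MOL2 = "MOL2", PDB = "PDB",
                     SMI = "SMILES", SMILES = "SMILES",
                     stop("cannot guess format from extension: ", path))
  }
  format <- toupper(format)
  if (format == "SMILES") {
    smi <- if (file.exists(path)) trimws(readLines(path)[1]) else path
    smi_str <- strsplit(smi, "\\s+")[[1]]
    mol <- smiles_to_molecule_raw(smi_str[1],
                                  name = if (length(smi_str) > 1) smi_str[2] else smi_str[1],
                                  seed = embed_seed)
    if (minimize && n_atoms(mol) > 1) {
      mol <- minimize_molecule(mol, minimization_config(max_iterations = 300L))
    }
    return(mol)
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "SDF") {
    mols <- read_sdf_text(readLines(path), source = path)
    if (length(mols) == 1) return(mols[[1]])
    return(mols)
  }
  if (format == "MOL2") {
    txt <- ChemmineOB::convertFormatFile("MOL2", "SDF", path, tempf <- tempfile(fileext = ".sdf"))
    mols <- read_sdf_text(readLines(tempf), source = path)
    unlink(tempf)
    if (length(mols) == 1) return(mols[[1]])
    return(mols)
  }
  if (format == "PDB") {
    return(read_pdb_molecule(path))
  }
  stop("unsupported format: ", format)
}

# PDB -> molecule: first model only, altloc A (or blank) wins, ATOM+HETATM.
read_pdb_molecule <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  keep <- at$alt %in% c(NA, "", "A")
  at <- at[keep, , drop = FALSE]
  elem <- at$elesy
  missing_el <- is.na(elem) | !nzchar(trimws(elem))
  if (any(missing_el)) {
    elem[missing_el] <- substr(trimws(at$elety[missing_el]), 1, 1)
  }
  elem <- trimws(elem)
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, 2)))
  atoms <- data.frame(
    element = elem, x = at$x, y = at$y, z = at$z,
    formal_charge = 0L, partial_charge = NA_real_,
    stringsAsFactors = FALSE
  )
  mol <- molecule(atoms, NULL, name = basename(path),
                  provenance = list(source = path, format = "PDB"))
  mol$pdb_meta <- data.frame(
    type = at$type, resid = at$resid, chain = at$chain, resno = at$resno,
    elety = at$elety, stringsAsFactors = FALSE
  )
  mol
}
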