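# Side-chain template sets A, B and C.
#
# Templates are small hydrocarbons (no heteroatoms, at most two aromatic
# rings) with exactly one attachment point, written as SMILES with a leading
# dummy atom "*". Three nested sets are shipped: set C (25 templates),
# set B (38) and set A (78), with C within B within A. Every set contains
# the direct-attachment derivatives of nine base scaffolds; aromatic
# scaffolds (ids 8 and 9) additionally spawn linker variants: -CH2-,
# -CH2-CH2-, and (set A only) trans -CH=CH-.

.LINKERS_BY_SET <- list(
  A = c("CH2", "CH2CH2", "CHeqCH"),
  B = c("CH2", "CH2CH2"),
  C = c("CH2")
)

.TIERS_BY_SET <- list(A = c("C", "B", "A"), B = c("C", "B"), C = "C")

.EXPECTED_SET_SIZE <- c(A = 78L, B = 38L, C = 25L)

.LINKER_SCAFFOLDS <- 8:9

linker_smiles <- function(smiles, linker) {
  if (!startsWith(smiles, "*")) {
    stop("library error: template SMILES must start with the attachment dummy '*'")
  }
  switch(linker,
    direct = smiles,
    CH2 = sub("^\\*", "*C", smiles),
    CH2CH2 = sub("^\\*", "*CC", smiles),
    CHeqCH = sub("^\\*", "*/C=C/", smiles), # trans (E) geometry
    stop("library error: unknown linker '", linker, "'")
  )
}

default_scaffold_file <- function() {
  system.file("extdata", "sidechains", "scaffolds.tsv", package = "fraggrow",
              mustWork = TRUE)
}

read_scaffold_table <- function(scaffold_file) {
  # comment.char must stay disabled: '#' is the SMILES triple-bond symbol
  sc <- utils::read.delim(scaffold_file, stringsAsFactors = FALSE,
                          comment.char = "")
  need <- c("scaffold_id", "variant_id", "name", "smiles", "set")
  if (!all(need %in% names(sc))) {
    stop("scaffold config error: file must have columns ",
         paste(need, collapse = ", "))
  }
  if (!all(sc$scaffold_id %in% 1:9)) {
    stop("scaffold config error: scaffold_id must be in 1..9")
  }
  n_star <- vapply(gregexpr("\\*", sc$smiles),
                   function(m) sum(m > 0), numeric(1))
  if (any(n_star != 1)) {
    stop("scaffold config error: each marked position needs exactly one '*' (",
         paste(sc$name[n_star != 1], collapse = ", "), ")")
  }
  missing_sc <- setdiff(1:9, unique(sc$scaffold_id))
  if (length(missing_sc)) {
    stop("scaffold config error: scaffolds without marked positions: ",
         paste(missing_sc, collapse = ", "))
  }
  if (!all(sc$set %in% c("A", "B", "C"))) {
    stop("scaffold config error: 'set' column must be A, B or C")
  }
  sc
}

#' Validate a side-chain template
#'
#' Enforces the template invariants: hydrocarbon only (C/H), exactly one
#' attachment dummy `*`, and at most two aromatic rings.
#'
#' @param smiles template SMILES with a `*` attachment point.
#' @param name label used in error messages.
#' @return the parsed template `molecule`, invisibly; errors on violation.
#' @export
validate_template <- function(smiles, name = smiles) {
  mol <- smiles_to_molecule_raw(smiles, name = name)
  el <- mol$atoms$element
  if (sum(el == "*") != 1) {
    stop("library integrity error: template '", name,
         "' must contain exactly one attachment dummy")
  }
  het <- setdiff(unique(el), c("C", "H", "*"))
  if (length(het)) {
    stop("library integrity error: template '", name,
         "' contains heteroatoms (", paste(het, collapse = ", "),
         "); side chains must be hydrocarbons")
  }
  nar <- count_aromatic_rings(mol)
  if (nar > 2) {
    stop("library integrity error: template '", name, "' has ", nar,
         " aromatic rings (at most two allowed)")
  }
  invisible(mol)
}

new_sidechain_set <- function(set_id, templates) {
  templates$generation_order <- seq_len(nrow(templates))
  structure(list(set_id = set_id, templates = templates),
            class = "sidechain_set")
}

#' @export
print.sidechain_set <- function(x, ...) {
  cat(sprintf("<sidechain_set %s> %d hydrocarbon templates (%d with linkers)\n",
              x$set_id, nrow(x$templates), sum(x$templates$linker != "direct")))
  invisible(x)
}

#' @export
length.sidechain_set <- function(x) nrow(x$templates)

#' Build a side-chain set from a scaffold table
#'
#' Applies the set construction rules to a scaffold file: every marked R
#' position of scaffolds 1-9 yields a direct-attachment template; marked
#' positions on the aromatic scaffolds 8-9 additionally yield linker
#' variants (-CH2-R and -CH2-CH2-R; set A also trans -CH=CH-R). The scaffold
#' table's `set` column records the smallest set each derivative belongs to
#' (the three sets list nested derivative collections, C within B within A).
#' Duplicates are removed by canonical SMILES.
#'
#' @param set_id "A", "B" or "C".
#' @param scaffold_file TSV with columns scaffold_id, variant_id, name,
#'   smiles (leading `*` attachment), set. Defaults to the shipped curated
#'   table, for which the construction yields exactly 78/38/25 templates.
#' @param check_cardinality verify the shipped 78/38/25 counts (default: on
#'   for the shipped file, off for user files).
#' @return a `sidechain_set`.
#' @export
build_set <- function(set_id = c("A", "B", "C"), scaffold_file = NULL,
                      check_cardinality = is.null(scaffold_file)) {
  set_id <- match.arg(set_id)
  if (is.null(scaffold_file)) scaffold_file <- default_scaffold_file()
  sc <- read_scaffold_table(scaffold_file)
  sc <- sc[sc$set %in% .TIERS_BY_SET[[set_id]], , drop = FALSE]

  rows <- list()
  for (r in seq_len(nrow(sc))) {
    rec <- sc[r, ]
    rows[[length(rows) + 1]] <- data.frame(
      name = rec$name, smiles = rec$smiles, linker = "direct",
      scaffold_id = rec$scaffold_id, variant_id = rec$variant_id,
      stringsAsFactors = FALSE
    )
    if (rec$scaffold_id %in% .LINKER_SCAFFOLDS) {
      for (lk in .LINKERS_BY_SET[[set_id]]) {
        rows[[length(rows) + 1]] <- data.frame(
          name = paste0(rec$name, "-", lk), smiles = linker_smiles(rec$smiles, lk),
          linker = lk, scaffold_id = rec$scaffold_id, variant_id = rec$variant_id,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  tpl <- do.call(rbind, rows)
  tpl$canonical <- canonical_smiles(tpl$smiles)
  tpl <- tpl[!duplicated(tpl$canonical), , drop = FALSE]
  rownames(tpl) <- NULL
  for (r in seq_len(nrow(tpl))) validate_template(tpl$smiles[r], tpl$name[r])

  if (isTRUE(check_cardinality) && nrow(tpl) != .EXPECTED_SET_SIZE[[set_id]]) {
    stop(sprintf(
      "library integrity error: set %s has %d templates, expected %d; members: %s",
      set_id, nrow(tpl), .EXPECTED_SET_SIZE[[set_id]],
      paste(tpl$name, collapse = ", ")
    ))
  }
  new_sidechain_set(set_id, tpl)
}

#' Save a side-chain set to a TSV library file
#'
#' @param set a `sidechain_set`.
#' @param path output path; SMILES-with-attachment dialect, one template per
#'   line with name/linker/scaffold metadata columns.
#' @return `path`, invisibly.
#' @export
save_library <- function(set, path) {
  stopifnot(inherits(set, "sidechain_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fraggrow side-chain library, set %s", set$set_id), con)
  utils::write.table(
    set$templates[, c("smiles", "name", "linker", "scaffold_id", "variant_id")],
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Load a side-chain set from a TSV library file
#'
#' @param path library file written by [save_library()] or hand-curated in
#'   the same dialect (tab-separated columns smiles, name, linker,
#'   scaffold_id, variant_id).
#' @return a `sidechain_set`.
#' @export
load_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path)
  first <- readLines(path, n = 1)
  set_id <- if (grepl("set [ABC]$", first)) sub(".*set ", "", first) else "custom"
  raw <- readLines(path)
  raw <- raw[!grepl("^#", raw) & nzchar(trimws(raw))]
  nfield <- lengths(strsplit(raw, "\t| +"))
  if (any(nfield != 5)) {
    stop("library parse error: expected 5 columns per line, got ",
         paste(unique(nfield[nfield != 5]), collapse = "/"),
         " on line(s) ", paste(which(nfield != 5), collapse = ", "))
  }
  tpl <- utils::read.table(text = raw, header = TRUE, sep = "",
                           stringsAsFactors = FALSE, comment.char = "")
  need <- c("smiles", "name", "linker", "scaffold_id", "variant_id")
  if (!identical(sort(names(tpl)), sort(need))) {
    stop("library parse error: columns must be ", paste(need, collapse = ", "))
  }
  tpl <- tpl[, need]
  tpl$canonical <- canonical_smiles(tpl$smiles)
  if (anyDuplicated(tpl$canonical)) {
    warning("library integrity warning: duplicate canonical forms on load (",
            paste(tpl$name[duplicated(tpl$canonical)], collapse = ", "), ")")
    tpl <- tpl[!duplicated(tpl$canonical), , drop = FALSE]
  }
  for (r in seq_len(nrow(tpl))) validate_template(tpl$smiles[r], tpl$name[r])
  rownames(tpl) <- NULL
  new_sidechain_set(set_id, tpl)
}

#' Canonical SMILES of all templates of a set (sorted)
#' @param set a `sidechain_set`.
#' @return character vector of canonical forms.
#' @export
sidechain_canonical_forms <- function(set) sort(set$templates$canonical)

#' Is one side-chain set contained in another (by canonical form)?
#' @param inner,outer `sidechain_set`s.
#' @return logical.
#' @export
is_subset_of <- function(inner, outer) {
  all(inner$templates$canonical %in% outer$templates$canonical)
}
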