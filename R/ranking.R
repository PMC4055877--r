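# Ranking of docked compounds, active-position prediction, ensemble
# merging, and true-lead spiking.

#' Rank docked compounds by score
#'
#' Sorts ascending by score (lower = better affinity) with deterministic,
#' stable tie-breaking by generation index, and assigns ordinal ranks 1..N.
#' Compounds with `NA` scores (no valid pose) are placed after all scored
#' compounds.
#'
#' @param results data.frame from [dock_library()] /
#'   [import_external_scores()], or a list of `dock_result`s.
#' @param target_name optional label carried into the table.
#' @return a `rank_table` (data.frame with `rank`, `generation_index`,
#'   `site_label`, `template_name`, `score`, `receptor_ref`).
#' @export
rank_compounds <- function(results, target_name = "") {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, function(r) data.frame(
      generation_index = r$compound_ref, site_label = r$site_label,
      template_name = r$template_name, score = r$score,
      receptor_ref = r$receptor_ref, stringsAsFactors = FALSE
    )))
  }
  if (nrow(results) == 0) stop("input error: no docking results to rank")
  if (any(is.nan(results$score))) {
    stop("input error: NaN docking score for generation_index ",
         paste(results$generation_index[is.nan(results$score)], collapse = ", "))
  }
  ord <- order(results$score, results$generation_index, na.last = TRUE)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("rank", "generation_index", "site_label", "template_name",
                 "score", "receptor_ref")]
  attr(out, "target_name") <- target_name
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Predict the top-k active positions
#'
#' Walks the rank table from the top, collecting distinct modified site
#' labels until `k` are found. With `k = 1` this is the headline
#' prediction: the modified position of the single best-scoring virtual
#' compound. `k = 2` adds the second-best distinct position.
#'
#' @param table a `rank_table`.
#' @param k number of distinct positions to return.
#' @return character vector of site labels in first-appearance order.
#' @export
predict_active_position <- function(table, k = 1L) {
  stopifnot(k >= 1)
  sites <- unique(table$site_label[order(table$rank)])
  if (length(sites) < k) {
    warning("only ", length(sites), " distinct sites in table (k = ", k, ")")
    return(sites)
  }
  sites[seq_len(k)]
}

#' Merge rank tables from an ensemble of receptor structures
#'
#' Concatenates all (compound, receptor, score) rows from per-structure
#' rank tables of the same compound library and re-ranks globally by score.
#'
#' @param tables list of `rank_table`s over the same library.
#' @return a merged `rank_table`.
#' @export
merge_ensemble <- function(tables) {
  stopifnot(length(tables) >= 1)
  ids <- lapply(tables, function(t) sort(t$generation_index))
  for (i in seq_along(ids)[-1]) {
    if (!identical(ids[[1]], ids[[i]])) {
      d1 <- setdiff(ids[[1]], ids[[i]]); d2 <- setdiff(ids[[i]], ids[[1]])
      stop("input error: inconsistent libraries across tables (missing: ",
           paste(d1, collapse = ","), "; extra: ", paste(d2, collapse = ","), ")")
    }
  }
  all_rows <- do.call(rbind, lapply(tables, function(t) {
    t$rank <- NULL
    as.data.frame(t)
  }))
  rank_compounds(all_rows,
                 target_name = attr(tables[[1]], "target_name"))
}

#' Rank of the first compound modified at a true active position
#'
#' @param table a `rank_table`.
#' @param active_sites nonempty character vector of true active site labels.
#' @return the smallest rank whose site label is active; if no ranked
#'   compound touches an active site, `nrow(table) + 1` with attribute
#'   `not_found = TRUE`.
#' @export
active_position_rank <- function(table, active_sites) {
  stopifnot(length(active_sites) >= 1)
  hit <- which(table$site_label %in% active_sites)
  if (!length(hit)) {
    return(structure(nrow(table) + 1L, not_found = TRUE))
  }
  min(table$rank[hit])
}

#' Spike true lead compounds into a virtual library
#'
#' Appends prepared lead molecules to the library as tagged members so the
#' ordinary ranking machinery measures where the known leads land.
#'
#' @param library a `virtual_library`.
#' @param leads nonempty list of prepared `molecule`s (protonation/charges
#'   as for library members).
#' @return a `virtual_library` whose compounds carry an `is_lead` flag;
#'   leads get fresh generation indices after the library.
#' @export
spike_true_leads <- function(library, leads) {
  stopifnot(inherits(library, "virtual_library"))
  if (length(leads) == 0) stop("precondition error: no lead compounds given")
  lib_canon <- vapply(library$compounds, function(vc) {
    paste(sort(vc$molecule$atoms$element), collapse = "")
  }, character(1))
  gen <- length(library$compounds)
  for (vc in library$compounds) vc$is_lead <- FALSE
  library$compounds <- lapply(library$compounds, function(vc) {
    vc$is_lead <- FALSE; vc
  })
  for (ld in leads) {
    key <- paste(sort(ld$atoms$element), collapse = "")
    if (key %in% lib_canon) {
      warning("lead '", ld$name, "' duplicates a library member (kept)")
    }
    gen <- gen + 1L
    library$compounds[[gen]] <- structure(list(
      molecule = ld, seed_name = library$seed_name,
      site = NULL, site_label = "lead",
      template_name = ld$name, generation_index = gen, is_lead = TRUE
    ), class = "virtual_compound")
  }
  library
}

#' Best rank achieved by any spiked lead
#'
#' @param table a `rank_table` over a lead-spiked library.
#' @param lead_indices generation indices of the leads.
#' @return smallest rank of any lead.
#' @export
best_lead_rank <- function(table, lead_indices) {
  stopifnot(length(lead_indices) >= 1)
  min(table$rank[table$generation_index %in% lead_indices])
}
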