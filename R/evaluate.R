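# Evaluation statistics over target records: success rates, random
# baselines, lead-spiking summaries, and report generation. The package
# ships record tables transcribed from a published benchmark of 15
# fragment-evolution case studies (plus 6 multi-structure ensembles and a
# 15-target lead-spiking experiment).

#' Load the embedded benchmark record tables
#'
#' Returns three record tables: `single` (one row per target: number of
#' replaceable H/F sites of the seed, number of true active positions, and
#' per side-chain set the library size and the rank of the first virtual
#' compound modified at a true active position), `ensemble` (per target the
#' merged multi-structure rank), and `lead_spiking` (library size, number
#' of spiked true leads, best lead rank).
#'
#' @param dir directory with the three CSVs (defaults to the shipped copies).
#' @return list with data.frames `single`, `ensemble`, `lead_spiking`.
#' @export
load_benchmark_tables <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- system.file("extdata", "benchmark", package = "fraggrow",
                       mustWork = TRUE)
  }
  single <- utils::read.csv(file.path(dir, "single_structure.csv"),
                            stringsAsFactors = FALSE)
  ensemble <- utils::read.csv(file.path(dir, "ensemble.csv"),
                              stringsAsFactors = FALSE)
  lead <- utils::read.csv(file.path(dir, "lead_spiking.csv"),
                          stringsAsFactors = FALSE)
  # integrity manifest: record counts and marginal sums are fixed properties
  # of the transcribed benchmark
  if (nrow(single) != 15 || nrow(ensemble) != 6 || nrow(lead) != 15) {
    stop("fixture-integrity error: expected 15/6/15 records, found ",
         nrow(single), "/", nrow(ensemble), "/", nrow(lead))
  }
  if (sum(single$n_sites) != 171 || sum(single$n_active) != 45) {
    stop("fixture-integrity error: single-structure site/active sums ",
         sum(single$n_sites), "/", sum(single$n_active),
         " differ from the manifest (171/45)")
  }
  if (any(single$n_active < 1) || any(single$n_active > single$n_sites)) {
    stop("fixture-integrity error: active counts out of range")
  }
  if (any(lead$n_true_leads < 1) || any(lead$n_true_leads >= lead$n_compounds) ||
      any(lead$best_lead_rank > lead$n_compounds)) {
    stop("fixture-integrity error: lead-spiking records out of range")
  }
  list(single = single, ensemble = ensemble, lead_spiking = lead)
}

rank_column <- function(records, set_id) {
  col <- paste0("rank_", set_id)
  if (!col %in% names(records)) {
    stop("input error: unknown side-chain set '", set_id, "'")
  }
  records[[col]]
}

#' Fraction of targets whose active position is predicted in the top k
#'
#' For `k = 1`, the fraction of targets where the single best-ranked
#' virtual compound is modified at a true active position (rank = 1); for
#' `k = 2`, where that rank is at most 2.
#'
#' @param records single-structure record table (see
#'   [load_benchmark_tables()]).
#' @param set_id side-chain set: "A", "B" or "C".
#' @param k 1 or 2.
#' @return fraction in [0, 1].
#' @export
success_rate <- function(records, set_id, k = 1L) {
  stopifnot(nrow(records) >= 1, k %in% c(1L, 2L))
  r <- rank_column(records, set_id)
  mean(r <= k)
}

#' Random-prediction baseline for active-position discovery
#'
#' Pools counts over targets: p = sum(active positions) / sum(H/F sites).
#' For `k = 1` returns p; for `k = 2` the probability that at least one of
#' two independent draws hits an active position, 1 - (1 - p)^2.
#'
#' @param records single-structure record table.
#' @param k 1 or 2.
#' @return probability in [0, 1].
#' @export
random_baseline <- function(records, k = 1L) {
  stopifnot(k %in% c(1L, 2L))
  total_sites <- sum(records$n_sites)
  if (total_sites == 0) stop("undefined: no replaceable sites in records")
  p <- sum(records$n_active) / total_sites
  if (k == 1L) p else 1 - (1 - p)^2
}

#' Random-selection baseline for the lead-spiking experiment
#'
#' Mean over targets of (number of true leads) / (library size including
#' leads): the chance that a uniformly random pick is a true lead.
#'
#' @param records lead-spiking record table.
#' @return probability in [0, 1].
#' @export
lead_baseline <- function(records) {
  stopifnot(nrow(records) >= 1)
  mean(records$n_true_leads / records$n_compounds)
}

#' Fraction of lead-spiking targets where a true lead ranks first
#'
#' @param records lead-spiking record table.
#' @return fraction in [0, 1].
#' @export
lead_rank1_rate <- function(records) {
  stopifnot(nrow(records) >= 1)
  mean(records$best_lead_rank == 1)
}

#' Fraction of ensemble targets with merged rank 1
#'
#' @param records ensemble record table.
#' @return fraction in [0, 1].
#' @export
ensemble_rank1_rate <- function(records) {
  stopifnot(nrow(records) >= 1)
  mean(records$rank == 1)
}

#' Write the evaluation report
#'
#' Emits per-target CSVs plus a Markdown summary with the headline
#' statistics: top-1/top-2 success rates per side-chain set, the pooled
#' random baselines, the ensemble rank-1 rate, and the lead-spiking rates.
#'
#' @param tables list as returned by [load_benchmark_tables()].
#' @param dir output directory (created if needed).
#' @return invisible list of the computed summary statistics (fractions).
#' @export
write_evaluation_report <- function(tables, dir) {
  if (is.null(tables$single) || nrow(tables$single) == 0) {
    stop("input error: empty record list")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tables$single, file.path(dir, "single_structure.csv"),
                   row.names = FALSE)
  utils::write.csv(tables$ensemble, file.path(dir, "ensemble.csv"),
                   row.names = FALSE)
  utils::write.csv(tables$lead_spiking, file.path(dir, "lead_spiking.csv"),
                   row.names = FALSE)
  stats <- list(
    random_baseline_top1 = random_baseline(tables$single, 1L),
    random_baseline_top2 = random_baseline(tables$single, 2L),
    success_top1 = vapply(c(A = "A", B = "B", C = "C"),
                          function(s) success_rate(tables$single, s, 1L), numeric(1)),
    success_top2 = vapply(c(A = "A", B = "B", C = "C"),
                          function(s) success_rate(tables$single, s, 2L), numeric(1)),
    ensemble_rank1 = ensemble_rank1_rate(tables$ensemble),
    lead_rank1 = lead_rank1_rate(tables$lead_spiking),
    lead_random = lead_baseline(tables$lead_spiking)
  )
  pct <- function(x) sprintf("%.2f%%", 100 * x)
  md <- c(
    "# Active-position prediction evaluation",
    "",
    sprintf("- Targets: %d (single structure), %d (ensembles), %d (lead spiking)",
            nrow(tables$single), nrow(tables$ensemble), nrow(tables$lead_spiking)),
    sprintf("- Random baseline (top-1, pooled sites): %s", pct(stats$random_baseline_top1)),
    sprintf("- Random baseline (top-2): %s", pct(stats$random_baseline_top2)),
    sprintf("- Top-1 success: set A %s, set B %s, set C %s",
            pct(stats$success_top1["A"]), pct(stats$success_top1["B"]),
            pct(stats$success_top1["C"])),
    sprintf("- Top-2 success: set A %s, set B %s, set C %s",
            pct(stats$success_top2["A"]), pct(stats$success_top2["B"]),
            pct(stats$success_top2["C"])),
    sprintf("- Ensemble merged rank-1 rate: %s", pct(stats$ensemble_rank1)),
    sprintf("- True lead at rank 1: %s (random selection: %s)",
            pct(stats$lead_rank1), pct(stats$lead_random))
  )
  writeLines(md, file.path(dir, "summary.md"))
  invisible(stats)
}
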