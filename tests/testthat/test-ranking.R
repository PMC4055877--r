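mk_results <- function(scores, sites = NULL, recs = "R1") {
  n <- length(scores)
  data.frame(
    generation_index = seq_len(n),
    site_label = if (is.null(sites)) paste0("S", seq_len(n)) else sites,
    template_name = paste0("t", seq_len(n)),
    score = scores,
    receptor_ref = rep_len(recs, n),
    stringsAsFactors = FALSE
  )
}

test_that("ranking sorts ascending with stable, deterministic tie-breaking", {
  rt <- rank_compounds(mk_results(c(-5, -7, -6)))
  expect_equal(rt$rank, 1:3)
  expect_equal(rt$generation_index, c(2, 3, 1))
  expect_equal(rt$score, c(-7, -6, -5))

  tie <- rank_compounds(mk_results(c(-5, -5)))
  expect_equal(tie$generation_index, c(1, 2)) # input order preserved

  # permuting untied input leaves the ranked sequence unchanged
  res <- mk_results(c(-2, -9, -4, -1, -7))
  rt1 <- rank_compounds(res)
  rt2 <- rank_compounds(res[c(4, 2, 5, 1, 3), ])
  expect_equal(rt1$generation_index, rt2$generation_index)
  expect_equal(rt1$score, rt2$score)

  expect_error(rank_compounds(mk_results(c(1, NaN))), "input error")
  # NA (no pose) ranks last
  rt3 <- rank_compounds(mk_results(c(-1, NA, -3)))
  expect_equal(rt3$generation_index[3], 2)
})

test_that("top-k prediction collects distinct site labels from the top", {
  rt <- rank_compounds(mk_results(c(-9, -8, -7, -6),
                                  sites = c("H3@C2", "H3@C2", "H5@C4", "H1@C1")))
  expect_equal(predict_active_position(rt, 1), "H3@C2")
  expect_equal(predict_active_position(rt, 2), c("H3@C2", "H5@C4"))
  expect_equal(predict_active_position(rt, 3), c("H3@C2", "H5@C4", "H1@C1"))
  expect_warning(p <- predict_active_position(rt, 5), "distinct sites")
  expect_length(p, 3)
})

test_that("ensemble merging equals a brute-force global sort", {
  t1 <- rank_compounds(mk_results(c(-5, -3, -1), recs = "R1"))
  t2 <- rank_compounds(mk_results(c(-4, -2, -6), recs = "R2"))
  merged <- merge_ensemble(list(t1, t2))
  expect_equal(nrow(merged), 6)
  expect_equal(merged$score, sort(c(-5, -3, -1, -4, -2, -6)))
  expect_equal(merged$rank, 1:6)
  # identity for one table
  expect_equal(merge_ensemble(list(t1))$score, t1$score)
  # disjoint ranges concatenate in range order
  lo <- rank_compounds(mk_results(c(-20, -19, -18), recs = "R3"))
  expect_equal(merge_ensemble(list(t1, lo))$receptor_ref[1:3], rep("R3", 3))
  # inconsistent libraries are rejected
  t3 <- rank_compounds(mk_results(c(-1, -2), recs = "R4"))
  expect_error(merge_ensemble(list(t1, t3)), "inconsistent")

  # randomized oracle: merged table = independent sort of the union
  set.seed(11)
  tabs <- lapply(1:4, function(k) {
    rank_compounds(mk_results(round(stats::rnorm(7), 4), recs = paste0("R", k)))
  })
  merged <- merge_ensemble(tabs)
  pool <- do.call(rbind, lapply(tabs, as.data.frame))
  expect_equal(merged$score, pool$score[order(pool$score, pool$generation_index)])
})

test_that("active-position rank finds the first hit or flags a miss", {
  rt <- rank_compounds(mk_results(c(-9, -8, -7, -6, -5),
                                  sites = c("a", "b", "c", "b", "d")))
  expect_equal(active_position_rank(rt, "a"), 1)
  expect_equal(active_position_rank(rt, c("b", "d")), 2)
  miss <- active_position_rank(rt, "zz")
  expect_equal(as.integer(miss), 6)
  expect_true(attr(miss, "not_found"))
})

test_that("lead spiking preserves mechanics and counts", {
  benz <- fix_benzene()
  lib <- enumerate_virtual_library(benz, singleton_set(), minimize = FALSE)
  lead <- load_molecule("CCO", format = "SMILES")
  lead$name <- "lead-1"
  spiked <- spike_true_leads(lib, list(lead))
  expect_length(spiked$compounds, 7)
  expect_true(spiked$compounds[[7]]$is_lead)
  expect_false(any(vapply(spiked$compounds[1:6], function(v) v$is_lead, logical(1))))
  expect_error(spike_true_leads(lib, list()), "precondition")

  # downstream ranking mechanics unchanged: best-scored lead is rank 1
  res <- mk_results(c(0, -1, -2, -3, -4, -5, -10),
                    sites = c(paste0("S", 1:6), "lead"))
  rt <- rank_compounds(res)
  expect_equal(best_lead_rank(rt, 7), 1)
})
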