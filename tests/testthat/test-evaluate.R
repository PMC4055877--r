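test_that("embedded benchmark tables load with verified marginals", {
  tabs <- load_benchmark_tables()
  expect_equal(nrow(tabs$single), 15)
  expect_equal(nrow(tabs$ensemble), 6)
  expect_equal(nrow(tabs$lead_spiking), 15)
  expect_equal(sum(tabs$single$n_sites), 171)
  expect_equal(sum(tabs$single$n_active), 45)
  mmp <- tabs$single[tabs$single$target == "MMP12", ]
  expect_equal(mmp$pdb_id, "1Y93")
  expect_equal(unlist(mmp[, c("n_sites", "n_active", "n_compounds_A", "rank_A")]),
               c(n_sites = 6, n_active = 3, n_compounds_A = 392, rank_A = 1))
  cdk2 <- tabs$single[tabs$single$target == "CDK2", ]
  expect_equal(cdk2$n_sites, 12); expect_equal(cdk2$n_active, 8)
  expect_equal(cdk2$rank_A, 1)
  pde4 <- tabs$single[tabs$single$target == "PDE4", ]
  expect_equal(pde4$n_sites, 14); expect_equal(pde4$n_active, 1)
  expect_equal(pde4$rank_A, 134)
})

test_that("tampered benchmark tables trigger fixture-integrity errors", {
  tmp <- tempdir()
  dir.create(d <- file.path(tmp, "bench_bad"), showWarnings = FALSE)
  tabs <- load_benchmark_tables()
  bad <- tabs$single
  bad$n_sites[1] <- bad$n_sites[1] + 1
  utils::write.csv(bad, file.path(d, "single_structure.csv"), row.names = FALSE)
  utils::write.csv(tabs$ensemble, file.path(d, "ensemble.csv"), row.names = FALSE)
  utils::write.csv(tabs$lead_spiking, file.path(d, "lead_spiking.csv"),
                   row.names = FALSE)
  expect_error(load_benchmark_tables(d), "fixture-integrity")
})

test_that("success rates are order-invariant and monotone in k", {
  tabs <- load_benchmark_tables()
  s <- tabs$single
  for (set_id in c("A", "B", "C")) {
    r1 <- success_rate(s, set_id, 1L)
    r2 <- success_rate(s, set_id, 2L)
    expect_gte(r2, r1)
    shuffled <- s[sample(nrow(s)), ]
    expect_equal(success_rate(shuffled, set_id, 1L), r1)
  }
  expect_error(success_rate(s, "Z", 1L), "unknown side-chain set")
  one <- s[s$rank_A == 1, ][1, ]
  expect_equal(success_rate(one, "A", 1L), 1.0)
})

test_that("random baselines pool counts and compose for two draws", {
  tabs <- load_benchmark_tables()
  p1 <- random_baseline(tabs$single, 1L)
  expect_equal(p1, 45 / 171, tolerance = 1e-12)
  p2 <- random_baseline(tabs$single, 2L)
  expect_equal(p2, 1 - (126 / 171)^2, tolerance = 1e-12)
  expect_gte(p2, p1)
  # degenerate single-record cases
  rec <- data.frame(n_sites = 5, n_active = 5)
  expect_equal(random_baseline(rec, 1L), 1.0)
  expect_error(random_baseline(data.frame(n_sites = 0, n_active = 0), 1L),
               "undefined")
})

test_that("lead-spiking summaries follow their definitions", {
  tabs <- load_benchmark_tables()
  expect_equal(lead_baseline(tabs$lead_spiking),
               mean(tabs$lead_spiking$n_true_leads / tabs$lead_spiking$n_compounds))
  one <- data.frame(n_compounds = 100, n_true_leads = 1, best_lead_rank = 5)
  expect_equal(lead_baseline(one), 0.01)
  expect_equal(lead_rank1_rate(one), 0)
})

test_that("the evaluation report reproduces records and headline statistics", {
  tabs <- load_benchmark_tables()
  dir <- file.path(tempdir(), "report_out")
  stats <- write_evaluation_report(tabs, dir)
  back <- utils::read.csv(file.path(dir, "single_structure.csv"))
  expect_equal(back, tabs$single)
  md <- readLines(file.path(dir, "summary.md"))
  for (needle in c("26.32%", "60.00%", "45.71%", "66.67%", "46.67%", "2.80%")) {
    expect_true(any(grepl(needle, md, fixed = TRUE)), label = needle)
  }
  expect_error(write_evaluation_report(list(single = NULL), tempdir()),
               "empty record")
})
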