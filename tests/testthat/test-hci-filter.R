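make_repo <- function(entries_df, assay = "BioID") {
  strata <- unique(entries_df$stratum)
  structure(list(entries = entries_df,
                 n_runs = structure(rep(10L, length(strata)),
                                    names = strata),
                 assay = assay, qc_min_proteins = NULL),
            class = "contaminant_repository")
}

scored_row <- function(prey, bfdr, avg_spec = 10, bait = "b1") {
  data.frame(bait_id = bait, prey_id = prey, counts = "1|1|1|1",
             avg_spec = avg_spec, control_avg = 0.5, fold_change = 20,
             probability = 1 - bfdr, bfdr = bfdr,
             stringsAsFactors = FALSE)
}

repo_entry <- function(prey, stratum, pct, avg_spec = 1) {
  data.frame(prey_id = prey, stratum = stratum, n_runs = 10L,
             pct = pct, avg_spec = avg_spec, max_spec = avg_spec,
             stringsAsFactors = FALSE)
}

test_that("the compound filter applies its clauses at the stated thresholds", {
  repo <- make_repo(rbind(
    repo_entry("clean", "All", 5),
    repo_entry("frequent", "All", 15, avg_spec = 9),
    repo_entry("nls_only", "NLS", 50, avg_spec = 5),
    repo_entry("nls_only", "All", 5, avg_spec = 5)))
  pol <- filter_policy()

  # bfdr 0.005, repo pct 5% -> retained
  r <- apply_hci_filter(scored_row("clean", 0.005), repo, pol)
  expect_identical(r$log$decision, "retained")
  expect_identical(r$log$clause, "pass")

  # bfdr 0.005, pct 15%, avg_spec 30 vs repo 9 -> rescued (30 >= 27)
  r <- apply_hci_filter(scored_row("frequent", 0.005, avg_spec = 30),
                        repo, pol)
  expect_identical(r$log$decision, "retained")
  expect_identical(r$log$clause, "rescued")

  # same but avg_spec 26 < 27 -> rejected by the elimination stratum All
  r <- apply_hci_filter(scored_row("frequent", 0.005, avg_spec = 26),
                        repo, pol)
  expect_identical(r$log$decision, "rejected")
  expect_identical(r$log$clause, "contaminant_All")

  # bfdr 0.02, pct 1% -> rejected on BFDR alone (first-fail order)
  r <- apply_hci_filter(scored_row("clean", 0.02), repo, pol)
  expect_identical(r$log$clause, "bfdr")

  # flagged in NLS only, clean in All -> rejected for BioID
  r <- apply_hci_filter(scored_row("nls_only", 0.005, avg_spec = 10),
                        repo, pol)
  expect_identical(r$log$decision, "rejected")
  expect_identical(r$log$clause, "contaminant_NLS")

  # ... but retained for AP-MS, where no elimination strata apply
  repo_ap <- make_repo(repo$entries, assay = "AP-MS")
  r <- apply_hci_filter(scored_row("nls_only", 0.005, avg_spec = 10),
                        repo_ap, filter_policy(assay = "AP-MS"))
  expect_identical(r$log$decision, "retained")
})

test_that("boundary semantics: strict BFDR and frequency, inclusive rescue", {
  repo <- make_repo(rbind(repo_entry("p10", "All", 10, avg_spec = 10),
                          repo_entry("p9", "All", 9.999)))
  pol <- filter_policy()
  # bfdr exactly at the cutoff fails (strict <)
  r <- apply_hci_filter(scored_row("p9", 0.01), repo, pol)
  expect_identical(r$log$clause, "bfdr")
  # pct exactly at the cutoff counts as flagged (strict < to pass)
  r <- apply_hci_filter(scored_row("p10", 0.005, avg_spec = 29), repo, pol)
  expect_identical(r$log$decision, "rejected")
  # rescue is inclusive: avg_spec exactly 3x repo avg passes
  r <- apply_hci_filter(scored_row("p10", 0.005, avg_spec = 30), repo, pol)
  expect_identical(r$log$decision, "retained")
  expect_identical(r$log$clause, "rescued")
})

test_that("missing repository entries pass the frequency clause and are logged", {
  repo <- make_repo(repo_entry("other", "All", 50))
  r <- apply_hci_filter(scored_row("unseen", 0.001), repo, filter_policy())
  expect_identical(r$log$decision, "retained")
  expect_true(r$log$repo_absent)
})

test_that("bait self-detection is excluded", {
  repo <- make_repo(repo_entry("other", "All", 1))
  self <- scored_row("b1", 0.001)
  r <- apply_hci_filter(self, repo, filter_policy())
  expect_identical(r$log$clause, "bait_self")
  r2 <- apply_hci_filter(self, repo, filter_policy(exclude_self = FALSE))
  expect_identical(r2$log$decision, "retained")
})

test_that("assay mismatch between repository and policy is an error", {
  repo <- make_repo(repo_entry("p", "All", 1), assay = "AP-MS")
  expect_error(apply_hci_filter(scored_row("p", 0.001), repo,
                                filter_policy(assay = "BioID")),
               "does not match")
})

test_that("tightening thresholds yields subsets (monotonicity) and the filter is idempotent", {
  sim <- toy_sim(seed = 19L)
  repo <- build_repository(sim$runs, assay = "BioID")
  scored <- score_interactions(sim$runs)
  key <- function(d) paste(d$bait_id, d$prey_id)

  loose <- apply_hci_filter(scored, repo, filter_policy(bfdr_max = 0.05))
  tight <- apply_hci_filter(scored, repo, filter_policy(bfdr_max = 0.01))
  expect_true(all(key(tight$hci) %in% key(loose$hci)))

  low_rescue <- apply_hci_filter(scored, repo,
                                 filter_policy(rescue_fold = 2))
  high_rescue <- apply_hci_filter(scored, repo,
                                  filter_policy(rescue_fold = 5))
  expect_true(all(key(high_rescue$hci) %in% key(low_rescue$hci)))

  # idempotence: re-filtering the retained set changes nothing
  again <- apply_hci_filter(tight$hci, repo, filter_policy(bfdr_max = 0.01))
  expect_identical(key(again$hci), key(tight$hci))

  # every record's log names exactly one clause
  expect_false(any(is.na(tight$log$clause)))
  expect_true(all(tight$log$clause[tight$log$decision == "rejected"] %in%
                    c("bfdr", "bait_self", "contaminant_All",
                      "contaminant_NLS", "frequency")))
})

test_that("HCI summaries count totals and unique preys", {
  hci <- data.frame(bait_id = c("b1", "b1", "b2", "b2"),
                    prey_id = c("A", "B", "B", "C"))
  s <- summarize_hcis(hci)
  expect_identical(s$total, 4L)
  expect_identical(s$unique_preys, 3L)
  expect_identical(s$per_bait$n_hci, c(2L, 2L))
  empty <- summarize_hcis(hci[0, ])
  expect_identical(empty$total, 0L)
  expect_identical(empty$unique_preys, 0L)
})
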