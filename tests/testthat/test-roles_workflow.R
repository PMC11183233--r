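test_that("annotate_series recovers the planted design from a clean series", {
  spec <- corpus_spec(5, seed = 21)
  corpus <- generate_corpus(spec)
  tpl <- prompt_template("optimal_annotator", version = 1L)
  be <- mock_backend(seed = 1)
  for (b in corpus) {
    res <- annotate_series(b$series, tpl, be)
    expect_length(res$failures, 0)
    expect_length(res$annotations, length(b$gold))
    expect_length(check_against_gold(res$annotations, b$gold)$field, 0)
  }
})

test_that("a series with two independent designs yields two annotations", {
  spec <- corpus_spec(4, multi_design_rate = 1, seed = 8)
  corpus <- generate_corpus(spec)
  tpl <- prompt_template("optimal_annotator", version = 1L)
  be <- mock_backend(seed = 1)
  for (b in corpus) {
    res <- annotate_series(b$series, tpl, be)
    expect_length(res$annotations, 2)
    expect_length(check_against_gold(res$annotations, b$gold)$field, 0)
  }
})

test_that("a degenerate series is recorded as a failure, not raised", {
  flat <- series_record("GSEF", samples = lapply(1:3, function(i)
    sample_record(sprintf("S%d", i), characteristics = c(tissue = "liver"))))
  res <- annotate_series(flat, prompt_template("original_annotator"),
                         mock_backend(seed = 1))
  expect_length(res$annotations, 0)
  expect_length(res$failures, 1)
  expect_match(res$failures[[1]]$reason, "empty group")
})

test_that("check_against_gold emits one discrepancy per differing field", {
  s <- two_arm_series()
  g <- two_arm_gold(s)
  expect_equal(nrow(check_against_gold(list(g), list(g))), 0)

  # pert_name difference without a synonym table is one discrepancy
  a_name <- annotation_record(s$series_id, g$ctrl_ids, g$pert_ids, "drug",
                              "acetylsalicylic acid", "K562")
  g_asa <- annotation_record(s$series_id, g$ctrl_ids, g$pert_ids, "drug",
                             "aspirin", "K562")
  d <- check_against_gold(list(a_name), list(g_asa))
  expect_equal(d$field, "pert_name")
  expect_equal(d$expected, "aspirin")

  # swapped groups are a single grouping discrepancy, not two id-set ones
  a_swap <- annotation_record(s$series_id, ctrl_ids = g$pert_ids,
                              pert_ids = g$ctrl_ids, pert_type = "drug",
                              pert_name = "imatinib", cell_type = "K562")
  d2 <- check_against_gold(list(a_swap), list(g))
  expect_equal(d2$field, "grouping")
  expect_equal(nrow(d2), 1)
})

test_that("unmatched gold designs surface as grouping discrepancies", {
  spec <- corpus_spec(1, dose_rate = 1, seed = 3)
  b <- generate_corpus(spec)[[1]]
  tpl0 <- prompt_template("original_annotator", version = 0L)
  res <- annotate_series(b$series, tpl0, mock_backend(seed = 1))
  expect_length(res$annotations, 1)      # dose-blind: merged arms
  d <- check_against_gold(res$annotations, b$gold)
  expect_true(nrow(d) >= 2)
  expect_true("grouping" %in% d$field || "pert_ids" %in% d$field)
})

test_that("optimize_prompt bumps the version by exactly one and needs input", {
  tpl <- prompt_template("original_annotator", version = 0L)
  d <- data.frame(series_id = "G", field = "pert_ids", expected = "x",
                  observed = "y")
  tpl1 <- optimize_prompt(tpl, d)
  expect_equal(tpl1$version, 1L)
  expect_gt(nchar(tpl1$instruction_text), nchar(tpl$instruction_text))
  expect_error(optimize_prompt(tpl, d[0, ]), "non-empty")
})

test_that("training converges on the planted dose-blindness deficiency", {
  spec <- corpus_spec(6, dose_rate = 0.5, seed = 11)
  corpus <- generate_corpus(spec)
  tpl0 <- prompt_template("original_annotator", version = 0L)
  hist <- train_optimal_annotator(corpus, tpl0, mock_backend(seed = 2),
                                  max_iters = 3)
  expect_true(hist$converged)
  expect_lte(nrow(hist$history), 3)
  expect_equal(hist$history$n_discrepancies[nrow(hist$history)], 0)
  expect_true(all(diff(hist$history$n_discrepancies) < 0))
  expect_true(all(diff(hist$history$version) == 1))

  # already-concordant template: converged at iteration 0
  tpl1 <- prompt_template("optimal_annotator", version = 1L)
  h0 <- train_optimal_annotator(corpus, tpl1, mock_backend(seed = 2))
  expect_true(h0$converged)
  expect_equal(nrow(h0$history), 1)
  expect_equal(h0$history$n_discrepancies, 0)

  # no optimization budget: unconverged, template returned untouched
  hm <- train_optimal_annotator(corpus, tpl0, mock_backend(seed = 2),
                                max_iters = 0)
  expect_false(hm$converged)
  expect_equal(hm$final_template$version, 0L)
})

test_that("run_waterfall on a clean corpus passes everything in round 1", {
  corpus <- generate_corpus(corpus_spec(20, seed = 31))
  tpl <- prompt_template("optimal_annotator", version = 1L)
  rep <- run_waterfall(corpus, tpl, mock_backend(seed = 7))
  expect_equal(rep$metrics$apr, 1.0)
  expect_equal(rep$metrics$dpr, 1.0)
  expect_equal(rep$metrics$qcc, 1.0)
  expect_true(all(rep$final$rounds == 1L))
  expect_equal(rep$metrics$n_datasets, 20L)
})

test_that("round-2 annotations exist exactly for channel disagreements", {
  corpus <- generate_corpus(corpus_spec(40, seed = 32))
  tpl <- prompt_template("optimal_annotator", version = 1L)
  rep <- run_waterfall(corpus, tpl,
                       mock_backend(seed = 7, disagreement_rate = 0.25))
  rounds <- vapply(rep$annotations, `[[`, integer(1), "round_index")
  round2_sids <- unique(vapply(rep$annotations[rounds == 2L], `[[`,
                               character(1), "series_id"))
  disagreed_sids <- unique(rep$final$series_id[rep$final$channels_disagreed])
  expect_setequal(round2_sids, disagreed_sids)
  expect_true(any(rep$final$channels_disagreed))   # rate 0.25 over 40 series
  expect_true(all(rep$final$rounds[rep$final$channels_disagreed] == 2L))
})

test_that("an empty corpus yields an empty report without error", {
  rep <- run_waterfall(list(), prompt_template("optimal_annotator"),
                       mock_backend(seed = 1))
  expect_equal(rep$metrics$n_annotations, 0L)
  expect_equal(nrow(rep$final), 0)
})

test_that("waterfall runs are byte-identical under the mock backend", {
  corpus <- generate_corpus(corpus_spec(10, error_rates = c(confounder = 0.2),
                                        seed = 17))
  tpl <- prompt_template("optimal_annotator", version = 1L)
  j1 <- report_to_json(run_waterfall(corpus, tpl,
                                     mock_backend(seed = 4,
                                                  disagreement_rate = 0.2)))
  j2 <- report_to_json(run_waterfall(corpus, tpl,
                                     mock_backend(seed = 4,
                                                  disagreement_rate = 0.2)))
  expect_identical(j1, j2)
})
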