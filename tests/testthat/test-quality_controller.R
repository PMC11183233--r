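test_that("alignment ignores sex/age but flags other differing keys", {
  s <- two_arm_series()
  a <- two_arm_gold(s)
  expect_true(qc_criterion_alignment(a, s)$ok)

  # age-only difference between the groups is expressly ignored
  s_age <- s
  s_age$samples$GSE_T1_P1$characteristics[["age"]] <- "34"
  s_age$samples$GSE_T1_P2$characteristics[["age"]] <- "34"
  s_age$samples$GSE_T1_C1$characteristics[["age"]] <- "60"
  s_age$samples$GSE_T1_C2$characteristics[["age"]] <- "60"
  expect_true(qc_criterion_alignment(a, s_age)$ok)

  s_tis <- s
  s_tis$samples$GSE_T1_P1$characteristics[["tissue"]] <- "kidney"
  s_tis$samples$GSE_T1_P2$characteristics[["tissue"]] <- "kidney"
  res <- qc_criterion_alignment(a, s_tis)
  expect_false(res$ok)
  expect_match(res$reasons, "tissue")
})

test_that("uniformity demands consolidation of same-profile samples", {
  # 5-sample toy: 3 identical vehicle samples, only 2 assigned as controls
  mk <- function(id, tr) make_sample_fx(id, treatment = tr, tissue = "liver")
  s <- series_record("GSEU", samples = list(
    mk("V1", "vehicle"), mk("V2", "vehicle"), mk("V3", "vehicle"),
    mk("P1", "drugA"), mk("P2", "drugA")))
  a_split <- annotation_record("GSEU", c("V1", "V2"), c("P1", "P2"),
                               "drug", "drugA")
  res <- qc_criterion_uniformity(a_split, s)
  expect_false(res$ok)
  expect_match(res$reasons, "V3")
  a_all <- annotation_record("GSEU", c("V1", "V2", "V3"), c("P1", "P2"),
                             "drug", "drugA")
  expect_true(qc_criterion_uniformity(a_all, s)$ok)

  # a perturbation group mixing two doses while an unmixed grouping exists
  sd_ <- series_record("GSED", samples = list(
    mk("V1", "vehicle"), mk("V2", "vehicle"),
    mk("D1", "drugA 10 mg"), mk("D2", "drugA 50 mg")))
  a_mix <- annotation_record("GSED", c("V1", "V2"), c("D1", "D2"),
                             "drug", "drugA")
  res2 <- qc_criterion_uniformity(a_mix, sd_)
  expect_false(res2$ok)
  expect_match(res2$reasons, "mixes 2 distinct")
  a_one <- annotation_record("GSED", c("V1", "V2"), "D1", "drug", "drugA")
  expect_true(qc_criterion_uniformity(a_one, sd_)$ok)
})

test_that("perturbation criterion checks name, type and direction", {
  s <- two_arm_series()
  a <- two_arm_gold(s)
  expect_true(qc_criterion_perturbation(a, s)$ok)

  swapped <- annotation_record(s$series_id, ctrl_ids = a$pert_ids,
                               pert_ids = a$ctrl_ids, pert_type = "drug",
                               pert_name = "imatinib", cell_type = "K562")
  res <- qc_criterion_perturbation(swapped, s)
  expect_false(res$ok)
  expect_true(any(grepl("direction", res$reasons)))

  empty <- annotation_record(s$series_id, a$ctrl_ids, a$pert_ids, "drug",
                             pert_name = "")
  expect_false(qc_criterion_perturbation(empty, s)$ok)

  # synonym table rescues a renamed perturbation
  asa <- annotation_record(s$series_id, a$ctrl_ids, a$pert_ids, "drug",
                           pert_name = "gleevec")
  expect_false(qc_criterion_perturbation(asa, s)$ok)
  expect_true(qc_criterion_perturbation(
    asa, s, synonyms = list(gleevec = "imatinib"))$ok)
})

test_that("run_rule_qc combines the three criteria deterministically", {
  s <- two_arm_series()
  a <- two_arm_gold(s)
  v <- run_rule_qc(a, s)
  expect_equal(v$status, "Success")
  expect_true(all(v$criteria))
  expect_equal(v, run_rule_qc(a, s))   # idempotent

  # unknown sample id: hard fail naming the sample
  bad <- annotation_record(s$series_id, "GHOST", a$pert_ids, "drug",
                           "imatinib")
  vb <- run_rule_qc(bad, s)
  expect_equal(vb$status, "Fail")
  expect_match(vb$reasons, "unknown sample")
})

test_that("verdicts are invariant to sample and key order", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_series(sprintf("PERM%d", i))
    a <- random_annotation(s)
    v0 <- run_rule_qc(a, s)
    s_perm <- s
    s_perm$samples <- s$samples[sample(length(s$samples))]
    s_perm$samples <- lapply(s_perm$samples, function(sm) {
      sm$characteristics <- sm$characteristics[
        sample(length(sm$characteristics))]
      sm
    })
    names(s_perm$samples) <- vapply(s_perm$samples, `[[`, character(1),
                                    "sample_id")
    v1 <- run_rule_qc(a, s_perm)
    expect_equal(v1$criteria, v0$criteria)
    expect_equal(v1$status, v0$status)
  }
})

test_that("mock llm QC reproduces the rule verdict at disagreement rate 0 and flips at 1", {
  corpus <- generate_corpus(corpus_spec(15, error_rates = c(confounder = 0.3),
                                        seed = 5))
  tpl <- prompt_template("quality_controller")
  be0 <- mock_backend(seed = 2, disagreement_rate = 0)
  be1 <- mock_backend(seed = 2, disagreement_rate = 1)
  for (b in corpus) {
    rule <- run_rule_qc(b$gold[[1]], b$series)
    llm0 <- run_llm_qc(b$gold[[1]], b$series, tpl, be0)
    llm1 <- run_llm_qc(b$gold[[1]], b$series, tpl, be1)
    expect_equal(llm0$status, rule$status)
    expect_equal(llm0$criteria, rule$criteria)
    expect_true(llm1$status != rule$status)
  }
})

test_that("consensus follows two-agree / majority-of-three with a demanded third round", {
  v <- function(st, round = 1L)
    qc_verdict("G", "a", "rule", st == "Success", st == "Success",
               st == "Success", round_index = round)
  expect_equal(consensus_qc(list(v("Success"), v("Success")))$status,
               "Success")
  expect_equal(consensus_qc(list(v("Success"), v("Fail"), v("Fail", 2L)))$status,
               "Fail")
  expect_equal(consensus_qc(list(v("Fail"), v("Success"), v("Success", 2L)))$status,
               "Success")
  expect_error(consensus_qc(list(v("Success"), v("Fail"))),
               "third quality-control round")
  expect_error(consensus_qc(list(v("Success"))), "at least 2")
})

test_that("rule QC matches the brute-force oracle on random series", {
  set.seed(13)
  for (i in 1:60) {
    s <- random_series(sprintf("OR%d", i))
    a <- random_annotation(s)
    v <- run_rule_qc(a, s)
    expect_equal(unname(v$criteria), unname(oracle_rule_qc(a, s)),
                 info = sprintf("series %s, annotation %s", s$series_id,
                                format(a)))
  }
})
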