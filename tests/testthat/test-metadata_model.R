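test_that("parse_soft reads a minimal series with characteristics", {
  text <- paste(
    "^SERIES = GSE1",
    "!Series_title = toy study",
    "!Series_summary = a summary",
    "!Series_overall_design = two arms",
    "^SAMPLE = GSM1",
    "!Sample_title = control rep1",
    "!Sample_characteristics_ch1 = tissue: liver",
    "!Sample_characteristics_ch1 = treatment: vehicle",
    "^SAMPLE = GSM2",
    "!Sample_title = treated rep1",
    "!Sample_characteristics_ch1 = tissue: liver",
    "!Sample_characteristics_ch1 = treatment: drugA",
    sep = "\n")
  s <- parse_soft(text)
  expect_s3_class(s, "gc_series")
  expect_equal(s$series_id, "GSE1")
  expect_length(s$samples, 2)
  expect_equal(s$samples[["GSM1"]]$characteristics,
               c(tissue = "liver", treatment = "vehicle"))
  # line without a colon becomes characteristic_<n>
  s2 <- parse_soft(c("^SERIES = G", "^SAMPLE = S1",
                     "!Sample_characteristics_ch1 = just text"))
  expect_equal(names(s2$samples$S1$characteristics), "characteristic_1")
})

test_that("parse_soft rejects malformed input naming the offending line", {
  expect_error(parse_soft(c("^SAMPLE = GSM1", "^SERIES = GSE1")),
               "line 1.*before series")
  expect_error(parse_soft(c("^SERIES = G", "^SAMPLE = S1",
                            "^SAMPLE = S1")),
               "duplicate sample id 'S1'")
  expect_error(parse_soft("no soft here"), "before \\^SERIES|no \\^SERIES")
})

test_that("SOFT serialization round-trips field-for-field", {
  set.seed(42)
  for (i in 1:10) {
    s <- random_series(sprintf("RT%d", i))
    s2 <- parse_soft(write_soft(s))
    expect_equal(s2$series_id, s$series_id)
    expect_equal(names(s2$samples), names(s$samples))
    for (id in names(s$samples))
      expect_equal(s2$samples[[id]]$characteristics,
                   s$samples[[id]]$characteristics)
  }
})

test_that("characteristic normalization case-folds, trims and is idempotent", {
  s <- sample_record("S1", characteristics = c(" Tissue " = "  liver ",
                                               "CELL   Line" = "K562"))
  n1 <- normalize_characteristics(s)
  expect_equal(names(n1$characteristics), c("tissue", "cell line"))
  expect_equal(unname(n1$characteristics[["tissue"]]), "liver")
  expect_identical(normalize_characteristics(n1)$characteristics,
                   n1$characteristics)
  # property: idempotence over random key strings
  set.seed(1)
  for (i in 1:50) {
    key <- paste(sample(c(LETTERS, letters, " ", "\t", "(", ")"), 12,
                        replace = TRUE), collapse = "")
    sr <- sample_record("S", characteristics = stats::setNames("v", key))
    a <- normalize_characteristics(sr)
    expect_identical(normalize_characteristics(a)$characteristics,
                     a$characteristics)
  }
})

test_that("sex/age synonym classes are recognized", {
  expect_equal(key_class("gender"), "sex")
  expect_equal(key_class(" Sex "), "sex")
  expect_equal(key_class("age (years)"), "age")
  expect_equal(key_class("tissue"), "other")
  cfg <- key_config(sex = c("sexo"))
  expect_equal(key_class("sexo", cfg), "sex")
  expect_equal(key_class("gender", cfg), "other")
})

test_that("annotation records enforce their invariants", {
  expect_error(annotation_record("G", c("a"), c("a", "b"), "drug"),
               "overlapping groups")
  expect_error(annotation_record("G", character(), "b", "drug"),
               "non-empty")
  expect_error(annotation_record("G", "a", "b", "chemical"),
               "unknown pert_type 'chemical'.*drug, disease, gene")
  s <- two_arm_series()
  expect_error(annotation_record(s$series_id, "nope", names(s$samples)[3],
                                 "drug", series = s),
               "unknown sample")
})

test_that("annotation tables round-trip through TSV", {
  s <- two_arm_series()
  recs <- list(two_arm_gold(s),
               annotation_record("GSE9", c("GSM1", "GSM2"), "GSM3",
                                 "gene", "tp53", "HeLa",
                                 annotator_tag = "gold", round_index = 2L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(recs, path)
  back <- read_annotations(path)
  expect_equal(back, recs)
  expect_equal(back[[1]]$ctrl_ids, recs[[1]]$ctrl_ids)
  # unknown pert_type token in the file is rejected with the allowed list
  df <- read.delim(path)
  df$pert_type[1] <- "chemical"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_annotations(path), "chemical.*drug, disease, gene")
})
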