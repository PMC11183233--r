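test_that("the mock backend is deterministic and never fails transport", {
  s <- two_arm_series()
  tpl <- prompt_template("original_annotator")
  r1 <- complete(tpl, s, mock_backend(seed = 5))
  r2 <- complete(tpl, s, mock_backend(seed = 5))
  expect_identical(r1, r2)
  # same backend, same payload twice: still byte-identical
  be <- mock_backend(seed = 5)
  expect_identical(complete(tpl, s, be), complete(tpl, s, be))
  # distinct seeds must not crash (annotation responses are rule-based)
  expect_no_error(complete(tpl, s, mock_backend(seed = 99)))
})

test_that("exchange log holds exactly one entry per completion call", {
  s <- two_arm_series()
  tpl <- prompt_template("original_annotator")
  be <- mock_backend(seed = 1)
  for (i in 1:5) complete(tpl, s, be)
  expect_equal(be$n_calls, 5L)
  expect_length(be$log, 5L)
  expect_equal(vapply(be$log, `[[`, character(1), "role_name"),
               rep("original_annotator", 5))
})

test_that("live transport failures are retried then raised as backend errors", {
  tpl <- prompt_template("original_annotator")
  n_attempts <- 0
  failing <- function(template, payload, backend) {
    n_attempts <<- n_attempts + 1
    stop("socket down")
  }
  be <- live_backend(failing, retry_limit = 0L)
  expect_error(complete(tpl, "x", be), "backend error after 1 attempt")
  expect_equal(n_attempts, 1)
  n_attempts <- 0
  be2 <- live_backend(failing, retry_limit = 2L)
  expect_error(complete(tpl, "x", be2), "after 3 attempt")
  expect_equal(n_attempts, 3)
  # a transport that recovers is logged with its retry count
  flaky <- local({
    k <- 0
    function(template, payload, backend) {
      k <<- k + 1
      if (k < 3) stop("transient") else "ok"
    }
  })
  be3 <- live_backend(flaky, retry_limit = 5L)
  expect_equal(complete(tpl, "x", be3), "ok")
  expect_equal(be3$log[[1]]$retries, 2L)
})

test_that("backend_from_config builds both kinds", {
  be <- backend_from_config(list(kind = "mock", seed = 9,
                                 disagreement_rate = 0.5))
  expect_equal(be$kind, "mock")
  expect_equal(be$disagreement_rate, 0.5)
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("kind: mock", "seed: 4"), cfg)
  expect_equal(backend_from_config(cfg)$seed, 4L)
  expect_error(backend_from_config(list(kind = "live")), "transport")
  expect_error(backend_from_config(list(kind = "weird")), "unknown backend")
})

test_that("parse_annotation_response validates the schema", {
  s <- two_arm_series()
  ids <- names(s$samples)
  good <- sprintf(
    '{"ctrl_ids":["%s","%s"],"pert_ids":["%s","%s"],"pert_type":"drug","pert_name":"imatinib","cell_type":"K562"}',
    ids[1], ids[2], ids[3], ids[4])
  rec <- parse_annotation_response(good, s)
  expect_s3_class(rec, "gc_annotation")
  expect_equal(rec$pert_name, "imatinib")
  # overlapping id sets are a parse failure, not an exception
  bad <- sub(sprintf('"pert_ids":\\["%s"', ids[3]),
             sprintf('"pert_ids":["%s"', ids[1]), good)
  f <- parse_annotation_response(bad, s)
  expect_true(is_parse_failure(f))
  expect_match(f$reason, "overlapping groups")
  f2 <- parse_annotation_response("nothing structured here", s)
  expect_true(is_parse_failure(f2))
  f3 <- parse_annotation_response('{"ctrl_ids":["a"]}', s)
  expect_match(f3$reason, "missing required field")
  f4 <- parse_annotation_response(gsub("drug", "chemical", good), s)
  expect_match(f4$reason, "unknown pert_type")
})

test_that("parse_annotation_response is total over arbitrary text", {
  set.seed(7)
  alphabet <- c(letters, '{', '}', '"', ':', ',', '[', ']', ' ', '0', '1')
  for (i in 1:200) {
    txt <- paste(sample(alphabet, sample(0:60, 1), replace = TRUE),
                 collapse = "")
    expect_no_error(parse_annotation_response(txt))
  }
  expect_no_error(parse_annotation_response(NA_character_))
  expect_no_error(parse_annotation_response(character()))
})

test_that("mock annotator splits on the perturbation key and obeys versions", {
  s <- two_arm_series()
  tpl0 <- prompt_template("original_annotator", version = 0L)
  resp <- mock_annotate(s, tpl0)
  objs <- jsonlite::fromJSON(resp, simplifyVector = FALSE)
  expect_length(objs, 1)
  expect_setequal(unlist(objs[[1]]$ctrl_ids), grep("_C", names(s$samples),
                                                   value = TRUE))
  expect_equal(objs[[1]]$pert_name, "imatinib")
  expect_equal(objs[[1]]$cell_type, "K562")

  # three-arm dose series: version 0 merges the doses, version 1 separates
  dose <- two_arm_series()
  dose$samples[["GSE_T1_P1"]]$characteristics[["treatment"]] <- "imatinib 10 mg"
  dose$samples[["GSE_T1_P2"]]$characteristics[["treatment"]] <- "imatinib 50 mg"
  o0 <- jsonlite::fromJSON(mock_annotate(dose, tpl0), simplifyVector = FALSE)
  expect_length(o0, 1)
  expect_length(o0[[1]]$pert_ids, 2)
  tpl1 <- prompt_template("original_annotator", version = 1L)
  o1 <- jsonlite::fromJSON(mock_annotate(dose, tpl1), simplifyVector = FALSE)
  expect_length(o1, 2)
  expect_equal(sort(vapply(o1, function(a) length(a$pert_ids), integer(1))),
               c(1L, 1L))
  expect_equal(unique(vapply(o1, `[[`, character(1), "pert_name")),
               "imatinib")

  # no partitioning key: deliberately degenerate response (all samples in
  # pert_ids) that downstream validation rejects
  flat <- series_record("GSEF", samples = lapply(1:3, function(i)
    sample_record(sprintf("S%d", i), characteristics = c(tissue = "liver"))))
  od <- jsonlite::fromJSON(mock_annotate(flat, tpl0), simplifyVector = FALSE)
  expect_length(od[[1]]$ctrl_ids, 0)
  expect_length(od[[1]]$pert_ids, 3)
})
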