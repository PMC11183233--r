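#' Quality-control verdict
#'
#' Outcome of one quality-control pass over one annotation. For the `rule`
#' and `llm` channels `status` is `"Success"` exactly when all three
#' criterion flags are true; the `manual` channel carries a [manual_grade()]
#' instead of criterion flags.
#'
#' @param series_id series identifier
#' @param annotation_id stable reference to the annotation
#'   (`format(annotation)` by default)
#' @param channel `"rule"`, `"llm"` or `"manual"`
#' @param alignment,uniformity,perturbation logical criterion outcomes
#' @param reasons character vector naming each violation
#' @param round_index which annotation round the verdict refers to
#' @param grade a [manual_grade()] (manual channel only)
#' @return object of class `gc_verdict`
#' @export
qc_verdict <- function(series_id, annotation_id, channel,
                       alignment = NA, uniformity = NA, perturbation = NA,
                       reasons = character(), round_index = 1L,
                       grade = NULL) {
  channel <- match.arg(channel, c("rule", "llm", "manual"))
  if (channel == "manual") {
    if (is.null(grade)) stop_gc("manual channel requires a manual_grade")
    status <- if (grade$grade %in% c("Excellent", "Moderate")) "Success" else "Fail"
    crit <- c(alignment = NA, uniformity = NA, perturbation = NA)
  } else {
    crit <- c(alignment = isTRUE(alignment),
              uniformity = isTRUE(uniformity),
              perturbation = isTRUE(perturbation))
    status <- if (all(crit)) "Success" else "Fail"
  }
  structure(list(series_id = series_id, annotation_id = annotation_id,
                 channel = channel, status = status,
                 criteria = crit, reasons = as.character(reasons),
                 round_index = as.integer(round_index), grade = grade),
            class = "gc_verdict")
}

#' Manual quality grade
#'
#' Three-level human assessment of an automated annotation: `Excellent`
#' (the automated call surpassed the existing curation), `Moderate`
#' (essentially consistent or ambiguous) or `Error`. An error cause is
#' recorded only for `Error` grades; the documented causes are multiple
#' disturbances, sample age differences and inconsistent disturbance names.
#'
#' @param grade one of `"Excellent"`, `"Moderate"`, `"Error"`
#' @param cause for `Error` only: `"multiple_disturbances"`,
#'   `"age_difference"`, `"name_inconsistency"` or `"other"`
#' @return object of class `gc_manual_grade`
#' @export
manual_grade <- function(grade, cause = NULL) {
  grade <- match.arg(grade, c("Excellent", "Moderate", "Error"))
  if (!is.null(cause)) {
    if (grade != "Error")
      stop_gc("cause may only accompany grade 'Error'")
    cause <- match.arg(cause, c("multiple_disturbances", "age_difference",
                                "name_inconsistency", "other"))
  }
  structure(list(grade = grade, cause = cause), class = "gc_manual_grade")
}

#' @export
print.gc_verdict <- function(x, ...) {
  cat(sprintf("<verdict %s/%s %s round %d> %s%s\n", x$series_id, x$channel,
              x$status, x$round_index,
              paste(sprintf("%s=%s", names(x$criteria), x$criteria), collapse = " "),
              if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = "; "), "]") else ""))
  invisible(x)
}

# ---- shared helpers ---------------------------------------------------------

ABSENT <- "<absent>"

# per-sample normalized characteristics for a set of sample ids
chars_of <- function(series, ids, config) {
  lapply(series$samples[ids], function(s)
    normalize_characteristics(s, config)$characteristics)
}

# value set of key `k` over a list of characteristic vectors; missing key
# contributes the ABSENT sentinel
value_set <- function(chs, k) {
  sorted_unique(vapply(chs, function(ch)
    if (k %in% names(ch)) ch[[k]] else ABSENT, character(1)))
}

non_ignored_keys <- function(chs, config) {
  keys <- sorted_unique(unlist(lapply(chs, names), use.names = FALSE))
  keys[!is_ignored_key(keys, config)]
}

#' Designate the perturbation key of an annotation
#'
#' The characteristic key that encodes the perturbation is never declared in
#' real metadata, so it is inferred: (1) the lexicographically first
#' non-ignored key one of whose values contains `pert_name`
#' (case-insensitive substring); (2) failing that, the unique non-ignored
#' key whose control and perturbation value sets are disjoint (it perfectly
#' separates the two groups); (3) otherwise `NA`, in which case
#' characteristic alignment is checked over all non-ignored keys and the
#' perturbation criterion falls back to text search alone.
#'
#' @param annotation a [annotation_record()]
#' @param series its [series_record()]
#' @param config a [key_config()]
#' @return a key name or `NA_character_`
#' @export
designate_pert_key <- function(annotation, series, config = key_config()) {
  ids <- annotation_samples(annotation)
  chs <- chars_of(series, ids, config)
  keys <- non_ignored_keys(chs, config)
  if (!length(keys)) return(NA_character_)
  name <- tolower(trim_collapse(annotation$pert_name))
  if (nzchar(name)) {
    by_name <- keys[vapply(keys, function(k) {
      vals <- setdiff(value_set(chs, k), ABSENT)
      any(grepl(name, tolower(vals), fixed = TRUE))
    }, logical(1))]
    if (length(by_name)) return(by_name[1])
  }
  ctrl_chs <- chs[annotation$ctrl_ids]
  pert_chs <- chs[annotation$pert_ids]
  separating <- keys[vapply(keys, function(k) {
    length(intersect(value_set(ctrl_chs, k), value_set(pert_chs, k))) == 0L
  }, logical(1))]
  if (length(separating) == 1L) return(separating)
  NA_character_
}

check_ids_known <- function(annotation, series) {
  setdiff(annotation_samples(annotation), sample_ids(series))
}

# ---- the three criteria -----------------------------------------------------

#' Criterion 1: strict alignment with sample characteristics
#'
#' Every non-ignored characteristic key other than the designated
#' perturbation key must show the same value set in the control group as in
#' the perturbation group. Sex and age keys are expressly ignored; replicate
#' counts may differ between groups, so values are compared as sets.
#'
#' @param annotation a [annotation_record()]
#' @param series its [series_record()]
#' @param config a [key_config()]
#' @param pert_key designated perturbation key; computed via
#'   [designate_pert_key()] when missing
#' @return list with elements `ok` (logical) and `reasons` (character,
#'   naming each violating key)
#' @export
qc_criterion_alignment <- function(annotation, series, config = key_config(),
                                   pert_key = NULL) {
  unknown <- check_ids_known(annotation, series)
  if (length(unknown))
    return(list(ok = FALSE,
                reasons = sprintf("unknown sample: %s",
                                  paste(unknown, collapse = ", "))))
  if (is.null(pert_key)) pert_key <- designate_pert_key(annotation, series, config)
  chs <- chars_of(series, annotation_samples(annotation), config)
  keys <- setdiff(non_ignored_keys(chs, config),
                  if (!is.na(pert_key)) pert_key else character())
  ctrl_chs <- chs[annotation$ctrl_ids]
  pert_chs <- chs[annotation$pert_ids]
  bad <- keys[vapply(keys, function(k) {
    !setequal(value_set(ctrl_chs, k), value_set(pert_chs, k))
  }, logical(1))]
  list(ok = length(bad) == 0L,
       reasons = if (length(bad))
         sprintf("characteristic '%s' differs between groups", bad)
       else character())
}

#' Criterion 2: grouping uniformity
#'
#' All samples of the same type must be consolidated into a single group:
#' (a) no sample left out of the annotation may share the full non-ignored
#' characteristic profile of an assigned sample, and (b) when a perturbation
#' key is designated, neither group may mix two distinct values of it.
#'
#' @inheritParams qc_criterion_alignment
#' @return list with `ok` and `reasons`
#' @export
qc_criterion_uniformity <- function(annotation, series, config = key_config(),
                                    pert_key = NULL) {
  unknown <- check_ids_known(annotation, series)
  if (length(unknown))
    return(list(ok = FALSE,
                reasons = sprintf("unknown sample: %s",
                                  paste(unknown, collapse = ", "))))
  if (is.null(pert_key)) pert_key <- designate_pert_key(annotation, series, config)
  assigned <- annotation_samples(annotation)
  all_ids <- sample_ids(series)
  chs_all <- chars_of(series, all_ids, config)
  keys <- non_ignored_keys(chs_all, config)
  profile <- vapply(chs_all, function(ch)
    paste(vapply(keys, function(k)
      if (k %in% names(ch)) ch[[k]] else ABSENT, character(1)),
      collapse = "\x1f"), character(1))
  reasons <- character()
  unassigned <- setdiff(all_ids, assigned)
  stray <- unassigned[profile[unassigned] %in% profile[assigned]]
  if (length(stray))
    reasons <- c(reasons,
                 sprintf("sample '%s' shares the profile of an assigned group but is unassigned",
                         stray))
  if (!is.na(pert_key)) {
    chs <- chs_all[assigned]
    for (grp in list(ctrl = annotation$ctrl_ids, pert = annotation$pert_ids)) {
      vals <- value_set(chs_all[grp], pert_key)
      if (length(vals) > 1L)
        reasons <- c(reasons,
                     sprintf("group mixes %d distinct '%s' values (%s)",
                             length(vals), pert_key, paste(vals, collapse = ", ")))
    }
  }
  list(ok = length(reasons) == 0L, reasons = reasons)
}

# concatenated searchable text of one sample (title, source, characteristic
# values), lower case
sample_text <- function(sample, config) {
  ch <- normalize_characteristics(sample, config)$characteristics
  tolower(paste(c(sample$title, sample$source, unname(ch)), collapse = " "))
}

#' Criterion 3: correct perturbation assignment
#'
#' The perturbation must be real and point the right way: `pert_type` is a
#' valid type, `pert_name` is non-empty and appears (case-insensitive
#' substring, optionally via a synonym table) in the perturbation-group
#' sample texts, and the control group must not carry it as its value of the
#' designated perturbation key (direction).
#'
#' @inheritParams qc_criterion_alignment
#' @param synonyms optional named list mapping a pert_name to accepted
#'   synonym strings; matching stays exact-substring otherwise
#' @return list with `ok` and `reasons`
#' @export
qc_criterion_perturbation <- function(annotation, series,
                                      config = key_config(),
                                      pert_key = NULL, synonyms = NULL) {
  unknown <- check_ids_known(annotation, series)
  if (length(unknown))
    return(list(ok = FALSE,
                reasons = sprintf("unknown sample: %s",
                                  paste(unknown, collapse = ", "))))
  if (is.null(pert_key)) pert_key <- designate_pert_key(annotation, series, config)
  reasons <- character()
  if (!annotation$pert_type %in% PERT_TYPES)
    reasons <- c(reasons, sprintf("invalid pert_type '%s'", annotation$pert_type))
  name <- tolower(trim_collapse(annotation$pert_name))
  if (!nzchar(name)) {
    reasons <- c(reasons, "empty pert_name")
    return(list(ok = FALSE, reasons = reasons))
  }
  terms <- tolower(trim_collapse(c(annotation$pert_name,
                                   synonyms[[annotation$pert_name]])))
  pert_texts <- vapply(series$samples[annotation$pert_ids], sample_text,
                       character(1), config = config)
  found <- any(vapply(terms, function(t)
    any(grepl(t, pert_texts, fixed = TRUE)), logical(1)))
  if (!found)
    reasons <- c(reasons,
                 sprintf("pert_name '%s' not found in perturbation-group sample texts",
                         annotation$pert_name))
  if (!is.na(pert_key)) {
    ctrl_vals <- setdiff(value_set(chars_of(series, annotation$ctrl_ids, config),
                                   pert_key), ABSENT)
    carried <- any(vapply(terms, function(t)
      any(grepl(t, tolower(ctrl_vals), fixed = TRUE)), logical(1)))
    if (carried)
      reasons <- c(reasons,
                   sprintf("direction: control group carries '%s' as its '%s' value",
                           annotation$pert_name, pert_key))
  }
  list(ok = length(reasons) == 0L, reasons = reasons)
}

#' Rule-based quality control of one annotation
#'
#' Evaluates the three criteria — characteristic alignment (sex and age
#' ignored), grouping uniformity and correct perturbation assignment — and
#' returns `Success` exactly when all three hold. Deterministic and
#' idempotent; invariant to sample and key order.
#'
#' @inheritParams qc_criterion_perturbation
#' @return a [qc_verdict()] on channel `"rule"`
#' @export
run_rule_qc <- function(annotation, series, config = key_config(),
                        synonyms = NULL) {
  unknown <- check_ids_known(annotation, series)
  if (length(unknown)) {
    reason <- sprintf("unknown sample: %s", paste(unknown, collapse = ", "))
    return(qc_verdict(series$series_id, format(annotation), "rule",
                      alignment = FALSE, uniformity = FALSE,
                      perturbation = FALSE, reasons = reason,
                      round_index = annotation$round_index))
  }
  pk <- designate_pert_key(annotation, series, config)
  c1 <- qc_criterion_alignment(annotation, series, config, pert_key = pk)
  c2 <- qc_criterion_uniformity(annotation, series, config, pert_key = pk)
  c3 <- qc_criterion_perturbation(annotation, series, config, pert_key = pk,
                                  synonyms = synonyms)
  qc_verdict(series$series_id, format(annotation), "rule",
             alignment = c1$ok, uniformity = c2$ok, perturbation = c3$ok,
             reasons = c(c1$reasons, c2$reasons, c3$reasons),
             round_index = annotation$round_index)
}

#' LLM-channel quality control
#'
#' Sends the series metadata plus the annotation to the quality-controller
#' role and parses its structured verdict. With a [mock_backend()] the
#' response reproduces the rule verdict, with status flipped at the
#' backend's configured disagreement rate (one Bernoulli draw from the
#' backend's private stream per call) — this is the knob that lets the
#' consistency machinery be exercised at any target level.
#'
#' @inheritParams run_rule_qc
#' @param template a [prompt_template()] for role `quality_controller`
#' @param backend a backend object ([mock_backend()] or [live_backend()])
#' @return a [qc_verdict()] on channel `"llm"`
#' @export
run_llm_qc <- function(annotation, series, template, backend,
                       config = key_config(), synonyms = NULL) {
  payload <- list(series = series, annotation = annotation,
                  config = config, synonyms = synonyms)
  response <- complete(template, payload, backend)
  v <- parse_verdict_response(response, series, annotation)
  if (is.null(v)) {
    response <- complete(template, payload, backend)   # one re-prompt
    v <- parse_verdict_response(response, series, annotation)
  }
  if (is.null(v))
    v <- qc_verdict(series$series_id, format(annotation), "llm",
                    alignment = FALSE, uniformity = FALSE,
                    perturbation = FALSE, reasons = "unparseable",
                    round_index = annotation$round_index)
  v
}

parse_verdict_response <- function(text, series, annotation) {
  obj <- tryCatch(jsonlite::fromJSON(text, simplifyVector = TRUE),
                  error = function(e) NULL)
  need <- c("status", "alignment", "uniformity", "perturbation")
  if (is.null(obj) || !all(need %in% names(obj))) return(NULL)
  qc_verdict(series$series_id, format(annotation), "llm",
             alignment = isTRUE(obj$alignment),
             uniformity = isTRUE(obj$uniformity),
             perturbation = isTRUE(obj$perturbation),
             reasons = as.character(obj$reasons %||% character()),
             round_index = annotation$round_index)
}

#' Multi-round quality-control consensus
#'
#' Two agreeing verdicts settle the status. Two disagreeing verdicts demand
#' a third round; with three, the majority status wins. Reasons are
#' concatenated across the contributing verdicts.
#'
#' @param verdicts list of 2 or 3 [qc_verdict()] for the same annotation
#' @return a consensus [qc_verdict()] on the channel of the majority
#' @export
consensus_qc <- function(verdicts) {
  n <- length(verdicts)
  if (n < 2L)
    stop_gc("consensus requires at least 2 verdicts, got %d", n)
  statuses <- vapply(verdicts, `[[`, character(1), "status")
  if (n == 2L && statuses[1] != statuses[2])
    stop_gc("verdicts disagree (%s vs %s): a third quality-control round is required",
            statuses[1], statuses[2])
  status <- names(sort(table(statuses), decreasing = TRUE))[1]
  winners <- verdicts[statuses == status]
  crit <- if (status == "Success") {
    c(alignment = TRUE, uniformity = TRUE, perturbation = TRUE)
  } else {
    # a Fail consensus fails each criterion any contributing verdict failed
    Reduce(`&`, lapply(winners, function(v) !is.na(v$criteria) & v$criteria))
  }
  v <- winners[[1]]
  qc_verdict(v$series_id, v$annotation_id, v$channel,
             alignment = crit[["alignment"]],
             uniformity = crit[["uniformity"]],
             perturbation = crit[["perturbation"]],
             reasons = unique(unlist(lapply(verdicts, `[[`, "reasons"))),
             round_index = max(vapply(verdicts, `[[`, integer(1), "round_index")))
}

#' @export
as_json.gc_verdict <- function(x, ...) {
  jsonlite::toJSON(list(series_id = x$series_id,
                        annotation_id = x$annotation_id,
                        channel = x$channel, status = x$status,
                        alignment = x$criteria[["alignment"]],
                        uniformity = x$criteria[["uniformity"]],
                        perturbation = x$criteria[["perturbation"]],
                        reasons = as.list(x$reasons),
                        round_index = x$round_index),
                   auto_unbox = TRUE, na = "null", ...)
}

#' Serialize verdicts to a tab-separated table
#' @param verdicts list of [qc_verdict()]
#' @param path optional output path
#' @return a data.frame (written to `path` when given)
#' @export
verdicts_to_df <- function(verdicts, path = NULL) {
  df <- data.frame(
    series_id = vapply(verdicts, `[[`, character(1), "series_id"),
    annotation_id = vapply(verdicts, `[[`, character(1), "annotation_id"),
    channel = vapply(verdicts, `[[`, character(1), "channel"),
    status = vapply(verdicts, `[[`, character(1), "status"),
    alignment = vapply(verdicts, function(v) v$criteria[["alignment"]], logical(1)),
    uniformity = vapply(verdicts, function(v) v$criteria[["uniformity"]], logical(1)),
    perturbation = vapply(verdicts, function(v) v$criteria[["perturbation"]], logical(1)),
    round_index = vapply(verdicts, `[[`, integer(1), "round_index"),
    reasons = vapply(verdicts, function(v) paste(v$reasons, collapse = "; "), character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
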