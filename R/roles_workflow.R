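#' Annotate one series
#'
#' Sends the series (title, summary, overall design and per-sample
#' characteristics) to the annotator role and parses the structured
#' response. A series may contain several experimental designs, so zero or
#' more annotations come back. Responses that fail to parse are re-prompted
#' once, then recorded as failures — never raised — so one bad series cannot
#' abort a corpus run.
#'
#' @param series a [series_record()] (>= 2 samples)
#' @param template annotator [prompt_template()]
#' @param backend a backend
#' @param round_index annotation round recorded on the records
#' @return list with `annotations` (list of [annotation_record()]) and
#'   `failures` (list of parse failures)
#' @export
annotate_series <- function(series, template, backend, round_index = 1L) {
  if (length(series$samples) < 2L)
    stop_gc("series %s has fewer than 2 samples", series$series_id)
  tag <- sprintf("%s_v%d", template$role_name, template$version)
  parse_all <- function(response) {
    objs <- tryCatch(jsonlite::fromJSON(response, simplifyVector = FALSE),
                     error = function(e) NULL)
    if (is.null(objs) || !is.list(objs))
      return(list(annotations = list(),
                  failures = list(structure(
                    list(reason = "no JSON array found",
                         fragment = substr(response, 1, 200)),
                    class = "gc_parse_failure"))))
    annotations <- list()
    failures <- list()
    for (obj in objs) {
      rec <- annotation_from_fields(
        obj, series, annotator_tag = tag, round_index = round_index,
        failure = function(reason, fragment = "")
          structure(list(reason = reason,
                         fragment = substr(paste(fragment, collapse = " "), 1, 200)),
                    class = "gc_parse_failure"))
      if (is_parse_failure(rec)) failures[[length(failures) + 1L]] <- rec
      else annotations[[length(annotations) + 1L]] <- rec
    }
    list(annotations = annotations, failures = failures)
  }
  response <- tryCatch(complete(template, series, backend),
                       error = function(e)
                         stop_gc("backend error for series %s: %s",
                                 series$series_id, conditionMessage(e)))
  res <- parse_all(response)
  if (length(res$failures)) {
    # one re-prompt, then failures stand
    response2 <- complete(template, series, backend)
    res2 <- parse_all(response2)
    if (length(res2$failures) < length(res$failures)) res <- res2
  }
  res
}

#' Field-level discrepancy between an annotation and its gold counterpart
#' @keywords internal
discrepancy_row <- function(series_id, field, expected, observed) {
  data.frame(series_id = series_id, field = field,
             expected = as.character(expected),
             observed = as.character(observed),
             stringsAsFactors = FALSE)
}

empty_discrepancies <- function() {
  data.frame(series_id = character(), field = character(),
             expected = character(), observed = character(),
             stringsAsFactors = FALSE)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Check annotations against a gold standard
#'
#' The result-checker role: each annotation is paired with the gold record
#' maximizing the Jaccard similarity of its combined sample set (ties broken
#' by perturbation-name equality, then gold order), and one discrepancy is
#' emitted per differing field. A control/perturbation swap relative to gold
#' is one conceptual error and yields a single `grouping` discrepancy. Gold
#' records left unmatched (a design the annotator missed or merged) each
#' yield a `grouping` discrepancy. An empty result means full concordance.
#'
#' @param annotations list of [annotation_record()]
#' @param gold non-empty list of gold [annotation_record()]
#' @return data.frame with columns series_id, field, expected, observed
#' @export
check_against_gold <- function(annotations, gold) {
  if (!length(gold)) stop_gc("gold standard is empty")
  out <- empty_discrepancies()
  matched_gold <- rep(FALSE, length(gold))
  for (a in annotations) {
    sims <- vapply(gold, function(g)
      jaccard(annotation_samples(a), annotation_samples(g)), numeric(1))
    best <- which(sims == max(sims))
    if (length(best) > 1L) {
      name_eq <- vapply(gold[best], function(g)
        tolower(trim_collapse(g$pert_name)) == tolower(trim_collapse(a$pert_name)),
        logical(1))
      if (any(name_eq)) best <- best[name_eq]
    }
    best <- best[1]
    matched_gold[best] <- TRUE
    g <- gold[[best]]
    sid <- a$series_id
    if (setequal(a$ctrl_ids, g$pert_ids) && setequal(a$pert_ids, g$ctrl_ids)) {
      out <- rbind(out, discrepancy_row(sid, "grouping",
                                        "ctrl vs pert as in gold",
                                        "groups swapped"))
    } else {
      if (!setequal(a$ctrl_ids, g$ctrl_ids))
        out <- rbind(out, discrepancy_row(sid, "ctrl_ids",
                                          paste(g$ctrl_ids, collapse = "|"),
                                          paste(a$ctrl_ids, collapse = "|")))
      if (!setequal(a$pert_ids, g$pert_ids))
        out <- rbind(out, discrepancy_row(sid, "pert_ids",
                                          paste(g$pert_ids, collapse = "|"),
                                          paste(a$pert_ids, collapse = "|")))
    }
    if (a$pert_type != g$pert_type)
      out <- rbind(out, discrepancy_row(sid, "pert_type", g$pert_type, a$pert_type))
    if (tolower(trim_collapse(a$pert_name)) != tolower(trim_collapse(g$pert_name)))
      out <- rbind(out, discrepancy_row(sid, "pert_name", g$pert_name, a$pert_name))
    if (tolower(trim_collapse(a$cell_type)) != tolower(trim_collapse(g$cell_type)))
      out <- rbind(out, discrepancy_row(sid, "cell_type", g$cell_type, a$cell_type))
  }
  for (i in which(!matched_gold)) {
    g <- gold[[i]]
    out <- rbind(out, discrepancy_row(g$series_id, "grouping",
                                      format(g), "no matching annotation"))
  }
  out
}

#' Revise a template in response to discrepancies
#'
#' The prompt-optimizer role. The majority discrepancy field determines the
#' revision; the returned template has `version + 1`. With the mock
#' annotator the version bump activates the rule class addressing
#' grouping-type discrepancies (dose-aware splitting); with a live backend
#' the optimizer role proposes edited instruction text.
#'
#' @param template current [prompt_template()]
#' @param discrepancies non-empty data.frame from [check_against_gold()]
#' @param backend optional backend; when live, the optimizer role is asked
#'   for the revised instruction text
#' @return a new [prompt_template()] with version incremented by exactly 1
#' @export
optimize_prompt <- function(template, discrepancies, backend = NULL) {
  if (is.null(discrepancies) || nrow(discrepancies) == 0L)
    stop_gc("optimize_prompt requires a non-empty discrepancy set")
  majority <- names(sort(table(discrepancies$field), decreasing = TRUE))[1]
  hint <- switch(majority,
    grouping = ,
    ctrl_ids = ,
    pert_ids = "Split perturbation groups by each distinct value of the perturbation key (e.g. one group per dose); never merge distinct arms.",
    pert_name = "Report the perturbation name exactly as it appears in the sample characteristics, without qualifiers.",
    pert_type = "Classify the perturbation as drug, disease or gene from the characteristic key naming it.",
    cell_type = "Copy the cell type verbatim from the cell-class characteristic key.")
  instruction <- paste(template$instruction_text, hint)
  if (!is.null(backend) && backend$kind == "live") {
    opt_template <- prompt_template("prompt_optimizer")
    instruction <- complete(opt_template,
                            list(instruction = template$instruction_text,
                                 majority_field = majority,
                                 discrepancies = discrepancies),
                            backend)
  }
  prompt_template(template$role_name,
                  system_text = template$system_text,
                  instruction_text = instruction,
                  few_shot_examples = template$few_shot_examples,
                  version = template$version + 1L)
}

#' Train the optimal annotator against a gold standard
#'
#' The negative-feedback loop: annotate the training corpus, check against
#' gold, and when discrepancies remain let the prompt optimizer revise the
#' template; repeat until the discrepancy rate (total discrepancies per gold
#' record) drops to `target_rate` or `max_iters` optimizations have been
#' spent. The returned history records every iteration.
#'
#' @param corpus list of bundles, each with fields `series` and `gold`
#'   (as produced by [generate_corpus()])
#' @param template0 starting annotator template
#' @param backend a backend
#' @param max_iters maximum number of prompt optimizations (default 5)
#' @param target_rate stop when the discrepancy rate is at or below this
#'   (default 0)
#' @return object of class `gc_training_history`: fields `history`
#'   (data.frame iteration/version/n_discrepancies/rate), `converged`,
#'   `final_template`
#' @export
train_optimal_annotator <- function(corpus, template0, backend,
                                    max_iters = 5L, target_rate = 0) {
  if (!length(corpus)) stop_gc("training corpus is empty")
  if (max_iters < 0L) stop_gc("max_iters must be >= 0")
  template <- template0
  history <- data.frame(iteration = integer(), version = integer(),
                        n_discrepancies = integer(), rate = numeric())
  converged <- FALSE
  iteration <- 0L
  repeat {
    disc <- empty_discrepancies()
    n_gold <- 0L
    for (bundle in corpus) {
      res <- annotate_series(bundle$series, template, backend)
      disc <- rbind(disc, check_against_gold(res$annotations, bundle$gold))
      n_gold <- n_gold + length(bundle$gold)
    }
    rate <- nrow(disc) / n_gold
    history <- rbind(history,
                     data.frame(iteration = iteration,
                                version = template$version,
                                n_discrepancies = nrow(disc), rate = rate))
    if (rate <= target_rate) {
      converged <- TRUE
      break
    }
    if (iteration >= max_iters) break
    template <- optimize_prompt(template, disc, backend)
    iteration <- iteration + 1L
  }
  structure(list(history = history, converged = converged,
                 final_template = template),
            class = "gc_training_history")
}

#' Full annotation run with quality control
#'
#' The staged production pass: every series is annotated with the optimal
#' template (round 1) and every annotation goes through the configured
#' quality-control channels. When the two channels disagree, a second
#' annotation of the series is conducted and rule quality control of the
#' round-2 annotation supplies the third verdict; the majority decides
#' (exactly one re-annotation round). Unparseable responses are recorded as
#' `Fail` verdicts with reason "unparseable". Per-series failures are
#' logged and skipped; the run never aborts on one bad series. With the
#' mock backend and a fixed seed the whole report is byte-identical across
#' runs.
#'
#' @param corpus list of [series_record()] or of bundles with a `series`
#'   field (labels, when present, feed the error-cause report)
#' @param optimal trained annotator [prompt_template()]
#' @param backend a backend
#' @param qc_channels `c("rule", "llm")` (default) or `"rule"`
#' @param config a [key_config()]
#' @param synonyms optional perturbation-name synonym table
#' @return object of class `gc_run_report`: fields `annotations`,
#'   `verdicts` (data.frame), `final` (per-annotation consensus
#'   data.frame), `metrics` (a [metrics_report()]), `skipped`
#' @export
run_waterfall <- function(corpus, optimal, backend,
                          qc_channels = c("rule", "llm"),
                          config = key_config(), synonyms = NULL) {
  qc_channels <- match.arg(qc_channels, c("rule", "llm"), several.ok = TRUE)
  qc_template <- prompt_template("quality_controller")
  annotations <- list()
  verdicts <- list()
  final <- list()
  skipped <- list()
  labels <- character()       # annotation_id -> injected class
  pair_stats <- list()
  for (item in corpus) {
    bundle <- if (inherits(item, "gc_series")) list(series = item) else item
    series <- bundle$series
    res <- tryCatch(annotate_series(series, optimal, backend),
                    error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <- list(series_id = series$series_id,
                                              reason = conditionMessage(res))
      next
    }
    for (f in res$failures) {
      aid <- sprintf("%s:unparseable", series$series_id)
      v <- qc_verdict(series$series_id, aid, "rule", FALSE, FALSE, FALSE,
                      reasons = paste("unparseable:", f$reason))
      verdicts[[length(verdicts) + 1L]] <- v
      final[[length(final) + 1L]] <- list(series_id = series$series_id,
                                          annotation_id = aid,
                                          status = "Fail", rounds = 1L,
                                          channels_disagreed = FALSE)
    }
    for (a in res$annotations) {
      aid <- format(a)
      if (!is.null(bundle$labels))
        labels[aid] <- bundle$labels[1]
      rule1 <- run_rule_qc(a, series, config, synonyms)
      verdicts[[length(verdicts) + 1L]] <- rule1
      vlist <- list(rule1)
      disagreed <- FALSE
      rounds <- 1L
      if ("llm" %in% qc_channels) {
        llm1 <- run_llm_qc(a, series, qc_template, backend, config, synonyms)
        verdicts[[length(verdicts) + 1L]] <- llm1
        vlist <- c(vlist, list(llm1))
        pair_stats[[length(pair_stats) + 1L]] <-
          list(rule = rule1$status, llm = llm1$status)
        disagreed <- rule1$status != llm1$status
        if (disagreed) {
          res2 <- annotate_series(series, optimal, backend, round_index = 2L)
          rounds <- 2L
          third <- if (length(res2$annotations)) {
            a2 <- res2$annotations[[best_match_index(res2$annotations, a)]]
            run_rule_qc(a2, series, config, synonyms)
          } else {
            qc_verdict(series$series_id, aid, "rule", FALSE, FALSE, FALSE,
                       reasons = "unparseable re-annotation",
                       round_index = 2L)
          }
          if (length(res2$annotations)) {
            a2 <- res2$annotations[[best_match_index(res2$annotations, a)]]
            annotations[[length(annotations) + 1L]] <- a2
          }
          verdicts[[length(verdicts) + 1L]] <- third
          vlist <- c(vlist, list(third))
        }
      }
      cons <- consensus_qc(vlist)
      annotations[[length(annotations) + 1L]] <- a
      final[[length(final) + 1L]] <- list(series_id = series$series_id,
                                          annotation_id = aid,
                                          status = cons$status,
                                          rounds = rounds,
                                          channels_disagreed = disagreed)
    }
  }
  final_df <- do.call(rbind, c(list(data.frame(series_id = character(),
                                               annotation_id = character(),
                                               status = character(),
                                               rounds = integer(),
                                               channels_disagreed = logical())),
                               lapply(final, as.data.frame)))
  metrics <- run_metrics(final_df, pair_stats, verdicts, labels)
  structure(list(annotations = annotations,
                 verdicts = verdicts,
                 verdict_table = verdicts_to_df(verdicts),
                 final = final_df,
                 metrics = metrics,
                 skipped = skipped),
            class = "gc_run_report")
}

best_match_index <- function(annotations, target) {
  sims <- vapply(annotations, function(x)
    jaccard(annotation_samples(x), annotation_samples(target)), numeric(1))
  which.max(sims)
}

run_metrics <- function(final_df, pair_stats, verdicts, labels) {
  if (nrow(final_df) == 0L) {
    return(metrics_report(qcc = NA_real_, apr = NA_real_, dpr = NA_real_,
                          n_annotations = 0L, n_datasets = 0L,
                          per_round = data.frame(round_index = integer(),
                                                 n = integer(), apr = numeric()),
                          error_causes = list()))
  }
  qcc <- if (length(pair_stats)) {
    mean(vapply(pair_stats, function(p) p$rule == p$llm, logical(1)))
  } else NA_real_
  apr <- mean(final_df$status == "Success")
  dpr <- mean(vapply(split(final_df$status, final_df$series_id),
                     function(s) any(s == "Success"), logical(1)))
  rounds <- vapply(verdicts, `[[`, integer(1), "round_index")
  statuses <- vapply(verdicts, `[[`, character(1), "status")
  channels <- vapply(verdicts, `[[`, character(1), "channel")
  per_round <- do.call(rbind, lapply(sort(unique(rounds)), function(r) {
    sel <- rounds == r & channels == "rule"
    data.frame(round_index = r, n = sum(sel),
               apr = if (any(sel)) mean(statuses[sel] == "Success") else NA_real_)
  }))
  causes <- list()
  if (length(labels)) {
    fail_ids <- final_df$annotation_id[final_df$status == "Fail"]
    fl <- labels[intersect(names(labels), fail_ids)]
    fl <- fl[!is.na(fl) & fl != "clean"]
    causes <- as.list(table(fl))
  }
  metrics_report(qcc = qcc, apr = apr, dpr = dpr,
                 n_annotations = nrow(final_df),
                 n_datasets = length(unique(final_df$series_id)),
                 per_round = per_round, error_causes = causes)
}

#' @export
print.gc_run_report <- function(x, ...) {
  cat(sprintf("<run report> %d annotations over %d datasets\n",
              x$metrics$n_annotations, x$metrics$n_datasets))
  print(x$metrics)
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Stable, timestamp-free serialization: with the mock backend and a fixed
#' seed two runs of the same corpus produce byte-identical output.
#'
#' @param report a run report from [run_waterfall()]
#' @param path optional output path
#' @return JSON text
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(
    annotations = lapply(report$annotations, function(a)
      jsonlite::fromJSON(as_json(a), simplifyVector = FALSE)),
    verdicts = lapply(report$verdicts, function(v)
      jsonlite::fromJSON(as_json(v), simplifyVector = FALSE)),
    final = report$final,
    metrics = unclass(report$metrics),
    skipped = report$skipped)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                          dataframe = "rows")
  if (!is.null(path)) writeLines(txt, path)
  as.character(txt)
}
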