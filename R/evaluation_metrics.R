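#' Metrics report
#'
#' Container for the three run-level evaluation metrics — quality-control
#' consistency (QCC: agreement between two quality-control channels),
#' annotation pass rate (APR: fraction of annotations passing) and dataset
#' pass rate (DPR: fraction of datasets with at least one passing
#' annotation) — plus per-round breakdown, the manual-versus-automatic
#' cross-tabulation and error-cause counts.
#'
#' @param qcc,apr,dpr proportions in `[0, 1]` (NA when not measured)
#' @param n_annotations,n_datasets integers
#' @param per_round data.frame with columns round_index, n, apr
#' @param crosstab optional grade-by-status count table
#' @param error_causes named list of cause counts
#' @return object of class `gc_metrics`
#' @export
metrics_report <- function(qcc = NA_real_, apr = NA_real_, dpr = NA_real_,
                           n_annotations = 0L, n_datasets = 0L,
                           per_round = NULL, crosstab = NULL,
                           error_causes = list()) {
  structure(list(qcc = qcc, apr = apr, dpr = dpr,
                 n_annotations = as.integer(n_annotations),
                 n_datasets = as.integer(n_datasets),
                 per_round = per_round, crosstab = crosstab,
                 error_causes = error_causes),
            class = "gc_metrics")
}

#' @export
print.gc_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf("  QCC %s | APR %s | DPR %s (%d annotations, %d datasets)\n",
              fmt(x$qcc), fmt(x$apr), fmt(x$dpr),
              x$n_annotations, x$n_datasets))
  if (!is.null(x$per_round) && nrow(x$per_round)) {
    for (i in seq_len(nrow(x$per_round)))
      cat(sprintf("  round %d: n=%d APR=%s\n", x$per_round$round_index[i],
                  x$per_round$n[i], fmt(x$per_round$apr[i])))
  }
  if (length(x$error_causes)) {
    cat("  error causes:",
        paste(sprintf("%s=%d", names(x$error_causes),
                      unlist(x$error_causes)), collapse = ", "), "\n")
  }
  invisible(x)
}

verdict_status <- function(v) {
  if (inherits(v, "gc_verdict")) v$status else as.character(v)
}

#' Quality-control consistency (QCC)
#'
#' Proportion of annotation pairs whose two quality-control outcomes agree.
#' Consistency is judged on final status only, not per-criterion flags.
#'
#' @param pairs non-empty list of 2-element lists/pairs of [qc_verdict()]
#'   (or bare `"Success"`/`"Fail"` strings) referring to the same annotation
#' @return proportion in `[0, 1]`
#' @export
compute_qcc <- function(pairs) {
  if (!length(pairs)) stop_gc("QCC is undefined on an empty verdict set")
  mean(vapply(pairs, function(p) {
    if (length(p) != 2L) stop_gc("each QCC element must hold exactly 2 verdicts")
    verdict_status(p[[1]]) == verdict_status(p[[2]])
  }, logical(1)))
}

#' Annotation pass rate (APR)
#'
#' Proportion of annotations whose verdict is `Success`.
#'
#' @param verdicts non-empty list of [qc_verdict()] (or status strings)
#' @return proportion in `[0, 1]`
#' @export
compute_apr <- function(verdicts) {
  if (!length(verdicts)) stop_gc("APR is undefined on an empty verdict set")
  mean(vapply(verdicts, verdict_status, character(1)) == "Success")
}

#' Dataset pass rate (DPR)
#'
#' A dataset passes when it carries at least one annotation that conforms to
#' the quality standards; DPR is the fraction of datasets passing. When
#' every dataset holds exactly one annotation, DPR equals APR.
#'
#' @param by_dataset non-empty named list: dataset id -> list of verdicts
#'   (or status strings)
#' @return proportion in `[0, 1]`
#' @export
compute_dpr <- function(by_dataset) {
  if (!length(by_dataset)) stop_gc("DPR is undefined on an empty dataset set")
  mean(vapply(by_dataset, function(vs) {
    if (!length(vs)) stop_gc("DPR is undefined for a dataset with no verdicts")
    any(vapply(vs, verdict_status, character(1)) == "Success")
  }, logical(1)))
}

#' Cross-tabulate manual grades against automatic verdicts
#'
#' The manual-versus-automatic comparison: a 3x2 count table of
#' {Excellent, Moderate, Error} against {Success, Fail}, aligned by
#' annotation, plus the consistency summary. The agreement convention:
#' Excellent and Moderate agree with Success, Error agrees with Fail — a
#' Fail on a manually Error-graded annotation shows the controller
#' correctly identifying an incorrect grouping, so it counts as agreement.
#'
#' @param manual list of [manual_grade()]
#' @param auto list of [qc_verdict()] (or status strings), same length and
#'   order as `manual`
#' @return list with `crosstab` (3x2 table) and `consistency` (proportion)
#' @export
crosstab_grades <- function(manual, auto) {
  if (length(manual) != length(auto))
    stop_gc("manual grades (%d) and automatic verdicts (%d) differ in length",
            length(manual), length(auto))
  if (!length(manual)) stop_gc("cross-tabulation is undefined on empty input")
  grades <- vapply(manual, function(g)
    if (inherits(g, "gc_manual_grade")) g$grade else as.character(g),
    character(1))
  statuses <- vapply(auto, verdict_status, character(1))
  tab <- table(factor(grades, levels = c("Excellent", "Moderate", "Error")),
               factor(statuses, levels = c("Success", "Fail")))
  names(dimnames(tab)) <- c("manual", "automatic")
  agree <- (grades %in% c("Excellent", "Moderate") & statuses == "Success") |
    (grades == "Error" & statuses == "Fail")
  list(crosstab = tab, consistency = mean(agree))
}

#' Error-cause report for failed annotations
#'
#' Counts the injected error classes among failing annotations. Only
#' synthetic corpora carry labels; on unlabeled real data the report says so
#' instead of fabricating counts.
#'
#' @param verdicts list of [qc_verdict()] (or status strings)
#' @param labels character vector of generator labels aligned with
#'   `verdicts` (`"clean"` or a cause class), or NULL for real data
#' @return named list of counts per cause, or `list(unlabeled = TRUE)`
#' @export
error_cause_report <- function(verdicts, labels = NULL) {
  if (is.null(labels)) return(list(unlabeled = TRUE))
  if (length(labels) != length(verdicts))
    stop_gc("labels (%d) and verdicts (%d) differ in length",
            length(labels), length(verdicts))
  statuses <- vapply(verdicts, verdict_status, character(1))
  causes <- labels[statuses == "Fail" & labels != "clean"]
  if (!length(causes)) return(list())
  as.list(table(causes))
}

#' @export
as_json.gc_metrics <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, na = "null", digits = NA,
                   dataframe = "rows", ...)
}
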