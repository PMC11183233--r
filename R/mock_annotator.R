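#' Vocabulary of control-arm values
#'
#' First tokens (or whole values) that mark a sample as belonging to the
#' control arm of a design: vehicle/untreated/wild-type style labels.
#' @export
CONTROL_VOCAB <- c("vehicle", "control", "untreated", "none", "mock", "pbs",
                   "dmso", "wild type", "wildtype", "wt", "healthy",
                   "baseline", "sham", "placebo")

is_control_value <- function(values) {
  v <- tolower(trim_collapse(values))
  first <- vapply(strsplit(v, " ", fixed = TRUE), `[`, character(1), 1)
  v %in% CONTROL_VOCAB | first %in% CONTROL_VOCAB
}

# map a characteristic key name to a perturbation type
key_to_pert_type <- function(key) {
  k <- normalize_key(key)
  if (grepl("disease|diagnosis|condition|status", k)) return("disease")
  if (grepl("genotype|gene|knock|transfect|mutation", k)) return("gene")
  "drug"
}

#' Rule-based mock annotator
#'
#' Deterministic stand-in for the annotator roles: it reads the structured
#' characteristics (never the prose) and emits the JSON annotation array the
#' response schema demands. The rules:
#'
#' 1. Keys in the sex/age ignore class are dropped.
#' 2. A varying key with at least one control-vocabulary value
#'    ([CONTROL_VOCAB]) is a perturbation key; other varying keys stratify
#'    the series (e.g. two cell lines, each with its own vehicle arm).
#' 3. Within each stratum, control samples carry the control value and the
#'    rest are perturbed. At template version 0 all perturbed samples form
#'    one group (dose-blind); from version 1 on, perturbed samples are split
#'    per distinct perturbation-key value (dose-aware), so prompt
#'    optimization measurably changes behaviour.
#' 4. `pert_name` is the first whitespace token of the perturbation value;
#'    `cell_type` the value of the first cell-class key; `pert_type` is read
#'    off the perturbation key's name.
#'
#' A series with no perturbation key yields one deliberately degenerate
#' response (all samples in `pert_ids`) that downstream validation rejects,
#' exercising the quality-control failure path. The `inject` knob
#' reproduces labelled error classes: `"swap"` exchanges the two groups,
#' `"name_inconsistency"` corrupts the emitted name.
#'
#' @param series a [series_record()]
#' @param template a [prompt_template()] (its `version` gates rule 3)
#' @param config a [key_config()]
#' @param inject optional error class to reproduce
#' @return JSON text (array of annotation objects)
#' @export
mock_annotate <- function(series, template, config = key_config(),
                          inject = NULL) {
  chs <- chars_of(series, sample_ids(series), config)
  chs <- lapply(chs, function(ch) ch[!is_ignored_key(names(ch), config)])
  ids <- sample_ids(series)
  keys <- sorted_unique(unlist(lapply(chs, names), use.names = FALSE))
  vals_by_key <- lapply(keys, function(k)
    vapply(chs, function(ch) if (k %in% names(ch)) ch[[k]] else ABSENT,
           character(1)))
  names(vals_by_key) <- keys
  varying <- keys[vapply(vals_by_key, function(v) length(unique(v)) > 1, logical(1))]
  pert_keys <- varying[vapply(varying, function(k)
    any(is_control_value(vals_by_key[[k]])), logical(1))]
  strat_keys <- setdiff(varying, pert_keys)
  cell_key <- keys[key_class(keys, config) == "cell"][1]

  if (!length(pert_keys)) {
    degenerate <- list(list(ctrl_ids = list(), pert_ids = as.list(ids),
                            pert_type = "drug", pert_name = "",
                            cell_type = ""))
    return(as.character(jsonlite::toJSON(degenerate, auto_unbox = TRUE)))
  }

  strata <- if (length(strat_keys)) {
    split(ids, apply(do.call(cbind, vals_by_key[strat_keys]), 1,
                     paste, collapse = "\x1f"))
  } else list(all = ids)
  # a stratification that separates controls from perturbed samples is a
  # confounded design, not two experiments: fall back to a global split
  usable <- vapply(strata, function(sids) {
    any(vapply(pert_keys, function(k) {
      ctrl <- is_control_value(vals_by_key[[k]][sids])
      any(ctrl) && any(!ctrl)
    }, logical(1)))
  }, logical(1))
  if (!any(usable)) strata <- list(all = ids)

  out <- list()
  for (sids in strata) {
    for (k in pert_keys) {
      v <- vals_by_key[[k]][sids]
      ctrl <- sids[is_control_value(v)]
      pert <- sids[!is_control_value(v) & v != ABSENT]
      if (!length(ctrl) || !length(pert)) next
      cell <- if (!is.na(cell_key)) {
        cv <- unique(vals_by_key[[cell_key]][sids])
        if (length(cv) == 1L && cv != ABSENT) cv else ""
      } else ""
      groups <- if (template$version >= 1L) {
        split(pert, vals_by_key[[k]][pert])
      } else list(pert)
      for (g in groups) {
        pname <- strsplit(trim_collapse(vals_by_key[[k]][g[1]]), " ",
                          fixed = TRUE)[[1]][1]
        out[[length(out) + 1L]] <- list(
          ctrl_ids = as.list(sort(ctrl)), pert_ids = as.list(sort(g)),
          pert_type = key_to_pert_type(k), pert_name = pname,
          cell_type = cell)
      }
    }
  }
  if (!length(out)) {
    out <- list(list(ctrl_ids = list(), pert_ids = as.list(ids),
                     pert_type = "drug", pert_name = "", cell_type = ""))
  }
  if (!is.null(inject) && !is.na(inject)) {
    out <- lapply(out, function(a) {
      if (inject == "swap") {
        tmp <- a$ctrl_ids; a$ctrl_ids <- a$pert_ids; a$pert_ids <- tmp
      } else if (inject == "name_inconsistency") {
        a$pert_name <- paste0("zz-", a$pert_name, "-alt")
      }
      a
    })
  }
  as.character(jsonlite::toJSON(out, auto_unbox = TRUE))
}
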