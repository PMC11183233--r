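#' Annotator role names
#' @export
ROLE_NAMES <- c("original_annotator", "result_checker", "prompt_optimizer",
                "optimal_annotator", "quality_controller")

#' Prompt template for one role
#'
#' Every role is driven by a versioned template. Along an optimization
#' lineage the version strictly increases; with the mock backend the version
#' gates which annotation rules are active, so prompt optimization has a
#' measurable, deterministic effect on behaviour.
#'
#' @param role_name one of [ROLE_NAMES]
#' @param system_text,instruction_text the prompt body (free text)
#' @param few_shot_examples list of `list(input = , output = )` pairs
#' @param version integer >= 0
#' @return object of class `gc_template`
#' @export
prompt_template <- function(role_name,
                            system_text = default_system_text(role_name),
                            instruction_text = default_instruction_text(role_name),
                            few_shot_examples = list(),
                            version = 0L) {
  role_name <- match.arg(role_name, ROLE_NAMES)
  version <- as.integer(version)
  if (is.na(version) || version < 0L) stop_gc("version must be an integer >= 0")
  structure(list(role_name = role_name,
                 system_text = as.character(system_text),
                 instruction_text = as.character(instruction_text),
                 few_shot_examples = few_shot_examples,
                 version = version),
            class = "gc_template")
}

default_system_text <- function(role_name) {
  switch(role_name,
    original_annotator = "You are a biomedical curator extracting control/perturbation experimental designs from gene-expression series metadata.",
    optimal_annotator = "You are a trained biomedical curator extracting control/perturbation experimental designs from gene-expression series metadata.",
    result_checker = "You compare machine annotations against a gold standard and report field-level discrepancies.",
    prompt_optimizer = "You revise annotation instructions to address recurring discrepancy classes.",
    quality_controller = "You verify annotations against three criteria: characteristic alignment (sex/age ignored), grouping uniformity, correct perturbation assignment.")
}

default_instruction_text <- function(role_name) {
  switch(role_name,
    original_annotator = ,
    optimal_annotator = paste(
      "Given the series title, summary, overall design and per-sample",
      "characteristics, identify every control-versus-perturbation design.",
      "Answer ONLY with a JSON array of objects with fields ctrl_ids,",
      "pert_ids, pert_type (drug|disease|gene), pert_name, cell_type."),
    result_checker = "Answer with a JSON array of {field, expected, observed} objects.",
    prompt_optimizer = "Answer with revised instruction text addressing the majority discrepancy field.",
    quality_controller = paste(
      "Answer ONLY with a JSON object {status, alignment, uniformity,",
      "perturbation, reasons}."))
}

#' Deterministic mock backend
#'
#' A rule-based stand-in for a live language-model endpoint so the whole
#' pipeline runs offline and reproducibly. Annotation responses are a pure
#' function of the template version and the payload; quality-controller
#' responses reproduce the rule verdict with the status flipped at
#' `disagreement_rate` (one Bernoulli draw per call from a private stream
#' seeded at construction). `error_labels` is the error-injection knob: a
#' named vector `series_id -> class` making the annotator reproduce labelled
#' failure classes (`"swap"` exchanges the groups, `"name_inconsistency"`
#' corrupts the perturbation name) — with an empty knob the rules are the
#' only source of behaviour.
#'
#' @param seed integer seed for the backend's private stream
#' @param disagreement_rate probability that the mock quality-controller
#'   flips the rule status
#' @param error_labels named character vector, `series_id -> error class`
#' @param log_path optional JSONL path; every exchange is appended there
#' @return backend environment of class `gc_backend`
#' @export
mock_backend <- function(seed = 1L, disagreement_rate = 0,
                         error_labels = character(), log_path = NULL) {
  if (disagreement_rate < 0 || disagreement_rate > 1)
    stop_gc("disagreement_rate must lie in [0, 1]")
  env <- new.env(parent = emptyenv())
  env$kind <- "mock"
  env$seed <- as.integer(seed)
  env$disagreement_rate <- disagreement_rate
  env$error_labels <- error_labels
  env$log <- list()
  env$n_calls <- 0L
  env$rng_state <- NULL
  env$log_path <- log_path
  env$retry_limit <- 0L
  class(env) <- "gc_backend"
  env
}

#' Live backend configuration
#'
#' Contract for a real text-completion endpoint. The transport is injected
#' as a function `(template, payload, config) -> response text` so the
#' package itself never opens a connection; `complete()` retries transport
#' failures up to `retry_limit` before raising a backend error. Temperature
#' and seed are surfaced so deterministic settings can be pinned where the
#' API allows.
#'
#' @param transport function performing one request
#' @param endpoint,model informational strings recorded in the log
#' @param retry_limit how many retries after the first failed attempt
#' @param temperature,seed sampling controls passed to the transport
#' @param log_path optional JSONL path
#' @return backend environment of class `gc_backend`
#' @export
live_backend <- function(transport, endpoint = "", model = "",
                         retry_limit = 2L, temperature = 0, seed = 0L,
                         log_path = NULL) {
  if (!is.function(transport)) stop_gc("transport must be a function")
  env <- new.env(parent = emptyenv())
  env$kind <- "live"
  env$transport <- transport
  env$endpoint <- endpoint
  env$model <- model
  env$retry_limit <- as.integer(retry_limit)
  env$temperature <- temperature
  env$seed <- as.integer(seed)
  env$log <- list()
  env$n_calls <- 0L
  env$log_path <- log_path
  class(env) <- "gc_backend"
  env
}

#' Build a backend from a configuration file or list
#'
#' @param config path to a YAML/JSON file or a list with fields `kind`
#'   (`"mock"` or `"live"`), `seed`, `disagreement_rate`, `endpoint`,
#'   `model`, `retry_limit`, `log_path`
#' @param transport required for `kind = "live"`
#' @return a backend
#' @export
backend_from_config <- function(config, transport = NULL) {
  if (is.character(config))
    config <- yaml::read_yaml(config)
  kind <- config$kind %||% "mock"
  if (kind == "mock") {
    mock_backend(seed = config$seed %||% 1L,
                 disagreement_rate = config$disagreement_rate %||% 0,
                 log_path = config$log_path)
  } else if (kind == "live") {
    if (is.null(transport)) stop_gc("live backend requires a transport function")
    live_backend(transport, endpoint = config$endpoint %||% "",
                 model = config$model %||% "",
                 retry_limit = config$retry_limit %||% 2L,
                 temperature = config$temperature %||% 0,
                 seed = config$seed %||% 0L,
                 log_path = config$log_path)
  } else stop_gc("unknown backend kind '%s'", kind)
}

log_exchange <- function(backend, role_name, payload_digest, response,
                         parse_status = "n/a", retries = 0L) {
  backend$n_calls <- backend$n_calls + 1L
  entry <- list(call_index = backend$n_calls, role_name = role_name,
                payload_digest = payload_digest,
                response = response, parse_status = parse_status,
                retries = as.integer(retries))
  backend$log[[backend$n_calls]] <- entry
  if (!is.null(backend$log_path))
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
        file = backend$log_path, append = TRUE, sep = "")
  invisible(entry)
}

#' Role-conditioned completion
#'
#' Sends a payload to the backend under a role template and returns the raw
#' response text. Exactly one exchange-log entry is appended per call. The
#' mock backend is a pure function of (template version, payload, backend
#' seed) and never fails transport; the live backend retries up to its
#' retry limit and then raises a backend error.
#'
#' @param template a [prompt_template()]
#' @param payload structured input (role-dependent; see [annotate_series()],
#'   [run_llm_qc()])
#' @param backend a [mock_backend()] or [live_backend()]
#' @return raw response text
#' @export
complete <- function(template, payload, backend) {
  stopifnot(inherits(template, "gc_template"), inherits(backend, "gc_backend"))
  digest <- fnv1a32(payload_fingerprint(payload))
  if (backend$kind == "mock") {
    response <- mock_response(template, payload, backend)
    log_exchange(backend, template$role_name, digest, response)
    return(response)
  }
  attempts <- backend$retry_limit + 1L
  last_error <- NULL
  for (i in seq_len(attempts)) {
    response <- tryCatch(backend$transport(template, payload, backend),
                         error = function(e) {
                           last_error <<- conditionMessage(e)
                           NULL
                         })
    if (!is.null(response)) {
      log_exchange(backend, template$role_name, digest, response,
                   retries = i - 1L)
      return(response)
    }
  }
  log_exchange(backend, template$role_name, digest, "", "transport_failure",
               retries = attempts - 1L)
  stop_gc("backend error after %d attempt(s): %s", attempts, last_error)
}

payload_fingerprint <- function(payload) {
  if (inherits(payload, "gc_series")) return(as.character(as_json(payload)))
  if (is.list(payload)) {
    parts <- vapply(payload, function(p) {
      if (inherits(p, "gc_series") || inherits(p, "gc_annotation"))
        as.character(as_json(p))
      else paste(utils::capture.output(utils::str(p)), collapse = "")
    }, character(1))
    return(paste(parts, collapse = "|"))
  }
  paste(format(payload), collapse = "|")
}

mock_response <- function(template, payload, backend) {
  switch(template$role_name,
    original_annotator = ,
    optimal_annotator = {
      series <- if (inherits(payload, "gc_series")) payload else payload$series
      mock_annotate(series, template,
                    inject = unname(backend$error_labels[series$series_id]))
    },
    quality_controller = mock_qc_response(payload, backend),
    result_checker = "[]",
    prompt_optimizer = template$instruction_text)
}

mock_qc_response <- function(payload, backend) {
  rule <- run_rule_qc(payload$annotation, payload$series,
                      config = payload$config %||% key_config(),
                      synonyms = payload$synonyms)
  u <- with_private_rng(backend, backend$seed, stats::runif(1))
  flip <- u < backend$disagreement_rate
  status_ok <- (rule$status == "Success") != flip
  crit <- if (status_ok) c(TRUE, TRUE, TRUE)
          else if (flip) c(FALSE, rule$criteria[c("uniformity", "perturbation")])
          else rule$criteria
  jsonlite::toJSON(list(status = if (status_ok) "Success" else "Fail",
                        alignment = isTRUE(crit[[1]]),
                        uniformity = isTRUE(crit[[2]]),
                        perturbation = isTRUE(crit[[3]]),
                        reasons = as.list(if (flip) "mock disagreement"
                                          else rule$reasons)),
                   auto_unbox = TRUE)
}

#' Parse a structured annotation response
#'
#' All annotator roles must answer in a fixed JSON schema (an object with
#' fields `ctrl_ids`, `pert_ids`, `pert_type`, `pert_name`, `cell_type`).
#' This parser is total: on any input it returns either a validated
#' [annotation_record()] or a structured parse failure carrying the
#' offending fragment — it never raises, so one malformed response cannot
#' abort a corpus run.
#'
#' @param text raw response text containing one JSON object
#' @param series optional [series_record()]; enables identifier validation
#'   and fills `series_id`
#' @param annotator_tag,round_index bookkeeping carried into the record
#' @return an [annotation_record()] or an object of class
#'   `gc_parse_failure` with fields `reason` and `fragment`
#' @export
parse_annotation_response <- function(text, series = NULL,
                                      annotator_tag = "", round_index = 1L) {
  failure <- function(reason, fragment = text) {
    structure(list(reason = reason,
                   fragment = substr(paste(fragment, collapse = " "), 1, 200)),
              class = "gc_parse_failure")
  }
  if (!is.character(text) || length(text) != 1L || is.na(text))
    return(failure("response is not a single string", ""))
  start <- regexpr("{", text, fixed = TRUE)
  end <- max(gregexpr("}", text, fixed = TRUE)[[1]])
  if (start < 0 || end < 0 || end < start)
    return(failure("no JSON object found"))
  obj <- tryCatch(jsonlite::fromJSON(substr(text, start, end),
                                     simplifyVector = FALSE),
                  error = function(e) NULL)
  if (is.null(obj)) return(failure("invalid JSON"))
  annotation_from_fields(obj, series, annotator_tag, round_index,
                         failure = failure)
}

annotation_from_fields <- function(obj, series, annotator_tag, round_index,
                                   failure) {
  need <- c("ctrl_ids", "pert_ids", "pert_type", "pert_name", "cell_type")
  missing <- setdiff(need, names(obj))
  if (length(missing))
    return(failure(sprintf("missing required field(s): %s",
                           paste(missing, collapse = ", "))))
  ctrl <- unlist(obj$ctrl_ids, use.names = FALSE)
  pert <- unlist(obj$pert_ids, use.names = FALSE)
  if (length(intersect(ctrl, pert)))
    return(failure("overlapping groups"))
  if (!length(ctrl) || !length(pert))
    return(failure("empty group"))
  pt <- unlist(obj$pert_type, use.names = FALSE)
  if (!is.character(pt) || length(pt) != 1L || !pt %in% PERT_TYPES)
    return(failure(sprintf("unknown pert_type '%s'; allowed values: %s",
                           paste(pt, collapse = ","),
                           paste(PERT_TYPES, collapse = ", "))))
  rec <- tryCatch(
    annotation_record(series_id = if (!is.null(series)) series$series_id
                                  else as.character(obj$series_id %||% ""),
                      ctrl_ids = ctrl, pert_ids = pert,
                      pert_type = pt,
                      pert_name = paste(unlist(obj$pert_name), collapse = " "),
                      cell_type = paste(unlist(obj$cell_type), collapse = " "),
                      annotator_tag = annotator_tag,
                      round_index = round_index,
                      series = series),
    error = function(e) failure(conditionMessage(e)))
  rec
}

#' Is an object a parse failure?
#' @param x object returned by [parse_annotation_response()]
#' @export
is_parse_failure <- function(x) inherits(x, "gc_parse_failure")
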