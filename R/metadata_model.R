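#' Characteristic key classes
#'
#' GEO submitters spell sample characteristics freely ("Sex", "gender",
#' "age (years)" ...). Quality control ignores sex and age entirely, and the
#' annotator roles use cell-type keys to fill the `cell_type` field, so the
#' key classifier ships a configurable synonym list with sensible defaults.
#'
#' @param sex,age,cell character vectors of key spellings (compared after
#'   [normalize_key()]) belonging to each class
#' @return a named list of class `gc_key_config`
#' @export
#' @examples
#' key_class("Gender")            # "sex"
#' key_class("age (years)")       # "age"
#' key_class("tissue")            # "other"
key_config <- function(sex = c("sex", "gender"),
                       age = c("age", "age (years)", "age_yrs"),
                       cell = c("cell type", "cell line", "cell_line", "cell")) {
  structure(list(sex = normalize_key(sex),
                 age = normalize_key(age),
                 cell = normalize_key(cell)),
            class = "gc_key_config")
}

#' Normalize a characteristic key
#'
#' Case-fold, trim, and collapse internal whitespace. One deterministic rule
#' keeps quality control reproducible across free-text metadata.
#' @param key character vector
#' @return normalized character vector
#' @export
normalize_key <- function(key) {
  trim_collapse(tolower(key))
}

#' @describeIn key_config classify a key as "sex", "age", "cell" or "other"
#' @param key character vector of keys (raw or normalized)
#' @param config a [key_config()]
#' @export
key_class <- function(key, config = key_config()) {
  k <- normalize_key(key)
  out <- rep("other", length(k))
  out[k %in% config$sex] <- "sex"
  out[k %in% config$age] <- "age"
  out[k %in% config$cell] <- "cell"
  out
}

is_ignored_key <- function(key, config = key_config()) {
  key_class(key, config) %in% c("sex", "age")
}

#' Sample record
#'
#' One sample (GSM-style) of a series: identifier, descriptive text and an
#' ordered key/value characteristics mapping.
#'
#' @param sample_id unique identifier within the series (any non-empty token;
#'   GSM-style accessions are a convention, not validated)
#' @param title,organism,source,platform_id free-text fields
#' @param characteristics named character vector (ordered mapping)
#' @param raw character vector of unrecognized source lines, kept verbatim
#' @return object of class `gc_sample`
#' @export
sample_record <- function(sample_id, title = "", organism = "", source = "",
                          characteristics = character(), platform_id = "",
                          raw = character()) {
  sample_id <- as.character(sample_id)
  if (length(sample_id) != 1L || is.na(sample_id) || !nzchar(trimws(sample_id)))
    stop_gc("sample_id must be a single non-empty string")
  ch <- as.character(characteristics)
  names(ch) <- names(characteristics) %||% character(length(ch))
  if (length(ch) && anyDuplicated(names(ch)))
    stop_gc("duplicate characteristic keys in sample '%s'", sample_id)
  structure(list(sample_id = sample_id,
                 title = as.character(title),
                 organism = as.character(organism),
                 source = as.character(source),
                 characteristics = ch,
                 platform_id = as.character(platform_id),
                 raw = as.character(raw)),
            class = "gc_sample")
}

#' Normalize a sample's characteristics
#'
#' Keys are case-folded, trimmed and internally collapsed; values are trimmed
#' with whitespace runs collapsed. Keys colliding after normalization are
#' disambiguated with a numeric suffix so the mapping stays unique. The
#' operation is idempotent.
#'
#' @param sample a [sample_record()]
#' @param config a [key_config()] (classification is by normalized key, see
#'   [key_class()])
#' @return the sample with normalized characteristics
#' @export
normalize_characteristics <- function(sample, config = key_config()) {
  ch <- sample$characteristics
  if (length(ch)) {
    keys <- normalize_key(names(ch))
    keys <- make.unique(keys, sep = "_")
    vals <- trim_collapse(ch)
    names(vals) <- keys
    sample$characteristics <- vals
  }
  sample
}

#' Series record
#'
#' A study (GSE-style): identifying text plus its samples.
#'
#' @param series_id unique identifier
#' @param title,summary,overall_design free-text fields
#' @param samples list of [sample_record()] with unique identifiers
#' @param raw unrecognized source lines, kept verbatim
#' @return object of class `gc_series`
#' @export
series_record <- function(series_id, title = "", summary = "",
                          overall_design = "", samples = list(),
                          raw = character()) {
  series_id <- as.character(series_id)
  if (length(series_id) != 1L || !nzchar(trimws(series_id)))
    stop_gc("series_id must be a single non-empty string")
  if (!all(vapply(samples, inherits, logical(1), "gc_sample")))
    stop_gc("samples must all be sample_record objects")
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop_gc("duplicate sample id '%s' in series '%s'",
            ids[duplicated(ids)][1], series_id)
  names(samples) <- ids
  structure(list(series_id = series_id,
                 title = as.character(title),
                 summary = as.character(summary),
                 overall_design = as.character(overall_design),
                 samples = samples,
                 raw = as.character(raw)),
            class = "gc_series")
}

sample_ids <- function(series) names(series$samples)

#' Perturbation types recognized by the pipeline
#' @export
PERT_TYPES <- c("drug", "disease", "gene")

#' Annotation record
#'
#' One experimental-design call: which samples are controls, which carry the
#' perturbation, and what the perturbation is.
#'
#' @param series_id series the annotation refers to
#' @param ctrl_ids,pert_ids character vectors of sample identifiers; disjoint
#'   and each non-empty (stored sorted and de-duplicated)
#' @param pert_type one of `"drug"`, `"disease"`, `"gene"`
#' @param pert_name perturbation name (drug, disease or gene symbol)
#' @param cell_type cell type or line of the annotated samples
#' @param annotator_tag which role/round produced the call
#' @param round_index annotation round (>= 1; round 2 is the re-annotation of
#'   quality-control-inconsistent calls)
#' @param series optional [series_record()]; when given, all ids must exist
#'   in it
#' @return object of class `gc_annotation`
#' @export
annotation_record <- function(series_id, ctrl_ids, pert_ids, pert_type,
                              pert_name = "", cell_type = "",
                              annotator_tag = "", round_index = 1L,
                              series = NULL) {
  ctrl_ids <- sorted_unique(ctrl_ids)
  pert_ids <- sorted_unique(pert_ids)
  if (length(ctrl_ids) == 0L || length(pert_ids) == 0L)
    stop_gc("ctrl_ids and pert_ids must each be non-empty")
  overlap <- intersect(ctrl_ids, pert_ids)
  if (length(overlap))
    stop_gc("overlapping groups: %s in both ctrl_ids and pert_ids",
            paste(overlap, collapse = ", "))
  pert_type <- as.character(pert_type)
  if (length(pert_type) != 1L || !pert_type %in% PERT_TYPES)
    stop_gc("unknown pert_type '%s'; allowed values: %s",
            pert_type, paste(PERT_TYPES, collapse = ", "))
  if (!is.null(series)) {
    missing <- setdiff(c(ctrl_ids, pert_ids), sample_ids(series))
    if (length(missing))
      stop_gc("unknown sample id(s) in annotation for %s: %s",
              series$series_id, paste(missing, collapse = ", "))
  }
  round_index <- as.integer(round_index)
  if (is.na(round_index) || round_index < 1L)
    stop_gc("round_index must be an integer >= 1")
  structure(list(series_id = as.character(series_id),
                 ctrl_ids = ctrl_ids,
                 pert_ids = pert_ids,
                 pert_type = pert_type,
                 pert_name = as.character(pert_name),
                 cell_type = as.character(cell_type),
                 annotator_tag = as.character(annotator_tag),
                 round_index = round_index),
            class = "gc_annotation")
}

annotation_samples <- function(annotation) {
  c(annotation$ctrl_ids, annotation$pert_ids)
}

#' @export
print.gc_series <- function(x, ...) {
  cat(sprintf("<series %s> %s\n  %d samples\n",
              x$series_id, x$title, length(x$samples)))
  invisible(x)
}

#' @export
print.gc_annotation <- function(x, ...) {
  cat(sprintf("<annotation %s round %d> %s '%s' | ctrl: %s | pert: %s\n",
              x$series_id, x$round_index, x$pert_type, x$pert_name,
              paste(x$ctrl_ids, collapse = ","),
              paste(x$pert_ids, collapse = ",")))
  invisible(x)
}

#' @export
format.gc_annotation <- function(x, ...) {
  sprintf("%s:%s|%s", x$series_id,
          paste(x$ctrl_ids, collapse = ","),
          paste(x$pert_ids, collapse = ","))
}

annotation_equal <- function(a, b) {
  setequal(a$ctrl_ids, b$ctrl_ids) && setequal(a$pert_ids, b$pert_ids) &&
    a$pert_type == b$pert_type &&
    tolower(trim_collapse(a$pert_name)) == tolower(trim_collapse(b$pert_name)) &&
    tolower(trim_collapse(a$cell_type)) == tolower(trim_collapse(b$cell_type))
}

#' JSON serialization with stable field names
#'
#' @param x a series, sample, annotation, verdict or metrics object
#' @param ... passed to methods
#' @return a `json` string (jsonlite)
#' @export
as_json <- function(x, ...) UseMethod("as_json")

#' @export
as_json.gc_sample <- function(x, ...) {
  jsonlite::toJSON(list(sample_id = x$sample_id, title = x$title,
                        organism = x$organism, source = x$source,
                        characteristics = as.list(x$characteristics),
                        platform_id = x$platform_id),
                   auto_unbox = TRUE, ...)
}

#' @export
as_json.gc_series <- function(x, ...) {
  jsonlite::toJSON(list(series_id = x$series_id, title = x$title,
                        summary = x$summary,
                        overall_design = x$overall_design,
                        samples = lapply(unname(x$samples), function(s)
                          jsonlite::fromJSON(as_json(s), simplifyVector = FALSE))),
                   auto_unbox = TRUE, ...)
}

#' @export
as_json.gc_annotation <- function(x, ...) {
  jsonlite::toJSON(list(series_id = x$series_id,
                        ctrl_ids = as.list(x$ctrl_ids),
                        pert_ids = as.list(x$pert_ids),
                        pert_type = x$pert_type, pert_name = x$pert_name,
                        cell_type = x$cell_type,
                        annotator_tag = x$annotator_tag,
                        round_index = x$round_index),
                   auto_unbox = TRUE, ...)
}
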