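#' Read and write annotation tables
#'
#' Annotations travel as UTF-8 tab-separated tables with a header row and
#' pipe-separated identifier lists, the schema used by crowd-curated
#' signature collections: `series_id`, `ctrl_ids`, `pert_ids`, `pert_type`,
#' `cell_type`, `pert_name`, plus the bookkeeping columns `annotator_tag`
#' and `round_index`. `write_annotations()` followed by `read_annotations()`
#' reproduces the records exactly.
#'
#' @param path file path of the TSV
#' @return `read_annotations()`: a list of [annotation_record()];
#'   `write_annotations()`: the path, invisibly
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  required <- c("series_id", "ctrl_ids", "pert_ids", "pert_type",
                "cell_type", "pert_name")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_gc("annotation table %s lacks column(s): %s", path,
            paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$pert_type), PERT_TYPES)
  if (length(bad))
    stop_gc("unknown pert_type '%s'; allowed values: %s",
            bad[1], paste(PERT_TYPES, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    annotation_record(
      series_id = df$series_id[i],
      ctrl_ids = split_ids(df$ctrl_ids[i]),
      pert_ids = split_ids(df$pert_ids[i]),
      pert_type = df$pert_type[i],
      pert_name = df$pert_name[i],
      cell_type = df$cell_type[i],
      annotator_tag = if ("annotator_tag" %in% names(df)) df$annotator_tag[i] else "",
      round_index = if ("round_index" %in% names(df)) as.integer(df$round_index[i]) else 1L)
  })
}

#' @rdname read_annotations
#' @param records list of [annotation_record()]
#' @export
write_annotations <- function(records, path) {
  df <- annotations_to_df(records)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

annotations_to_df <- function(records) {
  data.frame(
    series_id = vapply(records, `[[`, character(1), "series_id"),
    ctrl_ids = vapply(records, function(r) paste(r$ctrl_ids, collapse = "|"), character(1)),
    pert_ids = vapply(records, function(r) paste(r$pert_ids, collapse = "|"), character(1)),
    pert_type = vapply(records, `[[`, character(1), "pert_type"),
    cell_type = vapply(records, `[[`, character(1), "cell_type"),
    pert_name = vapply(records, `[[`, character(1), "pert_name"),
    annotator_tag = vapply(records, `[[`, character(1), "annotator_tag"),
    round_index = vapply(records, `[[`, integer(1), "round_index"),
    stringsAsFactors = FALSE)
}

split_ids <- function(x) {
  out <- strsplit(x, "|", fixed = TRUE)[[1]]
  trimws(out[nzchar(trimws(out))])
}
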