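#' Read a series from SOFT-dialect text
#'
#' Line-oriented reader for the subset of GEO's SOFT family format the
#' annotator roles consume: one `^SERIES` block followed by `^SAMPLE` blocks,
#' with `!Series_*` / `!Sample_*` attribute lines. Characteristic lines of
#' the form `key: value` are split into the characteristics mapping; a
#' characteristic line without a colon becomes key `characteristic_<n>`.
#' Unrecognized lines are preserved verbatim in the owning block's `raw`
#' field so round-tripping loses nothing.
#'
#' @param text a single string or character vector of lines
#' @param normalize normalize characteristics on the way in (default TRUE)
#' @param config a [key_config()]
#' @return a [series_record()]
#' @export
parse_soft <- function(text, normalize = TRUE, config = key_config()) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  series <- NULL
  samples <- list()
  cur <- NULL          # current sample under construction (list)
  in_series <- FALSE
  n_anon <- 0L

  finish_sample <- function() {
    if (is.null(cur)) return()
    if (cur$sample_id %in% names(samples))
      stop_gc("line %d: duplicate sample id '%s'", cur$line, cur$sample_id)
    s <- sample_record(cur$sample_id, cur$title, cur$organism, cur$source,
                       cur$characteristics, cur$platform_id, cur$raw)
    if (normalize) s <- normalize_characteristics(s, config)
    samples[[s$sample_id]] <<- s
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    if (grepl("^\\^SERIES", line)) {
      if (in_series) stop_gc("line %d: second ^SERIES block", i)
      in_series <- TRUE
      series <- list(series_id = soft_value(line), title = "", summary = "",
                     overall_design = "", raw = character())
    } else if (grepl("^\\^SAMPLE", line)) {
      if (!in_series)
        stop_gc("line %d: sample block before series block", i)
      finish_sample()
      cur <- list(sample_id = soft_value(line), title = "", organism = "",
                  source = "", characteristics = character(),
                  platform_id = "", raw = character(), line = i)
      n_anon <- 0L
    } else if (!in_series) {
      stop_gc("line %d: attribute line before ^SERIES block", i)
    } else if (is.null(cur)) {
      # series attributes
      if (grepl("^!Series_title", line)) {
        series$title <- soft_value(line)
      } else if (grepl("^!Series_summary", line)) {
        series$summary <- paste_nonempty(series$summary, soft_value(line))
      } else if (grepl("^!Series_overall_design", line)) {
        series$overall_design <- paste_nonempty(series$overall_design,
                                                soft_value(line))
      } else {
        series$raw <- c(series$raw, line)
      }
    } else {
      if (grepl("^!Sample_title", line)) {
        cur$title <- soft_value(line)
      } else if (grepl("^!Sample_organism", line)) {
        cur$organism <- soft_value(line)
      } else if (grepl("^!Sample_source_name", line)) {
        cur$source <- soft_value(line)
      } else if (grepl("^!Sample_platform_id", line)) {
        cur$platform_id <- soft_value(line)
      } else if (grepl("^!Sample_characteristics", line)) {
        v <- soft_value(line)
        if (grepl(":", v, fixed = TRUE)) {
          key <- sub(":.*$", "", v)
          val <- sub("^[^:]*:", "", v)
        } else {
          n_anon <- n_anon + 1L
          key <- sprintf("characteristic_%d", n_anon)
          val <- v
        }
        if (trimws(key) %in% trimws(names(cur$characteristics)))
          cur$raw <- c(cur$raw, line)   # duplicate key: keep verbatim
        else {
          cur$characteristics[[trimws(key)]] <- trimws(val)
        }
      } else {
        cur$raw <- c(cur$raw, line)
      }
    }
  }
  if (!in_series) stop_gc("no ^SERIES block found")
  finish_sample()
  series_record(series$series_id, series$title, series$summary,
                series$overall_design, unname(samples), series$raw)
}

soft_value <- function(line) {
  trimws(sub("^[^=]*=", "", line))
}

paste_nonempty <- function(a, b) {
  if (!nzchar(a)) b else paste(a, b)
}

#' Serialize a series to SOFT-dialect text
#'
#' Inverse of [parse_soft()]: `parse_soft(write_soft(x))` reproduces `x`
#' field for field (characteristics assumed normalized).
#'
#' @param series a [series_record()]
#' @param path optional file path; when given the text is also written there
#' @return the SOFT text, invisibly when `path` is given
#' @export
write_soft <- function(series, path = NULL) {
  out <- c(sprintf("^SERIES = %s", series$series_id),
           sprintf("!Series_title = %s", series$title),
           sprintf("!Series_summary = %s", series$summary),
           sprintf("!Series_overall_design = %s", series$overall_design),
           series$raw)
  for (s in series$samples) {
    out <- c(out,
             sprintf("^SAMPLE = %s", s$sample_id),
             sprintf("!Sample_title = %s", s$title),
             sprintf("!Sample_organism_ch1 = %s", s$organism),
             sprintf("!Sample_source_name_ch1 = %s", s$source),
             sprintf("!Sample_platform_id = %s", s$platform_id),
             if (length(s$characteristics))
               sprintf("!Sample_characteristics_ch1 = %s: %s",
                       names(s$characteristics), s$characteristics),
             s$raw)
  }
  text <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(text))
  }
  text
}
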