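# Independent brute-force oracles. These re-derive every quantity with
# plain loops straight from the criterion definitions, sharing no logic
# with the package's rule engine beyond the exported normalization
# primitives.

oracle_value <- function(series, id, key) {
  ch <- normalize_characteristics(series$samples[[id]])$characteristics
  if (key %in% names(ch)) ch[[key]] else "<absent>"
}

oracle_keys <- function(series, ids) {
  keys <- character()
  for (id in ids) {
    ch <- normalize_characteristics(series$samples[[id]])$characteristics
    keys <- union(keys, names(ch))
  }
  sort(keys[!key_class(keys) %in% c("sex", "age")])
}

oracle_pert_key <- function(annotation, series) {
  ids <- c(annotation$ctrl_ids, annotation$pert_ids)
  keys <- oracle_keys(series, ids)
  name <- tolower(gsub("[[:space:]]+", " ", trimws(annotation$pert_name)))
  if (nzchar(name)) {
    for (k in keys) {            # keys are sorted: first hit wins
      for (id in ids) {
        v <- oracle_value(series, id, k)
        if (v != "<absent>" && grepl(name, tolower(v), fixed = TRUE))
          return(k)
      }
    }
  }
  separating <- character()
  for (k in keys) {
    cv <- unique(sapply(annotation$ctrl_ids, oracle_value,
                        series = series, key = k))
    pv <- unique(sapply(annotation$pert_ids, oracle_value,
                        series = series, key = k))
    if (length(intersect(cv, pv)) == 0) separating <- c(separating, k)
  }
  if (length(separating) == 1) separating else NA_character_
}

oracle_rule_qc <- function(annotation, series) {
  ids <- c(annotation$ctrl_ids, annotation$pert_ids)
  if (!all(ids %in% names(series$samples)))
    return(c(alignment = FALSE, uniformity = FALSE, perturbation = FALSE))
  pk <- oracle_pert_key(annotation, series)

  # criterion 1: every non-ignored key except the perturbation key shows
  # the same value set in both groups
  c1 <- TRUE
  for (k in oracle_keys(series, ids)) {
    if (!is.na(pk) && k == pk) next
    cv <- unique(sapply(annotation$ctrl_ids, oracle_value,
                        series = series, key = k))
    pv <- unique(sapply(annotation$pert_ids, oracle_value,
                        series = series, key = k))
    if (!(all(cv %in% pv) && all(pv %in% cv))) c1 <- FALSE
  }

  # criterion 2a: no unassigned sample shares the full non-ignored profile
  # of an assigned sample
  c2 <- TRUE
  all_keys <- oracle_keys(series, names(series$samples))
  prof <- function(id)
    paste(sapply(all_keys, oracle_value, series = series, id = id),
          collapse = "|")
  for (u in setdiff(names(series$samples), ids)) {
    for (a in ids) if (prof(u) == prof(a)) c2 <- FALSE
  }
  # criterion 2b: neither group mixes two values of the perturbation key
  if (!is.na(pk)) {
    for (grp in list(annotation$ctrl_ids, annotation$pert_ids)) {
      if (length(unique(sapply(grp, oracle_value,
                               series = series, key = pk))) > 1)
        c2 <- FALSE
    }
  }

  # criterion 3: valid type, name present in pert-group texts, direction
  name <- tolower(gsub("[[:space:]]+", " ", trimws(annotation$pert_name)))
  c3 <- annotation$pert_type %in% c("drug", "disease", "gene") &&
    nzchar(name)
  if (c3) {
    found <- FALSE
    for (id in annotation$pert_ids) {
      s <- series$samples[[id]]
      ch <- normalize_characteristics(s)$characteristics
      text <- tolower(paste(c(s$title, s$source, unname(ch)), collapse = " "))
      if (grepl(name, text, fixed = TRUE)) found <- TRUE
    }
    if (!found) c3 <- FALSE
    if (c3 && !is.na(pk)) {
      for (id in annotation$ctrl_ids) {
        v <- oracle_value(series, id, pk)
        if (v != "<absent>" && grepl(name, tolower(v), fixed = TRUE))
          c3 <- FALSE
      }
    }
  }
  c(alignment = c1, uniformity = c2, perturbation = c3)
}

# one-line counting oracles for the run metrics
oracle_qcc <- function(a, b) 1 - sum(a != b) / length(a)
oracle_apr <- function(status) sum(status == "Success") / length(status)
oracle_dpr <- function(status, dataset) {
  passed <- tapply(status == "Success", dataset, any)
  sum(passed) / length(passed)
}
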