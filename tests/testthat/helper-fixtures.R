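# Hand-built fixtures used across the suite.

make_sample_fx <- function(id, ..., title = id, source = "liver") {
  sample_record(id, title = title, organism = "Homo sapiens",
                source = source, characteristics = c(...),
                platform_id = "GPL1")
}

# minimal two-arm series: 2 vehicle controls, 2 imatinib-treated
two_arm_series <- function(sid = "GSE_T1", drug = "imatinib",
                           n_ctrl = 2, n_pert = 2) {
  samples <- c(
    lapply(seq_len(n_ctrl), function(i)
      make_sample_fx(sprintf("%s_C%d", sid, i),
                     treatment = "vehicle", tissue = "liver",
                     `cell line` = "K562",
                     title = sprintf("K562 control rep%d", i))),
    lapply(seq_len(n_pert), function(i)
      make_sample_fx(sprintf("%s_P%d", sid, i),
                     treatment = drug, tissue = "liver",
                     `cell line` = "K562",
                     title = sprintf("K562 %s treated rep%d", drug, i))))
  series_record(sid, title = sprintf("%s response", drug),
                summary = sprintf("%s vs vehicle", drug),
                overall_design = "treated vs control", samples = samples)
}

two_arm_gold <- function(series, drug = "imatinib") {
  ids <- names(series$samples)
  annotation_record(series$series_id,
                    ctrl_ids = grep("_C", ids, value = TRUE),
                    pert_ids = grep("_P", ids, value = TRUE),
                    pert_type = "drug", pert_name = drug,
                    cell_type = "K562", series = series)
}

# random series for oracle-equivalence sweeps: <= 6 samples, <= 4 keys
random_series <- function(sid, max_samples = 6, max_keys = 4) {
  key_pool <- c("treatment", "tissue", "genotype", "sex", "age", "dose")
  val_pool <- c("vehicle", "drugA", "drugA 10 mg", "drugB", "liver",
                "kidney", "wt", "ko", "male", "female", "10", "50")
  n <- sample(2:max_samples, 1)
  keys <- sample(key_pool, sample(1:max_keys, 1))
  samples <- lapply(seq_len(n), function(j) {
    ch <- vapply(keys, function(k) sample(val_pool, 1), character(1))
    # keys occasionally dropped to exercise the absent-value path
    keep <- runif(length(ch)) > 0.15
    if (!any(keep)) keep[1] <- TRUE
    sample_record(sprintf("%s_S%d", sid, j),
                  title = paste("sample", j, paste(ch[keep], collapse = " ")),
                  source = "x", characteristics = ch[keep])
  })
  series_record(sid, title = "random", summary = "random",
                overall_design = "random", samples = samples)
}

random_annotation <- function(series) {
  ids <- names(series$samples)
  n <- length(ids)
  n_ctrl <- sample(seq_len(n - 1), 1)
  perm <- sample(ids)
  ctrl <- perm[seq_len(n_ctrl)]
  rest <- setdiff(perm, ctrl)
  n_pert <- sample(seq_along(rest), 1)
  annotation_record(series$series_id, ctrl, rest[seq_len(n_pert)],
                    pert_type = sample(PERT_TYPES, 1),
                    pert_name = sample(c("drugA", "drugB", "ko", "absentX",
                                         ""), 1),
                    cell_type = "x")
}
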