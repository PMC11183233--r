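PERT_NAME_POOL <- c("alpharin", "betazol", "curcamab", "deltanib",
                    "epirubine", "foxitinib", "gammaron", "heliprex",
                    "ibexafen", "jandomycin", "kelarib", "lumestat",
                    "mirvanol", "neoptra", "orzafine", "pexilor",
                    "quandrel", "rubexin", "silvastat", "tovazix")
TISSUE_POOL <- c("liver", "lung", "kidney", "spleen", "cortex", "muscle",
                 "skin", "colon")
CELL_POOL <- c("HepG2", "A549", "K562", "MCF7", "HEK293", "Jurkat",
               "THP-1", "HeLa")
STRAIN_POOL <- c("c57bl/6", "balb/c", "sprague-dawley")

#' Injectable error classes of the synthetic corpus generator
#' @export
ERROR_CLASSES <- c("confounder", "swap", "name_inconsistency",
                   "multiple_disturbances", "age_difference")

#' Synthetic-corpus specification
#'
#' Defines the study conditions a generated corpus emulates: series with a
#' control arm and a perturbation arm, constant background characteristics
#' (tissue, cell line, strain) plus ignored sex/age keys, and labelled
#' error classes injected at the given rates. `age_difference` is a benign
#' class: it perturbs only sex/age metadata, which quality control expressly
#' ignores, so those bundles must still pass. `swap` exchanges the two
#' groups in the emitted gold annotation, exercising the direction check;
#' `confounder` plants a tissue difference between the groups;
#' `name_inconsistency` corrupts the annotated perturbation name;
#' `multiple_disturbances` adds a second varying treatment key.
#' `multi_design_rate` produces series holding two independent designs (two
#' cell lines, each with its own vehicle arm); `dose_rate` produces
#' three-arm dose series whose gold standard keeps the dose groups apart.
#'
#' @param n_series number of series
#' @param samples_per_group inclusive range for each group's size
#' @param error_rates named numeric vector over [ERROR_CLASSES] (missing
#'   classes default to 0); each in `[0, 1]`
#' @param multi_design_rate,dose_rate proportions of two-design and
#'   three-arm dose series
#' @param name_pool,tissue_pool,cell_pool perturbation-name and background
#'   vocabularies
#' @param seed mandatory integer seed
#' @return object of class `gc_corpus_spec`
#' @export
corpus_spec <- function(n_series, samples_per_group = c(2L, 4L),
                        error_rates = numeric(), multi_design_rate = 0,
                        dose_rate = 0, name_pool = PERT_NAME_POOL,
                        tissue_pool = TISSUE_POOL, cell_pool = CELL_POOL,
                        seed) {
  if (missing(seed)) stop_gc("a corpus seed is mandatory")
  rates <- stats::setNames(numeric(length(ERROR_CLASSES)), ERROR_CLASSES)
  if (length(error_rates)) {
    unknown <- setdiff(names(error_rates), ERROR_CLASSES)
    if (length(unknown))
      stop_gc("unknown error class(es): %s", paste(unknown, collapse = ", "))
    rates[names(error_rates)] <- error_rates
  }
  if (any(rates < 0 | rates > 1) || multi_design_rate < 0 || dose_rate < 0)
    stop_gc("rates must lie in [0, 1]")
  total <- sum(rates) + multi_design_rate + dose_rate
  if (total > 1)
    stop_gc("error, multi-design and dose rates sum to %.2f > 1: no clean series remain",
            total)
  structure(list(n_series = as.integer(n_series),
                 samples_per_group = as.integer(samples_per_group),
                 error_rates = rates,
                 multi_design_rate = multi_design_rate,
                 dose_rate = dose_rate,
                 name_pool = name_pool, tissue_pool = tissue_pool,
                 cell_pool = cell_pool, seed = as.integer(seed)),
            class = "gc_corpus_spec")
}

pert_key_name <- function(pert_type) {
  switch(pert_type, drug = "treatment", disease = "disease state",
         gene = "genotype")
}

ctrl_value_for <- function(pert_type) {
  switch(pert_type, drug = "vehicle", disease = "healthy",
         gene = "wild type")
}

make_sample <- function(sid, j, group, chars, cell, tissue, pert_name) {
  label <- if (group == "ctrl") "control"
           else sprintf("%s treated", pert_name)
  sample_record(
    sample_id = sprintf("%s_GSM%02d", sid, j),
    title = sprintf("%s %s rep%d", cell, label, j),
    organism = "Homo sapiens",
    source = tissue,
    characteristics = chars,
    platform_id = "GPL570")
}

#' Generate a labelled synthetic corpus
#'
#' Deterministic given the spec's seed. Each bundle carries the series, its
#' gold annotations, one label per gold annotation (`"clean"` or the
#' injected class) and the scenario name; every label corresponds to an
#' actual edit of the series or gold, so rule quality-control failures on a
#' generated corpus are exactly the non-benign injections.
#'
#' @param spec a [corpus_spec()]
#' @return list of bundles (class `gc_bundle`): fields `series`, `gold`,
#'   `labels`, `scenario`
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "gc_corpus_spec"))
  set.seed(spec$seed)
  scenarios <- c(names(spec$error_rates), "multi_design", "dose", "clean")
  probs <- c(spec$error_rates, spec$multi_design_rate, spec$dose_rate,
             1 - sum(spec$error_rates) - spec$multi_design_rate - spec$dose_rate)
  lapply(seq_len(spec$n_series), function(i) {
    scenario <- sample(scenarios, 1, prob = probs)
    generate_bundle(spec, sprintf("SYN%04d", i), scenario)
  })
}

generate_bundle <- function(spec, sid, scenario) {
  rng_int <- function(lo, hi) {
    # sample() on a length-1 vector would draw from 1:x
    if (lo >= hi) return(lo)
    sample(seq.int(lo, hi), 1)
  }
  grp_n <- function() rng_int(spec$samples_per_group[1], spec$samples_per_group[2])
  pert_type <- sample(PERT_TYPES, 1, prob = c(0.6, 0.2, 0.2))
  key <- pert_key_name(pert_type)
  ctrl_val <- ctrl_value_for(pert_type)
  pert_name <- sample(spec$name_pool, 1)
  tissue <- sample(spec$tissue_pool, 1)
  cell <- sample(spec$cell_pool, 1)
  strain <- sample(STRAIN_POOL, 1)
  base_age <- "8 weeks"

  base_chars <- function(treat_val, age = base_age) {
    c(stats::setNames(treat_val, key),
      tissue = tissue, `cell line` = cell, strain = strain,
      sex = sample(c("male", "female"), 1), age = age)
  }

  if (scenario == "multi_design") {
    cell2 <- sample(setdiff(spec$cell_pool, cell), 1)
    name2 <- sample(setdiff(spec$name_pool, pert_name), 1)
    samples <- list(); gold_sets <- list()
    j <- 0L
    for (d in 1:2) {
      dcell <- c(cell, cell2)[d]
      dname <- c(pert_name, name2)[d]
      ctrl_ids <- character(); pert_ids <- character()
      for (g in seq_len(grp_n())) {
        j <- j + 1L
        ch <- base_chars(ctrl_val); ch[["cell line"]] <- dcell
        s <- make_sample(sid, j, "ctrl", ch, dcell, tissue, dname)
        samples[[length(samples) + 1L]] <- s
        ctrl_ids <- c(ctrl_ids, s$sample_id)
      }
      for (g in seq_len(grp_n())) {
        j <- j + 1L
        ch <- base_chars(dname); ch[["cell line"]] <- dcell
        s <- make_sample(sid, j, "pert", ch, dcell, tissue, dname)
        samples[[length(samples) + 1L]] <- s
        pert_ids <- c(pert_ids, s$sample_id)
      }
      gold_sets[[d]] <- list(ctrl = ctrl_ids, pert = pert_ids,
                             name = dname, cell = dcell)
    }
    series <- build_series(sid, samples, pert_name, tissue,
                           "two independent perturbation designs")
    gold <- lapply(gold_sets, function(g)
      annotation_record(sid, g$ctrl, g$pert, pert_type, g$name, g$cell,
                        annotator_tag = "gold", series = series))
    return(bundle(series, gold, rep("clean", 2L), scenario))
  }

  if (scenario == "dose") {
    doses <- c("10 mg", "50 mg")
    samples <- list(); j <- 0L
    ctrl_ids <- character()
    for (g in seq_len(grp_n())) {
      j <- j + 1L
      s <- make_sample(sid, j, "ctrl", base_chars(ctrl_val), cell, tissue,
                       pert_name)
      samples[[length(samples) + 1L]] <- s
      ctrl_ids <- c(ctrl_ids, s$sample_id)
    }
    dose_ids <- lapply(doses, function(d) {
      ids <- character()
      for (g in seq_len(grp_n())) {
        j <<- j + 1L
        s <- make_sample(sid, j, "pert",
                         base_chars(sprintf("%s %s", pert_name, d)),
                         cell, tissue, pert_name)
        samples[[length(samples) + 1L]] <<- s
        ids <- c(ids, s$sample_id)
      }
      ids
    })
    series <- build_series(sid, samples, pert_name, tissue,
                           "dose-response design with a shared vehicle arm")
    gold <- lapply(dose_ids, function(ids)
      annotation_record(sid, ctrl_ids, ids, pert_type, pert_name, cell,
                        annotator_tag = "gold", series = series))
    return(bundle(series, gold, rep("clean", 2L), scenario))
  }

  # single-design scenarios
  n_ctrl <- grp_n(); n_pert <- grp_n()
  samples <- list(); ctrl_ids <- character(); pert_ids <- character()
  j <- 0L
  for (g in seq_len(n_ctrl)) {
    j <- j + 1L
    ch <- base_chars(ctrl_val)
    if (scenario == "multiple_disturbances") ch[["co-treatment"]] <- "none"
    s <- make_sample(sid, j, "ctrl", ch, cell, tissue, pert_name)
    samples[[length(samples) + 1L]] <- s
    ctrl_ids <- c(ctrl_ids, s$sample_id)
  }
  conf_tissue <- sample(setdiff(spec$tissue_pool, tissue), 1)
  co_name <- sample(setdiff(spec$name_pool, pert_name), 1)
  for (g in seq_len(n_pert)) {
    j <- j + 1L
    age <- if (scenario == "age_difference") "52 weeks" else base_age
    ch <- base_chars(pert_name, age = age)
    if (scenario == "confounder") ch[["tissue"]] <- conf_tissue
    if (scenario == "multiple_disturbances") ch[["co-treatment"]] <- co_name
    s <- make_sample(sid, j, "pert", ch, cell,
                     if (scenario == "confounder") conf_tissue else tissue,
                     pert_name)
    samples[[length(samples) + 1L]] <- s
    pert_ids <- c(pert_ids, s$sample_id)
  }
  series <- build_series(sid, samples, pert_name, tissue,
                         sprintf("%d control vs %d %s-perturbed samples",
                                 n_ctrl, n_pert, pert_name))
  annotated_name <- if (scenario == "name_inconsistency")
    paste0("zz-", pert_name, "-alt") else pert_name
  gold <- list(
    if (scenario == "swap")
      annotation_record(sid, ctrl_ids = pert_ids, pert_ids = ctrl_ids,
                        pert_type = pert_type, pert_name = annotated_name,
                        cell_type = cell, annotator_tag = "gold",
                        series = series)
    else
      annotation_record(sid, ctrl_ids, pert_ids, pert_type, annotated_name,
                        cell, annotator_tag = "gold", series = series))
  label <- if (scenario == "clean") "clean" else scenario
  bundle(series, gold, label, scenario)
}

bundle <- function(series, gold, labels, scenario) {
  structure(list(series = series, gold = gold,
                 labels = as.character(labels), scenario = scenario),
            class = "gc_bundle")
}

build_series <- function(sid, samples, pert_name, tissue, design) {
  series_record(
    sid,
    title = sprintf("Transcriptional response to %s in %s", pert_name, tissue),
    summary = sprintf(
      "Expression profiling of %s-perturbed versus control samples in %s tissue.",
      pert_name, tissue),
    overall_design = design,
    samples = samples)
}

#' Generate an expression matrix with planted effects
#'
#' Gaussian log-scale (or negative-binomial count) matrix over the bundle's
#' samples, with per-gene effects added to the perturbation group of the
#' bundle's first gold annotation. Passing a shared or negated
#' `effect_vector` across bundles plants similar or opposing signature
#' relationships for connectivity tests.
#'
#' @param bundle a generated bundle with at least one gold annotation
#' @param n_genes number of genes
#' @param n_de number of differentially expressed genes (ignored when
#'   `effect_vector` is given)
#' @param effect_size log2 effect for the differential genes
#' @param noise_sd residual standard deviation on the log scale
#' @param effect_vector optional full per-gene effect vector to reuse
#' @param negate negate the effect vector (plants an opposing pair)
#' @param scale `"log_intensity"` (Gaussian) or `"counts"`
#'   (negative binomial on the exponentiated mean)
#' @param seed mandatory integer seed
#' @return list with `matrix` (an [expression_matrix()]) and
#'   `effect_vector`
#' @export
generate_expression <- function(bundle, n_genes = 500L, n_de = 50L,
                                effect_size = 1, noise_sd = 1,
                                effect_vector = NULL, negate = FALSE,
                                scale = c("log_intensity", "counts"),
                                seed) {
  if (missing(seed)) stop_gc("an expression seed is mandatory")
  scale <- match.arg(scale)
  if (!length(bundle$gold)) stop_gc("bundle has no gold annotation")
  set.seed(seed)
  ann <- bundle$gold[[1]]
  ids <- sample_ids(bundle$series)
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (is.null(effect_vector)) {
    effect_vector <- stats::setNames(numeric(n_genes), genes)
    de <- sample.int(n_genes, min(n_de, n_genes))
    effect_vector[de] <- effect_size * sample(c(-1, 1), length(de),
                                              replace = TRUE)
  } else {
    stopifnot(length(effect_vector) == n_genes)
    names(effect_vector) <- genes
  }
  eff <- if (negate) -effect_vector else effect_vector
  baseline <- stats::rnorm(n_genes, mean = 7, sd = 1)
  m <- matrix(stats::rnorm(n_genes * length(ids), sd = noise_sd),
              nrow = n_genes,
              dimnames = list(genes, ids))
  m <- m + baseline
  m[, ann$pert_ids] <- m[, ann$pert_ids] + eff
  if (scale == "counts") {
    mu <- 2^m
    m <- matrix(stats::rnbinom(length(mu), mu = mu, size = 20),
                nrow = n_genes, dimnames = dimnames(mu))
  }
  list(matrix = expression_matrix(m, scale = scale),
       effect_vector = eff)
}

#' Write a corpus to disk
#'
#' Emits one SOFT-dialect file per series plus a combined gold TSV and a
#' labels TSV.
#'
#' @param corpus list of bundles from [generate_corpus()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gold <- list(); labels <- list()
  for (b in corpus) {
    write_soft(b$series, file.path(dir, paste0(b$series$series_id, ".soft")))
    gold <- c(gold, b$gold)
    labels[[length(labels) + 1L]] <- data.frame(
      series_id = b$series$series_id,
      annotation_id = vapply(b$gold, format, character(1)),
      label = b$labels, scenario = b$scenario,
      stringsAsFactors = FALSE)
  }
  write_annotations(gold, file.path(dir, "gold.tsv"))
  utils::write.table(do.call(rbind, labels), file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a corpus directory written by [write_corpus()]
#' @param dir corpus directory
#' @return list with `series` (list of series), `gold`, `labels`
#' @export
read_corpus <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.soft$", full.names = TRUE))
  series <- lapply(files, function(f)
    parse_soft(paste(readLines(f), collapse = "\n")))
  gold_path <- file.path(dir, "gold.tsv")
  labels_path <- file.path(dir, "labels.tsv")
  list(series = series,
       gold = if (file.exists(gold_path)) read_annotations(gold_path) else NULL,
       labels = if (file.exists(labels_path))
         utils::read.delim(labels_path, stringsAsFactors = FALSE) else NULL)
}
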