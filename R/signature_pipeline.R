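#' Expression matrix
#'
#' Genes-by-samples numeric matrix with a declared scale. Counts must be
#' non-negative; log-intensity values are taken as already normalized.
#'
#' @param values numeric matrix, rows = genes, columns = samples
#' @param genes,samples identifiers (default: dimnames of `values`)
#' @param scale `"log_intensity"` or `"counts"`
#' @return object of class `gc_expression`
#' @export
expression_matrix <- function(values, genes = rownames(values),
                              samples = colnames(values),
                              scale = c("log_intensity", "counts")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(genes) || is.null(samples))
    stop_gc("gene and sample identifiers are required")
  if (anyDuplicated(genes)) stop_gc("duplicate gene identifiers")
  if (anyDuplicated(samples)) stop_gc("duplicate sample identifiers")
  if (nrow(values) != length(genes) || ncol(values) != length(samples))
    stop_gc("values must be a %d x %d matrix", length(genes), length(samples))
  if (scale == "counts" && any(values < 0))
    stop_gc("counts must be non-negative")
  dimnames(values) <- list(genes, samples)
  structure(list(values = values, genes = as.character(genes),
                 samples = as.character(samples), scale = scale),
            class = "gc_expression")
}

#' Read/write an expression matrix as TSV
#'
#' Gene rows, sample columns, first column `gene`.
#' @param path file path
#' @param scale declared scale of the stored values
#' @return an [expression_matrix()]
#' @export
read_expression <- function(path, scale = c("log_intensity", "counts")) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, scale = match.arg(scale))
}

#' @rdname read_expression
#' @param x an [expression_matrix()]
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = x$genes, x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Differential-expression signature
#'
#' Signed per-gene statistics summarizing a perturbation's transcriptomic
#' effect, labelled by perturbation and series.
#'
#' @param statistic named numeric vector (gene -> signed statistic)
#' @param label perturbation label (conventionally `pert_name@series_id`)
#' @param n_ctrl,n_pert group sizes behind the statistic
#' @return object of class `gc_signature`
#' @export
gene_signature <- function(statistic, label = "", n_ctrl = NA_integer_,
                           n_pert = NA_integer_) {
  if (is.null(names(statistic)) || anyDuplicated(names(statistic)))
    stop_gc("statistic must be a named vector with unique gene names")
  if (any(!is.finite(statistic)))
    stop_gc("statistic must be finite for every gene")
  structure(list(statistic = statistic, label = as.character(label),
                 n_ctrl = as.integer(n_ctrl), n_pert = as.integer(n_pert)),
            class = "gc_signature")
}

#' Compute a perturbation signature from an annotation
#'
#' One standardized procedure for both microarray and RNA-seq: counts are
#' library-size normalized to counts-per-million and transformed as
#' `log2(x + 1)`; log-intensity values are used as-is. The per-gene
#' statistic is the Welch t-statistic of perturbation versus control on the
#' log scale. Genes whose variance is zero in both groups carry no usable
#' contrast and are dropped.
#'
#' @param matrix an [expression_matrix()]
#' @param annotation a quality-passed [annotation_record()]; both groups
#'   need >= 2 samples present in the matrix
#' @return a [gene_signature()]
#' @export
compute_signature <- function(matrix, annotation) {
  ctrl <- intersect(annotation$ctrl_ids, matrix$samples)
  pert <- intersect(annotation$pert_ids, matrix$samples)
  if (length(ctrl) < 2L || length(pert) < 2L)
    stop_gc("insufficient replicates: %d control and %d perturbation samples in the matrix",
            length(ctrl), length(pert))
  v <- matrix$values
  if (matrix$scale == "counts") {
    cpm <- t(t(v) / pmax(colSums(v), 1)) * 1e6
    v <- log2(cpm + 1)
  }
  x <- v[, ctrl, drop = FALSE]
  y <- v[, pert, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  keep <- v1 > 0 | v2 > 0
  se <- sqrt(v1[keep] / n1 + v2[keep] / n2)
  stat <- (m2[keep] - m1[keep]) / se
  gene_signature(stat,
            label = sprintf("%s@%s", annotation$pert_name, annotation$series_id),
            n_ctrl = n1, n_pert = n2)
}

#' Connectivity between two signatures
#'
#' Spearman rank correlation over the union of each signature's `n_top`
#' strongest-|statistic| genes, restricted to genes the two signatures
#' share. Rank correlation is robust to the scale differences between
#' platforms (microarray intensity versus RNA-seq counts). The p-value
#' comes from permuting the target's gene labels `n_perm` times
#' (two-sided, with the +1 correction); the direction is `similar` for a
#' positive correlation and `opposing` otherwise.
#'
#' @param query,target [gene_signature()] objects sharing >= 10 genes
#' @param n_top genes taken from each signature by |statistic| (default 250)
#' @param n_perm permutation draws (default 10000)
#' @param seed mandatory integer seed for the permutations
#' @return object of class `gc_connectivity`: fields `query`, `target`,
#'   `correlation`, `p_value`, `direction`, `n_genes`
#' @export
connectivity <- function(query, target, n_top = 250L, n_perm = 10000L,
                         seed) {
  if (missing(seed)) stop_gc("a permutation seed is required")
  shared <- intersect(names(query$statistic), names(target$statistic))
  if (length(shared) < 10L)
    stop_gc("signatures share only %d genes (>= 10 required)", length(shared))
  m <- length(shared)
  k <- min(n_top, m)
  q_all <- query$statistic[shared]
  t_all <- target$statistic[shared]
  top_q <- order(abs(q_all), decreasing = TRUE)[seq_len(k)]
  # the statistic is recomputed in full (selection + correlation) for every
  # permutation of the target's gene labels, so the p-value is exact under
  # label exchangeability
  stat_fun <- function(t_vec) {
    top_t <- order(abs(t_vec), decreasing = TRUE)[seq_len(k)]
    sel <- union(top_q, top_t)
    stats::cor(rank(q_all[sel]), rank(t_vec[sel]))  # Pearson on ranks = Spearman
  }
  rho <- stat_fun(t_all)
  n <- length(union(top_q, order(abs(t_all), decreasing = TRUE)[seq_len(k)]))
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i)
    stat_fun(t_all[sample.int(m)]), numeric(1))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
  structure(list(query = query$label, target = target$label,
                 correlation = rho, p_value = p,
                 direction = if (rho > 0) "similar" else "opposing",
                 n_genes = n),
            class = "gc_connectivity")
}

#' Rank a signature library for repurposing candidates
#'
#' Connectivity of the query against every library member,
#' Benjamini-Hochberg q-values across the library, sorted by correlation
#' (most similar first; the strongest opposing — repurposing — candidates
#' sit at the bottom). Library members sharing fewer than 10 genes with the
#' query are skipped with a warning and are absent from the result.
#'
#' @param query a [gene_signature()]
#' @param library non-empty list of [gene_signature()]
#' @param n_top,n_perm,seed as in [connectivity()]
#' @return data.frame with columns query, target, correlation, p_value,
#'   q_value, direction, n_genes
#' @export
rank_repurposing <- function(query, library, n_top = 250L, n_perm = 10000L,
                             seed) {
  if (!length(library)) stop_gc("signature library is empty")
  if (missing(seed)) stop_gc("a permutation seed is required")
  rows <- list()
  for (i in seq_along(library)) {
    res <- tryCatch(connectivity(query, library[[i]], n_top, n_perm,
                                 seed = seed + i),
                    error = function(e) {
                      warning(sprintf("skipping library member %d (%s): %s",
                                      i, library[[i]]$label,
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
    if (!is.null(res))
      rows[[length(rows) + 1L]] <- data.frame(
        query = res$query, target = res$target,
        correlation = res$correlation, p_value = res$p_value,
        direction = res$direction, n_genes = res$n_genes,
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(query = character(), target = character(),
                      correlation = numeric(), p_value = numeric(),
                      q_value = numeric(), direction = character(),
                      n_genes = integer()))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$correlation, decreasing = TRUE),
      c("query", "target", "correlation", "p_value", "q_value",
        "direction", "n_genes")]
}
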