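planted_bundle <- function(seed = 1) {
  generate_corpus(corpus_spec(1, samples_per_group = c(3L, 3L),
                              seed = seed))[[1]]
}

test_that("compute_signature drops flat genes and finds planted effects", {
  b <- planted_bundle()
  gx <- generate_expression(b, n_genes = 100, n_de = 10, effect_size = 2,
                            noise_sd = 0.1, seed = 5)
  m <- gx$matrix
  # make one gene exactly constant in both groups
  m$values["g0100", ] <- 3.14
  sig <- compute_signature(m, b$gold[[1]])
  expect_false("g0100" %in% names(sig$statistic))
  up <- names(gx$effect_vector)[gx$effect_vector > 0]
  down <- names(gx$effect_vector)[gx$effect_vector < 0]
  expect_true(all(sig$statistic[up] > 0))
  expect_true(all(sig$statistic[down] < 0))

  # swapping group labels negates every statistic
  ann <- b$gold[[1]]
  rev_ann <- annotation_record(ann$series_id, ann$pert_ids, ann$ctrl_ids,
                               ann$pert_type, ann$pert_name, ann$cell_type)
  sig_rev <- compute_signature(m, rev_ann)
  expect_equal(sig_rev$statistic, -sig$statistic[names(sig_rev$statistic)])
})

test_that("counts are normalized to CPM and log-transformed before testing", {
  b <- planted_bundle(2)
  gx <- generate_expression(b, n_genes = 60, n_de = 10, effect_size = 2,
                            noise_sd = 0.2, scale = "counts", seed = 9)
  sig <- compute_signature(gx$matrix, b$gold[[1]])
  up <- names(gx$effect_vector)[gx$effect_vector > 0]
  expect_gt(mean(sig$statistic[up]), 0)
  expect_error(compute_signature(gx$matrix,
                                 annotation_record(b$series$series_id,
                                                   b$gold[[1]]$ctrl_ids[1],
                                                   b$gold[[1]]$pert_ids,
                                                   "drug", "x")),
               "insufficient replicates")
})

test_that("connectivity is exactly +/-1 on identity and negation", {
  set.seed(4)
  s <- gene_signature(stats::setNames(rnorm(100), sprintf("g%03d", 1:100)),
                      label = "q")
  neg <- gene_signature(-s$statistic, label = "neg")
  c_id <- connectivity(s, s, n_top = 50, n_perm = 100, seed = 1)
  expect_equal(c_id$correlation, 1.0)
  expect_equal(c_id$direction, "similar")
  c_neg <- connectivity(s, neg, n_top = 50, n_perm = 100, seed = 1)
  expect_equal(c_neg$correlation, -1.0)
  expect_equal(c_neg$direction, "opposing")
  tiny <- gene_signature(stats::setNames(rnorm(5), sprintf("g%03d", 1:5)))
  expect_error(connectivity(s, tiny, seed = 1), "share only")
})

test_that("connectivity is invariant to positive rescaling (rank-based)", {
  set.seed(8)
  a <- gene_signature(stats::setNames(rnorm(200), sprintf("g%03d", 1:200)))
  b <- gene_signature(stats::setNames(rnorm(200), sprintf("g%03d", 1:200)))
  c1 <- connectivity(a, b, n_top = 100, n_perm = 50, seed = 2)
  a2 <- gene_signature(a$statistic * 1000)
  c2 <- connectivity(a2, b, n_top = 100, n_perm = 50, seed = 2)
  expect_equal(c2$correlation, c1$correlation)
  expect_equal(c2$p_value, c1$p_value)
})

test_that("rank_repurposing ranks the query first and flags planted opposites", {
  b1 <- planted_bundle(3)
  gx1 <- generate_expression(b1, n_genes = 200, n_de = 40, effect_size = 2,
                             noise_sd = 0.3, seed = 11)
  query <- compute_signature(gx1$matrix, b1$gold[[1]])
  # planted opposing partner: same effect vector, negated
  b2 <- planted_bundle(4)
  gx2 <- generate_expression(b2, n_genes = 200,
                             effect_vector = gx1$effect_vector,
                             negate = TRUE, noise_sd = 0.3, seed = 12)
  opposing <- compute_signature(gx2$matrix, b2$gold[[1]])
  # unrelated member
  b3 <- planted_bundle(5)
  gx3 <- generate_expression(b3, n_genes = 200, n_de = 40, effect_size = 2,
                             noise_sd = 0.3, seed = 13)
  unrelated <- compute_signature(gx3$matrix, b3$gold[[1]])

  res <- rank_repurposing(query, list(query, opposing, unrelated),
                          n_top = 100, n_perm = 200, seed = 3)
  expect_equal(res$target[1], query$label)
  expect_equal(res$correlation[1], 1.0)
  expect_equal(res$target[nrow(res)], opposing$label)
  expect_lt(res$correlation[nrow(res)], 0)
  expect_equal(res$direction[nrow(res)], "opposing")
  # BH q-values are monotone in p-value rank
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))

  # members with too little overlap are skipped with a warning
  stranger <- gene_signature(stats::setNames(rnorm(20),
                                             sprintf("x%03d", 1:20)))
  expect_warning(res2 <- rank_repurposing(query, list(query, stranger),
                                          n_perm = 50, seed = 3),
                 "skipping")
  expect_equal(nrow(res2), 1)
})
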