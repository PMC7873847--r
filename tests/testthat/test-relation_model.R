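test_that("smoothed MLE conditionals match hand arithmetic on a 4-doc toy", {
  M <- matrix(c(1, 1, 0, 0,   # feature x
                1, 1, 0, 0),  # target y
              ncol = 2, dimnames = list(NULL, c("CB01", "CT01")))
  mat <- as_tbkg_matrix(M, node_types = c("biomarker", "tumor"))
  fit <- fit_nb(mat, "CT01", "biomarker", alpha = 1)
  expect_equal(fit$conditionals$p_present, 3 / 4)
  expect_equal(fit$conditionals$p_absent, 1 / 4)
  expect_equal(fit$prior, 0.5)
  expect_equal(importance(fit, "CB01")$importance, log2(3))
})

test_that("alpha = 0 reproduces the pure MLE and zero probabilities are rejected only there", {
  M <- matrix(c(0, 0, 1, 0,
                1, 1, 0, 0),
              ncol = 2, dimnames = list(NULL, c("CB01", "CT01")))
  mat <- as_tbkg_matrix(M, node_types = c("biomarker", "tumor"))
  raw <- fit_nb(mat, "CT01", "biomarker", alpha = 0)
  expect_equal(raw$conditionals$p_present, 0)     # never co-occurs with y=1
  expect_equal(raw$conditionals$p_absent, 1 / 2)
  expect_error(importance(raw, "CB01"), class = "tbkg_undefined_error")
  smoothed <- fit_nb(mat, "CT01", "biomarker", alpha = 1)
  expect_gt(smoothed$conditionals$p_present, 0)
  expect_silent(importance(smoothed, "CB01"))
})

test_that("a target never present is a degenerate-target error", {
  M <- matrix(c(1, 0, 0, 0), ncol = 2,
              dimnames = list(NULL, c("CB01", "CT01")))
  mat <- as_tbkg_matrix(M, node_types = c("biomarker", "tumor"))
  expect_error(fit_nb(mat, "CT01", "biomarker"),
               class = "tbkg_degenerate_error")
})

test_that("fitted conditionals equal the exhaustive counting oracle on random small corpora", {
  set.seed(123)
  for (rep in 1:20) {
    n <- sample(4:50, 1)
    M <- matrix(rbinom(n * 4, 1, runif(1, 0.2, 0.7)), nrow = n,
                dimnames = list(NULL, c("CB01", "CB02", "CT01", "CT02")))
    if (sum(M[, "CT01"]) == 0) M[1, "CT01"] <- 1
    mat <- as_tbkg_matrix(M, c("biomarker", "biomarker", "tumor", "tumor"))
    alpha <- sample(c(1, 2, 0.5), 1)
    fit <- fit_nb(mat, "CT01", "biomarker", alpha = alpha)
    for (f in c("CB01", "CB02")) {
      oracle <- oracle_conditionals(M, "CT01", f, alpha)
      row <- fit$conditionals[fit$conditionals$concept_id == f, ]
      expect_equal(row$p_present, oracle$p_present)
      expect_equal(row$p_absent, oracle$p_absent)
      expect_equal(importance(fit, f)$importance,
                   log2(oracle$p_present) - log2(oracle$p_absent))
    }
  }
})

test_that("importance is zero at equal conditionals and monotone in both arguments", {
  expect_equal(importance_value(0.2, 0.2), 0)
  grid <- expand.grid(p1 = seq(0.05, 0.95, by = 0.15),
                      p0 = seq(0.05, 0.95, by = 0.15))
  expect_equal(importance_value(grid$p1, grid$p1), rep(0, nrow(grid)))
  # strictly increasing in p_present, strictly decreasing in p_absent
  for (i in seq_len(nrow(grid))) {
    v <- importance_value(grid$p1[i], grid$p0[i])
    expect_gt(importance_value(grid$p1[i] + 0.02, grid$p0[i]), v)
    expect_lt(importance_value(grid$p1[i], grid$p0[i] + 0.02), v)
  }
  expect_error(importance_value(0, 0.1), class = "tbkg_undefined_error")
})

test_that("discover_relations respects thresholds and deterministic ordering", {
  g <- generate_graph(seed = 31)
  sim <- generate_corpus(g, n_docs = 400, seed = 32)
  rel_all <- discover_relations(sim$matrix, c("tumor", "biomarker"),
                                threshold = -Inf)
  n_t <- sum(sim$matrix$entities$node_type == "tumor")
  n_b <- sum(sim$matrix$entities$node_type == "biomarker")
  expect_equal(nrow(rel_all), n_t * n_b)
  expect_equal(nrow(discover_relations(sim$matrix, c("tumor", "biomarker"),
                                       threshold = Inf)), 0L)
  expect_true(all(diff(rel_all$importance) <= 0))
  # same-type pair is rejected
  expect_error(discover_relations(sim$matrix, c("tumor", "tumor")),
               class = "tbkg_validation_error")
  # rerunning gives identical output (no hidden state)
  expect_identical(rel_all,
                   discover_relations(sim$matrix, c("tumor", "biomarker"),
                                      threshold = -Inf))
})

test_that("cross-validation is perfect on separable data and chance-level on noise", {
  # noiseless: feature == target in every document
  y <- rep(c(1, 0), each = 30)
  M <- cbind(CB01 = y, CT01 = y)
  mat <- as_tbkg_matrix(M, c("biomarker", "tumor"))
  res <- cross_validate(mat, "tumor", "biomarker", k = 3, seed = 1)
  expect_equal(res$accuracy, 1.0)

  # independent balanced labels: accuracy near 1/2
  set.seed(99)
  n <- 2000
  M0 <- cbind(matrix(rbinom(n * 5, 1, 0.5), n,
                     dimnames = list(NULL, sprintf("CB%02d", 1:5))),
              CT01 = rbinom(n, 1, 0.5))
  mat0 <- as_tbkg_matrix(M0, c(rep("biomarker", 5), "tumor"))
  res0 <- cross_validate(mat0, "tumor", "biomarker", k = 3, seed = 2)
  expect_lt(abs(res0$accuracy - 0.5), 0.05)
})

test_that("cross-validation is invariant to document order under the same seed", {
  g <- generate_graph(seed = 41)
  sim <- generate_corpus(g, n_docs = 300, seed = 42)
  mat <- sim$matrix
  res1 <- cross_validate(mat, "tumor", "biomarker", k = 3, seed = 7)
  perm <- sample(length(mat$docs))
  shuf <- tbkg:::new_tbkg_matrix(mat$docs[perm], mat$entities,
                                 mat$incidence[perm, , drop = FALSE], 1L)
  res2 <- cross_validate(shuf, "tumor", "biomarker", k = 3, seed = 7)
  expect_equal(res1$accuracy, res2$accuracy)
  # too many folds for the corpus is a configuration error
  tiny <- as_tbkg_matrix(matrix(c(1, 0, 1, 1), 2, 2,
                                dimnames = list(NULL, c("CB01", "CT01"))),
                         c("biomarker", "tumor"))
  expect_error(cross_validate(tiny, "tumor", "biomarker", k = 3),
               class = "tbkg_config_error")
})

test_that("estimated importance converges to the planted value", {
  g <- generate_graph(seed = 55)
  imp_true <- log2(0.3 / 0.03)
  err_for <- function(n) {
    sim <- generate_corpus(g, n_docs = n, seed = 56)
    errs <- vapply(seq_len(nrow(g$edges)), function(i) {
      fit <- fit_nb(sim$matrix, g$edges$parent[i],
                    g$nodes$node_type[match(g$edges$child[i],
                                            g$nodes$concept_id)])
      abs(importance(fit, g$edges$child[i])$importance - imp_true)
    }, numeric(1))
    mean(errs)
  }
  e400 <- err_for(400)
  e5000 <- err_for(5000)
  expect_lt(e5000, e400)   # error shrinks with corpus size
  expect_lt(e5000, 0.2)    # and is small at n = 5000
})
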