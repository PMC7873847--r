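test_that("co-occurrence ranking matches hand counts and brute-force intersections", {
  M <- matrix(c(1, 1, 1,    # CD01 in all three docs
                1, 1, 0,    # CA01 with it twice
                1, 0, 0),   # CA02 once
              nrow = 3,
              dimnames = list(NULL, c("CD01", "CA01", "CA02")))
  mat <- as_tbkg_matrix(M, c("drug", "adr", "adr"))
  r <- cooccurrence_rank(mat, c("drug", "adr"))
  expect_equal(r$target_id, c("CA01", "CA02"))
  expect_equal(r$count, c(2L, 1L))
  # disjoint entities -> all zero
  M0 <- matrix(c(1, 0, 0, 1), 2,
               dimnames = list(NULL, c("CD01", "CA01")))
  r0 <- cooccurrence_rank(as_tbkg_matrix(M0, c("drug", "adr")),
                          c("drug", "adr"))
  expect_equal(r0$count, 0L)
  # brute-force oracle on random corpora, and document-order invariance
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    R <- matrix(rbinom(n * 4, 1, 0.4), n,
                dimnames = list(NULL, c("CD01", "CD02", "CA01", "CA02")))
    mat <- as_tbkg_matrix(R, c("drug", "drug", "adr", "adr"))
    r <- cooccurrence_rank(mat, c("drug", "adr"))
    for (i in seq_len(nrow(r))) {
      docs_a <- which(R[, r$source_id[i]] == 1)
      docs_b <- which(R[, r$target_id[i]] == 1)
      expect_equal(r$count[i], length(intersect(docs_a, docs_b)))
    }
    shuf <- as_tbkg_matrix(R[sample(n), , drop = FALSE],
                           c("drug", "drug", "adr", "adr"))
    expect_equal(cooccurrence_rank(shuf, c("drug", "adr")), r)
  }
})

test_that("agreement statistics match closed forms and an independent implementation", {
  perfect <- agreement(confusion_table(40, 0, 0, 40))
  expect_equal(perfect$kappa, 1.0)
  expect_equal(perfect$sensitivity, 1.0)
  expect_equal(perfect$specificity, 1.0)

  mid <- agreement(confusion_table(30, 10, 10, 30))
  expect_equal(mid$kappa, 0.5)
  expect_equal(mid$sensitivity, 0.75)
  expect_equal(mid$specificity, 0.75)
  expect_equal(mid$p_observed, 0.75)
  expect_equal(mid$p_expected, 0.5)

  skip_if_not_installed("e1071")
  set.seed(3)
  for (rep in 1:10) {
    cells <- rmultinom(1, 200, runif(4, 0.05, 1))
    tab <- confusion_table(cells[1], cells[2], cells[3], cells[4])
    ours <- tryCatch(agreement(tab), error = function(e) NULL)
    if (is.null(ours)) next
    ref <- e1071::classAgreement(matrix(cells, 2, 2, byrow = TRUE))
    expect_equal(ours$kappa, ref$kappa, tolerance = 1e-12)
  }
})

test_that("kappa is near zero for random labels with matched margins", {
  set.seed(17)
  n <- 1000
  gold <- rep(c(TRUE, FALSE), c(300, 700))
  model <- sample(gold)          # same margin, random assignment
  tab <- confusion_table(sum(model & gold), sum(model & !gold),
                         sum(!model & gold), sum(!model & !gold))
  expect_lt(abs(agreement(tab)$kappa), 0.1)
})

test_that("agreement errors name the undefined statistic", {
  expect_error(agreement(confusion_table(0, 10, 0, 10)),
               regexp = "sensitivity")
  expect_error(agreement(confusion_table(10, 0, 10, 0)),
               regexp = "specificity")
  expect_error(confusion_table(0, 0, 0, 0), class = "tbkg_validation_error")
  expect_error(confusion_table(-1, 2, 3, 4), class = "tbkg_validation_error")
})

labeled_findings <- function(important, unlikely, middle = character(0)) {
  adr <- c(important, middle, unlikely)
  f <- data.frame(drug = "CD1", adr = adr,
                  direct_importance = NA_real_, path_support = NA_real_,
                  n_paths = 0L, score = rev(seq_along(adr)),
                  rank = seq_along(adr),
                  label = c(rep("important", length(important)),
                            rep("unlabeled", length(middle)),
                            rep("unlikely", length(unlikely))),
                  stringsAsFactors = FALSE)
  class(f) <- c("tbkg_findings", "data.frame")
  f
}

test_that("gold-standard evaluation builds the extremes-only table", {
  f <- labeled_findings(important = c("CA1", "CA2"),
                        unlikely = c("CA5", "CA6"),
                        middle = c("CA3", "CA4"))
  # important set equals gold, unlikely disjoint from it -> kappa 1
  res <- evaluate_against_gold(f, gold = c("CA1", "CA2"))
  expect_equal(res$kappa, 1.0)
  expect_equal(res$n_excluded, 2L)          # middle 90% analog stays out
  expect_equal(res$table$n, 4L)
  # swapping labels flips sensitivity and specificity
  fswap <- f
  fswap$label <- c(important = "unlikely", unlikely = "important",
                   unlabeled = "unlabeled")[f$label]
  res2 <- evaluate_against_gold(fswap, gold = c("CA1", "CA2"))
  expect_equal(res2$sensitivity, 1 - res$sensitivity)
  expect_equal(res2$specificity, 1 - res$specificity)
  expect_error(evaluate_against_gold(f, gold = character(0)),
               class = "tbkg_config_error")
})

test_that("labels shuffled against the gold list drive kappa to zero", {
  set.seed(23)
  n_side <- 50
  adrs <- sprintf("CA%03d", 1:(2 * n_side))
  kappas <- replicate(20, {
    picked <- sample(adrs)
    f <- labeled_findings(important = picked[1:n_side],
                          unlikely = picked[(n_side + 1):(2 * n_side)])
    evaluate_against_gold(f, gold = adrs[1:n_side])$kappa
  })
  expect_lt(abs(mean(kappas)), 0.1)
})

test_that("gold lists resolve surface terms through the lexicon", {
  lex <- toy_lexicon()
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "dry skin", "C-ILD", "unknown thing"), path)
  expect_warning(gold <- read_gold(path, lex), "unresolvable")
  expect_setequal(gold, c("C-DS", "C-ILD"))
})
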