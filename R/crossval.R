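#' K-fold cross-validated naive-Bayes classification accuracy
#'
#' For every target entity of `target_type`, the documents are split into
#' `k` random folds; a Bernoulli naive-Bayes classifier over the features
#' of `feature_type` is trained on `k - 1` folds and predicts the target's
#' presence on the held-out fold (predict 1 exactly when the posterior
#' odds exceed 1; at odds exactly 1 the tie goes to 0, so the rule is
#' deterministic). The value returned is the accuracy averaged over folds
#' and then over targets -- a per-target binary classification accuracy,
#' which is this package's operational definition of graph-construction
#' accuracy.
#'
#' Fold membership is drawn over documents sorted by id, so the result is
#' invariant to the order of rows in the matrix given the same seed.
#'
#' @param mat A `tbkg_matrix`.
#' @param target_type Node type of the targets (one model per entity).
#' @param feature_type Node type of the features.
#' @param k Number of folds, `>= 2`. Default 3.
#' @param seed Integer seed for the fold assignment; `NULL` leaves the RNG
#'   state alone.
#' @param alpha Training smoothing pseudo-count. Default 1.
#' @return A list: `accuracy` (grand mean), `per_target` (data frame of
#'   mean accuracy per target), `k`, `seed`.
#' @export
cross_validate <- function(mat, target_type, feature_type, k = 3L,
                           seed = NULL, alpha = 1) {
  k <- as.integer(k)
  if (k < 2L) {
    tbkg_stop("tbkg_config_error", "k must be >= 2 (got %d)", k)
  }
  n <- length(mat$docs)
  if (n < k) {
    tbkg_stop("tbkg_config_error",
              "%d documents cannot fill %d folds", n, k)
  }
  tsel <- mat$entities$node_type == target_type
  fsel <- mat$entities$node_type == feature_type
  if (!any(tsel) || !any(fsel)) {
    tbkg_stop("tbkg_validation_error",
              "matrix lacks entities of type '%s'",
              if (any(tsel)) feature_type else target_type)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  ord <- order(mat$docs)
  fold_sorted <- sample(rep_len(seq_len(k), n))
  fold <- integer(n)
  fold[ord] <- fold_sorted
  if (any(tabulate(fold, k) == 0L)) {
    tbkg_stop("tbkg_config_error", "a fold received zero test documents")
  }

  targets <- mat$entities$concept_id[tsel]
  targets <- sort(targets)
  acc <- vapply(targets, function(tg) {
    j <- match(tg, mat$entities$concept_id)
    y <- as.numeric(mat$incidence[, j])
    feat <- fsel & mat$entities$concept_id != tg
    Xf <- mat$incidence[, feat, drop = FALSE]
    fold_acc <- vapply(seq_len(k), function(f) {
      te <- fold == f
      pred <- nb_predict(Xf[!te, , drop = FALSE], y[!te],
                         Xf[te, , drop = FALSE], alpha)
      mean(pred == y[te])
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  list(accuracy = mean(acc),
       per_target = data.frame(target_id = targets, accuracy = unname(acc),
                               stringsAsFactors = FALSE),
       k = k, seed = seed)
}

# Train on (Xtr, ytr), predict 0/1 on Xte. Prior odds use the raw MLE
# counts; a training fold with no positives predicts all zero.
nb_predict <- function(Xtr, ytr, Xte, alpha = 1) {
  n1 <- sum(ytr)
  n0 <- length(ytr) - n1
  if (n1 == 0) return(rep(0L, nrow(Xte)))
  if (n0 == 0) return(rep(1L, nrow(Xte)))
  c11 <- as.numeric(Matrix::crossprod(Xtr, ytr))
  c10 <- as.numeric(Matrix::colSums(Xtr)) - c11
  p1 <- (c11 + alpha) / (n1 + 2 * alpha)
  p0 <- (c10 + alpha) / (n0 + 2 * alpha)
  w_pres <- log(p1) - log(p0)
  w_abs <- log1p(-p1) - log1p(-p0)
  score <- (log(n1) - log(n0)) + sum(w_abs) +
    as.numeric(Xte %*% (w_pres - w_abs))
  as.integer(score > 0)
}
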