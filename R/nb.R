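# Bernoulli naive Bayes over the binary incidence matrix, and the
# importance measure used as the knowledge-graph edge weight:
#
#   IMP(x, y) = log2 p(x=1 | y=1) - log2 p(x=1 | y=0)
#
# One model is fitted per target entity y (e.g. per tumor); the features x
# are all entities of one other type. Parameters are maximum-likelihood
# counts with optional Laplace smoothing.

#' Evaluate the importance measure from two conditional probabilities
#'
#' `importance_value(p_present, p_absent)` is the base-2 log ratio
#' `log2(p_present / p_absent)`: positive when the feature entity is more
#' probable in documents where the target entity is present, zero when the
#' two conditionals agree. Base 2 is the convention used throughout the
#' package; a score of 1 means the feature is twice as likely when the
#' target is present.
#'
#' @param p_present `p(x = 1 | y = 1)`, in (0, 1].
#' @param p_absent `p(x = 1 | y = 0)`, in (0, 1].
#' @return The importance score (vectorized).
#' @export
#' @examples
#' importance_value(0.104, 0.005)
importance_value <- function(p_present, p_absent) {
  if (any(p_present <= 0) || any(p_absent <= 0)) {
    tbkg_stop("tbkg_undefined_error",
              "importance undefined for zero conditional probability; use smoothing (alpha > 0)")
  }
  log2(p_present) - log2(p_absent)
}

#' Fit a per-target Bernoulli naive-Bayes model
#'
#' For a target entity `y` and all feature entities of one node type, the
#' smoothed maximum-likelihood conditionals are
#' `p(x = 1 | y = v) = (count(x = 1, y = v) + alpha) / (count(y = v) + 2 alpha)`
#' and the prior is `count(y = 1) / n_docs`. `alpha = 1` (Laplace) is the
#' default; `alpha = 0` gives the pure MLE, in which zero counts yield zero
#' probabilities and the importance of the affected feature is undefined.
#'
#' @param mat A `tbkg_matrix`.
#' @param target Concept id of the target entity (must be a column of
#'   `mat`).
#' @param feature_type Node type of the feature entities.
#' @param alpha Pseudo-count, `>= 0`. Default 1.
#' @return A `tbkg_nb` model: target, feature type, prior, per-feature
#'   conditionals, counts and `alpha`.
#' @export
fit_nb <- function(mat, target, feature_type, alpha = 1) {
  j <- match(target, mat$entities$concept_id)
  if (is.na(j)) {
    tbkg_stop("tbkg_lookup_error", "target entity not in matrix: %s", target)
  }
  fsel <- mat$entities$node_type == feature_type &
    mat$entities$concept_id != target
  if (!any(fsel)) {
    tbkg_stop("tbkg_validation_error",
              "no feature columns of type '%s'", feature_type)
  }
  y <- as.numeric(mat$incidence[, j])
  n <- length(y)
  n1 <- sum(y)
  if (n1 == 0) {
    tbkg_stop("tbkg_degenerate_error",
              "target %s has zero positive documents", target)
  }
  Xf <- mat$incidence[, fsel, drop = FALSE]
  c11 <- as.numeric(Matrix::crossprod(Xf, y))
  c10 <- as.numeric(Matrix::colSums(Xf)) - c11
  cond <- data.frame(
    concept_id = mat$entities$concept_id[fsel],
    p_present = (c11 + alpha) / (n1 + 2 * alpha),
    p_absent = (c10 + alpha) / ((n - n1) + 2 * alpha),
    n11 = c11, n10 = c10,
    stringsAsFactors = FALSE)
  structure(list(target = list(concept_id = target,
                               node_type = mat$entities$node_type[j]),
                 feature_type = feature_type,
                 prior = n1 / n,
                 n_docs = n, n_target_pos = n1,
                 alpha = alpha,
                 conditionals = cond),
            class = "tbkg_nb")
}

#' @export
print.tbkg_nb <- function(x, ...) {
  cat(sprintf("naive-Bayes model for %s (%s): %d %s features, prior %.4f, alpha=%g\n",
              x$target$concept_id, x$target$node_type,
              nrow(x$conditionals), x$feature_type, x$prior, x$alpha))
  invisible(x)
}

#' Importance score of one feature under a fitted model
#'
#' @param model A `tbkg_nb` from [fit_nb()].
#' @param feature Concept id of a feature with fitted conditionals.
#' @return A one-row data frame (`tbkg_relations` shape): `target_id`,
#'   `target_type`, `feature_id`, `feature_type`, `importance`,
#'   `p_present`, `p_absent`.
#' @export
importance <- function(model, feature) {
  i <- match(feature, model$conditionals$concept_id)
  if (is.na(i)) {
    tbkg_stop("tbkg_lookup_error",
              "feature %s has no fitted conditionals", feature)
  }
  p1 <- model$conditionals$p_present[i]
  p0 <- model$conditionals$p_absent[i]
  out <- data.frame(target_id = model$target$concept_id,
                    target_type = model$target$node_type,
                    feature_id = feature,
                    feature_type = model$feature_type,
                    importance = importance_value(p1, p0),
                    p_present = p1, p_absent = p0,
                    stringsAsFactors = FALSE)
  class(out) <- c("tbkg_relations", "data.frame")
  out
}

#' Discover relations between two entity types
#'
#' Fits one naive-Bayes model per target entity of `type_pair[1]` over all
#' features of `type_pair[2]` and keeps the (target, feature) pairs whose
#' importance exceeds `threshold`. Targets with zero positive documents
#' carry no information and are skipped. The default threshold of 1 keeps
#' features at least twice as likely when the target is present.
#'
#' @param mat A `tbkg_matrix`.
#' @param type_pair Character vector `c(target_type, feature_type)`; the
#'   two types must differ.
#' @param threshold Minimum importance (exclusive). Default 1.
#' @param alpha Smoothing pseudo-count passed to [fit_nb()].
#' @return A `tbkg_relations` data frame ordered by descending importance,
#'   ties by target then feature concept id.
#' @export
discover_relations <- function(mat, type_pair, threshold = 1, alpha = 1) {
  stopifnot(length(type_pair) == 2)
  if (type_pair[1] == type_pair[2]) {
    tbkg_stop("tbkg_validation_error",
              "target and feature types must differ (got '%s' twice)",
              type_pair[1])
  }
  tsel <- mat$entities$node_type == type_pair[1]
  fsel <- mat$entities$node_type == type_pair[2]
  if (!any(tsel) || !any(fsel)) {
    tbkg_stop("tbkg_validation_error",
              "matrix lacks entities of type '%s'",
              if (any(tsel)) type_pair[2] else type_pair[1])
  }
  Xt <- mat$incidence[, tsel, drop = FALSE]
  Xf <- mat$incidence[, fsel, drop = FALSE]
  n <- length(mat$docs)
  ny1 <- as.numeric(Matrix::colSums(Xt))
  nf <- as.numeric(Matrix::colSums(Xf))
  N11 <- as.matrix(Matrix::crossprod(Xt, Xf))        # targets x features
  N01 <- sweep(-N11, 2, nf, "+")                     # x=1, y=0 counts
  p1 <- (N11 + alpha) / (ny1 + 2 * alpha)            # recycled down columns
  p0 <- (N01 + alpha) / ((n - ny1) + 2 * alpha)
  imp <- suppressWarnings(log2(p1) - log2(p0))
  out <- data.frame(
    target_id = rep(mat$entities$concept_id[tsel], times = sum(fsel)),
    target_type = type_pair[1],
    feature_id = rep(mat$entities$concept_id[fsel], each = sum(tsel)),
    feature_type = type_pair[2],
    importance = as.vector(imp),
    p_present = as.vector(p1),
    p_absent = as.vector(p0),
    stringsAsFactors = FALSE)
  out <- out[rep(ny1 > 0, times = sum(fsel)), , drop = FALSE]
  out <- out[is.finite(out$importance) & out$importance > threshold, ,
             drop = FALSE]
  out <- out[order(-out$importance, out$target_id, out$feature_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tbkg_relations", "data.frame")
  out
}

#' Write discovered relations to TSV
#'
#' @param relations A `tbkg_relations` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_relations <- function(relations, path) {
  df <- as.data.frame(relations)
  for (col in c("importance", "p_present", "p_absent")) {
    df[[col]] <- sprintf("%.12g", df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
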