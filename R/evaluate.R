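#' Co-occurrence baseline ranking
#'
#' The classical literature-mining baseline: entity pairs of the two
#' requested types are ordered by the number of documents in which both
#' occur. Ties break by concept id, so the ranking is deterministic and
#' independent of document order.
#'
#' @param mat A `tbkg_matrix`.
#' @param type_pair Character vector of two distinct node types.
#' @return A data frame `source_id`, `source_type`, `target_id`,
#'   `target_type`, `count`, ordered by descending count.
#' @export
cooccurrence_rank <- function(mat, type_pair) {
  stopifnot(length(type_pair) == 2)
  asel <- mat$entities$node_type == type_pair[1]
  bsel <- mat$entities$node_type == type_pair[2]
  if (!any(asel) || !any(bsel)) {
    tbkg_stop("tbkg_validation_error",
              "matrix lacks entities of type '%s'",
              if (any(asel)) type_pair[2] else type_pair[1])
  }
  counts <- as.matrix(Matrix::crossprod(mat$incidence[, asel, drop = FALSE],
                                        mat$incidence[, bsel, drop = FALSE]))
  out <- data.frame(
    source_id = rep(mat$entities$concept_id[asel], times = sum(bsel)),
    source_type = type_pair[1],
    target_id = rep(mat$entities$concept_id[bsel], each = sum(asel)),
    target_type = type_pair[2],
    count = as.integer(counts),
    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$source_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a 2x2 confusion table
#'
#' Cell `a` counts pairs positive under both the model and the gold
#' standard, `b` model-positive only, `c` gold-positive only, `d` negative
#' under both.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return A `tbkg_confusion` list with the four cells and `n`.
#' @export
confusion_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    tbkg_stop("tbkg_validation_error",
              "confusion cells must be non-negative integers")
  }
  n <- sum(cells)
  if (n == 0) {
    tbkg_stop("tbkg_validation_error", "confusion table is empty")
  }
  structure(list(a = a, b = b, c = c, d = d, n = n),
            class = "tbkg_confusion")
}

#' Agreement statistics for a 2x2 table
#'
#' Sensitivity `a / (a + c)`, specificity `d / (b + d)`, and Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o = (a + d) / n`
#' and chance agreement
#' `p_e = ((a + b)(a + c) + (c + d)(b + d)) / n^2`. A statistic whose
#' denominator vanishes (no gold positives, no gold negatives, or expected
#' agreement exactly 1) raises an error naming it.
#'
#' @param table A `tbkg_confusion` from [confusion_table()].
#' @return A list: `kappa`, `sensitivity`, `specificity`, `p_observed`,
#'   `p_expected`.
#' @export
agreement <- function(table) {
  stopifnot(inherits(table, "tbkg_confusion"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d; n <- table$n
  if (a + c == 0) {
    tbkg_stop("tbkg_undefined_error",
              "sensitivity undefined: no gold-positive pairs")
  }
  if (b + d == 0) {
    tbkg_stop("tbkg_undefined_error",
              "specificity undefined: no gold-negative pairs")
  }
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  if (p_e >= 1) {
    tbkg_stop("tbkg_undefined_error",
              "kappa undefined: expected agreement is 1")
  }
  list(kappa = (p_o - p_e) / (1 - p_e),
       sensitivity = a / (a + c),
       specificity = d / (b + d),
       p_observed = p_o,
       p_expected = p_e)
}

#' Evaluate labeled findings against a gold ADR list
#'
#' Model-positive means the `"important"` label, model-negative means
#' `"unlikely"`; the unlabeled middle of the ranking is excluded from the
#' table entirely (the agreement is computed on the extremes only, where
#' the model actually commits). Gold membership is by exact concept id.
#'
#' @param findings A labeled `tbkg_findings` (see [label_extremes()]).
#' @param gold Character vector of gold ADR concept ids.
#' @return A list: `table` (`tbkg_confusion`), `kappa`, `sensitivity`,
#'   `specificity`, `n_excluded` (unlabeled findings left out).
#' @export
evaluate_against_gold <- function(findings, gold) {
  gold <- unique(as.character(gold))
  if (length(gold) == 0) {
    tbkg_stop("tbkg_config_error", "gold ADR set is empty")
  }
  lab <- findings[findings$label != "unlabeled", , drop = FALSE]
  if (nrow(lab) == 0) {
    tbkg_stop("tbkg_config_error",
              "no labeled findings; run label_extremes() first")
  }
  pos <- lab$label == "important"
  in_gold <- lab$adr %in% gold
  tab <- confusion_table(a = sum(pos & in_gold),
                         b = sum(pos & !in_gold),
                         c = sum(!pos & in_gold),
                         d = sum(!pos & !in_gold))
  stats <- agreement(tab)
  c(list(table = tab, n_excluded = nrow(findings) - nrow(lab)), stats)
}

#' Read a gold ADR list from a plain-text file
#'
#' One ADR per line, either a concept id or a surface term; terms are
#' resolved to concept ids through the lexicon (exact lower-case match).
#' Lines resolving to nothing are dropped with a warning.
#'
#' @param path Text file, one entry per line; blank lines and `#` comments
#'   ignored.
#' @param lexicon Optional `tbkg_lexicon` used to resolve surface terms.
#' @return Character vector of gold ADR concept ids.
#' @export
read_gold <- function(path, lexicon = NULL) {
  if (!file.exists(path)) {
    tbkg_stop("tbkg_missing_input", "gold list not found: %s", path)
  }
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (is.null(lexicon)) return(unique(lines))
  ids <- character(0)
  unresolved <- character(0)
  for (x in lines) {
    hit <- lexicon$concept_id[lexicon$term == tolower(x)]
    if (length(hit) > 0) {
      ids <- c(ids, hit[1])
    } else if (x %in% lexicon$concept_id) {
      ids <- c(ids, x)
    } else {
      unresolved <- c(unresolved, x)
    }
  }
  if (length(unresolved) > 0) {
    warning(sprintf("dropped %d unresolvable gold entr%s",
                    length(unresolved),
                    if (length(unresolved) > 1) "ies" else "y"),
            call. = FALSE)
  }
  unique(ids)
}
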