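#' Rank candidate ADRs for one drug with explanation paths
#'
#' Every adr-type node in the graph becomes a candidate. A candidate with a
#' direct drug-ADR edge is scored by that edge's importance; a candidate
#' reachable only through biomarker/tumor intermediates falls back to its
#' path support, the widest-bottleneck value `max` over its explanation
#' paths of the `min` edge weight along the path, and is ranked below every
#' directly-connected candidate. Unreachable candidates score `-Inf` and
#' sink to the bottom. Ties break by path support, then concept id, so the
#' ranking is deterministic.
#'
#' @param graph A `tbkg` graph.
#' @param drug Concept id of a drug-type node in the graph.
#' @param max_len Maximum explanation-path length in edges (see
#'   [enumerate_paths()]).
#' @return A `tbkg_findings` data frame with columns `drug`, `adr`,
#'   `direct_importance` (`NA` when no direct edge), `path_support`,
#'   `n_paths`, `score`, `rank`, `label` (all `"unlabeled"`); the full
#'   path list of each finding is in `attr(, "paths")`, named by ADR id.
#' @export
rank_adrs <- function(graph, drug, max_len = 3L) {
  if (!drug %in% graph$nodes$concept_id) {
    tbkg_stop("tbkg_lookup_error", "drug not in graph: %s", drug)
  }
  if (node_type_of(graph, drug) != "drug") {
    tbkg_stop("tbkg_validation_error", "node %s is not drug-type", drug)
  }
  adrs <- sort(graph$nodes$concept_id[graph$nodes$node_type == "adr"])
  paths <- lapply(adrs, function(a) enumerate_paths(graph, drug, a, max_len))
  names(paths) <- adrs
  direct <- vapply(paths, function(pl) {
    d <- Filter(function(p) length(p$nodes) == 2, pl)
    if (length(d) > 0) d[[1]]$weights[1] else NA_real_
  }, numeric(1))
  support <- vapply(paths, function(pl) {
    if (length(pl) == 0) return(-Inf)
    max(vapply(pl, function(p) min(p$weights), numeric(1)))
  }, numeric(1))
  score <- ifelse(is.na(direct), support, direct)
  out <- data.frame(drug = drug, adr = adrs,
                    direct_importance = unname(direct),
                    path_support = unname(support),
                    n_paths = unname(lengths(paths)),
                    score = unname(score),
                    stringsAsFactors = FALSE)
  ord <- order(is.na(out$direct_importance), -out$score, -out$path_support,
               out$adr)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$label <- "unlabeled"
  rownames(out) <- NULL
  attr(out, "paths") <- paths[out$adr]
  class(out) <- c("tbkg_findings", "data.frame")
  out
}

#' Label the extremes of a ranked ADR list
#'
#' The top `ceiling(fraction * N)` findings are labeled `"important"` and
#' the bottom `ceiling(fraction * N)` are labeled `"unlikely"`; everything
#' between stays `"unlabeled"`. With the default 5 percent fraction a list
#' of 775 candidates yields 39 of each. The two label sets must not
#' overlap, which requires `N >= 2 * ceiling(fraction * N)`.
#'
#' @param findings A `tbkg_findings` data frame from [rank_adrs()].
#' @param fraction Fraction labeled at each extreme, in `[0, 0.5]`.
#'   Default 0.05.
#' @return The findings with the `label` column filled in.
#' @export
label_extremes <- function(findings, fraction = 0.05) {
  n <- nrow(findings)
  if (n == 0) {
    tbkg_stop("tbkg_validation_error", "findings list is empty")
  }
  if (fraction < 0) {
    tbkg_stop("tbkg_config_error", "fraction must be non-negative")
  }
  findings$label <- "unlabeled"
  if (fraction == 0) return(findings)
  m <- ceiling(fraction * n)
  if (n < 2 * m) {
    tbkg_stop("tbkg_config_error",
              "%d findings are too few for disjoint top/bottom labels of size %d",
              n, m)
  }
  findings$label[seq_len(m)] <- "important"
  findings$label[seq(n - m + 1L, n)] <- "unlikely"
  findings
}

#' Write ranked findings and their explanation paths
#'
#' `path` receives a TSV (`drug`, `adr`, `score`, `label`, `n_paths`,
#' `direct_importance`, `path_support`, `rank`). When `paths_path` is
#' given, one JSON record per finding is written there, carrying the full
#' explanation-path list with per-edge weights.
#'
#' @param findings A `tbkg_findings`.
#' @param path Output TSV path.
#' @param paths_path Optional JSONL path for the per-finding paths.
#' @return `path`, invisibly.
#' @export
write_findings <- function(findings, path, paths_path = NULL) {
  df <- as.data.frame(findings)[, c("drug", "adr", "score", "label",
                                    "n_paths", "direct_importance",
                                    "path_support", "rank")]
  for (col in c("score", "direct_importance", "path_support")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "NA", sprintf("%.12g", df[[col]]))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(paths_path)) {
    all_paths <- attr(findings, "paths")
    con <- file(paths_path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(findings))) {
      rec <- list(drug = findings$drug[i], adr = findings$adr[i],
                  score = findings$score[i], label = findings$label[i],
                  paths = lapply(all_paths[[findings$adr[i]]], function(p) {
                    list(nodes = p$nodes, weights = p$weights)
                  }))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}
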