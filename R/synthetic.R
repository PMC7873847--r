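# Planted-truth generator: a typed graph with known conditional
# probabilities, and corpora of entity-bag abstracts sampled from it, so
# the entire pipeline (tagging, matrix, relation discovery, ranking) can
# be exercised and its estimates compared with known truth.

synth_prefix <- c(tumor = "tum", drug = "drg", biomarker = "bio", adr = "adr")
synth_cid <- c(tumor = "CT", drug = "CD", biomarker = "CB", adr = "CA")
synth_category <- c(tumor = "T191", drug = "T121", biomarker = "T116",
                    adr = "WHO")

# Type pairs in layer order (earlier layer first = parent side).
synth_pairs <- list(c("tumor", "drug"), c("tumor", "biomarker"),
                    c("tumor", "adr"), c("drug", "biomarker"),
                    c("drug", "adr"), c("biomarker", "adr"))

#' Generate a planted typed graph
#'
#' Nodes of the four types are created and a set of true edges is planted,
#' each carrying the conditional probabilities `(p_present, p_absent)`:
#' the probability that the child entity appears in a document given that
#' its parent does / does not. Two layouts are available:
#'
#' * `"matched"` (default): edges form a degree-constrained matching --
#'   every node takes part in at most one planted edge, with the
#'   earlier-layer node (layer order tumor, drug, biomarker, ADR) as the
#'   parent. Under this layout each planted edge's population importance
#'   is exactly `log2(p_present / p_absent)` and non-edges are exactly
#'   independent, so estimates can be compared to closed-form truth for
#'   any seed. Per type pair, `ceiling(edge_density * min(available))`
#'   edges are drawn among the still-unmatched nodes.
#' * `"pairwise"`: every type-valid node pair becomes an edge
#'   independently with probability `edge_density` (so density 1 with one
#'   node per type plants all six edges). Children may then have several
#'   parents and correlations propagate along chains; per-edge importance
#'   is no longer identifiable in closed form.
#'
#' @param sizes Named integer vector with entries `tumor`, `drug`,
#'   `biomarker`, `adr`, each `>= 1`. Default `c(4, 6, 10, 10)`.
#' @param edge_density Edge-sampling density in `(0, 1]`. Default 0.3.
#' @param effect Named numeric vector `c(p_present=, p_absent=)` with
#'   `0 < p_absent < p_present < 1`. Default `c(0.3, 0.03)`, i.e. a
#'   planted importance of `log2(10) = 3.32`.
#' @param background_rate Marginal appearance rate of entities in no
#'   planted edge. Default 0.02.
#' @param anchor_rate Marginal activation rate of root entities (tumors,
#'   parentless drugs, and any node acting as a parent). Default 0.25.
#' @param layout `"matched"` or `"pairwise"` (see above).
#' @param seed Integer seed; the same seed reproduces the same graph.
#' @return A `tbkg_planted` list: `nodes` (with synthetic surface terms),
#'   `edges` (`parent`, `child`, `pair`, `p_present`, `p_absent`),
#'   `params`, `layout`, `seed`.
#' @export
generate_graph <- function(sizes = c(tumor = 4L, drug = 6L,
                                     biomarker = 10L, adr = 10L),
                           edge_density = 0.3,
                           effect = c(p_present = 0.3, p_absent = 0.03),
                           background_rate = 0.02,
                           anchor_rate = 0.25,
                           layout = c("matched", "pairwise"),
                           seed = NULL) {
  layout <- match.arg(layout)
  if (!all(tbkg_node_types %in% names(sizes)) ||
      any(sizes[tbkg_node_types] < 1)) {
    tbkg_stop("tbkg_validation_error",
              "sizes must name all four node types with values >= 1")
  }
  if (edge_density <= 0 || edge_density > 1) {
    tbkg_stop("tbkg_validation_error", "edge_density must be in (0, 1]")
  }
  p1 <- unname(effect["p_present"]); p0 <- unname(effect["p_absent"])
  if (is.na(p1) || is.na(p0) || !(0 < p0 && p0 < p1 && p1 < 1)) {
    tbkg_stop("tbkg_validation_error",
              "effect must satisfy 0 < p_absent < p_present < 1")
  }
  for (r in c(background_rate, anchor_rate)) {
    if (r <= 0 || r >= 1) {
      tbkg_stop("tbkg_validation_error", "rates must be in (0, 1)")
    }
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  nodes <- do.call(rbind, lapply(tbkg_node_types, function(tp) {
    ix <- seq_len(sizes[[tp]])
    data.frame(concept_id = sprintf("%s%03d", synth_cid[[tp]], ix),
               node_type = tp,
               term = sprintf("%s%03d", synth_prefix[[tp]], ix),
               layer = match(tp, tbkg_node_types),
               stringsAsFactors = FALSE)
  }))

  ids_of <- function(tp) nodes$concept_id[nodes$node_type == tp]
  edges <- data.frame(parent = character(), child = character(),
                      pair = character(), stringsAsFactors = FALSE)
  if (layout == "matched") {
    matched <- character(0)
    for (pr in synth_pairs) {
      availA <- setdiff(ids_of(pr[1]), matched)
      availB <- setdiff(ids_of(pr[2]), matched)
      k <- min(ceiling(edge_density * min(length(availA), length(availB))),
               length(availA), length(availB))
      if (k <= 0) next
      pa <- sample(availA, k)
      ch <- sample(availB, k)
      matched <- c(matched, pa, ch)
      edges <- rbind(edges, data.frame(parent = pa, child = ch,
                                       pair = paste(pr, collapse = "-"),
                                       stringsAsFactors = FALSE))
    }
  } else {
    for (pr in synth_pairs) {
      combos <- expand.grid(parent = ids_of(pr[1]), child = ids_of(pr[2]),
                            stringsAsFactors = FALSE)
      take <- stats::runif(nrow(combos)) < edge_density
      if (any(take)) {
        edges <- rbind(edges, data.frame(parent = combos$parent[take],
                                         child = combos$child[take],
                                         pair = paste(pr, collapse = "-"),
                                         stringsAsFactors = FALSE))
      }
    }
  }
  if (nrow(edges) > 0) {
    edges$p_present <- p1
    edges$p_absent <- p0
    edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges$p_present <- numeric(0)
    edges$p_absent <- numeric(0)
  }
  structure(list(nodes = nodes, edges = edges,
                 params = list(sizes = sizes, edge_density = edge_density,
                               p_present = p1, p_absent = p0,
                               background_rate = background_rate,
                               anchor_rate = anchor_rate),
                 layout = layout, seed = seed),
            class = "tbkg_planted")
}

#' Planted importance of every true edge
#'
#' The population value of the importance measure for a planted edge,
#' `log2(p_present / p_absent)` -- `log2(0.3 / 0.03) = 3.32` at the
#' default effect sizes.
#'
#' @param graph A `tbkg_planted`.
#' @return Numeric vector, one value per planted edge.
#' @export
planted_importance <- function(graph) {
  importance_value(graph$edges$p_present, graph$edges$p_absent)
}

# marginal activation probability of each node (matched layout: exact).
planted_marginals <- function(graph) {
  pars <- graph$params
  marg <- setNames(numeric(nrow(graph$nodes)), graph$nodes$concept_id)
  is_parent <- graph$nodes$concept_id %in% graph$edges$parent
  for (i in order(graph$nodes$layer)) {
    id <- graph$nodes$concept_id[i]
    e <- graph$edges[graph$edges$child == id, , drop = FALSE]
    if (nrow(e) == 1) {
      pm <- marg[[e$parent]]
      marg[[id]] <- pm * e$p_present + (1 - pm) * e$p_absent
    } else if (nrow(e) > 1) {
      tbkg_stop("tbkg_validation_error",
                "closed-form marginals require the matched layout")
    } else if (graph$nodes$node_type[i] %in% c("tumor", "drug") ||
               is_parent[i]) {
      marg[[id]] <- pars$anchor_rate
    } else {
      marg[[id]] <- pars$background_rate
    }
  }
  marg
}

#' Closed-form Bayes-optimal classification accuracy
#'
#' For a matched-layout planted graph, the best achievable accuracy of
#' predicting each target entity's presence from the features of one type:
#' a target whose planted child is of the feature type is predicted from
#' that single informative feature
#' (`sum_x max_y P(x | y) P(y)`), any other target is predicted by its
#' majority class. Averaged over the targets of `target_type`, this is the
#' ceiling against which cross-validated naive-Bayes accuracy is compared.
#'
#' @param graph A `tbkg_planted` with `layout = "matched"`.
#' @param target_type,feature_type Node types, as in [cross_validate()].
#' @return A list: `accuracy` (mean over targets), `per_target`.
#' @export
bayes_accuracy <- function(graph, target_type, feature_type) {
  if (graph$layout != "matched") {
    tbkg_stop("tbkg_validation_error",
              "bayes_accuracy requires the matched layout")
  }
  marg <- planted_marginals(graph)
  targets <- sort(graph$nodes$concept_id[graph$nodes$node_type == target_type])
  ftype <- setNames(graph$nodes$node_type, graph$nodes$concept_id)
  acc <- vapply(targets, function(tg) {
    pi1 <- marg[[tg]]
    e <- graph$edges[graph$edges$parent == tg, , drop = FALSE]
    e <- e[ftype[e$child] == feature_type, , drop = FALSE]
    if (nrow(e) == 1) {
      p1 <- e$p_present; p0 <- e$p_absent
      max(pi1 * p1, (1 - pi1) * p0) + max(pi1 * (1 - p1), (1 - pi1) * (1 - p0))
    } else {
      max(pi1, 1 - pi1)
    }
  }, numeric(1))
  list(accuracy = mean(acc),
       per_target = data.frame(target_id = targets, accuracy = unname(acc),
                               stringsAsFactors = FALSE))
}

#' Sample a corpus of entity-bag abstracts from a planted graph
#'
#' Documents are sampled independently. Per document, nodes activate in
#' layer order: roots (tumors, parentless drugs, and parent nodes) with
#' the anchor rate, planted children with `p_present` when at least one of
#' their parents is active and `p_absent` otherwise, and unlinked
#' biomarkers/ADRs with the background rate. Each active entity
#' contributes one carrier sentence to the abstract body, so the
#' dictionary tagger recovers exactly the planted incidence; linguistic
#' realism (negation, paraphrase, ambiguity) is deliberately absent --
#' the generator tests counting, not NLP.
#'
#' @param graph A `tbkg_planted`.
#' @param n_docs Number of documents, `>= 1`.
#' @param seed Integer seed.
#' @return A `tbkg_sim` list: `corpus` (a `tbkg_corpus`), `lexicon`
#'   (a `tbkg_lexicon` covering every synthetic term), `matrix` (the exact
#'   `tbkg_matrix`, no frequency filtering), `truth` (per planted edge the
#'   exhaustive 2x2 counts `n11`, `n10`, `n01`, `n00` over the emitted
#'   matrix), and `graph`.
#' @export
generate_corpus <- function(graph, n_docs, seed = NULL) {
  stopifnot(inherits(graph, "tbkg_planted"))
  n_docs <- as.integer(n_docs)
  if (is.na(n_docs) || n_docs < 1) {
    tbkg_stop("tbkg_validation_error", "n_docs must be >= 1")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  nodes <- graph$nodes[order(graph$nodes$layer, graph$nodes$concept_id), ,
                       drop = FALSE]
  pars <- graph$params
  is_parent <- nodes$concept_id %in% graph$edges$parent
  A <- matrix(0L, nrow = n_docs, ncol = nrow(nodes),
              dimnames = list(NULL, nodes$concept_id))
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$concept_id[i]
    e <- graph$edges[graph$edges$child == id, , drop = FALSE]
    if (nrow(e) > 0) {
      any_parent <- if (nrow(e) == 1) A[, e$parent] > 0 else
        rowSums(A[, e$parent, drop = FALSE]) > 0
      p <- ifelse(any_parent, e$p_present[1], e$p_absent[1])
      A[, i] <- stats::rbinom(n_docs, 1L, p)
    } else if (nodes$node_type[i] %in% c("tumor", "drug") || is_parent[i]) {
      A[, i] <- stats::rbinom(n_docs, 1L, pars$anchor_rate)
    } else {
      A[, i] <- stats::rbinom(n_docs, 1L, pars$background_rate)
    }
  }

  doc_ids <- sprintf("doc%05d", seq_len(n_docs))
  filler <- paste("This synthetic abstract summarizes entity mentions",
                  "sampled from a planted typed graph for pipeline testing.")
  term_of <- setNames(nodes$term, nodes$concept_id)
  bodies <- vapply(seq_len(n_docs), function(d) {
    act <- colnames(A)[A[d, ] > 0]
    paste(c(filler,
            sprintf("We observed %s in this cohort.", term_of[act])),
          collapse = " ")
  }, character(1))
  corpus <- data.frame(doc_id = doc_ids,
                       title = sprintf("Synthetic abstract %05d",
                                       seq_len(n_docs)),
                       body = bodies,
                       year = 2020L,
                       stringsAsFactors = FALSE)
  class(corpus) <- c("tbkg_corpus", "data.frame")

  lexicon <- as_lexicon(data.frame(
    term = nodes$term,
    concept_id = nodes$concept_id,
    semantic_category = synth_category[nodes$node_type],
    stringsAsFactors = FALSE))

  ord <- order(nodes$concept_id)
  inc <- methods::as(Matrix::Matrix(A[, ord, drop = FALSE] * 1,
                                    sparse = TRUE), "CsparseMatrix")
  dimnames(inc) <- list(doc_ids, nodes$concept_id[ord])
  ents <- data.frame(concept_id = nodes$concept_id[ord],
                     node_type = nodes$node_type[ord],
                     stringsAsFactors = FALSE)
  mat <- new_tbkg_matrix(doc_ids, ents, inc, 1L)

  truth <- graph$edges
  if (nrow(truth) > 0) {
    counts <- t(vapply(seq_len(nrow(truth)), function(i) {
      y <- A[, truth$parent[i]]
      x <- A[, truth$child[i]]
      c(n11 = sum(x & y), n10 = sum(!x & y),
        n01 = sum(x & !y), n00 = sum(!x & !y))
    }, c(n11 = 0, n10 = 0, n01 = 0, n00 = 0)))
    truth <- cbind(truth, as.data.frame(counts))
  }
  structure(list(corpus = corpus, lexicon = lexicon, matrix = mat,
                 truth = truth, graph = graph, seed = seed),
            class = "tbkg_sim")
}

#' Write the truth tables of a simulated corpus to TSV
#'
#' @param sim A `tbkg_sim` from [generate_corpus()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  utils::write.table(sim$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
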