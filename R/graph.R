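# The typed weighted knowledge graph. Nodes carry one of four types
# (tumor, biomarker, drug, adr); undirected edges connect two nodes of
# *different* types and are weighted by the naive-Bayes importance score.

new_tbkg <- function(nodes, edges) {
  nodes <- nodes[order(nodes$concept_id), c("concept_id", "node_type"),
                 drop = FALSE]
  rownames(nodes) <- NULL
  if (nrow(edges) > 0) {
    flip <- edges$source > edges$target
    tmp <- edges$source[flip]
    edges$source[flip] <- edges$target[flip]
    edges$target[flip] <- tmp
    edges <- edges[order(edges$source, edges$target),
                   c("source", "target", "weight"), drop = FALSE]
  } else {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "tbkg")
}

#' @export
print.tbkg <- function(x, ...) {
  tt <- table(x$nodes$node_type)
  cat(sprintf("tbkg graph: %d nodes (%s), %d edges\n", nrow(x$nodes),
              paste(sprintf("%s=%d", names(tt), as.integer(tt)),
                    collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

node_type_of <- function(graph, ids) {
  graph$nodes$node_type[match(ids, graph$nodes$concept_id)]
}

#' Assemble the typed knowledge graph from importance scores
#'
#' Takes one or several `tbkg_relations` data frames (one per type pair)
#' and builds the graph: one node per entity, one undirected weighted edge
#' per surviving score. Inserting the same pair twice with equal weight is
#' idempotent; conflicting weights for one pair, self-loops, and edges
#' between two nodes of the same type are rejected.
#'
#' @param relations A `tbkg_relations` data frame or a list of them.
#' @return A `tbkg` graph (sorted node and edge tables).
#' @export
assemble_graph <- function(relations) {
  if (is.data.frame(relations)) relations <- list(relations)
  rel <- do.call(rbind, lapply(relations, as.data.frame))
  if (is.null(rel) || nrow(rel) == 0) {
    return(new_tbkg(data.frame(concept_id = character(),
                               node_type = character(),
                               stringsAsFactors = FALSE),
                    data.frame(source = character(), target = character(),
                               weight = numeric(), stringsAsFactors = FALSE)))
  }
  if (any(rel$target_id == rel$feature_id)) {
    tbkg_stop("tbkg_validation_error", "self-loop relation rejected")
  }
  same <- rel$target_type == rel$feature_type
  if (any(same)) {
    tbkg_stop("tbkg_validation_error",
              "edge between two '%s' nodes rejected: the graph only links distinct types",
              rel$target_type[which(same)[1]])
  }
  nodes <- unique(rbind(
    data.frame(concept_id = rel$target_id, node_type = rel$target_type,
               stringsAsFactors = FALSE),
    data.frame(concept_id = rel$feature_id, node_type = rel$feature_type,
               stringsAsFactors = FALSE)))
  if (anyDuplicated(nodes$concept_id)) {
    bad <- unique(nodes$concept_id[duplicated(nodes$concept_id)])
    tbkg_stop("tbkg_validation_error",
              "entity with conflicting node types: %s",
              paste(bad, collapse = ", "))
  }
  key <- paste(pmin(rel$target_id, rel$feature_id),
               pmax(rel$target_id, rel$feature_id), sep = "\r")
  w_by_key <- split(rel$importance, key)
  spread <- vapply(w_by_key, function(w) diff(range(w)), numeric(1))
  if (any(spread > 1e-9)) {
    bad <- names(w_by_key)[which(spread > 1e-9)[1]]
    tbkg_stop("tbkg_conflict_error",
              "conflicting weights for edge %s",
              gsub("\r", " -- ", bad))
  }
  first <- !duplicated(key)
  edges <- data.frame(source = rel$target_id[first],
                      target = rel$feature_id[first],
                      weight = rel$importance[first],
                      stringsAsFactors = FALSE)
  new_tbkg(nodes, edges)
}

adjacency_list <- function(graph) {
  ids <- graph$nodes$concept_id
  adj <- setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(graph$edges))) {
    s <- graph$edges$source[i]; t <- graph$edges$target[i]
    w <- graph$edges$weight[i]
    adj[[s]] <- rbind(adj[[s]], data.frame(to = t, weight = w,
                                           stringsAsFactors = FALSE))
    adj[[t]] <- rbind(adj[[t]], data.frame(to = s, weight = w,
                                           stringsAsFactors = FALSE))
  }
  lapply(adj, function(a) {
    if (is.null(a)) {
      data.frame(to = character(), weight = numeric(),
                 stringsAsFactors = FALSE)
    } else {
      a[order(a$to), , drop = FALSE]
    }
  })
}

#' Enumerate explanation paths between a drug and an ADR
#'
#' Depth-first search for every simple path of at most `max_len` edges
#' from `drug` to `adr` whose interior nodes are biomarkers or tumors --
#' other drugs and ADRs are not allowed as intermediates, so each path
#' reads as a mechanistic explanation (e.g. drug - biomarker - ADR).
#' Paths are returned shortest first, ties in lexicographic order of the
#' node id sequence, so the output is independent of node insertion order.
#'
#' @param graph A `tbkg` graph.
#' @param drug Concept id of a drug-type node.
#' @param adr Concept id of an adr-type node.
#' @param max_len Maximum number of edges per path. Default 3 (covers the
#'   drug - biomarker - ADR motif and tumor-mediated three-hop paths).
#' @return A list of paths; each path is a list with `nodes` (character
#'   vector, drug first) and `weights` (per-edge weights, length
#'   `length(nodes) - 1`). Empty list when the two nodes are disconnected.
#' @export
enumerate_paths <- function(graph, drug, adr, max_len = 3L) {
  for (id in c(drug, adr)) {
    if (!id %in% graph$nodes$concept_id) {
      tbkg_stop("tbkg_lookup_error", "node not in graph: %s", id)
    }
  }
  if (node_type_of(graph, drug) != "drug" ||
      node_type_of(graph, adr) != "adr") {
    tbkg_stop("tbkg_validation_error",
              "path endpoints must be a drug-type and an adr-type node")
  }
  adj <- adjacency_list(graph)
  interior_ok <- setNames(graph$nodes$node_type %in% c("biomarker", "tumor"),
                          graph$nodes$concept_id)
  found <- list()
  dfs <- function(at, nodes, weights) {
    nb <- adj[[at]]
    for (i in seq_len(nrow(nb))) {
      nxt <- nb$to[i]
      if (nxt %in% nodes) next
      if (nxt == adr) {
        found[[length(found) + 1L]] <<- list(nodes = c(nodes, nxt),
                                             weights = c(weights, nb$weight[i]))
      } else if (length(weights) + 1L < max_len && interior_ok[[nxt]]) {
        dfs(nxt, c(nodes, nxt), c(weights, nb$weight[i]))
      }
    }
  }
  if (max_len >= 1L) dfs(drug, drug, numeric())
  if (length(found) == 0) return(found)
  keys <- vapply(found, function(p) paste(p$nodes, collapse = "\r"),
                 character(1))
  found[order(lengths(lapply(found, `[[`, "nodes")), keys)]
}

#' Save / load a knowledge graph as a sectioned TSV
#'
#' A single plain-text file with a `>nodes` section (concept id, node
#' type) and a `>edges` section (source, target, weight). Weights are
#' written with 17 significant digits, so a save/load round trip is the
#' identity for all practical purposes.
#'
#' @param graph A `tbkg` graph.
#' @param path File path.
#' @return `save_graph`: `path`, invisibly. `load_graph`: the restored
#'   `tbkg`.
#' @export
save_graph <- function(graph, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#tbkg-graph\t1", con)
  writeLines(">nodes", con)
  writeLines("concept_id\tnode_type", con)
  if (nrow(graph$nodes) > 0) {
    writeLines(paste(graph$nodes$concept_id, graph$nodes$node_type,
                     sep = "\t"), con)
  }
  writeLines(">edges", con)
  writeLines("source\ttarget\tweight", con)
  if (nrow(graph$edges) > 0) {
    writeLines(paste(graph$edges$source, graph$edges$target,
                     sprintf("%.17g", graph$edges$weight), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path) {
  if (!file.exists(path)) {
    tbkg_stop("tbkg_missing_input", "graph file not found: %s", path)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[1], "#tbkg-graph")) {
    tbkg_stop("tbkg_format_error", "%s is not a tbkg graph file", path)
  }
  ni <- which(lines == ">nodes")
  ei <- which(lines == ">edges")
  if (length(ni) != 1 || length(ei) != 1 || ei < ni) {
    tbkg_stop("tbkg_format_error", "malformed graph file: %s", path)
  }
  parse_block <- function(hdr, body, ncol_expect) {
    if (length(body) == 0) return(NULL)
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != ncol_expect)) {
      tbkg_stop("tbkg_format_error", "malformed row in graph file: %s", path)
    }
    as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  }
  nb <- parse_block(lines[ni + 1], lines[seq_len(ei - ni - 2) + ni + 1], 2)
  eb <- parse_block(lines[ei + 1],
                    if (ei + 2 <= length(lines)) lines[(ei + 2):length(lines)]
                    else character(),
                    3)
  nodes <- if (is.null(nb)) {
    data.frame(concept_id = character(), node_type = character(),
               stringsAsFactors = FALSE)
  } else setNames(nb, c("concept_id", "node_type"))
  edges <- if (is.null(eb)) {
    data.frame(source = character(), target = character(),
               weight = numeric(), stringsAsFactors = FALSE)
  } else {
    eb <- setNames(eb, c("source", "target", "weight"))
    eb$weight <- as.numeric(eb$weight)
    eb
  }
  bad_types <- setdiff(unique(nodes$node_type), tbkg_node_types)
  if (length(bad_types) > 0) {
    tbkg_stop("tbkg_format_error", "unknown node type(s) in %s: %s",
              path, paste(bad_types, collapse = ", "))
  }
  g <- new_tbkg(nodes, edges)
  validate_tbkg(g)
  g
}

validate_tbkg <- function(graph) {
  if (nrow(graph$edges) == 0) return(invisible(graph))
  st <- node_type_of(graph, graph$edges$source)
  tt <- node_type_of(graph, graph$edges$target)
  if (anyNA(st) || anyNA(tt)) {
    tbkg_stop("tbkg_validation_error", "edge references unknown node")
  }
  if (any(graph$edges$source == graph$edges$target)) {
    tbkg_stop("tbkg_validation_error", "self-loop in graph")
  }
  if (any(st == tt)) {
    tbkg_stop("tbkg_validation_error", "same-type edge in graph")
  }
  key <- paste(graph$edges$source, graph$edges$target)
  if (anyDuplicated(key)) {
    tbkg_stop("tbkg_validation_error", "duplicate edge in graph")
  }
  invisible(graph)
}

#' Export a graph to GraphML for visualization
#'
#' Node type is stored as the `type` vertex attribute, the importance as
#' the `weight` edge attribute.
#'
#' @param graph A `tbkg` graph.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(graph, path) {
  g <- igraph::graph_from_data_frame(
    d = graph$edges,
    directed = FALSE,
    vertices = data.frame(name = graph$nodes$concept_id,
                          type = graph$nodes$node_type,
                          stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
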