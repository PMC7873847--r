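# Shared fixtures and independent oracles. Oracles are deliberately naive
# (loops, exhaustive enumeration) and share no code with the package paths
# they check.

# Wrap a dense 0/1 matrix as a tbkg_matrix (columns already named by
# concept id, types supplied per column).
as_tbkg_matrix <- function(M, node_types, doc_ids = NULL) {
  if (is.null(doc_ids)) doc_ids <- sprintf("d%03d", seq_len(nrow(M)))
  ents <- data.frame(concept_id = colnames(M), node_type = node_types,
                     stringsAsFactors = FALSE)
  ord <- order(ents$concept_id)
  ents <- ents[ord, , drop = FALSE]
  M <- M[, ord, drop = FALSE]
  inc <- methods::as(Matrix::Matrix(M * 1, sparse = TRUE), "CsparseMatrix")
  dimnames(inc) <- list(doc_ids, ents$concept_id)
  tbkg:::new_tbkg_matrix(doc_ids, ents, inc, 1L)
}

# Exhaustive 2x2 counting oracle for the smoothed Bernoulli conditionals.
oracle_conditionals <- function(M, target, feature, alpha) {
  n11 <- 0; n10 <- 0; n01 <- 0; n00 <- 0
  for (d in seq_len(nrow(M))) {
    x <- M[d, feature]; y <- M[d, target]
    if (x == 1 && y == 1) n11 <- n11 + 1
    if (x == 0 && y == 1) n10 <- n10 + 1
    if (x == 1 && y == 0) n01 <- n01 + 1
    if (x == 0 && y == 0) n00 <- n00 + 1
  }
  list(p_present = (n11 + alpha) / (n11 + n10 + 2 * alpha),
       p_absent = (n01 + alpha) / (n01 + n00 + 2 * alpha))
}

# Independent simple-path enumerator: tries every interior node sequence
# of every admissible length and keeps those whose edges all exist. Only
# feasible for tiny graphs, which is the point.
oracle_paths <- function(graph, drug, adr, max_len = 3L) {
  ids <- graph$nodes$concept_id
  type <- setNames(graph$nodes$node_type, ids)
  ekey <- paste(pmin(graph$edges$source, graph$edges$target),
                pmax(graph$edges$source, graph$edges$target))
  has_edge <- function(u, v) paste(pmin(u, v), pmax(u, v)) %in% ekey
  interior <- ids[type[ids] %in% c("biomarker", "tumor")]
  found <- list()
  for (L in seq_len(max_len)) {
    n_int <- L - 1L
    seqs <- if (n_int == 0) list(character(0)) else {
      grid <- do.call(expand.grid,
                      c(rep(list(interior), n_int),
                        list(stringsAsFactors = FALSE)))
      lapply(seq_len(nrow(grid)), function(i) as.character(grid[i, ]))
    }
    for (mid in seqs) {
      nodes <- c(drug, mid, adr)
      if (anyDuplicated(nodes)) next
      if (all(has_edge(nodes[-length(nodes)], nodes[-1]))) {
        found[[length(found) + 1L]] <- nodes
      }
    }
  }
  found
}

# Random typed graph expressed as a relations table (so the package's own
# assemble_graph builds it).
random_typed_relations <- function(n_nodes, p_edge = 0.4) {
  types <- sample(c("tumor", "biomarker", "drug", "adr"), n_nodes,
                  replace = TRUE)
  # at least one drug and one adr so path queries are well-posed
  types[1] <- "drug"; types[2] <- "adr"
  ids <- sprintf("N%02d", seq_len(n_nodes))
  combos <- utils::combn(n_nodes, 2)
  rows <- list()
  for (k in seq_len(ncol(combos))) {
    i <- combos[1, k]; j <- combos[2, k]
    if (types[i] != types[j] && runif(1) < p_edge) {
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = ids[i], target_type = types[i],
        feature_id = ids[j], feature_type = types[j],
        importance = round(runif(1, 0.5, 6), 3),
        p_present = NA_real_, p_absent = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) NULL else do.call(rbind, rows)
}

path_keys <- function(paths) {
  vapply(paths, function(p) {
    nodes <- if (is.list(p)) p$nodes else p
    paste(nodes, collapse = ">")
  }, character(1))
}

minimal_medline_xml <- function() {
  long1 <- paste(rep("Gefitinib resistance mechanisms involve receptor signalling.", 4),
                 collapse = " ")
  long2 <- paste(rep("Interstitial lung disease risk after kinase inhibition.", 4),
                 collapse = " ")
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n<PubmedArticleSet>\n',
    '<PubmedArticle><MedlineCitation><PMID>1001</PMID>',
    '<Article><ArticleTitle>First article</ArticleTitle>',
    '<Abstract><AbstractText>', long1, '</AbstractText></Abstract>',
    '<Journal><JournalIssue><PubDate><Year>2018</Year></PubDate>',
    '</JournalIssue></Journal></Article></MedlineCitation></PubmedArticle>\n',
    '<PubmedArticle><MedlineCitation><PMID>1002</PMID>',
    '<Article><ArticleTitle>Short one</ArticleTitle>',
    '<Abstract><AbstractText>Too short to keep.</AbstractText></Abstract>',
    '</Article></MedlineCitation></PubmedArticle>\n',
    '<PubmedArticle><MedlineCitation><PMID>1003</PMID>',
    '<Article><ArticleTitle>Third article</ArticleTitle>',
    '<Abstract><AbstractText>', long2, '</AbstractText></Abstract>',
    '<Journal><JournalIssue><PubDate><Year>2020</Year></PubDate>',
    '</JournalIssue></Journal></Article></MedlineCitation></PubmedArticle>\n',
    '</PubmedArticleSet>\n')
}

toy_lexicon <- function() {
  as_lexicon(data.frame(
    term = c("epidermal growth factor receptor", "growth factor",
             "interstitial lung disease", "osimertinib", "lung cancer",
             "dry skin"),
    concept_id = c("C-EGFR", "C-GF", "C-ILD", "C-OSI", "C-LC", "C-DS"),
    semantic_category = c("T116", "T123", "WHO", "T121", "T191", "WHO"),
    stringsAsFactors = FALSE))
}
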