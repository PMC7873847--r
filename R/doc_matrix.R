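#' Build the binary document-entity incidence matrix
#'
#' Rows are documents (in corpus order), columns are entities (sorted by
#' concept id). A cell is 1 exactly when the entity is mentioned positively
#' (non-negated) at least once in the document, never a count. Entities
#' whose document frequency falls below `min_entity_freq` are removed;
#' the default of 50 suppresses rare terms whose conditional probabilities
#' could not be estimated reliably, and is meant for corpora of MEDLINE
#' scale -- lower it for toy corpora.
#'
#' @param records A `tbkg_corpus` data frame.
#' @param mentions Mention data frame from [tag_corpus()] /
#'   [tag_entities()].
#' @param min_entity_freq Minimum number of documents an entity must occur
#'   in to keep its column. Default 50.
#' @return A `tbkg_matrix`: list with `docs` (ordered doc ids), `entities`
#'   (data frame `concept_id`, `node_type`, sorted by `concept_id`) and
#'   `incidence` (sparse 0/1 `Matrix` with dimnames).
#' @export
build_matrix <- function(records, mentions, min_entity_freq = 50L) {
  docs <- as.character(records$doc_id)
  unknown <- setdiff(unique(mentions$doc_id), docs)
  if (length(unknown) > 0) {
    tbkg_stop("tbkg_validation_error",
              "mentions reference unknown doc_id(s): %s",
              paste(utils::head(unknown, 5), collapse = ", "))
  }
  pos <- mentions[!mentions$negated, , drop = FALSE]
  ents <- unique(pos[, c("concept_id", "node_type")])
  if (anyDuplicated(ents$concept_id)) {
    bad <- ents$concept_id[duplicated(ents$concept_id)]
    tbkg_stop("tbkg_validation_error",
              "concept id(s) with more than one node type: %s",
              paste(unique(bad), collapse = ", "))
  }
  ents <- ents[order(ents$concept_id), , drop = FALSE]
  rownames(ents) <- NULL
  if (nrow(ents) == 0) {
    inc <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(length(docs), 0L))
    dimnames(inc) <- list(docs, character())
    return(new_tbkg_matrix(docs, ents, inc, min_entity_freq))
  }
  inc <- Matrix::sparseMatrix(i = match(pos$doc_id, docs),
                              j = match(pos$concept_id, ents$concept_id),
                              x = 1,
                              dims = c(length(docs), nrow(ents)))
  inc <- methods::as(1 * (inc > 0), "CsparseMatrix")
  keep <- Matrix::colSums(inc) >= min_entity_freq
  ents <- ents[keep, , drop = FALSE]
  rownames(ents) <- NULL
  inc <- inc[, keep, drop = FALSE]
  dimnames(inc) <- list(docs, ents$concept_id)
  new_tbkg_matrix(docs, ents, inc, min_entity_freq)
}

new_tbkg_matrix <- function(docs, entities, incidence, min_entity_freq) {
  structure(list(docs = docs, entities = entities, incidence = incidence,
                 min_entity_freq = as.integer(min_entity_freq)),
            class = "tbkg_matrix")
}

#' @export
print.tbkg_matrix <- function(x, ...) {
  cat(sprintf("tbkg document-entity matrix: %d docs x %d entities (%s)\n",
              length(x$docs), nrow(x$entities),
              paste(sprintf("%s=%d", names(table(x$entities$node_type)),
                            as.integer(table(x$entities$node_type))),
                    collapse = ", ")))
  invisible(x)
}

#' Serialize / restore a document-entity matrix
#'
#' The incidence is written as MatrixMarket sparse triplets
#' (`<prefix>.mtx`) with two sidecar TSVs: `<prefix>_docs.tsv` (document
#' index) and `<prefix>_entities.tsv` (entity index with node type).
#'
#' @param mat A `tbkg_matrix`.
#' @param dir Directory for the three files (created if needed).
#' @param prefix File-name prefix, default `"matrix"`.
#' @return `write_matrix`: the directory, invisibly. `read_matrix`: the
#'   restored `tbkg_matrix`.
#' @export
write_matrix <- function(mat, dir, prefix = "matrix") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inc <- methods::as(mat$incidence, "generalMatrix")
  dimnames(inc) <- NULL
  Matrix::writeMM(inc, file.path(dir, paste0(prefix, ".mtx")))
  utils::write.table(data.frame(doc_id = mat$docs),
                     file.path(dir, paste0(prefix, "_docs.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ents <- mat$entities
  ents$min_entity_freq <- mat$min_entity_freq
  utils::write.table(ents, file.path(dir, paste0(prefix, "_entities.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(dir, prefix = "matrix") {
  paths <- file.path(dir, paste0(prefix, c(".mtx", "_docs.tsv",
                                           "_entities.tsv")))
  for (p in paths) {
    if (!file.exists(p)) {
      tbkg_stop("tbkg_missing_input", "matrix component not found: %s", p)
    }
  }
  inc <- methods::as(Matrix::readMM(paths[1]), "CsparseMatrix")
  inc <- 1 * (inc > 0)
  docs <- utils::read.delim(paths[2], colClasses = "character")$doc_id
  ents <- utils::read.delim(paths[3],
                            colClasses = c(concept_id = "character",
                                           node_type = "character"))
  mef <- if ("min_entity_freq" %in% names(ents)) ents$min_entity_freq[1] else 1L
  ents <- ents[, c("concept_id", "node_type")]
  if (nrow(inc) != length(docs) || ncol(inc) != nrow(ents)) {
    tbkg_stop("tbkg_format_error",
              "matrix dimensions disagree with sidecar indexes in %s", dir)
  }
  dimnames(inc) <- list(docs, ents$concept_id)
  new_tbkg_matrix(docs, ents, inc, as.integer(mef))
}
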