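#' Semantic-category to node-type mapping
#'
#' The knowledge graph recognizes four node types. Thirteen UMLS semantic
#' category codes map onto three of them: `T191` (Neoplastic Process) is
#' tumor-type; `T121` (Pharmacologic Substance) and `T200` (Clinical Drug)
#' are drug-type; the ten molecular categories `T109`, `T114`, `T116`,
#' `T123`, `T125`, `T126`, `T129`, `T130`, `T192`, `T195` are
#' biomarker-type. ADR-type entries do not come from a semantic category but
#' from a designated ADR source dictionary; such lexicon rows carry the
#' source code `WHO` in the `semantic_category` column.
#'
#' @return A data frame with columns `semantic_category`, `meaning` and
#'   `node_type`, one row per recognized code.
#' @export
#' @examples
#' semantic_type_table()
semantic_type_table <- function() {
  data.frame(
    semantic_category = c("T109", "T114", "T116", "T121", "T123", "T125",
                          "T126", "T129", "T130", "T191", "T192", "T195",
                          "T200", "WHO"),
    meaning = c("Organic Chemical",
                "Nucleic Acid, Nucleoside, or Nucleotide",
                "Amino Acid, Peptide, or Protein",
                "Pharmacologic Substance",
                "Biologically Active Substance",
                "Hormone",
                "Enzyme",
                "Immunologic Factor",
                "Indicator, Reagent, or Diagnostic Aid",
                "Neoplastic Process",
                "Receptor",
                "Antibiotic",
                "Clinical Drug",
                "ADR source dictionary"),
    node_type = c("biomarker", "biomarker", "biomarker", "drug", "biomarker",
                  "biomarker", "biomarker", "biomarker", "biomarker",
                  "tumor", "biomarker", "biomarker", "drug", "adr"),
    stringsAsFactors = FALSE
  )
}

new_lexicon <- function(df) {
  df <- df[, c("term", "concept_id", "semantic_category", "node_type")]
  rownames(df) <- NULL
  class(df) <- c("tbkg_lexicon", "data.frame")
  df
}

#' Load a typed entity lexicon from a TSV file
#'
#' The lexicon drives dictionary tagging: each row maps a surface term to a
#' concept id and a semantic category, from which the node type is derived
#' (see [semantic_type_table()]). Terms are lower-cased on load. Rows whose
#' category is neither one of the thirteen recognized codes nor the ADR
#' source code `WHO` are dropped with a warning (or rejected when
#' `strict = TRUE`).
#'
#' @param path Path to a UTF-8 TSV file with columns `term`, `concept_id`
#'   and `semantic_category`.
#' @param strict If `TRUE`, any unknown semantic category is an error
#'   instead of a counted warning.
#' @return A `tbkg_lexicon` data frame with columns `term`, `concept_id`,
#'   `semantic_category`, `node_type`. The number of rejected rows is
#'   attached as attribute `n_rejected`.
#' @export
load_lexicon <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    tbkg_stop("tbkg_missing_input", "lexicon file not found: %s", path)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  needed <- c("term", "concept_id", "semantic_category")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    tbkg_stop("tbkg_format_error", "lexicon TSV lacks column(s): %s",
              paste(missing_cols, collapse = ", "))
  }
  as_lexicon(df, strict = strict)
}

#' Build a lexicon from an in-memory table
#'
#' @param df Data frame with columns `term`, `concept_id`,
#'   `semantic_category`.
#' @inheritParams load_lexicon
#' @return A `tbkg_lexicon` data frame; see [load_lexicon()].
#' @export
as_lexicon <- function(df, strict = FALSE) {
  map <- semantic_type_table()
  df$term <- trimws(tolower(df$term))
  if (any(!nzchar(df$term))) {
    tbkg_stop("tbkg_validation_error", "lexicon contains %d empty term(s)",
              sum(!nzchar(df$term)))
  }
  idx <- match(df$semantic_category, map$semantic_category)
  n_rejected <- sum(is.na(idx))
  if (n_rejected > 0) {
    if (strict) {
      bad <- unique(df$semantic_category[is.na(idx)])
      tbkg_stop("tbkg_validation_error",
                "unknown semantic categor%s in strict mode: %s",
                if (length(bad) > 1) "ies" else "y",
                paste(bad, collapse = ", "))
    }
    warning(sprintf("dropped %d lexicon row(s) with unmapped semantic categories",
                    n_rejected), call. = FALSE)
    df <- df[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  df$node_type <- map$node_type[idx]
  out <- new_lexicon(df)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a lexicon to TSV
#'
#' Inverse of [load_lexicon()] (the derived `node_type` column is included
#' for human readers but recomputed on load).
#'
#' @param lexicon A `tbkg_lexicon`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.table(as.data.frame(lexicon), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
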