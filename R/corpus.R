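#' Read a corpus of literature abstracts
#'
#' Two dialects are supported. `"jsonl"` holds one JSON object per line with
#' keys `doc_id`, `title`, `body` and optional `year`. `"medline-xml"` is a
#' minimal MEDLINE/PubMed XML reader that extracts only the PMID, the
#' article title, the abstract text (all `AbstractText` sections
#' concatenated) and the publication year; every other element of the DTD
#' is ignored. Abstracts shorter than `min_body_chars` are dropped, the
#' usual guard against uninformative stub abstracts.
#'
#' @param path Path to the corpus file (UTF-8).
#' @param format `"jsonl"` or `"medline-xml"`.
#' @param min_body_chars Minimum abstract length in characters; shorter
#'   records are removed. Default 100.
#' @return A `tbkg_corpus` data frame with columns `doc_id`, `title`,
#'   `body`, `year` (integer, `NA` when absent), in order of appearance.
#' @export
read_corpus <- function(path, format = c("jsonl", "medline-xml"),
                        min_body_chars = 100L) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    tbkg_stop("tbkg_missing_input", "corpus file not found: %s", path)
  }
  recs <- switch(format,
                 "jsonl" = read_corpus_jsonl(path),
                 "medline-xml" = read_corpus_medline(path))
  if (anyDuplicated(recs$doc_id)) {
    dup <- unique(recs$doc_id[duplicated(recs$doc_id)])
    tbkg_stop("tbkg_validation_error", "duplicate doc_id in corpus: %s",
              paste(utils::head(dup, 5), collapse = ", "))
  }
  recs <- recs[nchar(recs$body) >= min_body_chars, , drop = FALSE]
  rownames(recs) <- NULL
  class(recs) <- c("tbkg_corpus", "data.frame")
  recs
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(doc_id = character(), title = character(),
                      body = character(), year = integer(),
                      stringsAsFactors = FALSE))
  }
  parse_one <- function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) {
                      tbkg_stop("tbkg_format_error",
                                "record %d of %s is not valid JSON: %s",
                                i, path, conditionMessage(e))
                    })
    if (is.null(rec$doc_id) || is.null(rec$body)) {
      tbkg_stop("tbkg_format_error",
                "record %d of %s lacks doc_id or body", i, path)
    }
    data.frame(doc_id = as.character(rec$doc_id),
               title = if (is.null(rec$title)) "" else as.character(rec$title),
               body = as.character(rec$body),
               year = if (is.null(rec$year)) NA_integer_ else as.integer(rec$year),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_along(lines), parse_one))
}

read_corpus_medline <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    tbkg_stop("tbkg_format_error", "cannot parse %s as XML: %s",
                              path, conditionMessage(e))
                  })
  cites <- xml2::xml_find_all(doc, ".//MedlineCitation")
  if (length(cites) == 0) {
    return(data.frame(doc_id = character(), title = character(),
                      body = character(), year = integer(),
                      stringsAsFactors = FALSE))
  }
  parse_one <- function(i) {
    cite <- cites[[i]]
    pmid <- xml2::xml_text(xml2::xml_find_first(cite, "./PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      tbkg_stop("tbkg_format_error",
                "citation %d of %s has no PMID", i, path)
    }
    title <- xml2::xml_text(xml2::xml_find_first(cite, ".//ArticleTitle"))
    abst <- xml2::xml_find_all(cite, ".//Abstract/AbstractText")
    body <- paste(xml2::xml_text(abst), collapse = " ")
    year <- xml2::xml_text(xml2::xml_find_first(cite, ".//PubDate/Year"))
    data.frame(doc_id = pmid,
               title = if (is.na(title)) "" else title,
               body = body,
               year = if (is.na(year)) NA_integer_ else as.integer(year),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_along(cites), parse_one))
}

#' Write a corpus in the JSONL dialect
#'
#' One JSON object per line with keys `doc_id`, `title`, `body` and, when
#' known, `year`. Reading the result back with
#' `read_corpus(format = "jsonl", min_body_chars = 0)` is the identity.
#'
#' @param corpus A `tbkg_corpus` data frame (or any data frame with the
#'   same columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    rec <- list(doc_id = corpus$doc_id[i], title = corpus$title[i],
                body = corpus$body[i])
    if (!is.na(corpus$year[i])) rec$year <- as.integer(corpus$year[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}
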