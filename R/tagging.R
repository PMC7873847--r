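# Dictionary tagging: case-insensitive exact longest-match over tokenized
# text, with a small negation-cue filter standing in for a full clinical
# NLP polarity module.

negation_cues_single <- c("no", "not", "without", "denies")
negation_cues_bigram <- list(c("absence", "of"), c("negative", "for"))

tokenize <- function(text) {
  text <- tolower(text)
  m <- gregexpr("[[:alnum:]']+", text)[[1]]
  if (m[1] == -1L) {
    return(list(tokens = character(), start = integer(), end = integer()))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  list(tokens = substring(text, start, start + len - 1L),
       start = start, end = start + len - 1L)
}

# Index lexicon terms by first token; within a bucket, longer terms first,
# ties by term then concept_id so ambiguous dictionaries tag deterministically.
prep_lexicon <- function(lexicon) {
  toks <- lapply(lexicon$term, function(t) tokenize(t)$tokens)
  keep <- lengths(toks) > 0
  lexicon <- lexicon[keep, , drop = FALSE]
  toks <- toks[keep]
  ord <- order(lexicon$term, lexicon$concept_id)
  lexicon <- lexicon[ord, , drop = FALSE]
  toks <- toks[ord]
  first <- vapply(toks, `[`, character(1), 1L)
  buckets <- split(seq_along(first), first)
  buckets <- lapply(buckets, function(ix) ix[order(-lengths(toks[ix]))])
  list(lexicon = lexicon, tokens = toks, buckets = buckets)
}

negated_at <- function(tokens, i, window = 3L) {
  lo <- max(1L, i - window)
  if (lo > i - 1L) return(FALSE)
  win <- tokens[lo:(i - 1L)]
  if (any(win %in% negation_cues_single)) return(TRUE)
  for (cue in negation_cues_bigram) {
    if (length(win) >= 2) {
      for (j in seq_len(length(win) - 1L)) {
        if (win[j] == cue[1] && win[j + 1L] == cue[2]) return(TRUE)
      }
    }
  }
  FALSE
}

tag_text <- function(doc_id, text, prep, negation = TRUE,
                     negation_window = 3L) {
  tk <- tokenize(text)
  n <- length(tk$tokens)
  out <- list()
  i <- 1L
  while (i <= n) {
    bucket <- prep$buckets[[tk$tokens[i]]]
    hit <- 0L
    if (!is.null(bucket)) {
      for (ix in bucket) {
        tt <- prep$tokens[[ix]]
        L <- length(tt)
        if (i + L - 1L <= n && all(tk$tokens[i:(i + L - 1L)] == tt)) {
          hit <- ix
          break
        }
      }
    }
    if (hit > 0L) {
      L <- length(prep$tokens[[hit]])
      out[[length(out) + 1L]] <- data.frame(
        doc_id = doc_id,
        concept_id = prep$lexicon$concept_id[hit],
        node_type = prep$lexicon$node_type[hit],
        start = tk$start[i],
        end = tk$end[i + L - 1L],
        negated = negation && negated_at(tk$tokens, i, negation_window),
        stringsAsFactors = FALSE)
      i <- i + L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0) empty_mentions() else do.call(rbind, out)
}

empty_mentions <- function() {
  data.frame(doc_id = character(), concept_id = character(),
             node_type = character(), start = integer(), end = integer(),
             negated = logical(), stringsAsFactors = FALSE)
}

#' Tag entity mentions in one abstract
#'
#' Scans the concatenated title and body (lower-cased, tokenized on
#' alphanumeric runs) left to right and emits the longest lexicon term
#' matching at each position; shorter terms overlapping a longer match are
#' suppressed. A mention is flagged `negated` when a negation cue (`no`,
#' `not`, `without`, `denies`, `absence of`, `negative for`) occurs within
#' the `negation_window` tokens immediately preceding it; negated mentions
#' are excluded later when the incidence matrix is built, so only entities
#' mentioned positively count as related to an abstract.
#'
#' @param record A single corpus row (list or one-row data frame with
#'   `doc_id`, `title`, `body`).
#' @param lexicon A `tbkg_lexicon`.
#' @param negation Apply the negation-cue filter? Default `TRUE`.
#' @param negation_window Number of preceding tokens searched for a cue.
#' @return A data frame of mentions: `doc_id`, `concept_id`, `node_type`,
#'   `start`, `end` (character offsets into `paste(title, body)`),
#'   `negated`.
#' @export
tag_entities <- function(record, lexicon, negation = TRUE,
                         negation_window = 3L) {
  if (nrow(lexicon) == 0) {
    tbkg_stop("tbkg_validation_error", "lexicon is empty")
  }
  prep <- prep_lexicon(lexicon)
  text <- paste(record$title, record$body)
  tag_text(as.character(record$doc_id), text, prep,
           negation = negation, negation_window = negation_window)
}

#' Tag an entire corpus
#'
#' Applies [tag_entities()] to every record, preparing the lexicon index
#' once.
#'
#' @param corpus A `tbkg_corpus` data frame.
#' @inheritParams tag_entities
#' @return A data frame of mentions across all documents (possibly
#'   zero-row).
#' @export
tag_corpus <- function(corpus, lexicon, negation = TRUE,
                       negation_window = 3L) {
  if (nrow(lexicon) == 0) {
    tbkg_stop("tbkg_validation_error", "lexicon is empty")
  }
  prep <- prep_lexicon(lexicon)
  res <- lapply(seq_len(nrow(corpus)), function(i) {
    tag_text(corpus$doc_id[i], paste(corpus$title[i], corpus$body[i]),
             prep, negation = negation, negation_window = negation_window)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) empty_mentions() else out
}
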