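test_that("minimal MEDLINE XML is read and short abstracts are dropped", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(minimal_medline_xml(), path)
  recs <- read_corpus(path, format = "medline-xml", min_body_chars = 100)
  expect_equal(recs$doc_id, c("1001", "1003"))
  expect_equal(recs$year, c(2018L, 2020L))
  expect_true(all(nchar(recs$body) >= 100))
  # with the filter off, all three parse and order is preserved
  all3 <- read_corpus(path, format = "medline-xml", min_body_chars = 0)
  expect_equal(all3$doc_id, c("1001", "1002", "1003"))
})

test_that("jsonl corpus handles empty files, bad records and duplicates", {
  empty <- withr::local_tempfile(fileext = ".jsonl")
  file.create(empty)
  expect_equal(nrow(read_corpus(empty, format = "jsonl")), 0L)

  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"doc_id":"a","title":"t","body":"b"}', "{not json"), bad)
  expect_error(read_corpus(bad, format = "jsonl", min_body_chars = 0),
               class = "tbkg_format_error")
  expect_error(read_corpus(bad, format = "jsonl", min_body_chars = 0),
               regexp = "record 2")

  dup <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(rep('{"doc_id":"a","title":"t","body":"same body text"}', 2), dup)
  expect_error(read_corpus(dup, format = "jsonl", min_body_chars = 0),
               class = "tbkg_validation_error")
})

test_that("jsonl write/read round-trips a generated corpus exactly", {
  g <- generate_graph(seed = 11)
  sim <- generate_corpus(g, n_docs = 10, seed = 12)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(sim$corpus, path)
  back <- read_corpus(path, format = "jsonl", min_body_chars = 0)
  expect_equal(as.data.frame(back), as.data.frame(sim$corpus))
})

test_that("lexicon loading maps the thirteen category codes and rejects others", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\tconcept_id\tsemantic_category",
               "malignant neoplasm\tC000X\tT191",
               "combo pill\tC000Y\tT200",
               "random disease\tC000Z\tT047",
               "rash\tC000W\tWHO"),
             path)
  expect_warning(lex <- load_lexicon(path), "dropped 1")
  expect_equal(attr(lex, "n_rejected"), 1L)
  expect_equal(nrow(lex), 3L)
  expect_equal(lex$node_type[lex$concept_id == "C000X"], "tumor")
  expect_equal(lex$node_type[lex$concept_id == "C000Y"], "drug")
  expect_equal(lex$node_type[lex$concept_id == "C000W"], "adr")
  expect_error(load_lexicon(path, strict = TRUE),
               class = "tbkg_validation_error")
  # full mapping sanity: 13 semantic codes plus the ADR source designation
  map <- semantic_type_table()
  expect_equal(nrow(map), 14L)
  expect_equal(sum(map$node_type == "biomarker"), 10L)
  expect_equal(map$node_type[map$semantic_category == "T191"], "tumor")
})

test_that("tagger prefers the longest match and is case-insensitive", {
  lex <- toy_lexicon()
  rec <- list(doc_id = "d1", title = "",
              body = "The Epidermal Growth Factor Receptor pathway")
  m <- tag_entities(rec, lex)
  expect_equal(m$concept_id, "C-EGFR")   # not the embedded "growth factor"
  # same text lower-cased tags identically
  rec2 <- list(doc_id = "d1", title = "", body = tolower(rec$body))
  expect_equal(tag_entities(rec2, lex), m)
  # a free-standing shorter term still matches
  m2 <- tag_entities(list(doc_id = "d2", title = "",
                          body = "a growth factor was assayed"), lex)
  expect_equal(m2$concept_id, "C-GF")
  # no lexicon term present -> empty result
  m3 <- tag_entities(list(doc_id = "d3", title = "", body = "nothing here"),
                     lex)
  expect_equal(nrow(m3), 0L)
})

test_that("negation cues within three preceding tokens flag mentions", {
  lex <- toy_lexicon()
  neg <- tag_entities(list(doc_id = "d1", title = "",
                           body = "no interstitial lung disease was observed"),
                      lex)
  expect_true(neg$negated)
  far <- tag_entities(list(
    doc_id = "d2", title = "",
    body = "no new events were seen although interstitial lung disease occurred"),
    lex)
  expect_false(far$negated)
  bigram <- tag_entities(list(doc_id = "d3", title = "",
                              body = "absence of dry skin was noted"), lex)
  expect_true(bigram$negated)
  off <- tag_entities(list(doc_id = "d4", title = "",
                           body = "no interstitial lung disease"), lex,
                      negation = FALSE)
  expect_false(off$negated)
})

test_that("incidence matrix binarizes, filters by frequency and validates ids", {
  lex <- toy_lexicon()
  corpus <- data.frame(
    doc_id = c("d1", "d2"),
    title = c("", ""),
    body = c("osimertinib osimertinib osimertinib with dry skin",
             "osimertinib alone"),
    year = NA_integer_, stringsAsFactors = FALSE)
  mentions <- tag_corpus(corpus, lex)
  m <- build_matrix(corpus, mentions, min_entity_freq = 1)
  # hand-computed incidence; repeated mentions stay 1
  expect_equal(as.matrix(m$incidence),
               matrix(c(1, 0, 1, 1), 2, 2,
                      dimnames = list(c("d1", "d2"), c("C-DS", "C-OSI"))))
  # frequency filter: dry skin occurs in 1 of 2 docs
  m2 <- build_matrix(corpus, mentions, min_entity_freq = 2)
  expect_equal(m2$entities$concept_id, "C-OSI")
  # entity below the cutoff in 49 of 50 docs is removed at the default 50
  big <- data.frame(doc_id = sprintf("d%03d", 1:50), title = "",
                    body = c(rep("osimertinib and dry skin", 49),
                             "osimertinib alone"),
                    year = NA_integer_, stringsAsFactors = FALSE)
  mm <- build_matrix(big, tag_corpus(big, lex), min_entity_freq = 50)
  expect_equal(mm$entities$concept_id, "C-OSI")
  # unknown doc id in mentions
  rogue <- mentions
  rogue$doc_id[1] <- "ghost"
  expect_error(build_matrix(corpus, rogue, min_entity_freq = 1),
               class = "tbkg_validation_error")
  # negated mentions never enter the matrix
  negcorp <- data.frame(doc_id = "d1", title = "",
                        body = "without dry skin but osimertinib given",
                        year = NA_integer_, stringsAsFactors = FALSE)
  mn <- build_matrix(negcorp, tag_corpus(negcorp, lex), min_entity_freq = 1)
  expect_equal(mn$entities$concept_id, "C-OSI")
})

test_that("matrix cells are 0/1 and column frequencies respect the cutoff on random corpora", {
  set.seed(42)
  for (rep in 1:5) {
    g <- generate_graph(seed = 100 + rep, layout = "pairwise",
                        edge_density = 0.2)
    sim <- generate_corpus(g, n_docs = 60, seed = 200 + rep)
    mentions <- tag_corpus(sim$corpus, sim$lexicon)
    cutoff <- sample(1:5, 1)
    m <- build_matrix(sim$corpus, mentions, min_entity_freq = cutoff)
    vals <- unique(as.numeric(m$incidence))
    expect_true(all(vals %in% c(0, 1)))
    if (ncol(m$incidence) > 0) {
      expect_true(all(Matrix::colSums(m$incidence) >= cutoff))
    }
  }
})

test_that("matrix serialization round-trips through MatrixMarket + sidecars", {
  g <- generate_graph(seed = 5)
  sim <- generate_corpus(g, n_docs = 40, seed = 6)
  dir <- withr::local_tempdir()
  write_matrix(sim$matrix, dir)
  back <- read_matrix(dir)
  expect_equal(back$docs, sim$matrix$docs)
  expect_equal(back$entities, sim$matrix$entities)
  expect_equal(as.matrix(back$incidence), as.matrix(sim$matrix$incidence))
})
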