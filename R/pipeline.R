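# Pipeline driver: a flat key-value configuration, one function per
# stage, and a run log so any artifact can be traced to the exact
# configuration and seed that produced it.

#' Default pipeline configuration
#'
#' A flat list of every tunable the pipeline understands. File paths
#' (`corpus`, `lexicon`, `gold`, `graph`, `matrix_dir`) default to
#' locations inside `out_dir`, so consecutive stages chain without extra
#' wiring. The synthetic-generation keys mirror the defaults of
#' [generate_graph()] and are only consulted by the `simulate` stage.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    out_dir = "tbkg_run",
    corpus = NULL,            # default: <out_dir>/corpus.jsonl
    corpus_format = "jsonl",
    lexicon = NULL,           # default: <out_dir>/lexicon.tsv
    gold = NULL,
    drug = NULL,
    min_body_chars = 100,
    min_entity_freq = 50,
    alpha = 1,
    importance_threshold = 1.0,
    max_path_len = 3,
    label_fraction = 0.05,
    cv_folds = 3,
    cv_target_type = "tumor",
    cv_feature_type = "biomarker",
    seed = 1,
    # simulate stage
    n_docs = 5000,
    n_tumor = 4, n_drug = 6, n_biomarker = 10, n_adr = 10,
    edge_density = 0.3,
    p_present = 0.3, p_absent = 0.03,
    background_rate = 0.02, anchor_rate = 0.25,
    layout = "matched"
  )
}

merge_config <- function(config = list(), config_file = NULL) {
  cfg <- default_config()
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      tbkg_stop("tbkg_missing_input", "config file not found: %s",
                config_file)
    }
    from_file <- yaml::read_yaml(config_file)
    cfg[names(from_file)] <- from_file
  }
  cfg[names(config)] <- config
  unknown <- setdiff(names(cfg), names(default_config()))
  if (length(unknown) > 0) {
    tbkg_stop("tbkg_config_error", "unknown config key(s): %s",
              paste(unknown, collapse = ", "))
  }
  num_keys <- c("min_body_chars", "min_entity_freq", "alpha",
                "importance_threshold", "max_path_len", "label_fraction",
                "cv_folds", "seed", "n_docs", "n_tumor", "n_drug",
                "n_biomarker", "n_adr", "edge_density", "p_present",
                "p_absent", "background_rate", "anchor_rate")
  for (k in num_keys) cfg[[k]] <- as.numeric(cfg[[k]])
  if (anyNA(unlist(cfg[num_keys]))) {
    tbkg_stop("tbkg_config_error", "non-numeric value for a numeric key")
  }
  if (cfg$label_fraction < 0 || cfg$label_fraction > 0.5) {
    tbkg_stop("tbkg_config_error", "label_fraction must be in [0, 0.5]")
  }
  cfg
}

config_hash <- function(cfg) {
  canon <- cfg[order(names(cfg))]
  txt <- vapply(names(canon), function(k) {
    sprintf("%s=%s", k, paste(format(canon[[k]], digits = 15),
                              collapse = ","))
  }, character(1))
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

cfg_path <- function(cfg, key, default_name) {
  p <- cfg[[key]]
  if (is.null(p)) file.path(cfg$out_dir, default_name) else p
}

log_run <- function(cfg, stage, counts) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg[order(names(cfg))],
                   file.path(cfg$out_dir, "config_used.yml"))
  line <- sprintf("stage=%s\tconfig_hash=%s\tseed=%s\t%s",
                  stage, config_hash(cfg), format(cfg$seed),
                  paste(sprintf("%s=%s", names(counts), counts),
                        collapse = "\t"))
  cat(line, "\n", sep = "",
      file = file.path(cfg$out_dir, "run_log.tsv"), append = TRUE)
  message(line)
}

#' Run one pipeline stage
#'
#' Stages chain through files under `out_dir`:
#' \describe{
#'   \item{`simulate`}{Plant a graph, sample a corpus; writes
#'     `corpus.jsonl`, `lexicon.tsv`, `truth_edges.tsv`.}
#'   \item{`tag`}{Read corpus and lexicon, tag mentions, build the
#'     frequency-filtered incidence matrix; writes `matrix.mtx` plus
#'     sidecars.}
#'   \item{`build-graph`}{Score all six type pairs with the importance
#'     measure at `importance_threshold` and assemble the graph; writes
#'     `graph.tsv` and `graph.graphml`.}
#'   \item{`discover`}{Rank every ADR for `drug` with explanation paths
#'     and label the top/bottom `label_fraction`; writes `findings.tsv`
#'     and `findings_paths.jsonl`.}
#'   \item{`evaluate`}{Compare labeled findings with the `gold` ADR list;
#'     writes `evaluation.json`.}
#'   \item{`crossval`}{Cross-validated naive-Bayes accuracy on the
#'     matrix; writes `crossval.json`.}
#' }
#' Every stage echoes the full configuration (with its MD5 hash and the
#' seed) to `config_used.yml` and appends a line to `run_log.tsv`;
#' identical configuration and seed reproduce byte-identical artifacts.
#'
#' @param subcommand One of `simulate`, `tag`, `build-graph`, `discover`,
#'   `evaluate`, `crossval`.
#' @param config Named list of overrides on top of [default_config()].
#' @param config_file Optional YAML file applied between the defaults and
#'   `config`.
#' @return The stage's main result, invisibly.
#' @export
run_pipeline <- function(subcommand, config = list(), config_file = NULL) {
  cfg <- merge_config(config, config_file)
  stages <- c("simulate", "tag", "build-graph", "discover", "evaluate",
              "crossval")
  if (!subcommand %in% stages) {
    tbkg_stop("tbkg_config_error", "unknown subcommand '%s' (expected %s)",
              subcommand, paste(stages, collapse = ", "))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(subcommand,
         "simulate" = stage_simulate(cfg),
         "tag" = stage_tag(cfg),
         "build-graph" = stage_build_graph(cfg),
         "discover" = stage_discover(cfg),
         "evaluate" = stage_evaluate(cfg),
         "crossval" = stage_crossval(cfg))
}

stage_simulate <- function(cfg) {
  sizes <- c(tumor = cfg$n_tumor, drug = cfg$n_drug,
             biomarker = cfg$n_biomarker, adr = cfg$n_adr)
  g <- generate_graph(sizes = sizes, edge_density = cfg$edge_density,
                      effect = c(p_present = cfg$p_present,
                                 p_absent = cfg$p_absent),
                      background_rate = cfg$background_rate,
                      anchor_rate = cfg$anchor_rate,
                      layout = cfg$layout, seed = cfg$seed)
  sim <- generate_corpus(g, n_docs = cfg$n_docs, seed = cfg$seed + 1)
  write_corpus_jsonl(sim$corpus, cfg_path(cfg, "corpus", "corpus.jsonl"))
  write_lexicon(sim$lexicon, cfg_path(cfg, "lexicon", "lexicon.tsv"))
  write_truth(sim, file.path(cfg$out_dir, "truth_edges.tsv"))
  log_run(cfg, "simulate",
          c(n_docs = nrow(sim$corpus), n_nodes = nrow(g$nodes),
            n_true_edges = nrow(g$edges)))
  invisible(sim)
}

stage_tag <- function(cfg) {
  corpus <- read_corpus(cfg_path(cfg, "corpus", "corpus.jsonl"),
                        format = cfg$corpus_format,
                        min_body_chars = cfg$min_body_chars)
  lexicon <- load_lexicon(cfg_path(cfg, "lexicon", "lexicon.tsv"))
  mentions <- tag_corpus(corpus, lexicon)
  mat <- build_matrix(corpus, mentions,
                      min_entity_freq = cfg$min_entity_freq)
  write_matrix(mat, cfg$out_dir)
  log_run(cfg, "tag",
          c(n_docs = length(mat$docs), n_mentions = nrow(mentions),
            n_entities = nrow(mat$entities)))
  invisible(mat)
}

stage_build_graph <- function(cfg) {
  mat <- read_matrix(cfg$out_dir)
  present <- unique(mat$entities$node_type)
  rels <- list()
  for (pr in synth_pairs) {
    if (all(pr %in% present)) {
      rels[[paste(pr, collapse = "-")]] <-
        discover_relations(mat, pr, threshold = cfg$importance_threshold,
                           alpha = cfg$alpha)
    }
  }
  graph <- assemble_graph(rels)
  save_graph(graph, file.path(cfg$out_dir, "graph.tsv"))
  export_graphml(graph, file.path(cfg$out_dir, "graph.graphml"))
  log_run(cfg, "build-graph",
          c(n_nodes = nrow(graph$nodes), n_edges = nrow(graph$edges)))
  invisible(graph)
}

stage_discover <- function(cfg) {
  if (is.null(cfg$drug)) {
    tbkg_stop("tbkg_config_error", "the discover stage needs config key 'drug'")
  }
  graph <- load_graph(file.path(cfg$out_dir, "graph.tsv"))
  findings <- rank_adrs(graph, cfg$drug, max_len = cfg$max_path_len)
  findings <- label_extremes(findings, fraction = cfg$label_fraction)
  write_findings(findings, file.path(cfg$out_dir, "findings.tsv"),
                 file.path(cfg$out_dir, "findings_paths.jsonl"))
  log_run(cfg, "discover",
          c(drug = cfg$drug, n_findings = nrow(findings),
            n_important = sum(findings$label == "important")))
  invisible(findings)
}

stage_evaluate <- function(cfg) {
  if (is.null(cfg$gold)) {
    tbkg_stop("tbkg_config_error", "the evaluate stage needs config key 'gold'")
  }
  findings_path <- file.path(cfg$out_dir, "findings.tsv")
  if (!file.exists(findings_path)) {
    tbkg_stop("tbkg_missing_input", "findings not found: %s", findings_path)
  }
  findings <- utils::read.delim(findings_path,
                                colClasses = c(adr = "character",
                                               label = "character"))
  lex_path <- cfg_path(cfg, "lexicon", "lexicon.tsv")
  lexicon <- if (file.exists(lex_path)) load_lexicon(lex_path) else NULL
  gold <- read_gold(cfg$gold, lexicon)
  res <- evaluate_against_gold(findings, gold)
  out <- list(table = res$table[c("a", "b", "c", "d", "n")],
              kappa = res$kappa, sensitivity = res$sensitivity,
              specificity = res$specificity,
              n_excluded = res$n_excluded,
              config_hash = config_hash(cfg))
  jsonlite::write_json(out, file.path(cfg$out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_run(cfg, "evaluate",
          c(kappa = sprintf("%.4f", res$kappa),
            sensitivity = sprintf("%.4f", res$sensitivity),
            specificity = sprintf("%.4f", res$specificity)))
  invisible(res)
}

stage_crossval <- function(cfg) {
  mat <- read_matrix(cfg$out_dir)
  res <- cross_validate(mat, cfg$cv_target_type, cfg$cv_feature_type,
                        k = cfg$cv_folds, seed = cfg$seed,
                        alpha = cfg$alpha)
  out <- list(accuracy = res$accuracy, k = res$k, seed = cfg$seed,
              target_type = cfg$cv_target_type,
              feature_type = cfg$cv_feature_type,
              per_target = res$per_target,
              config_hash = config_hash(cfg))
  jsonlite::write_json(out, file.path(cfg$out_dir, "crossval.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  log_run(cfg, "crossval", c(accuracy = sprintf("%.4f", res$accuracy)))
  invisible(res)
}

#' Command-line entry point
#'
#' Thin argument parser behind the `inst/cli/tbkg.R` script:
#' `tbkg.R <subcommand> [--config file.yml] [--key value ...]`, where any
#' `--key value` pair overrides the corresponding configuration key.
#' Returns (rather than calls) the exit status so it can be tested:
#' 0 on success, 2 when a required input file is missing, 1 on any other
#' validation or configuration failure.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: tbkg.R <simulate|tag|build-graph|discover|evaluate|crossval>",
                 "[--config file.yml] [--key value ...]")
  if (length(args) < 1) {
    message(usage)
    return(1L)
  }
  subcommand <- args[1]
  rest <- args[-1]
  if (length(rest) %% 2 != 0 || (length(rest) > 0 &&
                                 !all(startsWith(rest[c(TRUE, FALSE)], "--")))) {
    message("malformed flags; ", usage)
    return(1L)
  }
  keys <- sub("^--", "", rest[c(TRUE, FALSE)])
  vals <- rest[c(FALSE, TRUE)]
  config_file <- NULL
  overrides <- list()
  for (i in seq_along(keys)) {
    if (keys[i] == "config") {
      config_file <- vals[i]
    } else {
      v <- suppressWarnings(as.numeric(vals[i]))
      overrides[[keys[i]]] <- if (is.na(v)) vals[i] else v
    }
  }
  tryCatch({
    run_pipeline(subcommand, config = overrides, config_file = config_file)
    0L
  },
  tbkg_missing_input = function(e) {
    message("error: ", conditionMessage(e))
    2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}
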