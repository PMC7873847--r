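# tbkg — typed knowledge graphs for explainable ADR discovery

`tbkg` mines adverse-drug-reaction (ADR) signals for antitumor drugs from
literature abstracts, and attaches to every ranked drug–ADR candidate the
*explanation paths* (drug – biomarker – ADR, drug – tumor – … – ADR) that
connect the two in a typed knowledge graph. It is aimed at
pharmacovigilance and literature-mining researchers who need signal
rankings they can interrogate, not just a score.

## The method

1. **Corpus → matrix.** Abstracts (minimal MEDLINE XML or JSONL) are tagged
   with a dictionary longest-match tagger driven by a typed lexicon
   (UMLS-style semantic categories map terms to tumor, biomarker, drug or
   ADR nodes; a small negation-cue window keeps only positive mentions).
   The corpus becomes a binary documents × entities incidence matrix;
   entities in fewer than `min_entity_freq` documents (default 50) are
   dropped.
2. **Matrix → graph.** For each target entity *y* and feature entity *x*, a
   per-target Bernoulli naive-Bayes model is fitted by smoothed maximum
   likelihood and the relation is scored with the importance measure

   IMP(x, y) = log₂ p̂(x=1 | y=1) − log₂ p̂(x=1 | y=0),

   the base-2 log ratio of the feature's conditional presence probability
   given the target's presence versus absence. Scores above a threshold
   (default 1.0 ≙ "twice as likely") become weighted, undirected,
   strictly inter-type edges.
3. **Graph → findings.** For a query drug, every ADR node is ranked: by the
   direct drug–ADR edge weight when it exists, otherwise by the
   widest-bottleneck support of its explanation paths (depth-first
   enumeration, interior nodes restricted to biomarkers/tumors). The top
   and bottom 5% are labeled *important* / *unlikely*, and agreement with a
   gold ADR list is reported as Cohen's kappa, sensitivity and specificity,
   next to a classical co-occurrence baseline.

A planted-truth synthetic generator (known conditional probabilities,
exact truth tables) makes the whole pipeline testable without licensed
corpora or dictionaries. See `vignettes/tbkg-methods.Rmd` for the model,
parameter choices, and known limitations.

## Worked example

```r
library(tbkg)

# The importance score for a drug-ADR pair whose ADR appears in 10.4% of
# the abstracts mentioning the drug and 0.5% of the rest:
importance_value(0.104, 0.005)
#> [1] 4.378512      # log2(0.104/0.005); >1 means "more than twice as likely"

# End to end on a planted corpus of 5,000 synthetic abstracts:
g   <- generate_graph(seed = 7)                 # planted truth: 10 edges, IMP = 3.32
sim <- generate_corpus(g, n_docs = 5000, seed = 7)
sim$matrix
#> tbkg document-entity matrix: 5000 docs x 30 entities (adr=10, biomarker=10, drug=6, tumor=4)

pairs <- list(c("tumor","drug"), c("tumor","biomarker"), c("tumor","adr"),
              c("drug","biomarker"), c("drug","adr"), c("biomarker","adr"))
graph <- assemble_graph(lapply(pairs, function(pr)
  discover_relations(sim$matrix, pr, threshold = 1)))
graph
#> tbkg graph: 27 nodes (adr=8, biomarker=10, drug=5, tumor=4), 16 edges

head(as.data.frame(rank_adrs(graph, "CD003"))[
  , c("adr", "score", "direct_importance", "n_paths", "rank")], 2)
#>     adr    score direct_importance n_paths rank
#> 1 CA009 3.301687          3.301687       1    1
#> 2 CA001     -Inf                NA       0    2
```

`CA009` is the ADR planted as a child of drug `CD003`; its estimated
importance 3.30 sits within sampling error of the planted
log₂(0.3/0.03) = 3.32, and the attached path is the direct edge. Three-fold
cross-validated naive-Bayes accuracy on the same corpus
(`cross_validate(sim$matrix, "tumor", "biomarker", k = 3, seed = 7)`)
gives 0.766 against the generator's closed-form Bayes ceiling of 0.763
(`bayes_accuracy(g, "tumor", "biomarker")`).

The same run is available from a shell via the pipeline script:

```sh
Rscript inst/cli/tbkg.R simulate    --out_dir run --seed 7
Rscript inst/cli/tbkg.R tag         --out_dir run --min_entity_freq 5
Rscript inst/cli/tbkg.R build-graph --out_dir run
Rscript inst/cli/tbkg.R discover    --out_dir run --drug CD003
```

Each stage appends to `run/run_log.tsv` with an MD5 hash of the full
configuration; identical configuration and seed reproduce every artifact
byte for byte.

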