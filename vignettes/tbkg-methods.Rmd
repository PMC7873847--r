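---
title: "Methods: literature-mined knowledge graphs for explainable ADR discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: literature-mined knowledge graphs for explainable ADR discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbkg)
```

## The problem

Rare and serious adverse drug reactions (ADRs) of antitumor drugs are hard to
catch in premarket trials: sample sizes are small and oncology patients are
systematically unrepresentative. Literature mining offers a complementary
signal — millions of abstracts jointly mention tumors, molecular biomarkers,
drugs and adverse events — but a bare association score between a drug and an
ADR is difficult to act on. `tbkg` builds a typed knowledge graph from
abstracts so that every ranked drug–ADR candidate arrives with *explanation
paths*: chains such as drug – biomarker – ADR whose intermediate nodes suggest
a mechanism.

## From abstracts to a binary incidence matrix

Abstracts are read from minimal MEDLINE XML (PMID, title, abstract text,
year; every other DTD element is ignored) or from a JSONL dialect. Abstracts
shorter than `min_body_chars` (default 100 characters) are removed as
uninformative stubs.

Entity tagging is a dictionary longest match: the lexicon maps lower-cased
surface terms to concept ids, and a term's UMLS-style semantic category
determines its node type — `T191` (Neoplastic Process) is tumor-type,
`T121`/`T200` are drug-type, ten molecular categories (`T109`, `T114`,
`T116`, `T123`, `T125`, `T126`, `T129`, `T130`, `T192`, `T195`) are
biomarker-type, and ADR-type entries come from a designated ADR source
dictionary (`WHO` rows in the lexicon). We deliberately do not ship a full
clinical NLP stack: matching is exact, case-insensitive and longest-first,
and polarity is approximated by a negation-cue window — a mention is negated
when `no`, `not`, `without`, `denies`, `absence of` or `negative for` occurs
within the three preceding tokens. Only positively mentioned entities count.
This is a testable stand-in, not a reconstruction of a specific NLP
pipeline; corpora rich in hedged or negated language will be tagged more
coarsely than by a dedicated clinical engine.

The corpus becomes a documents × entities incidence matrix with strictly 0/1
cells (an entity mentioned five times in one abstract still scores 1).
Entities appearing in fewer than `min_entity_freq` documents (default 50,
meant for MEDLINE-scale corpora; lower it for toys) are dropped, since their
conditional probabilities cannot be estimated usefully.

## The importance measure

For a target entity $y$ (say, a tumor) and a feature entity $x$ (say, a
biomarker), a Bernoulli naive-Bayes model is fitted per target by maximum
likelihood with Laplace smoothing:

$$\hat p(x{=}1 \mid y{=}v) \;=\; \frac{n_{x=1,y=v} + \alpha}{n_{y=v} + 2\alpha},
\qquad \alpha = 1 \text{ by default.}$$

The relation score is the importance measure

$$\mathrm{IMP}(x, y) \;=\; \log_2 \hat p(x{=}1 \mid y{=}1) \;-\;
\log_2 \hat p(x{=}1 \mid y{=}0),$$

positive when the feature is more probable in documents where the target is
present. The base-2 convention makes the threshold interpretable: a score of
1 means "twice as likely", and the worked drug–ADR pair with conditionals
10.4% and 0.5% scores $\log_2(0.104/0.005) = 4.38$. With $\alpha = 0$ the
estimator is the pure MLE and a zero count makes the score undefined (an
explicit error rather than an infinity).

Relations with importance above `importance_threshold` (default 1.0; the
threshold is an operating-point choice, not an estimated quantity) become
edges of the graph. Nodes are typed, edges are undirected and weighted by
importance, and only the six distinct-type pair classes occur — same-type
edges and self-loops are rejected at assembly.

## Ranking and explanation

For a query drug, every ADR node is a candidate. A candidate with a direct
drug–ADR edge is scored by that edge's importance. A candidate reachable only
through biomarker/tumor intermediates is scored by its *path support*: over
all simple paths of at most `max_path_len` edges (default 3) whose interior
nodes are biomarkers or tumors, the maximum of the per-path minimum edge
weight (widest bottleneck). Path-only candidates always rank below directly
connected ones: the direct conditional evidence is primary and paths are the
explanation layer. Ties break by path support and then concept id, so
rankings are reproducible byte for byte. Path enumeration is a depth-first
search; restricting interiors to biomarker/tumor nodes keeps each path
readable as a mechanistic hypothesis rather than a chain through other drugs.

The top `ceiling(f N)` candidates are labeled *important* and the bottom
`ceiling(f N)` *unlikely* (default $f = 0.05$; ceiling is used because the
labeling must never be empty for modest lists). Agreement with a gold ADR
list uses only these two extremes — the unlabeled middle is excluded from the
2×2 table, since the model makes no commitment there — and is summarized by
sensitivity $a/(a{+}c)$, specificity $d/(b{+}d)$, and Cohen's kappa
$(p_o - p_e)/(1 - p_e)$. A co-occurrence ranking (documents containing both
entities) is included as the classical baseline.

Cross-validated accuracy is this package's operational check of graph
construction: per target entity, documents are split into `cv_folds` random
folds (default 3, drawn over sorted document ids so the result is invariant
to row order), the naive-Bayes classifier predicts the target from the
features of one type (predict 1 exactly when the posterior odds exceed 1;
odds exactly 1 predict 0), and accuracies are averaged over folds and then
targets. Defining "accuracy" as per-target document classification is an
interpretation — the alternative, edge-prediction accuracy, is not
well-defined without held-out edge labels.

## The synthetic generator

Licensed corpora and dictionaries cannot be redistributed, so every stage is
tested against a planted-truth generator. A typed graph is planted whose
edges carry conditional probabilities $(p_1, p_0)$, and documents are
sampled as entity bags: root entities (tumors, parentless drugs, and any
node acting as a parent) activate with the anchor rate, a planted child
appears with $p_1$ when a parent is active and $p_0$ otherwise, and unlinked
entities appear with the background rate. Each active entity contributes one
carrier sentence, so the dictionary tagger recovers the planted incidence
exactly; the generator tests counting and estimation, not language
understanding, and says nothing about tagger behavior on real prose.

Defaults, chosen once as a realistic sparse-graph regime and used by the
test suite: 4 tumors, 6 drugs, 10 biomarkers, 10 ADRs; edge density 0.3;
$p_1 = 0.3$, $p_0 = 0.03$ (planted importance $\log_2 10 = 3.32$, in the
range of scores the method typically assigns to real drug–ADR signals);
background rate 0.02; anchor rate 0.25 (an anchor topic in about a quarter
of abstracts). Simulation sizes in the tests are 5{,}000 documents for
recovery and cross-validation checks and 10{,}000 for concentration checks.

Two layouts are available. The default `"matched"` layout constrains planted
edges to a matching (every node in at most one edge, the earlier layer as
parent). This is a deliberate design choice: with degree at most one there
are no multi-parent children and no ancestor chains, so each planted edge's
population importance is *exactly* $\log_2(p_1/p_0)$ and every non-edge is
exactly independent — estimates can be compared to closed-form truth for any
seed, and the Bayes-optimal classification accuracy has a closed form
(`bayes_accuracy()`). The `"pairwise"` layout instead samples every
type-valid pair independently with the density as probability; it produces
denser, more entangled graphs (useful for structural tests) but per-edge
truth is no longer identifiable in closed form, so quantitative recovery
claims are only made under the matched layout.

## Numerical choices and degenerate inputs

* Laplace $\alpha = 1$ by default everywhere; $\alpha = 0$ recovers the MLE.
* A target entity present in zero documents is a degenerate-target error,
  not a silent `NaN`; in bulk discovery such targets are skipped.
* Posterior-odds ties predict 0; ranking ties break by concept id; relation
  lists sort by score, then target, then feature id. Every output is
  deterministic given configuration and seed, and the pipeline stamps each
  artifact with an MD5 hash of its full configuration.
* Duplicate edge insertions are idempotent when weights agree to 1e-9 and a
  conflict error otherwise.
* Graph weights serialize with 17 significant digits, so save/load round
  trips are exact to double precision.

## Known limitations

* Thresholding the smoothed importance is unreliable for low-prevalence
  targets. A target present in only ~100 documents gives the conditional
  $\hat p(x{=}1\mid y{=}1)$ roughly Poisson counting noise, and for a rare
  independent feature the probability that the score exceeds 1.0 is on the
  order of 0.1–0.2 (Laplace smoothing also biases the rare-target
  conditional upward, by about half a bit in that regime). Consequently, at
  realistic background rates a thresholded edge list contains false edges
  between rare unlinked entities: with the default planted conditions
  (background 0.02, 5{,}000 documents) discovery recovers every planted
  edge, but precision against planted truth sits near 0.6–0.7 rather than
  above 0.9, for essentially any seed. Raising the entity frequency floor,
  the threshold, or the corpus size are the practical remedies; the package
  reports the conditionals alongside each score so downstream users can
  filter on support.
* The importance measure is associational. A drug–biomarker edge cannot
  distinguish treatment, adverse reaction, or co-study relationships, and
  explanation paths are hypotheses, not causal claims.
* The tagger has no word-sense disambiguation, no spelling variation
  handling, and a fixed negation window; dictionary quality bounds graph
  quality.
* Drug–drug interactions and dose/severity are out of scope.
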