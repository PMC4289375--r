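---
title: "Methods: integrating miRNA-target evidence and summarizing its Gene Ontology enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating miRNA-target evidence and summarizing its Gene Ontology enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtargo)
```

## The question and the pipeline

MicroRNAs (miRNAs) repress protein-coding genes post-transcriptionally. A
genomics route to "what do miRNAs do" is to collect the set of genes with
credible evidence of miRNA interaction and characterize that set's
biological roles through the Gene Ontology (GO). mirtargo implements this
as five composable stages:

1. **Interaction integration** (`read_interaction_table()`, `union_sets()`,
   `venn_counts()`): evidence-labelled tables from validated-interaction
   databases are filtered to strong experimental evidence (default
   whitelist: reporter assay, western blot; a separate whitelist, e.g.
   `"direct"`, applies to a second source) and unified with computationally
   predicted interactions into one deduplicated (miRNA, gene) pair set with
   per-pair provenance.
2. **Prediction filtering** (`fit_score_model()`, `posterior_validity()`,
   `filter_predictions()`): raw context scores of predicted pairs are
   converted into posterior probabilities of being a valid interaction,
   calibrated against the scores of the empirically validated subset; only
   predictions with posterior above 0.98 are kept.
3. **Over-representation analysis** (`parse_obo()`, `propagate()`,
   `run_ora()`): the combined gene set is tested per GO term with a
   one-sided Fisher exact test (hypergeometric tail) against the propagated
   annotation background, with Bonferroni family-wise error control, and
   the significant sub-DAG and its leaves (most specific significant
   terms) are extracted.
4. **Functional abstraction** (`select_functional_areas()`): the
   significant-term DAG is condensed into a small set of "functional
   areas" balancing coverage, certainty, information value and
   conciseness.
5. **Validation** (`null_control()`, `split_concordance()`): a
   random-gene-set null control and a miRNA degree-split concordance check
   probe whether the enrichment machinery produces spurious findings or is
   driven only by a few hub miRNAs.

`run_pipeline()` chains stages 1–4 from a single `run_config()` and writes
the per-stage tables, DOT figures and a summary JSON.

## Statistical model of the enrichment test

For a term with $K$ annotated genes in a background of $N$ annotated genes,
and a query set of $n$ annotated genes of which $k$ fall in the term, the
over-representation p-value is the hypergeometric upper tail

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n),$$

identical to the one-sided Fisher exact test of the 2x2 table. The expected
count is $nK/N$. Family-wise error is controlled by Bonferroni,
$p_{adj} = \min(1, m\,p)$, where $m$ counts the terms actually tested in
the namespace (those with $K$ at least `min_term_size`, default 1), not
the whole ontology — the number of performable tests is the defensible
multiplicity and is reported per run. The query size $n$ counts only
annotated query genes; unannotated genes are reported but excluded. The
default significance threshold is $t_p = 10^{-5}$ for main analyses and
$0.05$ for null controls. Only the over-direction defines the significant
DAG; the under-direction can be computed (`direction = "both"`) and is
typically empty for target-gene sets.

**Annotation propagation.** A gene annotated to a term is implicitly
annotated to all ancestors along `is_a` and `part_of` edges (true-path
rule). `regulates` edges are parsed and kept for display but do not
propagate, matching standard GO practice; the propagating edge set is a
parameter of `propagate()`. Backgrounds are per namespace: the genes with
at least one propagated annotation in that namespace. A single global
background would make expected counts ill-defined across namespaces of
different annotation coverage.

**Significant sub-DAG.** Edges connect each significant term to its
*nearest* significant ancestors, skipping non-significant intermediates,
so every significant ancestor remains reachable by an induced path; leaves
are significant terms with no significant descendant.

## The posterior score filter

Prediction context scores (more negative = stronger predicted repression)
are modelled as a two-component mixture: a *valid* component, calibrated on
the scores of predictions whose pairs are experimentally validated, and a
*background* component for spurious predictions. Both components are
Gaussian; with a validated sample available (`family = "gaussian"`), the
valid component is its maximum-likelihood fit, and the background
parameters plus the mixing weight $\pi$ are estimated by EM on the pooled
predicted scores with the valid component held fixed. Without a clean
validated sample, `family = "gaussian_mixture"` runs an unanchored
two-component EM and labels as valid the component nearer the validated
mean. The posterior for score $s$ is

$$P(\text{valid} \mid s) =
  \frac{\pi f_v(s)}{\pi f_v(s) + (1 - \pi) f_b(s)},$$

computed on log densities so far tails stay numerically stable. A
prediction is kept when the posterior exceeds the threshold (default
0.98). When the two components are nearly indistinguishable (standardized
mean separation below 0.5), the model is flagged non-identifiable and the
mixing-weight estimate should not be trusted. The Gaussian family here is
a deliberate, parameterized modelling choice: it is the simplest family
that realizes the posterior-probability rule and whose parameters are
verifiable by recovery tests on simulated mixtures; `ScoreModel` objects
serialize to JSON at full precision so posteriors reproduce bit-for-bit.

## Functional abstraction

Reading 150+ significant terms is not a summary. `select_functional_areas()`
selects a small antichain of significant terms greedily: each candidate is
scored by $\text{coverage} \times \text{information value}$, where coverage
is the fraction of the annotated query set under the term and information
value is $-\log_2(K/N)$ bits (term specificity). The best candidate is
picked repeatedly subject to: no candidate related by ancestry to an
already selected area (conciseness, an antichain in the DAG); marginal
coverage gain at least `min_coverage_gain` (default 0.02 of the query
set); information value at least 1 bit (excludes near-root terms);
at most `max_areas` (default 25) areas. Ties break toward higher
information value, then the deeper term — so an ancestor/descendant pair
with identical gene sets resolves to the more specific descendant — then
the lexicographically smaller id, making selection deterministic. All four
per-area quantities (coverage, certainty as $-\log_{10} p_{adj}$,
information value, and the implied conciseness of the antichain) are
reported so alternative selectors can be compared; the defaults were
chosen so that an input with on the order of 150 significant terms in one
namespace condenses to roughly 15–25 areas. Topic labels (e.g.
"Metabolism") are a user-supplied mapping via `apply_topic_map()` —
topical grouping is editorial, not algorithmic.

## Validation procedures

**Null control.** `null_control()` draws gene sets uniformly *without
replacement* from the annotated background (the draw scheme is explicit
and seeded) and runs the full ORA per draw. Under Bonferroni control at
$\alpha = 0.05$, the fraction of runs with any significant term is the
empirical family-wise error rate and should not exceed $\alpha$ beyond
binomial noise.

**Degree split.** miRNA out-degrees are heavy-tailed: a few hubs target
hundreds of genes while many miRNAs have a single known target.
`degree_split()` partitions miRNAs at a degree threshold (default 6, i.e.
the low-degree side holds miRNAs with fewer than 6 targets; ties at the
threshold go to the high-degree side) or, alternatively, by taking miRNAs
in decreasing degree order until their targets cover a set fraction of the
gene universe (`mode = "cover_fraction"`, default 0.75) — both readings of
"the hubs" are legitimate, so both are provided.
`split_concordance()` then re-runs ORA plus abstraction on each side's
target genes and reports which functional areas of the full analysis each
side reproduces, with per-run medians of $-\log_{10} p_{adj}$ over the
selected areas (the lower median for even counts, so the summary is always
an attained value).

## The synthetic-data generator

Every stage is testable offline against corpora with known ground truth.
The generator's defaults define the study conditions and are not tuned per
test:

- **Ontology** (`make_ontology()`): per namespace, a layered DAG with a
  single root and geometrically growing layers; every non-root term has
  one propagating parent in the layer above and, with probability 0.4, a
  second parent of type `is_a`, `part_of` or `regulates`. Acyclic by
  construction.
- **Corpus** (`make_corpus()`): term sizes are assigned top-down — the
  root covers the whole gene universe and each child draws a nested gene
  pool from its first propagating parent, shrunk by
  $2^{-\text{term\_size\_exponent}}$ (default exponent 1.3) per layer with
  log-normal jitter (sd 0.6 on the log scale). Realized propagated sizes
  therefore span orders of magnitude and track the assigned size law,
  mimicking the GO's few huge and many tiny terms.
- **Interactions** (`make_interactions()`): target genes are drawn without
  replacement with weight multiplied by the fold enrichment for genes
  under planted terms; miRNA out-degrees follow a discrete Pareto law
  (exponent 2.2), yielding hubs and a large single-target majority. Note
  that sequential weighted sampling attenuates a planted fold $f$: the
  realized observed/expected ratio concentrates near
  $K(1 - e^{-nf/W})/(nK/N)$ with $W = fK + N - K$, below $f$ itself —
  about 3.2 for $f = 5$ at desk scale. Tests assert against this design
  expectation, and planted terms still dominate the enrichment ranking by
  many orders of magnitude of $p$.
- **Scores** (`make_scores()`): a labelled two-component Gaussian score
  population (defaults: valid $\mathcal{N}(-0.40, 0.10^2)$, background
  $\mathcal{N}(-0.05, 0.05^2)$, 10% valid), with valid rows reusing
  empirical pairs so the pipeline can calibrate on the
  predicted-and-validated overlap.

The `"desk"` preset (500 terms, 2,000 genes, 100 miRNAs, query sets of
300) keeps full-pipeline runs in the seconds range while preserving this
qualitative regime; `"paper"` is genome scale (17,794 genes, 788 miRNAs,
query sets of 2,954). Statistical checks in the test suite use desk-scale
corpora, 100-repeat null controls, and 10-seed recovery experiments; the
planted-enrichment experiment uses 10,000-gene backgrounds with a
500-gene planted term and 300-gene query sets.

What the generator does *not* emulate: sequence-level structure (no seed
sites or UTRs), annotation evidence-code semantics, gene aliasing, or
correlated annotation noise between related genes. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
generative assumptions, not robustness to the identifier messiness and
annotation bias of real databases.

## Numerical and design choices

- **Rounding** of reported percents and ratios is half-up to one decimal
  (`fraction_percent()`, `count_ratio()`); base R's round-half-to-even
  would alter table-style outputs at ties. Shares of miRNA subsets are
  reported to the nearest integer percent.
- **Identifiers**: gene symbols are trimmed and upper-cased; no alias
  resolution is attempted (offline operation; an alias map can be applied
  upstream). miRNA names keep their case.
- **Duplicate scored pairs** keep the strongest (most negative) score.
- **Degenerate inputs**: empty interaction sets, gene sets disjoint from
  the background, cyclic ontologies, identical-score samples and
  undersized calibration samples (< 30 scores) are rejected with specific
  errors; empty post-filter results and annotations to unknown terms warn
  and continue.
- **Determinism**: every stochastic routine takes an explicit seed;
  pipeline sub-seeds are derived per stage from the run seed, so re-runs
  are byte-identical (verified in the test suite).
- **Multiplicity** $m$ is per namespace over tested terms; both raw and
  adjusted p-values are emitted, and $-\log_{10}$ is taken on the adjusted
  value (floored at the smallest double to avoid infinities in output
  tables).

## Known limitations

- The Bonferroni-over-tested-terms choice makes adjusted p-values depend
  on `min_term_size`; the run metadata records $m$ so results are
  interpretable.
- The greedy abstraction selector is a documented default, not a claim of
  optimality; different coverage/information trade-offs can be explored
  through its three parameters.
- OBO support covers the `[Term]` stanza subset relevant here (id, name,
  namespace, is_a, part_of/regulates relationships, obsoletion), not the
  full 1.4 grammar.
- Per-namespace backgrounds are the only supported background mode; custom
  gene universes should be imposed by pre-filtering the annotation table.

## A worked desk-scale example

```{r example, eval = FALSE}
spec <- synthetic_spec("desk", seed = 1)
study <- simulate_study(spec, tempfile("study"))
cfg <- run_config(
  empirical = study$paths$empirical,
  predicted = study$paths$predicted,
  obo = study$paths$obo,
  annotations = study$paths$annotations,
  out_dir = tempfile("out"),
  evidence_filters = list(NULL),
  p_threshold = 1e-4)
res <- run_pipeline(cfg)
print(res$ora)
print(res$areas)
```
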