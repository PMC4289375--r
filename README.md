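# mirtargo

Integration of miRNA-target evidence and Gene Ontology over-representation
analysis, with functional abstraction of the enrichment DAG.

## The problem

MicroRNAs (miRNAs) repress protein-coding genes, and the catalogue of their
targets is split across heterogeneous sources: databases of experimentally
validated interactions (with evidence labels of varying strength) and
large-scale computational predictions (with per-pair context scores and a
high false-positive burden). mirtargo is for analysts who want to go from
those interaction tables to a defensible, reproducible statement of the
biological roles of miRNA-regulated genes:

1. filter and unify the interaction sources into one gene set, keeping
   only strong experimental evidence and only high-confidence predictions;
2. test that gene set for Gene Ontology term over-representation;
3. condense the resulting polyhierarchy of significant terms into a short
   table of "functional areas";
4. check that the machinery does not produce such findings from random
   gene sets, and that the result is not an artifact of a few hub miRNAs.

A synthetic-data module generates ontologies, annotation corpora,
interaction tables and prediction scores with known ground truth, so the
whole pipeline is testable offline.

## The statistics at the core

**Enrichment.** For a term with `K` annotated genes in a background of `N`
annotated genes, and a query set of `n` annotated genes of which `k` fall
in the term, the over-representation p-value is the hypergeometric upper
tail `P(X >= k)` with `X ~ Hypergeom(N, K, n)` — the one-sided Fisher
exact test — Bonferroni-adjusted over the `m` terms tested in the
namespace. Annotations are propagated to ancestor terms along `is_a` and
`part_of` edges (true-path rule) before testing. Significant terms form a
sub-DAG whose leaves are the most specific significant findings.

**Prediction filtering.** Context scores are modelled as a two-component
Gaussian mixture — a valid component calibrated on the scores of
empirically validated pairs, and a background component fitted by EM on
the pooled predicted scores. A prediction is kept when its posterior
probability of validity, `pi f_v(s) / (pi f_v(s) + (1-pi) f_b(s))`,
exceeds 0.98.

**Abstraction.** Functional areas are selected greedily by
`coverage x information value` (information value `= -log2(K/N)` bits)
among the significant terms, never selecting two terms related by
ancestry, until the marginal coverage gain drops below 2% of the query
set.

See `vignettes/mirtargo-methods.Rmd` for the full model description,
parameter defaults and design rationale.

## Worked example

A desk-scale synthetic study with one term planted at 6-fold enrichment:

```r
library(mirtargo)

spec <- synthetic_spec("desk", seed = 1)
g    <- make_ontology(spec)
corp <- make_corpus(g, spec)
sizes <- vapply(corp$term_genes, length, 0L)
tid  <- names(sizes)[order(abs(sizes - 150))][1]   # a 150-gene term
spec$planted_terms <- setNames(6, tid)
study <- simulate_study(spec, file.path(tempdir(), "study"))

cfg <- run_config(
  empirical   = study$paths$empirical,
  predicted   = study$paths$predicted,
  obo         = study$paths$obo,
  annotations = study$paths$annotations,
  out_dir     = file.path(tempdir(), "out"),
  evidence_filters = list(NULL),
  p_threshold = 1e-5)
res <- run_pipeline(cfg)

print(res$model)
#> score_model (gaussian)
#>   valid:      Normal(mean = -0.4040, sd = 0.1050)
#>   background: Normal(mean = -0.0506, sd = 0.0494)
#>   prior_valid = 0.0470, posterior threshold = 0.980
print(res$ora)
#> ora_result: query 167 genes ( 0 unannotated ); 2 significant records at p_adj <= 1e-05
#>   biological_process: n = 167, m = 500, 2 significant, 2 leaves
print(res$areas)
#> functional_areas: 2 areas, total coverage 30.5%
#>         term                      name observed fraction% coverage iv_bits
#> 1 ST1:000068 synthetic term ST1:000068       41      24.6    0.246    3.74
#> 2 ST1:000107 synthetic term ST1:000107       48      28.7    0.287    3.05
```

The fitted score model recovers the generating components (valid scores
centred at -0.40, background at -0.05) and the planted term `ST1:000068`
surfaces as a functional area: 41 of the 167 annotated query genes fall
under it (24.6% of the set, against an expected `n*K/N = 167*150/2000 =
12.5`), and it is specific to `-log2(150/2000) = 3.74` bits. The output
directory holds the merged interaction table, per-namespace enrichment
TSVs, DOT renderings of the significant DAG and a `summary.json` with the
source composition and filter accounting.

The matching null control stays silent, as it should on unstructured
draws:

```r
null_control(study$corpus, study$graph, set_size = 300, repeats = 10,
             alpha = 0.05, seed = 1)
#> null_control: 10 repeats of 300 genes, alpha = 0.05 (bonferroni)
#>   runs with zero significant terms: 10 / 10 (empirical FWER 0.000)
```

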