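#' @title Synthetic study generator
#' @description Generates every input the pipeline consumes with known
#'   ground truth: layered ontology DAGs, annotation corpora with power-law
#'   term sizes, miRNA-gene interaction sets with planted term enrichment
#'   and heavy-tailed miRNA out-degrees, and two-component prediction score
#'   tables. Everything is reproducible bit-for-bit given the spec and seed.
#' @name synthetic_data
NULL

#' Specification of a synthetic study
#'
#' The `"desk"` preset (500 terms, 2,000 genes, query sets of 300) keeps a
#' full pipeline run in the seconds range while preserving the qualitative
#' regime of a genome-scale corpus: sparse deep terms spanning orders of
#' magnitude in size and heavy-tailed miRNA out-degrees with many
#' single-target miRNAs. The `"paper"` preset is genome scale (17,794
#' annotated genes, query sets of about 3,000).
#'
#' @param preset `"desk"` or `"paper"`.
#' @param seed integer seed (mandatory; sub-seeds per stage are derived from
#'   it deterministically).
#' @param n_terms,depth terms per namespace and number of DAG layers.
#' @param n_genes annotated genes in the corpus.
#' @param n_mirnas miRNAs in the interaction set.
#' @param set_size target genes drawn for the interaction set.
#' @param term_size_exponent per-layer geometric decay of term sizes: a
#'   child term's gene pool is about `2^-term_size_exponent` of its
#'   parent's (larger = steeper size decay down the DAG).
#' @param degree_exponent Pareto exponent of the miRNA out-degree law.
#' @param planted_terms named numeric vector: term id -> fold enrichment
#'   (>= 1) of its genes in the interaction target set.
#' @param namespaces character vector of namespace labels (one root each).
#' @param score_model list with `valid_mean`, `valid_sd`, `background_mean`,
#'   `background_sd`, `prior_valid`, `n_predictions` describing the
#'   two-component context-score population.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(preset = c("desk", "paper"), seed,
                           n_terms = NULL, depth = NULL, n_genes = NULL,
                           n_mirnas = NULL, set_size = NULL,
                           term_size_exponent = 1.3,
                           degree_exponent = 2.2,
                           planted_terms = NULL,
                           namespaces = "biological_process",
                           score_model = NULL) {
  preset <- match.arg(preset)
  if (missing(seed)) stop("seed is mandatory")
  d <- if (preset == "desk") {
    list(n_terms = 500L, depth = 6L, n_genes = 2000L, n_mirnas = 100L,
         set_size = 300L)
  } else {
    list(n_terms = 3000L, depth = 10L, n_genes = 17794L, n_mirnas = 788L,
         set_size = 2954L)
  }
  sm <- list(valid_mean = -0.40, valid_sd = 0.10,
             background_mean = -0.05, background_sd = 0.05,
             prior_valid = 0.10, n_predictions = 5000L)
  if (!is.null(score_model)) sm[names(score_model)] <- score_model
  spec <- list(preset = preset, seed = as.integer(seed),
               n_terms = as.integer(n_terms %||% d$n_terms),
               depth = as.integer(depth %||% d$depth),
               n_genes = as.integer(n_genes %||% d$n_genes),
               n_mirnas = as.integer(n_mirnas %||% d$n_mirnas),
               set_size = as.integer(set_size %||% d$set_size),
               term_size_exponent = term_size_exponent,
               degree_exponent = degree_exponent,
               planted_terms = planted_terms,
               namespaces = namespaces,
               score_model = sm)
  stopifnot(spec$n_terms >= spec$depth, spec$n_genes > 0,
            spec$set_size <= spec$n_genes,
            is.null(planted_terms) || all(planted_terms >= 1))
  structure(spec, class = "synthetic_spec")
}

#' Generate a layered ontology DAG
#'
#' Builds, per namespace, a rooted DAG of `n_terms` terms in `depth` layers:
#' layer sizes grow geometrically away from the single root, every non-root
#' term receives one propagating parent (`is_a` or `part_of`) in the layer
#' above plus, with some probability, a second parent (possibly a
#' non-propagating `regulates` edge). Acyclic by construction (edges only
#' point to strictly shallower layers).
#'
#' @param spec a [synthetic_spec()].
#' @return an [ontology_graph()]; the per-term layer is recorded in
#'   attribute `layers`.
#' @export
make_ontology <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(stage_seed(spec$seed, "ontology"))
  all_terms <- list(); all_edges <- list(); layer_rec <- list()
  for (ns_i in seq_along(spec$namespaces)) {
    ns <- spec$namespaces[ns_i]
    pre <- sprintf("ST%d", ns_i)
    n <- spec$n_terms
    depth <- spec$depth
    # geometric layer sizes, root layer = 1
    raw <- 2^(seq_len(depth) - 1)
    sizes <- pmax(1L, round(raw / sum(raw) * n))
    sizes[1] <- 1L
    while (sum(sizes) != n) {
      i <- if (sum(sizes) < n) depth else which.max(sizes)
      sizes[i] <- sizes[i] + sign(n - sum(sizes))
    }
    ids <- sprintf("%s:%06d", pre, seq_len(n))
    layer <- rep(seq_len(depth), sizes)
    ech <- epa <- ety <- character(0)
    for (l in 2:depth) {
      children <- ids[layer == l]
      parents_pool <- ids[layer == l - 1]
      p1 <- sample(parents_pool, length(children), replace = TRUE)
      t1 <- sample(c("is_a", "part_of"), length(children), replace = TRUE,
                   prob = c(0.85, 0.15))
      ech <- c(ech, children); epa <- c(epa, p1); ety <- c(ety, t1)
      # optional second parent anywhere above (40% of terms)
      extra <- stats::runif(length(children)) < 0.4
      if (any(extra)) {
        pool2 <- ids[layer < l]
        p2 <- sample(pool2, sum(extra), replace = TRUE)
        t2 <- sample(c("is_a", "part_of", "regulates"), sum(extra),
                     replace = TRUE, prob = c(0.70, 0.15, 0.15))
        ok <- p2 != p1[extra]
        ech <- c(ech, children[extra][ok]); epa <- c(epa, p2[ok])
        ety <- c(ety, t2[ok])
      }
    }
    all_terms[[ns]] <- data.frame(
      id = ids, name = sprintf("synthetic term %s", ids),
      namespace = ns, stringsAsFactors = FALSE)
    all_edges[[ns]] <- data.frame(child = ech, parent = epa, type = ety,
                                  stringsAsFactors = FALSE)
    layer_rec[[ns]] <- stats::setNames(layer, ids)
  }
  g <- ontology_graph(do.call(rbind, all_terms), do.call(rbind, all_edges))
  attr(g, "layers") <- layer_rec
  g
}

#' Generate an annotation corpus with power-law term sizes
#'
#' Term sizes are assigned top-down along the DAG, the way real ontology
#' corpora are structured: each namespace root covers the whole gene
#' universe and every child term draws a nested gene pool from its first
#' propagating parent, shrunk geometrically per layer
#' (`size_child ~ size_parent * 2^-term_size_exponent`, with log-normal
#' jitter so sizes within a layer also spread). The resulting distribution
#' of term sizes is heavy-tailed and spans orders of magnitude from the
#' root to the deepest terms. Pool genes are directly annotated to their
#' term and then propagated; the assigned target pool sizes are recorded as
#' ground truth.
#'
#' @param graph a [make_ontology()] graph.
#' @param spec the [synthetic_spec()].
#' @return a [propagate()]d `annotation_table`; attribute `truth` holds the
#'   per-term assigned `target_sizes` and the realized
#'   `direct_counts`.
#' @export
make_corpus <- function(graph, spec) {
  stopifnot(inherits(graph, "ontology_graph"),
            inherits(spec, "synthetic_spec"))
  set.seed(stage_seed(spec$seed, "corpus"))
  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  shrink <- 2^(-spec$term_size_exponent)
  prop_edges <- graph$edges[graph$edges$type %in% c("is_a", "part_of"), ,
                            drop = FALSE]
  first_parent <- prop_edges$parent[match(graph$terms$id, prop_edges$child)]
  # topological order: parents before children
  depth <- lengths(term_ancestors(graph))
  ord <- order(depth[graph$terms$id])
  pools <- stats::setNames(vector("list", nrow(graph$terms)),
                           graph$terms$id)
  for (i in ord) {
    t <- graph$terms$id[i]
    if (t %in% graph$roots) {
      pools[[t]] <- seq_len(spec$n_genes)
      next
    }
    parent_pool <- pools[[first_parent[i]]]
    jitter <- exp(stats::rnorm(1, 0, 0.6))
    size <- max(2L, min(length(parent_pool),
                        round(length(parent_pool) * shrink * jitter)))
    pools[[t]] <- sort(sample(parent_pool, size))
  }
  cnt <- lengths(pools)
  direct <- data.frame(gene = genes[unlist(pools, use.names = FALSE)],
                       term = rep(graph$terms$id, cnt),
                       evidence_code = "IEA", stringsAsFactors = FALSE)
  ann <- propagate(graph, direct)
  attr(ann, "truth") <- list(
    target_sizes = stats::setNames(cnt, graph$terms$id),
    direct_counts = stats::setNames(cnt, graph$terms$id))
  ann
}

#' Generate a miRNA-gene interaction set with planted enrichment
#'
#' Draws `set_size` target genes from the corpus background without
#' replacement, with sampling weight multiplied by the fold enrichment for
#' genes annotated (after propagation) under a planted term; miRNA
#' out-degrees follow a discrete Pareto law (many single-target miRNAs, a
#' few hubs), and each miRNA targets a uniform subset of the drawn genes.
#'
#' @param graph the ontology.
#' @param corpus a [make_corpus()] annotation table.
#' @param spec the [synthetic_spec()]; `spec$planted_terms` is a named
#'   vector term id -> fold (>= 1).
#' @return an [interaction_set()] with evidence labels drawn from
#'   `{"reporter assay", "western blot", "direct"}`; attribute `truth` holds
#'   `target_genes`, the per-planted-term gene overlap, and the miRNA
#'   degrees.
#' @export
make_interactions <- function(graph, corpus, spec) {
  stopifnot(inherits(corpus, "annotation_table"),
            inherits(spec, "synthetic_spec"))
  set.seed(stage_seed(spec$seed, "interactions"))
  bg <- sort(unique(unlist(corpus$background, use.names = FALSE)))
  w <- rep(1, length(bg))
  planted <- spec$planted_terms
  if (length(planted)) {
    if (!all(names(planted) %in% graph$terms$id)) {
      stop("planted term not in the ontology")
    }
    for (t in names(planted)) {
      member <- bg %in% corpus$term_genes[[t]]
      if (!any(member)) stop("planted term ", t, " has no background genes")
      w[member] <- w[member] * planted[[t]]
    }
  }
  targets <- sample(bg, spec$set_size, prob = w)
  # discrete Pareto out-degrees with unit minimum
  u <- stats::runif(spec$n_mirnas)
  deg <- pmin(floor(u^(-1 / (spec$degree_exponent - 1))), spec$set_size)
  mirnas <- sprintf("syn-miR-%03d", seq_len(spec$n_mirnas))
  gi <- unlist(lapply(deg, function(d) sample.int(spec$set_size, d)),
               use.names = FALSE)
  mi <- rep(mirnas, deg)
  evidence <- sample(c("reporter assay", "western blot", "direct"),
                     length(gi), replace = TRUE, prob = c(0.5, 0.3, 0.2))
  set <- interaction_set(mi, targets[gi], source = "EMPIRICAL_A",
                         evidence = evidence, name = "synthetic_interactions")
  attr(set, "truth") <- list(
    target_genes = targets,
    planted_overlap = if (length(planted)) {
      vapply(names(planted),
             function(t) length(intersect(targets, corpus$term_genes[[t]])),
             0L)
    } else integer(0),
    degrees = stats::setNames(deg, mirnas))
  set
}

#' Generate labelled prediction context scores
#'
#' Draws a two-component score population: a `prior_valid` fraction of
#' predictions come from the valid component (scores centred well below
#' zero, as for genuinely repressed targets) and the rest from the
#' background component. Pair identities for valid rows reuse empirical
#' pairs when an interaction set is supplied, so the downstream pipeline
#' can calibrate on the predicted-and-validated overlap.
#'
#' @param spec the [synthetic_spec()] (`spec$score_model` gives the
#'   component parameters and `n_predictions`).
#' @param interactions optional [interaction_set()] whose pairs are reused
#'   for valid-labelled predictions.
#' @return data frame `mirna`, `gene`, `context_score`, `label`
#'   (`"valid"`/`"background"`), deduplicated by pair.
#' @export
make_scores <- function(spec, interactions = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(stage_seed(spec$seed, "scores"))
  sm <- spec$score_model
  n <- sm$n_predictions
  valid <- stats::runif(n) < sm$prior_valid
  score <- numeric(n)
  score[valid] <- stats::rnorm(sum(valid), sm$valid_mean, sm$valid_sd)
  score[!valid] <- stats::rnorm(sum(!valid), sm$background_mean, sm$background_sd)
  if (!is.null(interactions) && nrow(interactions)) {
    idx <- sample.int(nrow(interactions), sum(valid), replace = TRUE)
    vm <- interactions$mirna[idx]
    vg <- interactions$gene[idx]
  } else {
    vm <- sprintf("syn-miR-%03d", sample.int(spec$n_mirnas, sum(valid),
                                             replace = TRUE))
    vg <- sprintf("G%05d", sample.int(spec$n_genes, sum(valid),
                                      replace = TRUE))
  }
  bm <- sprintf("syn-miR-%03d", sample.int(spec$n_mirnas, sum(!valid),
                                           replace = TRUE))
  bg <- sprintf("G%05d", sample.int(spec$n_genes, sum(!valid),
                                    replace = TRUE))
  out <- data.frame(mirna = c(vm, bm), gene = c(vg, bg),
                    context_score = c(score[valid], score[!valid]),
                    label = rep(c("valid", "background"),
                                c(sum(valid), sum(!valid))),
                    stringsAsFactors = FALSE)
  out[!duplicated(paste(out$mirna, out$gene)), , drop = FALSE]
}

#' Write a full synthetic study to disk
#'
#' Generates ontology, corpus, interactions and scores for a spec and writes
#' them in the formats the pipeline readers consume: `ontology.obo`,
#' `annotations.tsv`, `empirical.tsv` (evidence-labelled interaction TSV),
#' `predicted.tsv` (context-score TSV) and `truth.json`.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects (`graph`, `corpus`,
#'   `interactions`, `scores`) and the written `paths`.
#' @export
simulate_study <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  graph <- make_ontology(spec)
  corpus <- make_corpus(graph, spec)
  interactions <- make_interactions(graph, corpus, spec)
  scores <- make_scores(spec, interactions)
  paths <- list(
    obo = file.path(out_dir, "ontology.obo"),
    annotations = file.path(out_dir, "annotations.tsv"),
    empirical = file.path(out_dir, "empirical.tsv"),
    predicted = file.path(out_dir, "predicted.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_obo(graph, paths$obo)
  write_annotations(corpus$direct, paths$annotations)
  emp <- data.frame(mirna = interactions$mirna, gene = interactions$gene,
                    evidence = vapply(strsplit(interactions$evidence, ";"),
                                      `[`, "", 1L))
  utils::write.table(emp, paths$empirical, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scores[, c("mirna", "gene", "context_score")],
                     paths$predicted, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(seed = spec$seed, preset = spec$preset,
                planted_terms = as.list(spec$planted_terms %||% list()),
                target_genes = attr(interactions, "truth")$target_genes,
                degrees = as.list(attr(interactions, "truth")$degrees),
                score_labels = scores$label)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(graph = graph, corpus = corpus,
                 interactions = interactions, scores = scores,
                 paths = paths))
}
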