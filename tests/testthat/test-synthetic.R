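test_that("generated ontologies are layered, rooted and acyclic", {
  tiny <- synthetic_spec("desk", seed = 1, n_terms = 3L, depth = 3L,
                         n_genes = 20L, set_size = 10L)
  g <- make_ontology(tiny)
  expect_equal(nrow(g$terms), 3L)
  expect_equal(length(g$roots), 1L)
  for (s in seq_len(20)) {
    spec <- synthetic_spec("desk", seed = s, n_terms = 60L, depth = 5L,
                           n_genes = 50L, set_size = 20L)
    g <- make_ontology(spec)
    ig <- igraph::graph_from_data_frame(g$edges[, c("child", "parent")],
                                        vertices = g$terms$id)
    expect_true(igraph::is_dag(ig))
    # every non-root term reaches the root along propagating edges
    prop <- g$edges[g$edges$type %in% c("is_a", "part_of"), ]
    pg <- igraph::graph_from_data_frame(prop[, c("child", "parent")],
                                        vertices = g$terms$id)
    d <- igraph::distances(pg, to = g$roots[[1]], mode = "out")
    expect_true(all(is.finite(d)))
  }
})

test_that("multi-namespace specs get one root per namespace", {
  spec <- synthetic_spec("desk", seed = 5, n_terms = 40L, depth = 4L,
                         n_genes = 60L, set_size = 20L,
                         namespaces = c("biological_process",
                                        "cellular_component"))
  g <- make_ontology(spec)
  expect_equal(sort(names(g$roots)),
               c("biological_process", "cellular_component"))
  expect_equal(nrow(g$terms), 80L)
  corp <- make_corpus(g, spec)
  expect_equal(sort(names(corp$background)), sort(names(g$roots)))
})

test_that("corpus background equals the distinct annotated genes", {
  spec <- synthetic_spec("desk", seed = 33, n_terms = 100L, n_genes = 500L,
                         set_size = 100L)
  g <- make_ontology(spec)
  corp <- make_corpus(g, spec)
  expect_equal(unname(corp$background_size["biological_process"]), 500L)
  expect_setequal(corp$background$biological_process,
                  unique(corp$direct$gene))
  # a chain with everything annotated at the leaf fills the root
  chain <- ontology_graph(
    terms = data.frame(id = c("T:R", "T:L"), name = c("r", "l"),
                       namespace = "bp"),
    edges = data.frame(child = "T:L", parent = "T:R", type = "is_a"))
  ann <- propagate(chain, data.frame(gene = sprintf("g%02d", 1:10),
                                     term = "T:L"))
  expect_equal(length(ann$term_genes[["T:R"]]), 10L)
})

test_that("propagated term sizes track the assigned size law", {
  for (s in 1:3) {
    spec <- synthetic_spec("desk", seed = 40 + s)
    g <- make_ontology(spec)
    corp <- make_corpus(g, spec)
    truth <- attr(corp, "truth")
    sizes <- vapply(corp$term_genes[names(truth$target_sizes)], length, 0L)
    rho <- cor(truth$target_sizes, sizes, method = "spearman")
    expect_gte(rho, 0.9)
    # sizes span orders of magnitude
    expect_gte(max(sizes) / max(1, min(sizes[sizes > 0])), 50)
  }
})

test_that("unplanted target sets are uniform draws from the background", {
  counts <- NULL
  for (s in 1:20) {
    spec <- synthetic_spec("desk", seed = 600 + s, n_terms = 50L,
                           n_genes = 500L, set_size = 100L)
    g <- make_ontology(spec); corp <- make_corpus(g, spec)
    ints <- make_interactions(g, corp, spec)
    hit <- corp$background[[1]] %in% attr(ints, "truth")$target_genes
    counts <- if (is.null(counts)) as.integer(hit) else counts + hit
  }
  # chi-square goodness of fit against uniform inclusion, pooled in bins
  bins <- tapply(counts, rep(1:20, each = 25), sum)
  expect_gt(stats::chisq.test(bins)$p.value, 0.01)
})

test_that("planted folds shift observed/expected ratios as designed", {
  obs_tot <- exp_tot <- design_tot <- 0
  for (s in 1:5) {
    spec <- synthetic_spec("desk", seed = 700 + s, n_terms = 200L,
                           n_genes = 2000L, set_size = 300L)
    g <- make_ontology(spec); corp <- make_corpus(g, spec)
    sizes <- vapply(corp$term_genes, length, 0L)
    tid <- names(sizes)[order(abs(sizes - 100))][1]
    spec$planted_terms <- stats::setNames(5, tid)
    ints <- make_interactions(g, corp, spec)
    obs <- length(intersect(attr(ints, "truth")$target_genes,
                            corp$term_genes[[tid]]))
    expect_equal(obs, unname(attr(ints, "truth")$planted_overlap[tid]))
    K <- unname(sizes[tid]); N <- 2000
    obs_tot <- obs_tot + obs
    exp_tot <- exp_tot + expected_count(300, K, N)
    # design expectation of the sequential weighted draw without
    # replacement: inclusion probability ~ 1 - exp(-n * w / W) with
    # per-gene weight w = fold and total weight W = fold*K + (N - K)
    design_tot <- design_tot + K * (1 - exp(-300 * 5 / (5 * K + N - K)))
  }
  realized_fold <- obs_tot / exp_tot
  design_fold <- design_tot / exp_tot
  expect_equal(realized_fold, design_fold, tolerance = 0.2)
  expect_gt(realized_fold, 3)
  expect_lt(realized_fold, 6)
})

test_that("degree law produces hubs and many single-target miRNAs", {
  spec <- synthetic_spec("desk", seed = 55)
  g <- make_ontology(spec); corp <- make_corpus(g, spec)
  ints <- make_interactions(g, corp, spec)
  deg <- attr(ints, "truth")$degrees
  expect_equal(max(deg), max(deg[order(-deg)][1:2]))
  expect_gte(mean(deg == 1), 0.3)
  expect_error({
    bad <- spec; bad$planted_terms <- c("T:NOPE" = 5)
    make_interactions(g, corp, bad)
  }, "planted term")
})

test_that("score labels follow the prior and zero prior gives background only", {
  spec0 <- synthetic_spec("desk", seed = 66,
                          score_model = list(prior_valid = 0,
                                             n_predictions = 1000L))
  sc0 <- make_scores(spec0)
  expect_true(all(sc0$label == "background"))
  spec <- synthetic_spec("desk", seed = 67,
                         score_model = list(prior_valid = 0.2,
                                            n_predictions = 10000L))
  sc <- make_scores(spec)
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_lt(abs(mean(sc$label == "valid") - 0.2), 3 * se + 0.01)
  # class means recoverable from the labelled draws
  expect_equal(mean(sc$context_score[sc$label == "valid"]), -0.40,
               tolerance = 0.02)
  expect_equal(mean(sc$context_score[sc$label == "background"]), -0.05,
               tolerance = 0.02)
})

test_that("generation is reproducible bit-for-bit given the seed", {
  spec <- synthetic_spec("desk", seed = 88, n_terms = 80L, n_genes = 300L,
                         set_size = 80L)
  run <- function() {
    g <- make_ontology(spec)
    corp <- make_corpus(g, spec)
    ints <- make_interactions(g, corp, spec)
    sc <- make_scores(spec, ints)
    list(g = g, d = corp$direct, i = as.data.frame(ints), s = sc)
  }
  a <- run(); b <- run()
  expect_identical(a, b)
})

test_that("written study files are re-read losslessly", {
  spec <- synthetic_spec("desk", seed = 90, n_terms = 80L, n_genes = 300L,
                         set_size = 80L)
  dir <- file.path(tempdir(), "study90")
  st <- simulate_study(spec, dir)
  g2 <- parse_obo(st$paths$obo)
  expect_setequal(g2$terms$id, st$graph$terms$id)
  ann2 <- read_annotations(st$paths$annotations)
  expect_equal(nrow(ann2), nrow(st$corpus$direct))
  emp <- read_interaction_table(st$paths$empirical, "empirical")
  expect_identical(sort(paste(emp$mirna, emp$gene)),
                   sort(paste(st$interactions$mirna, st$interactions$gene)))
  pred <- read_interaction_table(st$paths$predicted, "predicted")
  expect_equal(nrow(pred), nrow(st$scores))
  unlink(dir, recursive = TRUE)
})
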