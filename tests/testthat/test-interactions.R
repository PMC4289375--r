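test_that("evidence whitelist keeps only matching rows", {
  path <- write_tsv_fixture(data.frame(
    mirna = c("hsa-miR-1", "hsa-miR-1", "hsa-miR-2", "hsa-miR-3"),
    gene = c("TP53", "BCL2", "KRAS", "MYC"),
    evidence = c("reporter assay", "western blot", "microarray",
                 "reporter assay")))
  set <- read_interaction_table(path, "empirical",
                                evidence_filter = c("reporter assay",
                                                    "western blot"))
  expect_equal(nrow(set), 3L)
  expect_false("KRAS" %in% set$gene)
  # no filter keeps everything
  expect_equal(nrow(read_interaction_table(path, "empirical")), 4L)
  # empty result warns and returns an empty set
  expect_warning(empty <- read_interaction_table(path, "empirical",
                                                 evidence_filter = "luciferase"),
                 "no interactions")
  expect_equal(nrow(empty), 0L)
})

test_that("missing mandatory columns are reported by name", {
  path <- write_tsv_fixture(data.frame(mirna = "m1", gene = "G1"))
  expect_error(read_interaction_table(path, "empirical"), "evidence")
  expect_error(read_interaction_table(path, "predicted"), "context_score")
})

test_that("duplicate pairs collapse with provenance retained", {
  path <- write_tsv_fixture(data.frame(
    mirna = c("m1", "m1"), gene = c("G1", "G1"),
    evidence = c("reporter assay", "western blot")))
  set <- read_interaction_table(path, "empirical")
  expect_equal(nrow(set), 1L)
  expect_equal(set$n_records, 2L)
  expect_setequal(strsplit(set$evidence, ";")[[1]],
                  c("reporter assay", "western blot"))
})

test_that("gene symbols are trimmed and upper-cased", {
  set <- interaction_set(c("m1", "m2"), c(" tp53 ", "brca1"),
                         evidence = "direct")
  expect_setequal(set$gene, c("TP53", "BRCA1"))
})

test_that("deduplication matches a brute-force distinct-pair count", {
  set.seed(401)
  # 90 distinct pairs, 10 of them duplicated -> 100 rows
  mir <- sprintf("m%02d", 1:30)
  pairs <- expand.grid(mirna = mir, gene = sprintf("G%02d", 1:20),
                       stringsAsFactors = FALSE)
  base <- pairs[sample.int(nrow(pairs), 90L), ]
  rows <- rbind(base, base[sample.int(90L, 10L), ])
  path <- write_tsv_fixture(cbind(rows, evidence = "reporter assay"))
  set <- read_interaction_table(path, "empirical")
  oracle <- nrow(unique(rows))
  expect_equal(nrow(set), oracle)
  expect_equal(nrow(set), 90L)
})

test_that("union merges pairs and provenance", {
  a <- interaction_set(c("m1", "m1"), c("G1", "G2"), source = "EMPIRICAL_A")
  b <- interaction_set(c("m1", "m2"), c("G2", "G3"), source = "EMPIRICAL_B")
  u <- union_sets(list(a, b))
  expect_equal(nrow(u), 3L)
  expect_equal(length(unique(u$mirna)), 2L)
  expect_equal(length(unique(u$gene)), 3L)
  expect_equal(u$sources[u$gene == "G2"], "EMPIRICAL_A,EMPIRICAL_B")
})

test_that("union is idempotent, commutative and associative", {
  set.seed(402)
  for (i in 1:5) {
    a <- random_interaction_set(30); b <- random_interaction_set(25)
    c <- random_interaction_set(20)
    key <- function(s) sort(paste(s$mirna, s$gene))
    expect_identical(key(union_sets(list(a, a))), key(a))
    expect_identical(key(union_sets(list(a, b))), key(union_sets(list(b, a))))
    expect_identical(key(union_sets(list(union_sets(list(a, b)), c))),
                     key(union_sets(list(a, union_sets(list(b, c))))))
  }
})

test_that("union size follows inclusion-exclusion on constructed overlaps", {
  mk <- function(idx) interaction_set(sprintf("m%03d", idx),
                                      sprintf("G%03d", idx))
  a <- mk(1:50); b <- mk(31:70); c <- mk(61:90)
  u <- union_sets(list(a, b, c))
  # |A|+|B|+|C| - |AB| - |AC| - |BC| + |ABC|
  expect_equal(nrow(u), 50 + 40 + 30 - 20 - 0 - 10 + 0)
})

test_that("venn regions cover the trivial configurations", {
  mk <- function(g) interaction_set(rep("m1", length(g)), g)
  v <- venn_counts(list(mk(c("A", "B")), mk(c("C", "D", "E")),
                        mk(c("F", "G", "H", "I"))), by = "gene")
  expect_equal(unname(v$counts), c(2L, 3L, 4L, 0L, 0L, 0L, 0L))
  expect_equal(v$union, 9L)
  same <- mk(letters[1:5])
  v2 <- venn_counts(list(same, same, same), by = "gene")
  expect_equal(v2$counts[["111"]], 5L)
  expect_equal(sum(v2$counts), v2$counts[["111"]])
})

test_that("venn counts match exhaustive membership tabulation", {
  set.seed(403)
  for (i in 1:10) {
    sets <- list(random_interaction_set(40), random_interaction_set(40),
                 random_interaction_set(40))
    for (by in c("gene", "mirna", "pair")) {
      v <- venn_counts(sets, by = by)
      ent <- lapply(sets, function(s) unique(switch(by,
        gene = s$gene, mirna = s$mirna, pair = paste(s$mirna, s$gene))))
      uni <- unique(unlist(ent))
      # brute-force region tabulation
      memb <- sapply(uni, function(x) {
        paste(as.integer(vapply(ent, function(e) x %in% e, TRUE)),
              collapse = "")
      })
      oracle <- vapply(names(v$counts), function(r) sum(memb == r), 0L)
      expect_equal(v$counts, oracle)
      expect_true(all(v$counts >= 0L))
      expect_equal(sum(v$counts), length(uni))
    }
  }
})

test_that("degree split partitions at the threshold with ties going high", {
  set <- interaction_set(
    mirna = rep(c("m1", "m2", "m3", "m4"), c(10, 7, 5, 1)),
    gene = sprintf("G%02d", c(1:10, 1:7, 1:5, 1)))
  sp <- degree_split(set, threshold = 6)
  expect_setequal(sp$set_a, c("m1", "m2"))
  expect_setequal(sp$set_b, c("m3", "m4"))
  # ties at the threshold go to set A
  sp6 <- degree_split(set, threshold = 5)
  expect_true("m3" %in% sp6$set_a)
  expect_error(degree_split(interaction_set(character(0), character(0))),
               "empty")
})

test_that("set A share is reported as nearest integer percent", {
  # 181 high-degree miRNAs out of 788: the published A-share configuration
  deg <- c(rep(6L, 181), rep(1L, 607))
  mirnas <- sprintf("mir%03d", seq_len(788))
  set <- interaction_set(
    mirna = rep(mirnas, deg),
    gene = sprintf("G%04d", unlist(lapply(deg, seq_len))))
  sp <- degree_split(set, threshold = 6)
  expect_equal(length(sp$set_a), 181L)
  expect_equal(sp$a_share_percent, 23)
})

test_that("degree split properties hold on power-law degrees", {
  set.seed(404)
  for (i in 1:5) {
    spec <- synthetic_spec("desk", seed = 500 + i, n_terms = 50L,
                           n_genes = 300L, set_size = 120L, n_mirnas = 60L)
    g <- make_ontology(spec); corp <- make_corpus(g, spec)
    set <- make_interactions(g, corp, spec)
    sp <- degree_split(set, threshold = 6)
    deg <- table(set$mirna)
    expect_setequal(c(sp$set_a, sp$set_b), names(deg))
    expect_equal(length(intersect(sp$set_a, sp$set_b)), 0L)
    if (length(sp$set_a)) expect_gte(min(deg[sp$set_a]), 6)
    if (length(sp$set_b)) expect_lt(max(deg[sp$set_b]), 6)
    # coverage equals brute-force union of A's target lists
    oracle <- length(unique(set$gene[set$mirna %in% sp$set_a])) /
      length(unique(set$gene))
    expect_equal(sp$a_gene_coverage, oracle)
  }
})

test_that("cover_fraction mode reaches the requested coverage", {
  set.seed(405)
  spec <- synthetic_spec("desk", seed = 77, n_terms = 50L, n_genes = 300L,
                         set_size = 150L, n_mirnas = 80L)
  g <- make_ontology(spec); corp <- make_corpus(g, spec)
  set <- make_interactions(g, corp, spec)
  sp <- degree_split(set, mode = "cover_fraction", cover_fraction = 0.75)
  expect_gte(sp$a_gene_coverage, 0.75)
  # removing the last-added miRNA would drop below target (minimality)
  expect_setequal(c(sp$set_a, sp$set_b), unique(set$mirna))
})

test_that("write/read round-trip preserves the pair set exactly", {
  set.seed(406)
  set <- random_interaction_set(60)
  path <- tempfile(fileext = ".tsv")
  write_interaction_set(set, path)
  back <- read_interaction_table(path, "empirical")
  expect_identical(sort(paste(back$mirna, back$gene)),
                   sort(paste(set$mirna, set$gene)))
})
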