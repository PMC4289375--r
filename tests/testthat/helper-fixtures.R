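# Shared fixture builders. Everything is generated in code; files go to
# tempdir() and are removed by the caller or at session end.

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal diamond ontology: root <- a <- {b, c} <- d (d has two parents)
tiny_diamond_graph <- function() {
  ontology_graph(
    terms = data.frame(
      id = c("T:R", "T:A", "T:B", "T:C", "T:D"),
      name = paste("term", c("R", "A", "B", "C", "D")),
      namespace = "biological_process"),
    edges = data.frame(
      child = c("T:A", "T:B", "T:C", "T:D", "T:D"),
      parent = c("T:R", "T:A", "T:A", "T:B", "T:C"),
      type = "is_a"))
}

# deterministic multi-branch corpus: one filler branch holding most genes
# and `k` planted branches of `branch_genes` genes each; the query set takes
# `per_branch` genes from every planted branch and none from the filler.
branch_fixture <- function(k = 3L, branch_genes = 100L, filler_genes = 700L,
                           per_branch = 50L, children_per_branch = 2L) {
  ids <- c("T:ROOT", "T:FILL",
           sprintf("T:BR%d", seq_len(k)),
           unlist(lapply(seq_len(k), function(i) {
             sprintf("T:BR%d.%d", i, seq_len(children_per_branch))
           })))
  terms <- data.frame(id = ids, name = paste("syn", ids),
                      namespace = "biological_process")
  edges <- rbind(
    data.frame(child = c("T:FILL", sprintf("T:BR%d", seq_len(k))),
               parent = "T:ROOT", type = "is_a"),
    do.call(rbind, lapply(seq_len(k), function(i) {
      data.frame(child = sprintf("T:BR%d.%d", i, seq_len(children_per_branch)),
                 parent = sprintf("T:BR%d", i), type = "is_a")
    })))
  graph <- ontology_graph(terms, edges)
  genes <- sprintf("G%05d", seq_len(filler_genes + k * branch_genes))
  fill <- genes[seq_len(filler_genes)]
  branch <- split(genes[-seq_len(filler_genes)],
                  rep(seq_len(k), each = branch_genes))
  direct <- rbind(
    data.frame(gene = fill, term = "T:FILL"),
    do.call(rbind, lapply(seq_len(k), function(i) {
      # round-robin over the branch's children
      data.frame(gene = branch[[i]],
                 term = sprintf("T:BR%d.%d", i,
                                rep_len(seq_len(children_per_branch),
                                        branch_genes)))
    })))
  direct$evidence_code <- "IEA"
  ann <- propagate(graph, direct)
  query <- unlist(lapply(branch, function(g) g[seq_len(per_branch)]),
                  use.names = FALSE)
  list(graph = graph, annotations = ann, query = query,
       branch_roots = sprintf("T:BR%d", seq_len(k)), branches = branch)
}

# ancestor sets computed independently of the package internals, via igraph
# reachability on the propagating edges
igraph_ancestors <- function(graph, edge_types = c("is_a", "part_of")) {
  e <- graph$edges[graph$edges$type %in% edge_types, , drop = FALSE]
  g <- igraph::graph_from_data_frame(e[, c("child", "parent")],
                                     vertices = graph$terms$id)
  out <- lapply(graph$terms$id, function(t) {
    setdiff(names(igraph::subcomponent(g, t, mode = "out")), t)
  })
  stats::setNames(out, graph$terms$id)
}

# exhaustive hypergeometric tail via binomial coefficients (oracle)
enum_hyper_tail <- function(k, n, K, N, direction = "over") {
  js <- if (direction == "over") k:min(n, K) else 0:k
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# build a score_model by hand for closed-form posterior checks
manual_score_model <- function(valid_mean, valid_sd, bg_mean, bg_sd,
                               prior_valid, threshold = 0.98) {
  structure(list(
    valid = list(mean = valid_mean, sd = valid_sd, family = "gaussian"),
    background = list(mean = bg_mean, sd = bg_sd, family = "gaussian"),
    prior_valid = prior_valid, threshold = threshold,
    family = "gaussian", identifiable = TRUE,
    n = c(validated = 0L, predicted = 0L)), class = "score_model")
}

random_interaction_set <- function(n_pairs, n_mirnas = 20L, n_genes = 40L,
                                   name = "rand") {
  interaction_set(
    mirna = sprintf("m%02d", sample.int(n_mirnas, n_pairs, replace = TRUE)),
    gene = sprintf("g%02d", sample.int(n_genes, n_pairs, replace = TRUE)),
    source = "EMPIRICAL_A", evidence = "reporter assay", name = name)
}
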