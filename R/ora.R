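#' @title Gene Ontology over-representation analysis
#' @description Per-term one-sided Fisher exact tests (hypergeometric tails)
#'   of a query gene set against the propagated annotation background, with
#'   Bonferroni family-wise error control, extraction of the significant
#'   sub-DAG and identification of its leaves (the most specific significant
#'   terms).
#' @name ora
NULL

#' ORA configuration
#'
#' @param p_threshold significance threshold on the (adjusted) p-value;
#'   default `1e-5` for main analyses, `0.05` is typical for null controls.
#' @param correction `"bonferroni"` or `"none"`.
#' @param direction `"over"`, `"under"` or `"both"`.
#' @param min_term_size smallest background term size tested (m for the
#'   Bonferroni correction counts only tested terms).
#' @return an `ora_config` list.
#' @export
ora_config <- function(p_threshold = 1e-5,
                       correction = c("bonferroni", "none"),
                       direction = c("over", "under", "both"),
                       min_term_size = 1L) {
  stopifnot(p_threshold > 0, p_threshold <= 1, min_term_size >= 1L)
  structure(list(p_threshold = p_threshold,
                 correction = match.arg(correction),
                 direction = match.arg(direction),
                 min_term_size = as.integer(min_term_size)),
            class = "ora_config")
}

#' Hypergeometric tail probability (one-sided Fisher exact p)
#'
#' For a query set of size `n` drawn from a background of `N` genes of which
#' `K` are annotated to the term, and `k` annotated genes observed in the
#' query: `direction = "over"` returns `P(X >= k)` and `"under"` returns
#' `P(X <= k)` with `X ~ Hypergeometric(N, K, n)`. These equal the one-sided
#' Fisher exact p-values of the 2x2 contingency table.
#'
#' @param k observed count(s) of annotated genes in the query set.
#' @param n query set size.
#' @param K term's background annotation count.
#' @param N background size.
#' @param direction `"over"` or `"under"`.
#' @return probability vector (vectorized over `k`, `n`, `K`).
#' @export
hypergeom_tail <- function(k, n, K, N, direction = c("over", "under")) {
  direction <- match.arg(direction)
  if (any(K > N) || any(n > N) || any(k > pmin(n, K)) || any(k < 0)) {
    stop("inconsistent hypergeometric margins")
  }
  if (direction == "over") {
    stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  }
}

#' Expected count of annotated genes in a query set
#'
#' @param n query set size.
#' @param K term background count.
#' @param N background size (positive).
#' @return `n * K / N`.
#' @export
expected_count <- function(n, K, N) {
  if (any(N <= 0)) stop("background size must be positive")
  n * K / N
}

#' Bonferroni adjustment
#'
#' @param p raw p-value(s).
#' @param m number of tests (>= 1).
#' @return `min(1, m * p)` elementwise.
#' @export
bonferroni <- function(p, m) {
  stopifnot(all(m >= 1))
  pmin(1, m * p)
}

#' Run over-representation analysis
#'
#' Tests each ontology term for over- (and/or under-) representation of the
#' query gene set relative to the propagated annotation background of its
#' namespace, adjusts p-values by Bonferroni over the terms actually tested
#' in that namespace, and extracts the significant sub-DAG with its leaves.
#'
#' The query set is intersected with each namespace background before
#' testing; unannotated query genes are counted in the result but excluded
#' from the tests.
#'
#' @param gene_set character vector of gene ids.
#' @param annotations an [propagate()]d `annotation_table`.
#' @param graph the [ontology_graph()] the annotations were propagated on.
#' @param config an [ora_config()].
#' @return an `ora_result`: list with `records` (one data frame over all
#'   namespaces: `term`, `name`, `namespace`, `observed`, `expected`,
#'   `fraction_percent`, `p_raw`, `p_adj`, `minus_log10_p_adj`, `direction`,
#'   `significant`, `is_leaf`), `sig_dag` (per namespace: `nodes`, `edges`
#'   linking each significant term to its nearest significant ancestors,
#'   `leaves`), `n` (annotated query size per namespace), `m` (tested terms
#'   per namespace), `n_input`, `n_unannotated` and `config`.
#' @export
run_ora <- function(gene_set, annotations, graph, config = ora_config()) {
  stopifnot(inherits(annotations, "annotation_table"),
            inherits(graph, "ontology_graph"),
            inherits(config, "ora_config"))
  gene_set <- unique(toupper(trimws_vec(gene_set)))
  all_bg <- unique(unlist(annotations$background, use.names = FALSE))
  annotated <- intersect(gene_set, all_bg)
  if (!length(annotated)) stop("gene set has no overlap with the background")

  dirs <- if (config$direction == "both") c("over", "under")
          else config$direction
  rec_list <- list()
  n_by_ns <- m_by_ns <- integer(0)
  for (ns in names(annotations$background)) {
    bg <- annotations$background[[ns]]
    N <- length(bg)
    qs <- intersect(gene_set, bg)
    n <- length(qs)
    n_by_ns[ns] <- n
    terms_ns <- graph$terms$id[graph$terms$namespace == ns]
    K <- vapply(annotations$term_genes[terms_ns], length, 0L)
    tested <- terms_ns[K >= config$min_term_size]
    Kt <- K[K >= config$min_term_size]
    m_by_ns[ns] <- length(tested)
    if (!length(tested) || n == 0L) next
    obs <- vapply(annotations$term_genes[tested],
                  function(g) length(intersect(g, qs)), 0L)
    for (d in dirs) {
      p_raw <- hypergeom_tail(obs, n, Kt, N, direction = d)
      p_adj <- if (config$correction == "bonferroni")
        bonferroni(p_raw, length(tested)) else p_raw
      rec_list[[paste(ns, d)]] <- data.frame(
        term = tested,
        name = graph$terms$name[match(tested, graph$terms$id)],
        namespace = ns,
        observed = obs,
        expected = expected_count(n, Kt, N),
        fraction_percent = fraction_percent(obs, n),
        p_raw = p_raw,
        p_adj = p_adj,
        minus_log10_p_adj = -log10(pmax(p_adj, .Machine$double.xmin)),
        direction = d,
        significant = p_adj <= config$p_threshold,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec_list) %||%
    data.frame(term = character(0))
  rownames(records) <- NULL

  anc <- term_ancestors(graph)
  sig_dag <- list()
  if (nrow(records)) {
    records$is_leaf <- FALSE
    for (ns in unique(records$namespace)) {
      sel <- records$namespace == ns & records$significant &
        records$direction == dirs[1]
      sig_terms <- records$term[sel]
      edges <- significant_edges(sig_terms, anc)
      leaves <- setdiff(sig_terms, edges$parent)
      records$is_leaf[sel] <- records$term[sel] %in% leaves
      sig_dag[[ns]] <- list(
        nodes = records[sel, , drop = FALSE],
        edges = edges,
        leaves = leaves)
    }
  }
  structure(list(records = records, sig_dag = sig_dag,
                 n = n_by_ns, m = m_by_ns,
                 n_input = length(gene_set),
                 n_unannotated = length(setdiff(gene_set, all_bg)),
                 query = annotated,
                 config = config),
            class = "ora_result")
}

# edges from each significant term to its nearest significant ancestors
# (non-significant intermediates are skipped so that every significant
# ancestor stays connected by an induced path)
significant_edges <- function(sig_terms, anc) {
  ch <- pa <- character(0)
  sig <- sig_terms
  for (t in sig) {
    a_sig <- intersect(anc[[t]], sig)
    if (!length(a_sig)) next
    # nearest = those significant ancestors that are not ancestors of
    # another significant ancestor of t
    nearest <- a_sig[!vapply(a_sig, function(a) {
      any(vapply(setdiff(a_sig, a), function(b) a %in% anc[[b]], TRUE))
    }, TRUE)]
    ch <- c(ch, rep(t, length(nearest)))
    pa <- c(pa, nearest)
  }
  data.frame(child = ch, parent = pa, stringsAsFactors = FALSE)
}

#' @export
print.ora_result <- function(x, ...) {
  cat("ora_result: query", x$n_input, "genes (",
      x$n_unannotated, "unannotated );",
      sum(x$records$significant %||% FALSE), "significant records at p_adj <=",
      x$config$p_threshold, "\n")
  for (ns in names(x$sig_dag)) {
    cat(sprintf("  %s: n = %d, m = %d, %d significant, %d leaves\n",
                ns, x$n[[ns]], x$m[[ns]], nrow(x$sig_dag[[ns]]$nodes),
                length(x$sig_dag[[ns]]$leaves)))
  }
  invisible(x)
}

#' @export
summary.ora_result <- function(object, ...) {
  recs <- object$records
  sig <- recs[recs$significant, , drop = FALSE]
  sig[order(sig$p_adj, sig$term), , drop = FALSE]
}

#' Write ORA records to a TSV file
#'
#' @param result an `ora_result` from [run_ora()].
#' @param path output path.
#' @param areas optional `functional_areas` result used to flag records.
#' @return `path`, invisibly.
#' @export
write_ora <- function(result, path, areas = NULL) {
  recs <- result$records
  recs$is_functional_area <- recs$term %in% (areas$term %||% character(0))
  utils::write.table(recs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a significant sub-DAG as DOT text
#'
#' One node per significant term, labelled with the term name, observed and
#' expected counts and -log10 adjusted p; leaves (most specific significant
#' terms) are drawn in blue, functional areas filled yellow.
#'
#' @param dag one namespace entry of `ora_result$sig_dag`.
#' @param areas optional character vector of functional-area term ids.
#' @param graph_name DOT graph name.
#' @return a single DOT string (empty digraph with a warning if the DAG has
#'   no nodes).
#' @export
export_dag <- function(dag, areas = character(0), graph_name = "ora") {
  if (is.null(dag) || nrow(dag$nodes) == 0L) {
    warning("empty significant DAG")
    return(sprintf("digraph %s {\n}\n", graph_name))
  }
  nd <- dag$nodes
  q <- function(x) gsub("\"", "'", x)
  lab <- sprintf("%s\\n%s\\nobserved: %d\\nexpected: %.1f\\n-log10 p: %.1f",
                 q(nd$term), q(nd$name), nd$observed, nd$expected,
                 nd$minus_log10_p_adj)
  style <- ifelse(nd$term %in% areas,
                  "style=filled, fillcolor=yellow",
                  ifelse(nd$term %in% dag$leaves,
                         "color=blue", "color=red"))
  nodes <- sprintf("  \"%s\" [label=\"%s\", shape=ellipse, %s];",
                   q(nd$term), lab, style)
  edges <- if (nrow(dag$edges)) {
    sprintf("  \"%s\" -> \"%s\";", q(dag$edges$child), q(dag$edges$parent))
  } else character(0)
  paste0("digraph ", graph_name, " {\n",
         paste(c(nodes, edges), collapse = "\n"), "\n}\n")
}
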