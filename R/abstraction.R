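#' @title Functional abstraction of the significant-term DAG
#' @description Condenses the significant terms of one namespace into a
#'   small set of "functional areas": terms jointly chosen for high coverage
#'   of the query set, high certainty (small adjusted p), high information
#'   value (term specificity) and conciseness (no two selected terms related
#'   by ancestry).
#' @name abstraction
NULL

#' Select functional areas from an ORA result
#'
#' Greedy selection over the significant terms of one namespace. Each
#' candidate is scored by `coverage x information_value`, where coverage is
#' the fraction of the annotated query set under the term and information
#' value is `-log2(K / N)` bits (K = term background count, N = background
#' size). The best-scoring candidate is selected repeatedly, skipping any
#' term that is an ancestor or descendant of an already selected area and
#' any whose marginal coverage gain (newly covered query genes as a fraction
#' of the query set) falls below `min_coverage_gain`; selection stops at
#' `max_areas` or when no candidate qualifies. Ties break toward higher
#' information value, then the deeper (more specific) term, then the
#' lexicographically smaller term id, so selection is deterministic.
#'
#' @param result an [run_ora()] `ora_result`.
#' @param annotations the `annotation_table` used for the ORA.
#' @param graph the [ontology_graph()].
#' @param namespace which namespace to abstract (default: first with a
#'   non-empty significant DAG).
#' @param min_coverage_gain minimal marginal coverage gain per step
#'   (fraction of the annotated query set), default 0.02.
#' @param max_areas maximal number of areas, default 25.
#' @param min_information_value minimal information value in bits, default 1.
#' @return a `functional_areas` data frame: `term`, `name`, `namespace`,
#'   `observed`, `expected`, `fraction_percent`, `minus_log10_p_adj`,
#'   `information_value`, `coverage`, `topic` (initially `"unassigned"`),
#'   ordered by selection; attribute `total_coverage` gives the fraction of
#'   the query set covered by the union of the selected areas. Empty input
#'   gives an empty data frame.
#' @export
select_functional_areas <- function(result, annotations, graph,
                                    namespace = NULL,
                                    min_coverage_gain = 0.02,
                                    max_areas = 25L,
                                    min_information_value = 1) {
  stopifnot(inherits(result, "ora_result"),
            inherits(annotations, "annotation_table"))
  if (is.null(namespace)) {
    nonempty <- names(result$sig_dag)[vapply(result$sig_dag,
                                             function(d) nrow(d$nodes) > 0L,
                                             TRUE)]
    if (!length(nonempty)) return(empty_areas())
    namespace <- nonempty[1]
  }
  dag <- result$sig_dag[[namespace]]
  if (is.null(dag) || nrow(dag$nodes) == 0L) return(empty_areas())

  nd <- dag$nodes
  N <- annotations$background_size[[namespace]]
  qs <- intersect(result$query, annotations$background[[namespace]])
  n <- length(qs)
  K <- vapply(annotations$term_genes[nd$term], length, 0L)
  iv <- -log2(K / N)
  term_query <- lapply(annotations$term_genes[nd$term], intersect, qs)
  coverage <- vapply(term_query, length, 0L) / n
  cand <- data.frame(term = nd$term, iv = iv, coverage = coverage,
                     stringsAsFactors = FALSE)
  cand <- cand[cand$iv >= min_information_value, , drop = FALSE]

  anc <- term_ancestors(graph)
  depth <- lengths(anc)
  related <- function(a, b) a %in% anc[[b]] || b %in% anc[[a]]
  chosen <- character(0)
  covered <- character(0)
  while (length(chosen) < max_areas && nrow(cand)) {
    gain <- vapply(cand$term, function(t) {
      length(setdiff(term_query[[t]], covered)) / n
    }, 0)
    ok <- gain >= min_coverage_gain
    if (!any(ok)) break
    pool <- cand[ok, , drop = FALSE]
    score <- pool$coverage * pool$iv
    # ties: higher information value, then the deeper (more specific) term,
    # then the lexicographically smaller id - so an ancestor/descendant pair
    # with identical gene sets resolves to the descendant
    ord <- order(-score, -pool$iv, -depth[pool$term], pool$term)
    pick <- pool$term[ord[1]]
    chosen <- c(chosen, pick)
    covered <- union(covered, term_query[[pick]])
    drop <- cand$term == pick |
      vapply(cand$term, related, TRUE, b = pick)
    cand <- cand[!drop, , drop = FALSE]
  }
  if (!length(chosen)) return(empty_areas())
  sel <- match(chosen, nd$term)
  out <- data.frame(
    term = chosen,
    name = nd$name[sel],
    namespace = namespace,
    observed = nd$observed[sel],
    expected = nd$expected[sel],
    fraction_percent = nd$fraction_percent[sel],
    minus_log10_p_adj = nd$minus_log10_p_adj[sel],
    information_value = iv[sel],
    coverage = coverage[sel],
    topic = "unassigned",
    stringsAsFactors = FALSE)
  structure(out, total_coverage = length(covered) / n,
            class = c("functional_areas", "data.frame"))
}

empty_areas <- function() {
  structure(data.frame(term = character(0), name = character(0),
                       namespace = character(0), observed = integer(0),
                       expected = numeric(0), fraction_percent = numeric(0),
                       minus_log10_p_adj = numeric(0),
                       information_value = numeric(0), coverage = numeric(0),
                       topic = character(0), stringsAsFactors = FALSE),
            total_coverage = 0,
            class = c("functional_areas", "data.frame"))
}

#' @export
print.functional_areas <- function(x, ...) {
  cat("functional_areas:", nrow(x), "areas, total coverage",
      sprintf("%.1f%%", 100 * (attr(x, "total_coverage") %||% 0)), "\n")
  if (nrow(x)) {
    print.data.frame(data.frame(term = x$term, name = x$name,
                                observed = x$observed,
                                `fraction%` = x$fraction_percent,
                                coverage = round(x$coverage, 3),
                                iv_bits = round(x$information_value, 2),
                                topic = x$topic, check.names = FALSE))
  }
  invisible(x)
}

#' Attach topic labels to functional areas
#'
#' Topic grouping of areas (e.g. "Metabolism", "Development") is a manual,
#' user-supplied mapping; areas without a mapped label are labelled
#' `"unassigned"`, and map entries for unknown term ids are ignored with a
#' warning.
#'
#' @param areas a `functional_areas` data frame.
#' @param topic_map named character vector or list, term id -> label.
#' @return `areas` with the `topic` column filled in.
#' @export
apply_topic_map <- function(areas, topic_map = NULL) {
  stopifnot(inherits(areas, "functional_areas"))
  if (nrow(areas) == 0L) return(areas)
  areas$topic <- "unassigned"
  if (is.null(topic_map) || !length(topic_map)) return(areas)
  topic_map <- unlist(topic_map)
  unknown <- setdiff(names(topic_map), areas$term)
  if (length(unknown)) {
    warning("topic map entries for unknown terms ignored: ",
            paste(utils::head(unknown, 5L), collapse = ", "))
  }
  hit <- areas$term %in% names(topic_map)
  areas$topic[hit] <- unname(topic_map[areas$term[hit]])
  areas
}

#' Write a functional-area table
#'
#' @param areas a `functional_areas` data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_areas <- function(areas, path) {
  utils::write.table(as.data.frame(areas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
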