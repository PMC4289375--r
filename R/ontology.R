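#' @title Ontology DAG and annotation propagation
#' @description A minimal Gene-Ontology-style term DAG (typed child-to-parent
#'   edges, one root per namespace) plus gene annotations propagated to
#'   ancestors under the true-path rule.
#' @name ontology
NULL

#' Construct an ontology graph
#'
#' @param terms data frame with columns `id`, `name`, `namespace`.
#' @param edges data frame with columns `child`, `parent`, `type`
#'   (`is_a`, `part_of` or `regulates`); may have zero rows.
#' @return an `ontology_graph`: list with `terms`, `edges` and `roots` (named
#'   character vector, one root term id per namespace). The graph is checked
#'   for acyclicity.
#' @export
ontology_graph <- function(terms, edges) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("child", "parent", "type") %in% names(edges)))
  terms <- terms[!duplicated(terms$id), , drop = FALSE]
  rownames(terms) <- NULL
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(unknown)) {
    stop("edges reference unknown terms: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       vertices = terms$id)
    if (!igraph::is_dag(g)) {
      cyc <- tryCatch(
        names(igraph::feedback_arc_set(g)), error = function(e) character(0))
      stop("ontology contains a cycle (involving e.g. ",
           paste(utils::head(unique(c(edges$child[1], cyc)), 4L),
                 collapse = ", "), ")")
    }
  }
  has_parent <- terms$id %in% edges$child
  roots <- vapply(split(terms$id[!has_parent], terms$namespace[!has_parent]),
                  function(ids) ids[1L], "")
  structure(list(terms = terms, edges = edges, roots = roots),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", nrow(x$terms), "terms,", nrow(x$edges),
      "edges,", length(x$roots), "namespace(s):",
      paste(names(x$roots), collapse = ", "), "\n")
  invisible(x)
}

#' Parse an OBO 1.2-style ontology file
#'
#' Supports `[Term]` stanzas with `id:`, `name:`, `namespace:`, `is_a:`,
#' `relationship: part_of ...` / `relationship: regulates ...` and
#' `is_obsolete:` lines. Obsolete terms are dropped together with their
#' edges; unknown relationship types are ignored with a warning; edges to
#' undefined terms are dropped with a warning. A cycle check is performed.
#'
#' @param path path to the OBO file.
#' @return an [ontology_graph()].
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", lines)
  if (!length(term_starts)) stop("no [Term] stanzas in ", path)
  bounds <- c(stanza_starts, length(lines) + 1L)
  ids <- names <- nss <- character(0)
  ech <- epa <- ety <- character(0)
  unknown_rel <- character(0)
  for (s in term_starts) {
    e <- min(bounds[bounds > s]) - 1L
    blk <- lines[(s + 1L):e]
    val <- function(key) {
      m <- grep(paste0("^", key, ":"), blk, value = TRUE)
      sub("\\s*!.*$", "", trimws(sub(paste0("^", key, ":"), "", m)))
    }
    if (length(val("is_obsolete")) && any(val("is_obsolete") == "true")) next
    id <- val("id")[1]
    if (is.na(id) || !nzchar(id)) next
    ids <- c(ids, id)
    names <- c(names, val("name")[1] %||% id)
    ns <- val("namespace")
    nss <- c(nss, if (length(ns)) ns[1] else "default")
    isa <- val("is_a")
    if (length(isa)) {
      ech <- c(ech, rep(id, length(isa))); epa <- c(epa, isa)
      ety <- c(ety, rep("is_a", length(isa)))
    }
    rel <- val("relationship")
    for (r in rel) {
      parts <- strsplit(trimws(r), "\\s+")[[1]]
      if (length(parts) < 2L) next
      if (parts[1] %in% c("part_of", "regulates")) {
        ech <- c(ech, id); epa <- c(epa, parts[2]); ety <- c(ety, parts[1])
      } else {
        unknown_rel <- c(unknown_rel, parts[1])
      }
    }
  }
  if (length(unknown_rel)) {
    warning("ignored unknown relationship type(s): ",
            paste(unique(unknown_rel), collapse = ", "))
  }
  terms <- data.frame(id = ids, name = ifelse(is.na(names), ids, names),
                      namespace = nss, stringsAsFactors = FALSE)
  edges <- data.frame(child = ech, parent = epa, type = ety,
                      stringsAsFactors = FALSE)
  drop <- !(edges$parent %in% terms$id) | !(edges$child %in% terms$id)
  if (any(drop)) {
    warning(sum(drop), " edges to undefined or obsolete terms dropped")
    edges <- edges[!drop, , drop = FALSE]
  }
  ontology_graph(terms, edges)
}

#' Write an ontology graph as an OBO file
#'
#' Inverse of [parse_obo()] for the supported OBO subset.
#'
#' @param graph an [ontology_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  stopifnot(inherits(graph, "ontology_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  by_child <- split(seq_len(nrow(graph$edges)), graph$edges$child)
  for (i in seq_len(nrow(graph$terms))) {
    t <- graph$terms[i, ]
    out <- c("[Term]", paste0("id: ", t$id), paste0("name: ", t$name),
             paste0("namespace: ", t$namespace))
    for (j in by_child[[t$id]] %||% integer(0)) {
      e <- graph$edges[j, ]
      out <- c(out, if (e$type == "is_a") paste0("is_a: ", e$parent)
               else paste0("relationship: ", e$type, " ", e$parent))
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

#' Read a gene-annotation table
#'
#' GAF-like TSV reduced to columns `gene`, `term` and optional
#' `evidence_code`. Gene symbols are trimmed and upper-cased.
#'
#' @param path TSV path with a header row.
#' @return data frame with columns `gene`, `term`, `evidence_code`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  miss <- setdiff(c("gene", "term"), names(tab))
  if (length(miss)) {
    stop("annotation table lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  data.frame(gene = toupper(trimws_vec(tab$gene)),
             term = trimws_vec(tab$term),
             evidence_code = if ("evidence_code" %in% names(tab))
               trimws_vec(tab$evidence_code) else "",
             stringsAsFactors = FALSE)
}

#' Write a gene-annotation table
#'
#' @param annotations data frame with columns `gene`, `term` and optionally
#'   `evidence_code`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  cols <- intersect(c("gene", "term", "evidence_code"), names(annotations))
  utils::write.table(annotations[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ancestor term ids (self excluded) for every term, restricted to edge_types;
# memoized topological sweep
term_ancestors <- function(graph, edge_types = c("is_a", "part_of")) {
  e <- graph$edges[graph$edges$type %in% edge_types, , drop = FALSE]
  ids <- graph$terms$id
  anc <- stats::setNames(vector("list", length(ids)), ids)
  parents <- split(e$parent, factor(e$child, levels = ids))
  done <- stats::setNames(logical(length(ids)), ids)
  visit <- function(id) {
    stack <- id
    order <- character(0)
    # iterative DFS building a finish order so each node is resolved after
    # its parents
    while (length(stack)) {
      top <- stack[[length(stack)]]
      ps <- parents[[top]]
      todo <- ps[!done[ps]]
      todo <- setdiff(todo, stack)
      if (length(todo)) {
        stack <- c(stack, todo[1])
      } else {
        stack <- stack[-length(stack)]
        if (!done[top]) {
          anc[[top]] <<- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
          done[top] <<- TRUE
        }
      }
    }
  }
  for (id in ids) if (!done[id]) visit(id)
  anc
}

#' Propagate annotations to ancestor terms (true-path rule)
#'
#' A gene directly annotated to a term is implicitly annotated to every
#' ancestor of that term reachable along the propagating edge types
#' (`is_a` and `part_of` by default; `regulates` edges are retained in the
#' graph but do not propagate).
#'
#' @param graph an [ontology_graph()].
#' @param annotations data frame with columns `gene`, `term` (direct
#'   annotations). Annotations to unknown terms are dropped with a warning.
#' @param edge_types edge types along which annotations propagate.
#' @return an `annotation_table`: list with `direct` (the cleaned input
#'   rows), `term_genes` (named list term id -> character vector of annotated
#'   genes after propagation), `namespaces` (term id -> namespace),
#'   `background` (named list namespace -> genes with >= 1 propagated
#'   annotation in it) and `background_size` (named integer per namespace).
#' @export
propagate <- function(graph, annotations,
                      edge_types = c("is_a", "part_of")) {
  stopifnot(inherits(graph, "ontology_graph"))
  annotations$gene <- toupper(trimws_vec(annotations$gene))
  known <- annotations$term %in% graph$terms$id
  if (!all(known)) {
    warning(sum(!known), " annotations to unknown terms dropped")
    annotations <- annotations[known, , drop = FALSE]
  }
  annotations <- annotations[!duplicated(paste(annotations$gene,
                                               annotations$term)), ,
                             drop = FALSE]
  anc <- term_ancestors(graph, edge_types)
  # expand each (gene, term) to (gene, term + ancestors), then dedupe
  exp_terms <- lapply(annotations$term, function(t) c(t, anc[[t]]))
  n_each <- lengths(exp_terms)
  genes <- rep(annotations$gene, n_each)
  terms <- unlist(exp_terms, use.names = FALSE)
  key <- !duplicated(paste(genes, terms, sep = "\r"))
  genes <- genes[key]; terms <- terms[key]
  term_genes <- split(genes, factor(terms, levels = graph$terms$id))
  term_genes <- lapply(term_genes, unique)
  ns <- stats::setNames(graph$terms$namespace, graph$terms$id)
  background <- lapply(split(graph$terms$id, graph$terms$namespace),
                       function(ids) {
                         unique(unlist(term_genes[ids], use.names = FALSE)) %||%
                           character(0)
                       })
  structure(list(direct = annotations,
                 term_genes = term_genes,
                 namespaces = ns,
                 background = background,
                 background_size = vapply(background, length, 0L),
                 edge_types = edge_types),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("annotation_table:", nrow(x$direct), "direct annotations,",
      length(unique(x$direct$gene)), "genes;",
      "background per namespace:",
      paste(names(x$background_size), x$background_size,
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
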