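#' @title miRNA-gene interaction sets
#' @description Readers, combinators and degree statistics for tables of
#'   miRNA-gene interactions coming from empirical (evidence-labelled) and
#'   computationally predicted (context-scored) sources.
#' @name interactions
NULL

#' Construct an interaction set
#'
#' An `interaction_set` is a deduplicated table of (miRNA, gene) pairs with
#' per-pair provenance: which source sets contributed the pair and under which
#' evidence labels. Gene symbols are whitespace-trimmed and upper-cased;
#' miRNA identifiers are trimmed but keep their case (miRNA names are
#' case-sensitive by convention, e.g. "hsa-miR-34a").
#'
#' @param mirna,gene character vectors of equal length.
#' @param source single source label for all rows, or a vector.
#' @param evidence evidence labels (free text), recycled if length 1.
#' @param score optional numeric prediction scores (context scores).
#' @param name name of the set.
#' @return an `interaction_set`: a data frame with columns `mirna`, `gene`,
#'   `sources` (comma-joined), `evidence` (semicolon-joined), `n_records`
#'   (provenance rows collapsed into the pair) and, when scores are supplied,
#'   `context_score`; the set name is carried in attribute `name`.
#' @export
interaction_set <- function(mirna, gene, source = "UNKNOWN",
                            evidence = "", score = NULL, name = "set") {
  mirna <- trimws_vec(mirna)
  gene <- toupper(trimws_vec(gene))
  keep <- nzchar(mirna) & nzchar(gene)
  if (!all(keep)) {
    warning(sum(!keep), " interaction rows with empty identifiers dropped")
  }
  df <- data.frame(mirna = mirna[keep], gene = gene[keep],
                   source = rep_len(as.character(source), length(mirna))[keep],
                   evidence = rep_len(as.character(evidence), length(mirna))[keep],
                   stringsAsFactors = FALSE)
  if (!is.null(score)) df$context_score <- as.numeric(score)[keep]
  key <- paste(df$mirna, df$gene, sep = "\r")
  first <- !duplicated(key)
  out <- df[first, c("mirna", "gene"), drop = FALSE]
  grp <- match(key, key[first])
  out$sources <- vapply(split(df$source, grp),
                        function(s) paste(sort(unique(s)), collapse = ","), "")
  out$evidence <- vapply(split(df$evidence, grp),
                         function(e) paste(unique(e[nzchar(e)]), collapse = ";"), "")
  out$n_records <- as.integer(tabulate(grp, nbins = sum(first)))
  if (!is.null(score)) {
    # strongest (most negative) score is retained for a duplicated pair
    out$context_score <- vapply(split(df$context_score, grp), min, 0)
  }
  rownames(out) <- NULL
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, name = name, class = c("interaction_set", "data.frame"))
}

#' @export
print.interaction_set <- function(x, ...) {
  cat("interaction_set '", attr(x, "name"), "': ", nrow(x), " pairs, ",
      length(unique(x$mirna)), " miRNAs, ",
      length(unique(x$gene)), " genes\n", sep = "")
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @export
summary.interaction_set <- function(object, ...) {
  deg <- table(object$mirna)
  list(name = attr(object, "name"),
       n_pairs = nrow(object),
       n_mirnas = length(unique(object$mirna)),
       n_genes = length(unique(object$gene)),
       degree_summary = summary(as.integer(deg)),
       max_degree = if (nrow(object)) max(as.integer(deg)) else 0L)
}

#' Read a miRNA-gene interaction table
#'
#' Reads a tab-separated interaction table in one of two dialects. The
#' *empirical* dialect carries an evidence-type column (as in strong-evidence
#' exports of validated-interaction databases) and supports an evidence
#' whitelist; the *predicted* dialect carries a per-pair real-valued context
#' score (more negative = stronger predicted repression).
#'
#' @param path path to a UTF-8 TSV file with a header row. Empirical dialect
#'   columns: `mirna`, `gene`, `evidence` (optional `pmid`). Predicted
#'   dialect columns: `mirna`, `gene`, `context_score`.
#' @param dialect `"empirical"` or `"predicted"`.
#' @param evidence_filter optional character vector; empirical rows whose
#'   `evidence` label is not in the set are dropped. `NULL` keeps all rows.
#'   A typical strong-evidence whitelist is
#'   `c("reporter assay", "western blot")`.
#' @param source source label recorded for the pairs (defaults to the
#'   dialect, upper-cased).
#' @param name set name; defaults to the file name.
#' @return an [interaction_set()].
#' @export
read_interaction_table <- function(path,
                                   dialect = c("empirical", "predicted"),
                                   evidence_filter = NULL,
                                   source = NULL, name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "")
  need <- if (dialect == "empirical") c("mirna", "gene", "evidence")
          else c("mirna", "gene", "context_score")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("interaction table ", path, " lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  if (dialect == "empirical" && !is.null(evidence_filter)) {
    tab <- tab[trimws_vec(tab$evidence) %in% evidence_filter, , drop = FALSE]
  }
  if (dialect == "predicted") {
    sc <- suppressWarnings(as.numeric(tab$context_score))
    bad <- !is.finite(sc)
    if (any(bad)) {
      warning(sum(bad), " predicted rows with non-finite context_score dropped")
      tab <- tab[!bad, , drop = FALSE]
      sc <- sc[!bad]
    }
    tab$context_score <- sc
  }
  if (nrow(tab) == 0L) warning("no interactions left after filtering: ", path)
  interaction_set(
    mirna = tab$mirna, gene = tab$gene,
    source = source %||% toupper(dialect),
    evidence = if (dialect == "empirical") tab$evidence else "predicted",
    score = if (dialect == "predicted") tab$context_score else NULL,
    name = name %||% basename(path))
}

#' Write an interaction set to a TSV file
#'
#' Columns: `mirna`, `gene`, `sources` (comma-joined), `evidence`
#' (semicolon-joined) and `context_score` when present. The written file is
#' re-readable by [read_interaction_table()] (empirical dialect requires an
#' `evidence` column, which is always written).
#'
#' @param set an [interaction_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interaction_set <- function(set, path) {
  stopifnot(inherits(set, "interaction_set"))
  cols <- intersect(c("mirna", "gene", "sources", "evidence", "context_score"),
                    names(set))
  utils::write.table(as.data.frame(set)[, cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Union of interaction sets
#'
#' Distinct (miRNA, gene) pairs across all sets, with provenance (sources,
#' evidence labels) merged per pair.
#'
#' @param sets a list of [interaction_set()] objects (at least one).
#' @param name name for the combined set.
#' @return an [interaction_set()].
#' @export
union_sets <- function(sets, name = "union") {
  if (inherits(sets, "interaction_set")) sets <- list(sets)
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, TRUE, "interaction_set")))
  rows <- lapply(sets, function(s) {
    data.frame(mirna = s$mirna, gene = s$gene, source = s$sources,
               evidence = s$evidence,
               context_score = if ("context_score" %in% names(s))
                 s$context_score else NA_real_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  # split comma-joined sources back out so merged provenance stays flat
  src <- strsplit(df$source, ",", fixed = TRUE)
  n <- lengths(src)
  df <- df[rep(seq_len(nrow(df)), n), , drop = FALSE]
  df$source <- unlist(src)
  has_score <- any(is.finite(df$context_score))
  interaction_set(df$mirna, df$gene, df$source, df$evidence,
                  score = if (has_score) df$context_score else NULL,
                  name = name)
}

#' Three-set Venn region counts
#'
#' Tabulates the seven disjoint regions of a three-set Venn diagram over
#' genes, miRNAs or (miRNA, gene) pairs. Region names are binary membership
#' masks in the order of the input sets: `"100"` = only in set 1, `"110"` =
#' in sets 1 and 2 only, `"111"` = in all three, etc.
#'
#' @param sets a list of exactly three [interaction_set()] objects.
#' @param by count distinct `"gene"`, `"mirna"` or `"pair"` entities.
#' @return a list with `counts` (named integer vector of the 7 regions),
#'   `per_set` (distinct entities per input set), `union` (distinct entities
#'   overall) and `by`.
#' @export
venn_counts <- function(sets, by = c("gene", "mirna", "pair")) {
  by <- match.arg(by)
  stopifnot(is.list(sets), length(sets) == 3L,
            all(vapply(sets, inherits, TRUE, "interaction_set")))
  ent <- lapply(sets, function(s) {
    unique(switch(by,
                  gene = s$gene, mirna = s$mirna,
                  pair = paste(s$mirna, s$gene, sep = "\r")))
  })
  universe <- unique(unlist(ent))
  mask <- vapply(ent, function(e) universe %in% e, logical(length(universe)))
  if (length(universe) == 1L) mask <- matrix(mask, nrow = 1L)
  code <- apply(mask, 1L, function(m) paste(as.integer(m), collapse = ""))
  regions <- c("100", "010", "001", "110", "101", "011", "111")
  counts <- vapply(regions, function(r) sum(code == r), 0L)
  list(counts = counts,
       per_set = vapply(ent, length, 0L),
       union = length(universe),
       by = by)
}

#' Split miRNAs into high- and low-degree subsets
#'
#' Partitions the miRNAs of an interaction set into a high-degree set A and a
#' low-degree set B, either by a fixed degree threshold (set B holds the
#' miRNAs interacting with fewer than `threshold` genes) or by a target
#' coverage fraction (take miRNAs in decreasing degree order until their
#' targets cover at least `cover_fraction` of the gene universe).
#'
#' @param set an [interaction_set()] (must be non-empty).
#' @param threshold integer >= 1; miRNAs with degree >= `threshold` go to set
#'   A (ties at the threshold go to A). Default 6, i.e. set B = degree < 6.
#' @param mode `"degree"` (fixed threshold) or `"cover_fraction"`.
#' @param cover_fraction target fraction of the gene universe covered by set
#'   A's targets when `mode = "cover_fraction"`.
#' @return a `degree_split` list: `set_a`, `set_b` (character vectors of
#'   miRNA ids), `threshold` (the effective degree cut: the minimum degree in
#'   A), `a_share_percent` (A's share of all miRNAs, nearest integer
#'   percent), `a_gene_coverage` (fraction of the gene universe targeted by
#'   A), and per-side gene vectors `genes_a`, `genes_b`.
#' @export
degree_split <- function(set, threshold = 6L,
                         mode = c("degree", "cover_fraction"),
                         cover_fraction = 0.75) {
  stopifnot(inherits(set, "interaction_set"))
  if (nrow(set) == 0L) stop("cannot split an empty interaction set")
  mode <- match.arg(mode)
  deg <- sort(table(set$mirna), decreasing = TRUE)
  genes_of <- split(set$gene, set$mirna)
  n_genes <- length(unique(set$gene))
  if (mode == "degree") {
    stopifnot(threshold >= 1L)
    a <- names(deg)[as.integer(deg) >= threshold]
  } else {
    ord <- names(deg)
    covered <- character(0)
    a <- character(0)
    for (m in ord) {
      if (length(covered) >= cover_fraction * n_genes) break
      a <- c(a, m)
      covered <- union(covered, genes_of[[m]])
    }
    threshold <- if (length(a)) min(as.integer(deg[a])) else NA_integer_
  }
  b <- setdiff(names(deg), a)
  genes_a <- unique(unlist(genes_of[a], use.names = FALSE))
  genes_b <- unique(unlist(genes_of[b], use.names = FALSE))
  structure(list(
    set_a = a, set_b = b,
    threshold = as.integer(threshold),
    a_share_percent = round_half_up(100 * length(a) / length(deg)),
    a_gene_coverage = length(genes_a) / n_genes,
    genes_a = genes_a %||% character(0),
    genes_b = genes_b %||% character(0)),
    class = "degree_split")
}

#' @export
print.degree_split <- function(x, ...) {
  cat("degree_split: |A| =", length(x$set_a),
      sprintf("(%g%% of miRNAs),", x$a_share_percent),
      "|B| =", length(x$set_b),
      sprintf("; A covers %.1f%% of target genes (degree cut %d)\n",
              100 * x$a_gene_coverage, x$threshold))
  invisible(x)
}
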