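#' @title Robustness checks for the enrichment pipeline
#' @description Two reusable validity experiments: a random-gene-set null
#'   control (no term should reach significance for uniformly drawn gene
#'   sets under Bonferroni control) and a miRNA degree-split concordance
#'   check (the functional areas found from the high-degree miRNAs' targets,
#'   the low-degree miRNAs' targets and the full target set are compared).
#' @name validation
NULL

#' Random-gene-set null control
#'
#' Repeatedly samples gene sets uniformly without replacement from the
#' annotated background and runs the over-representation analysis; under the
#' complete null, Bonferroni control at level `alpha` should leave (almost)
#' every run without a single significant term.
#'
#' @param annotations a [propagate()]d `annotation_table`.
#' @param graph the [ontology_graph()].
#' @param set_size genes drawn per repeat (must not exceed the background).
#' @param repeats number of repeats, default 10.
#' @param alpha significance threshold, default 0.05.
#' @param seed integer seed; recorded in the report.
#' @param correction `"bonferroni"` or `"none"`.
#' @return a `null_control_report`: list with `repeats`, `set_size`,
#'   `alpha`, `correction`, `seed`, `significant_term_counts` (per repeat),
#'   `runs_with_zero` and `fwer` (fraction of runs with >= 1 significant
#'   term).
#' @export
null_control <- function(annotations, graph, set_size, repeats = 10L,
                         alpha = 0.05, seed = 1L,
                         correction = c("bonferroni", "none")) {
  stopifnot(inherits(annotations, "annotation_table"))
  correction <- match.arg(correction)
  bg <- unique(unlist(annotations$background, use.names = FALSE))
  if (set_size > length(bg)) {
    stop("set_size exceeds the annotated background (", length(bg), ")")
  }
  cfg <- ora_config(p_threshold = alpha, correction = correction,
                    direction = "over")
  set.seed(as.integer(seed))
  counts <- vapply(seq_len(repeats), function(i) {
    gs <- sample(bg, set_size)
    res <- run_ora(gs, annotations, graph, cfg)
    sum(res$records$significant)
  }, 0L)
  structure(list(repeats = as.integer(repeats),
                 set_size = as.integer(set_size),
                 alpha = alpha, correction = correction,
                 seed = as.integer(seed),
                 significant_term_counts = counts,
                 runs_with_zero = sum(counts == 0L),
                 fwer = mean(counts > 0L)),
            class = "null_control_report")
}

#' @export
print.null_control_report <- function(x, ...) {
  cat(sprintf(paste0("null_control: %d repeats of %d genes, alpha = %g (%s)\n",
                     "  runs with zero significant terms: %d / %d",
                     " (empirical FWER %.3f)\n"),
              x$repeats, x$set_size, x$alpha, x$correction,
              x$runs_with_zero, x$repeats, x$fwer))
  invisible(x)
}

# lower median: for even counts take the smaller of the two central values
lower_median <- function(x) {
  if (!length(x)) return(NA_real_)
  sort(x)[ceiling(length(x) / 2)]
}

#' Degree-split concordance of functional areas
#'
#' Splits the miRNAs of an interaction set by out-degree, runs the full
#' ORA + functional-abstraction analysis on the complete target gene set and
#' on the target sets of each side, and compares the resulting area sets.
#' Median -log10 adjusted p values are summarized per run over the selected
#' areas (lower median for even counts).
#'
#' @param interactions an [interaction_set()].
#' @param split a [degree_split()] of its miRNAs.
#' @param annotations a [propagate()]d `annotation_table`.
#' @param graph the [ontology_graph()].
#' @param config an [ora_config()].
#' @param namespace namespace to abstract; default first non-empty.
#' @param ... further arguments to [select_functional_areas()].
#' @return a `split_concordance` list: `areas_full`, `areas_a`, `areas_b`
#'   (term id vectors), `missing_in_a`, `missing_in_b` (areas of the full run
#'   absent from the respective side), `extra_in_a`, `extra_in_b`,
#'   `median_minus_log10_p_full`, `median_minus_log10_p_a`,
#'   `median_minus_log10_p_b` and per-side gene counts.
#' @export
split_concordance <- function(interactions, split, annotations, graph,
                              config = ora_config(), namespace = NULL, ...) {
  stopifnot(inherits(interactions, "interaction_set"),
            inherits(split, "degree_split"))
  mirnas <- unique(interactions$mirna)
  if (!setequal(c(split$set_a, split$set_b), mirnas)) {
    stop("split does not partition the interaction set's miRNAs")
  }
  if (!length(split$genes_a) || !length(split$genes_b)) {
    stop("a split side has an empty target gene set")
  }
  one_run <- function(genes) {
    res <- run_ora(genes, annotations, graph, config)
    areas <- select_functional_areas(res, annotations, graph,
                                     namespace = namespace, ...)
    list(terms = areas$term,
         median_mlp = lower_median(areas$minus_log10_p_adj))
  }
  full <- one_run(unique(interactions$gene))
  a <- one_run(split$genes_a)
  b <- one_run(split$genes_b)
  structure(list(
    areas_full = full$terms, areas_a = a$terms, areas_b = b$terms,
    missing_in_a = setdiff(full$terms, a$terms),
    missing_in_b = setdiff(full$terms, b$terms),
    extra_in_a = setdiff(a$terms, full$terms),
    extra_in_b = setdiff(b$terms, full$terms),
    median_minus_log10_p_full = full$median_mlp,
    median_minus_log10_p_a = a$median_mlp,
    median_minus_log10_p_b = b$median_mlp,
    n_genes_full = length(unique(interactions$gene)),
    n_genes_a = length(split$genes_a),
    n_genes_b = length(split$genes_b)),
    class = "split_concordance")
}

#' @export
print.split_concordance <- function(x, ...) {
  cat(sprintf("split_concordance: full %d areas; A %d areas (missing %d); B %d areas (missing %d)\n",
              length(x$areas_full), length(x$areas_a), length(x$missing_in_a),
              length(x$areas_b), length(x$missing_in_b)))
  cat(sprintf("  median -log10 p: full %.1f, A %.1f, B %.1f\n",
              x$median_minus_log10_p_full, x$median_minus_log10_p_a,
              x$median_minus_log10_p_b))
  invisible(x)
}
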