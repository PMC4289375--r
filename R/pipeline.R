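#' @title End-to-end pipeline
#' @description Orchestrates merge -> score filter -> over-representation
#'   analysis -> functional abstraction -> reporting from a single
#'   configuration, writing the per-stage tables, DOT figures and a summary
#'   JSON.
#' @name cli_report
NULL

#' Pipeline run configuration
#'
#' @param empirical character vector of empirical-dialect interaction TSV
#'   paths.
#' @param predicted predicted-dialect interaction TSV path (optional; omit
#'   to run on empirical evidence only).
#' @param obo ontology OBO path.
#' @param annotations annotation TSV path.
#' @param out_dir output directory.
#' @param evidence_filters list of evidence whitelists, one per empirical
#'   file (`NULL` entries keep all rows). Default: strong experimental
#'   evidence `c("reporter assay", "western blot")` for the first file,
#'   `c("direct")` for any further file.
#' @param posterior_threshold posterior validity cut for predictions,
#'   default 0.98.
#' @param score_family model family for [fit_score_model()].
#' @param p_threshold ORA significance threshold, default 1e-5.
#' @param correction multiple-testing correction, default `"bonferroni"`.
#' @param min_coverage_gain,max_areas,min_information_value functional-area
#'   selection parameters (see [select_functional_areas()]).
#' @param topic_map optional named vector term id -> topic label.
#' @param ratio_terms optional character vector of exactly two term ids; the
#'   summary reports the ratio of their observed counts (e.g. a
#'   nucleus-versus-cytoplasm comparison).
#' @param seed integer seed recorded in the summary.
#' @return a `run_config` list.
#' @export
run_config <- function(empirical, predicted = NULL, obo, annotations,
                       out_dir,
                       evidence_filters = NULL,
                       posterior_threshold = 0.98,
                       score_family = "gaussian",
                       p_threshold = 1e-5,
                       correction = "bonferroni",
                       min_coverage_gain = 0.02, max_areas = 25L,
                       min_information_value = 1,
                       topic_map = NULL, ratio_terms = NULL,
                       seed = 1L) {
  if (is.null(evidence_filters)) {
    evidence_filters <- c(list(c("reporter assay", "western blot")),
                          rep(list("direct"), max(0L, length(empirical) - 1L)))
  }
  stopifnot(length(evidence_filters) == length(empirical))
  structure(list(empirical = empirical, predicted = predicted,
                 obo = obo, annotations = annotations, out_dir = out_dir,
                 evidence_filters = evidence_filters,
                 posterior_threshold = posterior_threshold,
                 score_family = score_family,
                 p_threshold = p_threshold, correction = correction,
                 min_coverage_gain = min_coverage_gain,
                 max_areas = max_areas,
                 min_information_value = min_information_value,
                 topic_map = topic_map, ratio_terms = ratio_terms,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) read and evidence-filter the empirical interaction tables;
#' (2) read the predicted table, fit the two-component score model on the
#' validated-overlap scores and keep predictions with posterior validity
#' above the threshold; (3) take the union of all sources and its Venn
#' accounting; (4) parse the ontology, propagate annotations, and run the
#' over-representation analysis on the union gene set; (5) select and label
#' functional areas; (6) write `venn.json`, `merged.tsv`,
#' `enrichment_<namespace>.tsv`, `areas.tsv`, `dag_<namespace>.dot` and
#' `summary.json` into the output directory.
#'
#' A stage failure aborts the run with the stage name in the error message.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all stage objects (`sets`, `model`,
#'   `filtered`, `merged`, `venn`, `ora`, `areas`, `summary`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in c(config$empirical, config$predicted, config$obo,
              config$annotations)) {
    if (!file.exists(f)) stop("input file missing at run start: ", f)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sets <- stage("read_empirical", {
    lapply(seq_along(config$empirical), function(i) {
      read_interaction_table(config$empirical[i], "empirical",
                             evidence_filter = config$evidence_filters[[i]],
                             source = sprintf("EMPIRICAL_%s", LETTERS[i]))
    })
  })

  model <- filtered <- NULL
  if (!is.null(config$predicted)) {
    pred <- stage("read_predicted",
                  read_interaction_table(config$predicted, "predicted",
                                         source = "PREDICTED"))
    emp_pairs <- unlist(lapply(sets, function(s) paste(s$mirna, s$gene)))
    validated <- paste(pred$mirna, pred$gene) %in% emp_pairs
    model <- stage("fit_score_model", {
      if (sum(validated) < 30L) {
        stop("fewer than 30 predicted pairs overlap the validated set")
      }
      # the valid component is anchored on the validated-overlap scores;
      # the pooled population (validated rows included) feeds the EM, whose
      # responsibilities separate the background from the contamination
      fit_score_model(pred$context_score[validated],
                      pred$context_score,
                      family = config$score_family,
                      threshold = config$posterior_threshold)
    })
    filtered <- stage("filter_predictions", filter_predictions(pred, model))
    sets <- c(sets, list(filtered$kept))
  }

  merged <- stage("union", union_sets(sets, name = "merged"))
  venn <- if (length(sets) == 3L) {
    stage("venn", venn_counts(sets, by = "gene"))
  } else NULL

  graph <- stage("parse_obo", parse_obo(config$obo))
  ann <- stage("propagate",
               propagate(graph, read_annotations(config$annotations)))
  cfg <- ora_config(p_threshold = config$p_threshold,
                    correction = config$correction)
  ora <- stage("run_ora",
               run_ora(unique(merged$gene), ann, graph, cfg))

  areas_by_ns <- stage("abstraction", {
    out <- list()
    for (ns in names(ora$sig_dag)) {
      a <- select_functional_areas(
        ora, ann, graph, namespace = ns,
        min_coverage_gain = config$min_coverage_gain,
        max_areas = config$max_areas,
        min_information_value = config$min_information_value)
      out[[ns]] <- apply_topic_map(a, config$topic_map)
    }
    out
  })
  areas <- if (length(areas_by_ns)) {
    structure(do.call(rbind, lapply(areas_by_ns, as.data.frame)),
              class = c("functional_areas", "data.frame"))
  } else empty_areas()
  rownames(areas) <- NULL

  paths <- stage("write_outputs", {
    p <- list(merged = file.path(config$out_dir, "merged.tsv"),
              areas = file.path(config$out_dir, "areas.tsv"),
              summary = file.path(config$out_dir, "summary.json"))
    write_interaction_set(merged, p$merged)
    write_areas(areas, p$areas)
    if (!is.null(venn)) {
      p$venn <- file.path(config$out_dir, "venn.json")
      jsonlite::write_json(venn, p$venn, auto_unbox = TRUE, digits = NA)
    }
    for (ns in names(ora$sig_dag)) {
      tsv <- file.path(config$out_dir, paste0("enrichment_", ns, ".tsv"))
      recs <- ora$records[ora$records$namespace == ns, , drop = FALSE]
      recs$is_functional_area <- recs$term %in% areas$term
      utils::write.table(recs, tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p[[paste0("enrichment_", ns)]] <- tsv
      dot <- file.path(config$out_dir, paste0("dag_", ns, ".dot"))
      writeLines(export_dag(ora$sig_dag[[ns]],
                            areas = areas$term[areas$namespace == ns],
                            graph_name = gsub("\\W", "_", ns)), dot)
      p[[paste0("dag_", ns)]] <- dot
    }
    p
  })

  summary <- stage("summary", {
    union_genes <- unique(merged$gene)
    per_source <- lapply(sets, function(s) {
      list(name = attr(s, "name"),
           n_pairs = nrow(s),
           n_genes = length(unique(s$gene)),
           n_mirnas = length(unique(s$mirna)),
           gene_percent_of_union = round_half_up(
             100 * length(unique(s$gene)) / length(union_genes), 1L))
    })
    ratio <- NULL
    if (!is.null(config$ratio_terms)) {
      stopifnot(length(config$ratio_terms) == 2L)
      obs <- ora$records$observed[match(config$ratio_terms,
                                        ora$records$term)]
      if (!any(is.na(obs)) && obs[2] > 0) {
        ratio <- list(terms = config$ratio_terms,
                      observed = obs, ratio = count_ratio(obs[1], obs[2]))
      }
    }
    s <- list(seed = config$seed,
              n_union_genes = length(union_genes),
              n_union_mirnas = length(unique(merged$mirna)),
              sources = per_source,
              venn_genes = venn,
              filter_report = filtered$report,
              score_model = if (!is.null(model)) unclass(model),
              ora = list(n = as.list(ora$n), m = as.list(ora$m),
                         n_significant = sum(ora$records$significant),
                         p_threshold = config$p_threshold),
              areas = lapply(seq_len(nrow(areas)), function(i) {
                as.list(as.data.frame(areas)[i, ])
              }),
              term_count_ratio = ratio)
    jsonlite::write_json(s, paths$summary, auto_unbox = TRUE, digits = NA)
    s
  })

  invisible(list(sets = sets, model = model, filtered = filtered,
                 merged = merged, venn = venn, graph = graph,
                 annotations = ann, ora = ora, areas = areas,
                 summary = summary, paths = paths))
}
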