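#' Read and validate a pipeline run configuration
#'
#' The configuration is a single YAML file (or an equivalent list) naming
#' the source edge tables with their column specs, the positive lists, the
#' target node, the method parameters and the filter lists. Validation
#' happens before any computation: every referenced path must exist and the
#' ranked-paths threshold must lie in (0, 1].
#'
#' @param config A YAML file path or a list with the same structure; see
#'   the package vignette for the schema.
#' @return The validated config list, invisibly classed `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    methods = c("steiner", "paths_to_target", "ranked_paths"),
    threshold = 0.7, normalization = "max", paths_mode = "single",
    unmapped = "keep", seed = 1L
  )
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$sources) || length(cfg$sources) == 0) {
    stop("config must list at least one source edge table", call. = FALSE)
  }
  if (is.null(cfg$positives) || length(cfg$positives) == 0) {
    stop("config must list at least one positive-protein list", call. = FALSE)
  }
  if (!is.numeric(cfg$threshold) || cfg$threshold <= 0 || cfg$threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  bad <- setdiff(cfg$methods,
                 c("steiner", "paths_to_target", "ranked_paths"))
  if (length(bad) > 0) {
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("paths_to_target" %in% cfg$methods && is.null(cfg$target)) {
    stop("a target node is required for the paths_to_target method",
         call. = FALSE)
  }
  referenced <- c(
    vapply(cfg$sources, function(s) s$path, character(1)),
    unlist(cfg$positives, use.names = FALSE),
    cfg$mapping, cfg$known_pathway, cfg$known_interactors, cfg$expressed
  )
  missing <- referenced[!file.exists(referenced)]
  if (length(missing) > 0) {
    stop("referenced file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = c("run_config", "list"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full prediction pipeline
#'
#' Orchestrates build, predict, combine, filter and report: loads and
#' identifier-maps the source edge tables, merges them into one interactome,
#' assembles the positives, runs the configured prediction methods, combines
#' and filters the candidates, and (when `output_dir` is given) writes
#' deterministic artifacts: the merged interactome and candidate table as
#' TSV, the Steiner tree and path collection as edge lists, and a summary
#' JSON embedding the interactome summary, per-method candidate counts, the
#' Venn counts and the exact configuration used.
#'
#' @param config A YAML path or config list (see [read_run_config()]).
#' @param output_dir Optional directory for run artifacts.
#' @return A list with `interactome`, `summary`, `positives`, `results`
#'   (per-method `method_result`s), `table` (the filtered
#'   `candidate_table`), `scores` and `artifacts` (written file paths).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- read_run_config(config)

  records <- stage("build", {
    lapply(cfg$sources, function(s) {
      recs <- load_edge_table(
        s$path, s$name,
        edge_columns(s$id_a %||% "protein_a", s$id_b %||% "protein_b",
                     citations = s$citations, evidence_codes = s$evidence_codes,
                     sep = s$sep %||% ";")
      )
      if (!is.null(cfg$mapping)) {
        recs <- suppressWarnings(
          map_identifiers(recs, cfg$mapping, unmapped = cfg$unmapped)
        )
      }
      recs
    })
  })
  net <- stage("merge", merge_sources(records))
  summary <- interactome_summary(net)

  positives <- stage("positives", {
    lists <- cfg$positives
    if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
      names(lists) <- paste0("list", seq_along(lists))
    }
    assemble_positives(lapply(lists, read_id_list), net)
  })

  results <- list()
  scores <- NULL
  if ("steiner" %in% cfg$methods) {
    results$steiner <- stage("steiner", steiner_candidates(net, positives))
  }
  if ("paths_to_target" %in% cfg$methods) {
    results$paths_to_target <- stage(
      "paths_to_target",
      paths_to_target_candidates(net, positives, cfg$target,
                                 mode = cfg$paths_mode)
    )
  }
  if ("ranked_paths" %in% cfg$methods) {
    scores <- stage("ranked_paths",
                    ranked_paths_scores(net, positives,
                                        normalization = cfg$normalization))
    results$ranked_paths <- ranked_candidates(scores, cfg$threshold)
  }

  table <- stage("combine", combine_methods(unname(results)))
  table <- stage("filter", filter_candidates(
    table,
    known_pathway = if (is.null(cfg$known_pathway)) character(0)
                    else read_id_list(cfg$known_pathway),
    known_interactors = if (is.null(cfg$known_interactors)) character(0)
                        else read_id_list(cfg$known_interactors),
    expressed = if (is.null(cfg$expressed)) NULL
                else read_id_list(cfg$expressed)
  ))

  artifacts <- character(0)
  if (!is.null(output_dir)) {
    artifacts <- stage("report",
                       write_run_artifacts(output_dir, cfg, net, summary,
                                           positives, results, table, scores))
  }
  list(interactome = net, summary = summary, positives = positives,
       results = results, table = table, scores = scores,
       artifacts = artifacts)
}

write_run_artifacts <- function(output_dir, cfg, net, summary, positives,
                                results, table, scores) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    interactome = file.path(output_dir, "interactome.tsv"),
    candidates = file.path(output_dir, "candidates.tsv"),
    summary = file.path(output_dir, "summary.json")
  )
  write_interactome(net, paths[["interactome"]])
  write_candidate_table(table, paths[["candidates"]], scores = scores)
  if (!is.null(results$steiner)) {
    paths[["steiner_tree"]] <- file.path(output_dir, "steiner_tree.tsv")
    readr::write_tsv(results$steiner$support, paths[["steiner_tree"]],
                     progress = FALSE)
  }
  if (!is.null(results$paths_to_target)) {
    paths[["paths"]] <- file.path(output_dir, "paths_to_target.tsv")
    flat <- results$paths_to_target$support |>
      dplyr::mutate(path = vapply(.data$path, paste, character(1),
                                  collapse = "|"))
    readr::write_tsv(flat, paths[["paths"]], progress = FALSE)
  }
  summary_json <- list(
    interactome = as.list(glance.interactome_summary(summary)),
    per_source = summary$per_source,
    positives = list(n_total = nrow(positives),
                     n_in_graph = sum(positives$in_graph),
                     missing = positives_missing(positives)),
    method_counts = lapply(results, function(r) length(r$candidates)),
    venn_counts = venn_counts(table),
    config = unclass(cfg)
  )
  jsonlite::write_json(summary_json, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
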