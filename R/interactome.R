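#' Describe the columns of a source edge table
#'
#' Each upstream interaction database ships its own schema, so the two
#' protein-identifier columns and the optional evidence columns are named
#' per source. Multi-valued cells (several citations backing one row) are
#' split on `sep`.
#'
#' @param id_a,id_b Names of the columns holding the two interactor IDs.
#' @param citations Optional name of a column of literature IDs (e.g. PubMed).
#' @param evidence_codes Optional name of a column of PSI-MI method codes.
#' @param sep Separator used inside multi-valued cells. Default `";"`.
#' @return A list of class `edge_columns` for use with [load_edge_table()].
#' @export
#' @examples
#' edge_columns("FBgn_A", "FBgn_B", citations = "pubmed_ids")
edge_columns <- function(id_a, id_b, citations = NULL, evidence_codes = NULL,
                         sep = ";") {
  stopifnot(is.character(id_a), length(id_a) == 1L, nzchar(id_a),
            is.character(id_b), length(id_b) == 1L, nzchar(id_b))
  structure(
    list(id_a = id_a, id_b = id_b, citations = citations,
         evidence_codes = evidence_codes, sep = sep),
    class = "edge_columns"
  )
}

split_multi <- function(x, sep) {
  out <- strsplit(ifelse(is.na(x), "", as.character(x)), sep, fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    sort(unique(v[nzchar(v)]))
  })
}

#' Load one source database's edge table
#'
#' Reads a tab-separated edge table with a header row and returns one edge
#' record per usable data row. Rows with a missing or empty identifier are
#' skipped and counted in the attached load report; self-loops are *kept*
#' here — they are removed when sources are merged, so the report of what
#' each database contributed stays faithful to its raw content.
#'
#' @param path Path to a TSV file with a header.
#' @param source_db Label for this source database (e.g. `"DroID"`).
#' @param columns An [edge_columns()] specification.
#' @return A tibble with columns `protein_a`, `protein_b`, `source_db`,
#'   `citations` (list of character), `evidence_codes` (list of character),
#'   carrying a `load_report` attribute (see [load_report()]).
#' @seealso [map_identifiers()], [merge_sources()]
#' @export
load_edge_table <- function(path, source_db, columns) {
  if (!file.exists(path)) {
    stop("edge table not found: ", path, call. = FALSE)
  }
  stopifnot(inherits(columns, "edge_columns"),
            is.character(source_db), length(source_db) == 1L, nzchar(source_db))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  needed <- c(columns$id_a, columns$id_b, columns$citations, columns$evidence_codes)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("column(s) not present in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  a <- trimws(raw[[columns$id_a]])
  b <- trimws(raw[[columns$id_b]])
  ok <- !is.na(a) & nzchar(a) & !is.na(b) & nzchar(b)
  cit <- if (is.null(columns$citations)) {
    rep(list(character(0)), sum(ok))
  } else {
    split_multi(raw[[columns$citations]][ok], columns$sep)
  }
  ev <- if (is.null(columns$evidence_codes)) {
    rep(list(character(0)), sum(ok))
  } else {
    split_multi(raw[[columns$evidence_codes]][ok], columns$sep)
  }
  records <- tibble::tibble(
    protein_a = a[ok],
    protein_b = b[ok],
    source_db = source_db,
    citations = cit,
    evidence_codes = ev
  )
  attr(records, "load_report") <- list(
    path = path, source_db = source_db,
    n_rows = length(ok), n_loaded = sum(ok), n_skipped = sum(!ok),
    skipped_rows = which(!ok)
  )
  records
}

#' Retrieve the load report attached to an edge-record tibble
#'
#' @param records The tibble returned by [load_edge_table()].
#' @return A list with the source path, row counts and skipped row indices.
#' @export
load_report <- function(records) {
  attr(records, "load_report")
}

#' Map foreign protein identifiers to canonical (FlyBase) IDs
#'
#' Replaces every identifier found in the mapping by its canonical form
#' (FBgn convention). Identifiers absent from the mapping are either kept
#' as-is (default, with a warning) or dropped together with their records.
#' Comparison is case-sensitive. Many foreign IDs may map to one canonical
#' ID; such records collapse into a single edge at merge time.
#'
#' @param records An edge-record tibble ([load_edge_table()] output, or any
#'   tibble with `protein_a`/`protein_b` columns).
#' @param mapping A two-column data frame (foreign ID, canonical ID), a named
#'   character vector `c(foreign = "canonical")`, or a TSV path to the former.
#' @param unmapped Policy for IDs absent from the mapping: `"keep"` (default)
#'   or `"drop"` (removes the whole record).
#' @return The records with identifiers substituted; an `unmapped_report`
#'   attribute lists the distinct IDs that had no mapping.
#' @export
map_identifiers <- function(records, mapping, unmapped = c("keep", "drop")) {
  unmapped <- match.arg(unmapped)
  map <- as_id_map(mapping)
  a <- records$protein_a
  b <- records$protein_b
  ma <- map[a]
  mb <- map[b]
  unknown <- sort(unique(c(a[is.na(ma)], b[is.na(mb)])))
  out <- records
  out$protein_a <- unname(ifelse(is.na(ma), a, ma))
  out$protein_b <- unname(ifelse(is.na(mb), b, mb))
  if (unmapped == "drop") {
    keep <- !is.na(ma) & !is.na(mb)
    out <- out[keep, , drop = FALSE]
  } else if (length(unknown) > 0) {
    warning(length(unknown), " identifier(s) had no mapping and were kept as-is",
            call. = FALSE)
  }
  attr(out, "unmapped_report") <- list(policy = unmapped, unmapped_ids = unknown)
  out
}

as_id_map <- function(mapping) {
  if (is.character(mapping) && is.null(dim(mapping)) && length(mapping) == 1L &&
      !rlang::is_named(mapping)) {
    mapping <- readr::read_tsv(mapping,
                               col_types = readr::cols(.default = readr::col_character()),
                               progress = FALSE, show_col_types = FALSE)
  }
  if (is.data.frame(mapping)) {
    stopifnot(ncol(mapping) >= 2)
    map <- stats::setNames(as.character(mapping[[2]]), as.character(mapping[[1]]))
  } else if (is.character(mapping) && rlang::is_named(mapping)) {
    map <- mapping
  } else {
    stop("mapping must be a data frame, a named character vector, or a TSV path",
         call. = FALSE)
  }
  if (anyDuplicated(names(map))) {
    first <- !duplicated(names(map))
    conflicting <- tapply(map, names(map), function(v) length(unique(v)) > 1)
    if (any(conflicting)) {
      stop("mapping is not a function: foreign ID(s) map to several canonical IDs: ",
           paste(utils::head(names(conflicting)[conflicting], 5), collapse = ", "),
           call. = FALSE)
    }
    map <- map[first]
  }
  map
}

canonical_pair <- function(a, b) {
  swap <- b < a
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

#' Merge identifier-mapped edge records from several sources into one graph
#'
#' Edges are deduplicated as unordered pairs across all sources, self-loops
#' are removed (and counted), and evidence is kept per (edge, source) with
#' citations and PSI-MI codes unioned over duplicate rows. The node set is
#' the union of edge endpoints; isolated nodes can be added explicitly via
#' `extra_nodes` (needed when a positive protein has no recorded
#' interaction).
#'
#' @param records A single edge-record tibble carrying a `source_db` column,
#'   or a list of such tibbles (e.g. one [load_edge_table()] result per
#'   source).
#' @param extra_nodes Optional character vector of node IDs to include even
#'   if they touch no edge.
#' @return An object of class `interactome`: a list with an `igraph` graph
#'   (`$graph`), the unique edge tibble (`$edges`), the per-(edge, source)
#'   evidence tibble (`$evidence`) and `$provenance` metadata.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   protein_a = c("p", "q", "q"), protein_b = c("q", "p", "r"),
#'   source_db = c("A", "B", "A"),
#'   citations = list("PMID:1", character(0), "PMID:2"),
#'   evidence_codes = list(character(0), "MI:0018", character(0))
#' )
#' merge_sources(recs)
merge_sources <- function(records, extra_nodes = character(0)) {
  if (is.data.frame(records)) records <- list(records)
  stopifnot(is.list(records))
  recs <- dplyr::bind_rows(lapply(records, normalize_records))
  n_self <- 0L
  if (nrow(recs) > 0) {
    pair <- canonical_pair(recs$protein_a, recs$protein_b)
    recs$protein_a <- pair$a
    recs$protein_b <- pair$b
    self <- recs$protein_a == recs$protein_b
    n_self <- sum(self)
    recs <- recs[!self, , drop = FALSE]
  }
  evidence <- recs |>
    dplyr::group_by(.data$protein_a, .data$protein_b, .data$source_db) |>
    dplyr::summarise(
      citations = list(sort(unique(unlist(.data$citations)))),
      evidence_codes = list(sort(unique(unlist(.data$evidence_codes)))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$protein_a, .data$protein_b, .data$source_db)
  edges <- dplyr::distinct(evidence, .data$protein_a, .data$protein_b)
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b, extra_nodes)))
  graph <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  structure(
    list(
      graph = graph,
      edges = edges,
      evidence = evidence,
      provenance = list(
        sources = sort(unique(recs$source_db)),
        n_self_loops_dropped = n_self,
        n_isolated_added = length(setdiff(extra_nodes,
                                          c(edges$protein_a, edges$protein_b)))
      )
    ),
    class = "interactome"
  )
}

normalize_records <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("protein_a", "protein_b", "source_db") %in% names(x)))
  if (is.null(x$citations)) x$citations <- rep(list(character(0)), nrow(x))
  if (is.null(x$evidence_codes)) x$evidence_codes <- rep(list(character(0)), nrow(x))
  tibble::as_tibble(x[c("protein_a", "protein_b", "source_db",
                        "citations", "evidence_codes")])
}

#' @export
print.interactome <- function(x, ...) {
  cat("<interactome> ", igraph::vcount(x$graph), " proteins, ",
      nrow(x$edges), " interactions from ",
      length(x$provenance$sources), " source(s): ",
      paste(x$provenance$sources, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Node identifiers of an interactome
#' @param x An `interactome`.
#' @return Character vector of canonical protein IDs.
#' @export
interactome_nodes <- function(x) {
  stopifnot(inherits(x, "interactome"))
  igraph::V(x$graph)$name
}

#' Summarize a merged interactome
#'
#' Counts nodes, unique edges, distinct literature citations and PSI-MI
#' evidence codes, and — per source — the number of merged edges the source
#' supports and the number it does *not* support (edges that would be missed
#' by an analysis restricted to that source alone).
#'
#' @param x An `interactome` from [merge_sources()].
#' @return An `interactome_summary` list; use [glance()] for a one-row
#'   tibble or `$per_source` for the per-database counts.
#' @export
interactome_summary <- function(x) {
  stopifnot(inherits(x, "interactome"))
  n_edges_total <- nrow(x$edges)
  per_source <- x$evidence |>
    dplyr::count(.data$source_db, name = "n_edges") |>
    dplyr::mutate(n_exclusive_of_source = n_edges_total - .data$n_edges) |>
    dplyr::arrange(dplyr::desc(.data$n_edges))
  structure(
    list(
      n_nodes = igraph::vcount(x$graph),
      n_edges = n_edges_total,
      per_source = per_source,
      n_citations = length(unique(unlist(x$evidence$citations))),
      n_evidence_codes = length(unique(unlist(x$evidence$evidence_codes)))
    ),
    class = "interactome_summary"
  )
}

#' @export
print.interactome_summary <- function(x, ...) {
  cat("<interactome summary>\n",
      "  nodes: ", x$n_nodes, "   edges: ", x$n_edges, "\n",
      "  citations: ", x$n_citations,
      "   evidence codes: ", x$n_evidence_codes, "\n", sep = "")
  print(x$per_source)
  invisible(x)
}

#' @rdname interactome_summary
#' @param ... Unused.
#' @export
glance.interactome_summary <- function(x, ...) {
  tibble::tibble(
    n_nodes = x$n_nodes, n_edges = x$n_edges,
    n_sources = nrow(x$per_source),
    n_citations = x$n_citations, n_evidence_codes = x$n_evidence_codes
  )
}

#' @rdname interactome_summary
#' @export
glance.interactome <- function(x, ...) {
  glance.interactome_summary(interactome_summary(x), ...)
}

collapse_multi <- function(x, sep = ";") {
  vapply(x, paste, character(1), collapse = sep)
}

#' Write a merged interactome to disk
#'
#' The TSV layout has one row per unique edge with the supporting sources,
#' citations and PSI-MI codes collapsed with `";"`; GraphML is written via
#' igraph for external network viewers.
#'
#' @param x An `interactome`.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(x, path, format = c("tsv", "graphml")) {
  stopifnot(inherits(x, "interactome"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(x$graph, path, format = "graphml")
    return(invisible(path))
  }
  flat <- x$evidence |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::summarise(
      sources = paste(sort(unique(.data$source_db)), collapse = ";"),
      citations = paste(sort(unique(unlist(.data$citations))), collapse = ";"),
      evidence_codes = paste(sort(unique(unlist(.data$evidence_codes))), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' Read an interactome written by [write_interactome()]
#'
#' @param path Path to the merged-edge TSV.
#' @return An `interactome`.
#' @export
read_interactome <- function(path) {
  flat <- readr::read_tsv(path,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE, show_col_types = FALSE)
  stopifnot(all(c("protein_a", "protein_b") %in% names(flat)))
  if (is.null(flat$sources)) flat$sources <- "unknown"
  recs <- flat |>
    dplyr::mutate(
      source_db = strsplit(.data$sources, ";", fixed = TRUE),
      citations = split_multi(flat$citations %||% rep("", nrow(flat)), ";"),
      evidence_codes = split_multi(flat$evidence_codes %||% rep("", nrow(flat)), ";")
    ) |>
    tidyr::unnest_longer("source_db") |>
    dplyr::select("protein_a", "protein_b", "source_db",
                  "citations", "evidence_codes")
  merge_sources(recs)
}
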