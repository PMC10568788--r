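#' Pool labeled positive proteins and locate them in the interactome
#'
#' The prediction algorithms are seeded by *positives*: proteins already
#' known to act in the process of interest (for the Fog pathway, a
#' contractility screen pooled with the apical-constriction and gastrulation
#' GO terms). Several labeled lists are unioned, each protein keeps the set
#' of lists it came from, and the pool is partitioned into the proteins
#' present in the graph and those missing from it. Re-running a prediction
#' round with an updated list (e.g. adding validated screen hits) is just a
#' new call with the extra list appended.
#'
#' @param lists A named list of character vectors of protein IDs (names are
#'   the origin labels), or a data frame with columns `label` and `id`.
#' @param interactome An `interactome` from [merge_sources()].
#' @return A `positive_set` tibble with columns `id`, `origins` (list of
#'   labels) and `in_graph` (logical).
#' @export
#' @examples
#' g <- merge_sources(tibble::tibble(
#'   protein_a = "p", protein_b = "q", source_db = "A",
#'   citations = list(character(0)), evidence_codes = list(character(0))
#' ))
#' assemble_positives(list(screen = c("p", "r"), go = "q"), g)
assemble_positives <- function(lists, interactome) {
  stopifnot(inherits(interactome, "interactome"))
  if (is.data.frame(lists)) {
    stopifnot(all(c("label", "id") %in% names(lists)))
    lists <- split(as.character(lists$id), lists$label)
  }
  if (!is.list(lists) || length(lists) == 0) {
    stop("at least one labeled positive list is required", call. = FALSE)
  }
  stopifnot(rlang::is_named(lists))
  long <- purrr::imap(lists, function(ids, label) {
    tibble::tibble(id = unique(as.character(ids)), label = label)
  }) |>
    dplyr::bind_rows()
  if (nrow(long) == 0) stop("no positive proteins supplied", call. = FALSE)
  nodes <- interactome_nodes(interactome)
  out <- long |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(origins = list(sort(unique(.data$label))), .groups = "drop") |>
    dplyr::mutate(in_graph = .data$id %in% nodes) |>
    dplyr::arrange(.data$id)
  class(out) <- c("positive_set", class(out))
  out
}

positive_ids <- function(positives) {
  if (inherits(positives, "positive_set")) return(positives$id)
  as.character(positives)
}

#' In-graph members of a positive set
#' @param positives A `positive_set`.
#' @return Character vector of positives present in the interactome.
#' @export
positives_in_graph <- function(positives) {
  stopifnot(inherits(positives, "positive_set"))
  positives$id[positives$in_graph]
}

#' Positives absent from the interactome
#' @param positives A `positive_set`.
#' @return Character vector of pooled IDs with no node in the graph.
#' @export
positives_missing <- function(positives) {
  stopifnot(inherits(positives, "positive_set"))
  positives$id[!positives$in_graph]
}

#' Read a plain-text positive list (one ID per line)
#'
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Character vector of IDs.
#' @export
read_id_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
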