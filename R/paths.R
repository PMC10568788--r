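#' Shortest paths from every positive to a target protein
#'
#' The Steiner method ignores the pathway's end point, so this method aims
#' the predictions at it: for each in-graph positive, compute a shortest
#' path to the target (for Fog signaling, Sqh — the myosin regulatory light
#' chain), and collect the unlabeled interior nodes of those paths as
#' candidates. Unreachable positives are reported, not fatal.
#'
#' In `"single"` mode one deterministic path is kept per positive: among all
#' equal-length paths, the lexicographically smallest node sequence. In
#' `"all"` mode every shortest path is unioned, which can only enlarge the
#' candidate set.
#'
#' @param x An `interactome` or undirected `igraph`.
#' @param positives A `positive_set` or character vector.
#' @param target Node name of the target protein; must be in the graph.
#' @param mode `"single"` (default) or `"all"`.
#' @return A `method_result`; `support` is a tibble with one row per kept
#'   path (`positive`, `length`, `path` list-column), and `unreachable`
#'   lists positives with no path to the target.
#' @export
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' paths_to_target_candidates(g, "a", target = "c")$candidates  # "b"
paths_to_target_candidates <- function(x, positives, target,
                                       mode = c("single", "all")) {
  mode <- match.arg(mode)
  g <- as_graph(x)
  nodes <- igraph::V(g)$name
  if (!is.character(target) || length(target) != 1 || !(target %in% nodes)) {
    stop("target node not present in the graph: ", target, call. = FALSE)
  }
  pos <- positive_ids(positives)
  pos_in <- sort(intersect(pos, nodes))
  if (length(pos_in) == 0) {
    stop("no positive protein is present in the graph", call. = FALSE)
  }
  dist_to_target <- igraph::distances(g, v = target)[1, ]
  reachable <- pos_in[is.finite(dist_to_target[pos_in])]
  unreachable <- setdiff(pos_in, reachable)
  paths <- purrr::map(reachable, function(p) {
    if (mode == "single") {
      list(lex_shortest_path(g, p, dist_to_target))
    } else {
      vp <- igraph::all_shortest_paths(g, from = p, to = target)$vpaths
      lapply(vp, function(v) v$name)
    }
  })
  support <- tibble::tibble(
    positive = rep(reachable, lengths(paths)),
    path = purrr::flatten(paths)
  ) |>
    dplyr::mutate(length = lengths(.data$path) - 1L) |>
    dplyr::select("positive", "length", "path")
  interior <- unique(unlist(lapply(support$path, function(p) {
    if (length(p) > 2) p[-c(1, length(p))] else character(0)
  })))
  new_method_result(
    method = "paths_to_target",
    candidates = setdiff(interior, c(pos, target)),
    support = support,
    parameters = list(target = target, mode = mode),
    extras = list(unreachable = unreachable)
  )
}
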