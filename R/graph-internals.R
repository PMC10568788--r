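# Internal graph helpers shared by the prediction algorithms.

as_graph <- function(x) {
  if (inherits(x, "interactome")) return(x$graph)
  if (igraph::is_igraph(x)) {
    stopifnot(!igraph::is_directed(x))
    if (is.null(igraph::V(x)$name)) {
      igraph::V(x)$name <- as.character(seq_len(igraph::vcount(x)))
    }
    return(x)
  }
  stop("expected an interactome or an undirected igraph", call. = FALSE)
}

# Lexicographically smallest shortest path from `from` to the node that
# `dist_to` was computed from. `dist_to[v]` must be the unweighted distance
# from v to the destination. Greedily stepping to the smallest-named
# neighbour one step closer yields the lexicographically smallest node
# sequence among all shortest paths. Returns a character vector of node
# names (from ... destination), or NULL when unreachable.
lex_shortest_path <- function(graph, from, dist_to) {
  d <- dist_to[[from]]
  if (!is.finite(d)) return(NULL)
  path <- character(d + 1L)
  cur <- from
  path[1L] <- cur
  if (d == 0) return(path)
  for (step in seq_len(d)) {
    nb <- igraph::neighbors(graph, cur)$name
    nxt <- nb[dist_to[nb] == d - step]
    cur <- min(nxt)
    path[step + 1L] <- cur
  }
  path
}

path_edges <- function(path) {
  if (length(path) < 2) {
    return(tibble::tibble(protein_a = character(0), protein_b = character(0)))
  }
  a <- path[-length(path)]
  b <- path[-1]
  pair <- canonical_pair(a, b)
  tibble::tibble(protein_a = pair$a, protein_b = pair$b)
}

dedupe_edges <- function(edges) {
  dplyr::distinct(dplyr::arrange(edges, .data$protein_a, .data$protein_b))
}

new_method_result <- function(method, candidates, support, parameters,
                              extras = list()) {
  structure(
    c(list(method = method,
           candidates = sort(unique(candidates)),
           support = support,
           parameters = parameters),
      extras),
    class = "method_result"
  )
}

#' @export
print.method_result <- function(x, ...) {
  cat("<method_result: ", x$method, "> ", length(x$candidates),
      " candidate(s)\n", sep = "")
  if (length(x$candidates)) {
    cat("  ", paste(utils::head(x$candidates, 10), collapse = ", "),
        if (length(x$candidates) > 10) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a prediction-method result
#'
#' @param x A `method_result` from [steiner_candidates()],
#'   [paths_to_target_candidates()] or [ranked_candidates()].
#' @param ... Unused.
#' @return A tibble with one row per candidate protein.
#' @export
tidy.method_result <- function(x, ...) {
  tibble::tibble(id = x$candidates, method = x$method)
}

#' @export
glance.method_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_candidates = length(x$candidates))
}
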