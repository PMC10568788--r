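#' Steiner tree approximation over the positive proteins
#'
#' Connects the in-graph positives ("terminals") with as few interactions as
#' possible; the unlabeled proteins recruited to make those connections are
#' the method's candidates. Uses the classic metric-closure construction
#' (Kou-Markowsky-Berman): build the complete graph on terminals weighted by
#' pairwise shortest-path distance, take its minimum spanning tree, expand
#' each tree edge into an actual shortest path, take a spanning tree of the
#' resulting subgraph, and prune non-terminal leaves. On a unit-weight graph
#' the returned tree costs at most twice the optimal Steiner tree
#' (see [exact_steiner()] for a certified optimum on small instances).
#'
#' When terminals fall in several connected components, a tree is built per
#' component holding at least two terminals and the trees are unioned;
#' singleton terminals are reported as dropped. If no two terminals are
#' mutually reachable the call errors, naming the components.
#'
#' @param x An `interactome` or an undirected `igraph`.
#' @param positives A `positive_set` or character vector of positive IDs.
#' @return A `method_result` with `candidates` (tree nodes that are not
#'   positives), `support` (the tree's edge tibble), `cost` (edge count) and
#'   `dropped_terminals`.
#' @export
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' steiner_candidates(g, c("a", "c"))$candidates  # "b"
steiner_candidates <- function(x, positives) {
  g <- as_graph(x)
  pos <- positive_ids(positives)
  terminals <- sort(intersect(pos, igraph::V(g)$name))
  if (length(terminals) == 0) {
    stop("no positive protein is present in the graph", call. = FALSE)
  }
  comp <- igraph::components(g)$membership
  groups <- split(terminals, comp[terminals])
  usable <- groups[lengths(groups) >= 2]
  dropped <- unlist(groups[lengths(groups) < 2], use.names = FALSE)
  if (length(usable) == 0) {
    stop("no two positives are mutually reachable; components: ",
         paste(vapply(groups, paste, character(1), collapse = ","),
               collapse = " | "), call. = FALSE)
  }
  trees <- lapply(usable, function(terms) kmb_tree(g, terms))
  edges <- dedupe_edges(dplyr::bind_rows(trees))
  tree_nodes <- unique(c(edges$protein_a, edges$protein_b))
  new_method_result(
    method = "steiner",
    candidates = setdiff(tree_nodes, pos),
    support = edges,
    parameters = list(n_terminals = length(terminals)),
    extras = list(
      cost = nrow(edges),
      dropped_terminals = sort(dropped %||% character(0)),
      n_components_used = length(usable)
    )
  )
}

# Kou-Markowsky-Berman 2-approximation on one component (unit weights).
kmb_tree <- function(g, terminals) {
  terminals <- sort(terminals)
  if (length(terminals) == 2) {
    d <- igraph::distances(g, v = terminals[2])[1, ]
    return(path_edges(lex_shortest_path(g, terminals[1], d)))
  }
  dmat <- igraph::distances(g, v = terminals, to = terminals)
  # MST of the metric closure; Kruskal with deterministic (weight, a, b) order
  k <- length(terminals)
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  closure <- tibble::tibble(
    a = terminals[pairs[, 1]], b = terminals[pairs[, 2]],
    w = dmat[pairs]
  ) |>
    dplyr::arrange(.data$w, .data$a, .data$b)
  parent <- stats::setNames(terminals, terminals)
  find <- function(v) {
    while (parent[[v]] != v) v <- parent[[v]]
    v
  }
  mst_edges <- vector("list", k - 1L)
  n_taken <- 0L
  for (i in seq_len(nrow(closure))) {
    ra <- find(closure$a[i]); rb <- find(closure$b[i])
    if (ra != rb) {
      parent[[ra]] <- rb
      n_taken <- n_taken + 1L
      mst_edges[[n_taken]] <- c(closure$a[i], closure$b[i])
      if (n_taken == k - 1L) break
    }
  }
  # expand each closure edge into a lexicographic shortest path in g
  expanded <- dplyr::bind_rows(lapply(mst_edges[seq_len(n_taken)], function(e) {
    d <- igraph::distances(g, v = e[2])[1, ]
    path_edges(lex_shortest_path(g, e[1], d))
  }))
  sub <- igraph::graph_from_data_frame(dedupe_edges(expanded), directed = FALSE)
  span <- igraph::mst(sub)
  prune_tree(span, terminals)
}

# Iteratively remove non-terminal leaves; return the edge tibble.
prune_tree <- function(tree, terminals) {
  repeat {
    deg <- igraph::degree(tree)
    drop <- names(deg)[deg <= 1 & !(names(deg) %in% terminals)]
    if (length(drop) == 0) break
    tree <- igraph::delete_vertices(tree, drop)
  }
  el <- igraph::as_edgelist(tree)
  pair <- canonical_pair(el[, 1], el[, 2])
  dedupe_edges(tibble::tibble(protein_a = pair$a, protein_b = pair$b))
}

#' Exact minimum Steiner tree (Dreyfus-Wagner dynamic program)
#'
#' Certified optimum for small instances, used as the oracle behind the
#' 2-approximation guarantee of [steiner_candidates()]. The dynamic program
#' is exponential in the number of terminals, so the call refuses graphs
#' with more than `max_nodes` nodes or more than `max_terminals` terminals.
#' Unit edge weights throughout. All terminals must be mutually reachable.
#'
#' @param x An `interactome` or an undirected `igraph`.
#' @param terminals Character vector of terminal node names.
#' @param max_nodes,max_terminals Refusal bounds for the exponential program.
#' @return A list with `cost` (the optimal edge count) and `edges` (an edge
#'   tibble of one optimal tree).
#' @export
exact_steiner <- function(x, terminals, max_nodes = 20, max_terminals = 6) {
  g <- as_graph(x)
  nodes <- igraph::V(g)$name
  terminals <- sort(unique(as.character(terminals)))
  if (!all(terminals %in% nodes)) {
    stop("terminal(s) absent from graph: ",
         paste(setdiff(terminals, nodes), collapse = ", "), call. = FALSE)
  }
  if (length(nodes) > max_nodes || length(terminals) > max_terminals) {
    stop("instance too large for the exact dynamic program (",
         length(nodes), " nodes, ", length(terminals), " terminals; bounds ",
         max_nodes, "/", max_terminals, ")", call. = FALSE)
  }
  if (length(terminals) <= 1) {
    return(list(cost = 0,
                edges = tibble::tibble(protein_a = character(0),
                                       protein_b = character(0))))
  }
  D <- igraph::distances(g)[nodes, nodes, drop = FALSE]
  if (!all(is.finite(D[terminals, terminals]))) {
    stop("terminals are not mutually reachable", call. = FALSE)
  }
  n <- length(nodes)
  root <- terminals[1]
  q <- terminals[-1]
  m <- length(q)
  n_sets <- bitwShiftL(1L, m) - 1L
  f <- matrix(Inf, nrow = n_sets, ncol = n, dimnames = list(NULL, nodes))
  # choice bookkeeping for tree reconstruction:
  # via[s, v]  : the node u the (s, v) solution routes through
  # sub[s, v]  : the subset split at u (0 for singleton sets)
  via <- matrix(NA_character_, nrow = n_sets, ncol = n, dimnames = list(NULL, nodes))
  sub <- matrix(0L, nrow = n_sets, ncol = n, dimnames = list(NULL, nodes))

  set_bits <- function(s) which(bitwAnd(s, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
  for (i in seq_len(m)) {
    s <- bitwShiftL(1L, i - 1L)
    f[s, ] <- D[, q[i]]
    via[s, ] <- q[i]
  }
  sizes <- vapply(seq_len(n_sets), function(s) length(set_bits(s)), integer(1))
  for (s in order(sizes)) {
    if (sizes[s] < 2) next
    # merge step at every node u (deterministic: subsets ascending, strict <)
    merged <- rep(Inf, n)
    merged_sub <- rep(0L, n)
    t <- bitwAnd(s - 1L, s)
    while (t > 0L) {
      comp <- bitwAnd(s, bitwNot(t))
      if (t < comp) {  # each unordered split once
        cand <- f[t, ] + f[comp, ]
        better <- cand < merged
        merged[better] <- cand[better]
        merged_sub[better] <- t
      }
      t <- bitwAnd(t - 1L, s)
    }
    # propagate through the shortest-path metric
    for (vi in seq_len(n)) {
      cand <- merged + D[, vi]
      ui <- which.min(cand)
      f[s, vi] <- cand[ui]
      via[s, vi] <- nodes[ui]
      sub[s, vi] <- merged_sub[ui]
    }
  }
  full <- n_sets
  cost <- f[full, root]
  edges <- dedupe_edges(dw_backtrack(g, D, f, via, sub, full, root))
  stopifnot(nrow(edges) == cost)
  list(cost = as.numeric(cost), edges = edges)
}

dw_backtrack <- function(g, D, f, via, sub, s, v) {
  u <- via[s, v]
  dist_to_u <- D[, u]
  walk <- path_edges(lex_shortest_path(g, v, dist_to_u))
  split_sub <- sub[s, v]
  if (split_sub == 0L) {
    # singleton set: the solution is just the path v -> terminal
    return(walk)
  }
  comp <- bitwAnd(s, bitwNot(split_sub))
  dplyr::bind_rows(
    walk,
    dw_backtrack(g, D, f, via, sub, split_sub, u),
    dw_backtrack(g, D, f, via, sub, comp, u)
  )
}
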