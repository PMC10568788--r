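# Brute-force oracles, independent of the package internals (and of igraph):
# plain adjacency lists + hand-rolled BFS / enumeration. Used to check the
# graph algorithms against first principles on small instances.

# adjacency list (named list of character vectors) from an edge matrix
oracle_adjacency <- function(edges) {
  nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  lapply(adj, sort)
}

# single-source BFS distances; unreachable = Inf
oracle_bfs <- function(adj, from) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[from] <- 0
  frontier <- from
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# every shortest path from `from` to `to`, as a list of node vectors
oracle_all_shortest_paths <- function(adj, from, to) {
  dist <- oracle_bfs(adj, to)
  if (!is.finite(dist[from])) return(list())
  extend <- function(path) {
    cur <- path[length(path)]
    if (cur == to) return(list(path))
    nxt <- adj[[cur]][dist[adj[[cur]]] == dist[cur] - 1]
    unlist(lapply(nxt, function(v) extend(c(path, v))), recursive = FALSE)
  }
  extend(from)
}

# inverse-distance score by summing BFS runs from every positive
oracle_ranked_scores <- function(adj, positives, nodes = names(adj)) {
  unlabeled <- setdiff(nodes, positives)
  score <- stats::setNames(rep(0, length(unlabeled)), unlabeled)
  for (p in intersect(positives, names(adj))) {
    dist <- oracle_bfs(adj, p)
    for (v in unlabeled) {
      d <- if (v %in% names(dist)) dist[[v]] else Inf
      if (is.finite(d) && d > 0) score[v] <- score[v] + 1 / d
    }
  }
  score
}

# exact Steiner cost by exhaustive enumeration of Steiner-node subsets:
# minimum over S of |terminals U S| - 1 such that the induced subgraph on
# terminals U S is connected
oracle_steiner_cost <- function(adj, terminals) {
  nodes <- names(adj)
  others <- setdiff(nodes, terminals)
  induced_connected <- function(keep) {
    sub <- lapply(adj[keep], intersect, keep)
    seen <- oracle_bfs(sub, keep[1])
    all(is.finite(seen[keep]))
  }
  for (k in 0:length(others)) {
    subsets <- if (k == 0) list(character(0)) else
      utils::combn(others, k, simplify = FALSE)
    for (s in subsets) {
      keep <- c(terminals, s)
      if (induced_connected(keep)) return(length(keep) - 1)
    }
  }
  Inf
}

# seeded random connected graph as an igraph with named nodes; a random
# chain is added so connectivity never depends on the draw
random_connected_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
    chain <- sample(igraph::V(g)$name)
    g <- igraph::add_edges(g, as.vector(rbind(chain[-n], chain[-1])))
    igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  })
}

graph_edge_matrix <- function(g) {
  el <- igraph::as_edgelist(g)
  matrix(as.character(el), ncol = 2)
}

# small evidence-carrying record tibble for interactome tests
make_records <- function(a, b, source, citations = NULL) {
  n <- length(a)
  tibble::tibble(
    protein_a = a, protein_b = b, source_db = source,
    citations = if (is.null(citations)) rep(list(character(0)), n) else citations,
    evidence_codes = rep(list(character(0)), n)
  )
}

write_tsv_fixture <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  readr::write_tsv(df, path, progress = FALSE)
  path
}
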