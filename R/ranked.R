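#' Inverse-distance score of every unlabeled node against the positives
#'
#' Some regulators are not near the pathway's end point but sit close to
#' many known positives at once. For each unlabeled node the unweighted
#' shortest-path distance \eqn{d_i} to every in-graph positive is computed,
#' and the raw score is the sum of reciprocal distances
#' \eqn{\sum_i 1/d_i}, with \eqn{1/\infty = 0} for unreachable positives
#' (so positives isolated from a node simply contribute nothing).
#'
#' Scores are then normalized. The default divides by the maximum raw score,
#' putting scores on \eqn{[0, 1]} so a fixed selection threshold is
#' meaningful; `"sum"` normalization (divide by the total) is available as
#' an alternative convention.
#'
#' @param x An `interactome` or undirected `igraph`.
#' @param positives A `positive_set` or character vector.
#' @param normalization `"max"` (default) or `"sum"`.
#' @return A `ranked_scores` tibble with columns `id`, `raw`, `normalized`,
#'   sorted by decreasing score.
#' @seealso [ranked_candidates()] for thresholded selection.
#' @export
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C)
#' ranked_paths_scores(g, "A")  # raw: B = 1, C = 0.5
ranked_paths_scores <- function(x, positives, normalization = c("max", "sum")) {
  normalization <- match.arg(normalization)
  g <- as_graph(x)
  nodes <- igraph::V(g)$name
  pos <- positive_ids(positives)
  pos_in <- sort(intersect(pos, nodes))
  if (length(pos_in) == 0) {
    stop("no positive protein is present in the graph", call. = FALSE)
  }
  unlabeled <- setdiff(nodes, pos)
  if (length(unlabeled) == 0) {
    out <- tibble::tibble(id = character(0), raw = numeric(0),
                          normalized = numeric(0))
    attr(out, "normalization") <- normalization
    attr(out, "n_positives_used") <- length(pos_in)
    class(out) <- c("ranked_scores", class(out))
    return(out)
  }
  D <- igraph::distances(g, v = pos_in, to = unlabeled)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0  # unreachable (and the impossible d = 0) drop out
  raw <- colSums(inv)
  denom <- switch(normalization, max = max(raw), sum = sum(raw))
  normalized <- if (denom > 0) raw / denom else raw * 0
  out <- tibble::tibble(id = unlabeled, raw = unname(raw),
                        normalized = unname(normalized)) |>
    dplyr::arrange(dplyr::desc(.data$normalized), .data$id)
  attr(out, "normalization") <- normalization
  attr(out, "n_positives_used") <- length(pos_in)
  class(out) <- c("ranked_scores", class(out))
  out
}

#' Select ranked-score candidates above a threshold
#'
#' Keeps the unlabeled nodes whose normalized score is strictly greater
#' than the threshold (default 0.7, the framework's published operating
#' point under max-normalization).
#'
#' @param scores A `ranked_scores` tibble from [ranked_paths_scores()].
#' @param threshold Scalar in \eqn{(0, 1]}; strict comparison.
#' @return A `method_result` whose `support` is the full score table.
#' @export
ranked_candidates <- function(scores, threshold = 0.7) {
  stopifnot(inherits(scores, "ranked_scores"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be a single number in (0, 1]", call. = FALSE)
  }
  new_method_result(
    method = "ranked_paths",
    candidates = scores$id[scores$normalized > threshold],
    support = scores,
    parameters = list(threshold = threshold,
                      normalization = attr(scores, "normalization"))
  )
}

#' Plot the normalized ranked-path score distribution
#'
#' @param object A `ranked_scores` tibble.
#' @param threshold Optional selection threshold drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ranked_scores <- function(object, threshold = 0.7, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$normalized)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "normalized inverse-distance score", y = "nodes",
                  title = "Ranked-paths score distribution") +
    ggplot2::theme_minimal()
}
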