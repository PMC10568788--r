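#' Combine candidate sets from several prediction methods
#'
#' Builds the per-protein membership table behind the methods' Venn diagram:
#' which methods proposed each candidate and in how many methods it appears.
#' Rows start unfiltered (`retained = TRUE`); see [filter_candidates()].
#'
#' @param results A list of 1-3 `method_result` objects from the same graph
#'   and positive set. Method labels must be distinct.
#' @return A `candidate_table` tibble with columns `id`, `methods`
#'   (list-column), `n_methods`, `excluded_reason`, `retained`, carrying a
#'   `venn_counts` attribute (see [venn_counts()]).
#' @export
#' @examples
#' a <- fognet:::new_method_result("steiner", c("x", "y"),
#'                                 NULL, list())
#' b <- fognet:::new_method_result("paths_to_target", c("y", "z"),
#'                                 NULL, list())
#' combine_methods(list(a, b))
combine_methods <- function(results) {
  if (inherits(results, "method_result")) results <- list(results)
  stopifnot(is.list(results), length(results) >= 1)
  ok <- vapply(results, inherits, logical(1), "method_result")
  if (!all(ok)) stop("all elements must be method_result objects", call. = FALSE)
  labels <- vapply(results, function(r) r$method, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate method labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  long <- purrr::map2(results, labels, function(r, lab) {
    tibble::tibble(id = r$candidates, method = lab)
  }) |>
    dplyr::bind_rows()
  tab <- long |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(methods = list(sort(unique(.data$method))), .groups = "drop") |>
    dplyr::mutate(
      n_methods = lengths(.data$methods),
      excluded_reason = NA_character_,
      retained = TRUE
    ) |>
    dplyr::arrange(.data$id)
  combo <- vapply(tab$methods, paste, character(1), collapse = "+")
  venn <- tibble::tibble(combination = combo) |>
    dplyr::count(.data$combination, name = "n") |>
    dplyr::arrange(.data$combination)
  attr(tab, "venn_counts") <- venn
  attr(tab, "method_labels") <- sort(labels)
  class(tab) <- c("candidate_table", class(tab))
  tab
}

#' Venn counts of a candidate table
#'
#' @param table A `candidate_table`.
#' @return A tibble with one row per observed method combination (labels
#'   joined by `"+"`) and the number of candidates found by exactly that
#'   combination. Counts sum to the number of distinct candidates.
#' @export
venn_counts <- function(table) {
  stopifnot(inherits(table, "candidate_table"))
  attr(table, "venn_counts")
}

#' Annotate and filter combined candidates
#'
#' Applies the screening filters in priority order: candidates already known
#' to belong to the studied pathway, then known interactors of the target
#' (for the published screen, known Sqh interactors), then candidates not
#' expressed in the assay cell line (only when an expression list is
#' supplied). The first matching rule is recorded as `excluded_reason`;
#' `retained` flags unexcluded rows.
#'
#' @param table A `candidate_table` from [combine_methods()].
#' @param known_pathway Character vector of IDs already in the pathway.
#' @param known_interactors Character vector of known target interactors.
#' @param expressed Optional character vector of IDs expressed in the assay
#'   cells; when `NULL` no expression filter is applied.
#' @return The annotated `candidate_table`.
#' @export
filter_candidates <- function(table, known_pathway = character(0),
                              known_interactors = character(0),
                              expressed = NULL) {
  stopifnot(inherits(table, "candidate_table"))
  reason <- rep(NA_character_, nrow(table))
  reason[table$id %in% known_interactors] <- "known_sqh_interactor"
  reason[table$id %in% known_pathway] <- "known_pathway"
  if (!is.null(expressed)) {
    not_expr <- is.na(reason) & !(table$id %in% expressed)
    reason[not_expr] <- "not_expressed"
  }
  out <- table
  out$excluded_reason <- reason
  out$retained <- is.na(reason)
  out
}

#' @export
print.candidate_table <- function(x, ...) {
  cat("<candidate_table> ", nrow(x), " candidate(s) from methods: ",
      paste(attr(x, "method_labels"), collapse = ", "), "\n", sep = "")
  NextMethod()
}

#' Tidy a candidate table into plain columns
#'
#' @param x A `candidate_table`.
#' @param ... Unused.
#' @return A tibble with `methods` collapsed to a `"+"`-joined string.
#' @export
tidy.candidate_table <- function(x, ...) {
  tibble::tibble(
    id = x$id,
    methods = vapply(x$methods, paste, character(1), collapse = "+"),
    n_methods = x$n_methods,
    excluded_reason = x$excluded_reason,
    retained = x$retained
  )
}

#' @export
glance.candidate_table <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x),
    n_retained = sum(x$retained),
    n_in_all_methods = sum(x$n_methods == length(attr(x, "method_labels"))),
    n_in_two_or_more = sum(x$n_methods >= 2)
  )
}

#' Plot candidate counts per method combination
#'
#' A bar-chart rendering of the Venn counts, with exclusion status stacked.
#'
#' @param object A `candidate_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.candidate_table <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(status = ifelse(.data$retained, "retained",
                                  .data$excluded_reason))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$methods, fill = .data$status)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "method combination", y = "candidates",
                  title = "Candidates per method combination") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Write a candidate table as TSV
#'
#' @param table A `candidate_table`.
#' @param path Output path.
#' @param scores Optional `ranked_scores` tibble; when given, the normalized
#'   score is joined onto the table.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(table, path, scores = NULL) {
  out <- tidy(table)
  if (!is.null(scores)) {
    out <- dplyr::left_join(
      out, dplyr::select(tibble::as_tibble(scores), "id", score = "normalized"),
      by = "id"
    )
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
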