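#' Generate a seeded synthetic interactome with planted positives
#'
#' Builds an Erdos-Renyi background graph and plants a known answer for the
#' prediction algorithms to recover. With `planting = "module"`, a target
#' node, `n_positives` positive proteins and `n_planted` "true candidate"
#' nodes are chosen, and each planted node is wired to `wiring_positives`
#' distinct positives and to the target. Planted nodes therefore sit on
#' short positive-to-target paths, close to many positives, and on cheap
#' trees connecting positives — so all three methods should recover them.
#'
#' Generation is a pure function of the arguments: the same seed always
#' yields the same graph. If the background density leaves some positive
#' isolated (degree zero), the graph is regenerated up to `max_retries`
#' times before erroring.
#'
#' @param n_nodes Number of proteins. Default 50.
#' @param edge_density Background edge probability. Default 0.08.
#' @param n_positives Number of planted positive proteins. Default 8.
#' @param planting `"module"` (default) or `"none"` (pure background graph).
#' @param n_planted Number of planted true-candidate nodes. Default 4.
#' @param wiring_positives Positives wired to each planted node. Default 3.
#' @param seed Integer seed; all randomness flows from it.
#' @param max_retries Regeneration attempts when a positive ends up isolated.
#' @return A list with `interactome`, `positives` (a `positive_set`),
#'   `planted_truth` (character vector, empty for `planting = "none"`),
#'   `target` (node name) and the generating `spec`.
#' @export
generate_interactome <- function(n_nodes = 50, edge_density = 0.08,
                                 n_positives = 8,
                                 planting = c("module", "none"),
                                 n_planted = 4, wiring_positives = 3,
                                 seed = 1L, max_retries = 20L) {
  planting <- match.arg(planting)
  stopifnot(n_nodes >= 2, edge_density > 0, edge_density <= 1,
            n_positives >= 1, n_positives < n_nodes, n_planted >= 0)
  if (planting == "module" && n_planted > 0) {
    stopifnot(wiring_positives >= 2, wiring_positives <= n_positives)
    if (n_positives + n_planted + 1 > n_nodes) {
      stop("n_nodes too small for the requested module", call. = FALSE)
    }
  }
  nodes <- sprintf("P%03d", seq_len(n_nodes))
  withr::with_seed(as.integer(seed), {
    for (attempt in seq_len(max_retries)) {
      g <- igraph::sample_gnp(n_nodes, edge_density)
      igraph::V(g)$name <- nodes
      roles <- sample(nodes, 1 + n_positives + n_planted)
      target <- roles[1]
      positives <- sort(roles[1 + seq_len(n_positives)])
      planted <- sort(roles[1 + n_positives + seq_len(n_planted)])
      if (planting == "module" && n_planted > 0) {
        extra <- unlist(lapply(planted, function(p) {
          anchors <- c(sample(positives, wiring_positives), target)
          rbind(p, anchors)
        }))
        g <- igraph::add_edges(g, extra)
        g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
      }
      deg <- igraph::degree(g)
      if (all(deg[positives] > 0) && deg[target] > 0) {
        el <- igraph::as_edgelist(g)
        pair <- canonical_pair(el[, 1], el[, 2])
        recs <- tibble::tibble(
          protein_a = pair$a, protein_b = pair$b, source_db = "synthetic",
          citations = rep(list(character(0)), nrow(el)),
          evidence_codes = rep(list(character(0)), nrow(el))
        )
        interactome <- merge_sources(recs)
        pos_set <- assemble_positives(list(planted_positives = positives),
                                      interactome)
        return(list(
          interactome = interactome,
          positives = pos_set,
          planted_truth = if (planting == "module") planted else character(0),
          target = target,
          spec = list(n_nodes = n_nodes, edge_density = edge_density,
                      n_positives = n_positives, planting = planting,
                      n_planted = n_planted,
                      wiring_positives = wiring_positives, seed = seed,
                      attempts = attempt)
        ))
      }
    }
    stop("density too low: a positive stayed isolated after ", max_retries,
         " attempts", call. = FALSE)
  })
}

disc_mask <- function(nr, nc, cy, cx, ry, rx) {
  row_i <- matrix(seq_len(nr), nr, nc)
  col_i <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((row_i - cy) / ry)^2 + ((col_i - cx) / rx)^2 <= 1
}

#' Generate a synthetic fluorescent cell image with its mask
#'
#' Emulates the phenotype classes scored in contractility experiments: a
#' coalesced peri-nuclear `"ring"` of signal, scattered `"punctate"` foci,
#' or a `"diffuse"` signal spread evenly over the cell. The cell is an
#' ellipse filling most of the frame; outside it the image is zero. Gaussian
#' noise (truncated at zero) is added with standard deviation `noise_sd`,
#' and with `noise_sd = 0` a diffuse cell is perfectly flat — by design the
#' degenerate input for [coalescence_index()].
#'
#' @param shape Integer vector `(rows, cols)`, each at least 8. Default
#'   `c(64, 64)`.
#' @param mode `"punctate"`, `"diffuse"` or `"ring"`.
#' @param foreground_level,background_level Intensities with
#'   `foreground_level > background_level >= 0`.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param n_puncta Number of foci in punctate mode.
#' @param seed Integer seed.
#' @return A list with `image` (numeric matrix), `mask` (logical matrix)
#'   and the generating `spec`.
#' @export
generate_cell_image <- function(shape = c(64, 64),
                                mode = c("punctate", "diffuse", "ring"),
                                foreground_level = 1,
                                background_level = 0.1,
                                noise_sd = 0.05, n_puncta = 12, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(shape) == 2, noise_sd >= 0,
            foreground_level > background_level, background_level >= 0)
  if (any(shape < 8)) stop("shape must be at least 8x8", call. = FALSE)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  ry <- 0.42 * nr; rx <- 0.42 * nc
  mask <- disc_mask(nr, nc, cy, cx, ry, rx)
  withr::with_seed(as.integer(seed), {
    img <- matrix(0, nr, nc)
    if (mode == "diffuse") {
      # foreground budget spread evenly over the whole cell
      img[mask] <- background_level +
        0.35 * (foreground_level - background_level)
    } else if (mode == "ring") {
      outer_r <- 0.8; inner_r <- 0.55
      ring <- disc_mask(nr, nc, cy, cx, outer_r * ry, outer_r * rx) &
        !disc_mask(nr, nc, cy, cx, inner_r * ry, inner_r * rx)
      img[mask] <- background_level
      img[ring & mask] <- foreground_level
    } else {
      img[mask] <- background_level
      idx <- which(mask, arr.ind = TRUE)
      centers <- idx[sample(nrow(idx), n_puncta, replace = nrow(idx) < n_puncta), ,
                     drop = FALSE]
      r_punct <- max(1.5, 0.03 * min(nr, nc))
      for (i in seq_len(nrow(centers))) {
        spot <- disc_mask(nr, nc, centers[i, 1], centers[i, 2], r_punct, r_punct)
        img[spot & mask] <- foreground_level
      }
    }
    if (noise_sd > 0) {
      img[mask] <- pmax(0, img[mask] + stats::rnorm(sum(mask), 0, noise_sd))
    }
    list(image = img, mask = mask,
         spec = list(shape = c(nr, nc), mode = mode,
                     foreground_level = foreground_level,
                     background_level = background_level,
                     noise_sd = noise_sd, n_puncta = n_puncta, seed = seed))
  })
}
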