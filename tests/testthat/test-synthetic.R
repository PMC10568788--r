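test_that("graph generation is a pure function of the seed", {
  a <- generate_interactome(seed = 3)
  b <- generate_interactome(seed = 3)
  expect_identical(a$interactome$edges, b$interactome$edges)
  expect_identical(a$positives$id, b$positives$id)
  expect_identical(a$planted_truth, b$planted_truth)
  expect_identical(a$target, b$target)
  c <- generate_interactome(seed = 4)
  expect_false(identical(a$interactome$edges, c$interactome$edges))
})

test_that("generated interactomes are simple, undirected, with wired planted modules", {
  for (s in c(1, 7, 13)) {
    sim <- generate_interactome(seed = s)
    g <- sim$interactome$graph
    expect_true(igraph::is_simple(g))
    expect_false(igraph::is_directed(g))
    edges <- sim$interactome$edges
    expect_true(all(edges$protein_a != edges$protein_b))
    # every planted node touches >= 2 positives and the target
    pos <- positives_in_graph(sim$positives)
    for (p in sim$planted_truth) {
      nb <- igraph::neighbors(g, p)$name
      expect_gte(length(intersect(nb, pos)), 2)
      expect_true(sim$target %in% nb)
    }
    expect_length(intersect(sim$planted_truth, sim$positives$id), 0)
    # positives are never isolated (the generator's retry guarantee)
    expect_true(all(igraph::degree(g)[pos] > 0))
  }
})

test_that("minimal and degenerate graph specs behave", {
  tiny <- generate_interactome(n_nodes = 2, edge_density = 1, n_positives = 1,
                               planting = "none", n_planted = 0,
                               wiring_positives = 2, seed = 1)
  expect_equal(nrow(tiny$interactome$edges), 1)
  expect_error(generate_interactome(n_positives = 50, seed = 1), "n_positives")
  expect_error(
    generate_interactome(n_nodes = 30, edge_density = 1e-4, n_positives = 5,
                         planting = "none", n_planted = 0,
                         wiring_positives = 2, seed = 1, max_retries = 3),
    "isolated")
})

test_that("image generation is seeded and validates its spec", {
  a <- generate_cell_image(mode = "ring", seed = 5)
  b <- generate_cell_image(mode = "ring", seed = 5)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_false(identical(a$image, generate_cell_image(mode = "ring",
                                                      seed = 6)$image))
  expect_true(all(a$image >= 0))            # noise truncated at zero
  expect_true(all(a$image[!a$mask] == 0))   # background outside the cell
  expect_error(generate_cell_image(shape = c(6, 64), seed = 1), "8x8")
  expect_error(generate_cell_image(foreground_level = 0.1,
                                   background_level = 0.5, seed = 1),
               "foreground_level")
})

test_that("a noiseless diffuse cell is the degenerate coalescence input", {
  sim <- generate_cell_image(mode = "diffuse", noise_sd = 0, seed = 2)
  expect_error(coalescence_index(sim$image, sim$mask), "spread")
})

test_that("binary coalescence separates ring from diffuse in the locked direction", {
  # direction measured once on generated pairs at equal total intensity and
  # locked: noisy diffuse signal binarizes near p = 0.5 (where the closed
  # form peaks), so the ring mode scores LOWER under binary preprocessing
  for (s in 1:3) {
    ring <- generate_cell_image(mode = "ring", seed = s)
    diff <- generate_cell_image(mode = "diffuse", seed = s)
    scaled <- diff$image
    scaled[diff$mask] <- scaled[diff$mask] *
      sum(ring$image[ring$mask]) / sum(scaled[diff$mask])
    ci_ring <- coalescence_index(ring$image, ring$mask, "binary")$ci
    ci_diff <- coalescence_index(scaled, diff$mask, "binary")$ci
    expect_lt(ci_ring, ci_diff)
  }
})

test_that("the planted module is recoverable by the three methods", {
  sim <- generate_interactome(seed = 5)
  st <- steiner_candidates(sim$interactome, sim$positives)
  pt <- paths_to_target_candidates(sim$interactome, sim$positives, sim$target)
  rk <- ranked_candidates(ranked_paths_scores(sim$interactome, sim$positives))
  inter <- Reduce(intersect, list(st$candidates, pt$candidates, rk$candidates))
  expect_gt(length(intersect(inter, sim$planted_truth)), 0)
})
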