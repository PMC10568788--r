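# Shared fixture: a two-source synthetic run configuration on disk.
make_pipeline_fixture <- function(dir, threshold = 0.7) {
  sim <- generate_interactome(seed = 17)
  edges <- sim$interactome$edges
  # split the edges into two "databases" with foreign IDs for one of them
  half <- seq_len(nrow(edges)) %% 2 == 0
  src1 <- data.frame(idA = edges$protein_a[!half], idB = edges$protein_b[!half],
                     pmid = "PMID:1")
  src2 <- data.frame(p1 = paste0("x_", edges$protein_a[half]),
                     p2 = paste0("x_", edges$protein_b[half]))
  nodes <- interactome_nodes(sim$interactome)
  mapping <- data.frame(foreign_id = paste0("x_", nodes), fbgn_id = nodes)
  paths <- list(
    src1 = file.path(dir, "src1.tsv"), src2 = file.path(dir, "src2.tsv"),
    mapping = file.path(dir, "mapping.tsv"),
    positives = file.path(dir, "positives.txt"),
    expressed = file.path(dir, "expressed.txt"),
    config = file.path(dir, "run.yaml")
  )
  readr::write_tsv(src1, paths$src1, progress = FALSE)
  readr::write_tsv(src2, paths$src2, progress = FALSE)
  readr::write_tsv(mapping, paths$mapping, progress = FALSE)
  writeLines(sim$positives$id, paths$positives)
  writeLines(nodes, paths$expressed)
  cfg <- list(
    sources = list(
      list(name = "dbOne", path = paths$src1, id_a = "idA", id_b = "idB",
           citations = "pmid"),
      list(name = "dbTwo", path = paths$src2, id_a = "p1", id_b = "p2")
    ),
    mapping = paths$mapping,
    positives = list(screen = paths$positives),
    target = sim$target,
    threshold = threshold,
    expressed = paths$expressed
  )
  yaml::write_yaml(cfg, paths$config)
  list(sim = sim, paths = paths, cfg = cfg)
}
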