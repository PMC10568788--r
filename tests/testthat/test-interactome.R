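test_that("edge tables load row-for-row, keeping self-loops and skipping bad rows", {
  path <- write_tsv_fixture(data.frame(
    idA = c("FBgn1", "FBgn2", "FBgn1", "FBgn3"),
    idB = c("FBgn2", "FBgn3", "FBgn1", ""),
    pmid = c("1;2", "", "3", "4")
  ))
  recs <- load_edge_table(path, "dbA",
                          edge_columns("idA", "idB", citations = "pmid"))
  expect_equal(nrow(recs), 3)                       # empty idB row skipped
  expect_equal(recs$protein_a, c("FBgn1", "FBgn2", "FBgn1"))
  expect_equal(recs$citations[[1]], c("1", "2"))
  expect_equal(recs$citations[[2]], character(0))
  expect_true(any(recs$protein_a == recs$protein_b))  # self-loop kept at load
  rep <- load_report(recs)
  expect_equal(rep$n_skipped, 1)
  expect_equal(rep$skipped_rows, 4L)

  # plain two-column table -> empty citation sets
  path2 <- write_tsv_fixture(data.frame(idA = c("a", "b", "c"),
                                        idB = c("b", "c", "a")))
  recs2 <- load_edge_table(path2, "dbB", edge_columns("idA", "idB"))
  expect_equal(nrow(recs2), 3)
  expect_true(all(lengths(recs2$citations) == 0))

  expect_error(load_edge_table(path, "dbA", edge_columns("idA", "nope")),
               "not present")
  expect_error(load_edge_table("/no/such/file.tsv", "dbA",
                               edge_columns("idA", "idB")),
               "not found")
})

test_that("identifier mapping substitutes, honours the unmapped policy, and reports", {
  recs <- make_records(c("X1", "X9"), c("X2", "X2"), "dbA")
  mapping <- c(X1 = "FBgnA", X2 = "FBgnB")
  mapped <- suppressWarnings(map_identifiers(recs, mapping))
  expect_equal(mapped$protein_a, c("FBgnA", "X9"))
  expect_equal(mapped$protein_b, c("FBgnB", "FBgnB"))
  expect_equal(attr(mapped, "unmapped_report")$unmapped_ids, "X9")
  expect_warning(map_identifiers(recs, mapping), "no mapping")

  dropped <- map_identifiers(recs, mapping, unmapped = "drop")
  expect_equal(nrow(dropped), 1)
  expect_equal(attr(dropped, "unmapped_report")$policy, "drop")

  # many-to-one mapping collapses records into one merged edge
  recs2 <- make_records(c("X1", "X3"), c("Y", "Y"), "dbA")
  mapped2 <- suppressWarnings(
    map_identifiers(recs2, c(X1 = "FBgnA", X3 = "FBgnA"))
  )
  net <- merge_sources(mapped2)
  expect_equal(nrow(net$edges), 1)

  expect_error(map_identifiers(recs, c(X1 = "A", X1 = "B")), "not a function")
})

test_that("merging deduplicates unordered pairs, drops self-loops, unions evidence", {
  a <- make_records("p", "q", "A", list("PMID:1"))
  b <- make_records("q", "p", "B", list("PMID:2"))
  net <- merge_sources(list(a, b))
  expect_equal(nrow(net$edges), 1)
  expect_equal(sort(net$evidence$source_db), c("A", "B"))

  withloop <- make_records(c("p", "p"), c("p", "q"), "A")
  net2 <- merge_sources(withloop)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$provenance$n_self_loops_dropped, 1)

  # hand-enumerated union: A:{(p,q),(q,r)}, B:{(q,r),(r,s)}
  net3 <- merge_sources(list(make_records(c("p", "q"), c("q", "r"), "A"),
                             make_records(c("q", "r"), c("r", "s"), "B")))
  expect_equal(nrow(net3$edges), 3)
  expect_equal(length(interactome_nodes(net3)), 4)
  qr <- net3$evidence[net3$evidence$protein_a == "q" &
                        net3$evidence$protein_b == "r", ]
  expect_equal(sort(qr$source_db), c("A", "B"))

  # duplicate rows within one source collapse with unioned citations
  dup <- make_records(c("p", "q"), c("q", "p"), "A",
                      list("PMID:1", "PMID:2"))
  net4 <- merge_sources(dup)
  expect_equal(nrow(net4$evidence), 1)
  expect_equal(net4$evidence$citations[[1]], c("PMID:1", "PMID:2"))

  empty <- merge_sources(make_records(character(0), character(0), character(0)))
  expect_equal(nrow(empty$edges), 0)

  iso <- merge_sources(make_records("p", "q", "A"), extra_nodes = "lonely")
  expect_true("lonely" %in% interactome_nodes(iso))
})

test_that("summary counts nodes, edges, and per-source exclusive support", {
  net <- merge_sources(list(make_records(c("p", "q"), c("q", "r"), "A"),
                            make_records(c("q", "r"), c("r", "s"), "B")))
  s <- interactome_summary(net)
  expect_equal(s$n_nodes, 4)
  expect_equal(s$n_edges, 3)
  per <- s$per_source
  expect_equal(per$n_exclusive_of_source[per$source_db == "A"], 1)  # {r,s}
  expect_equal(per$n_exclusive_of_source[per$source_db == "B"], 1)  # {p,q}
  expect_true(all(per$n_edges <= s$n_edges))

  single <- interactome_summary(merge_sources(make_records("p", "q", "A")))
  expect_equal(single$per_source$n_exclusive_of_source, 0)

  cited <- merge_sources(make_records(c("p", "q"), c("q", "r"), "A",
                                      list(c("1", "2"), c("2", "3"))))
  expect_equal(interactome_summary(cited)$n_citations, 3)
  expect_equal(glance(cited)$n_citations, 3)
})

test_that("merging is idempotent and invariant to row and source order", {
  a <- make_records(c("p", "q", "r"), c("q", "r", "s"), "A",
                    list("1", "2", "3"))
  b <- make_records(c("s", "q"), c("q", "p"), "B")
  net <- merge_sources(list(a, b))
  # re-split the merged evidence by source and merge again
  resplit <- split(net$evidence, net$evidence$source_db)
  net2 <- merge_sources(unname(resplit))
  expect_equal(net2$edges, net$edges)
  expect_equal(net2$evidence, net$evidence)
  # permuted input order
  net3 <- merge_sources(list(b[sample(nrow(b)), ], a[rev(seq_len(nrow(a))), ]))
  expect_equal(net3$edges, net$edges)
  expect_equal(net3$evidence, net$evidence)
  # structural invariants
  expect_true(all(net$edges$protein_a != net$edges$protein_b))
  expect_true(all(net$edges$protein_a < net$edges$protein_b))
  expect_equal(nrow(dplyr::distinct(net$edges)), nrow(net$edges))
})

test_that("interactome TSV round-trips through write and read", {
  net <- merge_sources(list(
    make_records(c("p", "q"), c("q", "r"), "A", list("1", "2")),
    make_records("q", "r", "B")
  ))
  path <- tempfile(fileext = ".tsv")
  withr::defer(unlink(path))
  write_interactome(net, path)
  back <- read_interactome(path)
  expect_equal(back$edges, net$edges)
  expect_equal(sort(unique(back$evidence$source_db)),
               sort(unique(net$evidence$source_db)))
  gml <- tempfile(fileext = ".graphml")
  withr::defer(unlink(gml))
  write_interactome(net, gml, format = "graphml")
  expect_true(file.size(gml) > 0)
})
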