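# Display graph construction and decremental connectivity.

test_that("display graph pools and deduplicates parent-child label pairs", {
  p <- toy_taxonomy_profile()
  g <- build_display_graph(p)
  expect_length(g$taxa, 18L) # a-l plus the six numeric labels
  expect_identical(sort(g$taxa),
                   sort(c(letters[1:12], as.character(1:6))))

  # a single tree gives the tree itself
  one <- slt_profile(list(parse_newick("((a,b)f,c)g;")))
  g1 <- build_display_graph(one)
  expect_identical(nrow(g1$edges), 4L)

  # two identical trees: same graph as one copy
  two <- slt_profile(list(parse_newick("((a,b)f,c)g;"),
                          parse_newick("((a,b)f,c)g;")))
  g2 <- build_display_graph(two)
  expect_identical(nrow(g2$edges), nrow(g1$edges))
})

test_that("worked example: deleting the exposed set yields the four blocks", {
  p <- toy_taxonomy_profile()
  marked <- unlist(position_children(p, initial_position(p)),
                   use.names = FALSE)
  for (backend in c("forest", "bfs")) {
    g <- build_display_graph(p, backend = backend)
    res <- delete_exposed(g, c("1", "4", "6"), marked = marked)
    expect_identical(res$components,
                     list(c("2", "b", "c"),
                          c("5", "f", "g", "i", "j", "k"),
                          c("d"), c("l")))
  }
})

test_that("component handles behave per the definition", {
  p <- toy_taxonomy_profile()
  g <- build_display_graph(p)
  expect_identical(component_of(g, "d"), component_of(g, "2"))
  delete_exposed(g, "1")
  expect_false(component_of(g, "d") == component_of(g, "2"))
  expect_error(component_of(g, "1"), "deleted")
  expect_error(delete_exposed(g, "1"), "already deleted")
})

test_that("simple deletions: leaves and path splitting", {
  p <- slt_profile(list(parse_newick("(b)a;"), parse_newick("(c)b;")))
  g <- build_display_graph(p) # path a - b - c
  res <- delete_exposed(g, "b")
  expect_identical(res$components, list("a", "c"))

  g2 <- build_display_graph(slt_profile(list(parse_newick("(b,c)a;"))))
  delete_exposed(g2, "c") # degree-1 vertex: no split of the rest
  expect_identical(graph_components(g2), list(c("a", "b")))
})

test_that("both backends track components exactly (fresh-BFS oracle)", {
  set.seed(101)
  for (rep in 1:8) {
    prof <- fully_label(slt_profile(lapply(1:3, function(i)
      random_labeled_tree(sample(letters[1:10],
                                 sample(4:10, 1))))))$profile
    vocab <- profile_taxa(prof)
    gf <- build_display_graph(prof, backend = "forest")
    gb <- build_display_graph(prof, backend = "bfs")
    edges <- gf$edges
    alive <- vocab
    del_order <- sample(vocab, min(50L, length(vocab) - 1L))
    for (v in del_order) {
      delete_exposed(gf, v)
      delete_exposed(gb, v)
      alive <- setdiff(alive, v)
      edges <- edges[edges[, 1] != v & edges[, 2] != v, , drop = FALSE]
      oracle <- bfs_partition(alive, edges)
      expect_same_partition(graph_components(gf), oracle)
      expect_same_partition(graph_components(gb), oracle)
    }
  }
})

test_that("igraph agrees with the component partition after deletions", {
  skip_if_not_installed("igraph")
  set.seed(102)
  prof <- fully_label(slt_profile(lapply(1:4, function(i)
    random_labeled_tree(sample(letters[1:12], sample(6:12, 1))))))$profile
  vocab <- profile_taxa(prof)
  g <- build_display_graph(prof)
  edges <- g$edges
  for (v in sample(vocab, length(vocab) - 2L)) {
    delete_exposed(g, v)
    edges <- edges[edges[, 1] != v & edges[, 2] != v, , drop = FALSE]
    vocab <- setdiff(vocab, v)
    ig <- igraph::graph_from_data_frame(
      as.data.frame(edges), directed = FALSE,
      vertices = data.frame(name = vocab))
    mem <- igraph::components(ig)$membership
    oracle <- split(names(mem), mem)
    oracle <- lapply(oracle, sort, method = "radix")
    names(oracle) <- NULL
    oracle <- oracle[order(vapply(oracle, `[`, character(1), 1L),
                           method = "radix")]
    expect_same_partition(graph_components(g), oracle)
  }
})

test_that("smaller-side scanning: move counters stay within the log bound", {
  set.seed(103)
  prof <- fully_label(slt_profile(lapply(1:5, function(i)
    random_labeled_tree(sample(letters[1:14], sample(8:14, 1))))))$profile
  vocab <- profile_taxa(prof)
  g <- build_display_graph(prof)
  nk <- length(vocab) * length(prof)
  for (v in sample(vocab, length(vocab) - 1L)) delete_exposed(g, v)
  expect_true(all(component_move_counts(g) <= ceiling(log2(nk))))
})

test_that("split logs report the moved (smaller) side and marked taxa", {
  p <- slt_profile(list(parse_newick("((a,b)c,(d)e)f;")))
  g <- build_display_graph(p)
  res <- delete_exposed(g, "f", marked = c("c", "e"))
  expect_true(length(res$splits) >= 1L)
  moved_all <- unlist(lapply(res$splits, `[[`, "moved"))
  expect_true(all(moved_all %in% c("a", "b", "c", "d", "e", "f")))
  # marked-set partition: c and e end up in different components
  expect_identical(res$components, list("c", "e"))
  expect_identical(graph_components(g), list(c("a", "b", "c"), c("d", "e")))
})

test_that("display graph dumps are written", {
  g <- build_display_graph(toy_taxonomy_profile())
  tsv <- tempfile(fileext = ".tsv")
  dot <- tempfile(fileext = ".dot")
  write_display_graph(g, tsv, "tsv")
  write_display_graph(g, dot, "dot")
  expect_identical(length(readLines(tsv)), nrow(g$edges))
  expect_true(any(grepl("--", readLines(dot), fixed = TRUE)))
})
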