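# Semi-labeled tree data model, Newick I/O, clusters, restriction.

test_that("parse_newick reads internal labels and preserves structure", {
  tr <- parse_newick("((a,b)f,c)g;")
  expect_s3_class(tr, "slt")
  expect_length(tr$parent, 5L)
  expect_identical(taxa(tr), c("a", "b", "c", "f", "g"))
  lm <- label_map(tr)
  expect_gt(length(tr$children[[lm[["f"]]]]), 0L) # f labels an internal node

  tr2 <- parse_newick("(a,b,c);")
  expect_false(is_fully_labeled(tr2))
  expect_true(is_singularly_labeled(tr2))
  expect_identical(taxa(tr2), c("a", "b", "c"))
})

test_that("parse_newick rejects malformed and invalid input", {
  expect_error(parse_newick("((a,b),(a,c));"), "duplicate label")
  expect_error(parse_newick("((a,b)"), "parse error at character")
  expect_error(parse_newick("(a,)x;"), "parse error")
  # unlabeled unary node violates the X-tree definition
  expect_error(parse_newick("((a));"), "X-tree violation")
  # but a labeled unary root is fine
  expect_silent(tr <- parse_newick("(a)g;"))
  expect_setequal(vapply(clusters(tr), paste, character(1), collapse = ""),
                  c("a", "ag"))
})

test_that("branch lengths are parsed, discarded, and warned about", {
  expect_warning(tr <- parse_newick("((a:0.1,b:0.2)f:1e-3,c)g;"),
                 "branch lengths")
  expect_identical(taxa(tr), c("a", "b", "c", "f", "g"))
})

test_that("quoted labels round-trip", {
  tr <- parse_newick("('sp one','it''s')r;")
  expect_true(all(c("sp one", "it's") %in% taxa(tr)))
  rt <- parse_newick(to_newick(tr))
  expect_true(same_clusters(tr, rt))
})

test_that("to_newick joins multi-taxon nodes sorted by the delimiter", {
  tr <- slt(c(0L, 1L, 1L), list(c("g", "4"), "a", "b"))
  expect_identical(to_newick(tr), "(a,b)4+g;")
  expect_identical(to_newick(tr, multi_label_delimiter = "|"), "(a,b)4|g;")
  one <- slt(0L, list("x"))
  expect_identical(to_newick(one), "x;")
  # parse side can split multi labels back
  back <- parse_newick("(a,b)4+g;", multi_label_delimiter = "+")
  expect_true(same_clusters(back, tr))
})

test_that("newick round trip preserves the cluster set", {
  txts <- c("((a,b)f,c)g;", "(((x,y),z),(w,v)u)r;", "(a,(b)q,c)p;")
  for (tx in txts) {
    tr <- parse_newick(tx)
    expect_true(same_clusters(tr, parse_newick(to_newick(tr))), info = tx)
    expect_true(same_clusters(tr,
                              parse_newick(to_newick(tr, canonical = TRUE))),
                info = tx)
  }
})

test_that("clusters match the definition", {
  tr <- parse_newick("((a,b)f,c)g;")
  got <- sort(vapply(clusters(tr), paste, character(1), collapse = ""))
  expect_identical(got, sort(c("a", "b", "c", "abf", "abcfg")))
  expect_identical(clusters(slt(0L, list("x")))[[1]], "x")
})

test_that("restriction follows the cluster-intersection definition", {
  tr <- parse_newick("((a,b)f,c)g;")
  r <- restrict_tree(tr, c("a", "b", "c"))
  got <- sort(vapply(clusters(r), paste, character(1), collapse = ""))
  expect_identical(got, sort(c("a", "b", "c", "ab", "abc")))
  expect_identical(taxa(r), c("a", "b", "c"))
  # identity restriction
  expect_true(same_clusters(restrict_tree(tr, taxa(tr)), tr))
  expect_error(restrict_tree(tr, character(0)), "empty")
})

test_that("restriction composes: (T|Y)|Z has the clusters of T|(Y int Z)", {
  set.seed(41)
  for (rep in 1:25) {
    tr <- random_labeled_tree(letters[1:8])
    y <- sample(letters[1:8], sample(3:8, 1))
    z <- sample(y, sample(seq_along(y), 1))
    a <- restrict_tree(restrict_tree(tr, y), z)
    b <- restrict_tree(tr, z)
    expect_true(same_clusters(a, b))
    # result never has an unlabeled unary node (slt() would have refused)
    expect_s3_class(a, "slt")
  }
})

test_that("restriction implements general cluster intersection too", {
  set.seed(42)
  for (rep in 1:20) {
    tr <- random_labeled_tree(letters[1:7])
    y <- sample(letters[1:7], sample(2:7, 1))
    r <- restrict_tree(tr, y)
    want <- unique(Filter(length,
                          lapply(clusters(tr), intersect, y = y)))
    want <- sort(vapply(lapply(want, sort_radix <- function(x)
      sort(x, method = "radix")), paste, character(1), collapse = ","))
    got <- sort(vapply(clusters(r), paste, character(1), collapse = ","))
    expect_identical(got, want)
  }
})

test_that("fully_label adds fresh labels exactly at unlabeled nodes", {
  raw <- toy_taxonomy_profile(labeled = FALSE)
  fl <- fully_label(raw)
  expect_length(fl$added, 6L) # six unlabeled nodes across the four trees
  expect_true(is_normalized(fl$profile))
  # placement matches the labeled fixture: same cluster sets up to renaming
  lab <- toy_taxonomy_profile(labeled = TRUE)
  for (i in seq_along(lab)) {
    a <- restrict_tree(fl$profile[[i]],
                       setdiff(taxa(fl$profile[[i]]), fl$added))
    b <- restrict_tree(lab[[i]], setdiff(taxa(lab[[i]]),
                                         as.character(1:6)))
    expect_true(same_clusters(a, b), info = i)
  }
  # already fully labeled profile passes through unchanged
  fl2 <- fully_label(toy_taxonomy_profile(labeled = TRUE))
  expect_length(fl2$added, 0L)
  # "(a,b);" gets exactly one fresh root label
  fl3 <- fully_label(slt_profile(list(parse_newick("(a,b);"))))
  expect_length(fl3$added, 1L)
  expect_true(is_fully_labeled(fl3$profile[[1]]))
})

test_that("fully_label refuses a clashing reserved prefix", {
  p <- slt_profile(list(parse_newick("(__anon1,b);")))
  expect_error(fully_label(p), "reserved prefix")
  expect_silent(fully_label(p, prefix = "__fresh"))
})

test_that("fully_label preserves original clusters within the old taxa", {
  set.seed(43)
  for (rep in 1:10) {
    tr <- random_labeled_tree(letters[1:6])
    y <- sample(letters[1:6], sample(3:6, 1))
    raw <- restrict_tree(tr, y) # may contain unlabeled nodes
    fl <- fully_label(slt_profile(list(raw)))
    stripped <- restrict_tree(fl$profile[[1]],
                              setdiff(taxa(fl$profile[[1]]), fl$added))
    expect_true(same_clusters(stripped, raw))
  }
})

test_that("agrees_with is the restriction-isomorphism predicate", {
  tr <- parse_newick("((a,b)f,c)g;")
  expect_true(agrees_with(tr, tr))
  sup <- parse_newick("((a,b),c)r;")
  inp <- parse_newick("((a,c),b)r;")
  expect_false(agrees_with(sup, inp))
  expect_error(agrees_with(inp, parse_newick("(a,z)r2;")), "missing")
  # a tree agrees with any of its restrictions
  set.seed(44)
  for (rep in 1:10) {
    t0 <- random_labeled_tree(letters[1:7])
    y <- sample(letters[1:7], sample(2:7, 1))
    expect_true(agrees_with(t0, restrict_tree(t0, y)))
  }
})

test_that("cluster equality implies identical canonical newick", {
  set.seed(45)
  for (rep in 1:15) {
    tr <- random_labeled_tree(letters[1:6])
    # shuffle children by rebuilding from a scrambled parent layout
    perm <- sample(length(tr$parent))
    inv <- order(perm)
    p_old <- tr$parent[perm]
    tr2 <- slt(ifelse(p_old == 0L, 0L, inv[pmax(p_old, 1L)]),
               tr$labels[perm])
    expect_true(same_clusters(tr, tr2))
    expect_identical(to_newick(tr, canonical = TRUE),
                     to_newick(tr2, canonical = TRUE))
  }
})

test_that("parser agrees with ape on plain leaf-labeled trees", {
  skip_if_not_installed("ape")
  txt <- "((a,(b,c)),(d,e));"
  ours <- parse_newick(txt)
  ape_tr <- ape::read.tree(text = txt)
  # leaf sets below each internal edge must coincide
  ape_clades <- lapply(ape::prop.part(ape_tr), function(ix)
    sort(ape_tr$tip.label[ix], method = "radix"))
  ours_cl <- clusters(ours)
  ours_cl <- ours_cl[vapply(ours_cl, length, integer(1)) > 1L]
  for (cl in ape_clades)
    expect_true(any(vapply(ours_cl, identical, logical(1), y = cl)))
})
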