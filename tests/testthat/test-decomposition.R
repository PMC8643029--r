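# Positions, exposure, and the maximal good decomposition.

test_that("initial position is the tuple of root labels", {
  p <- toy_taxonomy_profile()
  expect_identical(initial_position(p), c("1", "4", "g", "6"))
  one <- fully_label(slt_profile(list(slt(0L, list("x")))))$profile
  expect_identical(initial_position(one), "x")
  two <- slt_profile(list(parse_newick("(a,b)r;"), parse_newick("(a,b)r;")))
  expect_identical(initial_position(two), c("r", "r"))
  expect_true(position_is_valid(p, initial_position(p)))
})

test_that("exposed labels follow the definition", {
  p <- toy_taxonomy_profile()
  pos <- initial_position(p)
  expect_identical(exposed_labels(p, pos), c("1", "4", "6"))
  expect_false("g" %in% exposed_labels(p, pos)) # g sits below the root of T2
  one <- slt_profile(list(parse_newick("((a,b)f,c)g;")))
  expect_identical(exposed_labels(one, initial_position(one)), "g")
})

test_that("worked example: decompose reproduces every printed value", {
  p <- toy_taxonomy_profile()
  eng <- ast_engine(p, validate = TRUE)
  d <- decompose_position(eng, initial_position(p))

  expect_identical(d$exposed, c("1", "4", "6"))
  expect_identical(d$blocks_initial,
                   list(c("2", "b", "c"),
                        c("5", "f", "g", "i", "j", "k"),
                        "d", "l"))
  # both 4 and 6 are bad; the deterministic scan meets 4 first, and the
  # final state is the same whichever is eliminated first
  expect_setequal(d$bad_labels, c("4", "6"))
  expect_identical(d$merged_blocks[[2]],
                   c("2", "5", "b", "c", "f", "g", "i", "j", "k", "l"))
  expect_identical(d$S, "1")
  expect_identical(d$while_iters, 2L)
  expect_identical(d$successors,
                   list(c("2", "4", "g", "6"),
                        c("d", NA, NA, NA)))
  # merged block contents as sets: after one elimination the merge holds
  # {f,k,5,g,i,j} plus the children of the eliminated label's blocks
  expect_true(all(c("5", "f", "g", "i", "j", "k") %in%
                    d$merged_blocks[[1]]))
})

test_that("random bad-label order gives the identical decomposition", {
  p <- toy_taxonomy_profile()
  base <- decompose_position(ast_engine(p), initial_position(p))
  for (s in 1:5) {
    eng <- ast_engine(p, bad_order = "random", seed = s)
    d <- decompose_position(eng, initial_position(p))
    expect_identical(d$S, base$S)
    expect_identical(d$blocks_final, base$blocks_final)
    expect_identical(d$successors, base$successors)
  }
})

test_that("order independence holds over many random positions", {
  set.seed(107)
  done <- 0L
  while (done < 100L) {
    prof <- fully_label(slt_profile(lapply(1:3, function(i)
      random_labeled_tree(sample(letters[1:8], sample(3:8, 1))))))$profile
    pos <- initial_position(prof)
    base <- decompose_position(ast_engine(prof), pos)
    for (s in 1:5) {
      d <- decompose_position(ast_engine(prof, bad_order = "random",
                                         seed = s), pos)
      expect_identical(d$S, base$S)
      expect_identical(d$blocks_final, base$blocks_final)
    }
    done <- done + 1L
    # also exercise one successor position when available
    if (length(base$successors) && length(base$S)) {
      eng <- ast_engine(prof)
      decompose_position(eng, pos)
      d2 <- decompose_position(eng, base$successors[[1]])
      expect_true(is.list(d2))
      done <- done + 1L
    }
  }
})

test_that("decomposition invariants: partition audit and disjoint cover", {
  set.seed(108)
  for (rep in 1:30) {
    prof <- fully_label(slt_profile(lapply(
      1:sample(2:4, 1),
      function(i) random_labeled_tree(sample(letters[1:9],
                                             sample(3:9, 1))))))$profile
    pos <- initial_position(prof)
    # validate = TRUE makes the engine assert LCA validity of positions,
    # the N1/N2 audit and the disjoint cover internally on every call
    eng <- ast_engine(prof, validate = TRUE)
    d <- decompose_position(eng, pos)
    expect_lte(d$while_iters, length(prof))

    # nice-partition audit (N1/N2), recomputed independently of the engine
    kids <- position_children(prof, pos)
    blocks <- c(d$blocks_final)
    if (length(d$S)) {
      for (i in names(kids)) {
        a <- pos[as.integer(i)]
        for (bl in blocks) {
          inter <- intersect(kids[[i]], bl)
          if (a %in% d$S) {
            expect_lte(length(inter), 1L)
          } else if (length(inter)) {
            expect_setequal(intersect(kids[[i]], unlist(blocks)),
                            intersect(kids[[i]], bl))
          }
        }
      }
      # disjoint cover: X_P(pi) = S + union of successor label sets
      xp <- agreetree:::position_label_set(prof, pos)
      parts <- lapply(d$successors, function(sp)
        agreetree:::position_label_set(prof, sp))
      all_parts <- c(list(d$S), parts)
      expect_identical(sort(unlist(all_parts), method = "radix"), xp)
      expect_false(anyDuplicated(unlist(all_parts)) > 0L)
      # every successor position is valid
      for (sp in d$successors)
        expect_true(position_is_valid(prof, sp))
    }
  }
})

test_that("fan-vs-resolved conflict empties S at the initial position", {
  prof <- fully_label(slt_profile(list(parse_newick("(a,b,c);"),
                                       parse_newick("((a,b),c);"))))$profile
  eng <- ast_engine(prof, validate = TRUE)
  d <- decompose_position(eng, initial_position(prof))
  expect_identical(d$S, character(0))
  expect_length(d$bad_labels, 2L) # both fresh roots get eliminated
})

test_that("single-node tree decomposes to S with no successors", {
  prof <- slt_profile(list(slt(0L, list("x"))))
  d <- decompose_position(ast_engine(prof), initial_position(prof))
  expect_identical(d$S, "x")
  expect_length(d$successors, 0L)
})
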