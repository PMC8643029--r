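# Shared generators for randomized tests.  Everything is driven by an
# explicit seed so failures are reproducible.

# random fully labeled rooted tree on the given taxa (one taxon per node)
random_labeled_tree <- function(taxa) {
  n <- length(taxa)
  parent <- integer(n)
  if (n > 1L) {
    for (v in 2:n) parent[v] <- sample.int(v - 1L, 1L)
  }
  slt(parent, as.list(sample(taxa)))
}

# a profile of k random restrictions of one random seed tree (agrees by
# construction before perturbation); returns the normalized profile
random_coherent_profile <- function(taxa, k) {
  seedtree <- random_labeled_tree(taxa)
  trees <- lapply(seq_len(k), function(i) {
    y <- sample(taxa, sample(seq_along(taxa), 1L))
    restrict_tree(seedtree, y)
  })
  fully_label(slt_profile(trees))$profile
}

# restrictions drawn from two independent random seed trees on the same
# taxa; frequently (not always) conflicting
random_mixed_profile <- function(taxa, k) {
  s1 <- random_labeled_tree(taxa)
  s2 <- random_labeled_tree(taxa)
  trees <- lapply(seq_len(k), function(i) {
    y <- sample(taxa, sample(2:length(taxa), 1L))
    restrict_tree(if (i %% 2L == 0L) s1 else s2, y)
  })
  fully_label(slt_profile(trees))$profile
}

# random profile for the oracle-equivalence suite: coherent or mixed, with
# the post-normalization taxon count capped (a structural input guard)
random_small_profile <- function(max_taxa = 5L, max_k = 3L,
                                 p_mixed = 0.5) {
  repeat {
    nt <- sample(2:4, 1L)
    taxa <- letters[seq_len(nt)]
    k <- sample.int(max_k, 1L)
    prof <- if (stats::runif(1) < p_mixed && nt >= 3L)
      random_mixed_profile(taxa, max(2L, k))
    else random_coherent_profile(taxa, k)
    if (length(profile_taxa(prof)) <= max_taxa) return(prof)
  }
}

# component partition oracle: fresh BFS over an edge list
bfs_partition <- function(vertices, edges) {
  comp <- stats::setNames(seq_along(vertices), vertices)
  adj <- stats::setNames(vector("list", length(vertices)), vertices)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- stats::setNames(logical(length(vertices)), vertices)
  out <- list()
  for (v in vertices) {
    if (seen[[v]]) next
    queue <- v
    seen[[v]] <- TRUE
    compv <- character(0)
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      compv <- c(compv, x)
      for (y in adj[[x]]) if (!seen[[y]]) { seen[[y]] <- TRUE; queue <- c(queue, y) }
    }
    out[[length(out) + 1L]] <- sort(compv, method = "radix")
  }
  out[order(vapply(out, `[`, character(1), 1L), method = "radix")]
}

# canonical form of a component partition for comparison
partition_key <- function(parts) {
  paste(sort(vapply(parts, paste, character(1), collapse = ","),
             method = "radix"), collapse = ";")
}

expect_same_partition <- function(a, b) {
  expect_identical(partition_key(a), partition_key(b))
}
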