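# Synthetic profile generator -----------------------------------------------
#
# Emulates the benchmarking setup for profiles that are guaranteed to
# agree: a complete D-ary seed tree with m labeled nodes (levels filled
# left to right) is restricted to k random, partially overlapping label
# subsets.  Restriction can create unlabeled nodes (LCAs outside the
# subset); those receive fresh reserved-prefix labels, which does not
# affect agreement.  The seed tree, carrying the fresh labels at the nodes
# they came from and restricted to the union of the profile's taxa, is an
# agreement tree for the generated profile, giving a built-in soundness
# check.

#' Generator configuration
#'
#' @param D Children per internal seed-tree node (>= 2).
#' @param m Number of labeled nodes in the seed tree (>= 1).
#' @param k Number of trees in the profile (>= 1).
#' @param rng_seed Integer seed; identical configuration and seed give a
#'   byte-identical profile.
#' @param p_used Probability that each drawn label comes from the pool of
#'   labels already used by earlier draws (when that pool is nonempty);
#'   keeps the trees' taxon sets overlapping.
#' @param min_frac Lower bound on subset sizes as a fraction of `m`
#'   (subset size is uniform on `[max(2, ceiling(min_frac * m)), m]`).
#' @return A `generator_config` list.
#' @export
generator_config <- function(D, m, k, rng_seed = 1L, p_used = 0.5,
                             min_frac = 0.1) {
  stopifnot(D >= 2L, m >= 1L, k >= 1L, p_used >= 0, p_used <= 1,
            min_frac > 0, min_frac <= 1)
  structure(list(D = as.integer(D), m = as.integer(m), k = as.integer(k),
                 rng_seed = as.integer(rng_seed), p_used = p_used,
                 min_frac = min_frac),
            class = "generator_config")
}

#' Complete D-ary seed tree with m labeled nodes
#'
#' Nodes are added level by level, left to right (heap order), so every
#' level except possibly the last is completely filled; every node carries
#' a distinct label.
#'
#' @param D Children per internal node (>= 2).
#' @param m Number of nodes (>= 1).
#' @param label_prefix Prefix for the node labels (`t1`, `t2`, ...).
#' @return An `slt` that is fully and singularly labeled.
#' @export
make_seed_tree <- function(D, m, label_prefix = "t") {
  stopifnot(D >= 2L, m >= 1L)
  m <- as.integer(m); D <- as.integer(D)
  parent <- if (m == 1L) 0L else c(0L, ((2L:m - 2L) %/% D) + 1L)
  slt(parent, as.list(paste0(label_prefix, seq_len(m))))
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a profile guaranteed to agree
#'
#' @param config A [generator_config()].
#' @return A list with components `profile` (normalized `slt_profile`),
#'   `seed_tree` (the seed `slt`), `reference` (an agreement tree for the
#'   profile, namely the seed tree with the fresh labels attached and
#'   restricted to the profile's taxa), `subsets` (the drawn label
#'   subsets) and `added` (the fresh labels).
#' @export
generate_profile <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$rng_seed, {
    seed_tree <- make_seed_tree(config$D, config$m)
    all_labels <- paste0("t", seq_len(config$m))
    lo <- max(2L, as.integer(ceiling(config$min_frac * config$m)))
    lo <- min(lo, config$m)
    used <- logical(config$m)
    subsets <- vector("list", config$k)
    for (i in seq_len(config$k)) {
      size <- if (lo >= config$m) config$m else
        sample(lo:config$m, 1L)
      cur <- logical(config$m)
      for (d in seq_len(size)) {
        from_used <- used & !cur
        from_unused <- !used & !cur
        pool <- if (stats::runif(1L) < config$p_used && any(from_used))
          which(from_used)
        else if (any(from_unused)) which(from_unused)
        else which(from_used)
        pick <- if (length(pool) == 1L) pool else sample(pool, 1L)
        cur[pick] <- TRUE
        used[pick] <- TRUE
      }
      subsets[[i]] <- all_labels[cur]
    }
    raw <- lapply(subsets, function(y) restrict_tree(seed_tree, y))
    fl <- fully_label(slt_profile(raw))

    # reference agreement tree: attach each fresh label to the seed node
    # its unlabeled restriction node came from (seed nodes are stored in
    # preorder, so index by node, not by label number)
    ref_labels <- seed_tree$labels
    idx <- 0L
    for (i in seq_along(raw)) {
      src <- attr(raw[[i]], "source_node")
      empt <- which(lengths(raw[[i]]$labels) == 0L)
      for (v in empt) {
        idx <- idx + 1L
        s <- src[v]
        ref_labels[[s]] <- c(ref_labels[[s]], fl$added[idx])
      }
    }
    full_ref <- slt(seed_tree$parent, ref_labels)
    reference <- restrict_tree(full_ref, profile_taxa(fl$profile))

    list(profile = fl$profile, seed_tree = seed_tree,
         reference = reference, subsets = subsets, added = fl$added,
         config = config)
  })
}

#' Benchmark sweep over a configuration grid
#'
#' Runs the generator and the construction over a grid of `(D, m, k)`
#' cells, averaging wall time over `trials` replicates per cell.  Wall
#' times are hardware dependent and are reported, never asserted.
#'
#' @param grid Data frame with columns `D`, `m`, `k`.
#' @param trials Replicates per cell.
#' @param rng_seed Base seed; each replicate derives its own sub-seed.
#' @return Data frame with one row per cell: the configuration, the mean
#'   realized taxon count `n`, `M_P = n * k`, mean and standard deviation
#'   of wall time, and mean positions processed and bad labels eliminated.
#' @export
benchmark_sweep <- function(grid, trials = 3L, rng_seed = 1L) {
  stopifnot(is.data.frame(grid), all(c("D", "m", "k") %in% names(grid)))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    tvec <- numeric(trials); nvec <- numeric(trials)
    pvec <- numeric(trials); bvec <- numeric(trials)
    for (tt in seq_len(trials)) {
      sub_seed <- (rng_seed * 10000L + g * 100L + tt) %% .Machine$integer.max
      cfg <- generator_config(grid$D[g], grid$m[g], grid$k[g],
                              rng_seed = sub_seed)
      gen <- generate_profile(cfg)
      nvec[tt] <- length(profile_taxa(gen$profile))
      t0 <- proc.time()[["elapsed"]]
      res <- build_agreement_tree(gen$profile)
      tvec[tt] <- proc.time()[["elapsed"]] - t0
      if (res$status != "AGREES")
        stop("generator soundness violated: generated profile disagrees")
      pvec[tt] <- res$stats$positions_processed
      bvec[tt] <- res$stats$bad_eliminations
    }
    rows[[g]] <- data.frame(
      D = grid$D[g], m = grid$m[g], k = grid$k[g],
      n = mean(nvec), M_P = mean(nvec) * grid$k[g],
      time_mean = mean(tvec), time_sd = stats::sd(tvec),
      positions = mean(pvec), bad_eliminations = mean(bvec))
  }
  do.call(rbind, rows)
}
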