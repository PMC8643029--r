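# Engine plumbing -----------------------------------------------------------
#
# The construction engine (display graph, exposure bookkeeping, position
# decomposition) lives in compiled code.  An engine instance owns mutable
# state: graph deletions are destructive and performed at most once, so an
# instance supports either one full build or one top-down sequence of
# decompose calls.

engine_data <- function(profile) {
  profile <- slt_profile(profile)
  if (!is_normalized(profile))
    stop("engine requires a fully and singularly labeled profile; ",
         "run fully_label() first", call. = FALSE)
  vocab <- profile_taxa(profile)
  trees <- lapply(profile, function(tr) {
    tax <- vapply(tr$labels, `[`, character(1), 1L)
    list(parent = tr$parent, taxon = match(tax, vocab))
  })
  list(trees = trees, vocab = vocab)
}

#' Create a construction engine for a profile
#'
#' Exposes the stateful machinery behind [build_agreement_tree()]:
#' the display graph with decremental connectivity plus exposure
#' bookkeeping, and the position-decomposition step.  Use it to step
#' through a construction position by position; for the common case call
#' [build_agreement_tree()] directly.
#'
#' @param profile A normalized `slt_profile` (see [fully_label()]).
#' @param backend Connectivity backend: `"forest"` (spanning forest with
#'   replacement-edge search; default) or `"bfs"` (alternating
#'   bidirectional search over graph adjacency).  Results are identical;
#'   both are exercised by the test suite.
#' @param validate Run expensive internal invariant checks (position
#'   validity, disjoint cover, partition audit) on every call.
#' @param bad_order `"scan"` (deterministic: ascending tree index, then
#'   child order) or `"random"` (uniform among currently bad labels); the
#'   final decomposition is provably identical either way.
#' @param seed Seed for the `"random"` bad-label order.
#' @return An object of class `ast_engine`.
#' @export
ast_engine <- function(profile, backend = c("forest", "bfs"),
                       validate = FALSE, bad_order = c("scan", "random"),
                       seed = 1L) {
  backend <- match.arg(backend)
  bad_order <- match.arg(bad_order)
  ed <- engine_data(profile)
  ptr <- ae_create(ed$trees, length(ed$vocab), backend, validate, bad_order,
                   as.integer(seed))
  structure(list(ptr = ptr, vocab = ed$vocab, k = length(profile),
                 profile = profile),
            class = "ast_engine")
}

pos_to_idx <- function(engine, position) {
  if (length(position) != engine$k)
    stop("position must have one entry per tree", call. = FALSE)
  idx <- match(position, engine$vocab)
  if (any(!is.na(position) & is.na(idx)))
    stop("unknown taxa in position: ",
         paste(position[!is.na(position) & is.na(idx)], collapse = ", "),
         call. = FALSE)
  idx
}

idx_to_pos <- function(engine, idx) {
  out <- rep(NA_character_, length(idx))
  ok <- !is.na(idx)
  out[ok] <- engine$vocab[idx[ok]]
  out
}

#' Initial position of a profile
#'
#' The position whose per-tree entry is the root label of that tree.
#'
#' @param profile A normalized `slt_profile`.
#' @return Character vector of length `k` (the root labels).
#' @export
initial_position <- function(profile) {
  profile <- slt_profile(profile)
  if (!is_normalized(profile))
    stop("profile must be normalized", call. = FALSE)
  vapply(profile, function(tr) tr$labels[[tr$root]][1], character(1))
}

#' Compute the maximal good decomposition of a position
#'
#' Runs one decomposition step on the engine: newly exposed labels are
#' deleted from the display graph, the children of the position labels are
#' partitioned by connected component, bad labels (exposed labels with two
#' same-tree children in one block) are eliminated by virtually merging
#' blocks, and the successor positions are assembled.  An empty `S`
#' certifies that the position, hence the profile, has no agreement tree.
#'
#' @param engine An [ast_engine()].  State is consumed: calls must follow
#'   the top-down order of the construction.
#' @param position Character vector of length `k`; `NA` marks trees with no
#'   remaining taxa.
#' @return A list with components `exposed` (the exposed labels, i.e. `S`
#'   before elimination), `blocks_initial`, `bad_labels` (elimination
#'   order), `merged_blocks` (block content after each merge), `S` (the
#'   maximal nice exposed subset), `blocks_final`, `successors` (list of
#'   positions) and `while_iters`.
#' @export
decompose_position <- function(engine, position) {
  stopifnot(inherits(engine, "ast_engine"))
  res <- ae_decompose(engine$ptr, pos_to_idx(engine, position))
  list(
    exposed = idx_to_pos(engine, res$exposed),
    blocks_initial = lapply(res$blocks_initial, function(b)
      idx_to_pos(engine, b)),
    bad_labels = idx_to_pos(engine, res$bad_labels),
    merged_blocks = lapply(res$merged_blocks, function(b)
      idx_to_pos(engine, b)),
    S = idx_to_pos(engine, res$S),
    blocks_final = lapply(res$blocks_final, function(b)
      idx_to_pos(engine, b)),
    successors = lapply(res$successors, function(p) idx_to_pos(engine, p)),
    while_iters = res$while_iters
  )
}

#' Exposed labels of a position
#'
#' A label is exposed when it is the position's entry in every input tree
#' that contains it (within the current subproblem).  This is the direct
#' definition, independent of the engine's incremental unseen lists.
#'
#' @param profile A normalized `slt_profile`.
#' @param position Character vector of length `length(profile)`, `NA` for
#'   empty entries.
#' @return Character vector of the exposed labels, sorted.
#' @export
exposed_labels <- function(profile, position) {
  profile <- slt_profile(profile)
  xp <- position_label_set(profile, position)
  labs <- unique(stats::na.omit(position))
  ok <- vapply(labs, function(l) {
    for (i in seq_along(profile)) {
      if (l %in% taxa(profile[[i]]) && l %in% xp &&
          (is.na(position[i]) || position[i] != l))
        return(FALSE)
    }
    TRUE
  }, logical(1))
  sort_taxa(labs[ok])
}

# X_P(pi): all taxa in the subtrees rooted at the position labels
position_label_set <- function(profile, position) {
  out <- character(0)
  for (i in seq_along(profile)) {
    if (is.na(position[i])) next
    tr <- profile[[i]]
    lm <- label_map(tr)
    v <- lm[[position[i]]]
    cl <- node_clusters(tr)
    out <- c(out, cl[[v]])
  }
  sort_taxa(unique(out))
}

#' Is a position valid?
#'
#' A position is valid when, for every tree whose taxon set meets the
#' position's label set, the tree's entry is exactly the LCA of that
#' intersection (and empty otherwise).  Checked by direct LCA computation;
#' used for contract tests and the `validate` engine mode.
#'
#' @inheritParams exposed_labels
#' @return Logical scalar.
#' @export
position_is_valid <- function(profile, position) {
  profile <- slt_profile(profile)
  xp <- position_label_set(profile, position)
  for (i in seq_along(profile)) {
    tr <- profile[[i]]
    xi <- intersect(taxa(tr), xp)
    if (length(xi) == 0L) {
      if (!is.na(position[i])) return(FALSE)
    } else {
      l <- lca_taxa(tr, xi)
      if (is.na(position[i]) || length(l) == 0L || l[1] != position[i])
        return(FALSE)
    }
  }
  TRUE
}

#' Children of the labels of a position
#'
#' @inheritParams exposed_labels
#' @return Named list, one entry per tree with a non-empty position entry:
#'   the labels of that entry's children in the tree.
#' @export
position_children <- function(profile, position) {
  profile <- slt_profile(profile)
  out <- list()
  for (i in seq_along(profile)) {
    if (is.na(position[i])) next
    tr <- profile[[i]]
    lm <- label_map(tr)
    v <- lm[[position[i]]]
    kids <- tr$children[[v]]
    out[[as.character(i)]] <-
      vapply(kids, function(u) tr$labels[[u]][1], character(1))
  }
  out
}

#' Run-time statistics of an engine
#' @param engine An `ast_engine`.
#' @return List of counters (positions processed, decompose calls, bad
#'   label eliminations, edge/vertex deletions, the maximum number of times
#'   any vertex moved to a new component).
#' @export
engine_stats <- function(engine) ae_stats(engine$ptr)
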