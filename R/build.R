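# Agreement tree construction -----------------------------------------------

new_build_result <- function(status, tree = NULL, stats = NULL,
                             conflict_position = NULL, added = character(0)) {
  structure(list(status = status, tree = tree, stats = stats,
                 conflict_position = conflict_position,
                 added_labels = added),
            class = "build_result")
}

#' @export
print.build_result <- function(x, ...) {
  if (x$status == "AGREES") {
    cat("Profile agrees. Agreement tree:\n  ",
        to_newick(x$tree, canonical = TRUE), "\n", sep = "")
  } else {
    cat("Profile disagrees.\nConflict position (per-tree subtree roots):\n")
    cat("  ", paste(ifelse(is.na(x$conflict_position), ".",
                           x$conflict_position), collapse = " | "), "\n",
        sep = "")
  }
  if (!is.null(x$stats))
    cat(sprintf("Positions processed: %d, bad labels eliminated: %d\n",
                as.integer(x$stats$positions_processed),
                as.integer(x$stats$bad_eliminations)))
  invisible(x)
}

#' Build an agreement tree for a profile, or certify disagreement
#'
#' Top-down breadth-first construction.  Starting from the initial
#' position (the tuple of root labels), each position is decomposed into
#' its maximal nice exposed subset `S` and successor positions; `S` becomes
#' the label set of a new node whose children are the trees built for the
#' successors.  If some position's maximal `S` is empty, no agreement tree
#' exists and the offending position is reported.
#'
#' The profile is normalized first when needed: unlabeled nodes receive
#' fresh reserved-prefix taxa (see [fully_label()]); the returned tree then
#' carries those synthetic taxa, which [strip_synthetic_labels()] removes
#' without affecting agreement with the original profile.
#'
#' @param profile An `slt_profile` (or list of `slt`).
#' @param backend,bad_order,seed,validate Passed to [ast_engine()].
#' @param queue_order `"fifo"` (breadth-first, default) or `"lifo"`;
#'   immaterial to the result since each position's decomposition is
#'   deterministic.
#' @return A `build_result`: `status` (`"AGREES"` or `"DISAGREES"`),
#'   `tree` (an `slt`, when agreeing), `stats`, `conflict_position` (when
#'   disagreeing), `added_labels` (synthetic taxa added by normalization).
#' @export
#' @examples
#' p <- slt_profile(list(parse_newick("((a,b),c)r;"),
#'                       parse_newick("((a,b),d)r;")))
#' res <- build_agreement_tree(p)
#' res$status
build_agreement_tree <- function(profile, backend = c("forest", "bfs"),
                                 queue_order = c("fifo", "lifo"),
                                 bad_order = c("scan", "random"),
                                 seed = 1L, validate = FALSE) {
  backend <- match.arg(backend)
  queue_order <- match.arg(queue_order)
  bad_order <- match.arg(bad_order)
  profile <- slt_profile(profile)
  added <- character(0)
  if (!is_normalized(profile)) {
    fl <- fully_label(profile)
    profile <- fl$profile
    added <- fl$added
  }
  eng <- ast_engine(profile, backend = backend, validate = validate,
                    bad_order = bad_order, seed = seed)
  raw <- ae_build(eng$ptr, queue_order)
  if (raw$status == "DISAGREES") {
    return(new_build_result("DISAGREES",
                            conflict_position = idx_to_pos(eng,
                                                           raw$conflict_position),
                            stats = raw$stats, added = added))
  }
  labs <- lapply(raw$taxa, function(ix) eng$vocab[ix])
  tree <- slt(raw$parent, labs)
  new_build_result("AGREES", tree = tree, stats = raw$stats, added = added)
}

#' Build and self-verify
#'
#' Convenience wrapper: runs [build_agreement_tree()] and, on success,
#' checks the result with the independent characterization-based verifier
#' [verify_agreement()].  A verifier rejection indicates an internal error
#' and raises with the offending condition.
#'
#' @inheritParams build_agreement_tree
#' @return A `build_result` (see [build_agreement_tree()]).
#' @export
verify_and_build <- function(profile, backend = c("forest", "bfs"),
                             queue_order = c("fifo", "lifo")) {
  profile <- slt_profile(profile)
  added <- character(0)
  if (!is_normalized(profile)) {
    fl <- fully_label(profile)
    profile <- fl$profile
    added <- fl$added
  }
  res <- build_agreement_tree(profile, backend = backend,
                              queue_order = queue_order)
  res$added_labels <- added
  if (res$status == "AGREES") {
    rep <- verify_agreement(res$tree, profile)
    if (!rep$ok) {
      v <- rep$violations[1, ]
      stop("internal consistency failure: built tree rejected by the ",
           "verifier (tree ", v$tree, ", condition ", v$condition,
           ", taxa ", v$taxa, ")", call. = FALSE)
    }
  }
  res
}
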