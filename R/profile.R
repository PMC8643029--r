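# Profiles ------------------------------------------------------------------

#' Create a profile of semi-labeled trees
#'
#' A profile is an ordered collection of input trees over partially
#' overlapping taxon sets.  The agreement question asks for a supertree on
#' the union of the taxon sets whose restriction to each input tree's taxa
#' is isomorphic to that tree.
#'
#' @param trees A list of `slt` objects (see [slt()], [parse_newick()]).
#' @return An object of class `slt_profile`.
#' @export
slt_profile <- function(trees) {
  if (inherits(trees, "slt")) trees <- list(trees)
  stopifnot(is.list(trees), length(trees) >= 1L)
  ok <- vapply(trees, inherits, logical(1), what = "slt")
  if (!all(ok)) stop("all profile members must be slt trees", call. = FALSE)
  structure(trees, class = "slt_profile")
}

#' @export
print.slt_profile <- function(x, ...) {
  cat("Profile of", length(x), "semi-labeled trees,",
      length(profile_taxa(x)), "distinct taxa\n")
  for (i in seq_along(x))
    cat(sprintf("  [%d] %s\n", i, to_newick(x[[i]])))
  invisible(x)
}

#' Union of the taxon sets of a profile
#' @param profile An `slt_profile`.
#' @return Sorted character vector of all distinct taxa.
#' @export
profile_taxa <- function(profile) {
  sort_taxa(unique(unlist(lapply(profile, taxa), use.names = FALSE)))
}

#' Is every tree in the profile fully and singularly labeled?
#' @param profile An `slt_profile`.
#' @return Logical scalar.
#' @export
is_normalized <- function(profile) {
  all(vapply(profile, is_fully_labeled, logical(1))) &&
    all(vapply(profile, is_singularly_labeled, logical(1)))
}

#' Make every tree in a profile fully labeled
#'
#' Assigns a fresh taxon, drawn from a reserved namespace, to every
#' unlabeled node of every tree.  An agreement tree of the fully labeled
#' profile is an agreement tree of the original, so downstream code may
#' assume the bijection between labels and nodes within each tree.
#'
#' @param profile An `slt_profile` of singularly labeled trees.
#' @param prefix Reserved prefix for the fresh labels; an error is raised
#'   if an input taxon already uses it.
#' @return A list with components `profile` (the fully labeled profile) and
#'   `added` (character vector of the fresh taxa, in assignment order:
#'   tree by tree, node index order).
#' @export
fully_label <- function(profile, prefix = "__anon") {
  profile <- slt_profile(profile)
  if (!all(vapply(profile, is_singularly_labeled, logical(1))))
    stop("fully_label expects singularly labeled input trees", call. = FALSE)
  existing <- profile_taxa(profile)
  clash <- existing[startsWith(existing, prefix)]
  if (length(clash))
    stop("input taxa collide with the reserved prefix '", prefix,
         "' (e.g. '", clash[1], "'); choose a different prefix",
         call. = FALSE)
  counter <- 0L
  added <- character(0)
  trees <- lapply(profile, function(tr) {
    empt <- which(lengths(tr$labels) == 0L)
    if (length(empt) == 0L) return(tr)
    labs <- tr$labels
    for (v in empt) {
      counter <<- counter + 1L
      nm <- paste0(prefix, counter)
      labs[[v]] <- nm
      added <<- c(added, nm)
    }
    out <- slt(tr$parent, labs) # parent already preorder: ids preserved
    out
  })
  list(profile = slt_profile(trees), added = added)
}

#' Drop reserved synthetic labels from a tree
#'
#' Inverse-ish of [fully_label()] for presentation: removes all taxa with
#' the reserved prefix from the node label sets and suppresses nodes left
#' unlabeled with a single child.  The result still agrees with the
#' original (unlabeled) profile.
#'
#' @param tree An `slt`.
#' @param prefix The reserved prefix used by [fully_label()].
#' @return An `slt` on the non-synthetic taxa.
#' @export
strip_synthetic_labels <- function(tree, prefix = "__anon") {
  keep <- taxa(tree)
  keep <- keep[!startsWith(keep, prefix)]
  if (length(keep) == 0L)
    stop("all taxa are synthetic; nothing to keep", call. = FALSE)
  restrict_tree(tree, keep)
}

#' Restriction of a profile to a taxon subset
#'
#' @param profile An `slt_profile`.
#' @param taxon_set Character vector of taxa.
#' @return A profile of the member-wise restrictions (trees whose taxon
#'   sets do not meet `taxon_set` are dropped).
#' @export
restrict_profile <- function(profile, taxon_set) {
  out <- list()
  for (tr in profile) {
    y <- intersect(taxa(tr), taxon_set)
    if (length(y)) out[[length(out) + 1L]] <- restrict_tree(tr, y)
  }
  slt_profile(out)
}
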