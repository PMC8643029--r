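# Semi-labeled rooted trees ------------------------------------------------
#
# An `slt` stores a rooted tree together with a labeling map from taxa to
# nodes.  Every leaf and every unary node must carry at least one taxon;
# internal nodes of higher degree may be unlabeled.  A tree is *fully
# labeled* when every node carries a taxon and *singularly labeled* when no
# node carries more than one.  Nodes are stored in preorder (a node's parent
# always has a smaller index) and child order is preserved as given.

sort_taxa <- function(x) sort(x, method = "radix")

#' Construct a semi-labeled tree
#'
#' @param parent Integer vector; `parent[v]` is the parent node index of `v`
#'   and `0` marks the root (exactly one).
#' @param labels List of character vectors, one per node; the taxa labeling
#'   that node (possibly empty for non-unary internal nodes).
#' @return An object of class `slt` with fields `parent`, `labels`,
#'   `children`, `root`, and accessors [taxa()], [label_map()].
#' @export
slt <- function(parent, labels) {
  parent <- as.integer(parent)
  np <- length(parent)
  if (np == 0L) stop("a tree needs at least one node", call. = FALSE)
  if (!is.list(labels) || length(labels) != np)
    stop("labels must be a list with one entry per node", call. = FALSE)
  labels <- lapply(labels, function(x) unique(as.character(x)))
  root <- which(parent == 0L)
  if (length(root) != 1L)
    stop("tree must have exactly one root", call. = FALSE)
  if (any(parent < 0L | parent > np))
    stop("parent index out of range", call. = FALSE)

  # renumber to preorder, preserving child order
  kids <- split(seq_len(np), factor(parent, levels = 0:np))
  kids <- kids[-1L] # drop the root's pseudo parent 0
  order_new <- integer(np)
  stack <- root
  pos <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pos <- pos + 1L
    order_new[v] <- pos
    ch <- kids[[v]]
    if (length(ch)) stack <- c(stack, rev(ch))
  }
  if (pos != np)
    stop("tree is not connected (unreachable nodes present)", call. = FALSE)
  newparent <- integer(np)
  newlabels <- vector("list", np)
  for (v in seq_len(np)) {
    nv <- order_new[v]
    newparent[nv] <- if (parent[v] == 0L) 0L else order_new[parent[v]]
    newlabels[[nv]] <- labels[[v]]
  }
  # children in preorder id space; preorder assignment preserves sibling order
  children <- vector("list", np)
  for (v in seq_len(np)) children[[v]] <- integer(0)
  for (v in seq_len(np)) {
    p <- newparent[v]
    if (p > 0L) children[[p]] <- c(children[[p]], v)
  }

  nlab <- lengths(newlabels)
  nkid <- lengths(children)
  bad <- which(nkid <= 1L & nlab == 0L)
  if (length(bad))
    stop("X-tree violation: node with at most one child is unlabeled ",
         "(node ", bad[1], ")", call. = FALSE)
  all_taxa <- unlist(newlabels, use.names = FALSE)
  if (anyDuplicated(all_taxa)) {
    d <- all_taxa[duplicated(all_taxa)][1]
    stop("duplicate label within one tree: '", d, "'", call. = FALSE)
  }

  out <- list(parent = newparent, labels = newlabels, children = children,
              root = 1L)
  class(out) <- "slt"
  out
}

#' @export
print.slt <- function(x, ...) {
  cat("Semi-labeled tree:", length(x$parent), "nodes,",
      length(taxa(x)), "taxa\n")
  cat(" ", to_newick(x), "\n")
  invisible(x)
}

#' Taxa of a semi-labeled tree
#' @param tree An `slt`.
#' @return Character vector of all taxa (the tree's label set), sorted.
#' @export
taxa <- function(tree) {
  sort_taxa(unlist(tree$labels, use.names = FALSE))
}

#' Labeling map of a tree
#' @param tree An `slt`.
#' @return Named integer vector mapping each taxon to its node index.
#' @export
label_map <- function(tree) {
  nl <- lengths(tree$labels)
  stats::setNames(rep.int(seq_along(tree$labels), nl),
                  unlist(tree$labels, use.names = FALSE))
}

#' Is every node labeled / no node multiply labeled?
#' @param tree An `slt`.
#' @return Logical scalar.
#' @export
is_fully_labeled <- function(tree) all(lengths(tree$labels) >= 1L)

#' @rdname is_fully_labeled
#' @export
is_singularly_labeled <- function(tree) all(lengths(tree$labels) <= 1L)

node_depths <- function(tree) {
  d <- integer(length(tree$parent))
  for (v in seq_along(d)) d[v] <- if (tree$parent[v] == 0L) 0L else
    d[tree$parent[v]] + 1L
  d
}

# taxa in the subtree rooted at each node, as a list of character vectors
node_clusters <- function(tree) {
  np <- length(tree$parent)
  cl <- vector("list", np)
  for (v in np:1) {
    cl[[v]] <- c(tree$labels[[v]],
                 unlist(cl[tree$children[[v]]], use.names = FALSE))
  }
  lapply(cl, sort_taxa)
}

#' Clusters of a semi-labeled tree
#'
#' The cluster of a node is the set of taxa labeling the node or any of its
#' descendants.  The cluster set determines the tree up to isomorphism, so
#' cluster-set equality is the package's tree-equality test.
#'
#' @param tree An `slt`.
#' @return A list of distinct character vectors (each sorted), one per
#'   distinct cluster.
#' @export
clusters <- function(tree) {
  cl <- node_clusters(tree)
  cl[!duplicated(vapply(cl, paste, character(1), collapse = "\r"))]
}

# canonical string fingerprint of the cluster set
cluster_key <- function(tree) {
  keys <- vapply(node_clusters(tree), paste, character(1), collapse = "\r")
  paste(sort(unique(keys), method = "radix"), collapse = "\n")
}

#' Do two trees have identical cluster sets?
#' @param a,b `slt` objects.
#' @return Logical scalar: `TRUE` iff the trees are isomorphic as
#'   semi-labeled trees.
#' @export
same_clusters <- function(a, b) identical(cluster_key(a), cluster_key(b))

#' Lowest common ancestor of a set of taxa
#' @param tree An `slt`.
#' @param taxon_set Character vector of taxa present in the tree.
#' @return The taxa labeling the LCA node (character vector; may be empty
#'   for an unlabeled node), with attribute `"node"` giving the node index.
#' @export
lca_taxa <- function(tree, taxon_set) {
  lm <- label_map(tree)
  miss <- setdiff(taxon_set, names(lm))
  if (length(miss))
    stop("taxa not in tree: ", paste(miss, collapse = ", "), call. = FALSE)
  nodes <- unique(unname(lm[taxon_set]))
  d <- node_depths(tree)
  cur <- nodes[1]
  for (v in nodes[-1]) {
    a <- cur; b <- v
    while (a != b) {
      if (d[a] >= d[b]) a <- tree$parent[a] else b <- tree$parent[b]
    }
    cur <- a
  }
  structure(tree$labels[[cur]], node = cur)
}

#' Restrict a tree to a subset of its taxa
#'
#' Returns the semi-labeled tree whose clusters are the nonempty
#' intersections of the input tree's clusters with `taxon_set`: the minimal
#' subtree connecting the nodes labeled by `taxon_set`, with out-of-set
#' unary nodes suppressed and out-of-set taxa dropped.
#'
#' @param tree An `slt`.
#' @param taxon_set Nonempty character vector, a subset of `taxa(tree)`.
#' @return An `slt` with label set exactly `taxon_set`.  The attribute
#'   `"source_node"` maps each node of the result to the node of `tree` it
#'   came from (used by the synthetic-profile generator to place fresh
#'   labels consistently).
#' @export
restrict_tree <- function(tree, taxon_set) {
  stopifnot(inherits(tree, "slt"))
  taxon_set <- unique(as.character(taxon_set))
  if (length(taxon_set) == 0L)
    stop("cannot restrict to an empty taxon set", call. = FALSE)
  miss <- setdiff(taxon_set, taxa(tree))
  if (length(miss))
    stop("taxa not in tree: ", paste(miss, collapse = ", "), call. = FALSE)

  np <- length(tree$parent)
  keep_lab <- lapply(tree$labels, intersect, y = taxon_set)
  # results[[v]]: ids (into res_*) of result-subtree roots produced below v
  results <- vector("list", np)
  res_labels <- list()
  res_kids <- list()
  res_source <- integer(0)
  new_node <- function(labs, kids, src) {
    id <- length(res_source) + 1L
    res_labels[[id]] <<- labs
    res_kids[[id]] <<- kids
    res_source[id] <<- src
    id
  }
  for (v in np:1) { # children (higher preorder index) processed first
    sub <- unlist(results[tree$children[[v]]], use.names = FALSE)
    if (is.null(sub)) sub <- integer(0)
    if (length(keep_lab[[v]]) > 0L) {
      results[[v]] <- new_node(keep_lab[[v]], sub, v)
    } else if (length(sub) >= 2L) {
      results[[v]] <- new_node(character(0), sub, v)
    } else {
      results[[v]] <- sub # suppressed (or nothing below)
    }
    results[tree$children[[v]]] <- list(NULL)
  }
  top <- results[[tree$root]]
  stopifnot(length(top) == 1L) # taxon_set nonempty => a single root survives

  # emit in preorder, preserving the original sibling order
  nn <- length(res_source)
  parent <- integer(nn)
  labels <- vector("list", nn)
  source <- integer(nn)
  stack_id <- top
  stack_par <- 0L
  pos <- 0L
  while (length(stack_id)) {
    id <- stack_id[length(stack_id)]
    p <- stack_par[length(stack_par)]
    stack_id <- stack_id[-length(stack_id)]
    stack_par <- stack_par[-length(stack_par)]
    pos <- pos + 1L
    parent[pos] <- p
    labels[[pos]] <- res_labels[[id]]
    source[pos] <- res_source[id]
    ch <- res_kids[[id]]
    if (length(ch)) {
      stack_id <- c(stack_id, rev(ch))
      stack_par <- c(stack_par, rep.int(pos, length(ch)))
    }
  }
  out <- slt(parent, labels)
  attr(out, "source_node") <- source
  out
}

#' Does a supertree agree with an input tree?
#'
#' `TRUE` iff the clusters of `input_tree` equal the clusters of the
#' supertree restricted to the input tree's label set.  This is the
#' definitional test; an independent characterization-based verifier is
#' available as [verify_agreement()].
#'
#' @param supertree,input_tree `slt` objects; the input tree's label set
#'   must be contained in the supertree's.
#' @return Logical scalar.
#' @export
agrees_with <- function(supertree, input_tree) {
  xin <- taxa(input_tree)
  if (length(setdiff(xin, taxa(supertree))))
    stop("input tree has taxa missing from the supertree", call. = FALSE)
  identical(cluster_key(restrict_tree(supertree, xin)),
            cluster_key(input_tree))
}
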