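# Display graph -------------------------------------------------------------
#
# The display graph of a profile has one vertex per distinct taxon and one
# undirected edge per distinct parent-child label pair pooled over all
# input trees.  The construction algorithm only ever deletes vertices and
# edges, so the graph supports decremental connectivity with enumeration of
# the smaller side of every split.

#' Build the display graph of a normalized profile
#'
#' @param profile A normalized `slt_profile`.
#' @param backend `"forest"` (spanning forest with replacement-edge
#'   search) or `"bfs"` (alternating bidirectional search); identical
#'   semantics, different internals.
#' @return An object of class `display_graph` with fields `taxa` (the
#'   vertex names) and `edges` (two-column character matrix).  The object
#'   is mutable: deletions performed through [delete_exposed()] persist.
#' @export
build_display_graph <- function(profile, backend = c("forest", "bfs")) {
  backend <- match.arg(backend)
  profile <- slt_profile(profile)
  if (!is_normalized(profile))
    stop("display graph requires a normalized profile", call. = FALSE)
  vocab <- profile_taxa(profile)
  ef <- integer(0); et <- integer(0)
  for (tr in profile) {
    tax <- vapply(tr$labels, `[`, character(1), 1L)
    id <- match(tax, vocab)
    ch <- which(tr$parent > 0L)
    ef <- c(ef, id[tr$parent[ch]])
    et <- c(et, id[ch])
  }
  em <- cbind(pmin(ef, et), pmax(ef, et))
  em <- unique(em)
  ptr <- dg_create(length(vocab), em, backend == "forest")
  structure(list(ptr = ptr, taxa = vocab,
                 edges = cbind(vocab[em[, 1]], vocab[em[, 2]])),
            class = "display_graph")
}

#' @export
print.display_graph <- function(x, ...) {
  st <- dg_stats(x$ptr)
  cat("Display graph:", st$n_vertices, "taxa (", st$n_alive, "alive ),",
      nrow(x$edges), "initial edges\n")
  invisible(x)
}

#' Delete newly exposed labels from a display graph
#'
#' Removes, one edge at a time, all edges incident to each given taxon and
#' then the taxon itself.  Each vertex and edge is deleted at most once
#' over the life of the graph; deleting an already-deleted taxon is an
#' error (callers must skip old exposed labels).
#'
#' @param graph A [build_display_graph()] object (mutated in place).
#' @param new_labels Character vector of alive, never-deleted taxa.
#' @param marked Optional character vector; when given, each recorded
#'   component split also reports the moved side's intersection with this
#'   marked set (the child set of the current position, in the algorithm).
#' @return A list with `splits` (per split: the vertices moved to the new,
#'   smaller component, and their intersection with `marked`) and
#'   `components` (the component partition of the marked set after the
#'   deletions, or of all alive vertices when `marked` is `NULL`).
#' @export
delete_exposed <- function(graph, new_labels, marked = NULL) {
  stopifnot(inherits(graph, "display_graph"))
  idx <- match(new_labels, graph$taxa)
  if (anyNA(idx))
    stop("unknown taxa: ",
         paste(new_labels[is.na(idx)], collapse = ", "), call. = FALSE)
  raw <- dg_delete_exposed(graph$ptr, idx)
  splits <- lapply(raw, function(ev) {
    moved <- graph$taxa[ev$moved]
    list(moved = moved,
         marked_moved = if (is.null(marked)) NULL else
           intersect(moved, marked))
  })
  list(splits = splits,
       components = graph_components(graph, marked))
}

#' Component partition of (a subset of) the alive vertices
#'
#' @param graph A `display_graph`.
#' @param subset Optional character vector restricting the report.
#' @return A list of character vectors (each sorted), one per component
#'   intersecting the subset, ordered by smallest member.
#' @export
graph_components <- function(graph, subset = NULL) {
  comp <- dg_components(graph$ptr)
  names(comp) <- graph$taxa
  if (!is.null(subset)) comp <- comp[intersect(graph$taxa, subset)]
  comp <- comp[!is.na(comp)]
  if (length(comp) == 0L) return(list())
  out <- split(names(comp), comp)
  out <- lapply(out, sort_taxa)
  names(out) <- NULL
  out[order(vapply(out, `[`, character(1), 1L), method = "radix")]
}

#' Component handle of a taxon
#'
#' Handles are equal iff the taxa are currently in the same component.
#' Errors on deleted taxa.
#'
#' @param graph A `display_graph`.
#' @param taxon A single taxon name.
#' @return Integer component handle.
#' @export
component_of <- function(graph, taxon) {
  idx <- match(taxon, graph$taxa)
  if (is.na(idx)) stop("unknown taxon: ", taxon, call. = FALSE)
  dg_component_of(graph$ptr, idx)
}

#' Per-taxon smaller-side move counters
#'
#' Each split moves only the smaller side into a new component, so no
#' taxon can move more than about `log2(V)` times; the counters let tests
#' assert this bound.
#'
#' @param graph A `display_graph`.
#' @return Named integer vector.
#' @export
component_move_counts <- function(graph) {
  stats::setNames(dg_move_counts(graph$ptr), graph$taxa)
}

#' Dump a display graph for external tools
#'
#' @param graph A `display_graph`.
#' @param path Output file.
#' @param format `"tsv"` (two-column edge list) or `"dot"` (Graphviz).
#' @return `path`, invisibly.
#' @export
write_display_graph <- function(graph, path, format = c("tsv", "dot")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    q <- function(x) paste0("\"", gsub("\"", "\\\"", x, fixed = TRUE), "\"")
    lines <- c("graph display {",
               paste0("  ", q(graph$edges[, 1]), " -- ", q(graph$edges[, 2]),
                      ";"),
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}
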