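#' Parse a Newick string into a semi-labeled tree
#'
#' Reads a single rooted Newick expression.  Internal-node labels (the text
#' after a closing parenthesis) are kept and mapped to taxa, so taxonomies
#' and other internally labeled trees round-trip.  Branch lengths are parsed
#' and discarded with a one-time warning: the agreement problem is purely
#' topological.  Quoted labels (single quotes, doubled quote escapes) are
#' supported.
#'
#' Unlike most phylogenetics parsers, a root or internal node with a single
#' child is accepted provided it is labeled, because semi-labeled trees
#' require every unary node (and every leaf) to carry a taxon.
#'
#' @param text A single Newick string, terminated by `;`.
#' @param multi_label_delimiter Optional string; when non-`NULL`, node names
#'   are split on this delimiter into several taxa mapping to the same node
#'   (the inverse of [to_newick()] output for multiply labeled nodes).
#' @return An object of class `slt` (see [slt()]).
#' @export
#' @examples
#' tr <- parse_newick("((a,b)f,c)g;")
#' sort(taxa(tr))
parse_newick <- function(text, multi_label_delimiter = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  parent <- integer(0)
  label <- character(0)
  saw_branch_length <- FALSE

  fail <- function(msg, at = i) {
    stop(sprintf("Newick parse error at character %d: %s", at, msg),
         call. = FALSE)
  }
  peek <- function() if (i <= n) chars[i] else ""
  skip_ws <- function() {
    while (i <= n && chars[i] %in% c(" ", "\t", "\n", "\r")) i <<- i + 1L
  }
  new_node <- function(p) {
    parent[length(parent) + 1L] <<- p
    label[length(label) + 1L] <<- NA_character_
    length(parent)
  }
  read_name <- function() {
    skip_ws()
    if (peek() == "'") {
      i <<- i + 1L
      out <- character(0)
      repeat {
        if (i > n) fail("unterminated quoted label")
        ch <- chars[i]
        if (ch == "'") {
          if (i + 1L <= n && chars[i + 1L] == "'") {
            out <- c(out, "'")
            i <<- i + 2L
          } else {
            i <<- i + 1L
            break
          }
        } else {
          out <- c(out, ch)
          i <<- i + 1L
        }
      }
      paste(out, collapse = "")
    } else {
      start <- i
      while (i <= n && !(chars[i] %in% c("(", ")", ",", ";", ":", " ", "\t",
                                         "\n", "\r")))
        i <<- i + 1L
      if (i > start) paste(chars[start:(i - 1L)], collapse = "") else ""
    }
  }
  skip_branch_length <- function() {
    skip_ws()
    if (peek() == ":") {
      i <<- i + 1L
      start <- i
      while (i <= n && (chars[i] %in% c("0","1","2","3","4","5","6","7","8",
                                        "9",".","-","+","e","E")))
        i <<- i + 1L
      if (i == start) fail("expected a branch length after ':'")
      saw_branch_length <<- TRUE
    }
  }
  parse_subtree <- function(p) {
    skip_ws()
    node <- new_node(p)
    has_children <- FALSE
    if (peek() == "(") {
      has_children <- TRUE
      i <<- i + 1L
      repeat {
        parse_subtree(node)
        skip_ws()
        if (peek() == ",") {
          i <<- i + 1L
        } else break
      }
      if (peek() != ")") fail("expected ',' or ')'")
      i <<- i + 1L
    }
    nm <- read_name()
    if (nzchar(nm)) label[node] <<- nm
    else if (!has_children) fail("expected a subtree") # bare empty leaf
    skip_branch_length()
    node
  }

  skip_ws()
  if (i > n) fail("empty input")
  parse_subtree(0L)
  skip_ws()
  if (peek() != ";") fail("expected ';'")
  i <- i + 1L
  skip_ws()
  if (i <= n) fail("trailing characters after ';'")
  if (saw_branch_length)
    warning("branch lengths present in Newick input were discarded ",
            "(agreement is purely topological)", call. = FALSE)

  labs <- vector("list", length(parent))
  for (v in seq_along(parent)) {
    if (is.na(label[v])) {
      labs[[v]] <- character(0)
    } else if (!is.null(multi_label_delimiter)) {
      labs[[v]] <- strsplit(label[v], multi_label_delimiter,
                            fixed = TRUE)[[1]]
    } else {
      labs[[v]] <- label[v]
    }
  }
  slt(parent, labs)
}

#' Read a profile of trees from a Newick file
#'
#' One tree per line; blank lines and lines starting with `#` are skipped.
#'
#' @param path Path to a text file of Newick strings.
#' @param multi_label_delimiter Passed to [parse_newick()].
#' @return An `slt_profile` (a list of `slt` trees).
#' @export
read_profile <- function(path, multi_label_delimiter = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop("no trees found in ", path, call. = FALSE)
  slt_profile(lapply(lines, parse_newick,
                     multi_label_delimiter = multi_label_delimiter))
}

quote_if_needed <- function(x) {
  bad <- grepl("[(),;:'\\s]", x, perl = TRUE)
  x[bad] <- paste0("'", gsub("'", "''", x[bad], fixed = TRUE), "'")
  x
}

#' Serialize a semi-labeled tree to Newick
#'
#' Nodes carrying several taxa emit their taxa sorted and joined by
#' `multi_label_delimiter`.  With `canonical = TRUE` the children of every
#' node are ordered by the smallest taxon in their cluster, giving a
#' byte-identical representation for cluster-equal trees.
#'
#' @param tree An `slt`.
#' @param multi_label_delimiter Separator for multiply labeled nodes.
#' @param canonical Sort children by smallest contained taxon.
#' @return A Newick string terminated by `;`.
#' @export
to_newick <- function(tree, multi_label_delimiter = "+", canonical = FALSE) {
  stopifnot(inherits(tree, "slt"))
  kids <- tree$children
  labs <- tree$labels
  mins <- if (canonical) node_min_taxon(tree) else NULL
  emit <- function(v) {
    nm <- paste(quote_if_needed(sort_taxa(labs[[v]])),
                collapse = multi_label_delimiter)
    ch <- kids[[v]]
    if (length(ch) == 0L) return(nm)
    if (canonical) ch <- ch[order(mins[ch], method = "radix")]
    paste0("(", paste(vapply(ch, emit, character(1)), collapse = ","), ")",
           nm)
  }
  paste0(emit(tree$root), ";")
}

# smallest taxon (radix order) in the cluster of each node
node_min_taxon <- function(tree) {
  np <- length(tree$parent)
  mins <- character(np)
  for (v in np:1) { # reverse preorder = postorder-compatible
    own <- sort_taxa(tree$labels[[v]])
    cand <- c(if (length(own)) own[1], mins[tree$children[[v]]])
    mins[v] <- if (length(cand)) sort_taxa(cand)[1] else ""
  }
  mins
}
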