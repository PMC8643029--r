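# Brute-force agreement decider ----------------------------------------------
#
# For tiny instances, enumerate every rooted semi-labeled tree on the
# profile's taxon set in which every node is labeled (sufficient: an
# agreeing profile always has an agreement tree of that form, obtained by
# contracting unlabeled nodes) and test each candidate by the definitional
# cluster-restriction check.  Candidate trees are set partitions of the
# taxon set crossed with all rooted tree shapes on the blocks.

.brute_cache <- new.env(parent = emptyenv())

# all rooted trees on b distinguishable nodes, as parent vectors (0 = root)
rooted_parent_vectors <- function(b) {
  key <- as.character(b)
  if (!is.null(.brute_cache[[key]])) return(.brute_cache[[key]])
  out <- list()
  if (b == 1L) {
    out[[1L]] <- 0L
  } else {
    for (r in seq_len(b)) {
      slots <- setdiff(seq_len(b), r)
      choices <- lapply(slots, function(v) setdiff(seq_len(b), v))
      grid <- do.call(expand.grid, c(choices, list(KEEP.OUT.ATTRS = FALSE)))
      for (g in seq_len(nrow(grid))) {
        pv <- integer(b)
        pv[slots] <- as.integer(grid[g, ])
        # acyclicity: every node must reach the root
        ok <- TRUE
        for (v in slots) {
          x <- v; steps <- 0L
          while (x != r) {
            x <- pv[x]; steps <- steps + 1L
            if (steps > b) { ok <- FALSE; break }
          }
          if (!ok) break
        }
        if (ok) out[[length(out) + 1L]] <- pv
      }
    }
  }
  .brute_cache[[key]] <- out
  out
}

# all set partitions of x (restricted-growth enumeration, no duplicates);
# index partitions are cached by size and mapped onto x
set_partitions <- function(x) {
  n <- length(x)
  key <- paste0("p", n)
  parts <- .brute_cache[[key]]
  if (is.null(parts)) {
    res <- list()
    rec <- function(i, blocks) {
      if (i > n) {
        res[[length(res) + 1L]] <<- blocks
        return(invisible(NULL))
      }
      for (j in seq_along(blocks)) {
        b2 <- blocks
        b2[[j]] <- c(b2[[j]], i)
        rec(i + 1L, b2)
      }
      rec(i + 1L, c(blocks, list(i)))
    }
    if (n == 1L) res <- list(list(1L)) else rec(2L, list(1L))
    .brute_cache[[key]] <- res
    parts <- res
  }
  lapply(parts, function(blocks) lapply(blocks, function(ix) x[ix]))
}

#' Decide agreement by exhaustive enumeration (test oracle)
#'
#' Only usable for very small label sets; refuses larger inputs.  Returns
#' the first agreeing candidate in a fixed deterministic enumeration
#' order, so results are reproducible.
#'
#' @param profile A normalized `slt_profile`.
#' @param max_labels Guard on `|X_P|` (default 6).
#' @return A `build_result` with status `"AGREES"` (and the witness tree)
#'   or `"DISAGREES"`.
#' @export
brute_force_agreement <- function(profile, max_labels = 6L) {
  profile <- slt_profile(profile)
  if (!is_normalized(profile))
    stop("brute_force_agreement expects a normalized profile", call. = FALSE)
  xp <- profile_taxa(profile)
  if (length(xp) > max_labels)
    stop("refusing brute force on ", length(xp), " labels (max ",
         max_labels, "): combinatorial explosion", call. = FALSE)
  input_keys <- lapply(profile, cluster_key)
  input_taxa <- lapply(profile, taxa)
  for (blocks in set_partitions(xp)) {
    b <- length(blocks)
    for (pv in rooted_parent_vectors(b)) {
      cand <- slt(pv, blocks)
      ok <- TRUE
      for (i in seq_along(profile)) {
        if (!identical(cluster_key(restrict_tree(cand, input_taxa[[i]])),
                       input_keys[[i]])) {
          ok <- FALSE
          break
        }
      }
      if (ok) return(new_build_result("AGREES", tree = cand))
    }
  }
  new_build_result("DISAGREES")
}
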