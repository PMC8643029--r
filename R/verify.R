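# Independent agreement verifier --------------------------------------------
#
# A supertree T with label map phi agrees with every tree of a normalized
# profile iff for each input tree i and each taxon a in X_i:
#   E1: phi(a) is the LCA in T of the cluster of a in tree i;
#   E2: phi(a) is a proper ancestor of phi(b) for every child label b of a;
#   E3: distinct child labels b, c of a descend from distinct children of
#       phi(a) in T.
# This characterization is an iff, so the verifier is a complete oracle,
# implemented independently of the construction engine.  LCAs use binary
# lifting, vectorized over whole levels of each input tree.

#' Verify agreement of a supertree with a profile
#'
#' @param supertree An `slt` whose label set equals the union of the
#'   profile's taxa.
#' @param profile A normalized `slt_profile` (see [fully_label()]).
#' @return A `verifier_report`: list with `ok` (logical) and `violations`
#'   (data frame with columns `tree`, `condition` in `E1`/`E2`/`E3`, and
#'   `taxa`).
#' @export
verify_agreement <- function(supertree, profile) {
  profile <- slt_profile(profile)
  if (!is_normalized(profile))
    stop("verify_agreement expects a normalized profile", call. = FALSE)
  xp <- profile_taxa(profile)
  xt <- taxa(supertree)
  if (!identical(xp, xt))
    stop("supertree label set must equal the union of the profile's ",
         "taxon sets", call. = FALSE)

  par <- supertree$parent
  np <- length(par)
  depth <- node_depths(supertree)
  phi <- label_map(supertree)

  maxlog <- max(1L, as.integer(ceiling(log2(max(2L, max(depth) + 1L)))))
  up <- matrix(1L, nrow = np, ncol = maxlog + 1L)
  up[, 1] <- ifelse(par == 0L, seq_len(np), par)
  if (maxlog >= 1L)
    for (j in seq_len(maxlog)) up[, j + 1L] <- up[up[, j], j]

  anc <- function(v, steps) {
    j <- 1L
    while (any(steps > 0L)) {
      sel <- bitwAnd(steps, 1L) == 1L
      if (any(sel)) v[sel] <- up[v[sel], j]
      steps <- steps %/% 2L
      j <- j + 1L
    }
    v
  }
  lca2 <- function(u, v) {
    du <- depth[u]; dv <- depth[v]
    s <- du > dv
    if (any(s)) u[s] <- anc(u[s], du[s] - dv[s])
    s <- dv > du
    if (any(s)) v[s] <- anc(v[s], dv[s] - du[s])
    res <- integer(length(u))
    done <- u == v
    res[done] <- u[done]
    act <- which(!done)
    if (length(act)) {
      uu <- u[act]; vv <- v[act]
      for (j in (maxlog + 1L):1L) {
        au <- up[uu, j]; av <- up[vv, j]
        mv <- au != av
        if (any(mv)) { uu[mv] <- au[mv]; vv[mv] <- av[mv] }
      }
      res[act] <- up[uu, 1L]
    }
    res
  }
  is_proper_anc <- function(a, b) {
    depth[a] < depth[b] & anc(b, depth[b] - depth[a]) == a
  }

  viol <- list()
  note <- function(tree, cond, taxa_str) {
    viol[[length(viol) + 1L]] <<- data.frame(tree = tree, condition = cond,
                                             taxa = taxa_str,
                                             stringsAsFactors = FALSE)
  }

  for (i in seq_along(profile)) {
    tr <- profile[[i]]
    ntr <- length(tr$parent)
    ti_tax <- vapply(tr$labels, `[`, character(1), 1L)
    node_in_T <- unname(phi[ti_tax])

    # E1: bottom-up cluster LCAs, level by level
    L <- node_in_T
    pd <- node_depths(tr)
    ch_nodes <- which(tr$parent > 0L)
    if (length(ch_nodes)) {
      for (d in sort(unique(pd[ch_nodes]), decreasing = TRUE)) {
        ce <- ch_nodes[pd[ch_nodes] == d]
        pp <- tr$parent[ce]
        rk <- stats::ave(seq_along(ce), pp, FUN = seq_along)
        for (r in seq_len(max(rk))) {
          sel <- rk == r
          L[pp[sel]] <- lca2(L[pp[sel]], L[ce[sel]])
        }
      }
    }
    bad1 <- which(L != node_in_T)
    for (v in bad1) note(i, "E1", ti_tax[v])

    if (length(ch_nodes)) {
      a_node <- node_in_T[tr$parent[ch_nodes]]
      b_node <- node_in_T[ch_nodes]
      e2ok <- is_proper_anc(a_node, b_node)
      for (j in which(!e2ok))
        note(i, "E2", paste(ti_tax[tr$parent[ch_nodes[j]]],
                            ti_tax[ch_nodes[j]]))
      # E3 only meaningful where E2 holds (the child-of-ancestor is defined)
      ok <- which(e2ok)
      if (length(ok)) {
        tops <- anc(b_node[ok], depth[b_node[ok]] - depth[a_node[ok]] - 1L)
        key <- paste(tr$parent[ch_nodes[ok]], tops)
        dupgrp <- key[duplicated(key)]
        for (kk in unique(dupgrp)) {
          members <- ok[key == kk]
          note(i, "E3",
               paste(ti_tax[tr$parent[ch_nodes[members[1]]]], "->",
                     paste(ti_tax[ch_nodes[members]], collapse = ",")))
        }
      }
    }
  }

  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(tree = integer(0), condition = character(0),
               taxa = character(0), stringsAsFactors = FALSE)
  structure(list(ok = nrow(violations) == 0L, violations = violations),
            class = "verifier_report")
}

#' @export
print.verifier_report <- function(x, ...) {
  if (x$ok) cat("Verifier: OK (conditions E1-E3 hold for every tree)\n")
  else {
    cat("Verifier: FAILED with", nrow(x$violations), "violation(s)\n")
    print(x$violations)
  }
  invisible(x)
}
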