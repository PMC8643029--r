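# Worked example -------------------------------------------------------------

#' A small taxonomy-style example profile
#'
#' Four partially overlapping input trees over taxa `a` to `l`; the
#' numeric taxa `1` to `6` are the fresh labels that make every tree fully
#' labeled (with `labeled = FALSE` those nodes are left unlabeled, which
#' is how the trees would arrive from a user).  The profile agrees, and it
#' exercises every interesting part of the decomposition: on the initial
#' position the exposed set is `{1, 4, 6}`, labels `4` and `6` are bad and
#' get eliminated by virtual block merges, and the maximal nice exposed
#' subset is `{1}`.
#'
#' This profile is used as the worked example throughout the package
#' documentation and tests.
#'
#' @param labeled Return the fully labeled form (default) or the raw form
#'   with unlabeled internal nodes.
#' @return An `slt_profile` of four trees.
#' @export
toy_taxonomy_profile <- function(labeled = TRUE) {
  if (labeled) {
    txt <- c("(((a,c)3,b)2,d)1;",
             "(b,c,(e)g)4;",
             "(f,(h,e)5,k)g;",
             "((h)i,(k)j,l)6;")
  } else {
    txt <- c("(((a,c),b),d);",
             "(b,c,(e)g);",
             "(f,(h,e),k)g;",
             "((h)i,(k)j,l);")
  }
  slt_profile(lapply(txt, parse_newick))
}
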