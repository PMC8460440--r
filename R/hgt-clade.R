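#' Smallest-clade phylogenetic test for an HGT candidate
#'
#' Given a rooted gene tree containing the candidate plus its top database
#' hits, the smallest clade containing the candidate is the subtree rooted
#' at the candidate leaf's parent node. The candidate is confirmed as
#' horizontally transferred when no other leaf of that clade carries a
#' metazoan group label: its closest relatives in the gene tree are then all
#' foreign. Leaf labels follow the `"group|id"` convention
#' ([leaf_taxon_groups()]); support values are ignored.
#'
#' @param tree A rooted `phylo` object ([read_tree()]).
#' @param candidate_leaf Label of the candidate leaf; must occur exactly
#'   once.
#' @param metazoan_groups Group labels counted as metazoan (default: the
#'   non-annelid metazoan database and the annelid database).
#' @return A list: `confirmed` (logical) and `clade_leaves` (labels of the
#'   smallest clade).
#' @examples
#' tr <- ape::read.tree(text = "((cand:1,bacteria|b1:1):1,metazoa_excl_annelida|m1:2);")
#' clade_test(tr, "cand")$confirmed  # TRUE
#' @export
clade_test <- function(tree, candidate_leaf,
                       metazoan_groups = hgt_metazoan_groups) {
  hits <- which(tree$tip.label == candidate_leaf)
  if (length(hits) == 0L) {
    pw_usage_error(paste0("candidate leaf '", candidate_leaf, "' not in tree"))
  }
  if (length(hits) > 1L) {
    pw_usage_error(paste0("candidate leaf '", candidate_leaf, "' occurs ",
                          length(hits), " times"))
  }
  if (length(tree$tip.label) < 2L) {
    pw_usage_error("tree must contain leaves besides the candidate")
  }
  tip <- hits[1]
  parent <- tree$edge[tree$edge[, 2] == tip, 1]
  # collect tips under the parent node by walking the edge table
  stack <- parent
  tips <- integer(0)
  ntip <- length(tree$tip.label)
  while (length(stack)) {
    node <- stack[[1]]
    stack <- stack[-1]
    children <- tree$edge[tree$edge[, 1] == node, 2]
    tips <- c(tips, children[children <= ntip])
    stack <- c(stack, children[children > ntip])
  }
  clade_leaves <- tree$tip.label[sort(tips)]
  others <- setdiff(clade_leaves, candidate_leaf)
  groups <- leaf_taxon_groups(others)
  list(
    confirmed = !any(groups %in% metazoan_groups, na.rm = TRUE),
    clade_leaves = clade_leaves
  )
}
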