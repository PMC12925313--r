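#' Read and write Newick trees
#'
#' Thin wrappers around \pkg{ape} that enforce unique leaf labels and keep
#' the FastTree dialect in which internal node labels carry support values.
#'
#' @param path Path to a Newick file (first tree used) or a Newick string.
#' @return An \code{ape::phylo} tree.
#' @export
read_newick <- function(path) {
  tree <- if (grepl(";", path, fixed = TRUE) && !file.exists(path)) {
    ape::read.tree(text = path)
  } else {
    ape::read.tree(path)
  }
  if (is.null(tree)) stop("could not parse Newick input: ", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  tree
}

#' @rdname read_newick
#' @param tree An \code{ape::phylo} tree.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Root a tree with an outgroup leaf
#'
#' @param tree An \code{ape::phylo} tree.
#' @param outgroup_leaf Label of the outgroup leaf.
#' @return A rooted tree whose root separates the outgroup from all other
#'   leaves. Idempotent when already rooted on that outgroup.
#' @export
root_with_outgroup <- function(tree, outgroup_leaf) {
  if (!(outgroup_leaf %in% tree$tip.label)) {
    stop("outgroup leaf '", outgroup_leaf, "' not found in tree")
  }
  ape::root(tree, outgroup = outgroup_leaf, resolve.root = TRUE,
            edgelabel = TRUE)
}

#' Leaves descending from the LCA of two reference leaves
#'
#' Used to restrict an analysis to the clade spanned by two reference taxa:
#' genomes outside the last common ancestor of the references fall outside
#' the established taxonomic framework and are discarded.
#'
#' @param tree A rooted \code{ape::phylo} tree.
#' @param ref_a,ref_b Leaf labels of the two reference taxa.
#' @return Character vector of leaf labels in the clade.
#' @export
clade_filter <- function(tree, ref_a, ref_b) {
  miss <- setdiff(c(ref_a, ref_b), tree$tip.label)
  if (length(miss)) stop("reference leaf/leaves not in tree: ",
                         paste(miss, collapse = ", "))
  if (ref_a == ref_b) return(ref_a)
  lca <- ape::getMRCA(tree, c(ref_a, ref_b))
  if (lca == ape::Ntip(tree) + 1L) return(tree$tip.label)
  ape::extract.clade(tree, lca)$tip.label
}

#' Minimum gain/loss events for a binary character on a tree
#'
#' Small-parsimony count of the minimum number of state changes (gains plus
#' losses, counted together and unweighted) needed to explain a binary
#' presence/absence character on a rooted tree. Computed by unit-cost
#' dynamic programming over ancestral states, which generalizes Fitch's
#' algorithm exactly to multifurcating nodes.
#'
#' @param tree A rooted \code{ape::phylo} tree; polytomies allowed.
#' @param character Named 0/1 vector with one state per tree leaf; every
#'   leaf must have a non-missing state.
#' @return Nonnegative integer: the minimum number of state changes.
#' @export
fitch_changes <- function(tree, character) {
  tips <- tree$tip.label
  miss <- setdiff(tips, names(character))
  if (length(miss)) stop("leaf/leaves without a character state: ",
                         paste(miss, collapse = ", "))
  states <- character[tips]
  if (any(is.na(states)) || !all(states %in% c(0, 1))) {
    stop("character states must be 0/1 with no missing values")
  }
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  # cost[node, s+1] = minimal changes in the subtree of `node` given state s;
  # postorder edge traversal guarantees children are finished before parents
  cost <- matrix(0, nrow = n_node, ncol = 2)
  cost[seq_len(n_tip), ] <- Inf
  cost[cbind(seq_len(n_tip), states + 1)] <- 0
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    cost[p, 1] <- cost[p, 1] + min(cost[ch, 1], cost[ch, 2] + 1)
    cost[p, 2] <- cost[p, 2] + min(cost[ch, 2], cost[ch, 1] + 1)
  }
  root <- n_tip + 1L
  as.integer(min(cost[root, ]))
}

#' Fitch event counts for every sugar of a pathway-call table
#'
#' @param tree Rooted species tree whose leaves are genome ids.
#' @param calls Pathway-call table from [call_pathways()], restricted to the
#'   tree's leaves.
#' @return Data frame with columns \code{sugar_id} and \code{min_changes}.
#' @export
fitch_changes_all <- function(tree, calls) {
  sugars <- sort(unique(calls$sugar_id))
  counts <- vapply(sugars, function(s) {
    sub <- calls[calls$sugar_id == s, , drop = FALSE]
    char <- stats::setNames(as.integer(sub$detected), sub$genome_id)
    fitch_changes(tree, char)
  }, integer(1))
  data.frame(sugar_id = sugars, min_changes = unname(counts),
             stringsAsFactors = FALSE)
}

# Shared quantile convention: medians and interquartile ranges use linear
# interpolation (stats::quantile type 7).
median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

#' Summarize event counts (or any per-sugar values) by group
#'
#' Reports the median and interquartile range (linear-interpolation
#' quantiles) of the values in each label group.
#'
#' @param values Data frame with an id column (first), a value column
#'   (second).
#' @param labels Data frame with matching id column (first) and a
#'   \code{label} column restricted to \code{core}/\code{accessory}.
#' @return Data frame with one row per group: \code{label}, \code{n},
#'   \code{q1}, \code{median}, \code{q3}.
#' @export
summarize_by_group <- function(values, labels) {
  lab <- labels$label[match(values[[1]], labels[[1]])]
  if (any(is.na(lab))) {
    stop("unlabeled id(s): ", paste(values[[1]][is.na(lab)], collapse = ", "))
  }
  keep <- lab %in% c("core", "accessory")
  values <- values[keep, , drop = FALSE]
  lab <- lab[keep]
  groups <- c("core", "accessory")
  if (!all(groups %in% lab)) {
    stop("group(s) empty: ", paste(setdiff(groups, lab), collapse = ", "))
  }
  rows <- lapply(groups, function(g) {
    x <- values[[2]][lab == g]
    q <- median_iqr(x)
    data.frame(label = g, n = length(x), q1 = q[["q1"]],
               median = q[["median"]], q3 = q[["q3"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname summarize_by_group
#' @param counts Data frame from [fitch_changes_all()].
#' @param labels Sugar labels from [classify_sugar_prevalence()].
#' @export
summarize_events <- function(counts, labels) {
  summarize_by_group(counts, labels)
}
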