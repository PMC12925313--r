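# Descendant tip index sets for every edge's child side, on the tree as
# stored. Together with their complements these are all bipartition sides of
# the unrooted topology.
bipartition_sides <- function(tree) {
  n_tip <- ape::Ntip(tree)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  below <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- i
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  sides <- below[edge[, 2]]
  c(sides, lapply(sides, function(s) setdiff(seq_len(n_tip), s)))
}

#' Monophyly score of a target leaf set in a gene tree
#'
#' The score is the size of the largest clade consisting exclusively of
#' target leaves, divided by the total number of targets. Clades are taken
#' in the rooting-invariant sense: each side of each bipartition (edge) of
#' the unrooted topology. A score of 1 means the targets are perfectly
#' monophyletic; lower values indicate the targets are scattered over
#' several independent lineages. Clades containing any non-target leaf never
#' count, however target-rich.
#'
#' @param tree An \code{ape::phylo} gene tree with at least 3 leaves.
#' @param targets Character vector of target leaf labels (non-empty, all
#'   present in the tree).
#' @return Fraction in \verb{[1/|targets|, 1]}.
#' @export
monophyly_score <- function(tree, targets) {
  stopifnot(length(targets) > 0)
  targets <- unique(targets)
  miss <- setdiff(targets, tree$tip.label)
  if (length(miss)) stop("target leaf/leaves not in tree: ",
                         paste(miss, collapse = ", "))
  if (ape::Ntip(tree) < 3) stop("tree must have at least 3 leaves")
  tgt <- which(tree$tip.label %in% targets)
  best <- 1L  # a single target leaf is always a clade
  for (side in bipartition_sides(tree)) {
    if (length(side) > best && all(side %in% tgt)) best <- length(side)
  }
  best / length(tgt)
}

# Numeric support values from internal node labels; NA where unparseable.
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

# Detect whether supports are on a [0,1] or [0,100] scale.
support_scale <- function(supports) {
  s <- supports[!is.na(supports)]
  if (length(s) == 0 || max(s) <= 1) "fraction" else "percent"
}

#' Support for the last common ancestor of a target leaf set
#'
#' The tree is rooted first (midpoint by default; FastTree output is
#' unrooted) and the support value stored at the LCA node of the targets is
#' returned. When the targets are monophyletic this is the support of the
#' bipartition separating them, which does not depend on the rooting. The
#' support is \code{NA} when the LCA is the root (no edge, hence no support
#' is defined) or carries no numeric label.
#'
#' @param tree An \code{ape::phylo} gene tree with supports as internal node
#'   labels.
#' @param targets Character vector of target leaf labels.
#' @param rooting \code{"midpoint"} (default) or \code{"as-read"} to use the
#'   tree exactly as stored.
#' @return Numeric support on the tree's own scale, or \code{NA}.
#' @export
lca_support <- function(tree, targets, rooting = c("midpoint", "as-read")) {
  rooting <- match.arg(rooting)
  targets <- unique(targets)
  miss <- setdiff(targets, tree$tip.label)
  if (length(miss)) stop("target leaf/leaves not in tree: ",
                         paste(miss, collapse = ", "))
  if (rooting == "midpoint") {
    tree <- phangorn::midpoint(tree, node.labels = "support")
  }
  n_tip <- ape::Ntip(tree)
  if (length(targets) == n_tip) return(NA_real_)
  lca <- if (length(targets) == 1) {
    tree$edge[tree$edge[, 2] == match(targets, tree$tip.label), 1]
  } else {
    ape::getMRCA(tree, targets)
  }
  if (lca == n_tip + 1L) return(NA_real_)
  node_supports(tree)[lca - n_tip]
}

#' Score one gene family for monophyly with the support-based filter
#'
#' Computes the monophyly score and the support of the targets' LCA, and
#' flags the family for inclusion: families whose LCA support is below the
#' threshold (or undefined, e.g. the LCA is the root or the targets span
#' all leaves) carry too little phylogenetic signal and are excluded from
#' group summaries. The threshold is given as a fraction and interpreted on
#' the tree's own support scale (auto-detected: values <= 1 are fractional,
#' otherwise percent).
#'
#' @inheritParams lca_support
#' @param family_id Identifier attached to the result row.
#' @param support_threshold Minimum LCA support as a fraction. Default 0.8;
#'   the comparison is inclusive, so support exactly at the threshold is
#'   kept.
#' @return One-row data frame: \code{family_id}, \code{score},
#'   \code{lca_support}, \code{included}.
#' @export
score_family <- function(tree, targets, support_threshold = 0.8,
                         family_id = NA_character_,
                         rooting = c("midpoint", "as-read")) {
  score <- monophyly_score(tree, targets)
  sup <- lca_support(tree, targets, rooting)
  thr <- support_threshold
  if (!is.na(sup) && support_scale(node_supports(tree)) == "percent") {
    thr <- support_threshold * 100
  }
  included <- !is.na(sup) && sup >= thr &&
    length(unique(targets)) < ape::Ntip(tree)
  data.frame(family_id = family_id, score = score, lca_support = sup,
             included = included, stringsAsFactors = FALSE)
}

#' Score every gene family in a directory of Newick trees
#'
#' @param trees_dir Directory with one Newick file per family
#'   (\code{<family_id>.nwk}).
#' @param targets_manifest Data frame with columns \code{family_id} and
#'   \code{leaf}, listing the target leaves of each family's tree.
#' @inheritParams score_family
#' @return Data frame with one row per family, as in [score_family()].
#' @export
score_families <- function(trees_dir, targets_manifest,
                           support_threshold = 0.8,
                           rooting = c("midpoint", "as-read")) {
  files <- list.files(trees_dir, pattern = "\\.nwk$", full.names = TRUE)
  if (length(files) == 0) stop("no .nwk gene trees found in ", trees_dir)
  rows <- lapply(files, function(f) {
    fam <- tools::file_path_sans_ext(basename(f))
    tr <- read_newick(f)
    tg <- targets_manifest$leaf[targets_manifest$family_id == fam]
    if (length(tg) == 0) {
      stop("no target leaves listed for family '", fam, "'")
    }
    score_family(tr, tg, support_threshold, family_id = fam,
                 rooting = rooting)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize monophyly scores by core/accessory group
#'
#' Only families passing the LCA-support filter (\code{included}) enter the
#' summary. Medians and interquartile ranges use the same
#' linear-interpolation quantile convention as [summarize_events()].
#'
#' @param results Data frame from [score_families()].
#' @param labels Data frame with \code{family_id} (first column) and
#'   \code{label} (\code{core}/\code{accessory}).
#' @return Group summary data frame, as in [summarize_by_group()].
#' @export
summarize_monophyly <- function(results, labels) {
  kept <- results[results$included, c("family_id", "score"), drop = FALSE]
  if (nrow(kept) == 0) stop("no families pass the support filter")
  summarize_by_group(kept, labels)
}
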