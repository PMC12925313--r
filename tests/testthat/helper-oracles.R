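# Independent brute-force oracles used to validate the package's
# implementations on small instances.

# Minimum number of state changes by exhaustive enumeration of all internal
# labelings (2^Nnode), counting mismatches across every edge.
brute_fitch <- function(tree, character) {
  states <- character[tree$tip.label]
  n_tip <- ape::Ntip(tree)
  m <- tree$Nnode
  best <- Inf
  for (mask in 0:(2^m - 1)) {
    internal <- as.integer(intToBits(mask))[seq_len(m)]
    full <- c(states, internal)
    changes <- sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# Monophyly score by explicit enumeration of every bipartition side using
# ape::prop.part (clades of the rooted representation plus complements and
# single leaves).
brute_monophyly <- function(tree, targets) {
  n_tip <- ape::Ntip(tree)
  tgt <- which(tree$tip.label %in% targets)
  clades <- ape::prop.part(tree)
  sides <- c(lapply(seq_len(n_tip), identity), unclass(clades))
  sides <- c(sides, lapply(sides, function(s) setdiff(seq_len(n_tip), s)))
  sizes <- vapply(sides, function(s) {
    if (length(s) > 0 && length(s) < n_tip && all(s %in% tgt)) length(s)
    else 0L
  }, integer(1))
  max(c(1L, sizes)) / length(tgt)
}

# Exact two-sided permutation p-value by direct enumeration of all
# regroupings, computed with sort-based medians.
brute_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  med <- function(x) {
    s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  obs <- abs(med(a) - med(b))
  idx <- utils::combn(length(pooled), n_a)
  stats <- vapply(seq_len(ncol(idx)), function(j) {
    abs(med(pooled[idx[, j]]) - med(pooled[-idx[, j]]))
  }, numeric(1))
  mean(stats >= obs - 1e-12 * (1 + obs))
}

# Random binary character over a tree's leaves (at least one of each state
# not guaranteed).
random_character <- function(tree) {
  stats::setNames(sample(0:1, ape::Ntip(tree), replace = TRUE),
                  tree$tip.label)
}

# A small hit table row for parser-free tests.
make_hit <- function(genome, family, orf, bitscore = 300, evalue = 1e-50,
                     from = 1L, to = 200L, len = 200L) {
  data.frame(genome_id = genome, family_id = family, orf_id = orf,
             bitscore = bitscore, evalue = evalue, hmm_from = from,
             hmm_to = to, profile_length = len, stringsAsFactors = FALSE)
}

# Minimal linear toy network: source -> X -> sugar, one gene per reaction.
toy_chain_network <- function() {
  load_network(list(
    metabolites = c("S", "X", "P"),
    sources = "S",
    reactions = list(
      list(id = "r1", substrate = "S", product = "X", genes = list("K1")),
      list(id = "r2", substrate = "X", product = "P", genes = list("K2"))),
    products = list(P = "r2")))
}

# Branched 12-reaction, 10-gene toy network with alternative routes and one
# isoenzyme/complex requirement; used for the exhaustive pathway-rule check.
toy_branched_network <- function() {
  list(
    metabolites = c("S1", "S2", "A", "B", "C", "D", "E", "P1", "P2", "P3"),
    sources = c("S1", "S2"),
    reactions = list(
      list(id = "r1",  substrate = "S1", product = "A",  genes = list("g1")),
      list(id = "r2",  substrate = "A",  product = "B",  genes = list("g2")),
      list(id = "r3",  substrate = "B",  product = "P1",
           genes = list("g3", c("g2", "g4"))),
      list(id = "r4",  substrate = "S2", product = "C",  genes = list("g4")),
      list(id = "r5",  substrate = "C",  product = "B",  genes = list("g5")),
      list(id = "r6",  substrate = "B",  product = "D",  genes = list("g6")),
      list(id = "r7",  substrate = "D",  product = "P2", genes = list("g7")),
      list(id = "r8",  substrate = "A",  product = "D",  genes = list("g8")),
      list(id = "r9",  substrate = "C",  product = "E",  genes = list("g9")),
      list(id = "r10", substrate = "E",  product = "P3", genes = list("g10")),
      list(id = "r11", substrate = "A",  product = "E",  genes = list("g2")),
      list(id = "r12", substrate = "D",  product = "E",  genes = list("g5"))),
    products = list(P1 = "r3", P2 = "r7", P3 = "r10"))
}

# Completeness oracle on a loaded network via igraph simple-path
# enumeration (requires no parallel metabolite edges, true for the toy
# networks above).
igraph_completeness <- function(net, sugar, genome_row) {
  edges <- do.call(rbind, lapply(net$reactions, function(r) {
    data.frame(from = r$substrate, to = r$product, rid = r$id,
               stringsAsFactors = FALSE)
  }))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = net$metabolites)
  target <- net$reactions[[net$products[[sugar]]]]$product
  present <- vapply(net$reactions, function(r) {
    any(vapply(r$genes, function(alt) all(genome_row[alt] == 1), logical(1)))
  }, logical(1))
  best <- 0
  for (src in net$sources) {
    paths <- igraph::all_simple_paths(g, from = src, to = target,
                                      mode = "out")
    for (p in paths) {
      eids <- igraph::get_edge_ids(g, rep(names(p), each = 2)[-c(1, 2 * length(p))])
      rids <- igraph::edge_attr(g, "rid", eids)
      best <- max(best, mean(present[rids]))
    }
  }
  best
}
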