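# Derive a reproducible substream seed from a master seed and a stage name,
# so each simulation stage can be regenerated independently.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the structure of a single-genus MAG study: 61 curated
#' genomes, 9 core and 12 accessory nucleotide-sugars, core pathways lost
#' rarely (root present) and accessory pathways gained and lost frequently
#' (root absent), gene trees in which the study's sequences appear as one
#' (core) or several (accessory) implanted clades among database background
#' sequences.
#'
#' @param n_taxa Number of curated genomes on the species tree. Default 61.
#' @param n_core,n_accessory Number of core / accessory sugars. Defaults 9
#'   and 12.
#' @param core_loss_prob Per-branch loss probability for core characters
#'   (root state present). Default 0.005.
#' @param accessory_gain_prob,accessory_loss_prob Per-branch flip
#'   probabilities for accessory characters (root state absent). Defaults
#'   0.08 each.
#' @param gene_tree_background Background leaves per gene tree. Default 40.
#' @param target_clade_count_range Inclusive range the number of implanted
#'   target clades is drawn from for accessory families (core families
#'   always use one clade). Default c(2, 4).
#' @param n_steps Reactions per simulated linear pathway. Default 3.
#' @param n_lowqual Extra genomes failing the quality filter. Default 3.
#' @param support_range Range of simulated branch supports (fractions).
#'   Default c(0.85, 1).
#' @param kingdom_beta_core,kingdom_beta_accessory Beta shape parameters
#'   (c(alpha, beta)) for kingdom-wide prevalence of core / accessory
#'   sugars. Defaults c(8, 2) and c(2, 5).
#' @param marker_family Marker gene family id. Default "K00937" (ppk1).
#' @param seed Master seed; all stage randomness derives from it.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_taxa = 61, n_core = 9, n_accessory = 12,
                       core_loss_prob = 0.005,
                       accessory_gain_prob = 0.08,
                       accessory_loss_prob = 0.08,
                       gene_tree_background = 40,
                       target_clade_count_range = c(2, 4),
                       n_steps = 3, n_lowqual = 3,
                       support_range = c(0.85, 1),
                       kingdom_beta_core = c(8, 2),
                       kingdom_beta_accessory = c(2, 5),
                       marker_family = "K00937",
                       seed = 1L) {
  cfg <- list(n_taxa = n_taxa, n_core = n_core, n_accessory = n_accessory,
              core_loss_prob = core_loss_prob,
              accessory_gain_prob = accessory_gain_prob,
              accessory_loss_prob = accessory_loss_prob,
              gene_tree_background = gene_tree_background,
              target_clade_count_range = target_clade_count_range,
              n_steps = n_steps, n_lowqual = n_lowqual,
              support_range = support_range,
              kingdom_beta_core = kingdom_beta_core,
              kingdom_beta_accessory = kingdom_beta_accessory,
              marker_family = marker_family, seed = as.integer(seed))
  probs <- c(cfg$core_loss_prob, cfg$accessory_gain_prob,
             cfg$accessory_loss_prob)
  if (any(probs < 0 | probs > 1)) stop("flip probabilities must lie in [0,1]")
  if (cfg$n_taxa < 3 || cfg$n_core < 1 || cfg$n_accessory < 1 ||
      cfg$n_steps < 1 || cfg$gene_tree_background < 2) {
    stop("inconsistent simulation config: counts too small")
  }
  if (length(cfg$target_clade_count_range) != 2 ||
      cfg$target_clade_count_range[1] < 1 ||
      diff(cfg$target_clade_count_range) < 0) {
    stop("target_clade_count_range must be an increasing pair >= 1")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Yule topology as a Newick string: start from a cherry, then repeatedly
# split a uniformly chosen extant tip.
yule_topology <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 2)
  if (n == 2) return(paste0("(", labels[1], ",", labels[2], ");"))
  nwk <- paste0("(", labels[1], ",", labels[2], ");")
  extant <- labels[1:2]
  for (i in 3:n) {
    pick <- extant[sample.int(length(extant), 1)]
    nwk <- sub(paste0("(?<![A-Za-z0-9_])", pick, "(?![A-Za-z0-9_])"),
               paste0("(", pick, ",", labels[i], ")"), nwk, perl = TRUE)
    extant <- c(extant, labels[i])
  }
  nwk
}

#' Simulate a species tree
#'
#' Random bifurcating topology from a Yule split process (a uniformly chosen
#' extant lineage bifurcates at each step), exponential branch lengths, and
#' branch supports drawn uniformly from \code{support_range}.
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param seed Integer seed.
#' @param labels Optional leaf labels; default \code{g001, g002, ...}.
#' @param support_range Range of simulated supports. Default c(0.85, 1).
#' @return A rooted \code{ape::phylo} tree with supports as node labels.
#' @export
simulate_species_tree <- function(n_taxa, seed = NULL, labels = NULL,
                                  support_range = c(0.85, 1)) {
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- sprintf("g%03d", seq_len(n_taxa))
  tree <- ape::read.tree(text = yule_topology(labels))
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 10)
  tree$node.label <- c("", sprintf("%.3f", stats::runif(
    tree$Nnode - 1, support_range[1], support_range[2])))
  tree
}

#' Evolve a binary presence/absence character along a tree
#'
#' The root state propagates towards the tips; on each branch the state
#' flips with probability \code{gain_prob} (0 to 1) or \code{loss_prob}
#' (1 to 0). Every flip is recorded as an event, giving the ground truth
#' against which parsimony reconstructions can be compared.
#'
#' @param tree A rooted \code{ape::phylo} tree.
#' @param gain_prob,loss_prob Per-branch flip probabilities.
#' @param root_state 0 or 1.
#' @param seed Optional integer seed.
#' @return List with \code{character} (named 0/1 vector over the leaves)
#'   and \code{events} (data frame: \code{edge}, \code{child_node},
#'   \code{type}, \code{n_desc}).
#' @export
simulate_character <- function(tree, gain_prob, loss_prob, root_state = 1,
                               seed = NULL) {
  stopifnot(gain_prob >= 0, gain_prob <= 1, loss_prob >= 0, loss_prob <= 1,
            root_state %in% c(0, 1))
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  n_tip <- ape::Ntip(tr)
  state <- integer(n_tip + tr$Nnode)
  state[n_tip + 1L] <- root_state
  n_desc_below <- function(node) {
    if (node <= n_tip) 1L else length(ape::extract.clade(tr, node)$tip.label)
  }
  ev <- list()
  u <- stats::runif(nrow(tr$edge))
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
    s <- state[p]
    flip <- if (s == 1) u[i] < loss_prob else u[i] < gain_prob
    state[ch] <- if (flip) 1L - s else s
    if (flip) {
      ev[[length(ev) + 1L]] <- data.frame(
        edge = i, child_node = ch,
        type = if (s == 1) "loss" else "gain",
        n_desc = n_desc_below(ch), stringsAsFactors = FALSE)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(edge = integer(), child_node = integer(), type = character(),
               n_desc = integer(), stringsAsFactors = FALSE)
  list(character = stats::setNames(state[seq_len(n_tip)], tr$tip.label),
       events = events)
}

# Partition m targets into k nonempty clade sizes, uniformly over
# compositions; returns sizes sorted decreasingly.
draw_clade_sizes <- function(m, k) {
  k <- min(k, m)
  if (k == 1) return(m)
  cuts <- sort(sample.int(m - 1, k - 1))
  sizes <- diff(c(0, cuts, m))
  sort(sizes, decreasing = TRUE)
}

#' Simulate a gene-family tree with implanted target clades
#'
#' Builds a Yule background tree of database-like sequences, then implants
#' the target leaves as \code{k} independent clades: the targets are
#' partitioned into \code{k} groups, each group becomes a Yule subtree, and
#' each subtree is attached next to a distinct background leaf. By
#' construction the largest clade consisting only of targets is the largest
#' implanted group, so the monophyly-score truth is
#' \code{max(sizes)/sum(sizes)}.
#'
#' @param targets Character vector of target leaf labels.
#' @param n_background Number of background leaves.
#' @param k Number of implanted clades (capped at \code{length(targets)}
#'   and at \code{n_background}).
#' @param prefix Label prefix for background leaves.
#' @param support_range Range of simulated supports.
#' @param seed Optional integer seed.
#' @return List with \code{tree} (\code{ape::phylo}), \code{clade_sizes}
#'   (decreasing) and \code{true_score}.
#' @export
simulate_gene_tree <- function(targets, n_background, k = 1,
                               prefix = "bg", support_range = c(0.85, 1),
                               seed = NULL) {
  stopifnot(length(targets) >= 1, n_background >= 2)
  if (!is.null(seed)) set.seed(seed)
  k <- min(k, length(targets), n_background)
  bg <- sprintf("%s%03d", prefix, seq_len(n_background))
  nwk <- yule_topology(bg)
  sizes <- draw_clade_sizes(length(targets), k)
  groups <- split(targets, rep(seq_along(sizes), sizes))
  anchors <- sample(bg, length(sizes))  # distinct attachment points
  for (j in seq_along(groups)) {
    grp <- groups[[j]]
    sub <- if (length(grp) == 1) grp else
      sub(";$", "", yule_topology(grp))
    nwk <- sub(paste0("(?<![A-Za-z0-9_])", anchors[j], "(?![A-Za-z0-9_])"),
               paste0("(", anchors[j], ",", sub, ")"), nwk, perl = TRUE)
  }
  tree <- ape::read.tree(text = nwk)
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 10)
  tree$node.label <- c("", sprintf("%.3f", stats::runif(
    tree$Nnode - 1, support_range[1], support_range[2])))
  list(tree = tree, clade_sizes = sizes,
       true_score = max(sizes) / sum(sizes))
}

# Linear reference network for the simulated sugars: each sugar gets its own
# chain of n_steps reactions from fructose-6-phosphate, each gated by one
# dedicated gene family.
simulated_network_config <- function(sugars, n_steps) {
  mets <- "F6P"
  reactions <- list()
  products <- list()
  for (s in sugars) {
    chain <- c("F6P",
               if (n_steps > 1) paste0(s, "_int", seq_len(n_steps - 1)),
               s)
    mets <- c(mets, chain[-1])
    for (i in seq_len(n_steps)) {
      rid <- paste0(s, "_r", i)
      reactions[[length(reactions) + 1L]] <- list(
        id = rid, substrate = chain[i], product = chain[i + 1],
        genes = list(list(paste0("K_", s, "_", i))))
    }
    products[[s]] <- paste0(s, "_r", n_steps)
  }
  list(metabolites = unique(mets), sources = "F6P", reactions = reactions,
       products = products)
}

sugar_families <- function(sugar, n_steps) paste0("K_", sugar, "_",
                                                  seq_len(n_steps))

#' Simulate a complete study dataset with known ground truth
#'
#' Generates everything the pipeline consumes: a species tree (with an
#' outgroup leaf for rooting), binary pathway characters evolved with low
#' turnover for core sugars and high turnover for accessory sugars, a
#' matching linear reference network, per-genome homology hit tables and a
#' quality table in the exact dialects the parsers read, per-family gene
#' trees with implanted target clades, a kingdom-wide prevalence table, and
#' a truth record sufficient to recompute every expected pipeline output.
#'
#' @param config A [sim_config()] object.
#' @return A \code{sim_bundle} list; see Details.
#' @details Bundle elements: \code{species_tree} (incl. outgroup leaf
#'   \code{OUTGROUP}), \code{checkm}, \code{profiles}, \code{hits},
#'   \code{gene_trees} (named list), \code{targets_manifest},
#'   \code{kingdom_prevalence}, \code{network_config} /\code{network},
#'   \code{clade_refs} (two leaves whose LCA spans all curated genomes),
#'   \code{truth} and the echoed \code{config}.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  genomes <- sprintf("g%03d", seq_len(cfg$n_taxa))
  sugars <- c(sprintf("sugar_core_%02d", seq_len(cfg$n_core)),
              sprintf("sugar_acc_%02d", seq_len(cfg$n_accessory)))
  sugar_class <- stats::setNames(
    rep(c("core", "accessory"), c(cfg$n_core, cfg$n_accessory)), sugars)

  ingroup <- simulate_species_tree(cfg$n_taxa,
                                   seed = substream_seed(cfg$seed, "tree"),
                                   labels = genomes,
                                   support_range = cfg$support_range)
  # graft the outgroup at a new root
  ing_str <- sub(";\\s*$", "", ape::write.tree(ingroup))
  species_tree <- ape::read.tree(
    text = paste0("(OUTGROUP:1.0,", ing_str, ");"))

  # two reference leaves whose LCA is the ingroup root
  root_children <- ingroup$edge[ingroup$edge[, 1] == ape::Ntip(ingroup) + 1L, 2]
  leaf_under <- function(node) {
    if (node <= ape::Ntip(ingroup)) ingroup$tip.label[node]
    else ape::extract.clade(ingroup, node)$tip.label[1]
  }
  clade_refs <- c(leaf_under(root_children[1]), leaf_under(root_children[2]))

  # pathway characters
  set.seed(substream_seed(cfg$seed, "characters"))
  characters <- list(); truth_events <- list()
  for (s in sugars) {
    sim <- if (sugar_class[s] == "core") {
      simulate_character(ingroup, gain_prob = 0,
                         loss_prob = cfg$core_loss_prob, root_state = 1)
    } else {
      simulate_character(ingroup, gain_prob = cfg$accessory_gain_prob,
                         loss_prob = cfg$accessory_loss_prob, root_state = 0)
    }
    characters[[s]] <- sim$character
    truth_events[[s]] <- sim$events
  }

  # gene families: one per reaction step, co-present with the sugar character
  families <- unlist(lapply(sugars, sugar_families, n_steps = cfg$n_steps))
  presence <- matrix(0L, nrow = cfg$n_taxa, ncol = length(families),
                     dimnames = list(genomes, families))
  for (s in sugars) {
    fams <- sugar_families(s, cfg$n_steps)
    presence[, fams] <- matrix(rep(characters[[s]][genomes], length(fams)),
                               ncol = length(fams))
  }

  # quality table: curated genomes pass, extras fail on either bound
  set.seed(substream_seed(cfg$seed, "checkm"))
  lowq <- if (cfg$n_lowqual > 0) sprintf("bad%02d", seq_len(cfg$n_lowqual))
          else character(0)
  checkm <- data.frame(
    genome_id = c(genomes, lowq),
    completeness = c(stats::runif(cfg$n_taxa, 92, 100),
                     stats::runif(cfg$n_lowqual, 50, 85)),
    contamination = c(stats::runif(cfg$n_taxa, 0, 3),
                      stats::runif(cfg$n_lowqual, 6, 15)),
    stringsAsFactors = FALSE)

  # profile metadata: half the families use KEGG-style bitscore thresholds,
  # half the E-value/coverage fallback; plus one under-supported decoy family
  profiles <- data.frame(
    family_id = c(cfg$marker_family, families, "K_decoy"),
    threshold = c(100, ifelse(seq_along(families) %% 2 == 0, 100, NA), NA),
    n_known_sequences = c(1000L, rep(1000L, length(families)), 50L),
    stringsAsFactors = FALSE)

  # hit tables in domtblout-equivalent form: marker hit for every genome,
  # one hit per present family, decoy hits everywhere
  set.seed(substream_seed(cfg$seed, "hits"))
  all_genomes <- c(genomes, lowq)
  hit_rows <- list()
  add_hit <- function(g, fam, i) {
    data.frame(genome_id = g, family_id = fam,
               orf_id = sprintf("%s_orf%04d", g, i),
               bitscore = round(stats::runif(1, 250, 600), 1),
               evalue = 10^(-stats::runif(1, 40, 120)),
               hmm_from = 3L, hmm_to = 198L, profile_length = 200L,
               stringsAsFactors = FALSE)
  }
  for (g in all_genomes) {
    i <- 0L
    i <- i + 1L; hit_rows[[length(hit_rows) + 1L]] <- add_hit(g, cfg$marker_family, i)
    i <- i + 1L; hit_rows[[length(hit_rows) + 1L]] <- add_hit(g, "K_decoy", i)
    fams <- if (g %in% genomes) families[presence[g, ] == 1L] else
      families[seq_len(min(3, length(families)))]
    for (fam in fams) {
      i <- i + 1L
      hit_rows[[length(hit_rows) + 1L]] <- add_hit(g, fam, i)
    }
  }
  hits <- do.call(rbind, hit_rows)

  # gene trees: targets are the genomes carrying the family, implanted as
  # one clade (core) or several (accessory)
  set.seed(substream_seed(cfg$seed, "genetrees"))
  gene_trees <- list(); manifest <- list(); truth_clades <- list()
  for (s in sugars) {
    for (fam in sugar_families(s, cfg$n_steps)) {
      tg <- genomes[presence[, fam] == 1L]
      if (length(tg) == 0) next
      k <- if (sugar_class[s] == "core") 1L else
        sample(seq(cfg$target_clade_count_range[1],
                   cfg$target_clade_count_range[2]), 1)
      gt <- simulate_gene_tree(tg, cfg$gene_tree_background, k,
                               prefix = paste0(fam, "_bg"),
                               support_range = cfg$support_range)
      gene_trees[[fam]] <- gt$tree
      manifest[[fam]] <- data.frame(family_id = fam, leaf = tg,
                                    stringsAsFactors = FALSE)
      truth_clades[[fam]] <- list(clade_sizes = gt$clade_sizes,
                                  true_score = gt$true_score)
    }
  }
  targets_manifest <- do.call(rbind, manifest)
  rownames(targets_manifest) <- NULL

  # kingdom-wide prevalence: common for core sugars, rare for accessory
  set.seed(substream_seed(cfg$seed, "kingdom"))
  kingdom <- data.frame(
    sugar_id = sugars,
    kingdom_prevalence = ifelse(
      sugar_class == "core",
      stats::rbeta(length(sugars), cfg$kingdom_beta_core[1],
                   cfg$kingdom_beta_core[2]),
      stats::rbeta(length(sugars), cfg$kingdom_beta_accessory[1],
                   cfg$kingdom_beta_accessory[2])),
    stringsAsFactors = FALSE)

  network_config <- simulated_network_config(sugars, cfg$n_steps)
  structure(list(
    species_tree = species_tree, ingroup_tree = ingroup, checkm = checkm,
    profiles = profiles, hits = hits, presence = presence,
    gene_trees = gene_trees, targets_manifest = targets_manifest,
    kingdom_prevalence = kingdom, network_config = network_config,
    network = load_network(network_config), clade_refs = clade_refs,
    outgroup = "OUTGROUP",
    truth = list(sugar_class = sugar_class, characters = characters,
                 events = truth_events, gene_clades = truth_clades,
                 low_quality = lowq),
    config = cfg
  ), class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("sim_bundle:", x$config$n_taxa, "genomes,", x$config$n_core, "core +",
      x$config$n_accessory, "accessory sugars,", length(x$gene_trees),
      "gene trees (seed", x$config$seed, ")\n")
  invisible(x)
}

# Render one hit row as a HMMER 3.x domtblout line (23 columns; the target
# is the ORF, the query the profile).
format_domtbl_lines <- function(hits) {
  vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    paste(h$orf_id, "-", 350L, h$family_id, "-", h$profile_length,
          format(h$evalue, digits = 3), h$bitscore, 0.1, 1, 1,
          format(h$evalue, digits = 3), format(h$evalue, digits = 3),
          h$bitscore, 0.1, h$hmm_from, h$hmm_to, 5L, 200L, 3L, 202L,
          0.95, "-", sep = " ")
  }, character(1))
}

#' Write a simulated dataset to disk in the pipeline's input dialects
#'
#' Emits \code{species.nwk}, \code{genetrees/<family>.nwk},
#' \code{domtbl/<genome>.tsv} (HMMER domtblout dialect), \code{checkm.tsv},
#' \code{profiles.tsv}, \code{kingdom_prevalence.tsv}, \code{targets.tsv},
#' \code{network.yaml} and \code{truth.json}.
#'
#' @param bundle A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "genetrees"), showWarnings = FALSE)
  dir.create(file.path(dir, "domtbl"), showWarnings = FALSE)
  write_newick(bundle$species_tree, file.path(dir, "species.nwk"))
  for (fam in names(bundle$gene_trees)) {
    write_newick(bundle$gene_trees[[fam]],
                 file.path(dir, "genetrees", paste0(fam, ".nwk")))
  }
  for (g in unique(bundle$hits$genome_id)) {
    h <- bundle$hits[bundle$hits$genome_id == g, , drop = FALSE]
    writeLines(c("# --- full sequence --- (domtblout)",
                 format_domtbl_lines(h)),
               file.path(dir, "domtbl", paste0(g, ".tsv")))
  }
  ck <- bundle$checkm
  names(ck) <- c("Bin Id", "Completeness", "Contamination")
  utils::write.table(ck, file.path(dir, "checkm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$profiles, file.path(dir, "profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$kingdom_prevalence,
                     file.path(dir, "kingdom_prevalence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$targets_manifest, file.path(dir, "targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(bundle$network_config, file.path(dir, "network.yaml"))
  truth <- bundle$truth
  truth$characters <- lapply(truth$characters, as.list)
  jsonlite::write_json(
    list(sugar_class = as.list(truth$sugar_class),
         n_events = lapply(truth$events, nrow),
         gene_clades = truth$gene_clades,
         low_quality = truth$low_quality,
         seed = bundle$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
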