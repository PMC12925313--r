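#' Assemble a pipeline run configuration
#'
#' Collects every stage threshold with the study-style defaults: genome
#' quality bounds (90% completeness, 5% contamination), homology-evidence
#' cutoffs (1e-20 E-value with 75% profile coverage when no family-specific
#' bitscore threshold exists, families with fewer than 200 known sequences
#' excluded), core fractions (genes inclusive at 0.9, sugars strict at
#' 0.9), pathway detection (75% route completeness plus terminal enzyme),
#' monophyly support filter (0.8) and 100000 permutations.
#'
#' @param domtbl_dir Directory of per-genome domtblout files.
#' @param checkm_file CheckM-style quality TSV.
#' @param profiles_file Profile metadata TSV.
#' @param species_tree_file Newick species tree (may include the outgroup).
#' @param network_file Reference network YAML.
#' @param genetrees_dir Directory of per-family gene trees (optional;
#'   monophyly stage skipped when NULL).
#' @param targets_file Target-leaf manifest TSV for the gene trees.
#' @param kingdom_file Kingdom-prevalence TSV (optional; kingdom test
#'   skipped when NULL).
#' @param out_dir Output directory.
#' @param outgroup Outgroup leaf label used to root the species tree
#'   (optional).
#' @param clade_refs Two leaf labels whose LCA bounds the accepted clade
#'   (optional).
#' @param marker_family Marker gene family id. Default "K00937".
#' @param min_completeness,max_contamination Genome quality bounds.
#' @param fallback_evalue,min_query_cover,min_known_seqs Homology cutoffs.
#' @param gene_core_fraction,sugar_core_fraction Core thresholds.
#' @param pathway_min_completeness Pathway detection threshold.
#' @param support_threshold Monophyly LCA-support threshold.
#' @param n_permutations,seed Permutation-test settings.
#' @return A \code{run_config} list.
#' @export
run_config <- function(domtbl_dir, checkm_file, profiles_file,
                       species_tree_file, network_file,
                       genetrees_dir = NULL, targets_file = NULL,
                       kingdom_file = NULL, out_dir = "glycopan_out",
                       outgroup = NULL, clade_refs = NULL,
                       marker_family = "K00937",
                       min_completeness = 90, max_contamination = 5,
                       fallback_evalue = 1e-20, min_query_cover = 0.75,
                       min_known_seqs = 200, gene_core_fraction = 0.9,
                       sugar_core_fraction = 0.9,
                       pathway_min_completeness = 0.75,
                       support_threshold = 0.8, n_permutations = 100000,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(min_completeness >= 0, min_completeness <= 100,
            max_contamination >= 0, fallback_evalue >= 0,
            min_query_cover >= 0, min_query_cover <= 1,
            gene_core_fraction >= 0, gene_core_fraction <= 1,
            sugar_core_fraction >= 0, sugar_core_fraction <= 1,
            pathway_min_completeness >= 0, pathway_min_completeness <= 1,
            support_threshold >= 0, support_threshold <= 1,
            n_permutations >= 1)
  class(cfg) <- "run_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes screen, pathways, events, monophyly and the permutation tests
#' in order, writing every intermediate table to the output directory along
#' with a machine-readable summary and an echo of the configuration. The
#' run is a pure function of (inputs, config, seed): repeated runs produce
#' identical tables.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with all intermediates and the summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  # --- screen -----------------------------------------------------------
  screened <- stage("screen", {
    checkm <- read_checkm(cfg$checkm_file)
    good <- filter_genomes(checkm, cfg$min_completeness,
                           cfg$max_contamination)
    profiles <- read_profile_meta(cfg$profiles_file)
    kept_profiles <- exclude_small_families(profiles, cfg$min_known_seqs)
    hits <- parse_domtbl_dir(cfg$domtbl_dir)
    hits <- apply_thresholds(hits, profiles, cfg$fallback_evalue,
                             cfg$min_query_cover)
    hits <- best_hit_per_family(hits)
    marker <- select_marker_genomes(hits, cfg$marker_family)
    list(checkm = checkm, good = good, profiles = profiles,
         kept_profiles = kept_profiles, hits = hits, marker = marker)
  })

  tree <- stage("tree", {
    tr <- read_newick(cfg$species_tree_file)
    if (!is.null(cfg$outgroup)) tr <- root_with_outgroup(tr, cfg$outgroup)
    tr
  })
  clade_ok <- stage("tree", {
    if (!is.null(cfg$clade_refs)) {
      clade_filter(tree, cfg$clade_refs[1], cfg$clade_refs[2])
    } else setdiff(tree$tip.label, cfg$outgroup)
  })

  genomes <- intersect(intersect(screened$good, screened$marker$genome_id),
                       clade_ok)
  if (length(genomes) == 0) {
    stop("pipeline stage 'screen' failed: no genome passes quality, ",
         "marker and clade filters", call. = FALSE)
  }
  families <- setdiff(screened$kept_profiles$family_id, cfg$marker_family)

  matrix <- stage("screen", {
    build_presence_matrix(screened$hits, genomes, families)
  })
  gene_labels <- classify_gene_prevalence(matrix, cfg$gene_core_fraction)

  # --- pathways ---------------------------------------------------------
  pathways <- stage("pathways", {
    network <- load_network(cfg$network_file)
    calls <- call_pathways(network, matrix, cfg$pathway_min_completeness)
    labels <- classify_sugar_prevalence(calls, cfg$sugar_core_fraction)
    list(network = network, calls = calls, labels = labels)
  })

  # --- events -----------------------------------------------------------
  events <- stage("events", {
    pruned <- ape::keep.tip(tree, genomes)
    counts <- fitch_changes_all(pruned, pathways$calls)
    list(tree = pruned, counts = counts)
  })
  event_summary <- stage("events", {
    summarize_events(events$counts, pathways$labels)
  })

  # --- monophyly --------------------------------------------------------
  monophyly <- NULL
  if (!is.null(cfg$genetrees_dir)) {
    monophyly <- stage("monophyly", {
      manifest <- utils::read.delim(cfg$targets_file, sep = "\t",
                                    stringsAsFactors = FALSE)
      res <- score_families(cfg$genetrees_dir, manifest,
                            cfg$support_threshold)
      smry <- tryCatch(summarize_monophyly(res, gene_labels),
                       error = function(e) {
                         warning("monophyly summary unavailable: ",
                                 conditionMessage(e), call. = FALSE)
                         NULL
                       })
      list(results = res, summary = smry)
    })
  }

  # --- tests ------------------------------------------------------------
  tests <- stage("test", {
    out <- list()
    out$events <- compare_groups(
      stats::setNames(events$counts$min_changes, events$counts$sugar_id),
      pathways$labels, cfg$n_permutations, seed = cfg$seed)
    if (!is.null(monophyly)) {
      kept <- monophyly$results[monophyly$results$included, ]
      # a group can end up with < 2 support-filtered families; report the
      # comparison as unavailable rather than abort the run
      out$monophyly <- tryCatch(
        compare_groups(stats::setNames(kept$score, kept$family_id),
                       gene_labels, cfg$n_permutations,
                       seed = cfg$seed + 1L),
        error = function(e) {
          warning("monophyly group comparison unavailable: ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
    }
    if (!is.null(cfg$kingdom_file)) {
      kingdom <- utils::read.delim(cfg$kingdom_file, sep = "\t",
                                   stringsAsFactors = FALSE)
      out$kingdom <- kingdom_prevalence_test(
        kingdom, pathways$labels, cfg$n_permutations, seed = cfg$seed + 2L)
    }
    out
  })

  # --- outputs ----------------------------------------------------------
  w <- function(df, name) {
    utils::write.table(df, file.path(cfg$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_presence_matrix(matrix, file.path(cfg$out_dir, "presence_matrix.tsv"))
  w(gene_labels, "gene_prevalence.tsv")
  w(pathways$calls, "pathway_calls.tsv")
  w(pathways$labels, "sugar_prevalence.tsv")
  w(events$counts, "event_counts.tsv")
  w(event_summary, "event_summary.tsv")
  heat <- render_heatmap_table(pathways$calls, events$tree)
  write_presence_matrix(heat, file.path(cfg$out_dir, "heatmap_matrix.tsv"))
  if (!is.null(monophyly)) {
    w(monophyly$results, "monophyly_scores.tsv")
    if (!is.null(monophyly$summary)) {
      w(monophyly$summary, "monophyly_summary.tsv")
    }
  }
  test_rows <- lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(test = nm, median_core = t$median_a,
               median_accessory = t$median_b,
               statistic = t$statistic_observed, p_value = t$p_value,
               n_permutations = t$n_permutations, exact = t$exact,
               seed = t$seed, stringsAsFactors = FALSE)
  })
  test_table <- do.call(rbind, test_rows)
  w(test_table, "permutation_tests.tsv")

  summary <- list(
    n_genomes = length(genomes),
    core_sugars = pathways$labels$sugar_id[pathways$labels$label == "core"],
    accessory_sugars =
      pathways$labels$sugar_id[pathways$labels$label == "accessory"],
    event_summary = event_summary,
    monophyly_summary = if (!is.null(monophyly)) monophyly$summary,
    p_values = stats::setNames(test_table$p_value, test_table$test),
    seed = cfg$seed,
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "columns")
  cfg_echo <- cfg
  class(cfg_echo) <- NULL
  yaml::write_yaml(cfg_echo, file.path(cfg$out_dir, "config_echo.yaml"))

  invisible(list(genomes = genomes, matrix = matrix,
                 gene_labels = gene_labels, pathways = pathways,
                 events = events, event_summary = event_summary,
                 monophyly = monophyly, tests = tests,
                 test_table = test_table, summary = summary))
}

#' Order pathway calls as a tree-aligned heatmap matrix
#'
#' Rows follow the species tree's leaf traversal order so the matrix can be
#' plotted next to the dendrogram; columns are the sugars in alphabetical
#' order; cells are 0/1 detection calls.
#'
#' @param calls Pathway-call table from [call_pathways()].
#' @param tree Species tree containing every genome in \code{calls}.
#' @return Integer 0/1 matrix, genomes x sugars.
#' @export
render_heatmap_table <- function(calls, tree) {
  genomes <- unique(calls$genome_id)
  miss <- setdiff(genomes, tree$tip.label)
  if (length(miss)) stop("genome(s) absent from tree: ",
                         paste(miss, collapse = ", "))
  order <- tree$tip.label[tree$tip.label %in% genomes]
  sugars <- sort(unique(calls$sugar_id))
  m <- matrix(0L, nrow = length(order), ncol = length(sugars),
              dimnames = list(order, sugars))
  m[cbind(match(calls$genome_id, order), match(calls$sugar_id, sugars))] <-
    as.integer(calls$detected)
  m
}
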