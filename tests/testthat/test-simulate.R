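test_that("simulate_species_tree yields a reproducible bifurcating tree", {
  tr <- simulate_species_tree(61, seed = 4)
  expect_equal(ape::Ntip(tr), 61)
  expect_equal(tr$Nnode, 60)
  expect_true(ape::is.binary(tr))
  tr2 <- simulate_species_tree(61, seed = 4)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  expect_false(identical(ape::write.tree(tr),
                         ape::write.tree(simulate_species_tree(61, seed = 5))))
  expect_error(simulate_species_tree(2), "n_taxa")
})

test_that("simulate_character records every flip and honors extremes", {
  tr <- simulate_species_tree(20, seed = 1)
  none <- simulate_character(tr, gain_prob = 0, loss_prob = 0,
                             root_state = 1)
  expect_true(all(none$character == 1))
  expect_equal(nrow(none$events), 0)
  all_loss <- simulate_character(tr, gain_prob = 0, loss_prob = 1,
                                 root_state = 1)
  expect_true(all(all_loss$character %in% c(0, 1)))
  # loss on both root edges forces everything below to flip back and forth;
  # tips under an even number of flips end at 1, odd at 0 -- just check
  # determinism and event bookkeeping
  rep1 <- simulate_character(tr, 0.1, 0.1, 1, seed = 8)
  rep2 <- simulate_character(tr, 0.1, 0.1, 1, seed = 8)
  expect_identical(rep1$character, rep2$character)
  expect_identical(rep1$events, rep2$events)
})

test_that("parsimony count never exceeds the simulated event count", {
  tr <- simulate_species_tree(40, seed = 2)
  set.seed(21)
  for (i in 1:30) {
    sim <- simulate_character(tr, gain_prob = 0.06, loss_prob = 0.06,
                              root_state = sample(0:1, 1))
    expect_lte(fitch_changes(tr, sim$character), nrow(sim$events))
  }
})

test_that("events on edge-disjoint subtrees are recovered exactly", {
  # place single gains on two disjoint cherries of a fixed topology
  tr <- read_newick("(((A,B),(C,D)),((E,F),(G,H)));")
  ch <- c(A = 1, B = 1, C = 0, D = 0, E = 0, F = 0, G = 1, H = 1)
  expect_equal(fitch_changes(tr, ch), 2)
})

test_that("simulate_dataset has the configured dimensions and classes", {
  b <- simulate_dataset(sim_config(seed = 7))
  expect_equal(ape::Ntip(b$ingroup_tree), 61)
  expect_equal(ape::Ntip(b$species_tree), 62)  # + outgroup
  expect_true("OUTGROUP" %in% b$species_tree$tip.label)
  expect_equal(dim(b$presence), c(61, (9 + 12) * b$config$n_steps))
  expect_equal(sum(b$truth$sugar_class == "core"), 9)
  expect_equal(sum(b$truth$sugar_class == "accessory"), 12)
  expect_equal(nrow(b$checkm), 61 + 3)
  # low-quality genomes fail the filter, curated ones pass
  kept <- filter_genomes(b$checkm)
  expect_setequal(kept, sprintf("g%03d", 1:61))
  # identical seed reproduces the bundle
  b2 <- simulate_dataset(sim_config(seed = 7))
  expect_identical(b$presence, b2$presence)
  expect_identical(ape::write.tree(b$species_tree),
                   ape::write.tree(b2$species_tree))
})

test_that("core characters without loss are fixed at prevalence 1", {
  cfg <- sim_config(seed = 3, core_loss_prob = 0)
  b <- simulate_dataset(cfg)
  core_sugars <- names(b$truth$sugar_class)[b$truth$sugar_class == "core"]
  for (s in core_sugars) {
    expect_true(all(b$truth$characters[[s]] == 1))
  }
})

test_that("written dataset round-trips through the parsers", {
  dir <- withr::local_tempdir()
  b <- simulate_dataset(sim_config(seed = 12))
  write_dataset(b, dir)
  # hit tables re-parse to the same surviving hits
  hits <- parse_domtbl_dir(file.path(dir, "domtbl"))
  expect_setequal(unique(hits$genome_id), unique(b$hits$genome_id))
  expect_equal(nrow(hits), nrow(b$hits))
  ck <- read_checkm(file.path(dir, "checkm.tsv"))
  expect_equal(ck$genome_id, b$checkm$genome_id)
  expect_equal(ck$completeness, b$checkm$completeness, tolerance = 1e-6)
  net <- load_network(file.path(dir, "network.yaml"))
  expect_setequal(names(net$products), names(b$network$products))
  tr <- read_newick(file.path(dir, "species.nwk"))
  expect_setequal(tr$tip.label, b$species_tree$tip.label)
  gt_files <- list.files(file.path(dir, "genetrees"))
  expect_equal(length(gt_files), length(b$gene_trees))
  # monophyly truth holds on the emitted gene trees
  fam <- names(b$gene_trees)[1]
  tgt <- b$targets_manifest$leaf[b$targets_manifest$family_id == fam]
  expect_equal(monophyly_score(read_newick(
    file.path(dir, "genetrees", paste0(fam, ".nwk"))), tgt),
    b$truth$gene_clades[[fam]]$true_score)
})

test_that("gene-tree monophyly truth holds for every simulated family", {
  b <- simulate_dataset(sim_config(seed = 9))
  for (fam in names(b$gene_trees)) {
    tgt <- b$targets_manifest$leaf[b$targets_manifest$family_id == fam]
    expect_equal(monophyly_score(b$gene_trees[[fam]], tgt),
                 b$truth$gene_clades[[fam]]$true_score, info = fam)
  }
})
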