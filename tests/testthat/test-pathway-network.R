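test_that("load_network validates structure and reachability", {
  net <- toy_chain_network()
  expect_s3_class(net, "reference_network")
  expect_named(net$products, "P")

  bad_terminal <- list(
    metabolites = c("S", "P"), sources = "S",
    reactions = list(list(id = "r1", substrate = "S", product = "P",
                          genes = list("K1"))),
    products = list(P = "rMissing"))
  expect_error(load_network(bad_terminal), "rMissing")

  undeclared <- list(
    metabolites = c("S", "P"), sources = "S",
    reactions = list(list(id = "r1", substrate = "S", product = "Q",
                          genes = list("K1"))),
    products = list(P = "r1"))
  expect_error(load_network(undeclared), "Q")

  unreachable <- list(
    metabolites = c("S", "X", "P"), sources = "S",
    reactions = list(list(id = "r1", substrate = "X", product = "P",
                          genes = list("K1"))),
    products = list(P = "r1"))
  expect_error(load_network(unreachable), "unreachable")
})

test_that("reaction_present applies OR over isoenzymes, AND within complexes", {
  r_or <- list(id = "r", substrate = "a", product = "b",
               genes = list("K1", "K2"))
  r_and <- list(id = "r", substrate = "a", product = "b",
                genes = list(c("K1", "K2")))
  row <- c(K1 = 0L, K2 = 1L)
  expect_true(reaction_present(r_or, row))
  expect_false(reaction_present(r_and, row))
  expect_true(reaction_present(r_and, c(K1 = 1L, K2 = 1L)))
  expect_true(reaction_present(list(id = "r", genes = list("K1")),
                               c(K1 = 1L)))
  expect_error(reaction_present(r_or, c(K1 = 1L)), "K2")
})

linear4_network <- function() {
  load_network(list(
    metabolites = c("S", "A", "B", "C", "P"), sources = "S",
    reactions = list(
      list(id = "r1", substrate = "S", product = "A", genes = list("K1")),
      list(id = "r2", substrate = "A", product = "B", genes = list("K2")),
      list(id = "r3", substrate = "B", product = "C", genes = list("K3")),
      list(id = "r4", substrate = "C", product = "P", genes = list("K4"))),
    products = list(P = "r4")))
}

test_that("pathway_completeness counts present reactions along best route", {
  net <- linear4_network()
  all4 <- c(K1 = 1L, K2 = 1L, K3 = 1L, K4 = 1L)
  expect_equal(pathway_completeness(net, "P", all4), 1.0)
  expect_equal(pathway_completeness(net, "P",
                                    c(K1 = 1L, K2 = 1L, K3 = 1L, K4 = 0L)),
               0.75)
  # two routes: short (length 2, 1 present) vs long (length 4, all present)
  net2 <- load_network(list(
    metabolites = c("S", "A", "B", "C", "X", "P"), sources = "S",
    reactions = list(
      list(id = "l1", substrate = "S", product = "A", genes = list("K1")),
      list(id = "l2", substrate = "A", product = "B", genes = list("K2")),
      list(id = "l3", substrate = "B", product = "C", genes = list("K3")),
      list(id = "l4", substrate = "C", product = "P", genes = list("K4")),
      list(id = "s1", substrate = "S", product = "X", genes = list("K5")),
      list(id = "s2", substrate = "X", product = "P", genes = list("K6"))),
    products = list(P = "l4")))
  row <- c(K1 = 1L, K2 = 1L, K3 = 1L, K4 = 1L, K5 = 1L, K6 = 0L)
  expect_equal(pathway_completeness(net2, "P", row), 1.0)
})

test_that("call_pathway requires both completeness and the terminal enzyme", {
  net <- linear4_network()
  # complete route but terminal enzyme absent -> not detected
  no_term <- call_pathway(net, "P", c(K1 = 1L, K2 = 1L, K3 = 1L, K4 = 0L),
                          min_completeness = 0.5)
  expect_equal(no_term$completeness, 0.75)
  expect_false(no_term$terminal_present)
  expect_false(no_term$detected)
  at_thresh <- call_pathway(net, "P", c(K1 = 1L, K2 = 1L, K3 = 0L, K4 = 1L))
  expect_equal(at_thresh$completeness, 0.75)
  expect_true(at_thresh$detected)  # 0.75 meets the threshold, terminal on
  low <- call_pathway(net, "P", c(K1 = 1L, K2 = 0L, K3 = 0L, K4 = 1L))
  expect_false(low$detected)
})

test_that("completeness is monotone in gene presence", {
  net <- load_network(toy_branched_network())
  genes <- paste0("g", 1:10)
  set.seed(11)
  for (i in 1:50) {
    row <- stats::setNames(sample(0:1, 10, replace = TRUE), genes)
    off <- which(row == 0)
    if (length(off) == 0) next
    row2 <- row
    row2[sample(off, 1)] <- 1L
    for (s in names(net$products)) {
      expect_gte(pathway_completeness(net, s, row2),
                 pathway_completeness(net, s, row))
    }
  }
})

test_that("detected sugars always have their terminal reaction present", {
  net <- load_network(toy_branched_network())
  genes <- paste0("g", 1:10)
  set.seed(5)
  m <- matrix(sample(0:1, 10 * 30, replace = TRUE), nrow = 30,
              dimnames = list(sprintf("g%02d", 1:30), genes))
  calls <- call_pathways(net, m)
  expect_true(all(calls$completeness >= 0 & calls$completeness <= 1))
  expect_true(all(!calls$detected | calls$terminal_present))
})

test_that("classify_sugar_prevalence uses a strict core threshold", {
  mk_calls <- function(n_detected, n = 61, sugar = "s") {
    data.frame(genome_id = sprintf("g%02d", 1:n), sugar_id = sugar,
               completeness = 1, terminal_present = TRUE,
               detected = seq_len(n) <= n_detected, stringsAsFactors = FALSE)
  }
  calls <- rbind(mk_calls(60, sugar = "s60"), mk_calls(55, sugar = "s55"),
                 mk_calls(30, sugar = "s30"), mk_calls(0, sugar = "s0"))
  lab <- classify_sugar_prevalence(calls)
  expect_identical(lab$label[lab$sugar_id == "s60"], "core")   # 0.984
  expect_identical(lab$label[lab$sugar_id == "s55"], "core")   # 0.902 > 0.9
  expect_identical(lab$label[lab$sugar_id == "s30"], "accessory")
  expect_identical(lab$label[lab$sugar_id == "s0"], "absent")
  # exactly at the threshold stays accessory under the strict rule
  calls9 <- mk_calls(9, n = 10, sugar = "s9of10")
  expect_identical(classify_sugar_prevalence(calls9)$label, "accessory")
})

test_that("the shipped reference network loads and is fully reachable", {
  path <- system.file("extdata", "nucleotide_sugar_network.yaml",
                      package = "glycopan")
  net <- load_network(path)
  expect_gt(length(net$products), 5)
  all_genes <- unique(unlist(lapply(net$reactions, function(r) r$genes)))
  row <- stats::setNames(rep(1L, length(all_genes)), all_genes)
  for (s in names(net$products)) {
    expect_equal(pathway_completeness(net, s, row), 1.0)
  }
})
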