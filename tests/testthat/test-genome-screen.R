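test_that("filter_genomes enforces both quality bounds and is idempotent", {
  rec <- data.frame(
    genome_id = c("a", "b", "c", "d", "e"),
    completeness = c(95, 89.9, 95, 50, 90),
    contamination = c(2, 2, 5.1, 1, 5),
    stringsAsFactors = FALSE)
  kept <- filter_genomes(rec)
  expect_identical(kept, c("a", "e"))  # boundary values 90 / 5 are kept
  # idempotence
  again <- filter_genomes(rec[rec$genome_id %in% kept, ])
  expect_identical(again, kept)
})

test_that("filter_genomes rejects invalid records naming the genome", {
  rec <- data.frame(genome_id = c("ok", "neg"),
                    completeness = c(95, 95),
                    contamination = c(1, -2), stringsAsFactors = FALSE)
  expect_error(filter_genomes(rec), "neg")
  rec2 <- data.frame(genome_id = "over", completeness = 101,
                     contamination = 0, stringsAsFactors = FALSE)
  expect_error(filter_genomes(rec2), "over")
})

domtbl_fixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "gX.tsv")
  writeLines(lines, path)
  path
}

domtbl_line <- function(orf, fam, evalue = "1e-50", score = "250.0",
                        qlen = "200", hfrom = "10", hto = "190") {
  paste(orf, "-", "350", fam, "-", qlen, evalue, score, "0.1", "1", "1",
        evalue, evalue, score, "0.1", hfrom, hto, "5", "200", "3", "202",
        "0.95", "-")
}

test_that("parse_domtbl reads domain lines and skips comments", {
  path <- domtbl_fixture(c(
    "#                     --- full sequence ---",
    "# target name  accession  tlen  query name ...",
    domtbl_line("orf1", "K00001"),
    domtbl_line("orf2", "K00001", hfrom = "100", hto = "180"),
    domtbl_line("orf1", "K00002")))
  hits <- parse_domtbl(path)
  expect_equal(nrow(hits), 3)
  expect_identical(hits$genome_id, rep("gX", 3))
  expect_identical(hits$family_id, c("K00001", "K00001", "K00002"))
  expect_equal(hits$hmm_from[2], 100L)
  expect_equal(hits$profile_length, rep(200L, 3))
})

test_that("parse_domtbl handles empty files and flags truncated lines", {
  empty <- domtbl_fixture(c("# only", "# comments"))
  expect_equal(nrow(parse_domtbl(empty)), 0)
  trunc <- domtbl_fixture(c(domtbl_line("orf1", "K1"), "orf2 - 350 K1 -"))
  expect_error(parse_domtbl(trunc), "line 2")
})

test_that("apply_thresholds keeps KEGG-thresholded and fallback-passing hits", {
  profiles <- data.frame(
    family_id = c("Kthr", "Kfree"),
    threshold = c(100, NA),
    n_known_sequences = c(500L, 500L), stringsAsFactors = FALSE)
  hits <- rbind(
    make_hit("g1", "Kfree", "o1", evalue = 1e-21, from = 1L, to = 160L),
    make_hit("g1", "Kfree", "o2", evalue = 1e-19, from = 1L, to = 180L),
    make_hit("g1", "Kthr", "o3", bitscore = 120, evalue = 1, from = 1L,
             to = 20L),
    make_hit("g1", "Kthr", "o4", bitscore = 80))
  kept <- apply_thresholds(hits, profiles)
  # o1: no threshold, 1e-21 <= 1e-20, cover 0.80 -> kept
  # o2: 1e-19 fails the E-value cutoff despite cover 0.90
  # o3: bitscore 120 >= 100 -> kept regardless of cover/evalue
  # o4: bitscore below the family threshold
  expect_setequal(kept$orf_id, c("o1", "o3"))
  expect_error(apply_thresholds(make_hit("g1", "Kxx", "o9"), profiles),
               "Kxx")
})

test_that("apply_thresholds merges multi-domain coverage by span union", {
  profiles <- data.frame(family_id = "Kfree", threshold = NA,
                         n_known_sequences = 500L, stringsAsFactors = FALSE)
  # two domains of one ORF covering 1-100 and 81-160: union 160/200 = 0.80
  hits <- rbind(make_hit("g1", "Kfree", "o1", from = 1L, to = 100L),
                make_hit("g1", "Kfree", "o1", from = 81L, to = 160L))
  kept <- apply_thresholds(hits, profiles)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$cover, 0.80)
  # disjoint domains 1-50 and 141-160: union 70/200 = 0.35 -> dropped
  hits2 <- rbind(make_hit("g1", "Kfree", "o1", from = 1L, to = 50L),
                 make_hit("g1", "Kfree", "o1", from = 141L, to = 160L))
  expect_equal(nrow(apply_thresholds(hits2, profiles)), 0)
})

test_that("apply_thresholds with no cutoffs is the identity on hit pairs", {
  profiles <- data.frame(family_id = c("K1", "K2"), threshold = NA,
                         n_known_sequences = 500L, stringsAsFactors = FALSE)
  hits <- rbind(make_hit("g1", "K1", "o1", from = 1L, to = 10L),
                make_hit("g2", "K2", "o2", evalue = 1))
  kept <- apply_thresholds(hits, profiles, fallback_evalue = Inf,
                           min_query_cover = 0)
  expect_equal(nrow(kept), nrow(hits))
  expect_lte(nrow(apply_thresholds(hits, profiles)), nrow(hits))
})

test_that("exclude_small_families uses a strict lower bound", {
  pr <- data.frame(family_id = c("a", "b", "c"), threshold = NA,
                   n_known_sequences = c(199L, 200L, 0L),
                   stringsAsFactors = FALSE)
  expect_identical(exclude_small_families(pr)$family_id, "b")
  expect_identical(exclude_small_families(pr, 0)$family_id, pr$family_id)
})

test_that("best_hit_per_family keeps the top bitscore with stated tie-breaks", {
  hits <- rbind(
    make_hit("g1", "K1", "oLow", bitscore = 50),
    make_hit("g1", "K1", "oHigh", bitscore = 70),
    make_hit("g1", "K2", "oB", bitscore = 70, evalue = 1e-25),
    make_hit("g1", "K2", "oA", bitscore = 70, evalue = 1e-30),
    make_hit("g2", "K1", "only"))
  best <- best_hit_per_family(hits)
  expect_equal(nrow(best), 3)
  expect_identical(best$orf_id[best$genome_id == "g1" &
                                 best$family_id == "K1"], "oHigh")
  expect_identical(best$orf_id[best$genome_id == "g1" &
                                 best$family_id == "K2"], "oA")
  expect_identical(best$orf_id[best$genome_id == "g2"], "only")
})

test_that("build_presence_matrix is binary, idempotent and order-invariant", {
  hits <- rbind(make_hit("g1", "K1", "o1"),
                make_hit("g1", "K1", "o2"),   # duplicate pair -> still 1
                make_hit("g2", "K2", "o3"))
  m <- build_presence_matrix(hits, c("g1", "g2", "g3"), c("K1", "K2"))
  expect_equal(m, matrix(c(1L, 0L, 0L, 0L, 1L, 0L), nrow = 3,
                         dimnames = list(c("g1", "g2", "g3"),
                                         c("K1", "K2"))))
  shuffled <- hits[c(3, 1, 2), ]
  expect_equal(build_presence_matrix(shuffled, c("g1", "g2", "g3"),
                                     c("K1", "K2")), m)
  empty <- build_presence_matrix(hits[0, ], c("g1"), c("K1"))
  expect_true(all(empty == 0))
})

test_that("classify_gene_prevalence partitions families with inclusive core rule", {
  m <- matrix(0L, nrow = 61, ncol = 3,
              dimnames = list(sprintf("g%02d", 1:61), c("a", "b", "c")))
  m[1:55, "a"] <- 1L  # 55/61 = 0.902 >= 0.9 -> core
  m[1:54, "b"] <- 1L  # 54/61 = 0.885 -> accessory
  lab <- classify_gene_prevalence(m)
  expect_identical(lab$label, c("core", "accessory", "absent"))
  # monotonicity: raising the threshold never promotes accessory to core
  lab99 <- classify_gene_prevalence(m, 0.99)
  promoted <- lab$label == "accessory" & lab99$label == "core"
  expect_false(any(promoted))
})

test_that("select_marker_genomes keeps best marker ORF and drops hitless genomes", {
  hits <- rbind(make_hit("g1", "K00937", "oA", bitscore = 100),
                make_hit("g1", "K00937", "oB", bitscore = 200),
                make_hit("g2", "Kother", "oC"))
  sel <- select_marker_genomes(hits, "K00937")
  expect_equal(sel, data.frame(genome_id = "g1", orf_id = "oB",
                               stringsAsFactors = FALSE))
  expect_equal(nrow(select_marker_genomes(hits[0, ], "K00937")), 0)
})

test_that("presence matrix round-trips through TSV", {
  m <- matrix(sample(0:1, 12, replace = TRUE), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("K1", "K2", "K3", "K4")))
  storage.mode(m) <- "integer"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_presence_matrix(m, path)
  expect_equal(read_presence_matrix(path), m)
})
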