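# Helpers building the partitions reconcile operates on.
labs <- function(...) {
  v <- c(...)
  stats::setNames(as.integer(match(v, unique(v))), names(v))
}

test_that("cells are the intersection of the two COI partitions", {
  bin <- mkPartition(labs(a = 1, b = 1, c = 2), "threshold@0.022")
  ab <- mkPartition(labs(a = 1, b = 2, c = 2), "abgd")
  s16 <- mkPartition(labs(a = 1, b = 1, c = 1), "16s")
  rc <- refineCells(bin, ab, s16)
  expect_equal(unname(groupLabels(rc$partition)), c(1L, 2L, 3L))
  expect_length(rc$unassigned, 0)

  same <- refineCells(bin, bin, s16)
  expect_true(samePartition(groupLabels(same$partition), groupLabels(bin)))
})

test_that("specimens lacking COI join cells through their 16S cluster", {
  bin <- mkPartition(labs(a = 1, b = 2), "bin")
  ab <- mkPartition(labs(a = 1, b = 2), "abgd")
  # x shares a 16S cluster with b only -> joins b's cell; z's cluster has
  # no COI-bearing member -> founds a new cell
  s16 <- mkPartition(labs(a = 1, b = 2, x = 2, z = 3), "16s")
  rc <- refineCells(bin, ab, s16)
  lab <- groupLabels(rc$partition)
  expect_equal(lab[["x"]], lab[["b"]])
  expect_true(lab[["z"]] != lab[["a"]] && lab[["z"]] != lab[["b"]])

  s16amb <- mkPartition(labs(a = 1, b = 1, w = 1), "16s")
  bin2 <- mkPartition(labs(a = 1, b = 2), "bin")
  rc2 <- refineCells(bin2, bin2, s16amb)
  expect_identical(rc2$unassigned, "w")
  expect_false("w" %in% specimenIds(rc2$partition))
})

test_that("conspecific COI splits at one locality merge by rule R3", {
  # three specimens, one locality, two COI cells, one 16S clade: the two
  # cells are population-level variation of one species
  rec <- mkRecords(c("n1", "n2", "n3"), locality = "LMR1",
                   field_genus = "Nectophryne",
                   field_morphospecies = c("afra", "afra", "batesii"))
  cells <- mkPartition(labs(n1 = 1, n2 = 1, n3 = 2), "cells")
  s16 <- mkPartition(labs(n1 = 1, n2 = 1, n3 = 1), "16s")
  asn <- reconcileCells(cells, s16, rec)
  expect_equal(length(unique(otuOf(asn))), 1L)
  prov <- ruleProvenance(asn)
  expect_true(any(prov$rule == "R3" & prov$action == "merge"))
  expect_equal(nrow(ruleConflicts(asn)), 0L)
})

test_that("allopatric cells divergent at both loci stay separate species", {
  # two regions, different COI cells and different 16S clades, no
  # morphology flag: two species
  rec <- mkRecords(c("g1", "g2", "r1", "r2"),
                   locality = c("GAB", "GAB", "RC", "RC"),
                   field_genus = "Hemisus",
                   field_morphospecies = "perreti")
  cells <- mkPartition(labs(g1 = 1, g2 = 1, r1 = 2, r2 = 2), "cells")
  s16 <- mkPartition(labs(g1 = 1, g2 = 1, r1 = 2, r2 = 2), "16s")
  asn <- reconcileCells(cells, s16, rec)
  otu <- otuOf(asn)
  expect_equal(length(unique(otu)), 2L)
  expect_true(otu[["g1"]] != otu[["r1"]])
})

test_that("allopatric cells sharing a 16S clade merge by rule R2", {
  rec <- mkRecords(c("g1", "g2", "r1"), locality = c("GAB", "GAB", "RC"))
  cells <- mkPartition(labs(g1 = 1, g2 = 1, r1 = 2), "cells")
  s16 <- mkPartition(labs(g1 = 1, g2 = 1, r1 = 1), "16s")
  asn <- reconcileCells(cells, s16, rec)
  expect_equal(length(unique(otuOf(asn))), 1L)
  expect_true(any(ruleProvenance(asn)$rule == "R2"))
})

test_that("a shared morphology flag merges allopatric 16S-divergent cells", {
  rec <- mkRecords(c("x1", "y1"), locality = c("L1", "L2"),
                   morphology_flags = list(c(`Genus alpha` = TRUE),
                                           c(`Genus alpha` = TRUE)))
  cells <- mkPartition(labs(x1 = 1, y1 = 2), "cells")
  s16 <- mkPartition(labs(x1 = 1, y1 = 2), "16s")
  asn <- reconcileCells(cells, s16, rec)
  expect_equal(length(unique(otuOf(asn))), 1L)
  expect_true(any(ruleProvenance(asn)$rule == "R5"))

  rec2 <- mkRecords(c("x1", "y1"), locality = c("L1", "L2"))
  asn2 <- reconcileCells(cells, s16, rec2)
  expect_equal(length(unique(otuOf(asn2))), 2L)
})

test_that("single cell reconciles trivially with no rules fired", {
  rec <- mkRecords(c("a", "b", "c"))
  cells <- mkPartition(labs(a = 1, b = 1, c = 1), "cells")
  s16 <- mkPartition(labs(a = 1, b = 1, c = 1), "16s")
  asn <- reconcileCells(cells, s16, rec)
  expect_equal(length(unique(otuOf(asn))), 1L)
  expect_equal(nrow(ruleProvenance(asn)), 0L)
})

test_that("merge chains connecting a forbidden pair are cut and logged", {
  # c1 -R3- c2 -R3- c3 with c1/c3 sympatric in different 16S clades (R4):
  # the component must be split and the conflict recorded
  rec <- mkRecords(c("a", "b1", "b2", "c"), locality = "L1")
  cells <- mkPartition(labs(a = 1, b1 = 2, b2 = 2, c = 3), "cells")
  s16 <- mkPartition(labs(a = 1, b1 = 1, b2 = 2, c = 2), "16s")
  asn <- reconcileCells(cells, s16, rec)
  otu <- otuOf(asn)
  expect_true(otu[["a"]] != otu[["c"]])
  conf <- ruleConflicts(asn)
  expect_gt(nrow(conf), 0)
  expect_true(any(conf$rule == "R4"))
  prov <- ruleProvenance(asn)
  expect_true(any(prov$action == "merge_dropped"))
})

test_that("disabling all merge rules returns the cells unchanged", {
  set.seed(47)
  ids <- paste0("s", 1:8)
  rec <- mkRecords(ids, locality = sample(c("L1", "L2"), 8, replace = TRUE))
  cells <- mkPartition(stats::setNames(c(1, 1, 2, 2, 3, 3, 4, 4), ids))
  s16 <- mkPartition(stats::setNames(c(1, 1, 1, 1, 2, 2, 2, 2), ids))
  off <- ruleConfig(R2 = FALSE, R3 = FALSE, R4 = FALSE, R5 = FALSE)
  asn <- reconcileCells(cells, s16, rec, off)
  expect_true(samePartition(otuOf(asn), groupLabels(cells)))
  # and with rules on, the OTU count can only shrink
  asnOn <- reconcileCells(cells, s16, rec)
  expect_lte(length(unique(otuOf(asnOn))), groupCount(cells))
})

test_that("replaying surviving provenance merges reproduces the OTUs", {
  set.seed(53)
  for (rep in 1:5) {
    n <- 9
    ids <- paste0("s", 1:n)
    rec <- mkRecords(ids, locality = sample(c("L1", "L2", "L3"), n, TRUE))
    cells <- mkPartition(stats::setNames(sample(1:5, n, TRUE), ids))
    s16 <- mkPartition(stats::setNames(sample(1:3, n, TRUE), ids))
    asn <- reconcileCells(cells, s16, rec)
    prov <- ruleProvenance(asn)
    merges <- prov[prov$action == "merge", , drop = FALSE]
    # replay: union-find over cells using only surviving merges
    nc <- groupCount(cells)
    parent <- seq_len(nc)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_len(nrow(merges))) {
      ra <- find(merges$cell_a[k]); rb <- find(merges$cell_b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    replay <- vapply(groupLabels(cells), function(g) find(g), integer(1))
    expect_true(samePartition(otuOf(asn), replay))
  }
})

test_that("OTUs containing references adopt the majority reference name", {
  rec <- mkRecords(c("r1", "r2", "r3", "s1"),
                   role = c("reference", "reference", "reference", "survey"),
                   field_genus = c(NA, NA, NA, "Arthroleptis"),
                   field_morphospecies = c(NA, NA, NA, "spX"),
                   reference_name = c("Arthroleptis sylvaticus",
                                      "Arthroleptis sylvaticus",
                                      "Arthroleptis adelphus", NA))
  cells <- mkPartition(labs(r1 = 1, r2 = 1, r3 = 1, s1 = 1), "cells")
  s16 <- mkPartition(labs(r1 = 1, r2 = 1, r3 = 1, s1 = 1), "16s")
  D16 <- mkDist(matrix(0.01, 4, 4), c("r1", "r2", "r3", "s1"))
  asn <- assignNames(reconcileCells(cells, s16, rec), rec, s16, D16)
  nm <- otuNames(asn)
  expect_identical(nm$name[1], "Arthroleptis sylvaticus")
  expect_identical(nm$status[1], "named")
})

test_that("tied reference names take the alphabetical name with cf status", {
  rec <- mkRecords(c("r1", "r2"), role = "reference",
                   reference_name = c("Genus beta", "Genus alpha"))
  cells <- mkPartition(labs(r1 = 1, r2 = 1), "cells")
  s16 <- mkPartition(labs(r1 = 1, r2 = 1), "16s")
  D16 <- mkDist(matrix(0.01, 2, 2), c("r1", "r2"))
  asn <- assignNames(reconcileCells(cells, s16, rec), rec, s16, D16)
  nm <- otuNames(asn)
  expect_identical(nm$name[1], "Genus alpha")
  expect_identical(nm$status[1], "cf")
})

test_that("naming falls through 16S link, cf distance, and sp. letters", {
  ids <- c("ref", "a", "b", "c", "d")
  rec <- mkRecords(ids,
                   role = c("reference", rep("survey", 4)),
                   locality = c("EXT", "L1", "L1", "L2", "L2"),
                   field_genus = c(NA, "Lepto", "Lepto", "Lepto", "Lepto"),
                   field_morphospecies = c(NA, "m1", "m2", "m3", "m4"),
                   reference_name = c("Leptopelis macrotis", NA, NA, NA, NA))
  # four separate OTUs: a shares the reference's 16S cluster; b is within
  # dCf of the reference but in another cluster; c and d are far away
  cells <- mkPartition(labs(ref = 1, a = 2, b = 3, c = 4, d = 5), "cells")
  s16 <- mkPartition(labs(ref = 1, a = 1, b = 2, c = 3, d = 4), "16s")
  d <- matrix(0.3, 5, 5, dimnames = list(ids, ids)); diag(d) <- 0
  d["ref", "a"] <- d["a", "ref"] <- 0.005
  d["ref", "b"] <- d["b", "ref"] <- 0.04
  D16 <- mkDist(d, ids)
  off <- ruleConfig(R2 = FALSE, R3 = FALSE, R4 = FALSE, R5 = FALSE)
  asn <- assignNames(reconcileCells(cells, s16, rec, off), rec, s16, D16,
                     dCf = 0.05)
  nm <- as.data.frame(otuNames(asn))
  otu <- otuOf(asn)
  nameOf <- function(id) nm$name[nm$otu == otu[[id]]]
  statusOf <- function(id) nm$status[nm$otu == otu[[id]]]
  expect_identical(nameOf("a"), "Leptopelis macrotis")
  expect_identical(statusOf("a"), "named")
  expect_identical(nameOf("b"), "Leptopelis cf. macrotis")
  expect_identical(statusOf("b"), "cf")
  expect_identical(nameOf("c"), "Lepto sp. A")
  expect_identical(nameOf("d"), "Lepto sp. B")
  expect_identical(statusOf("d"), "provisional")
})
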