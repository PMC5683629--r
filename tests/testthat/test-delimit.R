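test_that("threshold partition chains by single linkage", {
  D <- mkDistPairs(c("a", "b", "c"), 0.05,
                   list("a", "b", 0.01), list("b", "c", 0.02))
  # d(a,c) = 0.05 but the a-b-c chain connects at t = 0.022
  p <- thresholdPartition(D, 0.022)
  expect_equal(groupCount(p), 1L)
  p2 <- thresholdPartition(D, 0.015)
  expect_equal(unname(groupLabels(p2)), c(1L, 1L, 2L))
  expect_match(partitionMethod(p2), "threshold@0.015")
})

test_that("threshold partition matches hclust single-linkage components", {
  set.seed(17)
  for (i in 1:15) {
    n <- sample(4:12, 1)
    d <- matrix(runif(n * n, 0, 0.2), n, n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    D <- mkDist(d)
    t <- runif(1, 0.02, 0.15)
    got <- groupLabels(thresholdPartition(D, t))
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    ref <- stats::cutree(hc, h = t)
    expect_true(samePartition(got, stats::setNames(ref, specimenIds(D))))
  }
})

test_that("threshold partition group count is non-increasing in t", {
  set.seed(19)
  d <- matrix(runif(100, 0, 0.2), 10, 10)
  d <- (d + t(d)) / 2; diag(d) <- 0
  D <- mkDist(d)
  counts <- vapply(seq(0, 0.2, by = 0.01),
                   function(t) groupCount(thresholdPartition(D, t)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(groupCount(thresholdPartition(D, 0)), 10L)
  expect_equal(groupCount(thresholdPartition(D, 1)), 1L)
})

test_that("all-identical sequences give one ABGD group at every prior", {
  D <- mkDist(matrix(0, 6, 6))
  res <- abgdPartition(D)
  s <- abgdSummary(res)
  expect_true(all(s$n_groups_initial == 1L))
  expect_true(all(s$n_groups_recursive == 1L))
  expect_equal(groupCount(selectedPartition(res)), 1L)
})

test_that("ABGD finds a clean two-cluster gap at every prior", {
  # intra <= 0.01, inter >= 0.08: the gap must be found at each prior on
  # the grid and the selected partition must match the clusters
  cl <- rep(1:2, each = 5)
  d <- outer(cl, cl, function(a, b) ifelse(a == b, 0.01, 0.09))
  D <- mkDist(d)
  res <- abgdPartition(D)
  s <- abgdSummary(res)
  # every prior below the inter-cluster distance must find the gap; a
  # prior above it (0.1 > 0.09) legitimately sees one group
  expect_true(all(s$n_groups_recursive[s$prior < 0.08] == 2L))
  expect_true(samePartition(groupLabels(selectedPartition(res)),
                            stats::setNames(cl, specimenIds(D))))
})

test_that("ABGD recursion recovers a gap masked by another group's continuum", {
  # group A (intra 0.004) and group B (intra 0.008) sit 0.036-0.048 apart;
  # group E's internal distances form a uniform ladder 0.012-0.032 that
  # fills the global gap between the A/B intra block and the A-B block,
  # so the only global gap is the jump to 0.25: the initial pass returns
  # {A+B | E}; the recursive pass, scanning A+B alone, sees the 0.008 ->
  # 0.036 jump and splits A from B.
  ids <- c("a1", "a2", "b1", "b2", "e1", "e2", "e3", "e4")
  d <- matrix(0.25, 8, 8, dimnames = list(ids, ids)); diag(d) <- 0
  d["a1", "a2"] <- d["a2", "a1"] <- 0.004
  d["b1", "b2"] <- d["b2", "b1"] <- 0.008
  ab <- c(0.036, 0.040, 0.044, 0.048); k <- 1
  for (i in c("a1", "a2")) for (j in c("b1", "b2")) {
    d[i, j] <- d[j, i] <- ab[k]; k <- k + 1
  }
  ev <- list(c("e1", "e2", 0.012), c("e1", "e3", 0.016),
             c("e2", "e3", 0.020), c("e1", "e4", 0.024),
             c("e2", "e4", 0.028), c("e3", "e4", 0.032))
  for (e in ev) d[e[1], e[2]] <- d[e[2], e[1]] <- as.numeric(e[3])
  res <- abgdPartition(mkDist(d, ids))
  s <- abgdSummary(res)
  expect_true(all(s$n_groups_initial == 2L))
  expect_true(any(s$n_groups_recursive == 3L))
  truth <- stats::setNames(c(1, 1, 2, 2, 3, 3, 3, 3), ids)
  expect_true(samePartition(groupLabels(selectedPartition(res)), truth))
  # single-linkage oracle at the two midpoints confirms both passes
  expect_true(samePartition(
    stats::cutree(stats::hclust(stats::as.dist(d), "single"), h = 0.149),
    stats::setNames(c(1, 1, 1, 1, 2, 2, 2, 2), ids)))
  expect_true(samePartition(
    stats::cutree(stats::hclust(stats::as.dist(d[1:4, 1:4]), "single"),
                  h = 0.022),
    stats::setNames(c(1, 1, 2, 2), ids[1:4])))
})

test_that("ABGD recursive group counts never fall below initial counts", {
  set.seed(23)
  for (i in 1:10) {
    sizes <- sample(2:5, sample(2:4, 1), replace = TRUE)
    cg <- cleanGapMatrix(sizes, a = runif(1, 0.002, 0.02))
    res <- abgdPartition(cg$D)
    s <- abgdSummary(res)
    expect_true(all(s$n_groups_recursive >= s$n_groups_initial))
    expect_true(sum(s$selected) == 1L)
  }
})

test_that("ABGD and the threshold proxy agree on clean data", {
  set.seed(29)
  cg <- cleanGapMatrix(c(4, 3, 5), a = 0.01)
  ab <- selectedPartition(abgdPartition(cg$D))
  th <- thresholdPartition(cg$D, 0.022)
  expect_equal(groupCount(ab), groupCount(th))
  expect_true(samePartition(groupLabels(ab), groupLabels(th)))
})

test_that("ABGD config validates its parameters", {
  expect_error(abgdConfig(Pmin = 0), "Pmin")
  expect_error(abgdConfig(Pmin = 0.2, Pmax = 0.1))
  expect_error(abgdConfig(steps = 1))
  expect_error(abgdConfig(X = 0))
  expect_error(abgdPartition(mkDist(matrix(0, 1, 1))), "at least 2")
})

test_that("NJ solves the two- and three-taxon cases exactly", {
  D2 <- mkDistPairs(c("A", "B"), 0.15)
  t2 <- neighborJoining(D2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(t2$edge.length, c(0.075, 0.075))

  D3 <- mkDistPairs(c("A", "B", "C"), 0,
                    list("A", "B", 0.2), list("A", "C", 0.3),
                    list("B", "C", 0.4))
  t3 <- neighborJoining(D3)
  len <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  # path equations: a+b=0.2, a+c=0.3, b+c=0.4
  expect_equal(len[["A"]], 0.05)
  expect_equal(len[["B"]], 0.15)
  expect_equal(len[["C"]], 0.25)
  expect_error(neighborJoining(mkDist(matrix(0, 1, 1))), "at least 2")
})

test_that("NJ recovers additive trees exactly for n <= 8", {
  set.seed(31)
  for (n in c(4, 5, 6, 8)) {
    for (rep in 1:5) {
      tree <- ape::rtree(n)
      tree$edge.length <- runif(nrow(tree$edge), 0.01, 0.1)
      dm <- ape::cophenetic.phylo(tree)
      dm <- dm[sort(rownames(dm)), sort(colnames(dm))]
      got <- neighborJoining(mkDist(dm))
      expect_equal(ape::dist.topo(ape::unroot(got), ape::unroot(tree)),
                   structure(0, names = "PH85"), ignore_attr = TRUE)
      back <- ape::cophenetic.phylo(got)
      expect_equal(back[rownames(dm), colnames(dm)], dm, tolerance = 1e-9)
    }
  }
})

test_that("NJ output is invariant to input order and clamps negatives", {
  set.seed(37)
  seqs <- c(mutSeqs(randCentroid(300), 3, 0.01, "a"),
            mutSeqs(randCentroid(300), 3, 0.01, "b"))
  D1 <- distanceMatrix(seqs, minOverlap = 50)
  D2 <- distanceMatrix(seqs[sample(6)], minOverlap = 50)
  t1 <- neighborJoining(D1); t2 <- neighborJoining(D2)
  expect_identical(t1$tip.label, t2$tip.label)
  expect_equal(t1$edge.length, t2$edge.length)
  expect_true(all(t1$edge.length >= 0))
})

test_that("16S threshold clustering reproduces single-linkage clusters", {
  D <- mkDist(matrix(0.01, 4, 4))
  p <- conspecificityClusters(D, "threshold", t16 = 0.03)
  expect_equal(groupCount(p), 1L)
  expect_match(partitionMethod(p), "16s-cluster@0.03")

  set.seed(41)
  cg <- cleanGapMatrix(c(4, 5), a = 0.01)
  p2 <- conspecificityClusters(cg$D, "threshold", t16 = 0.03)
  expect_true(samePartition(groupLabels(p2), cg$truth))
})

test_that("monophyly mode clusters survey tips with conspecific references", {
  # two survey specimens nested inside a clade of references of one
  # species join that species' cluster
  set.seed(43)
  seqs <- c(mutSeqs(randCentroid(400), 5, 0.01, "ad"),   # 3 refs + 2 survey
            mutSeqs(randCentroid(400), 3, 0.01, "out"))
  D <- distanceMatrix(seqs, minOverlap = 50)
  tree <- neighborJoining(D)
  refs <- stats::setNames(rep(NA_character_, 8), names(seqs))
  refs[c("ad1", "ad2", "ad3")] <- "Arthroleptis adelphus"
  refs["out1"] <- "Leptopelis aubryi"
  p <- conspecificityClusters(D, "monophyly", tree = tree,
                              referenceNames = refs)
  lab <- groupLabels(p)
  expect_equal(lab[["ad4"]], lab[["ad1"]])
  expect_equal(lab[["ad5"]], lab[["ad1"]])
  expect_true(lab[["out1"]] != lab[["ad1"]])
  expect_error(conspecificityClusters(D, "monophyly", tree = tree,
    referenceNames = stats::setNames(rep(NA_character_, 8), names(seqs))),
    "reference")
})
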