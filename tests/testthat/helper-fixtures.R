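# Shared builders for in-code fixtures: distance matrices, specimen
# tables, partitions, and random sequence clusters.

BASES <- c("A", "C", "G", "T")

# PDistanceMatrix straight from a symmetric matrix
mkDist <- function(d, ids = rownames(d)) {
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  diag(d) <- 0
  new("PDistanceMatrix", ids = ids, d = d,
      nSites = matrix(500L, nrow(d), ncol(d)))
}

# symmetric matrix from pair assignments: default value, then overrides
mkDistPairs <- function(ids, default, ...) {
  n <- length(ids)
  d <- matrix(default, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  pairs <- list(...)
  for (p in pairs) {
    d[p[[1]], p[[2]]] <- d[p[[2]], p[[1]]] <- p[[3]]
  }
  mkDist(d, ids)
}

# random sequences: n copies of a centroid mutated at per-site rate
mutSeqs <- function(centroid, n, rate, prefix = "s") {
  out <- vapply(seq_len(n), function(i) {
    s <- centroid
    hit <- which(stats::runif(length(s)) < rate)
    for (j in hit) s[j] <- sample(setdiff(BASES, s[j]), 1L)
    paste(s, collapse = "")
  }, character(1))
  names(out) <- paste0(prefix, seq_len(n))
  out
}

randCentroid <- function(L) sample(BASES, L, replace = TRUE)

# minimal specimen DataFrame; morphology flags default empty
mkRecords <- function(specimen_id, role = "survey", site = "LMR",
                      locality = "LOC01", sampling_event = "EV01",
                      season = NA_character_, field_genus = NA_character_,
                      field_morphospecies = NA_character_,
                      reference_name = NA_character_,
                      morphology_flags = NULL) {
  n <- length(specimen_id)
  df <- S4Vectors::DataFrame(
    specimen_id = specimen_id,
    role = rep_len(role, n), site = rep_len(site, n),
    locality = rep_len(locality, n),
    sampling_event = rep_len(sampling_event, n),
    catalog = NA_character_, region = NA_character_,
    season = rep_len(season, n),
    field_genus = rep_len(field_genus, n),
    field_morphospecies = rep_len(field_morphospecies, n),
    reference_name = rep_len(reference_name, n))
  df$morphology_flags <- if (is.null(morphology_flags))
    rep(list(logical(0)), n) else morphology_flags
  df
}

# partition with explicit labels (canonicalized)
mkPartition <- function(labels, method = "test") {
  lab <- match(labels, unique(labels))
  storage.mode(lab) <- "integer"
  names(lab) <- names(labels)
  new("Partition", method = method, labels = lab)
}

# cleanly gapped constructed matrix: every cluster shares the constant
# intra-cluster distance a; inter-cluster distances drawn above interMin
cleanGapMatrix <- function(sizes, a, interMin = 0.15, interMax = 0.4) {
  n <- sum(sizes)
  ids <- paste0("t", seq_len(n))
  cl <- rep(seq_along(sizes), sizes)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  K <- length(sizes)
  inter <- matrix(0, K, K)
  for (i in seq_len(K - 1L))
    for (j in seq.int(i + 1L, K))
      inter[i, j] <- inter[j, i] <- stats::runif(1, interMin, interMax)
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n))
      d[i, j] <- d[j, i] <- if (cl[i] == cl[j]) a else inter[cl[i], cl[j]]
  list(D = mkDist(d, ids), truth = stats::setNames(cl, ids))
}

# do two labelings induce the same grouping? (label <-> truth bijection)
samePartition <- function(labels, truth) {
  truth <- truth[names(labels)]
  tab <- table(unname(labels), unname(truth))
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# exhaustive sample-based rarefaction oracle: mean richness over all
# C(m, h) event subsets
exhaustiveTau <- function(mat, h) {
  m <- ncol(mat)
  subs <- utils::combn(m, h, simplify = FALSE)
  mean(vapply(subs, function(s)
    sum(rowSums(mat[, s, drop = FALSE]) > 0), numeric(1)))
}

# random incidence matrix with every species seen at least once
randIncidence <- function(K, m, p) {
  repeat {
    mat <- matrix(stats::rbinom(K * m, 1, p), K, m,
                  dimnames = list(paste0("sp", seq_len(K)),
                                  paste0("ev", seq_len(m))))
    if (any(rowSums(mat) > 0)) return(mat[rowSums(mat) > 0, , drop = FALSE])
  }
}
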