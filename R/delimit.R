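# Candidate OTU partitions from a p-distance matrix: fixed-threshold
# single linkage (BIN proxy), automatic barcode gap discovery, NJ trees,
# and a conspecificity predicate for 16S.

# connected components of the graph with edges d <= t, labels canonical by
# first appearance in id order
.singleLinkageGroups <- function(d, ids, t) {
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n))
      if (d[i, j] <= t) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
  roots <- vapply(seq_len(n), find, integer(1))
  canon <- match(roots, unique(roots))
  names(canon) <- ids
  canon
}

.makePartition <- function(labels, method) {
  canon <- match(labels, unique(labels))
  storage.mode(canon) <- "integer"
  names(canon) <- names(labels)
  new("Partition", method = method, labels = canon)
}

#' Fixed-threshold single-linkage partition (BIN proxy)
#'
#' Groups specimens into the connected components of the graph whose edges
#' join pairs with p-distance at most \code{t}. With the default
#' \code{t = 0.022} this is the package's proxy for Barcode Index Numbers:
#' BOLD's actual clustering algorithm is proprietary, and a fixed 2.2%
#' uncorrected COI difference is the standard characterisation of its
#' behaviour. Single linkage chains: a and c end up together whenever some
#' b is within \code{t} of both, even if d(a,c) > t.
#'
#' @param D a \linkS4class{PDistanceMatrix}.
#' @param t distance threshold (fraction).
#' @return a \linkS4class{Partition} with canonical labels and method tag
#'   \code{"threshold@<t>"}.
#' @export
thresholdPartition <- function(D, t = 0.022) {
  stopifnot(is(D, "PDistanceMatrix"), t >= 0)
  .makePartition(.singleLinkageGroups(D@d, D@ids, t),
                 sprintf("threshold@%g", t))
}

#' Configuration for automatic barcode gap discovery
#'
#' The prior maximum intraspecific divergence is scanned over a geometric
#' grid of \code{steps} values from \code{Pmin} to \code{Pmax}. \code{X} is
#' the minimum relative width of an acceptable gap (how many times wider
#' than the local slope of the ranked-distance curve it must be), and
#' \code{Nb} controls the sliding-window size used to estimate that slope
#' (window w = max(3, ceiling(N/Nb)) over the N sorted pairwise
#' distances). Defaults are the settings used throughout this package's
#' reference analyses: Pmin 0.001, Pmax 0.1, 10 steps, X 1.5, Nb 20.
#'
#' @param Pmin,Pmax prior range (fractions), 0 < Pmin < Pmax < 1.
#' @param steps number of priors on the geometric grid (>= 2).
#' @param X relative gap width (dimensionless, > 0).
#' @param Nb bin count for window sizing (>= 2).
#' @return a list of class \code{"abgdConfig"}.
#' @export
abgdConfig <- function(Pmin = 0.001, Pmax = 0.1, steps = 10L, X = 1.5,
                       Nb = 20L) {
  stopifnot(Pmin > 0, Pmin < Pmax, Pmax < 1, steps >= 2L, X > 0, Nb >= 2L)
  structure(list(Pmin = Pmin, Pmax = Pmax, steps = as.integer(steps), X = X,
                 Nb = as.integer(Nb)), class = "abgdConfig")
}

# first barcode gap in a sorted distance vector: the first index i with
# d[i+1] > P and d[i+1] - d[i] > X * theta(i), where theta(i) is the mean
# consecutive-gap width over a window of w sorted values ending at i.
# Returns the single-linkage threshold (midpoint of the gap) or NA.
.findGap <- function(dsort, P, X, Nb) {
  N <- length(dsort)
  if (N < 3L) return(NA_real_)
  w <- max(3L, ceiling(N / Nb))
  # i = 1 is skipped: a window holding a single distance carries no gap
  # and hence no local scale to compare against
  for (i in seq.int(2L, N - 1L)) {
    if (dsort[i + 1L] <= P) next
    gap <- dsort[i + 1L] - dsort[i]
    weff <- min(w, i)
    theta <- (dsort[i] - dsort[i - weff + 1L]) / (weff - 1L)
    if (gap > X * theta && gap > 0)
      return((dsort[i] + dsort[i + 1L]) / 2)
  }
  NA_real_
}

# one gap-splitting pass over a set of ids; NULL if no gap found
.abgdSplitOnce <- function(D, ids, P, X, Nb) {
  if (length(ids) < 2L) return(NULL)
  idx <- match(ids, D@ids)
  sub <- D@d[idx, idx, drop = FALSE]
  dsort <- sort(sub[upper.tri(sub)])
  thr <- .findGap(dsort, P, X, Nb)
  if (is.na(thr)) return(NULL)
  g <- .singleLinkageGroups(sub, ids, thr)
  if (length(unique(g)) < 2L) return(NULL)
  split(ids, g)
}

#' Automatic barcode gap discovery
#'
#' Partitions specimens at the discontinuity (the "barcode gap") between
#' the within-group and between-group parts of the ranked pairwise
#' distance distribution, scanned over a geometric grid of prior maximum
#' intraspecific divergences P. For each prior: the sorted distances are
#' searched for the first index i with \eqn{d_{(i+1)} > P} whose gap
#' \eqn{d_{(i+1)} - d_{(i)}} exceeds \code{X} times the local mean
#' consecutive-gap width (window of \eqn{w = \max(3, \lceil N/Nb \rceil)}
#' sorted distances ending at i); if found, the set is split by single
#' linkage at the gap midpoint, and the search is re-applied recursively
#' inside every resulting group on its intra-group distances until no
#' further split. The returned selection is the recursive partition whose
#' group count recurs over the longest run of consecutive priors, ties
#' resolved toward smaller priors.
#'
#' A degenerate all-zero matrix yields a single group at every prior: a
#' gap of width zero is never accepted.
#'
#' @param D a \linkS4class{PDistanceMatrix} over at least 2 specimens.
#' @param config an [abgdConfig()].
#' @return an \linkS4class{ABGDResult}.
#' @export
abgdPartition <- function(D, config = abgdConfig()) {
  stopifnot(is(D, "PDistanceMatrix"), inherits(config, "abgdConfig"))
  if (length(D@ids) < 2L)
    stop("need at least 2 specimens")
  k <- seq_len(config$steps) - 1L
  priors <- config$Pmin * (config$Pmax / config$Pmin)^(k / (config$steps - 1L))
  ids <- D@ids
  nInitial <- integer(length(priors))
  nRecursive <- integer(length(priors))
  partitions <- vector("list", length(priors))
  for (p in seq_along(priors)) {
    P <- priors[p]
    first <- .abgdSplitOnce(D, ids, P, config$X, config$Nb)
    nInitial[p] <- if (is.null(first)) 1L else length(first)
    groups <- if (is.null(first)) list(ids) else first
    # recursive refinement within groups
    repeat {
      again <- FALSE
      nxt <- list()
      for (g in groups) {
        sub <- .abgdSplitOnce(D, g, P, config$X, config$Nb)
        if (is.null(sub)) nxt <- c(nxt, list(g))
        else { nxt <- c(nxt, sub); again <- TRUE }
      }
      groups <- nxt
      if (!again) break
    }
    nRecursive[p] <- length(groups)
    lab <- integer(length(ids)); names(lab) <- ids
    for (gi in seq_along(groups)) lab[groups[[gi]]] <- gi
    partitions[[p]] <- .makePartition(
      lab, sprintf("abgd@P=%.6g", P))
  }
  # stability selection: longest run of consecutive priors with the same
  # recursive group count; ties -> the run at smaller priors
  runs <- rle(nRecursive)
  best <- which.max(runs$lengths)  # which.max takes the first maximum
  selIdx <- sum(runs$lengths[seq_len(best - 1L)]) + 1L
  new("ABGDResult", priors = priors, nInitial = nInitial,
      nRecursive = nRecursive, partitions = partitions,
      selected = partitions[[selIdx]], selectedIndex = as.integer(selIdx))
}

#' Neighbor-joining tree from a p-distance matrix
#'
#' Standard agglomerative neighbor joining (Q-matrix criterion) as used for
#' clustering similar barcode sequences — a clustering device here, not an
#' estimate of evolutionary history. Specimens are pre-sorted by id so the
#' result is deterministic under input reordering (ties in the Q matrix are
#' then always broken toward the lexicographically smallest pair), and
#' negative branch-length estimates are clamped to zero.
#'
#' @param D a \linkS4class{PDistanceMatrix} over at least 2 specimens.
#' @return an unrooted \code{phylo} tree with non-negative branch lengths.
#' @export
neighborJoining <- function(D) {
  stopifnot(is(D, "PDistanceMatrix"))
  n <- length(D@ids)
  if (n < 2L)
    stop("need at least 2 specimens")
  ord <- order(D@ids)
  if (n == 2L) {
    half <- D@d[1L, 2L] / 2
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 edge.length = c(half, half),
                 tip.label = D@ids[ord], Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  m <- D@d[ord, ord]
  tree <- ape::nj(stats::as.dist(m))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Conspecificity clusters from 16S data
#'
#' Treats 16S clades like COI partitions: either deterministic
#' single-linkage clustering at a 16S threshold (default mode; the 3%
#' default is configurable), or, when a tree and reference names are
#' available, the maximal clades of the midpoint-rooted tree that are
#' label-consistent — no tip inside carries a different reference name.
#' Monophyly mode reproduces the "survey specimens nested inside a clade
#' of conspecific references" reading of clade-based identification.
#'
#' @param D16 a \linkS4class{PDistanceMatrix} for the 16S locus.
#' @param mode \code{"threshold"} or \code{"monophyly"}.
#' @param t16 threshold (fraction) for threshold mode.
#' @param tree a \code{phylo} tree over the same tips (monophyly mode).
#' @param referenceNames named character vector tip id -> reference name,
#'   \code{NA} for unlabelled tips (monophyly mode).
#' @return a \linkS4class{Partition}.
#' @export
conspecificityClusters <- function(D16, mode = c("threshold", "monophyly"),
                                   t16 = 0.03, tree = NULL,
                                   referenceNames = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(D16, "PDistanceMatrix"))
  if (mode == "threshold") {
    p <- thresholdPartition(D16, t16)
    return(.makePartition(groupLabels(p), sprintf("16s-cluster@%g", t16)))
  }
  if (is.null(tree) || is.null(referenceNames))
    stop("monophyly mode requires 'tree' and 'referenceNames'")
  labels <- referenceNames[tree$tip.label]
  names(labels) <- tree$tip.label
  if (all(is.na(labels)))
    stop("monophyly mode requires at least one labelled reference tip")
  rooted <- phangorn::midpoint(tree)
  ntip <- length(rooted$tip.label)
  desc <- .tipDescendants(rooted)
  nodeNames <- lapply(desc, function(tips)
    unique(stats::na.omit(labels[rooted$tip.label[tips]])))
  consistent <- vapply(nodeNames, function(x) length(x) <= 1L, logical(1))
  parent <- integer(ntip + rooted$Nnode)
  parent[rooted$edge[, 2L]] <- rooted$edge[, 1L]
  rootNode <- setdiff(rooted$edge[, 1L], rooted$edge[, 2L])[1L]
  maximal <- which(consistent &
                     (seq_along(consistent) == rootNode |
                        !consistent[pmax(parent, 1L)]))
  lab <- integer(ntip)
  names(lab) <- rooted$tip.label
  for (gi in seq_along(maximal)) lab[desc[[maximal[gi]]]] <- gi
  # order clusters canonically by the original matrix id order
  lab <- lab[intersect(D16@ids, names(lab))]
  .makePartition(lab, "16s-monophyly")
}

# tips under each node (1..ntip are the tips themselves)
.tipDescendants <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(ntip)) desc[[i]] <- i
  # edges in postorder so children are resolved before parents
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}
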