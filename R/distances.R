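#' Uncorrected pairwise distance between two aligned sequences
#'
#' Computes the p-distance under pairwise deletion: only columns where both
#' sequences carry an unambiguous base (\code{A}, \code{C}, \code{G} or
#' \code{T}) are compared; the distance is the fraction of those columns
#' that mismatch. Gaps and \code{N} are excluded per pair, not per column,
#' so the usable site count varies between pairs — this matches keeping
#' ambiguous loop regions in the alignment rather than stripping them.
#' Distances are deliberately uncorrected (no multiple-hit correction):
#' every delimitation threshold in this package is quoted on the
#' uncorrected scale.
#'
#' @param a,b aligned sequences of equal length (character strings or
#'   anything coercible via \code{as.character}).
#' @param minOverlap minimum number of compared sites; fewer is an error.
#' @return named numeric vector \code{c(distance =, sites =)}.
#' @examples
#' pDistance("ACGTACGT", "ACGTACGT")          # 0 over 8 sites
#' pDistance("AC-TT", "ACGTA", minOverlap = 1) # 0.25 over 4 sites
#' @export
pDistance <- function(a, b, minOverlap = 1L) {
  a <- toupper(as.character(a)[1L])
  b <- toupper(as.character(b)[1L])
  if (nchar(a) != nchar(b))
    stop(sprintf("sequence length mismatch: %d vs %d", nchar(a), nchar(b)))
  stopifnot(minOverlap >= 1L)
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  ok <- av %in% DNA_BASES4 & bv %in% DNA_BASES4
  n <- sum(ok)
  if (n < minOverlap)
    stop(sprintf("insufficient overlap: %d compared sites < minOverlap = %d",
                 n, minOverlap))
  c(distance = sum(av[ok] != bv[ok]) / n, sites = n)
}

#' All-pairs p-distance matrix for one locus
#'
#' Computes every pairwise p-distance of an alignment with pairwise
#' deletion (see [pDistance()]). Internally uses per-base indicator
#' matrices and crossproducts, so the cost is a handful of BLAS calls
#' rather than an explicit pair loop. Pairs whose compared-site count falls
#' below \code{minOverlap} make the whole call fail with the list of
#' offending pairs, so the caller can drop degenerate fragments and retry.
#' The default of 100 sites guards against near-empty fragments while
#' excluding nothing in the ~500 bp range of real barcode data.
#'
#' @param x a \linkS4class{LocusAlignment}, a named \code{DNAStringSet}, or
#'   a named character vector of equal-length aligned sequences.
#' @param minOverlap minimum compared sites per retained pair.
#' @return a \linkS4class{PDistanceMatrix}.
#' @export
distanceMatrix <- function(x, minOverlap = 100L) {
  stopifnot(minOverlap >= 1L)
  if (is(x, "LocusAlignment")) x <- x@seqs
  ids <- names(x)
  seqs <- stats::setNames(toupper(as.character(x)), ids)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must be uniquely named by specimen id")
  n <- length(seqs)
  if (n < 2L)
    stop("need at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("all sequences must have equal length")
  M <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
              nrow = n, byrow = TRUE)
  V <- matrix(0, n, ncol(M))
  matches <- matrix(0, n, n)
  for (b in DNA_BASES4) {
    A <- (M == b) * 1
    matches <- matches + tcrossprod(A)
    V <- V + A
  }
  nS <- tcrossprod(V)
  low <- which(nS < minOverlap & upper.tri(nS), arr.ind = TRUE)
  if (nrow(low))
    stop("pairs below minOverlap = ", minOverlap, ": ",
         paste(sprintf("%s/%s (%d sites)", ids[low[, 1L]], ids[low[, 2L]],
                       nS[low]), collapse = "; "))
  d <- 1 - matches / nS
  d[d < 0] <- 0  # numeric fuzz
  diag(d) <- 0
  dimnames(d) <- dimnames(nS) <- list(ids, ids)
  storage.mode(nS) <- "integer"
  new("PDistanceMatrix", ids = ids, d = (d + t(d)) / 2, nSites = nS)
}

#' Restrict a distance matrix to a subset of specimens
#'
#' @param D a \linkS4class{PDistanceMatrix}.
#' @param ids specimen ids to keep, in the order given.
#' @return a \linkS4class{PDistanceMatrix} over \code{ids}.
#' @export
subsetDistances <- function(D, ids) {
  stopifnot(is(D, "PDistanceMatrix"))
  missing <- setdiff(ids, D@ids)
  if (length(missing))
    stop("ids absent from distance matrix: ", paste(missing, collapse = ", "))
  idx <- match(ids, D@ids)
  new("PDistanceMatrix", ids = ids, d = D@d[idx, idx, drop = FALSE],
      nSites = D@nSites[idx, idx, drop = FALSE])
}
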