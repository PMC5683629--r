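#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom S4Vectors DataFrame DFrame SimpleList
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats setNames
NULL

DNA_RESIDUES <- c("A", "C", "G", "T", "N", "-")
DNA_BASES4 <- c("A", "C", "G", "T")

#' One aligned locus over a set of specimens
#'
#' A \code{LocusAlignment} holds the aligned sequences of a single locus
#' (typically the COI barcode fragment or a 16S fragment) as a
#' \linkS4class{DNAStringSet} whose names are specimen identifiers. All
#' sequences have identical width and the alphabet is restricted to
#' \code{A,C,G,T,N,-}: ambiguity codes are collapsed to \code{N} on read
#' because pairwise-deletion distances treat all ambiguity alike.
#'
#' @slot locus single string naming the locus (e.g. \code{"COI"}, \code{"16S"}).
#' @slot seqs a \code{DNAStringSet} of equal-width sequences named by
#'   specimen id.
#'
#' @seealso [readLocusAlignment()], [distanceMatrix()]
#' @exportClass LocusAlignment
setClass("LocusAlignment",
  slots = c(locus = "character", seqs = "DNAStringSet"))

setValidity("LocusAlignment", function(object) {
  if (length(object@locus) != 1L || is.na(object@locus) || !nzchar(object@locus))
    return("'locus' must be a single non-empty string")
  n <- length(object@seqs)
  if (n == 0L)
    return("alignment contains no sequences")
  ids <- names(object@seqs)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    return("every sequence must be named by a specimen id")
  if (anyDuplicated(ids))
    return(sprintf("duplicate specimen id: %s", ids[duplicated(ids)][1L]))
  w <- Biostrings::width(object@seqs)
  if (length(unique(w)) != 1L) {
    bad <- ids[which(w != w[1L])[1L]]
    return(sprintf("unequal sequence lengths: '%s' has %d columns, expected %d",
                   bad, w[w != w[1L]][1L], w[1L]))
  }
  freq <- Biostrings::alphabetFrequency(object@seqs, collapse = TRUE)
  extra <- setdiff(names(freq)[freq > 0], DNA_RESIDUES)
  if (length(extra))
    return(sprintf("alphabet restricted to A,C,G,T,N,-; found: %s",
                   paste(extra, collapse = ", ")))
  TRUE
})

#' Specimens plus their per-locus alignments
#'
#' The central data container: a specimen metadata table (one row per
#' voucher/tissue, with locality, sampling event, role and field labels)
#' together with the per-locus alignments. A specimen may lack one locus,
#' but every sequence id must resolve to a row of the specimen table;
#' construction fails with the full list of orphan ids otherwise.
#'
#' @slot specimens a \code{DataFrame} with at least the columns
#'   \code{specimen_id}, \code{role} (\code{"survey"} or \code{"reference"}),
#'   \code{site}, \code{locality}, \code{sampling_event}.
#' @slot alignments a \code{SimpleList} of \linkS4class{LocusAlignment}
#'   objects, named by locus.
#'
#' @seealso [BarcodeDataset()], [readSpecimenTable()]
#' @exportClass BarcodeDataset
setClass("BarcodeDataset",
  slots = c(specimens = "DataFrame", alignments = "SimpleList"))

setValidity("BarcodeDataset", function(object) {
  sp <- object@specimens
  required <- c("specimen_id", "role", "site", "locality", "sampling_event")
  missing <- setdiff(required, colnames(sp))
  if (length(missing))
    return(sprintf("specimen table lacks required column(s): %s",
                   paste(missing, collapse = ", ")))
  if (anyDuplicated(sp$specimen_id))
    return(sprintf("duplicate specimen_id: %s",
                   sp$specimen_id[duplicated(sp$specimen_id)][1L]))
  for (i in seq_along(object@alignments)) {
    aln <- object@alignments[[i]]
    if (!is(aln, "LocusAlignment"))
      return("'alignments' must contain LocusAlignment objects")
    orphans <- setdiff(names(aln@seqs), sp$specimen_id)
    if (length(orphans))
      return(sprintf("%s alignment has ids absent from the specimen table: %s",
                     aln@locus, paste(orphans, collapse = ", ")))
  }
  TRUE
})

#' Pairwise uncorrected distances with pairwise deletion
#'
#' Symmetric matrix of p-distances (fraction of mismatching sites among the
#' columns where both sequences carry an unambiguous base) together with the
#' per-pair count of compared sites. This is the shared currency of every
#' delimitation method in the package.
#'
#' @slot ids ordered specimen ids (row/column order of the matrices).
#' @slot d symmetric numeric matrix of distances in \code{[0, 1]}, zero
#'   diagonal.
#' @slot nSites symmetric integer matrix of compared-site counts.
#'
#' @seealso [distanceMatrix()], [pDistance()]
#' @exportClass PDistanceMatrix
setClass("PDistanceMatrix",
  slots = c(ids = "character", d = "matrix", nSites = "matrix"))

setValidity("PDistanceMatrix", function(object) {
  n <- length(object@ids)
  if (!all(dim(object@d) == c(n, n)) || !all(dim(object@nSites) == c(n, n)))
    return("matrix dimensions must match the number of ids")
  if (any(abs(object@d - t(object@d)) > 1e-12))
    return("distance matrix must be symmetric")
  if (any(diag(object@d) != 0))
    return("distance matrix must have a zero diagonal")
  if (any(object@d < 0 | object@d > 1))
    return("distances must lie in [0, 1]")
  TRUE
})

#' A method-tagged partition of specimens into groups
#'
#' Maps each specimen to an integer group label. Labels are canonical:
#' consecutive integers starting at 1, assigned by order of first member
#' appearance in the stored id order, so that two partitions are comparable
#' label-by-label whenever they were built over the same id order.
#'
#' @slot method text tag identifying the method and its parameters, e.g.
#'   \code{"threshold@0.022"} or \code{"abgd@P=0.00215"}.
#' @slot labels named integer vector, one entry per specimen.
#'
#' @seealso [thresholdPartition()], [abgdPartition()],
#'   [conspecificityClusters()]
#' @exportClass Partition
setClass("Partition",
  slots = c(method = "character", labels = "integer"))

setValidity("Partition", function(object) {
  if (length(object@method) != 1L)
    return("'method' must be a single string")
  lab <- object@labels
  if (length(lab) == 0L)
    return("partition has no members")
  if (is.null(names(lab)) || anyDuplicated(names(lab)))
    return("labels must be uniquely named by specimen id")
  u <- unique(lab)
  if (!identical(u, seq_along(u)))
    return("labels must be consecutive integers in order of first appearance")
  TRUE
})

#' Result of automatic barcode gap discovery
#'
#' Stores, for each prior maximum intraspecific divergence on the geometric
#' grid, the initial (one-pass) and recursive group counts, the recursive
#' partitions themselves, and the stability-selected partition: the recursive
#' partition whose group count recurs over the longest run of consecutive
#' priors (ties resolved toward smaller priors).
#'
#' @slot priors numeric vector, the geometric grid of prior values.
#' @slot nInitial integer vector of initial-pass group counts per prior.
#' @slot nRecursive integer vector of recursive group counts per prior.
#' @slot partitions list of recursive \linkS4class{Partition} objects, one
#'   per prior.
#' @slot selected the stability-selected recursive \code{Partition}.
#' @slot selectedIndex index of the selected prior in \code{priors}.
#'
#' @seealso [abgdPartition()]
#' @exportClass ABGDResult
setClass("ABGDResult",
  slots = c(priors = "numeric", nInitial = "integer", nRecursive = "integer",
            partitions = "list", selected = "Partition",
            selectedIndex = "integer"))

setValidity("ABGDResult", function(object) {
  k <- length(object@priors)
  if (length(object@nInitial) != k || length(object@nRecursive) != k ||
      length(object@partitions) != k)
    return("per-prior slots must have one entry per prior")
  if (any(object@nRecursive < object@nInitial))
    return("recursive group counts cannot be below initial group counts")
  if (object@selectedIndex < 1L || object@selectedIndex > k)
    return("'selectedIndex' out of range")
  TRUE
})

#' Final species-level assignment with names and rule provenance
#'
#' The outcome of reconciling refined COI cells with 16S clusters and
#' localities: each specimen belongs to exactly one OTU, each OTU carries
#' exactly one name with a status (\code{named}, \code{cf} or
#' \code{provisional}), every merge between cells is justified by a recorded
#' rule, and transitivity conflicts (merge chains connecting a forbidden
#' pair) are flagged rather than silently resolved.
#'
#' @slot otu named integer vector mapping specimen id to OTU id.
#' @slot otuNames a \code{DataFrame} with columns \code{otu}, \code{name},
#'   \code{status}.
#' @slot provenance data.frame of rule firings: \code{cell_a}, \code{cell_b},
#'   \code{rule}, \code{action}.
#' @slot conflicts data.frame of flagged cluster pairs and dropped edges.
#'
#' @seealso [reconcileCells()], [assignNames()]
#' @exportClass SpeciesAssignment
setClass("SpeciesAssignment",
  slots = c(otu = "integer", otuNames = "DataFrame",
            provenance = "data.frame", conflicts = "data.frame"))

setValidity("SpeciesAssignment", function(object) {
  if (length(object@otu) && (is.null(names(object@otu)) ||
      anyDuplicated(names(object@otu))))
    return("'otu' must be uniquely named by specimen id")
  nm <- object@otuNames
  if (nrow(nm)) {
    if (!all(c("otu", "name", "status") %in% colnames(nm)))
      return("'otuNames' needs columns otu, name, status")
    if (anyDuplicated(nm$otu))
      return("every OTU must have exactly one name")
    if (!all(nm$status %in% c("named", "cf", "provisional")))
      return("status must be one of named, cf, provisional")
  }
  TRUE
})

#' Species-by-sampling-event incidence matrix
#'
#' Binary presence of each species (OTU or field morphospecies) in each
#' sampling event; the substrate of sample-based rarefaction and the Chao2
#' estimator. Species never observed are excluded, so every retained species
#' occurs in between 1 and \code{m} events.
#'
#' @slot mat logical matrix, species in rows, sampling events in columns.
#'
#' @seealso [buildIncidence()], [rarefactionCurve()], [chao2Estimate()]
#' @exportClass IncidenceMatrix
setClass("IncidenceMatrix", slots = c(mat = "matrix"))

setValidity("IncidenceMatrix", function(object) {
  m <- object@mat
  if (!is.logical(m))
    return("'mat' must be a logical matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("'mat' must have species rownames and event colnames")
  if (ncol(m) < 1L)
    return("at least one sampling event is required")
  y <- rowSums(m)
  if (any(y < 1L))
    return("species with no incidences must be excluded")
  TRUE
})
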