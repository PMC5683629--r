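#' @rdname accessors
#' @name accessors
#' @title Accessors for barcodeAudit classes
#'
#' @description Small accessor generics so that user code never reaches into
#' slots: specimen ids, group labels and counts, distance values and
#' compared-site counts, and incidence summaries (\code{S_obs}, the per
#' species incidence counts \code{Y_j}, and the unique/duplicate counts
#' \code{Q1}/\code{Q2} that drive Chao2).
#'
#' @param x an object of the documented class.
#' @param ... unused.
#' @return The extracted component; see each method.
NULL

#' @rdname accessors
#' @export
setGeneric("specimenIds", function(x, ...) standardGeneric("specimenIds"))

#' @rdname accessors
#' @export
setMethod("specimenIds", "LocusAlignment", function(x, ...) names(x@seqs))

#' @rdname accessors
#' @export
setMethod("specimenIds", "BarcodeDataset",
          function(x, ...) x@specimens$specimen_id)

#' @rdname accessors
#' @export
setMethod("specimenIds", "PDistanceMatrix", function(x, ...) x@ids)

#' @rdname accessors
#' @export
setMethod("specimenIds", "Partition", function(x, ...) names(x@labels))

#' @rdname accessors
#' @export
setGeneric("locusName", function(x) standardGeneric("locusName"))

#' @rdname accessors
#' @export
setMethod("locusName", "LocusAlignment", function(x) x@locus)

#' @rdname accessors
#' @export
setGeneric("alignedSeqs", function(x) standardGeneric("alignedSeqs"))

#' @rdname accessors
#' @export
setMethod("alignedSeqs", "LocusAlignment", function(x) x@seqs)

#' @rdname accessors
#' @export
setGeneric("specimenTable", function(x) standardGeneric("specimenTable"))

#' @rdname accessors
#' @export
setMethod("specimenTable", "BarcodeDataset", function(x) x@specimens)

#' @rdname accessors
#' @export
setGeneric("locusAlignment", function(x, locus) standardGeneric("locusAlignment"))

#' @rdname accessors
#' @param locus locus name to extract.
#' @export
setMethod("locusAlignment", "BarcodeDataset", function(x, locus) {
  if (!locus %in% names(x@alignments))
    stop("no alignment for locus '", locus, "'")
  x@alignments[[locus]]
})

#' @rdname accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname accessors
#' @export
setMethod("distances", "PDistanceMatrix", function(x) x@d)

#' @rdname accessors
#' @export
setGeneric("comparedSites", function(x) standardGeneric("comparedSites"))

#' @rdname accessors
#' @export
setMethod("comparedSites", "PDistanceMatrix", function(x) x@nSites)

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setMethod("groupLabels", "Partition", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("groupCount", function(x) standardGeneric("groupCount"))

#' @rdname accessors
#' @export
setMethod("groupCount", "Partition", function(x) length(unique(x@labels)))

#' @rdname accessors
#' @export
setGeneric("partitionMethod", function(x) standardGeneric("partitionMethod"))

#' @rdname accessors
#' @export
setMethod("partitionMethod", "Partition", function(x) x@method)

#' @rdname accessors
#' @export
setGeneric("selectedPartition", function(x) standardGeneric("selectedPartition"))

#' @rdname accessors
#' @export
setMethod("selectedPartition", "ABGDResult", function(x) x@selected)

#' @rdname accessors
#' @export
setGeneric("priorGrid", function(x) standardGeneric("priorGrid"))

#' @rdname accessors
#' @export
setMethod("priorGrid", "ABGDResult", function(x) x@priors)

#' Per-prior group counts of an ABGD analysis
#'
#' @param x an \linkS4class{ABGDResult}.
#' @return data.frame with columns \code{prior}, \code{n_groups_initial},
#'   \code{n_groups_recursive}, \code{selected}.
#' @export
abgdSummary <- function(x) {
  stopifnot(is(x, "ABGDResult"))
  data.frame(prior = x@priors,
             n_groups_initial = x@nInitial,
             n_groups_recursive = x@nRecursive,
             selected = seq_along(x@priors) == x@selectedIndex)
}

#' @rdname accessors
#' @export
setGeneric("otuOf", function(x) standardGeneric("otuOf"))

#' @rdname accessors
#' @export
setMethod("otuOf", "SpeciesAssignment", function(x) x@otu)

#' @rdname accessors
#' @export
setGeneric("otuNames", function(x) standardGeneric("otuNames"))

#' @rdname accessors
#' @export
setMethod("otuNames", "SpeciesAssignment", function(x) x@otuNames)

#' @rdname accessors
#' @export
setGeneric("ruleProvenance", function(x) standardGeneric("ruleProvenance"))

#' @rdname accessors
#' @export
setMethod("ruleProvenance", "SpeciesAssignment", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("ruleConflicts", function(x) standardGeneric("ruleConflicts"))

#' @rdname accessors
#' @export
setMethod("ruleConflicts", "SpeciesAssignment", function(x) x@conflicts)

#' @rdname accessors
#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))

#' @rdname accessors
#' @export
setMethod("incidence", "IncidenceMatrix", function(x) x@mat)

#' @rdname accessors
#' @export
setGeneric("sObs", function(x) standardGeneric("sObs"))

#' @rdname accessors
#' @export
setMethod("sObs", "IncidenceMatrix", function(x) nrow(x@mat))

#' @rdname accessors
#' @export
setGeneric("nSamplingEvents", function(x) standardGeneric("nSamplingEvents"))

#' @rdname accessors
#' @export
setMethod("nSamplingEvents", "IncidenceMatrix", function(x) ncol(x@mat))

#' @rdname accessors
#' @export
setGeneric("speciesIncidence", function(x) standardGeneric("speciesIncidence"))

#' @rdname accessors
#' @export
setMethod("speciesIncidence", "IncidenceMatrix", function(x) {
  y <- rowSums(x@mat)
  storage.mode(y) <- "integer"
  y
})

#' @rdname accessors
#' @export
setGeneric("qCounts", function(x) standardGeneric("qCounts"))

#' @rdname accessors
#' @export
setMethod("qCounts", "IncidenceMatrix", function(x) {
  y <- rowSums(x@mat)
  c(Q1 = sum(y == 1L), Q2 = sum(y == 2L))
})

setMethod("show", "LocusAlignment", function(object) {
  cat(sprintf("LocusAlignment [%s]: %d sequences x %d columns\n",
              object@locus, length(object@seqs),
              Biostrings::width(object@seqs)[1L]))
})

setMethod("show", "BarcodeDataset", function(object) {
  cat(sprintf("BarcodeDataset: %d specimens (%d survey, %d reference); loci: %s\n",
              nrow(object@specimens),
              sum(object@specimens$role == "survey"),
              sum(object@specimens$role == "reference"),
              paste(names(object@alignments), collapse = ", ")))
})

setMethod("show", "PDistanceMatrix", function(object) {
  off <- object@d[upper.tri(object@d)]
  cat(sprintf("PDistanceMatrix: %d specimens; distances %.4f-%.4f\n",
              length(object@ids),
              if (length(off)) min(off) else 0,
              if (length(off)) max(off) else 0))
})

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition [%s]: %d specimens in %d groups\n",
              object@method, length(object@labels),
              length(unique(object@labels))))
})

setMethod("show", "ABGDResult", function(object) {
  cat(sprintf(
    "ABGDResult: %d priors in [%.4g, %.4g]; selected %d groups at P=%.4g\n",
    length(object@priors), min(object@priors), max(object@priors),
    groupCount(object@selected), object@priors[object@selectedIndex]))
})

setMethod("show", "SpeciesAssignment", function(object) {
  cat(sprintf(
    "SpeciesAssignment: %d specimens in %d OTUs (%d named, %d cf, %d provisional); %d conflict(s)\n",
    length(object@otu), nrow(object@otuNames),
    sum(object@otuNames$status == "named"),
    sum(object@otuNames$status == "cf"),
    sum(object@otuNames$status == "provisional"),
    nrow(object@conflicts)))
})

setMethod("show", "IncidenceMatrix", function(object) {
  q <- qCounts(object)
  cat(sprintf("IncidenceMatrix: %d species x %d events (Q1=%d, Q2=%d)\n",
              nrow(object@mat), ncol(object@mat), q[["Q1"]], q[["Q2"]]))
})
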