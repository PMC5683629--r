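#' Read one pre-aligned locus from a FASTA file
#'
#' Reads an aligned FASTA file into a \linkS4class{LocusAlignment}. The
#' specimen id is the first whitespace-delimited token of each header (FASTA
#' headers cannot safely carry spaces, so ids use underscores; the metadata
#' table may keep a display form). Sequences are normalised on read:
#' upper-cased, \code{U} mapped to \code{T}, and every IUPAC ambiguity code
#' other than \code{N} collapsed to \code{N}. Gap characters \code{-} (and
#' \code{.}) are kept as \code{-}.
#'
#' Alignment is assumed to have been done upstream (e.g. with MAFFT); this
#' package starts at the distance matrix.
#'
#' @param path path to a FASTA file.
#' @param locus locus tag to attach, e.g. \code{"COI"} or \code{"16S"}.
#' @return a \linkS4class{LocusAlignment}.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 extra text", "ACGTAC", ">s2", "ACGTTC"), tf)
#' aln <- readLocusAlignment(tf, "COI")
#' specimenIds(aln)
#' @export
readLocusAlignment <- function(path, locus) {
  if (!file.exists(path))
    stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L)
    stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(raw), "[[:space:]]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate specimen id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U.", "T-", seqs)
  seqs <- gsub("[^-ACGT]", "N", seqs)
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    bad <- which(w != w[1L])[1L]
    stop(sprintf("unequal sequence lengths in %s: '%s' has %d columns, expected %d",
                 path, ids[bad], w[bad], w[1L]))
  }
  names(seqs) <- ids
  new("LocusAlignment", locus = locus, seqs = Biostrings::DNAStringSet(seqs))
}

#' Write an alignment back to FASTA
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeLocusAlignment <- function(aln, path) {
  stopifnot(is(aln, "LocusAlignment"))
  Biostrings::writeXStringSet(aln@seqs, path, width = 80L)
  invisible(path)
}

SPECIMEN_REQUIRED <- c("specimen_id", "role", "site", "locality",
                       "sampling_event")
SPECIMEN_OPTIONAL <- c("catalog", "region", "season", "field_genus",
                       "field_morphospecies", "reference_name")

#' Read the specimen metadata table
#'
#' Reads a tab-separated table with a header row into a
#' \code{\link[S4Vectors]{DataFrame}}, one row per specimen, preserving row
#' order. Required columns: \code{specimen_id}, \code{role}, \code{site},
#' \code{locality}, \code{sampling_event}. Recognised optional columns:
#' \code{catalog}, \code{region}, \code{season}, \code{field_genus},
#' \code{field_morphospecies}, \code{reference_name}, plus any number of
#' morphology flag columns named \code{morph_<candidate name>} holding
#' TRUE/FALSE (does the specimen fit that species' morphological
#' description). Unknown columns are dropped with a warning.
#'
#' Invariants enforced: unique \code{specimen_id}; \code{role} is
#' \code{"survey"} or \code{"reference"}; references carry a
#' \code{reference_name}; survey specimens carry a
#' \code{field_morphospecies}.
#'
#' @param path path to a TSV file.
#' @return a \code{DataFrame} with one list-column \code{morphology_flags}
#'   (named logical vectors, possibly empty) and the columns above; absent
#'   optional columns are filled with \code{NA}.
#' @export
readSpecimenTable <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), quote = "")
  missing <- setdiff(SPECIMEN_REQUIRED, colnames(tab))
  if (length(missing))
    stop("specimen table lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(tab$specimen_id))
    stop("duplicate specimen_id: ",
         paste(unique(tab$specimen_id[duplicated(tab$specimen_id)]),
               collapse = ", "))
  morphCols <- grep("^morph_", colnames(tab), value = TRUE)
  unknown <- setdiff(colnames(tab),
                     c(SPECIMEN_REQUIRED, SPECIMEN_OPTIONAL, morphCols))
  if (length(unknown))
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
  for (col in SPECIMEN_OPTIONAL)
    if (!col %in% colnames(tab)) tab[[col]] <- NA_character_
  bad <- !tab$role %in% c("survey", "reference")
  if (any(bad))
    stop("role must be 'survey' or 'reference'; offending specimen: ",
         tab$specimen_id[bad][1L])
  noRef <- tab$role == "reference" & is.na(tab$reference_name)
  if (any(noRef))
    stop("reference specimen without reference_name: ",
         paste(tab$specimen_id[noRef], collapse = ", "))
  noMorph <- tab$role == "survey" & is.na(tab$field_morphospecies)
  if (any(noMorph))
    stop("survey specimen without field_morphospecies: ",
         paste(tab$specimen_id[noMorph], collapse = ", "))
  flags <- lapply(seq_len(nrow(tab)), function(i) {
    v <- vapply(morphCols, function(cl) {
      x <- tab[[cl]][i]
      !is.na(x) && toupper(x) %in% c("TRUE", "T", "1", "YES")
    }, logical(1))
    names(v) <- sub("^morph_", "", morphCols)
    v
  })
  out <- S4Vectors::DataFrame(
    tab[, c(SPECIMEN_REQUIRED, SPECIMEN_OPTIONAL)], check.names = FALSE)
  out$morphology_flags <- flags
  rownames(out) <- NULL
  out
}

#' Write a specimen table to TSV
#'
#' Inverse of [readSpecimenTable()]: morphology flags are expanded back to
#' \code{morph_<name>} columns. Round-tripping preserves all known fields.
#'
#' @param specimens a \code{DataFrame} as returned by [readSpecimenTable()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSpecimenTable <- function(specimens, path) {
  df <- as.data.frame(specimens[, c(SPECIMEN_REQUIRED, SPECIMEN_OPTIONAL)])
  if ("morphology_flags" %in% colnames(specimens)) {
    cand <- unique(unlist(lapply(specimens$morphology_flags, names)))
    for (nm in cand)
      df[[paste0("morph_", nm)]] <- vapply(
        specimens$morphology_flags,
        function(v) isTRUE(unname(v[nm])), logical(1))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Assemble specimens and alignments into a validated dataset
#'
#' @param specimens a \code{DataFrame} from [readSpecimenTable()].
#' @param alignments a named list of \linkS4class{LocusAlignment} objects.
#' @return a \linkS4class{BarcodeDataset}; fails listing orphan ids when an
#'   alignment contains a specimen absent from the table.
#' @export
BarcodeDataset <- function(specimens, alignments) {
  if (is.null(names(alignments)))
    names(alignments) <- vapply(alignments, locusName, character(1))
  new("BarcodeDataset", specimens = specimens,
      alignments = S4Vectors::SimpleList(alignments))
}

#' Write a phylogenetic tree in newick format
#'
#' Thin wrapper over \code{\link[ape]{write.tree}} that first checks every
#' tip is labelled and every branch length is non-negative, and replaces
#' spaces in tip labels with underscores so the file round-trips.
#'
#' @param tree an \code{ape} \code{phylo} object.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeNewick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(!nzchar(tree$tip.label)))
    stop("every tip must be labelled")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("branch lengths must be non-negative")
  tree$tip.label <- gsub("[[:space:]]+", "_", tree$tip.label)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write the standard report files for a completed audit
#'
#' Emits deterministic TSV/JSON outputs: candidate partitions, the species
#' assignment with rule provenance, the concordance audit, and the richness
#' curves and estimates. Reruns with identical inputs produce byte-identical
#' files. Any component may be \code{NULL} to skip it; an empty assignment
#' yields files with headers only.
#'
#' @param partitions named list of \linkS4class{Partition} objects (or NULL).
#' @param assignment a \linkS4class{SpeciesAssignment} (or NULL).
#' @param audit a concordance report from [auditConcordance()] (or NULL).
#' @param richness a list with elements \code{curves} and \code{estimates}
#'   as data.frames (or NULL).
#' @param outDir output directory, created if needed.
#' @return invisibly, the character vector of files written.
#' @export
writeReports <- function(partitions = NULL, assignment = NULL, audit = NULL,
                         richness = NULL, outDir) {
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  written <- character(0)
  tsv <- function(df, file) {
    p <- file.path(outDir, file)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    written <<- c(written, p)
  }
  if (!is.null(partitions)) {
    rows <- lapply(partitions, function(p) {
      data.frame(specimen_id = specimenIds(p),
                 method = partitionMethod(p),
                 group = unname(groupLabels(p)))
    })
    tsv(do.call(rbind, c(rows, list(make.row.names = FALSE))),
        "partitions.tsv")
  }
  if (!is.null(assignment)) {
    otu <- otuOf(assignment)
    nm <- as.data.frame(otuNames(assignment))
    sp <- data.frame(specimen_id = names(otu), otu_id = unname(otu))
    sp <- merge(sp, nm, by.x = "otu_id", by.y = "otu", all.x = TRUE,
                sort = FALSE)
    sp <- sp[order(match(sp$specimen_id, names(otu))),
             c("specimen_id", "otu_id", "name", "status")]
    tsv(sp, "species_assignments.tsv")
    tsv(ruleConflicts(assignment), "conflicts.tsv")
    p <- file.path(outDir, "provenance.json")
    writeLines(jsonlite::toJSON(ruleProvenance(assignment),
                                dataframe = "rows", pretty = TRUE), p)
    written <- c(written, p)
  }
  if (!is.null(audit)) {
    p <- file.path(outDir, "audit.json")
    writeLines(jsonlite::toJSON(
      list(percent_correct = audit$percentCorrect,
           n_scored = audit$nScored,
           verdicts = audit$verdicts),
      dataframe = "rows", pretty = TRUE, auto_unbox = TRUE, digits = NA), p)
    written <- c(written, p)
    if (!is.null(audit$genusTable))
      tsv(audit$genusTable, "genus_table.tsv")
  }
  if (!is.null(richness)) {
    if (!is.null(richness$curves)) tsv(richness$curves, "richness_curves.tsv")
    if (!is.null(richness$estimates))
      tsv(richness$estimates, "richness_estimates.tsv")
  }
  invisible(written)
}

#' Export a distance matrix as TSV
#'
#' Writes ids as header row and first column with the full (symmetric)
#' matrix populated.
#'
#' @param D a \linkS4class{PDistanceMatrix}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeDistanceMatrix <- function(D, path) {
  stopifnot(is(D, "PDistanceMatrix"))
  df <- data.frame(specimen_id = D@ids, D@d, check.names = FALSE)
  colnames(df) <- c("specimen_id", D@ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
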