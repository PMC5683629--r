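# Scoring field identifications against barcode-derived OTUs.

# display form of a specimen's field label
.fieldLabel <- function(records) {
  g <- records$field_genus
  m <- records$field_morphospecies
  lab <- ifelse(is.na(g), m, paste(g, m))
  names(lab) <- records$specimen_id
  lab
}

#' Score field identifications against barcode OTUs
#'
#' A specimen is \emph{correct} when (a) its field name equals the name
#' assigned to its OTU, or (b) its field morphospecies label and its OTU
#' map one-to-one onto each other within the scored scope — the label is
#' used for no other OTU and the OTU carries no other label. If the
#' members of one OTU carry several different field labels, every one of
#' those members is \emph{misidentified}: a cluster field-split across
#' labels is evidence that none of those identifications can be trusted.
#' Specimens without a field label are left unscored and logged.
#'
#' @param records specimen \code{DataFrame} (see [readSpecimenTable()]).
#' @param assignment a named \linkS4class{SpeciesAssignment}.
#' @param scope optional character vector of \code{site} values to keep
#'   (e.g. the survey study area, excluding external reference sites);
#'   \code{NULL} keeps every site. Only survey specimens are scored.
#' @param seasons optional character vector of \code{season} values to
#'   keep.
#' @return a list of class \code{"concordanceReport"}: \code{verdicts}
#'   (data.frame: specimen_id, field_label, otu, verdict),
#'   \code{percentCorrect} (0-100 over scored specimens), \code{nScored},
#'   \code{unscored} (ids), and \code{genusTable} (\code{NULL}; filled by
#'   [genusSummary()]).
#' @export
auditConcordance <- function(records, assignment, scope = NULL,
                             seasons = NULL) {
  stopifnot(is(assignment, "SpeciesAssignment"))
  otu <- otuOf(assignment)
  nm <- otuNames(assignment)
  otuName <- nm$name
  names(otuName) <- as.character(nm$otu)
  keep <- records$role == "survey"
  if (!is.null(scope)) keep <- keep & records$site %in% scope
  if (!is.null(seasons)) keep <- keep & records$season %in% seasons
  rec <- records[keep, , drop = FALSE]
  inOtu <- rec$specimen_id %in% names(otu)
  if (!all(inOtu))
    stop("in-scope survey specimens without an OTU: ",
         paste(rec$specimen_id[!inOtu], collapse = ", "))
  labels <- .fieldLabel(rec)
  unscored <- rec$specimen_id[is.na(labels)]
  scored <- setdiff(rec$specimen_id, unscored)
  if (!length(scored))
    stop("no scorable specimens in scope")
  lab <- labels[scored]
  sotu <- otu[scored]
  labelsPerOtu <- tapply(lab, sotu, function(x) length(unique(x)))
  otusPerLabel <- tapply(sotu, lab, function(x) length(unique(x)))
  verdict <- vapply(scored, function(id) {
    o <- sotu[[id]]
    if (labelsPerOtu[[as.character(o)]] > 1L) return("misidentified")
    nameMatch <- identical(unname(lab[[id]]),
                           unname(otuName[[as.character(o)]]))
    bijective <- otusPerLabel[[lab[[id]]]] == 1L
    if (nameMatch || bijective) "correct" else "misidentified"
  }, character(1))
  verdicts <- data.frame(specimen_id = scored,
                         field_label = unname(lab),
                         otu = unname(sotu),
                         verdict = unname(verdict))
  if (length(unscored))
    verdicts <- rbind(verdicts, data.frame(
      specimen_id = unscored, field_label = NA_character_,
      otu = unname(otu[unscored]), verdict = "unscored"))
  structure(list(
    verdicts = verdicts,
    percentCorrect = 100 * sum(verdict == "correct") / length(verdict),
    nScored = length(verdict),
    unscored = unscored,
    genusTable = NULL), class = "concordanceReport")
}

#' @export
print.concordanceReport <- function(x, ...) {
  cat(sprintf("concordanceReport: %d scored, %.1f%% correct, %d unscored\n",
              x$nScored, x$percentCorrect, length(x$unscored)))
  invisible(x)
}

#' Per-genus field vs barcode species counts
#'
#' Tallies, per genus and per season plus combined, the number of distinct
#' species units each identification route recognises: the field count is
#' the number of distinct field morphospecies labels under each field
#' genus; the barcode count is the number of distinct OTUs whose assigned
#' name falls under each genus. Barcode counts are tallied under the
#' \emph{corrected} genus (the genus of the final assigned name), which may
#' differ from the field genus when specimens were misassigned at the
#' genus level, so a genus may show field species and zero barcode
#' species, or vice versa. A totals row is appended.
#'
#' @param records specimen \code{DataFrame}.
#' @param assignment a named \linkS4class{SpeciesAssignment}.
#' @param seasons character vector of season values defining the season
#'   columns (in order); defaults to the seasons observed in scope.
#' @param scope optional \code{site} filter as in [auditConcordance()].
#' @return data.frame with one row per genus plus \code{"Totals"}, and
#'   columns \code{field_<season>}, \code{barcode_<season>}, ...,
#'   \code{field_combined}, \code{barcode_combined}.
#' @export
genusSummary <- function(records, assignment, seasons = NULL, scope = NULL) {
  stopifnot(is(assignment, "SpeciesAssignment"))
  otu <- otuOf(assignment)
  nm <- otuNames(assignment)
  otuName <- nm$name
  names(otuName) <- as.character(nm$otu)
  keep <- records$role == "survey"
  if (!is.null(scope)) keep <- keep & records$site %in% scope
  rec <- records[keep, , drop = FALSE]
  if (is.null(seasons))
    seasons <- sort(unique(stats::na.omit(rec$season)))
  slices <- c(stats::setNames(as.list(seasons), seasons),
              list(combined = NULL))
  perSlice <- lapply(slices, function(s) {
    sub <- if (is.null(s)) rec else rec[!is.na(rec$season) &
                                          rec$season == s, , drop = FALSE]
    if (!nrow(sub))
      return(list(field = integer(0), barcode = integer(0)))
    lab <- .fieldLabel(sub)
    ok <- !is.na(sub$field_genus) & !is.na(lab)
    field <- if (any(ok))
      vapply(split(lab[ok], sub$field_genus[ok]),
             function(x) length(unique(x)), integer(1))
    else integer(0)
    ids <- intersect(sub$specimen_id, names(otu))
    otus <- unique(otu[ids])
    bgenus <- vapply(strsplit(otuName[as.character(otus)], " "),
                     `[`, character(1), 1L)
    barcode <- if (length(otus))
      vapply(split(otus, bgenus), function(x) length(unique(x)), integer(1))
    else integer(0)
    list(field = field, barcode = barcode)
  })
  genera <- sort(unique(unlist(lapply(perSlice, function(x)
    c(names(x$field), names(x$barcode))))))
  out <- data.frame(genus = c(genera, "Totals"))
  for (sl in names(perSlice)) {
    f <- perSlice[[sl]]$field[genera]
    b <- perSlice[[sl]]$barcode[genera]
    f[is.na(f)] <- 0L; b[is.na(b)] <- 0L
    out[[paste0("field_", sl)]] <- c(f, sum(f))
    out[[paste0("barcode_", sl)]] <- c(b, sum(b))
  }
  rownames(out) <- NULL
  out
}

#' Field-over-barcode species overestimation
#'
#' The headline overestimation percentage of a genus summary:
#' \code{(field_total - barcode_total) / barcode_total * 100}, reported to
#' one decimal, with the value rounded to the nearest ten alongside as the
#' headline figure.
#'
#' @param fieldTotal,barcodeTotal combined species totals for the two
#'   identification routes.
#' @return list with \code{percent} (one decimal) and \code{headline}
#'   (nearest ten).
#' @export
overestimationPercent <- function(fieldTotal, barcodeTotal) {
  p <- (fieldTotal - barcodeTotal) / barcodeTotal * 100
  list(percent = round(p, 1L), headline = round(p / 10) * 10)
}
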