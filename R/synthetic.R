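# Synthetic two-locus communities with known species truth and a
# configurable field-labelling error process.

#' Configuration for the synthetic community generator
#'
#' The generator emulates the structure a two-locus barcode survey sees:
#' \code{K} species whose conspecific p-distances are small
#' (\code{muIntra}) and whose species centroids are far apart
#' (\code{dMinInter}), specimens spread over localities and sampling
#' events, a fraction of reference specimens carrying true names, and a
#' field-labelling error process that lumps, splits and mis-genera labels.
#'
#' Defaults: locus lengths 654 (COI) and 550 (16S) match full-length
#' barcode fragments; \code{muIntra = 0.01} and \code{dMinInter = 0.08}
#' put the data in the clean-barcode-gap regime (about 1% conspecific vs
#' over 8% heterospecific divergence, typical of mitochondrial barcodes in
#' amphibians); error rates \code{pSplit = 0.2}, \code{pLump = 0.05},
#' \code{pWrongGenus = 0.1} are illustrative of a field team that mostly
#' splits too finely.
#'
#' @param K true species count (>= 1).
#' @param specimensPerSpecies integer range \code{c(lo, hi)} (or a single
#'   count) of survey+reference specimens per species.
#' @param coiLength,s16Length alignment columns per locus.
#' @param muIntra expected conspecific p-distance (must be <
#'   \code{dMinInter}).
#' @param dMinInter minimum inter-centroid p-distance.
#' @param nLocalities,nEvents number of localities and sampling events
#'   (events are nested in localities and alternate dry/wet seasons).
#' @param nGenera number of genera the species are spread over.
#' @param referenceFraction probability a specimen is a named reference.
#' @param pSplit,pLump,pWrongGenus field-labelling error rates in [0, 1].
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return a list of class \code{"syntheticConfig"}.
#' @export
syntheticConfig <- function(K = 6L, specimensPerSpecies = c(4L, 10L),
                            coiLength = 654L, s16Length = 550L,
                            muIntra = 0.01, dMinInter = 0.08,
                            nLocalities = 4L, nEvents = 12L,
                            nGenera = max(2L, ceiling(K / 3)),
                            referenceFraction = 0.15,
                            pSplit = 0.2, pLump = 0.05, pWrongGenus = 0.1,
                            seed = 1L) {
  stopifnot(K >= 1L, muIntra < dMinInter, muIntra >= 0, dMinInter <= 0.75,
            all(c(pSplit, pLump, pWrongGenus) >= 0),
            all(c(pSplit, pLump, pWrongGenus) <= 1),
            referenceFraction >= 0, referenceFraction <= 1,
            nLocalities >= 1L, nEvents >= 1L, nGenera >= 1L)
  if (length(specimensPerSpecies) == 1L)
    specimensPerSpecies <- rep(specimensPerSpecies, 2L)
  structure(list(K = as.integer(K),
                 specimensPerSpecies = as.integer(specimensPerSpecies),
                 coiLength = as.integer(coiLength),
                 s16Length = as.integer(s16Length),
                 muIntra = muIntra, dMinInter = dMinInter,
                 nLocalities = as.integer(nLocalities),
                 nEvents = as.integer(nEvents),
                 nGenera = as.integer(nGenera),
                 referenceFraction = referenceFraction,
                 pSplit = pSplit, pLump = pLump,
                 pWrongGenus = pWrongGenus,
                 seed = as.integer(seed)), class = "syntheticConfig")
}

.mutateSeq <- function(seq, rate) {
  hit <- which(stats::runif(length(seq)) < rate)
  for (i in hit)
    seq[i] <- sample(setdiff(DNA_BASES4, seq[i]), 1L)
  seq
}

.pdistVec <- function(a, b) mean(a != b)

#' Generate a synthetic community with known truth
#'
#' Builds \code{K} species-centroid pairs (COI, 16S) by mutating a shared
#' ancestral sequence and rejection-sampling until every pairwise centroid
#' p-distance reaches \code{dMinInter}; each specimen's sequences derive
#' from its species centroids by independent per-site substitution at rate
#' \code{muIntra/2} per copy, so the expected conspecific p-distance is
#' about \code{muIntra}. Both loci share the species structure (no
#' gene-tree discordance). Specimens are spread uniformly over sampling
#' events (events nested in localities, alternating dry/wet seasons);
#' reference specimens carry their true name and sit outside the survey
#' site. Survey specimens start with error-free field labels equal to the
#' truth; perturb them with [applyFieldErrors()].
#'
#' @param config a [syntheticConfig()].
#' @return list with \code{records} (specimen \code{DataFrame}),
#'   \code{alignments} (named list of \linkS4class{LocusAlignment}:
#'   \code{COI}, \code{16S}), and \code{truth} (class
#'   \code{"SyntheticTruth"}: \code{speciesOf}, \code{trueNames},
#'   \code{centroids}, realized distance summaries, \code{config}).
#' @export
generateCommunity <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(config$seed)
  K <- config$K
  genera <- paste0("Genus", LETTERS[rep_len(seq_len(config$nGenera), K)])
  epithets <- sprintf("species%02d", seq_len(K))
  trueNames <- paste(genera, epithets)
  anc <- list(COI = sample(DNA_BASES4, config$coiLength, replace = TRUE),
              `16S` = sample(DNA_BASES4, config$s16Length, replace = TRUE))
  centroids <- list(COI = vector("list", K), `16S` = vector("list", K))
  for (k in seq_len(K)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      cand <- lapply(anc, .mutateSeq, rate = config$dMinInter)
      far <- TRUE
      for (j in seq_len(k - 1L))
        for (loc in names(anc))
          if (.pdistVec(cand[[loc]], centroids[[loc]][[j]]) <
              config$dMinInter) far <- FALSE
      if (far) {
        centroids$COI[[k]] <- cand$COI
        centroids$`16S`[[k]] <- cand$`16S`
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("rejection sampling failed; reduce K or dMinInter")
  }
  counts <- sample(seq(config$specimensPerSpecies[1L],
                       config$specimensPerSpecies[2L]),
                   K, replace = TRUE)
  n <- sum(counts)
  speciesOf <- rep(seq_len(K), counts)
  ids <- sprintf("SYN%04d", seq_len(n))
  names(speciesOf) <- ids
  events <- sprintf("EV%02d", seq_len(config$nEvents))
  eventLocality <- sprintf("LOC%02d",
                           rep_len(seq_len(config$nLocalities),
                                   config$nEvents))
  # two sampling periods: first half of the events dry, second half wet
  eventSeason <- rep(c("dry", "wet"),
                     c(ceiling(config$nEvents / 2),
                       floor(config$nEvents / 2)))
  names(eventLocality) <- names(eventSeason) <- events
  ev <- sample(events, n, replace = TRUE)
  isRef <- stats::runif(n) < config$referenceFraction
  coi <- s16 <- character(n)
  for (i in seq_len(n)) {
    k <- speciesOf[i]
    coi[i] <- paste(.mutateSeq(centroids$COI[[k]], config$muIntra / 2),
                    collapse = "")
    s16[i] <- paste(.mutateSeq(centroids$`16S`[[k]], config$muIntra / 2),
                    collapse = "")
  }
  names(coi) <- names(s16) <- ids
  records <- S4Vectors::DataFrame(
    specimen_id = ids,
    role = ifelse(isRef, "reference", "survey"),
    site = ifelse(isRef, "external", "LMR"),
    locality = unname(eventLocality[ev]),
    sampling_event = ifelse(isRef, NA_character_, ev),
    catalog = NA_character_,
    region = "synthetic",
    season = ifelse(isRef, NA_character_, unname(eventSeason[ev])),
    field_genus = ifelse(isRef, NA_character_, genera[speciesOf]),
    field_morphospecies = ifelse(isRef, NA_character_,
                                 epithets[speciesOf]),
    reference_name = ifelse(isRef, trueNames[speciesOf], NA_character_))
  records$morphology_flags <- rep(list(logical(0)), n)
  alignments <- list(
    COI = new("LocusAlignment", locus = "COI",
              seqs = Biostrings::DNAStringSet(coi)),
    `16S` = new("LocusAlignment", locus = "16S",
                seqs = Biostrings::DNAStringSet(s16)))
  # realized distance summaries
  interMin <- Inf
  for (a in seq_len(K - 1L))
    for (b in seq.int(a + 1L, K))
      interMin <- min(interMin,
                      .pdistVec(centroids$COI[[a]], centroids$COI[[b]]))
  truth <- structure(list(
    speciesOf = speciesOf,
    trueNames = stats::setNames(trueNames, seq_len(K)),
    genera = stats::setNames(genera, seq_len(K)),
    epithets = stats::setNames(epithets, seq_len(K)),
    centroids = centroids,
    minInterCentroid = if (K > 1L) interMin else NA_real_,
    labelMap = NULL,
    config = config), class = "SyntheticTruth")
  list(records = records, alignments = alignments, truth = truth)
}

#' Perturb field labels with lumping, splitting and wrong-genus errors
#'
#' Rewrites the survey specimens' field labels according to the error
#' model: within each genus, species are paired and each pair is
#' \emph{lumped} (both species share the first species' label) with
#' probability \code{pLump}; each unlumped species is \emph{split} with
#' probability \code{pSplit}, its members partitioned among 2-4 distinct
#' morphospecies labels; finally each distinct label has its genus token
#' replaced by a different genus with probability \code{pWrongGenus}.
#' Deterministic given the config seed (an offset stream, so generation
#' and labelling are independently reproducible).
#'
#' @param truth the \code{"SyntheticTruth"} from [generateCommunity()].
#' @param records the matching specimen \code{DataFrame}.
#' @param config the same [syntheticConfig()].
#' @return list with updated \code{records} and \code{truth} (the
#'   \code{labelMap} element records the species-to-label assignment).
#' @export
applyFieldErrors <- function(truth, records, config = truth$config) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  set.seed(config$seed + 1L)
  K <- config$K
  speciesOf <- truth$speciesOf
  survey <- records$specimen_id[records$role == "survey"]
  genus <- truth$genera
  epithet <- truth$epithets
  # per-specimen provisional label: genus token + epithet token
  labG <- stats::setNames(unname(genus[speciesOf[survey]]), survey)
  labE <- stats::setNames(unname(epithet[speciesOf[survey]]), survey)
  lumped <- rep(FALSE, K)
  for (g in unique(genus)) {
    sp <- sample(which(genus == g))  # random pairing within the genus
    while (length(sp) >= 2L) {
      pair <- sp[1:2]; sp <- sp[-(1:2)]
      if (stats::runif(1L) < config$pLump) {
        lumped[pair] <- TRUE
        labE[survey[speciesOf[survey] == pair[2L]]] <- epithet[pair[1L]]
      }
    }
  }
  for (k in seq_len(K)) {
    if (lumped[k]) next
    members <- intersect(names(speciesOf)[speciesOf == k], survey)
    if (length(members) >= 2L && stats::runif(1L) < config$pSplit) {
      gparts <- min(sample(2:4, 1L), length(members))
      assign <- sample(c(seq_len(gparts),
                         sample(gparts, length(members) - gparts,
                                replace = TRUE)))
      labE[members] <- sprintf("%s-m%d", epithet[k], assign)
    }
  }
  # wrong-genus errors applied once per distinct label so that lumped or
  # split labels stay internally consistent
  allGenera <- unique(genus)
  key <- paste(labG, labE)
  finalG <- stats::setNames(labG[!duplicated(key)], unique(key))
  for (u in names(finalG)) {
    if (length(allGenera) > 1L && stats::runif(1L) < config$pWrongGenus)
      finalG[u] <- sample(setdiff(allGenera, finalG[[u]]), 1L)
  }
  labG <- unname(finalG[key])
  idx <- match(survey, records$specimen_id)
  records$field_genus[idx] <- labG
  records$field_morphospecies[idx] <- unname(labE)
  labelMap <- split(paste(labG, labE), truth$trueNames[speciesOf[survey]])
  labelMap <- lapply(labelMap, unique)
  truth$labelMap <- labelMap
  list(records = records, truth = truth)
}

#' Run the full two-locus audit pipeline
#'
#' Convenience wrapper chaining every stage: per-locus distance matrices,
#' the COI threshold (BIN proxy) and gap-discovery partitions, 16S
#' conspecificity clusters, refined cells, rule-based reconciliation and
#' naming.
#'
#' @param records specimen \code{DataFrame}.
#' @param alignments named list with \code{COI} and \code{16S}
#'   \linkS4class{LocusAlignment} objects.
#' @param tCoi COI threshold for the BIN proxy (default 0.022).
#' @param abgd an [abgdConfig()].
#' @param t16 16S conspecificity threshold (default 0.03).
#' @param dCf naming distance for \code{cf.} status (default 0.05).
#' @param rules a [ruleConfig()].
#' @param minOverlap minimum compared sites per pair.
#' @return list: \code{partitions} (bin, abgd, s16), \code{abgdResult},
#'   \code{cells} (with unassigned), \code{assignment} (named
#'   \linkS4class{SpeciesAssignment}), \code{distances} (per locus).
#' @export
runBarcodeAudit <- function(records, alignments, tCoi = 0.022,
                            abgd = abgdConfig(), t16 = 0.03, dCf = 0.05,
                            rules = ruleConfig(), minOverlap = 100L) {
  dCoi <- distanceMatrix(alignments$COI, minOverlap = minOverlap)
  d16 <- distanceMatrix(alignments$`16S`, minOverlap = minOverlap)
  bin <- thresholdPartition(dCoi, tCoi)
  ab <- abgdPartition(dCoi, abgd)
  s16 <- conspecificityClusters(d16, "threshold", t16 = t16)
  cells <- refineCells(bin, selectedPartition(ab), s16)
  asn <- reconcileCells(cells$partition, s16, records, rules)
  asn <- assignNames(asn, records, s16, d16, dCf = dCf)
  list(partitions = list(bin = bin, abgd = selectedPartition(ab),
                         s16 = s16),
       abgdResult = ab, cells = cells, assignment = asn,
       distances = list(COI = dCoi, `16S` = d16))
}
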