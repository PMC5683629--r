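# Rule-based reconciliation of COI partitions with 16S clusters and
# localities into named species-level OTUs.

#' Toggle the reconciliation rules
#'
#' All rules are enabled by default. \code{R5morphology} controls whether
#' rule R5 (different 16S clusters, disjoint localities) requires a shared
#' morphology flag to merge; with it off, R5 never merges.
#'
#' @param R2,R3,R4,R5 enable the corresponding rule (see
#'   [reconcileCells()]).
#' @param R5morphology require a shared TRUE morphology flag for R5 merges.
#' @return a list of class \code{"ruleConfig"}.
#' @export
ruleConfig <- function(R2 = TRUE, R3 = TRUE, R4 = TRUE, R5 = TRUE,
                       R5morphology = TRUE) {
  structure(list(R2 = R2, R3 = R3, R4 = R4, R5 = R5,
                 R5morphology = R5morphology), class = "ruleConfig")
}

#' Intersect the COI partitions into refined cells
#'
#' Specimens placed in the same group by both COI methods (the BIN proxy
#' and gap discovery) are candidate conspecifics; the refined cells are
#' therefore the intersection of the two partitions — the finest
#' assumption, which later merge rules re-join explicitly. A specimen with
#' no COI data joins the unique cell whose members share its 16S cluster;
#' if its 16S cluster spans several cells it is left unassigned and
#' reported, and if its 16S cluster contains no COI-bearing specimen it
#' founds a new cell of its own.
#'
#' @param binPart COI \linkS4class{Partition} from [thresholdPartition()].
#' @param abgdPart COI \linkS4class{Partition} from [abgdPartition()]
#'   (the selected partition).
#' @param s16Part 16S \linkS4class{Partition}; the only partition covering
#'   specimens that lack COI.
#' @return list with elements \code{partition} (a \code{Partition} with
#'   method \code{"cells"}) and \code{unassigned} (character vector of
#'   COI-less specimens whose 16S cluster spans multiple cells).
#' @export
refineCells <- function(binPart, abgdPart, s16Part) {
  stopifnot(is(binPart, "Partition"), is(abgdPart, "Partition"),
            is(s16Part, "Partition"))
  coiIds <- intersect(specimenIds(binPart), specimenIds(abgdPart))
  if (!length(coiIds))
    stop("the two COI partitions share no specimens")
  key <- paste(groupLabels(binPart)[coiIds], groupLabels(abgdPart)[coiIds])
  lab <- match(key, unique(key))
  names(lab) <- coiIds
  s16lab <- groupLabels(s16Part)
  unassigned <- character(0)
  extra <- integer(0)
  nextCell <- max(lab)
  for (id in setdiff(specimenIds(s16Part), coiIds)) {
    mates <- names(s16lab)[s16lab == s16lab[id]]
    cells <- unique(lab[intersect(mates, coiIds)])
    if (length(cells) == 1L) {
      extra[id] <- cells
    } else if (length(cells) == 0L) {
      # share a new cell with an earlier COI-less specimen of the same
      # 16S cluster, if any
      mate <- intersect(mates, names(extra))
      if (length(mate)) {
        extra[id] <- extra[[mate[1L]]]
      } else {
        nextCell <- nextCell + 1L
        extra[id] <- nextCell
      }
    } else {
      unassigned <- c(unassigned, id)
    }
  }
  lab <- c(lab, extra)
  storage.mode(lab) <- "integer"
  list(partition = .makePartition(lab, "cells"), unassigned = unassigned)
}

# localities, 16S clusters and TRUE morphology flags per cell
.cellFeatures <- function(cells, s16Part, records) {
  lab <- groupLabels(cells)
  s16 <- groupLabels(s16Part)
  loc <- records$locality
  names(loc) <- records$specimen_id
  flags <- records$morphology_flags
  names(flags) <- records$specimen_id
  lapply(seq_len(max(lab)), function(g) {
    members <- names(lab)[lab == g]
    fl <- unlist(lapply(flags[intersect(members, names(flags))],
                        function(v) names(v)[which(v)]))
    list(members = members,
         localities = unique(stats::na.omit(unname(loc[members]))),
         clusters = unique(unname(s16[intersect(members, names(s16))])),
         morphOK = unique(fl))
  })
}

#' Merge refined cells into OTUs by the COI/16S/locality rules
#'
#' Evaluates every pair of distinct cells against four decision rules:
#' \describe{
#'   \item{R2}{same 16S cluster, disjoint locality sets: merge — the same
#'     species with geographically structured COI variation.}
#'   \item{R3}{same 16S cluster, shared locality: merge — the same species
#'     with population-level COI variation.}
#'   \item{R4}{different 16S clusters, shared locality: forbid merging —
#'     sympatric and divergent at both loci, hence separate species.}
#'   \item{R5}{different 16S clusters, disjoint localities: merge only if
#'     both cells contain specimens flagged as fitting the morphological
#'     description of the same candidate species (geographic variation);
#'     otherwise keep separate.}
#' }
#' OTUs are the connected components of the merge graph. If a merge chain
#' connects a forbidden (R4) pair, the component is split by dropping merge
#' edges incident to the forbidden pair until the two cells are
#' disconnected — R3 edges are dropped before R2 (before R5) — and the
#' pair is logged in \code{conflicts}; nothing is dropped silently.
#'
#' @param cells refined-cell \linkS4class{Partition} from [refineCells()].
#' @param s16Part 16S \linkS4class{Partition} covering every specimen in
#'   \code{cells}.
#' @param records specimen \code{DataFrame} (see [readSpecimenTable()]).
#' @param config a [ruleConfig()].
#' @return a \linkS4class{SpeciesAssignment} with OTU membership,
#'   provenance and conflicts filled in; names are added by
#'   [assignNames()].
#' @export
reconcileCells <- function(cells, s16Part, records, config = ruleConfig()) {
  stopifnot(is(cells, "Partition"), is(s16Part, "Partition"),
            inherits(config, "ruleConfig"))
  miss <- setdiff(specimenIds(cells), specimenIds(s16Part))
  if (length(miss))
    stop("specimens in cells but not in the 16S partition: ",
         paste(miss, collapse = ", "))
  feats <- .cellFeatures(cells, s16Part, records)
  nc <- length(feats)
  prov <- list()
  edges <- list()     # merge edges: list(a, b, rule)
  forbidden <- list() # R4 pairs
  addProv <- function(a, b, rule, action)
    prov[[length(prov) + 1L]] <<- data.frame(cell_a = a, cell_b = b,
                                             rule = rule, action = action)
  if (nc > 1L) {
    for (a in seq_len(nc - 1L)) {
      for (b in seq.int(a + 1L, nc)) {
        share16 <- length(intersect(feats[[a]]$clusters,
                                    feats[[b]]$clusters)) > 0L
        shareLoc <- length(intersect(feats[[a]]$localities,
                                     feats[[b]]$localities)) > 0L
        if (share16 && !shareLoc && config$R2) {
          edges[[length(edges) + 1L]] <- list(a = a, b = b, rule = "R2")
          addProv(a, b, "R2", "merge")
        } else if (share16 && shareLoc && config$R3) {
          edges[[length(edges) + 1L]] <- list(a = a, b = b, rule = "R3")
          addProv(a, b, "R3", "merge")
        } else if (!share16 && shareLoc && config$R4) {
          forbidden[[length(forbidden) + 1L]] <- c(a, b)
          addProv(a, b, "R4", "forbid")
        } else if (!share16 && !shareLoc && config$R5) {
          shared <- intersect(feats[[a]]$morphOK, feats[[b]]$morphOK)
          if (config$R5morphology && length(shared)) {
            edges[[length(edges) + 1L]] <- list(a = a, b = b, rule = "R5")
            addProv(a, b, "R5", "merge")
          }
        }
      }
    }
  }
  conflicts <- .emptyConflicts()
  # resolve transitivity violations: a merge chain connecting a forbidden
  # pair is cut at the forbidden pair, dropping R3 edges before R2 (then R5)
  rulePref <- c(R3 = 1L, R2 = 2L, R5 = 3L)
  for (fp in forbidden) {
    repeat {
      path <- .edgePath(edges, fp[1L], fp[2L], nc)
      if (is.null(path)) break
      incident <- Filter(function(ei) {
        e <- edges[[ei]]
        any(c(e$a, e$b) %in% fp)
      }, path)
      cand <- if (length(incident)) incident else path
      pick <- cand[[order(vapply(cand, function(ei)
        rulePref[[edges[[ei]]$rule]], integer(1)))[1L]]]
      e <- edges[[pick]]
      conflicts <- rbind(conflicts, data.frame(
        cell_a = fp[1L], cell_b = fp[2L], rule = "R4",
        detail = sprintf("dropped %s merge %d-%d", e$rule, e$a, e$b)))
      for (pi in seq_along(prov)) {
        pr <- prov[[pi]]
        if (pr$cell_a == e$a && pr$cell_b == e$b && pr$rule == e$rule &&
            pr$action == "merge")
          prov[[pi]]$action <- "merge_dropped"
      }
      edges[[pick]] <- NULL
    }
  }
  # connected components over the surviving merge edges
  parent <- seq_len(nc)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (e in edges) {
    ra <- find(e$a); rb <- find(e$b)
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  comp <- vapply(seq_len(nc), find, integer(1))
  lab <- groupLabels(cells)
  otuRaw <- comp[lab]
  names(otuRaw) <- names(lab)
  otu <- match(otuRaw, unique(otuRaw))
  storage.mode(otu) <- "integer"
  names(otu) <- names(otuRaw)
  provenance <- if (length(prov)) do.call(rbind, prov) else .emptyProvenance()
  new("SpeciesAssignment", otu = otu,
      otuNames = S4Vectors::DataFrame(otu = integer(0), name = character(0),
                                      status = character(0)),
      provenance = provenance, conflicts = conflicts)
}

.emptyProvenance <- function()
  data.frame(cell_a = integer(0), cell_b = integer(0), rule = character(0),
             action = character(0))

.emptyConflicts <- function()
  data.frame(cell_a = integer(0), cell_b = integer(0), rule = character(0),
             detail = character(0))

# BFS path between cells a and b over merge edges; returns edge indices or
# NULL when disconnected
.edgePath <- function(edges, a, b, nc) {
  if (!length(edges)) return(NULL)
  adj <- vector("list", nc)
  for (ei in seq_along(edges)) {
    e <- edges[[ei]]
    adj[[e$a]] <- rbind(adj[[e$a]], c(e$b, ei))
    adj[[e$b]] <- rbind(adj[[e$b]], c(e$a, ei))
  }
  prev <- rep(NA_integer_, nc)   # edge used to reach each cell
  prevNode <- rep(NA_integer_, nc)
  seen <- rep(FALSE, nc)
  queue <- a; seen[a] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    if (cur == b) {
      path <- integer(0); node <- b
      while (node != a) {
        path <- c(path, prev[node])
        node <- prevNode[node]
      }
      return(as.list(path))
    }
    for (r in seq_len(NROW(adj[[cur]]))) {
      nxt <- adj[[cur]][r, 1L]
      if (!seen[nxt]) {
        seen[nxt] <- TRUE
        prev[nxt] <- adj[[cur]][r, 2L]
        prevNode[nxt] <- cur
        queue <- c(queue, nxt)
      }
    }
  }
  NULL
}

#' Name the OTUs of a reconciled assignment
#'
#' Assigns each OTU a name with a status, in OTU order:
#' \enumerate{
#'   \item an OTU containing reference specimens takes the majority
#'     \code{reference_name} (status \code{named}; a tie takes the
#'     alphabetically first name with status \code{cf});
#'   \item otherwise, if a member shares a 16S cluster with a named
#'     reference, that name is adopted (status \code{named});
#'   \item otherwise, if the nearest named reference by minimum 16S
#'     distance lies within \code{dCf}, the name becomes
#'     \code{"Genus cf. epithet"} (status \code{cf});
#'   \item otherwise a provisional \code{"Genus sp. A"}, \code{"sp. B"},
#'     ... under the modal field genus of the members, letters allocated
#'     per genus by order of first member appearance (status
#'     \code{provisional}).
#' }
#' An OTU whose members split evenly over several field genera is named
#' under the alphabetically first modal genus and the tie is logged in
#' \code{conflicts}.
#'
#' @param assignment a \linkS4class{SpeciesAssignment} from
#'   [reconcileCells()].
#' @param records specimen \code{DataFrame}.
#' @param s16Part 16S \linkS4class{Partition}.
#' @param D16 16S \linkS4class{PDistanceMatrix} (used for the \code{cf}
#'   distance rule; members without 16S data are skipped).
#' @param dCf maximum 16S distance for a \code{cf.} assignment; beyond it
#'   the OTU is provisionally named. The default 0.05 sits above
#'   conspecific 16S variation but well below typical congeneric
#'   divergence.
#' @return the \code{SpeciesAssignment} with \code{otuNames} filled in.
#' @export
assignNames <- function(assignment, records, s16Part, D16, dCf = 0.05) {
  stopifnot(is(assignment, "SpeciesAssignment"), is(s16Part, "Partition"),
            is(D16, "PDistanceMatrix"))
  otu <- otuOf(assignment)
  refIdx <- records$role == "reference" & !is.na(records$reference_name)
  refNames <- records$reference_name[refIdx]
  names(refNames) <- records$specimen_id[refIdx]
  s16 <- groupLabels(s16Part)
  fieldGenus <- records$field_genus
  names(fieldGenus) <- records$specimen_id
  conflicts <- ruleConflicts(assignment)
  usedLetters <- list()  # per genus
  out <- vector("list", max(otu))
  for (o in seq_len(max(otu))) {
    members <- names(otu)[otu == o]
    inRefs <- intersect(members, names(refNames))
    name <- NULL; status <- NULL
    if (length(inRefs)) {
      tab <- sort(table(refNames[inRefs]), decreasing = TRUE)
      top <- names(tab)[tab == max(tab)]
      if (length(top) > 1L) { name <- sort(top)[1L]; status <- "cf" }
      else { name <- top; status <- "named" }
    }
    if (is.null(name)) {
      clusters <- unique(unname(s16[intersect(members, names(s16))]))
      mates <- names(s16)[s16 %in% clusters]
      linked <- intersect(mates, names(refNames))
      if (length(linked)) {
        tab <- sort(table(refNames[linked]), decreasing = TRUE)
        name <- sort(names(tab)[tab == max(tab)])[1L]
        status <- "named"
      }
    }
    if (is.null(name)) {
      mids <- intersect(members, D16@ids)
      rids <- intersect(names(refNames), D16@ids)
      if (length(mids) && length(rids)) {
        sub <- D16@d[mids, rids, drop = FALSE]
        dmin <- apply(sub, 2L, min)
        byName <- tapply(dmin, refNames[rids], min)
        if (min(byName) <= dCf) {
          nearest <- sort(names(byName)[byName == min(byName)])[1L]
          parts <- strsplit(nearest, " ")[[1L]]
          name <- paste(parts[1L], "cf.",
                        paste(parts[-1L], collapse = " "))
          status <- "cf"
        }
      }
    }
    if (is.null(name)) {
      gen <- fieldGenus[members]
      gen <- gen[!is.na(gen)]
      genus <- if (length(gen)) {
        tab <- sort(table(gen), decreasing = TRUE)
        top <- sort(names(tab)[tab == max(tab)])
        if (length(top) > 1L)
          conflicts <- rbind(conflicts, data.frame(
            cell_a = o, cell_b = NA_integer_, rule = "naming",
            detail = sprintf("OTU %d spans modal genera: %s", o,
                             paste(top, collapse = ", "))))
        top[1L]
      } else "Incertae"
      used <- usedLetters[[genus]]
      letter <- LETTERS[length(used) + 1L]
      usedLetters[[genus]] <- c(used, letter)
      name <- paste(genus, "sp.", letter)
      status <- "provisional"
    }
    out[[o]] <- data.frame(otu = o, name = name, status = status)
  }
  nm <- do.call(rbind, out)
  new("SpeciesAssignment", otu = otu,
      otuNames = S4Vectors::DataFrame(nm),
      provenance = ruleProvenance(assignment), conflicts = conflicts)
}
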