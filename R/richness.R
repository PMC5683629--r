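# Incidence-based species richness: sample-based rarefaction, Chao2 with
# 84% confidence intervals, and the CI-overlap significance rule.

#' Normal quantile for two-sided 84% intervals
#'
#' Non-overlap of two 84% confidence intervals approximates a two-sample
#' test at P = 0.05, which is why richness curves and estimates here carry
#' 84% rather than 95% intervals by default.
#' @export
Z84 <- 1.4051

#' Build a species-by-sampling-event incidence matrix
#'
#' One row per species unit, one column per sampling event; an entry is
#' TRUE when at least one specimen of that unit was collected in that
#' event (duplicates collapse — incidence, not abundance). The species
#' unit is either the barcode OTU (tallied under its assigned name) or the
#' field morphospecies label, so the same records can be tallied both ways
#' and the two inventories compared.
#'
#' @param records specimen \code{DataFrame}; only survey specimens with a
#'   \code{sampling_event} contribute.
#' @param assignment a named \linkS4class{SpeciesAssignment}; required for
#'   \code{by = "otu"}.
#' @param by \code{"otu"} or \code{"field"}.
#' @param scope optional \code{site} filter.
#' @param seasons optional \code{season} filter.
#' @return an \linkS4class{IncidenceMatrix}.
#' @export
buildIncidence <- function(records, assignment = NULL,
                           by = c("otu", "field"), scope = NULL,
                           seasons = NULL) {
  by <- match.arg(by)
  keep <- records$role == "survey" & !is.na(records$sampling_event)
  if (!is.null(scope)) keep <- keep & records$site %in% scope
  if (!is.null(seasons)) keep <- keep & records$season %in% seasons
  rec <- records[keep, , drop = FALSE]
  if (!nrow(rec))
    stop("no survey specimens with sampling events in scope")
  if (by == "otu") {
    stopifnot(is(assignment, "SpeciesAssignment"))
    otu <- otuOf(assignment)
    nm <- otuNames(assignment)
    otuName <- nm$name
    names(otuName) <- as.character(nm$otu)
    rec <- rec[rec$specimen_id %in% names(otu), , drop = FALSE]
    species <- otuName[as.character(otu[rec$specimen_id])]
    # unnamed assignments fall back to OTU ids
    fallback <- paste0("OTU_", otu[rec$specimen_id])
    species[is.na(species)] <- fallback[is.na(species)]
  } else {
    species <- .fieldLabel(rec)
    rec <- rec[!is.na(species), , drop = FALSE]
    species <- species[rec$specimen_id]
  }
  if (!nrow(rec))
    stop("no species units in scope")
  events <- sort(unique(rec$sampling_event))
  mat <- table(species, factor(rec$sampling_event, levels = events)) > 0L
  mat <- matrix(as.logical(mat), nrow = nrow(mat),
                dimnames = list(rownames(mat), events))
  new("IncidenceMatrix", mat = mat[rowSums(mat) > 0L, , drop = FALSE])
}

#' Construct an incidence matrix directly
#'
#' @param mat logical or 0/1 matrix, species in rows, events in columns,
#'   with dimnames.
#' @return an \linkS4class{IncidenceMatrix}; all-zero rows are dropped.
#' @export
IncidenceMatrix <- function(mat) {
  m <- mat > 0
  if (is.null(rownames(m)))
    rownames(m) <- paste0("sp", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- paste0("ev", seq_len(ncol(m)))
  new("IncidenceMatrix", mat = m[rowSums(m) > 0L, , drop = FALSE])
}

# P(species with incidence y is missed in a draw of h of m events)
.alphaMat <- function(y, m, h) {
  outer(y, h, function(yy, hh)
    exp(lchoose(m - yy, hh) - lchoose(m, hh)))
}

#' Sample-based rarefaction curve with 84% intervals
#'
#' The expected species count when drawing \code{h} of the \code{m}
#' sampling events uniformly at random, computed analytically:
#' \deqn{\tau(h) = \sum_j \left[1 - \binom{m-Y_j}{h} / \binom{m}{h}\right]}
#' which equals the exhaustive mean over all \eqn{\binom{m}{h}} subsets.
#' The variance is the unconditional (estimator-based) form
#' \eqn{\sum_j (1-\alpha_{jh})^2 - \tau(h)^2/\tilde{S}} with
#' \eqn{\alpha_{jh} = \binom{m-Y_j}{h}/\binom{m}{h}} and \eqn{\tilde{S}}
#' an estimate of total richness (Chao2 by default), so the interval does
#' not collapse to zero at full effort — full-effort curves remain
#' comparable between identification routes. Intervals are
#' \eqn{\tau \pm z\sqrt{var}}, floored at zero.
#'
#' @param inc an \linkS4class{IncidenceMatrix}.
#' @param z normal quantile for the two-sided interval (default [Z84]).
#' @param h event counts to evaluate (default \code{0:m}); values above
#'   \code{m} are an error.
#' @param sTotal assumed total richness for the variance; default the
#'   Chao2 point estimate of \code{inc}.
#' @return data.frame of class \code{"rarefactionCurve"} with columns
#'   \code{h}, \code{tau}, \code{var}, \code{lo84}, \code{hi84} and
#'   attributes \code{z}, \code{m}, \code{sObs}.
#' @export
rarefactionCurve <- function(inc, z = Z84, h = NULL, sTotal = NULL) {
  stopifnot(is(inc, "IncidenceMatrix"))
  m <- nSamplingEvents(inc)
  if (is.null(h)) h <- 0:m
  if (any(h > m))
    stop("h exceeds the number of sampling events (", m, ")")
  if (any(h < 0))
    stop("h must be non-negative")
  y <- speciesIncidence(inc)
  if (is.null(sTotal)) sTotal <- chao2Estimate(inc, z = z)$estimate
  alpha <- .alphaMat(y, m, h)
  tau <- colSums(1 - alpha)
  v <- colSums((1 - alpha)^2) - tau^2 / sTotal
  v <- pmax(v, 0)
  out <- data.frame(h = h, tau = tau, var = v,
                    lo84 = pmax(tau - z * sqrt(v), 0),
                    hi84 = tau + z * sqrt(v))
  rownames(out) <- NULL
  attr(out, "z") <- z
  attr(out, "m") <- m
  attr(out, "sObs") <- sObs(inc)
  class(out) <- c("rarefactionCurve", "data.frame")
  out
}

#' Chao2 incidence-based richness estimate with 84% interval
#'
#' The non-parametric lower-bound estimator of total species richness from
#' incidence data, driven by the species found in exactly one (\eqn{Q_1})
#' and exactly two (\eqn{Q_2}) sampling events. With
#' \eqn{k = (m-1)/m}:
#' \deqn{\hat{S} = S_{obs} + k\,Q_1^2/(2 Q_2)}
#' when \eqn{Q_2 > 0}, and the bias-corrected
#' \eqn{\hat{S} = S_{obs} + k\,Q_1(Q_1-1)/2} when \eqn{Q_2 = 0}. The
#' variance follows the classic published forms for each branch, and the
#' confidence interval uses the log-normal construction on
#' \eqn{T = \hat{S} - S_{obs}}:
#' \eqn{R = \exp(z\sqrt{\ln(1 + var/T^2)})}, CI
#' \eqn{[S_{obs} + T/R,\; S_{obs} + T R]} — the lower bound can never fall
#' below the observed richness. With \eqn{Q_1 = 0} the estimate equals
#' \eqn{S_{obs}} and the interval is degenerate.
#'
#' @param inc an \linkS4class{IncidenceMatrix} with at least 2 events.
#' @param z normal quantile (default [Z84]).
#' @return a list of class \code{"richnessEstimate"}: \code{estimator},
#'   \code{estimate}, \code{variance}, \code{lo84}, \code{hi84},
#'   \code{sObs}, \code{q1}, \code{q2}, \code{m}, \code{z}.
#' @export
chao2Estimate <- function(inc, z = Z84) {
  stopifnot(is(inc, "IncidenceMatrix"))
  m <- nSamplingEvents(inc)
  if (m < 2L)
    stop("Chao2 requires at least 2 sampling events")
  S <- sObs(inc)
  q <- qCounts(inc)
  q1 <- q[["Q1"]]; q2 <- q[["Q2"]]
  k <- (m - 1) / m
  if (q1 == 0) {
    est <- S; v <- 0
  } else if (q2 > 0) {
    r <- q1 / q2
    est <- S + k * q1^2 / (2 * q2)
    v <- q2 * (k * r^2 / 2 + k^2 * r^3 + k^2 * r^4 / 4)
  } else {
    est <- S + k * q1 * (q1 - 1) / 2
    v <- k * q1 * (q1 - 1) / 2 + k^2 * q1 * (2 * q1 - 1)^2 / 4 -
      k^2 * q1^4 / (4 * est)
  }
  T <- est - S
  if (T > 0 && v > 0) {
    R <- exp(z * sqrt(log(1 + v / T^2)))
    lo <- S + T / R
    hi <- S + T * R
  } else {
    lo <- hi <- est
  }
  structure(list(estimator = "chao2", estimate = est, variance = v,
                 lo84 = lo, hi84 = hi, sObs = S, q1 = q1, q2 = q2,
                 m = m, z = z), class = "richnessEstimate")
}

#' @export
print.richnessEstimate <- function(x, ...) {
  cat(sprintf("%s: %.2f (S_obs %d, Q1 %d, Q2 %d, m %d), CI [%.2f, %.2f]\n",
              x$estimator, x$estimate, x$sObs, x$q1, x$q2, x$m,
              x$lo84, x$hi84))
  invisible(x)
}

.interval <- function(x, h = NULL) {
  if (inherits(x, "richnessEstimate"))
    return(list(lo = x$lo84, hi = x$hi84, z = x$z, m = x$m))
  if (inherits(x, "rarefactionCurve")) {
    m <- attr(x, "m")
    if (is.null(h)) h <- m
    if (h > m)
      stop("comparison point h = ", h, " exceeds curve effort m = ", m)
    row <- x[x$h == h, , drop = FALSE]
    if (!nrow(row))
      stop("curve was not evaluated at h = ", h)
    return(list(lo = row$lo84, hi = row$hi84, z = attr(x, "z"), m = m))
  }
  stop("inputs must be rarefaction curves or richness estimates")
}

#' Significance by 84% confidence-interval overlap
#'
#' Two richness estimates (or two rarefaction curves, compared at a common
#' effort level — by default the smaller of the two maximum efforts)
#' differ \emph{significantly} when their 84% confidence intervals are
#' disjoint; overlap means no significant difference at approximately
#' P = 0.05.
#'
#' @param a,b \code{"richnessEstimate"} objects or
#'   \code{"rarefactionCurve"} data.frames (mixing is allowed).
#' @param h comparison point for curves; default
#'   \code{min(m_a, m_b)}.
#' @return a list: \code{verdict} (\code{"significant"} or
#'   \code{"not_significant"}), \code{h}, and the two intervals.
#' @export
ciOverlap <- function(a, b, h = NULL) {
  if (is.null(h) && inherits(a, "rarefactionCurve") &&
      inherits(b, "rarefactionCurve"))
    h <- min(attr(a, "m"), attr(b, "m"))
  ia <- .interval(a, h)
  ib <- .interval(b, h)
  if (!isTRUE(all.equal(ia$z, ib$z)))
    stop("mismatched confidence levels: z = ", ia$z, " vs ", ib$z)
  disjoint <- ia$lo > ib$hi || ib$lo > ia$hi
  list(verdict = if (disjoint) "significant" else "not_significant",
       h = h, a = c(lo = ia$lo, hi = ia$hi), b = c(lo = ib$lo, hi = ib$hi))
}
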