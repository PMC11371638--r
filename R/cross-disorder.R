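## Cross-disorder comparison of epicenter architecture: spatial overlap of
## epicenter likelihood maps, and per-region differences between dependent
## overlapping correlations with Zou's modified-asymptotic CIs.

#' Spatial overlap of two epicenter maps
#'
#' Pearson correlation between the per-seed epicenter likelihood maps of two
#' disorders, with a spin p-value for cortical seeds (the first map is
#' rotated) or a label-shuffle p-value for subcortical seeds.
#'
#' @param epiA,epiB \linkS4class{EpicenterResult}s on the same parcellation,
#'   modality and seed scope
#' @param null a \linkS4class{SpinNull} (cortical seeds)
#' @param nPerm,seed shuffle settings (subcortical seeds)
#' @param tail test tail (default two-sided)
#' @return list with \code{r}, \code{p}, \code{nPerm}
#' @export
epicenterOverlap <- function(epiA, epiB, null = NULL, nPerm = 10000L,
                             seed = 1L,
                             tail = c("two", "positive", "negative")) {
  tail <- match.arg(tail)
  if (!identical(epiA@seedScope, epiB@seedScope) ||
      !identical(epiA@modality, epiB@modality) ||
      !identical(regionNames(epiA@parcellation),
                 regionNames(epiB@parcellation)))
    stop("epicenter results must share parcellation, modality and seed scope")
  mA <- epicenterLikelihoodMap(epiA)
  mB <- epicenterLikelihoodMap(epiB)
  if (epiA@seedScope == "cortical") {
    if (is.null(null)) stop("cortical seed scope requires a SpinNull")
    spinPvalue(mA, mB, null, tail = tail)
  } else {
    shufflePvalue(mA, mB, nPerm = nPerm, seed = seed, tail = tail)
  }
}

#' Zou's CI for the difference of two dependent overlapping correlations
#'
#' Compares r(j,k) and r(j,h) sharing variable j (here a region's
#' connectivity profile correlated with two disorder alteration maps over
#' the same n parcels). The confidence interval combines the individual
#' Fisher-z CIs with the correlation between the two correlation estimates
#' (Zou 2007, modified asymptotic method, as implemented in cocor).
#'
#' @param rJK,rJH the two overlapping correlations to compare
#' @param rKH the correlation between the two non-shared variables
#' @param n number of observations the correlations are computed on (> 3)
#' @param conf confidence level (default 0.95)
#' @return list with \code{difference} (rJK - rJH), \code{lower},
#'   \code{upper}
#' @export
zouDifferenceCI <- function(rJK, rJH, rKH, n, conf = 0.95) {
  if (any(abs(c(rJK, rJH)) >= 1))
    stop("|r| = 1: Fisher z-transform undefined")
  if (abs(rKH) > 1) stop("rKH outside [-1, 1]")
  if (n <= 3) stop("n must exceed 3")
  zcrit <- qnorm(1 - (1 - conf) / 2)
  fisher <- function(r) atanh(r)
  ci <- function(r) tanh(fisher(r) + c(-1, 1) * zcrit / sqrt(n - 3))
  c1 <- ci(rJK); c2 <- ci(rJH)
  ## correlation between the two correlation estimates (shared variable j)
  num <- (rKH - 0.5 * rJK * rJH) * (1 - rJK^2 - rJH^2 - rKH^2) + rKH^3
  den <- (1 - rJK^2) * (1 - rJH^2)
  cEst <- min(1, max(-1, num / den))    # guard against inconsistent triples
  diff <- rJK - rJH
  lower <- diff - sqrt((rJK - c1[1])^2 + (c2[2] - rJH)^2 -
                         2 * cEst * (rJK - c1[1]) * (c2[2] - rJH))
  upper <- diff + sqrt((c1[2] - rJK)^2 + (rJH - c2[1])^2 -
                         2 * cEst * (c1[2] - rJK) * (rJH - c2[1]))
  list(difference = diff, lower = lower, upper = upper)
}

#' Classify epicenters as disorder-unique or shared
#'
#' For every seed region, compares its epicenter likelihood across >= 2
#' disorders: \code{unique:<D>} if the region is a significant epicenter
#' only in disorder D and every pairwise Zou CI of D against the other
#' disorders excludes 0; \code{shared:<set>} if significant in two or more
#' disorders whose pairwise CIs include 0; otherwise \code{none}. For
#' comparisons across three or more disorders the smallest absolute pairwise
#' difference and its CI are reported per region.
#'
#' @param epis named list of \linkS4class{EpicenterResult} (>= 2 disorders,
#'   same parcellation and seed scope)
#' @param alterationMaps named list of the disorders' cortical alteration
#'   \linkS4class{RegionalMap}s (same names as \code{epis}); used for the
#'   correlation between disorder maps that enters Zou's CI
#' @param conf confidence level (default 0.95)
#' @return list with \code{table} (per region: classification, per-disorder
#'   r, smallest absolute pairwise difference and its CI) and
#'   \code{pairwise} (long data.frame of all pairwise differences and CIs).
#'   The number of parcels n entering each CI (the spatial map length) is
#'   recorded as attribute \code{"n"} on both tables.
#' @export
classifyEpicenters <- function(epis, alterationMaps, conf = 0.95) {
  if (length(epis) < 2) stop("need at least two disorders")
  disorders <- names(epis)
  if (is.null(disorders) || !identical(sort(disorders),
                                       sort(names(alterationMaps))))
    stop("epis and alterationMaps must be named consistently")
  regions <- epis[[1]]@table$region
  for (e in epis)
    if (!identical(e@table$region, regions))
      stop("inconsistent parcellation across disorders")
  nParcel <- length(alterationMaps[[1]]@values)
  rMat <- vapply(epis, function(e) e@table$r, numeric(length(regions)))
  sigMat <- vapply(epis, function(e) e@table$significant %in% TRUE,
                   logical(length(regions)))
  rownames(rMat) <- rownames(sigMat) <- regions
  pairs <- utils::combn(disorders, 2, simplify = FALSE)
  rKH <- vapply(pairs, function(pr)
    cor(alterationMaps[[pr[1]]]@values, alterationMaps[[pr[2]]]@values),
    numeric(1))
  pw <- list()
  for (ip in seq_along(pairs)) {
    pr <- pairs[[ip]]
    for (g in seq_along(regions)) {
      ciRes <- zouDifferenceCI(rMat[g, pr[1]], rMat[g, pr[2]], rKH[ip],
                               n = nParcel, conf = conf)
      pw[[length(pw) + 1]] <- data.frame(
        region = regions[g], pair = paste(pr, collapse = "-"),
        diff = ciRes$difference, lower = ciRes$lower, upper = ciRes$upper)
    }
  }
  pw <- do.call(rbind, pw)
  excludesZero <- function(rg, a, b) {
    row <- pw[pw$region == rg & pw$pair %in% c(paste(a, b, sep = "-"),
                                               paste(b, a, sep = "-")), ]
    row$lower > 0 | row$upper < 0
  }
  label <- character(length(regions))
  minDiff <- minLo <- minHi <- numeric(length(regions))
  for (g in seq_along(regions)) {
    rg <- regions[g]
    rows <- pw[pw$region == rg, ]
    best <- which.min(abs(rows$diff))
    minDiff[g] <- rows$diff[best]; minLo[g] <- rows$lower[best]
    minHi[g] <- rows$upper[best]
    sigSet <- disorders[sigMat[g, ]]
    if (length(sigSet) == 1) {
      others <- setdiff(disorders, sigSet)
      excl <- vapply(others, function(o) excludesZero(rg, sigSet, o),
                     logical(1))
      label[g] <- if (all(excl)) paste0("unique:", sigSet) else "none"
    } else if (length(sigSet) >= 2) {
      sharedWith <- character()
      sigPairs <- utils::combn(sigSet, 2, simplify = FALSE)
      for (pr in sigPairs)
        if (!excludesZero(rg, pr[1], pr[2]))
          sharedWith <- union(sharedWith, pr)
      label[g] <- if (length(sharedWith))
        paste0("shared:", paste(sort(sharedWith), collapse = ",")) else "none"
    } else label[g] <- "none"
  }
  tab <- data.frame(region = regions, classification = label, rMat,
                    min_abs_diff = minDiff, ci_lower = minLo,
                    ci_upper = minHi, row.names = NULL, check.names = FALSE)
  attr(tab, "n") <- nParcel
  attr(pw, "n") <- nParcel
  list(table = tab, pairwise = pw)
}
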