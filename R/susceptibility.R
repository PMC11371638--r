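## The two network susceptibility models: hub vulnerability (alteration map
## vs centrality map) and disease epicenter mapping (alteration map vs every
## region's normative connectivity profile), at group, stage and subject
## level, plus clinical association and resampling robustness.

.asAlterationMap <- function(alteration) {
  if (is(alteration, "CaseControlResult")) alterationMap(alteration, "t")
  else alteration
}

#' Hub vulnerability test
#'
#' Pearson correlation between a reduction-oriented alteration map and a
#' centrality map, with a spatial-null p-value: spin permutations for
#' cortical maps (the alteration map is the one rotated), label shuffles for
#' subcortical maps.
#'
#' @param alteration a reduction-oriented \linkS4class{RegionalMap} (or a
#'   \linkS4class{CaseControlResult}, whose t map is used)
#' @param centrality a \linkS4class{CentralityProfile} of matching scope
#' @param null a \linkS4class{SpinNull} (required for cortical scope)
#' @param nPerm,seed shuffle-null settings for subcortical scope
#' @param tail \code{two} (default), \code{positive} or \code{negative}
#' @return a \linkS4class{HubVulnerabilityResult}
#' @export
hubVulnerability <- function(alteration, centrality, null = NULL,
                             nPerm = 10000L, seed = 1L,
                             tail = c("two", "positive", "negative")) {
  tail <- match.arg(tail)
  alt <- .asAlterationMap(alteration)
  cmap <- centrality@map
  if (alt@scope != cmap@scope)
    stop("alteration and centrality scopes differ: ", alt@scope, " vs ",
         cmap@scope)
  if (alt@scope == "cortical") {
    if (is.null(null)) stop("cortical scope requires a SpinNull")
    res <- spinPvalue(alt, cmap, null, tail = tail)
  } else {
    res <- shufflePvalue(alt, cmap, nPerm = nPerm, seed = seed, tail = tail)
  }
  new("HubVulnerabilityResult", r = res$r, p = res$p,
      nPerm = as.integer(res$nPerm), modality = centrality@modality,
      metric = centrality@metric, scope = centrality@scope)
}

#' Disease epicenter mapping
#'
#' Correlates every seed region's normative connectivity profile (its full
#' cortico-cortical row for cortical seeds, including the zero self-entry,
#' or its subcortico-cortical row for subcortical seeds) with the cortical
#' alteration map. Spin p-values are obtained by rotating the alteration
#' map; significance is Bonferroni-corrected over the number of seeds.
#' Seeds are ranked by descending r. A seed with an all-zero (constant)
#' connectivity row is flagged undefined and excluded from the ranking.
#'
#' @param alteration a cortical reduction-oriented \linkS4class{RegionalMap}
#'   or \linkS4class{CaseControlResult}
#' @param conn a preprocessed \linkS4class{ConnectivityMatrix}
#' @param null a \linkS4class{SpinNull} on the same parcellation
#' @param alpha significance level after Bonferroni (default 0.05)
#' @param seedScope \code{cortical} (default) or \code{subcortical} seeds
#' @param excludeSelf drop the seed's own (zero) self-entry from its profile
#'   before correlating (default FALSE, the toolbox convention)
#' @param tail tail of the spin test (default two-sided)
#' @return an \linkS4class{EpicenterResult}
#' @export
epicenterMap <- function(alteration, conn, null, alpha = 0.05,
                         seedScope = c("cortical", "subcortical"),
                         excludeSelf = FALSE,
                         tail = c("two", "positive", "negative")) {
  seedScope <- match.arg(seedScope)
  tail <- match.arg(tail)
  alt <- .asAlterationMap(alteration)
  if (alt@scope != "cortical") stop("alteration map must be cortical")
  p <- conn@parcellation
  if (!identical(names(alt@values), scopeRegions(p, "cortical")))
    stop("alteration map does not match the connectivity parcellation")
  S <- if (seedScope == "cortical") corticoCortical(conn)
       else subcorticoCortical(conn)
  y <- alt@values
  nSeeds <- nrow(S)
  defined <- apply(S, 1, sd) > 0
  rObs <- rep(NA_real_, nSeeds)
  selfDrop <- excludeSelf && seedScope == "cortical"
  for (i in which(defined)) {
    keep <- if (selfDrop) -i else TRUE
    rObs[i] <- cor(S[i, keep], y[keep])
  }
  ## null: rotated alteration map against every intact seed profile at once
  P <- null@indices
  A <- .standardizeRows(matrix(y[P], nrow(P), ncol(P)))
  pSpin <- rep(NA_real_, nSeeds)
  if (selfDrop) {
    for (i in which(defined)) {
      ## permute the full map, then drop the seed's own entry
      Ai <- matrix(y[P], nrow(P), ncol(P))[, -i, drop = FALSE]
      rNull <- .standardizeRows(Ai) %*%
        ((S[i, -i] - mean(S[i, -i])) / sd(S[i, -i])) / (ncol(Ai) - 1)
      pSpin[i] <- .tailP(rObs[i], as.vector(rNull), tail)
    }
  } else {
    Ss <- .standardizeRows(S[defined, , drop = FALSE])
    rNull <- A %*% t(Ss) / (ncol(S) - 1)        # nPerm x nDefined
    for (k in seq_len(sum(defined))) {
      i <- which(defined)[k]
      pSpin[i] <- .tailP(rObs[i], rNull[, k], tail)
    }
  }
  pBonf <- pmin(1, pSpin * nSeeds)
  rnk <- rep(NA_integer_, nSeeds)
  rnk[defined] <- rank(-rObs[defined], ties.method = "first")
  tab <- data.frame(region = rownames(S), r = rObs, p_spin = pSpin,
                    p_bonf = pBonf, rank = rnk,
                    significant = !is.na(pBonf) & pBonf < alpha,
                    row.names = NULL)
  new("EpicenterResult", table = tab, modality = conn@modality,
      seedScope = seedScope, nPerm = nrow(P), alpha = alpha,
      parcellation = p)
}

#' Extract the epicenter likelihood map
#'
#' @param epi an \linkS4class{EpicenterResult}
#' @return a \linkS4class{RegionalMap} (kind \code{epicenter_r}) of per-seed
#'   correlation coefficients
#' @export
epicenterLikelihoodMap <- function(epi) {
  RegionalMap(setNames(epi@table$r, epi@table$region), epi@parcellation,
              epi@seedScope, "epicenter_r")
}

#' Centrality percentile of the top-ranked epicenters
#'
#' Locates the top-k ranked epicenters within the centrality distribution
#' and reports their percentiles (100 x fraction of regions with centrality
#' at or below each epicenter's) and the median.
#'
#' @param epi an \linkS4class{EpicenterResult}
#' @param centrality a \linkS4class{CentralityProfile} on the same scope
#' @param topK number of top-ranked epicenters to summarize
#' @return list with \code{percentiles} (named) and \code{median}
#' @export
epicenterCentralityPercentile <- function(epi, centrality, topK = 5L) {
  tab <- epi@table[!is.na(epi@table$rank), ]
  if (topK > nrow(tab)) stop("topK exceeds the number of ranked seeds")
  cvals <- mapValues(centrality)
  if (!all(tab$region %in% names(cvals)))
    stop("centrality does not cover the epicenter seeds")
  top <- tab$region[order(tab$rank)][seq_len(topK)]
  pct <- vapply(top, function(rg) 100 * mean(cvals <= cvals[rg]), numeric(1))
  list(percentiles = pct, median = median(pct))
}

#' Subset a cohort to a disease stage
#'
#' Patients are filtered by duration of illness: first-episode psychosis at
#' most 1 month, early course more than 1 month but under 2 years, chronic
#' over 20 years. All controls are retained; patients without a recorded
#' duration are dropped from every stage subset.
#'
#' @param cohort a \linkS4class{MorphoCohort}
#' @param stage \code{FEP}, \code{early} or \code{chronic}
#' @return the stage \linkS4class{MorphoCohort}
#' @export
stageSubset <- function(cohort, stage = c("FEP", "early", "chronic")) {
  stage <- match.arg(stage)
  cd <- SummarizedExperiment::colData(cohort)
  if (!"duration_of_illness" %in% colnames(cd))
    stop("duration_of_illness column required for stage subsetting")
  dur <- cd$duration_of_illness
  inStage <- switch(stage,
                    FEP = dur <= 1 / 12,
                    early = dur > 1 / 12 & dur < 2,
                    chronic = dur > 20)
  keep <- cd$diagnosis == "control" |
    (cd$diagnosis == "patient" & !is.na(dur) & inStage)
  cohort[, keep]
}

#' Compare epicenter significance across disease stages
#'
#' Labels each seed region by the set logic of its per-stage significance:
#' \code{convergent} if significant in all stages, \code{divergent:<stage>}
#' if significant in exactly one, otherwise \code{none} (regions significant
#' in a strict subset of more than one stage fall under \code{none},
#' matching the binary divergent/convergent taxonomy).
#'
#' @param stageResults named list of \linkS4class{EpicenterResult}, one per
#'   stage (>= 2), same parcellation, modality and seed scope
#' @return data.frame with columns region and label
#' @export
stageEpicenterComparison <- function(stageResults) {
  if (length(stageResults) < 2) stop("need at least two stages")
  if (is.null(names(stageResults)) || any(names(stageResults) == ""))
    stop("stageResults must be a named list")
  regions <- stageResults[[1]]@table$region
  mods <- vapply(stageResults, function(e) e@modality, character(1))
  for (e in stageResults) {
    if (!identical(e@table$region, regions))
      stop("mismatched parcellations across stages")
  }
  if (length(unique(mods)) != 1) stop("mismatched modalities across stages")
  sig <- vapply(stageResults,
                function(e) e@table$significant %in% TRUE,
                logical(length(regions)))
  nSig <- rowSums(sig)
  label <- rep("none", length(regions))
  label[nSig == length(stageResults)] <- "convergent"
  one <- nSig == 1
  label[one] <- paste0("divergent:",
                       colnames(sig)[apply(sig[one, , drop = FALSE], 1,
                                           which)])
  data.frame(region = regions, label = label, row.names = NULL)
}

#' Subject-level network susceptibility scores
#'
#' For each patient's abnormality z map, computes the hub-vulnerability
#' score \code{cor(-z, centrality)} and the per-seed epicenter likelihoods
#' \code{cor(connectivity profile, -z)}. The sign flip puts the z maps in
#' the same deficit-positive orientation as the group-level reduction t map.
#' Patients with a constant z map are masked and carry NA scores.
#'
#' @param zmaps a \linkS4class{SubjectZMaps} (cortical)
#' @param centrality a cortical \linkS4class{CentralityProfile}
#' @param conn a preprocessed \linkS4class{ConnectivityMatrix} of the same
#'   modality, for the epicenter likelihoods
#' @param seedScope seeds for the epicenter likelihoods
#' @return a \linkS4class{SubjectNetworkScores}
#' @export
subjectNetworkScores <- function(zmaps, centrality, conn,
                                 seedScope = c("cortical", "subcortical")) {
  seedScope <- match.arg(seedScope)
  if (zmaps@scope != "cortical") stop("z maps must be cortical")
  if (centrality@modality != conn@modality)
    stop("centrality and connectivity modalities differ")
  negZ <- -zmaps@z                                  # deficit-positive
  masked <- apply(negZ, 2, sd) == 0
  cvals <- mapValues(centrality@map)
  S <- if (seedScope == "cortical") corticoCortical(conn)
       else subcorticoCortical(conn)
  hub <- rep(NA_real_, ncol(negZ))
  epi <- matrix(NA_real_, nrow(S), ncol(negZ),
                dimnames = list(rownames(S), colnames(negZ)))
  ok <- !masked
  if (any(ok)) {
    hub[ok] <- as.vector(cor(negZ[, ok, drop = FALSE], cvals))
    epi[, ok] <- cor(t(S), negZ[, ok, drop = FALSE])
  }
  names(hub) <- colnames(negZ)
  new("SubjectNetworkScores", subjects = colnames(negZ), hubScores = hub,
      epicenterScores = epi, masked = masked, modality = centrality@modality,
      metric = centrality@metric)
}

#' Associate subject network scores with clinical variables
#'
#' Pearson correlation of each subject-level score (the hub-vulnerability
#' score and every seed region's epicenter likelihood) with each clinical
#' variable, over patients with both values available. Bonferroni correction
#' is over the number of tests actually run; tests with fewer than 10
#' complete pairs are skipped (and logged via \code{message}).
#'
#' @param scores a \linkS4class{SubjectNetworkScores}
#' @param cohort the \linkS4class{MorphoCohort} carrying the clinical columns
#' @param variables clinical columns to test (default the PANSS scores,
#'   duration of illness and antipsychotic dose present in the cohort)
#' @param includeEpicenters also test every seed region's likelihood
#'   (default TRUE)
#' @return data.frame with columns variable, score, r, p, p_bonf, df, n
#' @export
clinicalAssociation <- function(scores, cohort, variables = NULL,
                                includeEpicenters = TRUE) {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  if (is.null(variables))
    variables <- intersect(CLINICAL_COLUMNS, colnames(cd))
  scoreMat <- rbind(hub_vulnerability = scores@hubScores)
  if (includeEpicenters)
    scoreMat <- rbind(scoreMat, scores@epicenterScores)
  idx <- match(scores@subjects, cd$subject)
  rows <- list()
  for (v in variables) {
    clin <- cd[[v]][idx]
    for (s in rownames(scoreMat)) {
      sc <- scoreMat[s, ]
      ok <- stats::complete.cases(clin, sc)
      if (sum(ok) < 10) {
        message("skipping ", v, " x ", s, ": fewer than 10 complete pairs")
        next
      }
      r <- cor(clin[ok], sc[ok])
      df <- sum(ok) - 2
      tstat <- r * sqrt(df / (1 - r^2))
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, score = s, r = r,
        p = 2 * pt(abs(tstat), df, lower.tail = FALSE),
        df = df, n = sum(ok))
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(1, out$p * nrow(out))
  out[, c("variable", "score", "r", "p", "p_bonf", "df", "n")]
}

#' Resampling robustness of an analysis
#'
#' Repeats an analysis closure on subsamples of the cohort drawn without
#' replacement (default 100 rounds at 80 percent of the sample) and reports
#' the mean, SD and sign-consistency of every statistic the closure returns.
#' Rounds in which the closure fails (e.g. a subsample violates its
#' preconditions) are skipped and counted.
#'
#' @param analysis function taking a \linkS4class{MorphoCohort} and
#'   returning a named numeric vector of statistics
#' @param cohort the full \linkS4class{MorphoCohort}
#' @param nRounds number of resampling rounds (default 100)
#' @param fraction subsample fraction in (0, 1); 1 reuses the full sample
#' @param seed integer seed
#' @return list with \code{stats} (rounds x statistics matrix), \code{mean},
#'   \code{sd}, \code{signConsistency} (fraction of rounds matching the
#'   majority sign) and \code{skipped}
#' @export
stabilityResample <- function(analysis, cohort, nRounds = 100L,
                              fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- ncol(cohort)
  k <- round(fraction * n)
  set.seed(seed)
  rows <- list()
  skipped <- 0L
  for (b in seq_len(nRounds)) {
    sel <- if (fraction == 1) seq_len(n) else sort(sample.int(n, k))
    stat <- tryCatch(analysis(cohort[, sel]), error = function(e) NULL)
    if (is.null(stat)) skipped <- skipped + 1L else
      rows[[length(rows) + 1]] <- stat
  }
  if (!length(rows))
    return(list(stats = NULL, mean = NULL, sd = NULL,
                signConsistency = NULL, skipped = skipped))
  stats <- do.call(rbind, rows)
  sgn <- apply(stats, 2, function(x) max(mean(x > 0), mean(x < 0)))
  list(stats = stats, mean = colMeans(stats), sd = apply(stats, 2, sd),
       signConsistency = sgn, skipped = skipped)
}
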