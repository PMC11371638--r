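#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay "assay<-"
#'   colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats cor sd lm pnorm pt qnorm rnorm runif rbinom rgamma rlnorm
#'   p.adjust complete.cases setNames quantile median pf ks.test coef
#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

VALID_HEMIS <- c("left", "right", "none")
VALID_STRUCTURES <- c("cortical", "subcortical")
VALID_SCOPES <- c("cortical", "subcortical", "all")
VALID_MODALITIES <- c("functional", "structural")
VALID_MEASURES <- c("CT", "SA", "SV")
VALID_KINDS <- c("t", "cohens_d", "z", "centrality", "connectivity_profile",
                 "epicenter_r", "effect")

#' Parcellation of the brain into named regions
#'
#' Ordered set of named regions with hemisphere and structure class
#' (cortical/subcortical) and, for cortical parcels, a centroid on the unit
#' sphere of the corresponding hemisphere. The region order is the coordinate
#' system shared by every \linkS4class{RegionalMap} and
#' \linkS4class{ConnectivityMatrix} built on it, and the centroids are the
#' geometry used by the spin permutation null.
#'
#' @slot regions character vector of unique region names, canonical form
#'   \code{<hemi>_<name>} (e.g. \code{L_entorhinal}).
#' @slot hemisphere one of \code{left}, \code{right}, \code{none} per region.
#' @slot structure one of \code{cortical}, \code{subcortical} per region.
#' @slot centroids numeric matrix (n x 3); unit-norm rows for cortical
#'   regions, \code{NA} rows for subcortical regions.
#' @seealso [generateParcellation()], [dkParcellation()]
#' @export
setClass("Parcellation",
  representation(regions = "character", hemisphere = "character",
                 structure = "character", centroids = "matrix"))

setValidity("Parcellation", function(object) {
  n <- length(object@regions)
  msg <- character()
  if (anyDuplicated(object@regions))
    msg <- c(msg, "region names must be unique")
  if (length(object@hemisphere) != n || length(object@structure) != n)
    msg <- c(msg, "hemisphere/structure length must match regions")
  if (!all(object@hemisphere %in% VALID_HEMIS))
    msg <- c(msg, "invalid hemisphere labels")
  if (!all(object@structure %in% VALID_STRUCTURES))
    msg <- c(msg, "invalid structure labels")
  if (nrow(object@centroids) != n || ncol(object@centroids) != 3)
    msg <- c(msg, "centroids must be an n x 3 matrix")
  ctx <- object@structure == "cortical"
  if (any(ctx)) {
    cc <- object@centroids[ctx, , drop = FALSE]
    if (anyNA(cc)) {
      msg <- c(msg, "cortical regions require centroids")
    } else {
      nrm <- sqrt(rowSums(cc^2))
      if (any(abs(nrm - 1) > 1e-6))
        msg <- c(msg, "cortical centroids must have unit norm (tol 1e-6)")
    }
    if (any(object@hemisphere[ctx] == "none"))
      msg <- c(msg, "cortical regions must be lateralized")
  }
  if (length(msg)) msg else TRUE
})

#' One real value per region of a parcellation
#'
#' A regional brain map: t-values, Cohen's d, z-scores, centrality,
#' connectivity profiles or epicenter likelihoods over the cortical,
#' subcortical, or full scope of a \linkS4class{Parcellation}. Values may be
#' \code{NA} only where explicitly masked.
#'
#' @slot parcellation the \linkS4class{Parcellation} the map lives on.
#' @slot scope \code{cortical}, \code{subcortical} or \code{all}.
#' @slot values named numeric vector in parcellation order over the scope.
#' @slot kind semantic tag (\code{t}, \code{cohens_d}, \code{z},
#'   \code{centrality}, \code{connectivity_profile}, \code{epicenter_r},
#'   \code{effect}).
#' @export
setClass("RegionalMap",
  representation(parcellation = "Parcellation", scope = "character",
                 values = "numeric", kind = "character"))

setValidity("RegionalMap", function(object) {
  msg <- character()
  if (!object@scope %in% VALID_SCOPES) msg <- c(msg, "invalid scope")
  if (!object@kind %in% VALID_KINDS) msg <- c(msg, "invalid kind tag")
  expect <- scopeRegions(object@parcellation, object@scope)
  if (length(object@values) != length(expect))
    msg <- c(msg, sprintf("expected %d values for scope '%s', got %d",
                          length(expect), object@scope, length(object@values)))
  else if (!identical(names(object@values), expect))
    msg <- c(msg, "value names must equal in-scope regions in order")
  if (length(msg)) msg else TRUE
})

#' Weighted connectivity matrix over a parcellation
#'
#' Square, symmetric, weighted connectivity over all regions of a
#' parcellation, tagged functional or structural. After preprocessing
#' (\code{\link{preprocessConnectivity}}) all weights are nonnegative and the
#' diagonal is zero; provenance flags record what was applied.
#'
#' @slot parcellation the \linkS4class{Parcellation}.
#' @slot modality \code{functional} or \code{structural}.
#' @slot weights square symmetric numeric matrix with region dimnames.
#' @slot negativesZeroed,diagonalZeroed provenance flags.
#' @export
setClass("ConnectivityMatrix",
  representation(parcellation = "Parcellation", modality = "character",
                 weights = "matrix", negativesZeroed = "logical",
                 diagonalZeroed = "logical"))

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  W <- object@weights
  rn <- object@parcellation@regions
  if (!object@modality %in% VALID_MODALITIES) msg <- c(msg, "invalid modality")
  if (nrow(W) != length(rn) || ncol(W) != length(rn))
    msg <- c(msg, "weights must be square over all regions")
  else {
    if (!identical(rownames(W), rn) || !identical(colnames(W), rn))
      msg <- c(msg, "weight dimnames must equal region names in order")
    if (max(abs(W - t(W))) > 1e-10)
      msg <- c(msg, "weights must be symmetric within 1e-10")
    if (isTRUE(object@diagonalZeroed) && any(diag(W) != 0))
      msg <- c(msg, "diagonal must be exactly 0 after preprocessing")
    if (isTRUE(object@negativesZeroed) && any(W < 0))
      msg <- c(msg, "weights must be nonnegative after preprocessing")
  }
  if (length(msg)) msg else TRUE
})

#' Multi-site case-control morphometry cohort
#'
#' Extends \linkS4class{SummarizedExperiment}: one assay \code{"value"}
#' (regions x subjects) holding regional morphometry of a single measure
#' (\code{CT}, \code{SA} or \code{SV}); \code{colData} holds per-subject
#' demographics (\code{subject}, \code{diagnosis}, \code{site}, \code{age},
#' \code{sex}) and, for patients, optional clinical scores
#' (\code{panss_pos}, \code{panss_neg}, \code{panss_gen}, \code{panss_total},
#' \code{duration_of_illness}, \code{cpz_equiv}). The parcellation and
#' measure tag live in \code{metadata()}.
#'
#' @seealso [MorphoCohort()], [generateCohort()], [readCohort()]
#' @export
setClass("MorphoCohort", contains = "SummarizedExperiment")

setValidity("MorphoCohort", function(object) {
  msg <- character()
  md <- S4Vectors::metadata(object)
  if (is.null(md$parcellation) || !is(md$parcellation, "Parcellation"))
    return("metadata must carry the parcellation")
  if (is.null(md$measure) || !md$measure %in% VALID_MEASURES)
    msg <- c(msg, "metadata$measure must be one of CT, SA, SV")
  else {
    scope <- if (md$measure == "SV") "subcortical" else "cortical"
    if (!identical(rownames(object), scopeRegions(md$parcellation, scope)))
      msg <- c(msg, sprintf(
        "rows must be the %s regions of the parcellation, in order", scope))
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject", "diagnosis", "site", "age", "sex")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing subject columns:", paste(miss, collapse = ", ")))
  else {
    if (anyDuplicated(cd$subject)) msg <- c(msg, "duplicated subject ids")
    if (!all(cd$diagnosis %in% c("patient", "control")))
      msg <- c(msg, "diagnosis must be patient/control")
    if (!all(cd$sex %in% c("F", "M"))) msg <- c(msg, "sex must be F/M")
  }
  if (length(msg)) msg else TRUE
})

#' Spin permutation index table
#'
#' Stores \code{nPerm} mirrored random rotations of the cortical parcel
#' centroids as index rows: entry \code{[p, j]} is the index (into cortical
#' regions) of the original parcel whose value region \code{j} receives under
#' rotation \code{p}. Left-hemisphere parcels map only to left indices and
#' right to right (the right-hemisphere rotation is the x-mirror of the left
#' one), and repeats are permitted under the nearest-centroid rule.
#'
#' @slot indices integer matrix (nPerm x nCortical).
#' @slot seed integer seed the table was built from.
#' @slot parcellation the \linkS4class{Parcellation}.
#' @seealso [buildSpinRotations()], [spinPvalue()]
#' @export
setClass("SpinNull",
  representation(indices = "matrix", seed = "integer",
                 parcellation = "Parcellation"))

setValidity("SpinNull", function(object) {
  p <- object@parcellation
  ctx <- which(p@structure == "cortical")
  nC <- length(ctx)
  idx <- object@indices
  if (ncol(idx) != nC) return("index table must have one column per cortical region")
  if (any(idx < 1L) || any(idx > nC)) return("indices out of range")
  hemi <- p@hemisphere[ctx]
  same <- hemi[as.vector(idx)] == rep(hemi, each = nrow(idx))
  if (!all(same)) return("rotations must map left to left and right to right")
  TRUE
})

#' Fitted ComBat harmonization model
#'
#' Per-region covariate fit plus per-site empirical-Bayes location/scale
#' adjustments estimated by [combatFitTransform()]: \code{gammaStar} and
#' \code{deltaStar} are the shrunken site effects (sites x regions),
#' \code{gammaBar}/\code{tau2} the normal prior moments and
#' \code{aPrior}/\code{bPrior} the inverse-gamma prior parameters per site.
#'
#' @export
setClass("CombatModel",
  representation(alphaHat = "numeric", betaHat = "matrix",
                 gammaStar = "matrix", deltaStar = "matrix",
                 gammaBar = "numeric", tau2 = "numeric",
                 aPrior = "numeric", bPrior = "numeric",
                 varPooled = "numeric", batches = "character",
                 covariates = "character", parametric = "logical"))

#' Mass-univariate case-control difference map
#'
#' Per-region linear-model contrast control minus patient (positive t =
#' reduction in patients), with two-sided p, Benjamini-Hochberg q and Cohen's
#' d, computed by [fitGroupDifference()].
#'
#' @slot table data.frame with columns region, t, p, q, d.
#' @export
setClass("CaseControlResult",
  representation(table = "data.frame", nPatients = "integer",
                 nControls = "integer", covariates = "character",
                 measure = "character", scope = "character",
                 parcellation = "Parcellation"))

#' Individualized abnormality z-score maps
#'
#' Per-patient regional z maps relative to a control-only age/sex reference
#' regression (negative z = thinner/smaller than expected), plus the reference
#' model itself; see [subjectZScoreMaps()].
#'
#' @slot z numeric matrix, regions x patients.
#' @export
setClass("SubjectZMaps",
  representation(z = "matrix", refCoef = "matrix", residSD = "numeric",
                 covariates = "character", parcellation = "Parcellation",
                 scope = "character"))

#' Hub vulnerability test result
#'
#' Observed Pearson correlation between an alteration map and a centrality
#' map together with its spatial-null p-value; see [hubVulnerability()].
#' @export
setClass("HubVulnerabilityResult",
  representation(r = "numeric", p = "numeric", nPerm = "integer",
                 modality = "character", metric = "character",
                 scope = "character"))

#' Disease epicenter mapping result
#'
#' Per seed region, the correlation between its normative connectivity
#' profile and the cortical alteration map, with spin p, Bonferroni-adjusted
#' p, descending-r rank and significance flag; see [epicenterMap()].
#'
#' @slot table data.frame with columns region, r, p_spin, p_bonf, rank,
#'   significant.
#' @export
setClass("EpicenterResult",
  representation(table = "data.frame", modality = "character",
                 seedScope = "character", nPerm = "integer",
                 alpha = "numeric", parcellation = "Parcellation"))

#' Subject-level network susceptibility scores
#'
#' Per patient, the hub-vulnerability correlation and the per-seed epicenter
#' likelihood correlations derived from that patient's abnormality z map;
#' see [subjectNetworkScores()].
#' @export
setClass("SubjectNetworkScores",
  representation(subjects = "character", hubScores = "numeric",
                 epicenterScores = "matrix", masked = "logical",
                 modality = "character", metric = "character"))

scopeRegions <- function(parcellation, scope = c("all", "cortical", "subcortical")) {
  scope <- match.arg(scope)
  if (scope == "all") return(parcellation@regions)
  parcellation@regions[parcellation@structure == scope]
}
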