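#' @rdname NetSuscept-accessors
setMethod("regionNames", "Parcellation", function(x) x@regions)
#' @rdname NetSuscept-accessors
setMethod("nCortical", "Parcellation", function(x) sum(x@structure == "cortical"))
#' @rdname NetSuscept-accessors
setMethod("nSubcortical", "Parcellation", function(x) sum(x@structure == "subcortical"))
#' @rdname NetSuscept-accessors
setMethod("centroids", "Parcellation", function(x) {
  m <- x@centroids
  rownames(m) <- x@regions
  m
})
#' @rdname NetSuscept-accessors
setMethod("hemispheres", "Parcellation", function(x) setNames(x@hemisphere, x@regions))
#' @rdname NetSuscept-accessors
setMethod("structureClass", "Parcellation", function(x) setNames(x@structure, x@regions))

#' @rdname NetSuscept-accessors
setMethod("mapValues", "RegionalMap", function(x) x@values)
#' @rdname NetSuscept-accessors
setMethod("mapScope", "RegionalMap", function(x) x@scope)
#' @rdname NetSuscept-accessors
setMethod("mapKind", "RegionalMap", function(x) x@kind)
#' @rdname NetSuscept-accessors
setMethod("parcellationOf", "RegionalMap", function(x) x@parcellation)

#' @rdname NetSuscept-accessors
setMethod("connWeights", "ConnectivityMatrix", function(x) x@weights)
#' @rdname NetSuscept-accessors
setMethod("connModality", "ConnectivityMatrix", function(x) x@modality)
#' @rdname NetSuscept-accessors
setMethod("parcellationOf", "ConnectivityMatrix", function(x) x@parcellation)

#' @rdname NetSuscept-accessors
setMethod("corticoCortical", "ConnectivityMatrix", function(x) {
  ctx <- scopeRegions(x@parcellation, "cortical")
  x@weights[ctx, ctx, drop = FALSE]
})
#' @rdname NetSuscept-accessors
setMethod("subcorticoCortical", "ConnectivityMatrix", function(x) {
  ctx <- scopeRegions(x@parcellation, "cortical")
  sub <- scopeRegions(x@parcellation, "subcortical")
  x@weights[sub, ctx, drop = FALSE]
})

#' @rdname NetSuscept-accessors
setMethod("cohortMeasure", "MorphoCohort", function(x) S4Vectors::metadata(x)$measure)
#' @rdname NetSuscept-accessors
setMethod("parcellationOf", "MorphoCohort", function(x) S4Vectors::metadata(x)$parcellation)
#' @rdname NetSuscept-accessors
setMethod("parcellationOf", "SpinNull", function(x) x@parcellation)
#' @rdname NetSuscept-accessors
setMethod("parcellationOf", "CaseControlResult", function(x) x@parcellation)
#' @rdname NetSuscept-accessors
setMethod("parcellationOf", "EpicenterResult", function(x) x@parcellation)

#' @rdname NetSuscept-accessors
setMethod("resultTable", "CaseControlResult", function(x) x@table)
#' @rdname NetSuscept-accessors
setMethod("resultTable", "EpicenterResult", function(x) x@table)

## Arithmetic between regional maps requires matching parcellation and scope.
#' @export
setMethod("Ops", signature("RegionalMap", "RegionalMap"), function(e1, e2) {
  if (!identical(e1@parcellation@regions, e2@parcellation@regions) ||
      !identical(e1@scope, e2@scope))
    stop("RegionalMap arithmetic requires identical parcellation and scope")
  vals <- callGeneric(e1@values, e2@values)
  if (is.logical(vals)) return(vals)
  new("RegionalMap", parcellation = e1@parcellation, scope = e1@scope,
      values = vals, kind = "effect")
})

#' @export
setMethod("Ops", signature("RegionalMap", "numeric"), function(e1, e2) {
  vals <- callGeneric(e1@values, e2)
  if (is.logical(vals)) return(vals)
  initialize(e1, values = vals)
})

#' @export
setMethod("Ops", signature("numeric", "RegionalMap"), function(e1, e2) {
  vals <- callGeneric(e1, e2@values)
  if (is.logical(vals)) return(vals)
  initialize(e2, values = vals)
})

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation: %d regions (%d cortical, %d subcortical)\n",
              length(object@regions), nCortical(object), nSubcortical(object)))
  cat("  regions: ", paste(head(object@regions, 4), collapse = ", "),
      ", ...\n", sep = "")
})

setMethod("show", "RegionalMap", function(object) {
  v <- object@values
  cat(sprintf("RegionalMap <%s> over %d %s regions; range [%.4g, %.4g]%s\n",
              object@kind, length(v), object@scope,
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)),
              if (anyNA(v)) sprintf(" (%d masked)", sum(is.na(v))) else ""))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf(
    "ConnectivityMatrix <%s>: %d x %d; negatives zeroed: %s; diagonal zeroed: %s\n",
    object@modality, nrow(object@weights), ncol(object@weights),
    object@negativesZeroed, object@diagonalZeroed))
})

setMethod("show", "SpinNull", function(object) {
  cat(sprintf("SpinNull: %d rotations over %d cortical regions (seed %d)\n",
              nrow(object@indices), ncol(object@indices), object@seed))
})

setMethod("show", "MorphoCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("MorphoCohort <%s>: %d regions x %d subjects (%d patients, %d controls, %d sites)\n",
              cohortMeasure(object), nrow(object), ncol(object),
              sum(cd$diagnosis == "patient"), sum(cd$diagnosis == "control"),
              length(unique(cd$site))))
})

setMethod("show", "CaseControlResult", function(object) {
  cat(sprintf(
    "CaseControlResult <%s>: %d regions; %d patients vs %d controls; covariates: %s\n",
    object@measure, nrow(object@table), object@nPatients, object@nControls,
    paste(object@covariates, collapse = "+")))
  cat(sprintf("  t range [%.2f, %.2f]; %d regions FDR q < 0.05\n",
              min(object@table$t), max(object@table$t),
              sum(object@table$q < 0.05)))
})

setMethod("show", "HubVulnerabilityResult", function(object) {
  cat(sprintf("HubVulnerability <%s %s, %s>: r = %.3f, p = %.4g (%d perms)\n",
              object@modality, object@metric, object@scope, object@r,
              object@p, object@nPerm))
})

setMethod("show", "EpicenterResult", function(object) {
  tab <- object@table
  top <- tab$region[order(tab$rank)][seq_len(min(3, nrow(tab)))]
  cat(sprintf(
    "EpicenterResult <%s, %s seeds>: %d seeds, %d significant (alpha %.2g, Bonferroni/%d)\n",
    object@modality, object@seedScope, nrow(tab), sum(tab$significant),
    object@alpha, nrow(tab)))
  cat("  top ranked:", paste(top, collapse = ", "), "\n")
})

setMethod("show", "SubjectNetworkScores", function(object) {
  cat(sprintf(
    "SubjectNetworkScores <%s %s>: %d patients (%d masked); mean hub score %.3f\n",
    object@modality, object@metric, length(object@subjects),
    sum(object@masked), mean(object@hubScores, na.rm = TRUE)))
})

setMethod("show", "CombatModel", function(object) {
  cat(sprintf("CombatModel: %d batches x %d regions (%s EB); covariates: %s\n",
              nrow(object@gammaStar), ncol(object@gammaStar),
              if (object@parametric) "parametric" else "non-parametric",
              paste(object@covariates, collapse = "+")))
})
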