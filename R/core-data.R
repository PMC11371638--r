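## Constructors and plain-text IO for the pipeline's data contracts:
## regional map CSV (region,value), connectivity TSV (named square matrix),
## subject CSV (demographics + one column per region).

DK_BASE_NAMES <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal")

SUBCORTICAL_BASE_NAMES <- c("thalamus", "caudate", "putamen", "pallidum",
                            "accumbens", "amygdala", "hippocampus")

#' Construct a Parcellation
#'
#' @param regions character vector of unique region names.
#' @param hemisphere \code{left}/\code{right}/\code{none} per region.
#' @param structure \code{cortical}/\code{subcortical} per region.
#' @param centroids n x 3 matrix of unit-sphere centroids (rows may be
#'   \code{NA} for subcortical regions).
#' @return a validated \linkS4class{Parcellation}
#' @export
Parcellation <- function(regions, hemisphere, structure, centroids) {
  centroids <- as.matrix(centroids)
  dimnames(centroids) <- NULL
  new("Parcellation", regions = as.character(regions),
      hemisphere = as.character(hemisphere),
      structure = as.character(structure), centroids = centroids)
}

#' Construct a RegionalMap
#'
#' @param values numeric vector, one value per in-scope region. If named, the
#'   names are matched (case-insensitively) against the parcellation and
#'   reordered; if unnamed, parcellation order is assumed.
#' @param parcellation a \linkS4class{Parcellation}.
#' @param scope \code{cortical}, \code{subcortical} or \code{all}.
#' @param kind semantic tag, see \linkS4class{RegionalMap}.
#' @return a validated \linkS4class{RegionalMap}
#' @export
RegionalMap <- function(values, parcellation, scope = "cortical",
                        kind = "effect") {
  expect <- scopeRegions(parcellation, scope)
  if (!is.null(names(values))) {
    values <- matchRegionValues(values, expect)
  } else {
    if (length(values) != length(expect))
      stop(sprintf("expected %d values for scope '%s', got %d",
                   length(expect), scope, length(values)))
    names(values) <- expect
  }
  new("RegionalMap", parcellation = parcellation, scope = scope,
      values = values, kind = kind)
}

## Case-insensitive matching of named values onto canonical region order.
matchRegionValues <- function(values, expect) {
  idx <- match(tolower(expect), tolower(names(values)))
  if (anyNA(idx)) {
    stop("missing regions: ", paste(expect[is.na(idx)], collapse = ", "))
  }
  unknown <- setdiff(tolower(names(values)), tolower(expect))
  if (length(unknown))
    stop("unknown region names: ", paste(unknown, collapse = ", "))
  out <- as.numeric(values[idx])
  names(out) <- expect
  out
}

#' Construct a ConnectivityMatrix
#'
#' Mild asymmetry (at most 1e-6) is symmetrized to \code{(W + t(W))/2};
#' larger asymmetry is an integrity error.
#'
#' @param weights square numeric matrix over all regions (region dimnames
#'   optional; if present they are matched against the parcellation).
#' @param parcellation a \linkS4class{Parcellation}.
#' @param modality \code{functional} or \code{structural}.
#' @param negativesZeroed,diagonalZeroed provenance flags (set by
#'   [preprocessConnectivity()], not normally by hand).
#' @return a validated \linkS4class{ConnectivityMatrix}
#' @export
ConnectivityMatrix <- function(weights, parcellation,
                               modality = c("functional", "structural"),
                               negativesZeroed = FALSE,
                               diagonalZeroed = FALSE) {
  modality <- match.arg(modality)
  weights <- as.matrix(weights)
  rn <- regionNames(parcellation)
  if (nrow(weights) != ncol(weights))
    stop("connectivity matrix must be square")
  if (nrow(weights) != length(rn))
    stop(sprintf("matrix is %d x %d but parcellation has %d regions",
                 nrow(weights), ncol(weights), length(rn)))
  if (!is.null(rownames(weights))) {
    i <- match(tolower(rn), tolower(rownames(weights)))
    j <- match(tolower(rn), tolower(colnames(weights)))
    if (anyNA(i) || anyNA(j))
      stop("matrix dimnames do not cover all parcellation regions")
    weights <- weights[i, j, drop = FALSE]
  }
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-6)
    stop(sprintf("asymmetry %.3g exceeds tolerance 1e-6", asym))
  weights <- (weights + t(weights)) / 2
  dimnames(weights) <- list(rn, rn)
  new("ConnectivityMatrix", parcellation = parcellation, modality = modality,
      weights = weights, negativesZeroed = negativesZeroed,
      diagonalZeroed = diagonalZeroed)
}

#' Construct a MorphoCohort
#'
#' @param values numeric matrix, regions x subjects (rownames must cover the
#'   in-scope regions of the measure; CT/SA: cortical, SV: subcortical).
#' @param subjects data.frame with one row per subject: \code{subject},
#'   \code{diagnosis}, \code{site}, \code{age}, \code{sex}, plus optional
#'   clinical columns (missing clinical values stay \code{NA}).
#' @param parcellation a \linkS4class{Parcellation}.
#' @param measure \code{CT}, \code{SA} or \code{SV}.
#' @return a validated \linkS4class{MorphoCohort}
#' @export
MorphoCohort <- function(values, subjects, parcellation,
                         measure = c("CT", "SA", "SV")) {
  measure <- match.arg(measure)
  scope <- if (measure == "SV") "subcortical" else "cortical"
  expect <- scopeRegions(parcellation, scope)
  values <- as.matrix(values)
  if (!is.null(rownames(values))) {
    idx <- match(tolower(expect), tolower(rownames(values)))
    if (anyNA(idx))
      stop("missing regions: ", paste(expect[is.na(idx)], collapse = ", "))
    values <- values[idx, , drop = FALSE]
  } else if (nrow(values) != length(expect)) {
    stop(sprintf("expected %d region rows for measure %s", length(expect),
                 measure))
  }
  rownames(values) <- expect
  subjects <- as.data.frame(subjects)
  subjects$diagnosis <- as.character(subjects$diagnosis)
  subjects$site <- as.character(subjects$site)
  subjects$sex <- as.character(subjects$sex)
  colnames(values) <- subjects$subject
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(value = values),
    colData = S4Vectors::DataFrame(subjects, row.names = subjects$subject),
    metadata = list(parcellation = parcellation, measure = measure))
  new("MorphoCohort", se)
}

CLINICAL_COLUMNS <- c("panss_pos", "panss_neg", "panss_gen", "panss_total",
                      "duration_of_illness", "cpz_equiv")

#' Validate a cohort table for downstream analysis
#'
#' Checks the subject-table contract: unique ids, required demographics,
#' region columns matching the parcellation scope of the measure. Emits a
#' warning for sites with fewer than 2 subjects per diagnosis (ineligible for
#' harmonization) and for controls carrying clinical scores (those scores are
#' ignored downstream).
#'
#' @param cohort a \linkS4class{MorphoCohort}
#' @param verbose log a row-count report via \code{message()}
#' @return the cohort, invisibly validated
#' @export
validateCohort <- function(cohort, verbose = TRUE) {
  validObject(cohort)
  cd <- SummarizedExperiment::colData(cohort)
  if (anyNA(cd$age)) stop("missing 'age' for some subjects")
  tab <- table(cd$site, cd$diagnosis)
  bad <- rownames(tab)[apply(tab < 2, 1, any)]
  if (length(bad))
    warning("sites ineligible for harmonization (<2 subjects per diagnosis): ",
            paste(bad, collapse = ", "))
  clin <- intersect(CLINICAL_COLUMNS, colnames(cd))
  if (length(clin)) {
    ctl <- cd$diagnosis == "control"
    hasClin <- rowSums(!is.na(as.data.frame(cd[, clin, drop = FALSE]))) > 0
    if (any(ctl & hasClin))
      warning(sum(ctl & hasClin),
              " control(s) carry clinical scores; ignored downstream")
  }
  if (verbose)
    message(sprintf("cohort: %d subjects (%d patients, %d controls) at %d sites",
                    nrow(cd), sum(cd$diagnosis == "patient"),
                    sum(cd$diagnosis == "control"), nrow(tab)))
  invisible(cohort)
}

#' Read / write a regional map as CSV (region,value)
#'
#' Row order in the file is irrelevant: regions are matched by name
#' (case-insensitively) against the parcellation. A file missing any in-scope
#' region, or naming an unknown region, is rejected.
#'
#' @param path CSV file with columns \code{region}, \code{value}
#' @param parcellation a \linkS4class{Parcellation}
#' @param scope map scope
#' @param kind semantic tag for the loaded map
#' @return [readRegionalMap()]: a \linkS4class{RegionalMap};
#'   [writeRegionalMap()]: the path, invisibly
#' @export
readRegionalMap <- function(path, parcellation, scope = "cortical",
                            kind = "effect") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("region", "value") %in% colnames(df)))
    stop("regional map CSV must have columns region,value")
  if (!is.numeric(df$value))
    stop("non-numeric values in ", path)
  RegionalMap(setNames(df$value, df$region), parcellation, scope, kind)
}

#' @rdname readRegionalMap
#' @param map a \linkS4class{RegionalMap} to write
#' @export
writeRegionalMap <- function(map, path) {
  write.csv(data.frame(region = names(map@values), value = unname(map@values)),
            path, row.names = FALSE)
  invisible(path)
}

#' Read / write a connectivity matrix as dense TSV
#'
#' The TSV carries a header row and first column of region names; the matrix
#' must be square and symmetric within 1e-6 (mild asymmetry is averaged out,
#' anything larger is an integrity error).
#'
#' @param path TSV file
#' @param parcellation a \linkS4class{Parcellation}
#' @param modality \code{functional} or \code{structural}
#' @return [readConnectivity()]: a \linkS4class{ConnectivityMatrix};
#'   [writeConnectivity()]: the path, invisibly
#' @export
readConnectivity <- function(path, parcellation,
                             modality = c("functional", "structural")) {
  modality <- match.arg(modality)
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  W <- as.matrix(df)
  if (!is.numeric(W)) stop("non-numeric entries in ", path)
  ConnectivityMatrix(W, parcellation, modality)
}

#' @rdname readConnectivity
#' @param conn a \linkS4class{ConnectivityMatrix} to write
#' @export
writeConnectivity <- function(conn, path) {
  df <- data.frame(region = rownames(conn@weights), conn@weights,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a cohort as wide subject CSV
#'
#' One row per subject: \code{subject}, \code{diagnosis}, \code{site},
#' \code{age}, \code{sex}, the optional clinical columns, then one column per
#' region of the measure's scope. Empty clinical cells load as \code{NA}
#' (masked).
#'
#' @param path CSV file
#' @param parcellation a \linkS4class{Parcellation}
#' @param measure \code{CT}, \code{SA} or \code{SV}
#' @return [readCohort()]: a \linkS4class{MorphoCohort};
#'   [writeCohort()]: the path, invisibly
#' @export
readCohort <- function(path, parcellation, measure = c("CT", "SA", "SV")) {
  measure <- match.arg(measure)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject", "diagnosis", "site", "age", "sex")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  scope <- if (measure == "SV") "subcortical" else "cortical"
  expect <- scopeRegions(parcellation, scope)
  idx <- match(tolower(expect), tolower(colnames(df)))
  if (anyNA(idx))
    stop("missing region columns: ", paste(expect[is.na(idx)], collapse = ", "))
  vals <- t(as.matrix(df[, idx, drop = FALSE]))
  rownames(vals) <- expect
  meta <- df[, setdiff(seq_along(df), idx), drop = FALSE]
  MorphoCohort(vals, meta, parcellation, measure)
}

#' @rdname readCohort
#' @param cohort a \linkS4class{MorphoCohort} to write
#' @export
writeCohort <- function(cohort, path) {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  vals <- t(SummarizedExperiment::assay(cohort, "value"))
  out <- cbind(cd, as.data.frame(vals, check.names = FALSE))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
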