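## Mass-univariate case-control difference maps, FDR control, effect-size
## conversion, and individualized abnormality z maps.

#' Per-region case-control linear model
#'
#' Fits \code{value ~ diagnosis + age + sex} (ordinary least squares) for
#' every region and reports the diagnosis contrast as control minus patient,
#' so positive t means reduction in patients. Two-sided p, Benjamini-Hochberg
#' q and Cohen's d (from t) are attached.
#'
#' @param cohort a (typically harmonized) \linkS4class{MorphoCohort} with
#'   both diagnoses present
#' @param covariates nuisance covariates (default age and sex)
#' @return a \linkS4class{CaseControlResult}
#' @export
fitGroupDifference <- function(cohort, covariates = c("age", "sex")) {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  if (length(unique(cd$diagnosis)) < 2)
    stop("both diagnoses must be present")
  Y <- t(SummarizedExperiment::assay(cohort, "value"))  # subjects x regions
  sds <- apply(Y, 2, sd)
  if (any(sds == 0))
    stop("constant region values: ",
         paste(colnames(Y)[sds == 0], collapse = ", "))
  form <- stats::as.formula(
    paste("~ diagnosis +", paste(covariates, collapse = "+")))
  X <- stats::model.matrix(form, data = cd)
  if (nrow(X) <= ncol(X) + 1) stop("too few subjects for the design")
  fit <- stats::lm.fit(X, Y)
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  ## model.matrix codes diagnosis=patient as 1 (levels control < patient),
  ## so negate for the reduction-positive (control - patient) convention
  j <- grep("^diagnosispatient$", colnames(X))
  beta <- -fit$coefficients[j, ]
  se <- sqrt(sigma2 * XtXinv[j, j])
  t <- beta / se
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  nP <- sum(cd$diagnosis == "patient")
  nC <- sum(cd$diagnosis == "control")
  tab <- data.frame(region = colnames(Y), t = unname(t), p = unname(p),
                    q = fdrAdjust(unname(p)),
                    d = cohensDFromT(unname(t), nC, nP), row.names = NULL)
  scope <- if (cohortMeasure(cohort) == "SV") "subcortical" else "cortical"
  new("CaseControlResult", table = tab, nPatients = nP, nControls = nC,
      covariates = covariates, measure = cohortMeasure(cohort),
      scope = scope, parcellation = parcellationOf(cohort))
}

#' Extract the t map of a case-control result as a RegionalMap
#'
#' @param result a \linkS4class{CaseControlResult}
#' @param what column to extract (\code{t}, \code{d}, \code{p} or \code{q})
#' @return a \linkS4class{RegionalMap} (kind \code{t} or \code{cohens_d})
#' @export
alterationMap <- function(result, what = c("t", "d", "p", "q")) {
  what <- match.arg(what)
  kind <- switch(what, t = "t", d = "cohens_d", "effect")
  RegionalMap(setNames(result@table[[what]], result@table$region),
              result@parcellation, result@scope, kind)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement (delegates to
#' \code{\link[stats]{p.adjust}}); rejects p-values outside [0, 1].
#'
#' @param p vector of p-values in [0, 1]
#' @return vector of q-values
#' @export
fdrAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Cohen's d from a two-sample t statistic
#'
#' \code{d = t * sqrt(1/n1 + 1/n2)}; symmetric in the group sizes.
#'
#' @param t t statistic(s)
#' @param n1,n2 group sizes (>= 2)
#' @return Cohen's d
#' @export
cohensDFromT <- function(t, n1, n2) {
  if (any(c(n1, n2) < 2)) stop("group sizes must be >= 2")
  t * sqrt(1 / n1 + 1 / n2)
}

#' Individualized abnormality z-score maps
#'
#' Fits \code{value ~ age + sex} per region in controls only, then scores
#' every patient as \code{z = (observed - predicted) / SD(control
#' residuals)}. Negative z means thinner (or smaller) than expected for age
#' and sex.
#'
#' @param cohort a harmonized \linkS4class{MorphoCohort}
#' @param covariates reference-model covariates (default age and sex)
#' @return a \linkS4class{SubjectZMaps} (z is regions x patients)
#' @export
subjectZScoreMaps <- function(cohort, covariates = c("age", "sex")) {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  ctl <- cd$diagnosis == "control"
  if (sum(ctl) <= 10) stop("need more than 10 controls for the reference fit")
  form <- stats::as.formula(paste("~", paste(covariates, collapse = "+")))
  ## one design over all subjects so factor levels stay shared between the
  ## control reference and the patients being scored
  X <- stats::model.matrix(form, data = cd)
  Xc <- X[ctl, , drop = FALSE]
  Yc <- t(SummarizedExperiment::assay(cohort, "value"))[ctl, , drop = FALSE]
  fit <- stats::lm.fit(Xc, Yc)
  residSD <- sqrt(colSums(fit$residuals^2) / (nrow(Xc) - ncol(Xc)))
  if (any(residSD == 0))
    stop("zero control residual SD: ",
         paste(colnames(Yc)[residSD == 0], collapse = ", "))
  pat <- !ctl
  Xp <- X[pat, , drop = FALSE]
  Yp <- t(SummarizedExperiment::assay(cohort, "value"))[pat, , drop = FALSE]
  zs <- t((Yp - Xp %*% fit$coefficients) / rep(residSD, each = nrow(Xp)))
  colnames(zs) <- cd$subject[pat]
  scope <- if (cohortMeasure(cohort) == "SV") "subcortical" else "cortical"
  new("SubjectZMaps", z = zs, refCoef = fit$coefficients, residSD = residSD,
      covariates = covariates, parcellation = parcellationOf(cohort),
      scope = scope)
}
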