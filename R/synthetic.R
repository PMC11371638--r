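## Synthetic multi-site case-control cohort generator: hub-structured
## connectomes on a synthetic sphere, planted epicenter/hub effect maps,
## site location/scale batch effects, subject severity coupled to symptoms.

#' Configuration of the synthetic cohort generator
#'
#' All parameters of the generative model, with defaults emulating a large
#' multi-site case-control morphometry study (26 sites, 2439 patients, 2867
#' controls, 68 cortical + 14 subcortical parcels). Units are mm on the
#' cortical-thickness scale.
#'
#' @param nCorticalPerHemi cortical parcels per hemisphere (default 34).
#' @param nSubcortical subcortical regions (default 14; 7 bilateral pairs).
#' @param nSites number of acquisition sites (default 26).
#' @param nPatients,nControls cohort arm sizes (defaults 2439 / 2867).
#' @param epicenterRegions planted epicenter region names (default bilateral
#'   entorhinal cortex).
#' @param bEpi mm of deficit per unit min-max-normalized connectivity to the
#'   planted epicenters (default 0.4).
#' @param bHub mm of deficit per unit min-max-normalized weighted degree
#'   (default 0.2).
#' @param sigmaMap SD (mm) of i.i.d. spatial noise added to the effect map.
#' @param ageSlope mm/year of age effect on the measure (default -0.005).
#' @param sexOffset mm offset for males (default 0.02).
#' @param siteShiftSd SD (mm) of per-site, per-region additive shifts.
#' @param siteScaleRange range of per-site, per-region residual-scale
#'   multipliers.
#' @param severitySd log-scale SD of the lognormal per-patient severity
#'   (median 1, so effects are strictly deficits; modest spread keeps the
#'   group- and subject-level estimands consistent).
#' @param symptomLoading PANSS-total points per unit severity (lambda).
#' @param panssNoiseSd SD of PANSS-total noise.
#' @param noiseSd per-subject per-region residual SD (mm).
#' @param hubFraction fraction of cortical parcels designated hubs.
#' @param distanceDecay exponential decay of connection weight with
#'   geodesic centroid distance (per radian).
#' @param hubGain multiplicative connectivity gain of hub parcels.
#' @param edgeNoiseSd log-scale SD of lognormal edge noise.
#' @param baselineCortical,baselineSpread mean and regional SD (mm) of the
#'   healthy cortical baseline map.
#' @param baselineSubcortical healthy subcortical baseline (volume units).
#' @param svScale multiplier applied to all mm-scale effects when the
#'   generated measure is subcortical volume.
#' @param femaleFracPatients,femaleFracControls female fraction per arm.
#' @param durillShape,durillScale gamma parameters (years) of duration of
#'   illness (mean ~11.6 y, populating first-episode through chronic stages).
#' @param cpzMeanlog,cpzSdlog lognormal parameters of antipsychotic dose
#'   (chlorpromazine equivalents, mg/day), independent of severity.
#' @param seed integer seed.
#' @return a \code{GenerativeConfig} object
#' @export
GenerativeConfig <- function(nCorticalPerHemi = 34L, nSubcortical = 14L,
                             nSites = 26L, nPatients = 2439L,
                             nControls = 2867L,
                             epicenterRegions = c("L_entorhinal",
                                                  "R_entorhinal"),
                             bEpi = 0.4, bHub = 0.2, sigmaMap = 0.03,
                             ageSlope = -0.005, sexOffset = 0.02,
                             siteShiftSd = 0.1,
                             siteScaleRange = c(0.8, 1.25),
                             severitySd = 0.1, symptomLoading = 25,
                             panssNoiseSd = 8, noiseSd = 0.05,
                             hubFraction = 0.15, distanceDecay = 3.5,
                             hubGain = 2.5, edgeNoiseSd = 0.1,
                             baselineCortical = 2.5, baselineSpread = 0.15,
                             baselineSubcortical = 4.5, svScale = 1.8,
                             femaleFracPatients = 0.32,
                             femaleFracControls = 0.49,
                             durillShape = 0.55, durillScale = 21,
                             cpzMeanlog = log(300), cpzSdlog = 0.5,
                             seed = 1L) {
  cfg <- list(nCorticalPerHemi = as.integer(nCorticalPerHemi),
              nSubcortical = as.integer(nSubcortical),
              nSites = as.integer(nSites), nPatients = as.integer(nPatients),
              nControls = as.integer(nControls),
              epicenterRegions = epicenterRegions, bEpi = bEpi, bHub = bHub,
              sigmaMap = sigmaMap, ageSlope = ageSlope,
              sexOffset = sexOffset, siteShiftSd = siteShiftSd,
              siteScaleRange = siteScaleRange, severitySd = severitySd,
              symptomLoading = symptomLoading, panssNoiseSd = panssNoiseSd,
              noiseSd = noiseSd, hubFraction = hubFraction,
              distanceDecay = distanceDecay, hubGain = hubGain,
              edgeNoiseSd = edgeNoiseSd, baselineCortical = baselineCortical,
              baselineSpread = baselineSpread,
              baselineSubcortical = baselineSubcortical, svScale = svScale,
              femaleFracPatients = femaleFracPatients,
              femaleFracControls = femaleFracControls,
              durillShape = durillShape, durillScale = durillScale,
              cpzMeanlog = cpzMeanlog, cpzSdlog = cpzSdlog,
              seed = as.integer(seed))
  sds <- c(cfg$sigmaMap, cfg$siteShiftSd, cfg$severitySd, cfg$noiseSd,
           cfg$panssNoiseSd, cfg$edgeNoiseSd, cfg$baselineSpread)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (length(cfg$epicenterRegions) < 1)
    stop("epicenterRegions must be non-empty")
  if (cfg$nSites < 2) stop("nSites must be >= 2")
  if (cfg$hubFraction <= 0 || cfg$hubFraction >= 0.5)
    stop("hubFraction must be in (0, 0.5)")
  structure(cfg, class = "GenerativeConfig")
}

#' @export
print.GenerativeConfig <- function(x, ...) {
  cat(sprintf(
    "GenerativeConfig: %d+%d regions, %d sites, %d patients / %d controls\n",
    2L * x$nCorticalPerHemi, x$nSubcortical, x$nSites, x$nPatients,
    x$nControls))
  cat(sprintf("  epicenters: %s; bEpi=%.3g bHub=%.3g sigmaMap=%.3g seed=%d\n",
              paste(x$epicenterRegions, collapse = ","), x$bEpi, x$bHub,
              x$sigmaMap, x$seed))
  invisible(x)
}

## Fibonacci lattice covering the full unit sphere.
.fibonacciSphere <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

## Pairwise cortical distances respecting the two-sphere topology: plain
## great-circle arc within a hemisphere; across hemispheres, the right
## centroids are folded onto the left sphere via the x-mirror (homotopic
## alignment) and a fixed interhemispheric offset is added.
.corticalDistances <- function(parcellation, interHemi = 0.5) {
  ctx <- which(parcellation@structure == "cortical")
  cc <- parcellation@centroids[ctx, , drop = FALSE]
  hemi <- parcellation@hemisphere[ctx]
  folded <- cc
  folded[hemi == "right", 1] <- -folded[hemi == "right", 1]
  D <- acos(pmin(pmax(tcrossprod(folded), -1), 1))
  cross <- outer(hemi, hemi, "!=")
  D[cross] <- D[cross] + interHemi
  dimnames(D) <- list(parcellation@regions[ctx], parcellation@regions[ctx])
  D
}

## Fibonacci lattice on a spherical cap of half-angle pi/2 around `axis`
## (used for the interior subcortical pseudo-centroids).
.fibonacciHemisphere <- function(n, axis = c(-1, 0, 0)) {
  i <- seq_len(n)
  cosA <- 1 - (i - 0.5) / n          # polar angle from axis in [0, pi/2)
  sinA <- sqrt(pmax(0, 1 - cosA^2))
  phi <- i * pi * (3 - sqrt(5))      # golden angle
  ## orthonormal frame completing the axis
  u <- c(0, 1, 0); v <- c(0, 0, 1)
  if (abs(axis[1]) < 0.9) { u <- c(1, 0, 0); v <- c(0, 0, 1) }
  pts <- outer(cosA, axis) + outer(sinA * cos(phi), u) +
    outer(sinA * sin(phi), v)
  pts / sqrt(rowSums(pts^2))
}

#' Generate a synthetic parcellation
#'
#' Cortical centroids are placed by a Fibonacci lattice on each hemisphere's
#' unit sphere (the standard inflated-sphere representation a spin test
#' operates on), the right hemisphere mirrored from the left across x = 0;
#' subcortical regions carry no centroid. With the default sizes (34 per
#' hemisphere, 14 subcortical) regions take Desikan-Killiany-style names;
#' other sizes use generic \code{ctx_NN} / \code{sub_NN} names. Distances
#' across hemispheres are computed homotopically (right folded onto the left
#' sphere plus a fixed interhemispheric offset).
#'
#' @param nCorticalPerHemi cortical parcels per hemisphere (>= 4)
#' @param nSubcortical subcortical regions (even; bilateral pairs)
#' @return a \linkS4class{Parcellation}
#' @export
generateParcellation <- function(nCorticalPerHemi = 34L, nSubcortical = 14L) {
  n <- as.integer(nCorticalPerHemi)
  ns <- as.integer(nSubcortical)
  if (n < 4) stop("nCorticalPerHemi must be >= 4")
  if (ns %% 2 != 0) stop("nSubcortical must be even (bilateral pairs)")
  base <- if (n == 34) DK_BASE_NAMES else sprintf("ctx_%02d", seq_len(n))
  subBase <- if (ns == 14) SUBCORTICAL_BASE_NAMES
             else sprintf("sub_%02d", seq_len(ns %/% 2))
  left <- .fibonacciSphere(n)
  right <- left %*% diag(c(-1, 1, 1))
  subNames <- if (ns > 0) c(paste0("L_", subBase), paste0("R_", subBase))
              else character(0)
  regions <- c(paste0("L_", base), paste0("R_", base), subNames)
  hemi <- c(rep("left", n), rep("right", n),
            rep("left", ns %/% 2), rep("right", ns %/% 2))
  struct <- c(rep("cortical", 2L * n), rep("subcortical", ns))
  cent <- rbind(left, right, matrix(NA_real_, ns, 3))
  Parcellation(regions, hemi, struct, cent)
}

#' Desikan-Killiany-style synthetic parcellation (68 + 14 regions)
#'
#' Convenience wrapper around [generateParcellation()] with the study
#' default layout: 34 cortical parcels per hemisphere plus 14 bilateral
#' subcortical gray-matter structures (thalamus, caudate, putamen, pallidum,
#' accumbens, amygdala, hippocampus). Centroid geometry is synthetic
#' (Fibonacci lattice), not anatomical.
#'
#' @return a \linkS4class{Parcellation}
#' @export
dkParcellation <- function() generateParcellation(34L, 14L)

## Interior pseudo-coordinates (norm 0.3) for subcortical regions: used only
## to define connectome weights, never for the spin test.
.pseudoCentroids <- function(parcellation) {
  coords <- parcellation@centroids
  sub <- which(parcellation@structure == "subcortical")
  if (length(sub)) {
    hemi <- parcellation@hemisphere[sub]
    nl <- sum(hemi == "left")
    leftDir <- .fibonacciHemisphere(max(nl, 1L), c(-1, 0, 0))
    coords[sub[hemi == "left"], ] <- 0.3 * leftDir[seq_len(nl), , drop = FALSE]
    nr <- sum(hemi == "right")
    coords[sub[hemi == "right"], ] <-
      0.3 * (leftDir[seq_len(nr), , drop = FALSE] %*% diag(c(-1, 1, 1)))
  }
  coords
}

## Pairwise distances: great-circle arc between cortical centroids,
## Euclidean for pairs involving an interior subcortical pseudo-centroid.
.regionDistances <- function(parcellation) {
  coords <- .pseudoCentroids(parcellation)
  ctx <- parcellation@structure == "cortical"
  n <- nrow(coords)
  D <- matrix(0, n, n)
  D[ctx, ctx] <- .corticalDistances(parcellation)
  if (any(!ctx)) {
    other <- which(!ctx)
    for (i in other) {
      d <- sqrt(colSums((t(coords) - coords[i, ])^2))
      D[i, ] <- d
      D[, i] <- d
    }
  }
  diag(D) <- 0
  dimnames(D) <- list(parcellation@regions, parcellation@regions)
  D
}

## Deterministic mirrored hub set: evenly spaced cortical parcels per
## hemisphere.
.hubSet <- function(parcellation, hubFraction) {
  ctx <- which(parcellation@structure == "cortical")
  hubs <- character()
  for (h in c("left", "right")) {
    idx <- ctx[parcellation@hemisphere[ctx] == h]
    k <- max(1L, round(hubFraction * length(idx)))
    pick <- unique(round(seq(1, length(idx), length.out = k)))
    hubs <- c(hubs, parcellation@regions[idx[pick]])
  }
  hubs
}

#' Generate a pair of hub-structured normative connectomes
#'
#' Weights follow \code{exp(-decay * d(i,j)) * gain_i * gain_j * lognormal
#' noise}, where d is the great-circle distance between cortical centroids
#' (Euclidean for the interior subcortical pseudo-centroids) and gain is
#' elevated for a deterministic, hemispherically mirrored hub set. The
#' functional and structural matrices share the hub set and distance kernel
#' but have independent edge noise. Matrices are symmetric, nonnegative, with
#' zero diagonal.
#'
#' @param parcellation a \linkS4class{Parcellation}
#' @param hubFraction fraction of cortical parcels per hemisphere designated
#'   hubs, in (0, 0.5)
#' @param distanceDecay exponential decay rate per radian
#' @param seed integer seed for the edge noise
#' @param hubGain connectivity gain of hub parcels
#' @param edgeNoiseSd log-scale SD of the lognormal edge noise
#' @return list with elements \code{functional} and \code{structural}
#'   (\linkS4class{ConnectivityMatrix}) and \code{hubs} (character)
#' @export
generateConnectome <- function(parcellation, hubFraction = 0.15,
                               distanceDecay = 1.5, seed = 1L,
                               hubGain = 2.5, edgeNoiseSd = 0.3) {
  if (hubFraction <= 0 || hubFraction >= 0.5)
    stop("hubFraction must be in (0, 0.5)")
  D <- .regionDistances(parcellation)
  hubs <- .hubSet(parcellation, hubFraction)
  gain <- ifelse(parcellation@regions %in% hubs, hubGain, 1)
  base <- exp(-distanceDecay * D) * outer(gain, gain)
  diag(base) <- 0
  n <- nrow(base)
  set.seed(seed)
  draw <- function() {
    noise <- matrix(0, n, n)
    up <- upper.tri(noise)
    noise[up] <- rlnorm(sum(up), 0, edgeNoiseSd)
    noise <- noise + t(noise)
    W <- base * noise
    if (max(W) < 1e-12) stop("degenerate (all-zero) connectivity matrix")
    W
  }
  fun <- ConnectivityMatrix(draw(), parcellation, "functional",
                            negativesZeroed = TRUE, diagonalZeroed = TRUE)
  str <- ConnectivityMatrix(draw(), parcellation, "structural",
                            negativesZeroed = TRUE, diagonalZeroed = TRUE)
  list(functional = fun, structural = str, hubs = hubs)
}

#' Plant a ground-truth disease effect map
#'
#' The regional deficit (mm) is
#' \deqn{\Delta_j = b_{epi} \bar c_{jE} + b_{hub} \tilde g_j + \epsilon_j,}
#' clipped at 0, where \eqn{\bar c_{jE}} is region j's mean connectivity to
#' the planted epicenter set E (min-max normalized over regions) and
#' \eqn{\tilde g_j} the min-max-normalized weighted degree. This is the
#' generative inverse of the epicenter estimator: regions strongly connected
#' to E are strongly altered.
#'
#' @param conn a \linkS4class{ConnectivityMatrix} (typically the functional
#'   matrix of [generateConnectome()])
#' @param config a [GenerativeConfig()]
#' @return list with \code{delta} (\linkS4class{RegionalMap} over all
#'   regions, mm), \code{epicenters}, \code{bEpi}, \code{bHub}
#' @export
plantEffectMap <- function(conn, config = GenerativeConfig()) {
  p <- conn@parcellation
  E <- config$epicenterRegions
  bad <- setdiff(E, scopeRegions(p, "cortical"))
  if (length(bad))
    stop("epicenter regions not cortical parcels: ", paste(bad, collapse = ", "))
  if (config$bEpi == 0 && config$bHub == 0 && config$sigmaMap == 0)
    stop("no signal: bEpi, bHub and sigmaMap are all zero")
  W <- conn@weights
  minmax <- function(x) {
    r <- range(x)
    if (r[2] == r[1]) return(rep(0, length(x)))
    (x - r[1]) / (r[2] - r[1])
  }
  cbar <- minmax(rowMeans(W[, E, drop = FALSE]))
  gdeg <- minmax(rowSums(W))
  set.seed(config$seed + 7L)
  delta <- config$bEpi * cbar + config$bHub * gdeg +
    rnorm(nrow(W), 0, config$sigmaMap)
  delta <- pmax(delta, 0)
  list(delta = RegionalMap(setNames(delta, rownames(W)), p, "all", "effect"),
       epicenters = E, bEpi = config$bEpi, bHub = config$bHub)
}

#' Generate a multi-site case-control cohort
#'
#' Control values follow \code{baseline_j + ageSlope*(age-40) +
#' sexOffset*[male] + gamma_site,j + delta_site,j * eps}; patients
#' additionally lose \code{s_i * Delta_j}, with lognormal per-patient
#' severity s_i (median 1). PANSS total is \code{30 + lambda * s_i + noise},
#' split into subscales at fixed proportions above the floor (positive 0.25,
#' negative 0.30, general 0.45); duration of illness is gamma-distributed,
#' antipsychotic dose lognormal and independent of severity. Sites are
#' assigned round-robin; controls carry no clinical scores.
#'
#' @param parcellation a \linkS4class{Parcellation}
#' @param truth output of [plantEffectMap()] (its \code{delta} spans all
#'   regions; the slice matching \code{measure} is applied)
#' @param config a [GenerativeConfig()]
#' @param measure \code{CT}, \code{SA} (cortical) or \code{SV} (subcortical)
#' @param seed overrides \code{config$seed} if given
#' @return a \linkS4class{MorphoCohort}; \code{metadata()$truth} records the
#'   drawn severities and site effects
#' @export
generateCohort <- function(parcellation, truth, config = GenerativeConfig(),
                           measure = c("CT", "SA", "SV"),
                           seed = config$seed) {
  measure <- match.arg(measure)
  scope <- if (measure == "SV") "subcortical" else "cortical"
  regions <- scopeRegions(parcellation, scope)
  if (!identical(regionNames(truth$delta@parcellation),
                 regionNames(parcellation)))
    stop("ground truth does not match parcellation")
  sc <- if (measure == "SV") config$svScale else 1
  delta <- truth$delta@values[regions] * sc
  baseMean <- if (measure == "SV") config$baselineSubcortical
              else config$baselineCortical
  nP <- config$nPatients; nC <- config$nControls
  n <- nP + nC
  nR <- length(regions)
  set.seed(seed)
  baseline <- baseMean + rnorm(nR, 0, config$baselineSpread * sc)
  diagnosis <- c(rep("patient", nP), rep("control", nC))
  age <- runif(n, 18, 65)
  sex <- ifelse(runif(n) < ifelse(diagnosis == "patient",
                                  config$femaleFracPatients,
                                  config$femaleFracControls), "F", "M")
  site <- sprintf("site_%02d", rep_len(seq_len(config$nSites), n))
  gamma <- matrix(rnorm(config$nSites * nR, 0, config$siteShiftSd * sc),
                  config$nSites, nR)
  deltaScale <- matrix(runif(config$nSites * nR, config$siteScaleRange[1],
                             config$siteScaleRange[2]), config$nSites, nR)
  severity <- rlnorm(nP, 0, config$severitySd)
  siteIdx <- rep_len(seq_len(config$nSites), n)
  eps <- matrix(rnorm(n * nR, 0, config$noiseSd * sc), n, nR)
  vals <- matrix(baseline, n, nR, byrow = TRUE) +
    config$ageSlope * sc * (age - 40) +
    config$sexOffset * sc * (sex == "M") +
    gamma[siteIdx, ] + deltaScale[siteIdx, ] * eps
  vals[seq_len(nP), ] <- vals[seq_len(nP), ] - outer(severity, delta)
  panssTotal <- pmin(pmax(30 + config$symptomLoading * severity +
                            rnorm(nP, 0, config$panssNoiseSd), 30), 210)
  excess <- panssTotal - 30
  durill <- rgamma(nP, shape = config$durillShape, scale = config$durillScale)
  cpz <- rlnorm(nP, config$cpzMeanlog, config$cpzSdlog)
  subjects <- data.frame(
    subject = sprintf("s%05d", seq_len(n)),
    diagnosis = diagnosis, site = site, age = age, sex = sex,
    panss_pos = c(7 + 0.25 * excess, rep(NA_real_, nC)),
    panss_neg = c(7 + 0.30 * excess, rep(NA_real_, nC)),
    panss_gen = c(16 + 0.45 * excess, rep(NA_real_, nC)),
    panss_total = c(panssTotal, rep(NA_real_, nC)),
    duration_of_illness = c(durill, rep(NA_real_, nC)),
    cpz_equiv = c(cpz, rep(NA_real_, nC)))
  cohort <- MorphoCohort(t(vals), subjects, parcellation, measure)
  S4Vectors::metadata(cohort)$truth <- list(
    delta = delta, epicenters = truth$epicenters, severity = severity,
    siteShift = gamma, siteScale = deltaScale, seed = seed)
  cohort
}

#' Spatially smoothed Gaussian noise maps on the cortical sphere
#'
#' Draws i.i.d. Gaussian noise per cortical parcel and smooths it with a
#' great-circle Gaussian kernel, producing maps with realistic spatial
#' autocorrelation; used for null calibration of the spin test.
#'
#' @param parcellation a \linkS4class{Parcellation}
#' @param ell kernel length scale in radians (default 0.5)
#' @param n number of maps
#' @param seed integer seed
#' @return matrix (nCortical x n) of zero-mean, unit-SD smoothed maps, with
#'   cortical region rownames
#' @export
smoothSphericalNoise <- function(parcellation, ell = 0.5, n = 1, seed = 1L) {
  ctx <- which(parcellation@structure == "cortical")
  D <- .corticalDistances(parcellation)
  K <- exp(-D^2 / (2 * ell^2))
  set.seed(seed)
  raw <- K %*% matrix(rnorm(length(ctx) * n), length(ctx), n)
  out <- scale(raw)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  rownames(out) <- parcellation@regions[ctx]
  out
}
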