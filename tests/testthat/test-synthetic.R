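test_that("parcellation geometry is mirrored, spread and deterministic", {
  parc <- generateParcellation(34L, 14L)
  cc <- centroids(parc)
  left <- cc[1:34, ]; right <- cc[35:68, ]
  expect_equal(left %*% diag(c(-1, 1, 1)), right, tolerance = 1e-12,
               ignore_attr = TRUE)
  ## minimum pairwise angle is strictly positive even at the minimum size
  small <- centroids(generateParcellation(4L, 0L))
  ang <- acos(pmin(pmax(tcrossprod(small), -1), 1))
  expect_gt(min(ang[upper.tri(ang)]), 0)
  expect_identical(centroids(generateParcellation(34L, 14L)), cc)
  expect_error(generateParcellation(3L), ">= 4")
})

test_that("connectome elevates hub degree and decays with distance", {
  parc <- smallParcellation()
  net <- generateConnectome(parc, hubFraction = 0.25, seed = 3)
  deg <- rowSums(corticoCortical(net$functional))
  hubs <- intersect(net$hubs, names(deg))
  expect_gt(mean(deg[hubs]), mean(deg[setdiff(names(deg), hubs)]))
  ## strong decay kills all off-diagonal weight (decay chosen from the
  ## lattice spacing so the matrix is tiny but not identically zero)
  cc <- centroids(parc)[1:16, ]
  D <- acos(pmin(pmax(tcrossprod(cc), -1), 1))
  minD <- min(D[upper.tri(D)][D[upper.tri(D)] > 1e-9])
  dead <- generateConnectome(parc, distanceDecay = 20 / minD, seed = 3)
  W <- connWeights(dead$functional)
  expect_lt(max(W[upper.tri(W)]), 1e-6)
})

test_that("functional and structural degree rank-correlate across seeds", {
  parc <- dkParcellation()
  rho <- vapply(1:20, function(s) {
    net <- generateConnectome(parc, seed = s)
    cor(rowSums(corticoCortical(net$functional)),
        rowSums(corticoCortical(net$structural)), method = "spearman")
  }, numeric(1))
  expect_true(all(rho > 0))
})

test_that("planted effect map follows its generative invariant", {
  parc <- smallParcellation()
  net <- generateConnectome(parc, seed = 4)
  W <- connWeights(net$functional)
  ## bHub = 0, no noise, single epicenter: monotone in that region's row
  cfg1 <- smallConfig(epicenterRegions = "L_ctx_03", bHub = 0, sigmaMap = 0)
  d1 <- mapValues(plantEffectMap(net$functional, cfg1)$delta)
  expect_equal(cor(d1, W[, "L_ctx_03"], method = "spearman"), 1)
  ## bEpi = 0, no noise: perfect rank correlation with degree
  cfg2 <- smallConfig(bEpi = 0, sigmaMap = 0)
  d2 <- mapValues(plantEffectMap(net$functional, cfg2)$delta)
  expect_equal(cor(d2, rowSums(W), method = "spearman"), 1)
  ## no signal at all is an error
  expect_error(plantEffectMap(net$functional,
                              smallConfig(bEpi = 0, bHub = 0, sigmaMap = 0)),
               "no signal")
  ## default-config effect map is hub-coupled
  rr <- vapply(1:20, function(s) {
    nets <- generateConnectome(parc, seed = 100 + s)
    cfg <- smallConfig(seed = 100 + s)
    cor(mapValues(plantEffectMap(nets$functional, cfg)$delta),
        rowSums(connWeights(nets$functional)))
  }, numeric(1))
  expect_gt(median(rr), 0.4)
})

test_that("cohort generation is seed-deterministic with coupled symptoms", {
  parc <- smallParcellation()
  net <- generateConnectome(parc, seed = 5)
  truth <- plantEffectMap(net$functional, smallConfig())
  c1 <- generateCohort(parc, truth, smallConfig(), seed = 42)
  c2 <- generateCohort(parc, truth, smallConfig(), seed = 42)
  expect_identical(SummarizedExperiment::assay(c1),
                   SummarizedExperiment::assay(c2))
  expect_identical(as.data.frame(SummarizedExperiment::colData(c1)),
                   as.data.frame(SummarizedExperiment::colData(c2)))
  ## strong loading, tiny noise: PANSS total tracks severity
  cfg <- smallConfig(symptomLoading = 60, panssNoiseSd = 1)
  coh <- generateCohort(parc, truth, cfg, seed = 7)
  tr <- S4Vectors::metadata(coh)$truth
  cd <- SummarizedExperiment::colData(coh)
  expect_gt(cor(cd$panss_total[cd$diagnosis == "patient"], tr$severity), 0.9)
  ## subscales partition the total at fixed proportions
  pat <- cd$diagnosis == "patient"
  expect_equal(cd$panss_pos[pat] + cd$panss_neg[pat] + cd$panss_gen[pat],
               cd$panss_total[pat], tolerance = 1e-12)
})

test_that("null cohorts (zero effect map) give calibrated group models", {
  parc <- smallParcellation()
  truth <- nullTruth(parc)
  hits <- 0L; total <- 0L; anyFdr <- 0L
  for (s in 1:200) {
    coh <- generateCohort(parc, truth, smallConfig(), seed = 500 + s)
    cc <- resultTable(fitGroupDifference(combatFitTransform(coh)$cohort))
    hits <- hits + sum(cc$p < 0.05)
    total <- total + nrow(cc)
    anyFdr <- anyFdr + any(cc$q < 0.05)
  }
  expect_gt(hits / total, 0.03)
  expect_lt(hits / total, 0.07)
  ## under the global null, BH rejects anywhere with the Simes rate ~alpha;
  ## the run-level rate must stay within binomial noise of 5%
  expect_lte(anyFdr / 200, 0.1)
})

test_that("smoothed spherical noise has unit scale and autocorrelation", {
  parc <- dkParcellation()
  maps <- smoothSphericalNoise(parc, ell = 0.5, n = 5, seed = 1)
  expect_equal(colMeans(maps), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(maps, 2, sd), rep(1, 5), tolerance = 1e-12)
  ## neighbouring parcels are more similar than distant ones
  cc <- centroids(parc)[1:68, ]
  D <- acos(pmin(pmax(tcrossprod(cc), -1), 1))
  near <- D < 0.4 & upper.tri(D); far <- D > 2 & upper.tri(D)
  prod <- tcrossprod(maps[, 1])
  expect_gt(mean(prod[near]), mean(prod[far]))
})
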