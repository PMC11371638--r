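fixtureEnv <- new.env()

susFixture <- function() {
  if (is.null(fixtureEnv$fx)) {
    parc <- smallParcellation()
    net <- generateConnectome(parc, seed = 7)
    fu <- preprocessConnectivity(net$functional)
    fixtureEnv$fx <- list(
      parc = parc, fu = fu,
      cen = degreeCentrality(fu),
      null = buildSpinRotations(parc, 300, seed = 8))
  }
  fixtureEnv$fx
}

test_that("hub vulnerability is exact for self-correlation and affine-invariant", {
  fx <- susFixture()
  alt <- RegionalMap(mapValues(fx$cen), fx$parc, "cortical", "t")
  res <- hubVulnerability(alt, fx$cen, fx$null)
  expect_equal(res@r, 1)
  ## affine rescaling of either map leaves r untouched
  res2 <- hubVulnerability(3 * alt + 0.7, fx$cen, fx$null)
  expect_equal(res2@r, res@r, tolerance = 1e-12)
  ## scope mismatch is an error
  sub <- RegionalMap(rnorm(4), fx$parc, "subcortical", "t")
  expect_error(hubVulnerability(sub, fx$cen, fx$null), "scope")
  ## subcortical route uses the label shuffle
  cenSub <- degreeCentrality(fx$fu, "subcortico-cortical")
  resSub <- hubVulnerability(sub, cenSub, nPerm = 500, seed = 3)
  expect_true(resSub@p > 0 && resSub@p <= 1)
})

test_that("epicenter map ranks a seed's own profile first", {
  fx <- susFixture()
  W <- corticoCortical(fx$fu)
  k <- 5
  alt <- RegionalMap(W[k, ], fx$parc, "cortical", "t")
  epi <- epicenterMap(alt, fx$fu, fx$null)
  tab <- resultTable(epi)
  expect_equal(tab$r[k], 1)
  expect_equal(tab$rank[k], 1L)
  expect_true(all(sort(tab$rank) == seq_len(16)))
  ## Bonferroni divisor is the seed count
  expect_equal(tab$p_bonf, pmin(1, tab$p_spin * 16))
  ## a connectivity-weighted mixture ranks its support highest (single seed)
  expect_equal(resultTable(epicenterMap(
    RegionalMap(as.vector(W %*% (seq_len(16) == k)), fx$parc, "cortical",
                "t"), fx$fu, fx$null))$rank[k], 1L)
})

test_that("epicenter seeds with empty profiles are excluded from ranking", {
  fx <- susFixture()
  W <- connWeights(fx$fu)
  W[3, ] <- 0; W[, 3] <- 0
  conn <- ConnectivityMatrix(W, fx$parc, "functional",
                             negativesZeroed = TRUE, diagonalZeroed = TRUE)
  alt <- RegionalMap(smoothSphericalNoise(fx$parc, n = 1, seed = 1)[, 1],
                     fx$parc, "cortical", "t")
  tab <- resultTable(epicenterMap(alt, conn, fx$null))
  expect_true(is.na(tab$r[3]) && is.na(tab$rank[3]))
  expect_equal(sort(tab$rank[-3]), seq_len(15))
})

test_that("subcortical seeds correlate their rows with the cortical map", {
  fx <- susFixture()
  S <- subcorticoCortical(fx$fu)
  alt <- RegionalMap(S[2, ], fx$parc, "cortical", "t")
  tab <- resultTable(epicenterMap(alt, fx$fu, fx$null,
                                  seedScope = "subcortical"))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$r[2], 1)
  expect_equal(tab$p_bonf, pmin(1, tab$p_spin * 4))
})

test_that("excluding the self-entry is available behind a flag", {
  fx <- susFixture()
  W <- corticoCortical(fx$fu)
  alt <- RegionalMap(smoothSphericalNoise(fx$parc, n = 1, seed = 4)[, 1],
                     fx$parc, "cortical", "t")
  t1 <- resultTable(epicenterMap(alt, fx$fu, fx$null))
  t2 <- resultTable(epicenterMap(alt, fx$fu, fx$null, excludeSelf = TRUE))
  k <- 2
  expect_equal(t2$r[k], cor(W[k, -k], mapValues(alt)[-k]))
  expect_false(isTRUE(all.equal(t1$r, t2$r)))
})

test_that("epicenter centrality percentile summarizes the top seeds", {
  fx <- susFixture()
  cvals <- mapValues(fx$cen)
  ## epicenters ranked exactly by centrality: top-5 percentile is high
  alt <- RegionalMap(as.vector(scale(cvals)), fx$parc, "cortical", "t")
  epiLike <- epicenterMap(RegionalMap(corticoCortical(fx$fu)[which.max(cvals), ],
                                      fx$parc, "cortical", "t"),
                          fx$fu, fx$null)
  fake <- epiLike
  fake@table$r <- cvals
  fake@table$rank <- rank(-cvals, ties.method = "first")
  res <- epicenterCentralityPercentile(fake, fx$cen, topK = 3)
  expect_gt(res$median, 90)
  res1 <- epicenterCentralityPercentile(fake, fx$cen, topK = 1)
  expect_equal(unname(res1$percentiles), 100)
  expect_error(epicenterCentralityPercentile(fake, fx$cen, topK = 17),
               "topK")
})

test_that("stage subsetting follows the duration-of-illness windows", {
  parc <- smallParcellation()
  coh <- generateCohort(parc, nullTruth(parc), smallConfig(), seed = 10)
  cd <- SummarizedExperiment::colData(coh)
  dur <- cd$duration_of_illness
  ## plant known durations on the first four patients
  pats <- which(cd$diagnosis == "patient")[1:4]
  SummarizedExperiment::colData(coh)$duration_of_illness[pats] <-
    c(0.05, 5, 1, 25)
  fep <- stageSubset(coh, "FEP")
  early <- stageSubset(coh, "early")
  chronic <- stageSubset(coh, "chronic")
  inside <- function(sub, i)
    cd$subject[i] %in% SummarizedExperiment::colData(sub)$subject
  expect_true(inside(fep, pats[1]))                  # 0.05 yr <= 1 month
  expect_false(any(inside(fep, pats[2]), inside(early, pats[2]),
                   inside(chronic, pats[2])))        # 5 yr in no stage
  expect_true(inside(early, pats[3]))
  expect_true(inside(chronic, pats[4]))
  ## all controls retained in every subset
  nCtl <- sum(cd$diagnosis == "control")
  for (sub in list(fep, early, chronic))
    expect_equal(sum(SummarizedExperiment::colData(sub)$diagnosis ==
                       "control"), nCtl)
  expect_error(stageSubset(coh, "prodromal"))
})

test_that("stage comparison implements the divergent/convergent taxonomy", {
  fx <- susFixture()
  base <- epicenterMap(RegionalMap(
    smoothSphericalNoise(fx$parc, n = 1, seed = 6)[, 1], fx$parc,
    "cortical", "t"), fx$fu, fx$null)
  mk <- function(sig) { e <- base; e@table$significant <- sig; e }
  n <- 16
  sigA <- rep(FALSE, n); sigB <- rep(FALSE, n); sigC <- rep(FALSE, n)
  sigA[1:3] <- TRUE; sigB[c(1, 2, 4)] <- TRUE; sigC[c(1, 4, 5)] <- TRUE
  out <- stageEpicenterComparison(list(s1 = mk(sigA), s2 = mk(sigB),
                                       s3 = mk(sigC)))
  expect_equal(out$label[1], "convergent")          # significant in all 3
  expect_equal(out$label[3], "divergent:s1")        # only stage 1
  expect_equal(out$label[5], "divergent:s3")
  expect_equal(out$label[2], "none")                # 2 of 3 -> none
  expect_equal(out$label[4], "none")
  expect_error(stageEpicenterComparison(list(s1 = mk(sigA))), "two stages")
})

test_that("subject scores recover per-patient orientation and mask constants", {
  fx <- susFixture()
  cvals <- mapValues(fx$cen)
  ## three synthetic patients: -centrality, noise, constant
  z <- cbind(p1 = -as.vector(scale(cvals)),
             p2 = rnorm(16),
             p3 = rep(0, 16))
  rownames(z) <- names(cvals)
  zm <- new("SubjectZMaps", z = z, refCoef = matrix(0, 0, 0),
            residSD = rep(1, 16), covariates = c("age", "sex"),
            parcellation = fx$parc, scope = "cortical")
  sc <- subjectNetworkScores(zm, fx$cen, fx$fu)
  expect_equal(unname(sc@hubScores["p1"]), 1, tolerance = 1e-12)
  expect_true(sc@masked["p3"] && is.na(sc@hubScores["p3"]))
  ## epicenter likelihoods are profile-vs-(-z) correlations
  W <- corticoCortical(fx$fu)
  expect_equal(unname(sc@epicenterScores[4, "p2"]),
               cor(W[4, ], -z[, "p2"]), tolerance = 1e-12)
})

test_that("clinical association Bonferroni-corrects over tests run", {
  fx <- susFixture()
  cfg <- smallConfig(symptomLoading = 60, panssNoiseSd = 1)
  net <- generateConnectome(fx$parc, seed = 30)
  truth <- plantEffectMap(net$functional, cfg)
  coh <- generateCohort(fx$parc, truth, cfg, seed = 30)
  harm <- combatFitTransform(coh)$cohort
  zm <- subjectZScoreMaps(harm)
  sc <- subjectNetworkScores(zm, fx$cen, fx$fu)
  one <- clinicalAssociation(sc, harm, variables = "panss_total",
                             includeEpicenters = FALSE)
  expect_equal(nrow(one), 1L)
  expect_equal(one$p_bonf, one$p)                   # single test: no penalty
  expect_equal(one$df, one$n - 2)
  both <- clinicalAssociation(sc, harm,
                              variables = c("panss_total", "cpz_equiv"),
                              includeEpicenters = FALSE)
  expect_equal(both$p_bonf, pmin(1, both$p * 2))
  ## fewer than 10 complete pairs: the test is skipped with a log entry
  few <- harm
  SummarizedExperiment::colData(few)$cpz_equiv[] <- NA
  SummarizedExperiment::colData(few)$cpz_equiv[1:5] <- 300
  expect_message(
    res <- clinicalAssociation(sc, few, variables = "cpz_equiv",
                               includeEpicenters = FALSE),
    "fewer than 10")
  expect_equal(nrow(res), 0L)
})

test_that("stability resampling defaults and degenerate fraction behave", {
  parc <- smallParcellation()
  net <- generateConnectome(parc, seed = 12)
  cfg <- smallConfig()
  coh <- generateCohort(parc, plantEffectMap(net$functional, cfg), cfg,
                        seed = 12)
  stat <- function(co) {
    cc <- resultTable(fitGroupDifference(co))
    c(mean_t = mean(cc$t))
  }
  ## fraction 1: every round equals the full-sample statistic
  full <- stabilityResample(stat, coh, nRounds = 5, fraction = 1, seed = 1)
  expect_equal(unname(full$sd), 0)
  expect_equal(unname(full$mean), unname(stat(coh)))
  ## strong planted effect: sign consistency is perfect
  res <- stabilityResample(stat, coh, nRounds = 20, fraction = 0.8, seed = 2)
  expect_equal(unname(res$signConsistency), 1)
  expect_equal(nrow(res$stats) + res$skipped, 20L)
  expect_error(stabilityResample(stat, coh, fraction = 0), "fraction")
})
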