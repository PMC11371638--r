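makeSiteCohort <- function(shift = 0.5, scale = FALSE, nPerSite = 200L,
                           nSites = 2L, diagEffect = 0, seed = 11L) {
  parc <- smallParcellation()
  truth <- nullTruth(parc)
  truth$delta@values[] <- diagEffect
  cfg <- smallConfig(nSites = nSites, nPatients = nPerSite * nSites %/% 2,
                     nControls = nPerSite * nSites %/% 2,
                     siteShiftSd = 0, severitySd = 0,
                     siteScaleRange = if (scale) c(0.6, 1.6) else c(1, 1))
  coh <- generateCohort(parc, truth, cfg, seed = seed)
  ## overwrite the drawn (zero-SD) site shifts with a fixed planted shift
  cd <- SummarizedExperiment::colData(coh)
  a <- SummarizedExperiment::assay(coh)
  a[, cd$site == "site_02"] <- a[, cd$site == "site_02"] + shift
  SummarizedExperiment::assay(coh) <- a
  coh
}

test_that("a single-batch table passes through unchanged", {
  parc <- smallParcellation()
  cfg <- smallConfig(nSites = 2)
  coh <- generateCohort(parc, nullTruth(parc), cfg, seed = 3)
  cd <- SummarizedExperiment::colData(coh)
  one <- coh[, cd$site == "site_01"]
  out <- combatFitTransform(one)
  expect_equal(SummarizedExperiment::assay(out$cohort),
               SummarizedExperiment::assay(one), tolerance = 1e-8)
})

test_that("a planted batch shift is removed and diagnosis preserved", {
  coh <- makeSiteCohort(shift = 0.5, nPerSite = 200L, diagEffect = 0.2)
  out <- combatFitTransform(coh)
  cd <- SummarizedExperiment::colData(coh)
  a <- SummarizedExperiment::assay(out$cohort)
  siteDiff <- rowMeans(a[, cd$site == "site_02"]) -
    rowMeans(a[, cd$site == "site_01"])
  expect_lt(max(abs(siteDiff)), 0.02)
  ## planted -0.2 mm diagnosis effect preserved within 10%
  pre <- SummarizedExperiment::assay(coh)
  effPre <- rowMeans(pre[, cd$diagnosis == "control"]) -
    rowMeans(pre[, cd$diagnosis == "patient"])
  effPost <- rowMeans(a[, cd$diagnosis == "control"]) -
    rowMeans(a[, cd$diagnosis == "patient"])
  expect_lt(max(abs(effPost - effPre) / abs(effPre)), 0.1)
})

test_that("our ComBat matches the sva reference on the same data", {
  skip_if_not_installed("sva")
  coh <- makeSiteCohort(shift = 0.4, scale = TRUE, nPerSite = 80L,
                        nSites = 3L, diagEffect = 0.2, seed = 21L)
  ours <- combatFitTransform(coh)
  cd <- as.data.frame(SummarizedExperiment::colData(coh))
  mod <- stats::model.matrix(~ diagnosis + age + sex, cd)
  ref <- suppressMessages(
    sva::ComBat(SummarizedExperiment::assay(coh), batch = cd$site,
                mod = mod))
  expect_equal(SummarizedExperiment::assay(ours$cohort), ref,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("EB estimates converge to direct estimates at large batch n", {
  coh <- makeSiteCohort(shift = 0.3, scale = TRUE, nPerSite = 2000L,
                        seed = 31L)
  out <- combatFitTransform(coh)
  m <- out$model
  ## recompute the direct (non-EB) standardized batch effects
  cd <- as.data.frame(SummarizedExperiment::colData(coh))
  dat <- SummarizedExperiment::assay(coh)
  design <- cbind(stats::model.matrix(~ -1 + factor(site), cd),
                  stats::model.matrix(~ diagnosis + age + sex,
                                      cd)[, -1, drop = FALSE])
  BHat <- solve(crossprod(design), crossprod(design, t(dat)))
  nB <- as.vector(table(cd$site))
  grand <- crossprod(nB / sum(nB), BHat[1:2, ])
  varPooled <- rowMeans((dat - t(design %*% BHat))^2)
  standMean <- matrix(grand, nrow(dat), ncol(dat)) +
    t(design[, -(1:2), drop = FALSE] %*% BHat[-(1:2), , drop = FALSE])
  sdat <- (dat - standMean) / sqrt(varPooled)
  for (i in 1:2) {
    sel <- cd$site == sort(unique(cd$site))[i]
    gDirect <- rowMeans(sdat[, sel])
    dDirect <- apply(sdat[, sel], 1, stats::var)
    expect_equal(m@gammaStar[i, ], gDirect, tolerance = 0.02,
                 ignore_attr = TRUE)
    expect_equal(m@deltaStar[i, ], dDirect, tolerance = 0.02,
                 ignore_attr = TRUE)
  }
})

test_that("site partial R2 collapses after harmonization", {
  coh <- makeSiteCohort(shift = 0.5, scale = TRUE, nPerSite = 150L,
                        nSites = 3L, seed = 41L)
  out <- combatFitTransform(coh)
  svc <- siteVarianceCheck(coh, out$cohort)
  s <- attr(svc, "summary")
  expect_gt(s[["median_pre"]], 0.1)
  expect_lt(s[["max_post"]], 0.01)
  ## identical tables give identical R2 vectors
  same <- siteVarianceCheck(coh, coh)
  expect_identical(same$r2_pre, same$r2_post)
  ## mismatched subjects are rejected
  expect_error(siteVarianceCheck(coh, out$cohort[, -1]), "same subjects")
})

test_that("degenerate designs are rejected with informative errors", {
  parc <- smallParcellation()
  coh <- generateCohort(parc, nullTruth(parc), smallConfig(), seed = 51)
  ## a constant region has zero residual variance
  a <- SummarizedExperiment::assay(coh)
  a[1, ] <- 2
  flat <- coh
  SummarizedExperiment::assay(flat) <- a
  expect_error(combatFitTransform(flat), "zero pooled residual variance")
  ## site confounded with diagnosis makes the design singular
  cd <- SummarizedExperiment::colData(coh)
  conf <- coh
  SummarizedExperiment::colData(conf)$site <-
    ifelse(cd$diagnosis == "patient", "site_01", "site_02")
  expect_error(combatFitTransform(conf), "singular")
})
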