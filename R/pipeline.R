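## End-to-end orchestration: simulate -> harmonize -> case-control ->
## network -> nulls -> susceptibility (-> cross-disorder), with per-stage
## seeds derived from one master seed and a manifest of output hashes.

## Stage-name-keyed sub-seeds: adding a stage never perturbs the randomness
## of earlier stages.
.stageSeed <- function(seed, stage) {
  offsets <- c(simulate = 11L, connectome = 23L, cohort = 37L, nulls = 53L,
               harmonize = 67L, casecontrol = 79L, network = 97L,
               hubvuln = 113L, epicenter = 131L, subject = 149L,
               stages = 167L, clinical = 181L, crossdisorder = 197L)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% 2^31)
}

#' Run the full network-susceptibility pipeline
#'
#' Executes the stages in order on a synthetic cohort (or user-supplied
#' input files): simulation, ComBat harmonization with site-variance check,
#' mass-univariate case-control maps, network centrality, spin nulls, hub
#' vulnerability, epicenter mapping (cortical and subcortical seeds, both
#' modalities), disease-stage comparison, subject-level scores with clinical
#' association, and (when extra disorder maps are supplied) the
#' cross-disorder comparison. All outputs are plain-text CSV/TSV/JSON in
#' \code{outDir}; the returned manifest records per-stage status, counts and
#' MD5 hashes. Runs are deterministic for a fixed config: each stochastic
#' stage derives its own sub-seed from the master seed, keyed by stage name.
#'
#' @param outDir output directory (created if absent)
#' @param config a [GenerativeConfig()] for synthetic mode
#' @param inputs optional named list of file paths (\code{cohort},
#'   \code{functional}, \code{structural}) replacing simulation; stages
#'   whose inputs are absent are skipped and noted in the manifest
#' @param nPerm spin/shuffle permutations (default 10000)
#' @param alpha significance level (default 0.05)
#' @param seed master seed
#' @param measure morphometric measure to simulate/analyze
#' @param crossDisorderMaps optional named list of cortical alteration
#'   \linkS4class{RegionalMap}s (or CSV paths) of other disorders
#' @param stageAnalysis run the per-stage hub-vulnerability/epicenter
#'   comparison (default TRUE)
#' @return the manifest, invisibly (list with \code{stages},
#'   \code{outputs}, \code{hashes})
#' @export
runPipeline <- function(outDir, config = GenerativeConfig(), inputs = NULL,
                        nPerm = 10000L, alpha = 0.05, seed = 1L,
                        measure = c("CT", "SA", "SV"),
                        crossDisorderMaps = NULL, stageAnalysis = TRUE) {
  measure <- match.arg(measure)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, nPerm = nPerm, alpha = alpha,
                   measure = measure, stages = list())
  note <- function(stage, status, ...) {
    manifest$stages[[stage]] <<- c(list(status = status), list(...))
  }
  outFile <- function(name) file.path(outDir, name)

  ## -- simulate or load ------------------------------------------------
  if (is.null(inputs)) {
    parc <- generateParcellation(config$nCorticalPerHemi, config$nSubcortical)
    net <- generateConnectome(parc, config$hubFraction, config$distanceDecay,
                              seed = .stageSeed(seed, "connectome"),
                              hubGain = config$hubGain,
                              edgeNoiseSd = config$edgeNoiseSd)
    truth <- plantEffectMap(net$functional, config)
    cohort <- generateCohort(parc, truth, config, measure,
                             seed = .stageSeed(seed, "cohort"))
    writeConnectivity(net$functional, outFile("connectivity_functional.tsv"))
    writeConnectivity(net$structural, outFile("connectivity_structural.tsv"))
    writeCohort(cohort, outFile("cohort.csv"))
    jsonlite::write_json(
      list(epicenters = truth$epicenters, bEpi = truth$bEpi,
           bHub = truth$bHub, hubs = net$hubs),
      outFile("ground_truth.json"), auto_unbox = TRUE, digits = NA)
    note("simulate", "ok", subjects = ncol(cohort),
         regions = length(regionNames(parc)))
  } else {
    parc <- generateParcellation(config$nCorticalPerHemi, config$nSubcortical)
    cohort <- readCohort(inputs$cohort, parc, measure)
    net <- NULL
    if (!is.null(inputs$functional))
      net <- list(functional = readConnectivity(inputs$functional, parc,
                                                "functional"),
                  structural = if (!is.null(inputs$structural))
                    readConnectivity(inputs$structural, parc, "structural"))
    note("simulate", "loaded", subjects = ncol(cohort))
  }
  validateCohort(cohort, verbose = FALSE)

  ## -- harmonize -------------------------------------------------------
  harm <- combatFitTransform(cohort)
  svc <- siteVarianceCheck(cohort, harm$cohort)
  write.csv(svc, outFile("site_variance.csv"), row.names = FALSE)
  note("harmonize", "ok", sites = length(harm$model@batches),
       max_post_r2 = unname(attr(svc, "summary")["max_post"]))

  ## -- case-control ----------------------------------------------------
  cc <- fitGroupDifference(harm$cohort)
  write.csv(resultTable(cc), outFile(sprintf("casecontrol_%s.csv", measure)),
            row.names = FALSE)
  note("casecontrol", "ok", n_fdr_sig = sum(resultTable(cc)$q < alpha))

  if (is.null(inputs) || !is.null(net)) {
    ## -- network centrality ---------------------------------------------
    cents <- list()
    for (mod in c("functional", "structural")) {
      conn <- preprocessConnectivity(net[[mod]])
      net[[mod]] <- conn
      cents[[mod]] <- degreeCentrality(conn, "cortico-cortical")
      writeRegionalMap(cents[[mod]]@map,
                       outFile(sprintf("degree_%s.csv", mod)))
    }
    note("network", "ok", metrics = "degree")

    ## -- nulls -----------------------------------------------------------
    null <- buildSpinRotations(parc, nPerm, seed = .stageSeed(seed, "nulls"))
    writeSpinNull(null, outFile("spin_null.tsv"))
    note("nulls", "ok", n_perm = nPerm)

    ## -- hub vulnerability & epicenters ----------------------------------
    altT <- alterationMap(cc, "t")
    hv <- lapply(cents, function(cen) hubVulnerability(altT, cen, null))
    hvTab <- do.call(rbind, lapply(names(hv), function(mod)
      data.frame(modality = mod, metric = "degree", r = hv[[mod]]@r,
                 p_spin = hv[[mod]]@p)))
    write.csv(hvTab, outFile("hub_vulnerability.csv"), row.names = FALSE)
    note("hubvuln", "ok", r_functional = hv$functional@r)
    epis <- list()
    for (mod in c("functional", "structural")) {
      for (sc in c("cortical", "subcortical")) {
        epi <- epicenterMap(altT, net[[mod]], null, alpha, seedScope = sc)
        epis[[paste(mod, sc, sep = "_")]] <- epi
        write.csv(resultTable(epi),
                  outFile(sprintf("epicenters_%s_%s.csv", mod, sc)),
                  row.names = FALSE)
      }
    }
    note("epicenter", "ok",
         n_sig = sum(resultTable(epis$functional_cortical)$significant))

    ## -- disease stages --------------------------------------------------
    if (stageAnalysis && measure != "SV") {
      stageRes <- list()
      for (st in c("FEP", "early", "chronic")) {
        sub <- stageSubset(harm$cohort, st)
        if (sum(SummarizedExperiment::colData(sub)$diagnosis == "patient") < 10) {
          note("stages", "skipped", reason = paste("too few patients in", st))
          stageRes <- NULL
          break
        }
        stAlt <- alterationMap(fitGroupDifference(sub), "t")
        stageRes[[st]] <- epicenterMap(stAlt, net$functional, null, alpha,
                                       seedScope = "cortical")
      }
      if (!is.null(stageRes)) {
        cmp <- stageEpicenterComparison(stageRes)
        write.csv(cmp, outFile("stage_epicenters.csv"), row.names = FALSE)
        note("stages", "ok",
             n_convergent = sum(cmp$label == "convergent"))
      }
    }

    ## -- subject level ---------------------------------------------------
    if (measure != "SV") {
      zm <- subjectZScoreMaps(harm$cohort)
      scores <- subjectNetworkScores(zm, cents$functional, net$functional)
      write.csv(data.frame(subject = scores@subjects,
                           hub_score = scores@hubScores),
                outFile("subject_hub_scores.csv"), row.names = FALSE)
      clin <- clinicalAssociation(scores, harm$cohort,
                                  variables = intersect(
                                    c("panss_total", "panss_gen",
                                      "duration_of_illness", "cpz_equiv"),
                                    colnames(SummarizedExperiment::colData(
                                      harm$cohort))),
                                  includeEpicenters = FALSE)
      write.csv(clin, outFile("clinical_association.csv"), row.names = FALSE)
      note("subject", "ok", n_scored = sum(!scores@masked))
    }

    ## -- cross-disorder --------------------------------------------------
    if (!is.null(crossDisorderMaps)) {
      maps <- lapply(crossDisorderMaps, function(m)
        if (is.character(m)) readRegionalMap(m, parc, "cortical", "cohens_d")
        else m)
      maps <- c(list(index = RegionalMap(altT@values, parc, "cortical", "t")),
                maps)
      names(maps)[1] <- "primary"
      episXD <- lapply(maps, function(m)
        epicenterMap(m, net$functional, null, alpha, seedScope = "cortical"))
      cls <- classifyEpicenters(episXD, maps)
      write.csv(cls$table, outFile("cross_disorder.csv"), row.names = FALSE)
      note("crossdisorder", "ok",
           n_unique = sum(grepl("^unique", cls$table$classification)))
    } else {
      note("crossdisorder", "skipped", reason = "no extra disorder maps")
    }
  } else {
    note("network", "skipped", reason = "no connectivity input")
  }

  ## -- manifest --------------------------------------------------------
  files <- sort(list.files(outDir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  hashes <- as.vector(tools::md5sum(file.path(outDir, files)))
  manifest$outputs <- files
  manifest$hashes <- setNames(hashes, files)
  manifest$config <- unclass(config)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
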