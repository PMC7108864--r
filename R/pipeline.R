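# End-to-end orchestration: generate or load a dataset, fit per-epoch
# maximum-entropy models for Q ensembles, compute FIMs and sensitivities,
# and run the state, evoked, network and classification analyses. The
# stage runner persists artifacts under a run directory; runPipeline()
# does the same work in memory.

#' Analysis run configuration
#'
#' Defaults are the study's stated constants: ensembles of N = 10 single
#' units, 10-ms binarization, 100-s epochs, 1.5-s pre-stimulus windows,
#' 20-ms silence-density bins, 0.5-s modulation-index windows, gradient
#' descent with learning rate 0.1, moment tolerance 0.005 and at most 100
#' iterations, 100000 Metropolis samples per moment evaluation and 500000
#' FIM steps when \code{monteCarloMoments} asks for Monte Carlo moments, 5000
#' surrogate patterns, and 1000 permutations.
#'
#' @param ... overrides for any field, including \code{Q} (number of
#'   ensembles, default 20) and \code{generator}
#'   (a \code{\link{generatorConfig}}).
#' @return named list.
#' @export
runConfig <- function(...) {
  cfg <- list(
    N = 10, Q = 20, dt = 0.01, epochLength = 100, preWindow = 1.5,
    silenceBin = 0.02, miWindow = 0.5,
    alpha = 0.1, tol = 0.005, maxIter = 100, nMc = 100000,
    fimSteps = 500000, surrogatePatterns = 5000, nPerm = 1000,
    monteCarloMoments = FALSE,
    generator = generatorConfig())
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

.fitAllEnsembles <- function(dataset, ew, ens, cfg) {
  suIds <- sort(singleUnitIds(dataset))
  ok <- !ew$epochs$flagged
  epochIdx <- ew$epochs$epoch[ok]
  rasters <- lapply(epochIdx, function(t)
    binarize(dataset, ew$windows[[t]], dt = cfg$dt, units = suIds))
  names(rasters) <- epochIdx
  mm <- if (cfg$monteCarloMoments) "metropolis" else "exact"
  perEnsemble <- lapply(seq_along(ens$ensembles), function(q) {
    u <- sort(ens$ensembles[[q]])
    fitsP <- list(); fitsI <- list(); fims <- list()
    dataDists <- list(); modelDists <- list(); indepDists <- list()
    for (k in seq_along(epochIdx)) {
      t <- epochIdx[k]
      pats <- extractPatterns(rasters[[k]], u, epoch = t)
      fitsP[[k]] <- fitPairwise(pats, alpha = cfg$alpha, tol = cfg$tol,
                                maxIter = cfg$maxIter, momentMethod = mm,
                                nMc = cfg$nMc)
      fitsI[[k]] <- fitIndependent(pats, alpha = cfg$alpha, tol = cfg$tol,
                                   maxIter = cfg$maxIter, momentMethod = mm,
                                   nMc = cfg$nMc)
      fims[[k]] <- computeFim(fittedModel(fitsP[[k]]),
                              method = if (cfg$monteCarloMoments) "metropolis"
                                       else "exact",
                              nSteps = cfg$fimSteps)
      dataDists[[k]] <- empiricalDistribution(pats)
      modelDists[[k]] <- boltzmannDistribution(fittedModel(fitsP[[k]]))
      indepDists[[k]] <- boltzmannDistribution(fittedModel(fitsI[[k]]))
    }
    omegas <- t(vapply(fitsP, function(f) paramVector(fittedModel(f)),
                       numeric(cfg$N + cfg$N * (cfg$N - 1) / 2)))
    list(units = u, fitsPairwise = fitsP, fitsIndependent = fitsI,
         fims = fims, omegas = omegas, dataDists = dataDists,
         modelDists = modelDists, indepDists = indepDists)
  })
  list(perEnsemble = perEnsemble, epochs = epochIdx, rasters = rasters,
       singleUnits = suIds)
}

.goodnessOfFit <- function(fitRes) {
  rows <- list()
  for (q in seq_along(fitRes$perEnsemble)) {
    pe <- fitRes$perEnsemble[[q]]
    for (k in seq_along(fitRes$epochs)) {
      djsP <- jsDivergence(pe$dataDists[[k]], pe$modelDists[[k]])
      djsI <- jsDivergence(pe$dataDists[[k]], pe$indepDists[[k]])
      kr <- klRatio(pe$dataDists[[k]], pe$indepDists[[k]], pe$modelDists[[k]])
      rows[[length(rows) + 1]] <- data.frame(
        ensemble = q, epoch = fitRes$epochs[k],
        djs_pairwise = djsP, djs_independent = djsI,
        kl_ratio = kr$R,
        converged = isConverged(pe$fitsPairwise[[k]]))
    }
  }
  do.call(rbind, rows)
}

.pairedClassMeans <- function(fitRes, rcsTable) {
  # within-ensemble stiff/sloppy mean rcs, for the paired comparison
  rows <- lapply(fitRes$perEnsemble, function(pe) {
    sne <- sensitivityFirstEig(pe$fims)
    lab <- medianSplit(sne)
    keys <- paramKeys(pe$units)
    rcs <- rcsTable$rcs[match(keys, rcsTable$element)]
    data.frame(stiff = mean(rcs[lab == "stiff"], na.rm = TRUE),
               sloppy = mean(rcs[lab == "sloppy"], na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Run the full sloppiness analysis
#'
#' Generates (or accepts) a spike dataset and runs every analysis stage:
#' per-epoch pairwise and independent maximum-entropy fits for Q random
#' ensembles, goodness-of-fit divergences and KL ratios, FIM
#' eigen-analysis with projection-variance-by-rank and stationary
#' surrogates, silence-density state tracking with divergence and
#' observable correlations, evoked modulation-index relations, the
#' functional graph with betweenness and population coupling, and
#' stiff/sloppy ROC separation.
#'
#' @param config a \code{\link{runConfig}}.
#' @param seed master seed; every random choice derives from it.
#' @param dataset optional \linkS4class{SpikeDataset}; when NULL one is
#'   generated from \code{config$generator}.
#' @param truth optional ground truth matching \code{dataset}.
#' @param surrogates compute the stationary-surrogate control (default
#'   TRUE).
#' @return a named list of all stage results (see the vignette for a
#'   walk-through).
#' @export
runPipeline <- function(config = runConfig(), seed = 1, dataset = NULL,
                        truth = NULL, surrogates = TRUE) {
  cfg <- config
  if (is.null(dataset)) {
    gen <- generateDataset(cfg$generator, seed = seed)
    dataset <- gen$dataset
    truth <- gen$truth
  }
  ew <- segmentEpochs(dataset, cfg$epochLength, cfg$preWindow)
  cs <- silenceDensity(dataset, ew, bin = cfg$silenceBin)
  ens <- sampleEnsembles(sort(singleUnitIds(dataset)), N = cfg$N,
                         Q = cfg$Q, seed = seed + 1000L)
  fitRes <- withSeed(seed + 2000L, .fitAllEnsembles(dataset, ew, ens, cfg))
  gof <- .goodnessOfFit(fitRes)

  # sensitivities and classes
  L <- cfg$N + cfg$N * (cfg$N - 1) / 2
  sneMat <- t(vapply(fitRes$perEnsemble,
                     function(pe) sensitivityFirstEig(pe$fims), numeric(L)))
  sneWMat <- t(vapply(fitRes$perEnsemble,
                      function(pe) sensitivityWeighted(pe$fims), numeric(L)))
  sens <- aggregatePopulationSensitivity(sneMat, ens$ensembles,
                                         fitRes$singleUnits)
  sensW <- aggregatePopulationSensitivity(sneWMat, ens$ensembles,
                                          fitRes$singleUnits)
  sens$s_w <- sensW$s
  sens$label <- NA_character_
  for (kind in c("unit", "pair")) {
    sel <- sens$kind == kind
    sens$label[sel] <- medianSplit(sens$s[sel])
  }

  # projection variance by rank, averaged over ensembles
  profiles <- vapply(fitRes$perEnsemble, function(pe)
    projectionVarianceByRank(pe$fims, pe$omegas), numeric(L))
  profile <- rowMeans(profiles)

  # state analyses
  csVals <- cs$CS[match(fitRes$epochs, cs$epoch)]
  djsMat <- pairwisePatternDivergence(
    lapply(fitRes$perEnsemble, `[[`, "dataDists"))
  stateDiv <- stateDivergenceCorrelation(djsMat, csVals, nPerm = cfg$nPerm,
                                         seed = seed + 3000L)
  obs <- observableTimeseries(dataset, ew, units = fitRes$singleUnits,
                              dt = cfg$dt)
  obsAligned <- list(rates = obs$rates[fitRes$epochs, , drop = FALSE],
                     correlations = obs$correlations[fitRes$epochs, , drop = FALSE],
                     units = obs$units)
  rcsTable <- stateObservableCorrelation(obsAligned, csVals)
  paired <- .pairedClassMeans(fitRes, rcsTable)
  stateSens <- sensitivityStateRelation(rcsTable, sens, pairedMeans = paired)

  # evoked analyses
  counts <- trialCounts(dataset, ew, units = fitRes$singleUnits,
                        pre = cfg$miWindow, post = cfg$miWindow)
  evoked <- evokedSummary(counts)
  miSens <- miSensitivityRelation(evoked$session, sens)
  miEig <- miEigvecCorrelation(evoked$byEpoch,
                               lapply(fitRes$perEnsemble, `[[`, "fims"),
                               ens$ensembles)
  unitLabels <- sens[sens$kind == "unit", c("i", "label")]
  names(unitLabels) <- c("unit_id", "label")
  dmi <- deltaMiByState(evoked$byEpoch, unitLabels, cs)

  # network analyses
  graph <- buildGraph(obsAligned$correlations, obs$units)
  bc <- betweenness(graph)
  coupling <- populationCoupling(fitRes$rasters)
  meanRates <- colMeans(obsAligned$rates, na.rm = TRUE)
  ul <- unitLabels$label[match(obs$units, unitLabels$unit_id)]
  classComp <- topologyClassComparison(
    list(rate = unname(meanRates), BC = unname(bc),
         coupling = unname(coupling)),
    ul, nPerm = cfg$nPerm, seed = seed + 4000L)
  pairSel <- sens$kind == "pair" & !is.na(sens$label)
  meanCors <- colMeans(obsAligned$correlations, na.rm = TRUE)
  corKeys <- colnames(obs$correlations)
  pairAuc <- {
    v <- meanCors[match(sens$element[pairSel], corKeys)]
    okp <- !is.na(v)
    if (sum(okp) >= 4 &&
        length(unique(sens$label[pairSel][okp])) == 2) {
      roc <- rocAuc(v[okp], sens$label[pairSel][okp])
      data.frame(quantity = "pair_correlation", AUC = roc$auc,
                 p = permutationTest(v[okp], sens$label[pairSel][okp],
                                     nPerm = cfg$nPerm, seed = seed + 5000L),
                 n_sloppy = roc$n_sloppy, n_stiff = roc$n_stiff)
    } else NULL
  }

  # stationary surrogate control: one reference (ensemble, epoch)
  surro <- NULL
  if (surrogates) {
    refEpoch <- withSeed(seed + 6000L,
                         sample(seq_along(fitRes$epochs), 1))
    refModel <- fittedModel(
      fitRes$perEnsemble[[1]]$fitsPairwise[[refEpoch]])
    ss <- makeStationarySurrogates(refModel, nE = length(fitRes$epochs),
                                   nPatterns = cfg$surrogatePatterns,
                                   seed = seed + 7000L,
                                   alpha = cfg$alpha, tol = cfg$tol,
                                   maxIter = cfg$maxIter)
    surroProfile <- projectionVarianceByRank(ss$fims, ss$omegas)
    surro <- list(refEpoch = refEpoch, surrogates = ss,
                  profile = surroProfile,
                  flatness = surroProfile[L] / surroProfile[1])
  }

  list(config = cfg, seed = seed, dataset = dataset, truth = truth,
       epochWindows = ew, cs = cs, ensembles = ens, fits = fitRes,
       gof = gof, sensitivity = sens, sneMatrix = sneMat,
       projectionProfile = profile,
       nonstationaryFlatness = profile[L] / profile[1],
       djsMatrix = djsMat, stateDivergence = stateDiv,
       observables = obs, rcs = rcsTable, stateSensitivity = stateSens,
       evoked = evoked, miSensitivity = miSens, miEigvec = miEig,
       deltaMi = dmi, graph = graph, bc = bc, coupling = coupling,
       meanRates = meanRates, classComparison = classComp,
       pairAuc = pairAuc, surrogate = surro)
}

#' Write pipeline artifacts to a run directory
#'
#' Emits the CSV/JSON artifact set: per-epoch state (\code{state.csv}),
#' element sensitivities and state correlations (\code{rcs.csv}),
#' goodness-of-fit (\code{gof.csv}), evoked summaries (\code{evoked.csv},
#' \code{delta_mi.csv}), graph edges (\code{edges.csv}) and node table
#' (\code{bc.csv}), class separation (\code{auc.csv}), projection
#' profiles (\code{projection.csv}), fitted models
#' (\code{models/model_q<q>_t<t>.json}) and a manifest.
#'
#' @param res result of \code{\link{runPipeline}}.
#' @param outDir output directory (created if needed).
#' @return \code{outDir}, invisibly.
#' @export
writeArtifacts <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) write.csv(df, file.path(outDir, f), row.names = FALSE)
  w(res$cs, "state.csv")
  rcs <- merge(res$sensitivity, res$rcs, by = c("element", "kind"),
               all.x = TRUE)
  w(rcs, "rcs.csv")
  w(res$gof, "gof.csv")
  ev <- res$evoked$session
  w(ev, "evoked.csv")
  if (!is.null(res$deltaMi)) w(res$deltaMi, "delta_mi.csv")
  w(res$graph$edges, "edges.csv")
  units <- res$observables$units
  ul <- res$sensitivity[res$sensitivity$kind == "unit", ]
  w(data.frame(unit = units, BC = unname(res$bc[as.character(units)]),
               coupling = unname(res$coupling[as.character(units)]),
               rate = unname(res$meanRates),
               s = ul$s[match(units, ul$i)],
               label = ul$label[match(units, ul$i)]), "bc.csv")
  aucTab <- res$classComparison$auc
  if (!is.null(res$pairAuc)) aucTab <- rbind(aucTab, res$pairAuc)
  w(aucTab, "auc.csv")
  w(data.frame(rank = seq_along(res$projectionProfile),
               variance = res$projectionProfile,
               surrogate_variance = if (!is.null(res$surrogate))
                 res$surrogate$profile else NA_real_), "projection.csv")
  mdir <- file.path(outDir, "models")
  dir.create(mdir, showWarnings = FALSE)
  for (q in seq_along(res$fits$perEnsemble)) {
    pe <- res$fits$perEnsemble[[q]]
    for (k in seq_along(res$fits$epochs))
      writeModelJson(pe$fitsPairwise[[k]],
                     file.path(mdir, sprintf("model_q%02d_t%03d.json",
                                             q, res$fits$epochs[k])))
  }
  manifest <- list(seed = res$seed,
                   config = res$config[setdiff(names(res$config), "generator")],
                   generator = res$config$generator,
                   n_epochs = length(res$fits$epochs),
                   n_ensembles = length(res$fits$perEnsemble),
                   package_version = as.character(utils::packageVersion("sloppySpikes")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Run one pipeline stage against a run directory
#'
#' Thin stage runner over \code{\link{runPipeline}}: \code{"simulate"}
#' writes the spike tables and ground truth; \code{"analyse"} runs every
#' analysis stage on the simulated (or supplied) data and writes the
#' artifact set; \code{"report"} re-reads the artifacts and writes a
#' summary JSON. Stages check for their upstream artifacts and name the
#' producing stage when one is missing. Identical config and seed produce
#' identical artifacts.
#'
#' @param stage \code{"simulate"}, \code{"analyse"} or \code{"report"}.
#' @param config a \code{\link{runConfig}}.
#' @param outDir run directory.
#' @param seed master seed.
#' @return \code{outDir}, invisibly.
#' @export
runStage <- function(stage = c("simulate", "analyse", "report"),
                     config = runConfig(), outDir, seed = 1) {
  stage <- match.arg(stage)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  spikesPath <- file.path(outDir, "spikes.csv")
  if (stage == "simulate") {
    gen <- generateDataset(config$generator, seed = seed)
    writeSpikeTable(gen$dataset, spikesPath)
    writeTruthJson(gen$truth, file.path(outDir, "truth.json"))
  } else if (stage == "analyse") {
    if (!file.exists(spikesPath))
      stop("missing artifact ", spikesPath, ": run stage 'simulate' first")
    dataset <- readSpikeTable(spikesPath)
    res <- runPipeline(config, seed = seed, dataset = dataset)
    writeArtifacts(res, outDir)
  } else {
    aucPath <- file.path(outDir, "auc.csv")
    if (!file.exists(aucPath))
      stop("missing artifact ", aucPath, ": run stage 'analyse' first")
    auc <- read.csv(aucPath)
    gof <- read.csv(file.path(outDir, "gof.csv"))
    jsonlite::write_json(
      list(mean_kl_ratio = mean(gof$kl_ratio, na.rm = TRUE),
           fraction_pairwise_better =
             mean(gof$djs_pairwise < gof$djs_independent, na.rm = TRUE),
           auc = auc),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(outDir)
}
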