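# Synthetic spike-data generator. Emulates the statistical structure the
# analysis assumes: a correlated high-rate core, a variable low-rate
# periphery whose biases drift across epochs, a slow global excitability
# process producing synchronized/desynchronized state fluctuations, and
# click-evoked responses concentrated in the periphery. Spikes are drawn
# per 10-ms bin as Bernoulli with a logistic rate model; ground truth
# (core membership, state trajectory, evoked gains, drift) is returned
# alongside the dataset.

#' Default generator configuration
#'
#' Defaults emulate the target recordings: 60 single units (30\% core)
#' plus 20 multi-units, a 3000-s session (30 epochs of 100 s), clicks
#' every 2.5 s, baseline rates of 5-15 Hz (core) and 0.5-4 Hz
#' (periphery), two shared latent factors loading on the core, a slow
#' AR(1) excitability process (coefficient 0.999 per 20-ms step, innovation
#' SD chosen so silence-density excursions span roughly 0.1-0.7),
#' per-epoch random-walk jitter of periphery biases (SD 0.1), and evoked
#' log-gains that are large in the periphery (mixed excited/suppressed)
#' and small in the core.
#'
#' @param ... overrides for any default field.
#' @return named list of generator parameters.
#' @export
generatorConfig <- function(...) {
  cfg <- list(
    nSingle = 60, nMulti = 20, coreFraction = 0.3,
    duration = 3000, isi = 2.5, dt = 0.01,
    coreRateRange = c(5, 15), peripheryRateRange = c(0.5, 4),
    nFactors = 2, factorLoadingCore = c(0.4, 0.8),
    factorLoadingPeriphery = c(0, 0.1),
    stateArCoef = 0.999, stateInnovationSd = 0.11, stateStep = 0.02,
    stateLoadingCore = c(1.2, 1.8), stateLoadingPeriphery = c(0.6, 1.2),
    stateOffset = -1.2,
    epochLength = 100, peripheryDriftSd = 0.1,
    evokedDuration = 0.5,
    evokedLogGainPeriphery = c(1.5, 0.3), evokedLogGainCore = c(0.2, 0.05),
    excitedFraction = 0.5)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Generate a synthetic spike dataset with ground truth
#'
#' Each unit spikes per 10-ms bin with probability
#' \code{plogis(b_i + w_i (g(t) + g0) + sum_f lambda_if z_f(t) + G_i s(t))}
#' where \code{b_i} sets the baseline rate, \code{g(t)} is the slow AR(1)
#' excitability (held for two consecutive bins), \code{z_f} are shared
#' per-bin factors creating core correlations, and \code{G_i} applies for
#' 0.5 s after each click. Multi-units are merged pairs of hidden
#' periphery-like units and enter only the silence-density calculation.
#' Deterministic under \code{seed}.
#'
#' @param config from \code{\link{generatorConfig}}.
#' @param seed integer seed.
#' @return list with \code{dataset} (a \linkS4class{SpikeDataset}) and
#'   \code{truth} (core ids, state trajectory, biases, loadings, evoked
#'   log-gains, periphery drift matrix).
#' @export
generateDataset <- function(config = generatorConfig(), seed = 1) {
  withSeed(seed, {
    cfg <- config
    nCore <- round(cfg$coreFraction * cfg$nSingle)
    coreIds <- seq_len(nCore)
    periphIds <- setdiff(seq_len(cfg$nSingle), coreIds)
    isCore <- seq_len(cfg$nSingle) %in% coreIds

    rates <- numeric(cfg$nSingle)
    rates[isCore] <- runif(nCore, cfg$coreRateRange[1], cfg$coreRateRange[2])
    rates[!isCore] <- runif(cfg$nSingle - nCore, cfg$peripheryRateRange[1],
                            cfg$peripheryRateRange[2])
    # hidden units behind multi-units: periphery-like, merged in pairs
    nHidden <- 2 * cfg$nMulti
    hiddenRates <- runif(nHidden, cfg$peripheryRateRange[1],
                         cfg$peripheryRateRange[2])

    b <- stats::qlogis(pmin(rates * cfg$dt, 0.5))
    bHidden <- stats::qlogis(pmin(hiddenRates * cfg$dt, 0.5))
    w <- ifelse(isCore,
                runif(cfg$nSingle, cfg$stateLoadingCore[1], cfg$stateLoadingCore[2]),
                runif(cfg$nSingle, cfg$stateLoadingPeriphery[1],
                      cfg$stateLoadingPeriphery[2]))
    wHidden <- runif(nHidden, cfg$stateLoadingPeriphery[1],
                     cfg$stateLoadingPeriphery[2])
    lam <- matrix(0, cfg$nSingle, cfg$nFactors)
    lam[isCore, ] <- runif(nCore * cfg$nFactors, cfg$factorLoadingCore[1],
                           cfg$factorLoadingCore[2])
    lam[!isCore, ] <- runif((cfg$nSingle - nCore) * cfg$nFactors,
                            cfg$factorLoadingPeriphery[1],
                            cfg$factorLoadingPeriphery[2])

    # slow excitability: AR(1) per stateStep, stationary start
    nBins <- round(cfg$duration / cfg$dt)
    binsPerStep <- round(cfg$stateStep / cfg$dt)
    nSteps <- ceiling(nBins / binsPerStep)
    sdStat <- cfg$stateInnovationSd / sqrt(1 - cfg$stateArCoef^2)
    g <- numeric(nSteps)
    g[1] <- rnorm(1, 0, sdStat)
    innov <- rnorm(nSteps - 1, 0, cfg$stateInnovationSd)
    for (k in 2:nSteps) g[k] <- cfg$stateArCoef * g[k - 1] + innov[k - 1]
    gBin <- rep(g, each = binsPerStep)[seq_len(nBins)] + cfg$stateOffset

    z <- matrix(rnorm(nBins * cfg$nFactors), nBins, cfg$nFactors)

    # per-epoch random-walk drift of periphery biases
    nE <- floor(cfg$duration / cfg$epochLength)
    drift <- matrix(0, nE, cfg$nSingle)
    for (e in seq_len(nE)[-1])
      drift[e, periphIds] <- drift[e - 1, periphIds] +
        rnorm(length(periphIds), 0, cfg$peripheryDriftSd)
    binsPerEpoch <- round(cfg$epochLength / cfg$dt)
    epochOfBin <- pmin(((seq_len(nBins) - 1) %/% binsPerEpoch) + 1L, nE)

    # click train and evoked gains
    events <- seq(cfg$isi, cfg$duration - cfg$evokedDuration, by = cfg$isi)
    gain <- numeric(cfg$nSingle)
    signs <- ifelse(runif(cfg$nSingle) < cfg$excitedFraction, 1, -1)
    gain[isCore] <- signs[isCore] *
      abs(rnorm(nCore, cfg$evokedLogGainCore[1], cfg$evokedLogGainCore[2]))
    gain[!isCore] <- signs[!isCore] *
      abs(rnorm(cfg$nSingle - nCore, cfg$evokedLogGainPeriphery[1],
                cfg$evokedLogGainPeriphery[2]))
    stimOn <- numeric(nBins)
    binTime <- (seq_len(nBins) - 1) * cfg$dt
    for (o in events) {
      k0 <- floor(o / cfg$dt) + 1
      k1 <- min(nBins, floor((o + cfg$evokedDuration) / cfg$dt))
      stimOn[k0:k1] <- 1
    }

    drawUnit <- function(bi, wi, lami, gi, driftCol) {
      eta <- bi + wi * gBin + drop(z %*% lami) + gi * stimOn
      if (!is.null(driftCol)) eta <- eta + driftCol[epochOfBin]
      p <- stats::plogis(eta)
      fire <- runif(nBins) < p
      which(fire)
    }

    spikeRows <- vector("list", cfg$nSingle + cfg$nMulti)
    for (i in seq_len(cfg$nSingle)) {
      bins <- drawUnit(b[i], w[i], lam[i, ], gain[i], drift[, i])
      if (length(bins))
        spikeRows[[i]] <- data.frame(
          unit_id = i, time_s = binTime[bins] + runif(length(bins)) * cfg$dt)
    }
    for (m in seq_len(cfg$nMulti)) {
      hi <- c(2 * m - 1, 2 * m)
      bins <- unique(c(
        drawUnit(bHidden[hi[1]], wHidden[hi[1]], rep(0, cfg$nFactors), 0, NULL),
        drawUnit(bHidden[hi[2]], wHidden[hi[2]], rep(0, cfg$nFactors), 0, NULL)))
      if (length(bins))
        spikeRows[[cfg$nSingle + m]] <- data.frame(
          unit_id = cfg$nSingle + m,
          time_s = binTime[bins] + runif(length(bins)) * cfg$dt)
    }
    spikes <- do.call(rbind, spikeRows)
    units <- data.frame(
      unit_id = seq_len(cfg$nSingle + cfg$nMulti),
      class = c(rep("single", cfg$nSingle), rep("multi", cfg$nMulti)))
    dataset <- SpikeDataset(units = units, spikes = spikes,
                            events = events, duration = cfg$duration)
    truth <- list(coreIds = coreIds, peripheryIds = periphIds,
                  baselineRates = rates, biases = b, stateLoadings = w,
                  factorLoadings = lam, stateTrajectory = g,
                  stateOffset = cfg$stateOffset, evokedLogGain = gain,
                  peripheryDrift = drift, config = cfg, seed = seed)
    list(dataset = dataset, truth = truth)
  })
}

#' Check that a generated dataset matches its emulation targets
#'
#' Verifies, on the generated data themselves, that (1) the silence
#' density range overlaps [0.1, 0.7], (2) the core's mean firing rate
#' exceeds the periphery's, and (3) the mean absolute evoked log-gain is
#' larger in the periphery than in the core.
#'
#' @param dataset a generated \linkS4class{SpikeDataset}.
#' @param truth the matching ground-truth list.
#' @return data.frame with columns \code{check}, \code{value},
#'   \code{pass} (logical; NA where a check does not apply).
#' @export
emulationReport <- function(dataset, truth) {
  cfg <- truth$config
  ew <- segmentEpochs(dataset, cfg$epochLength)
  cs <- silenceDensity(dataset, ew)$CS
  csOverlap <- !is.na(max(cs, na.rm = TRUE)) &&
    max(cs, na.rm = TRUE) >= 0.1 && min(cs, na.rm = TRUE) <= 0.7
  s <- spikeTable(dataset)
  rateOf <- function(ids) {
    counts <- vapply(ids, function(u) sum(s$unit_id == u), numeric(1))
    mean(counts) / recordingDuration(dataset)
  }
  hasPeriph <- length(truth$peripheryIds) > 0
  coreRate <- rateOf(truth$coreIds)
  periphRate <- if (hasPeriph) rateOf(truth$peripheryIds) else NA_real_
  gPer <- if (hasPeriph) mean(abs(truth$evokedLogGain[truth$peripheryIds]))
    else NA_real_
  gCore <- mean(abs(truth$evokedLogGain[truth$coreIds]))
  if (!hasPeriph) message("no periphery units; periphery checks skipped")
  data.frame(
    check = c("cs_range_overlaps_0.1_0.7", "core_rate_gt_periphery",
              "evoked_gain_periphery_gt_core"),
    value = c(max(cs, na.rm = TRUE) - min(cs, na.rm = TRUE),
              coreRate - periphRate, gPer - gCore),
    pass = c(csOverlap,
             if (hasPeriph) coreRate > periphRate else NA,
             if (hasPeriph) gPer > gCore else NA))
}

#' Random ground-truth Ising model for recovery tests
#'
#' Sparse-activity regime: biases uniform in \code{hRange} (mostly
#' negative, so units favor silence as cortical units do at 10-ms
#' resolution) and Gaussian couplings. The default scales match the
#' parameter ranges of pairwise models fitted to the synthetic recordings
#' of \code{\link{generateDataset}}.
#'
#' @param N ensemble size (default 10).
#' @param hRange range of biases (default c(-2.5, 0)).
#' @param jSd coupling SD (default 0.12).
#' @param seed integer seed.
#' @return an \linkS4class{IsingModel}.
#' @export
randomIsingModel <- function(N = 10, hRange = c(-2.5, 0), jSd = 0.12,
                             seed = 1) {
  withSeed(seed, {
    h <- runif(N, hRange[1], hRange[2])
    J <- matrix(0, N, N)
    J[upper.tri(J)] <- rnorm(N * (N - 1) / 2, 0, jSd)
    J <- J + t(J)
    IsingModel(h, J)
  })
}

#' Write generator ground truth to JSON
#'
#' @param truth ground-truth list from \code{\link{generateDataset}}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
writeTruthJson <- function(truth, path) {
  jsonlite::write_json(truth[setdiff(names(truth), "config")], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
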