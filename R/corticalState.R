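# Cortical state via silence density, and its relation to collective
# pattern statistics, activity observables and parameter sensitivity.

#' Silence density per epoch (cortical state index)
#'
#' CS(t) is the fraction of 20-ms bins, within the epoch's spontaneous
#' windows, containing no spike from the merged population (by default all
#' single and multi units). High CS indicates a synchronized (up/down)
#' state, low CS a desynchronized state.
#'
#' @param dataset a \linkS4class{SpikeDataset}.
#' @param epochWindows output of \code{\link{segmentEpochs}}.
#' @param bin bin width in seconds (default 0.020).
#' @param units unit ids to merge (default: all units).
#' @return data.frame with columns \code{epoch} and \code{CS} (NA for
#'   epochs without spontaneous windows).
#' @export
silenceDensity <- function(dataset, epochWindows, bin = 0.020, units = NULL) {
  if (is.null(units)) units <- unitTable(dataset)$unit_id
  s <- spikeTable(dataset)
  s <- s[s$unit_id %in% units, , drop = FALSE]
  cs <- vapply(seq_along(epochWindows$windows), function(t) {
    w <- epochWindows$windows[[t]]
    if (nrow(w) == 0) return(NA_real_)
    nb <- round((w$w_end - w$w_start) / bin)
    empty <- 0L
    for (k in seq_len(nrow(w))) {
      tt <- s$time_s[s$time_s >= w$w_start[k] & s$time_s < w$w_end[k]]
      occ <- unique(pmin(floor((tt - w$w_start[k]) / bin) + 1, nb[k]))
      empty <- empty + nb[k] - length(occ)
    }
    empty / sum(nb)
  }, numeric(1))
  data.frame(epoch = epochWindows$epochs$epoch, CS = cs)
}

#' Between-epoch divergence of empirical pattern statistics
#'
#' \eqn{D_{JS}(t,t') = D_{JS}(P_{data,t}; P_{data,t'})} for every epoch
#' pair, averaged over ensembles when several are given.
#'
#' @param distsPerEnsemble either a list of per-epoch empirical pattern
#'   distributions (one ensemble) or a list of such lists (several
#'   ensembles, averaged).
#' @return symmetric NE x NE matrix with zero diagonal.
#' @export
pairwisePatternDivergence <- function(distsPerEnsemble) {
  if (is.numeric(distsPerEnsemble[[1]]))
    distsPerEnsemble <- list(distsPerEnsemble)
  nE <- length(distsPerEnsemble[[1]])
  acc <- matrix(0, nE, nE)
  for (dists in distsPerEnsemble) {
    for (t in seq_len(nE - 1)) for (u in (t + 1):nE) {
      d <- jsDivergence(dists[[t]], dists[[u]])
      acc[t, u] <- acc[t, u] + d
      acc[u, t] <- acc[u, t] + d
    }
  }
  acc / length(distsPerEnsemble)
}

#' Correlation between pattern divergence and cortical-state change
#'
#' Across epoch pairs (upper triangle), correlates
#' \eqn{D_{JS}(t,t')} with \eqn{d = |CS(t)-CS(t')|}; the p-value comes from
#' permuting epoch labels. Also returns a binned mean curve of DJS vs d.
#'
#' @param djsMatrix matrix from \code{\link{pairwisePatternDivergence}}.
#' @param cs numeric CS values per epoch.
#' @param nPerm permutations for the p-value (default 1000).
#' @param nBins bins for the summary curve (default 8).
#' @param seed RNG seed.
#' @return list with \code{rc}, \code{p}, and \code{curve}
#'   (data.frame d_mid, mean_djs, n); \code{rc} is NA when CS is constant.
#' @export
stateDivergenceCorrelation <- function(djsMatrix, cs, nPerm = 1000,
                                       nBins = 8, seed = 1) {
  up <- upper.tri(djsMatrix)
  dMat <- abs(outer(cs, cs, "-"))
  x <- dMat[up]; y <- djsMatrix[up]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2 || sd(y) == 0)
    return(list(rc = NA_real_, p = NA_real_, curve = NULL))
  rc <- cor(x, y)
  perm <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
    csP <- sample(cs)
    dP <- abs(outer(csP, csP, "-"))[up][ok]
    if (sd(dP) == 0) return(0)
    cor(dP, y)
  }, numeric(1)))
  p <- (1 + sum(abs(perm) >= abs(rc))) / (nPerm + 1)
  brk <- seq(min(x), max(x), length.out = nBins + 1)
  bin <- cut(x, brk, include.lowest = TRUE)
  curve <- data.frame(d_mid = (head(brk, -1) + brk[-1]) / 2,
                      mean_djs = as.numeric(tapply(y, bin, mean)),
                      n = as.integer(table(bin)))
  list(rc = rc, p = p, curve = curve)
}

#' Per-epoch activity observables: rates and pairwise correlations
#'
#' For each epoch, the firing rate of every single unit (spikes per second
#' over the spontaneous windows) and the Pearson correlation of every unit
#' pair's -1/+1 binarized trains (bin \code{dt}). Correlations involving a
#' constant train are NA.
#'
#' @param dataset a \linkS4class{SpikeDataset}.
#' @param epochWindows output of \code{\link{segmentEpochs}}.
#' @param units unit ids (default: single units).
#' @param dt bin width for binarized correlations (default 0.010).
#' @return list with \code{rates} (NE x Npop matrix), \code{correlations}
#'   (NE x Npairs matrix, columns in \code{\link{pairIndexMap}} order over
#'   sorted units), and \code{units} (sorted ids).
#' @export
observableTimeseries <- function(dataset, epochWindows, units = NULL,
                                 dt = 0.010) {
  if (is.null(units)) units <- singleUnitIds(dataset)
  units <- sort(units)
  nE <- nrow(epochWindows$epochs)
  pm <- pairIndexMap(length(units))
  rates <- matrix(NA_real_, nE, length(units),
                  dimnames = list(NULL, paste0("u:", units)))
  cors <- matrix(NA_real_, nE, nrow(pm),
                 dimnames = list(NULL, paste0("p:", units[pm$i], "-", units[pm$j])))
  for (t in seq_len(nE)) {
    w <- epochWindows$windows[[t]]
    if (nrow(w) == 0) next
    raster <- binarize(dataset, w, dt = dt, units = units)
    totalTime <- sum(w$w_end - w$w_start)
    rates[t, ] <- rowSums(raster == 1) / totalTime
    cc <- suppressWarnings(cor(t(raster)))
    cors[t, ] <- cc[cbind(pm$i, pm$j)]
  }
  list(rates = rates, correlations = cors, units = units)
}

#' Absolute correlation between observables and cortical state
#'
#' rcs for each observable (unit rate or pair correlation): the absolute
#' Pearson correlation of its epoch series with CS(t). NA when fewer than
#' 3 valid epochs or the observable is constant.
#'
#' @param obs output of \code{\link{observableTimeseries}}.
#' @param cs numeric CS per epoch.
#' @return data.frame with \code{element}, \code{kind} and \code{rcs},
#'   elements keyed as in \code{\link{aggregatePopulationSensitivity}}.
#' @export
stateObservableCorrelation <- function(obs, cs) {
  series <- cbind(obs$rates, obs$correlations)
  rcs <- apply(series, 2, function(v) {
    ok <- !is.na(v) & !is.na(cs)
    if (sum(ok) < 3 || sd(v[ok]) == 0 || sd(cs[ok]) == 0) return(NA_real_)
    abs(cor(v[ok], cs[ok]))
  })
  data.frame(element = colnames(series),
             kind = c(rep("unit", ncol(obs$rates)),
                      rep("pair", ncol(obs$correlations))),
             rcs = as.numeric(rcs))
}

#' Relation between state coupling (rcs) and sensitivity (s)
#'
#' Correlates each covered population element's sensitivity with its
#' absolute state correlation, and compares mean rcs between the stiff and
#' sloppy classes: a Welch two-sample test at the element level and, when
#' per-ensemble summaries are supplied, a paired t-test of within-ensemble
#' stiff/sloppy means.
#'
#' @param rcsTable data.frame from \code{\link{stateObservableCorrelation}}.
#' @param sensTable data.frame from
#'   \code{\link{aggregatePopulationSensitivity}} (with labels added via
#'   \code{\link{medianSplit}} or not; labels are recomputed if absent).
#' @param pairedMeans optional data.frame with columns \code{stiff},
#'   \code{sloppy}: per-ensemble mean rcs of each class.
#' @return list with \code{rc}, \code{ci} (95\% CI), \code{p},
#'   \code{groupMeans}, \code{welch_p}, and \code{paired_p} (NA if not
#'   supplied).
#' @export
sensitivityStateRelation <- function(rcsTable, sensTable, pairedMeans = NULL) {
  m <- merge(rcsTable, sensTable[, c("element", "s")], by = "element")
  m <- m[!is.na(m$rcs) & !is.na(m$s), , drop = FALSE]
  ct <- cor.test(m$s, m$rcs)
  label <- medianSplit(m$s)
  gm <- tapply(m$rcs, label, mean)
  welch <- if (length(unique(label[!is.na(label)])) == 2)
    t.test(m$rcs[label == "stiff"], m$rcs[label == "sloppy"])$p.value
  else NA_real_
  paired <- if (!is.null(pairedMeans) && nrow(pairedMeans) >= 2)
    t.test(pairedMeans$stiff, pairedMeans$sloppy, paired = TRUE)$p.value
  else NA_real_
  list(rc = unname(ct$estimate), ci = unname(ct$conf.int), p = ct$p.value,
       groupMeans = gm, welch_p = welch, paired_p = paired)
}

#' Temporal similarity of an epoch-indexed vector series
#'
#' \eqn{\gamma(\Delta t) = \frac{1}{N_E-\Delta t}\sum_t
#' \rho[v(t), v(t+\Delta t)]} where \eqn{\rho} is the Pearson correlation;
#' applicable to rate vectors, correlation vectors, biases, couplings, or
#' vectorized FIMs.
#'
#' @param series NE x M matrix, one vector per epoch (NA columns dropped
#'   pairwise).
#' @param lags integer lags to evaluate (default \code{0:(NE-2)}).
#' @return data.frame with \code{lag} and \code{gamma}.
#' @export
similarityGamma <- function(series, lags = NULL) {
  nE <- nrow(series)
  if (is.null(lags)) lags <- 0:(nE - 2)
  gamma <- vapply(lags, function(dt) {
    if (dt == 0) return(1)
    r <- vapply(seq_len(nE - dt), function(t) {
      a <- series[t, ]; b <- series[t + dt, ]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
      cor(a[ok], b[ok])
    }, numeric(1))
    mean(r, na.rm = TRUE)
  }, numeric(1))
  data.frame(lag = lags, gamma = gamma)
}

#' Vectorize a FIM for similarity analysis
#'
#' Upper triangle including the diagonal, row-major.
#' @param fimResult a \linkS4class{FimResult}.
#' @return numeric vector.
#' @export
vectorizeFim <- function(fimResult) {
  F <- fimMatrix(fimResult)
  t(F)[lower.tri(F, diag = TRUE)]
}

#' Cross-epoch model fit: mean divergence at lag
#'
#' \eqn{\langle D_{JS}\rangle(\Delta t) = \frac{1}{N_E-\Delta t}\sum_t
#' D_{JS}(P_{data,t}; P_{MEM,t+\Delta t})}: how well the model fitted at a
#' later epoch explains the data of an earlier one. Flat in lag for
#' stationary activity; rising when the model drifts.
#'
#' @param dataDists list of per-epoch empirical pattern distributions.
#' @param modelDists list of per-epoch model (Boltzmann) distributions.
#' @param lags integer lags (default \code{0:(NE-2)}).
#' @return data.frame with \code{lag} and \code{mean_djs}.
#' @export
laggedModelFit <- function(dataDists, modelDists, lags = NULL) {
  nE <- length(dataDists)
  if (is.null(lags)) lags <- 0:(nE - 2)
  md <- vapply(lags, function(dt) {
    mean(vapply(seq_len(nE - dt), function(t)
      jsDivergence(dataDists[[t]], modelDists[[t + dt]]), numeric(1)))
  }, numeric(1))
  data.frame(lag = lags, mean_djs = md)
}
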