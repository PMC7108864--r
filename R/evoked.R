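# Stimulus-response quantification: per-trial spike counts, the modulation
# index MI = |rstim - rspon| / (rstim + rspon), and its relations to
# sensitivity and cortical state.

#' Per-trial pre- and post-stimulus spike counts
#'
#' Counts each unit's spikes in \code{[onset-pre, onset)} and
#' \code{[onset, onset+post)} for every stimulus, and averages within
#' epochs.
#'
#' @param dataset a \linkS4class{SpikeDataset}.
#' @param epochWindows output of \code{\link{segmentEpochs}}.
#' @param units unit ids (default: single units).
#' @param pre,post window lengths in seconds (default 0.5 each).
#' @return list with \code{trial} (data.frame unit_id, epoch, onset,
#'   n_pre, n_post) and \code{epochMeans} (data.frame unit_id, epoch,
#'   rspon, rstim, n_trials).
#' @export
trialCounts <- function(dataset, epochWindows, units = NULL,
                        pre = 0.5, post = 0.5) {
  if (is.null(units)) units <- singleUnitIds(dataset)
  s <- spikeTable(dataset)
  rows <- list()
  for (t in seq_len(nrow(epochWindows$epochs))) {
    for (onset in epochWindows$events[[t]]) {
      sel <- s$unit_id %in% units & s$time_s >= onset - pre &
        s$time_s < onset + post
      ss <- s[sel, , drop = FALSE]
      nPre <- table(factor(ss$unit_id[ss$time_s < onset], levels = units))
      nPost <- table(factor(ss$unit_id[ss$time_s >= onset], levels = units))
      rows[[length(rows) + 1]] <- data.frame(
        unit_id = units, epoch = t, onset = onset,
        n_pre = as.integer(nPre), n_post = as.integer(nPost))
    }
  }
  trial <- do.call(rbind, rows)
  if (is.null(trial))
    return(list(trial = NULL, epochMeans = NULL))
  agg <- aggregate(cbind(rspon = n_pre, rstim = n_post) ~ unit_id + epoch,
                   data = trial, FUN = mean)
  nTr <- aggregate(onset ~ unit_id + epoch, data = trial, FUN = length)
  agg$n_trials <- nTr$onset[match(paste(agg$unit_id, agg$epoch),
                                  paste(nTr$unit_id, nTr$epoch))]
  list(trial = trial, epochMeans = agg[order(agg$unit_id, agg$epoch), ])
}

#' Modulation index
#'
#' \eqn{MI = |r_{stim} - r_{spon}| / (r_{stim} + r_{spon})}, in [0,1];
#' defined as 0 when both counts are 0 (unresponsive unit). Symmetric in
#' excitation and suppression of equal magnitude.
#'
#' @param rspon,rstim mean pre- and post-stimulus spike counts (vectors
#'   recycle).
#' @return numeric MI values.
#' @export
modulationIndex <- function(rspon, rstim) {
  denom <- rspon + rstim
  ifelse(denom > 0, abs(rstim - rspon) / denom, 0)
}

#' Session-level evoked summary per unit
#'
#' Pools trials over the whole session: session MI from the pooled mean
#' counts, response sign from \code{sign(rstim - rspon)} (\code{excited},
#' \code{suppressed}, or \code{null} on ties), and the per-epoch MI table.
#'
#' @param counts output of \code{\link{trialCounts}}.
#' @return list with \code{session} (data.frame unit_id, rspon, rstim, MI,
#'   sign) and \code{byEpoch} (data.frame unit_id, epoch, MI).
#' @export
evokedSummary <- function(counts) {
  tr <- counts$trial
  sess <- aggregate(cbind(rspon = n_pre, rstim = n_post) ~ unit_id,
                    data = tr, FUN = mean)
  sess$MI <- modulationIndex(sess$rspon, sess$rstim)
  sess$sign <- c("suppressed", "null", "excited")[
    sign(sess$rstim - sess$rspon) + 2]
  byEpoch <- counts$epochMeans
  byEpoch$MI <- modulationIndex(byEpoch$rspon, byEpoch$rstim)
  list(session = sess, byEpoch = byEpoch[, c("unit_id", "epoch", "MI")])
}

#' Correlation between responsiveness and sensitivity
#'
#' Pearson correlation of each unit's session MI with its population
#' sensitivity \eqn{s_i} (unit elements only), plus mean normalized
#' response levels for the stiff and sloppy classes split by response
#' sign.
#'
#' @param sessionMi data.frame with \code{unit_id}, \code{MI}, \code{sign}
#'   (from \code{\link{evokedSummary}}).
#' @param sensTable data.frame from
#'   \code{\link{aggregatePopulationSensitivity}} restricted to units.
#' @return list with \code{rc}, \code{p}, and \code{groups} (data.frame
#'   label, sign, mean_MI, n).
#' @export
miSensitivityRelation <- function(sessionMi, sensTable) {
  su <- sensTable[sensTable$kind == "unit", c("i", "s")]
  m <- merge(sessionMi, su, by.x = "unit_id", by.y = "i")
  m <- m[!is.na(m$s), , drop = FALSE]
  ct <- cor.test(m$MI, m$s)
  m$label <- medianSplit(m$s)
  groups <- aggregate(MI ~ label + sign, data = m, FUN = mean)
  groups$n <- aggregate(MI ~ label + sign, data = m, FUN = length)$MI
  names(groups)[names(groups) == "MI"] <- "mean_MI"
  list(rc = unname(ct$estimate), p = ct$p.value, groups = groups)
}

#' Per-epoch correlation between MI and the leading FIM eigenvector
#'
#' For each epoch, correlates the ensemble units' MI(t) with the absolute
#' h-block components of that epoch's first FIM eigenvector; summarizes
#' each ensemble by its median over epochs, with a two-sided sign test on
#' the per-ensemble medians across ensembles.
#'
#' @param miByEpoch data.frame with \code{unit_id}, \code{epoch}, \code{MI}.
#' @param fimsPerEnsemble list (length Q) of per-epoch
#'   \linkS4class{FimResult} lists.
#' @param ensembles list of sorted unit-id vectors.
#' @return list with \code{perEnsemble} (median correlation per ensemble)
#'   and \code{sign_p} (binomial sign-test p-value).
#' @export
miEigvecCorrelation <- function(miByEpoch, fimsPerEnsemble, ensembles) {
  med <- vapply(seq_along(ensembles), function(q) {
    u <- sort(ensembles[[q]])
    N <- length(u)
    rs <- vapply(seq_along(fimsPerEnsemble[[q]]), function(t) {
      v1 <- abs(fimEigenvectors(fimsPerEnsemble[[q]][[t]])[seq_len(N), 1])
      mi <- miByEpoch$MI[match(paste(u, t),
                               paste(miByEpoch$unit_id, miByEpoch$epoch))]
      ok <- !is.na(mi)
      if (sum(ok) < 3 || sd(mi[ok]) == 0 || sd(v1[ok]) == 0) return(NA_real_)
      cor(mi[ok], v1[ok])
    }, numeric(1))
    median(rs, na.rm = TRUE)
  }, numeric(1))
  ok <- !is.na(med) & med != 0
  sp <- if (any(ok)) binom.test(sum(med[ok] < 0), sum(ok))$p.value else NA_real_
  list(perEnsemble = med, sign_p = sp)
}

#' Sloppy-minus-stiff MI difference across cortical-state bins
#'
#' Epoch MI values are pooled by class within equal-width CS bins; the
#' curve is the mean MI of sloppy units minus that of stiff units per bin.
#' Bins holding fewer than \code{minEpochs} epochs are dropped.
#'
#' @param miByEpoch data.frame with \code{unit_id}, \code{epoch}, \code{MI}.
#' @param labels data.frame with \code{unit_id} and \code{label}
#'   (stiff/sloppy).
#' @param cs data.frame with \code{epoch}, \code{CS}.
#' @param nBins number of equal-width CS bins (default 8).
#' @param minEpochs minimum epochs per bin (default 3).
#' @return data.frame with \code{cs_mid}, \code{delta_mi}, \code{n_epochs}.
#' @export
deltaMiByState <- function(miByEpoch, labels, cs, nBins = 8, minEpochs = 3) {
  m <- merge(miByEpoch, labels, by = "unit_id")
  m <- merge(m, cs, by = "epoch")
  m <- m[!is.na(m$CS) & !is.na(m$label), , drop = FALSE]
  brk <- seq(min(m$CS), max(m$CS), length.out = nBins + 1)
  if (brk[1] == brk[nBins + 1]) brk <- brk[1] + c(-0.5, 0.5)
  m$bin <- cut(m$CS, brk, include.lowest = TRUE)
  out <- do.call(rbind, lapply(levels(m$bin), function(b) {
    mb <- m[m$bin == b, , drop = FALSE]
    nEp <- length(unique(mb$epoch))
    if (nEp < minEpochs) return(NULL)
    data.frame(
      cs_mid = (brk[match(b, levels(m$bin))] +
                brk[match(b, levels(m$bin)) + 1]) / 2,
      delta_mi = mean(mb$MI[mb$label == "sloppy"]) -
        mean(mb$MI[mb$label == "stiff"]),
      n_epochs = nEp)
  }))
  out
}

#' Normalized peri-stimulus time histogram
#'
#' Trial-averaged population rate around stimulus onset, per unit group,
#' divided by the group's mean pre-stimulus rate r0. Units with r0 = 0 are
#' excluded with a warning.
#'
#' @param dataset a \linkS4class{SpikeDataset}.
#' @param units unit ids to pool.
#' @param pre,post peri-stimulus extent in seconds (defaults 0.5).
#' @param dt histogram bin width (default 0.010).
#' @return data.frame with \code{time} (bin centers, 0 = onset) and
#'   \code{norm_rate}; NULL if no usable unit.
#' @export
normalizedPsth <- function(dataset, units, pre = 0.5, post = 0.5, dt = 0.010) {
  ev <- eventTimes(dataset)
  s <- spikeTable(dataset)
  edges <- seq(-pre, post, by = dt)
  mid <- (head(edges, -1) + edges[-1]) / 2
  perUnit <- lapply(units, function(u) {
    tt <- s$time_s[s$unit_id == u]
    rel <- unlist(lapply(ev, function(o) tt[tt >= o - pre & tt < o + post] - o))
    counts <- if (length(rel)) hist(rel, breaks = edges, plot = FALSE)$counts
      else rep(0L, length(mid))
    rate <- counts / (length(ev) * dt)
    r0 <- mean(rate[mid < 0])
    list(rate = rate, r0 = r0)
  })
  r0 <- vapply(perUnit, `[[`, numeric(1), "r0")
  if (any(r0 == 0)) {
    warning(sum(r0 == 0), " unit(s) with zero pre-stimulus rate excluded")
    perUnit <- perUnit[r0 > 0]
  }
  if (!length(perUnit)) return(NULL)
  curves <- vapply(perUnit, function(x) x$rate / x$r0, numeric(length(mid)))
  data.frame(time = mid, norm_rate = rowMeans(curves))
}
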