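# Spike table I/O and binarization.
# On-disk format: a spikes table (unit_id,time_s,class), a units table
# (unit_id,class), an events table (onset_s) and a small JSON with the
# duration, sharing the spikes file's stem.

.sidecar <- function(path, suffix, ext = NULL) {
  stem <- sub("\\.[^.]*$", "", path)
  if (is.null(ext)) ext <- sub(".*(\\.[^.]*)$", "\\1", path)
  paste0(stem, suffix, ext)
}

.sepFor <- function(format) if (format == "tsv") "\t" else ","

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded package operations do
#' not disturb the caller's RNG stream. A \code{NULL} seed leaves the
#' stream untouched.
#' @param seed integer seed or NULL.
#' @param expr expression to evaluate.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a spike dataset from delimited tables
#'
#' Reads the spikes table at \code{path} plus its sidecar units, events and
#' metadata files (written by \code{\link{writeSpikeTable}}). If the units
#' sidecar is absent, units are inferred from the spikes table; if the
#' metadata sidecar is absent, the duration is the latest spike or event
#' time rounded up to the next second.
#'
#' @param path path to the spikes table (columns \code{unit_id},
#'   \code{time_s}, \code{class}).
#' @param format \code{"csv"} or \code{"tsv"}.
#' @return a \linkS4class{SpikeDataset}.
#' @export
readSpikeTable <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- .sepFor(format)
  spikes <- read.csv(path, sep = sep)
  if (!all(c("unit_id", "time_s", "class") %in% names(spikes)))
    stop("format error: spikes table needs columns unit_id, time_s, class")
  if (nrow(spikes) > 0 && any(spikes$time_s < 0))
    stop("validation error: negative spike time")
  unitsPath <- .sidecar(path, "_units")
  if (file.exists(unitsPath)) {
    units <- read.csv(unitsPath, sep = sep)
    if (!all(c("unit_id", "class") %in% names(units)))
      stop("format error: units table needs columns unit_id, class")
  } else {
    units <- unique(spikes[, c("unit_id", "class")])
  }
  eventsPath <- .sidecar(path, "_events")
  events <- if (file.exists(eventsPath)) {
    ev <- read.csv(eventsPath, sep = sep)
    if (!"onset_s" %in% names(ev))
      stop("format error: events table needs column onset_s")
    ev$onset_s
  } else numeric(0)
  metaPath <- .sidecar(path, "_meta", ".json")
  duration <- if (file.exists(metaPath)) {
    jsonlite::fromJSON(metaPath)$duration_s
  } else {
    ceiling(max(c(spikes$time_s, events, 0)))
  }
  SpikeDataset(units = units,
               spikes = spikes[, c("unit_id", "time_s")],
               events = events, duration = duration)
}

#' Write a spike dataset to delimited tables
#'
#' Writes four files sharing \code{path}'s stem: the spikes table itself,
#' \code{<stem>_units}, \code{<stem>_events} and \code{<stem>_meta.json}.
#' Output is byte-stable for a fixed dataset.
#'
#' @param dataset a \linkS4class{SpikeDataset}.
#' @param path destination for the spikes table.
#' @param format \code{"csv"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeSpikeTable <- function(dataset, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- .sepFor(format)
  u <- unitTable(dataset)
  s <- spikeTable(dataset)
  s$class <- u$class[match(s$unit_id, u$unit_id)]
  s$time_s <- sprintf("%.6f", s$time_s)
  write.table(s[, c("unit_id", "time_s", "class")], path, sep = sep,
              row.names = FALSE, quote = FALSE)
  write.table(u, .sidecar(path, "_units"), sep = sep,
              row.names = FALSE, quote = FALSE)
  write.table(data.frame(onset_s = sprintf("%.6f", eventTimes(dataset))),
              .sidecar(path, "_events"), sep = sep,
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(duration_s = recordingDuration(dataset)),
                       .sidecar(path, "_meta", ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Cut a recording into adjacent epochs with pre-stimulus windows
#'
#' The recording is divided into \code{floor(duration/epochLength)} adjacent
#' epochs. Within each epoch, every stimulus onset contributes one
#' spontaneous window of length \code{preWindow} ending exactly at the
#' onset; windows that would start before the epoch does are dropped so all
#' windows have full length. Epochs containing no events are flagged
#' (excluded from evoked analyses downstream).
#'
#' @param dataset a \linkS4class{SpikeDataset}.
#' @param epochLength epoch length in seconds (default 100).
#' @param preWindow spontaneous window length in seconds (default 1.5).
#' @return list with \code{epochs} (data.frame epoch, t_start, t_end,
#'   n_events, flagged), \code{windows} (per-epoch data.frame w_start,
#'   w_end, onset) and \code{events} (per-epoch onset vector).
#' @export
segmentEpochs <- function(dataset, epochLength = 100, preWindow = 1.5) {
  dur <- recordingDuration(dataset)
  if (dur < epochLength) stop("duration shorter than one epoch")
  nE <- floor(dur / epochLength)
  starts <- (seq_len(nE) - 1) * epochLength
  ev <- eventTimes(dataset)
  windows <- vector("list", nE)
  events <- vector("list", nE)
  for (t in seq_len(nE)) {
    t0 <- starts[t]; t1 <- t0 + epochLength
    e <- ev[ev >= t0 & ev < t1]
    events[[t]] <- e
    keep <- e - preWindow >= t0
    windows[[t]] <- data.frame(w_start = e[keep] - preWindow,
                               w_end = e[keep], onset = e[keep])
  }
  nEvents <- vapply(events, length, integer(1))
  list(epochs = data.frame(epoch = seq_len(nE), t_start = starts,
                           t_end = starts + epochLength,
                           n_events = nEvents, flagged = nEvents == 0),
       windows = windows, events = events,
       epoch_length = epochLength, pre_window = preWindow)
}

#' Binarize spiking activity over a set of windows
#'
#' Concatenates the given windows in temporal order and discretizes each
#' into bins of width \code{dt} (half-open, \code{[t, t+dt)}); a unit's
#' value in a bin is +1 if it fired at least once there, else -1. Window
#' lengths must be exact multiples of \code{dt}.
#'
#' @param dataset a \linkS4class{SpikeDataset}.
#' @param windows data.frame with columns \code{w_start}, \code{w_end}.
#' @param dt bin width in seconds (default 0.010).
#' @param units unit ids to include (default: all units).
#' @return a units x bins matrix of -1/+1 with rownames the unit ids and
#'   attributes \code{dt} and \code{windows}.
#' @export
binarize <- function(dataset, windows, dt = 0.010, units = NULL) {
  if (is.null(units)) units <- unitTable(dataset)$unit_id
  windows <- as.data.frame(windows)
  windows <- windows[order(windows$w_start), , drop = FALSE]
  lens <- windows$w_end - windows$w_start
  nb <- lens / dt
  if (any(abs(nb - round(nb)) > 1e-6))
    stop("window length not an exact multiple of dt")
  nb <- as.integer(round(nb))
  total <- sum(nb)
  raster <- matrix(-1L, nrow = length(units), ncol = total,
                   dimnames = list(units, NULL))
  s <- spikeTable(dataset)
  s <- s[s$unit_id %in% units, , drop = FALSE]
  offset <- c(0L, cumsum(nb))
  rowOf <- match(s$unit_id, units)
  for (w in seq_len(nrow(windows))) {
    sel <- s$time_s >= windows$w_start[w] & s$time_s < windows$w_end[w]
    if (!any(sel)) next
    bin <- floor((s$time_s[sel] - windows$w_start[w]) / dt) + 1L
    bin <- pmin(bin, nb[w])  # guard exact float boundary
    raster[cbind(rowOf[sel], offset[w] + bin)] <- 1L
  }
  attr(raster, "dt") <- dt
  attr(raster, "windows") <- windows
  raster
}

#' Extract ensemble pattern samples from a raster
#'
#' @param raster a -1/+1 matrix from \code{\link{binarize}}.
#' @param ensemble unit ids, in the order defining the pattern coordinates.
#' @param epoch optional epoch label attached to the result.
#' @return a samples x N matrix of -1/+1 patterns (one row per bin) with
#'   attributes \code{unitIds} and \code{epoch}.
#' @export
extractPatterns <- function(raster, ensemble, epoch = NA_integer_) {
  idx <- match(as.character(ensemble), rownames(raster))
  if (anyNA(idx)) stop("unknown unit id(s): ",
                       paste(ensemble[is.na(idx)], collapse = ", "))
  patterns <- t(raster[idx, , drop = FALSE])
  dimnames(patterns) <- NULL
  attr(patterns, "unitIds") <- as.integer(ensemble)
  attr(patterns, "epoch") <- as.integer(epoch)
  patterns
}

#' Sample random ensembles of single units
#'
#' Draws \code{Q} ensembles of \code{N} distinct single units, uniformly
#' without replacement within each ensemble; different ensembles may
#' overlap. Deterministic under \code{seed}.
#'
#' @param singleUnitIds candidate unit ids.
#' @param N ensemble size (default 10).
#' @param Q number of ensembles.
#' @param seed integer seed.
#' @return list with \code{ensembles} (list of sorted id vectors), \code{N},
#'   and \code{seed}.
#' @export
sampleEnsembles <- function(singleUnitIds, N = 10, Q, seed = 1) {
  if (length(singleUnitIds) < N)
    stop("need at least ", N, " single units, got ", length(singleUnitIds))
  if (Q < 1) stop("Q must be >= 1")
  ens <- withSeed(seed, lapply(seq_len(Q), function(q)
    sort(sample(singleUnitIds, N, replace = FALSE))))
  list(ensembles = ens, N = N, seed = seed)
}
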