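#' @useDynLib sloppySpikes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cor cor.test median rnorm runif sd setNames aggregate
#'   t.test binom.test qlogis plogis
#' @importFrom graphics hist
#' @importFrom utils read.csv write.csv write.table head packageVersion
NULL

#' SpikeDataset: spike times, unit classes and stimulus events
#'
#' Container for one recording session: a unit table (id and class, single
#' or multi), a spike table (unit id, time in seconds), stimulus onset times
#' and the total duration. All times are in seconds from the start of the
#' recording.
#'
#' @slot units data.frame with columns \code{unit_id} (integer) and
#'   \code{class} (\code{"single"} or \code{"multi"}).
#' @slot spikes data.frame with columns \code{unit_id} and \code{time_s},
#'   sorted by unit then time.
#' @slot events numeric vector of stimulus onset times, strictly increasing.
#' @slot duration total recording duration in seconds.
#' @export
setClass("SpikeDataset",
  representation(units = "data.frame", spikes = "data.frame",
                 events = "numeric", duration = "numeric"))

setValidity("SpikeDataset", function(object) {
  msg <- character()
  u <- object@units; s <- object@spikes
  if (!all(c("unit_id", "class") %in% names(u)))
    msg <- c(msg, "units must have columns unit_id, class")
  if (!all(c("unit_id", "time_s") %in% names(s)))
    msg <- c(msg, "spikes must have columns unit_id, time_s")
  if (anyDuplicated(u$unit_id)) msg <- c(msg, "unit ids must be unique")
  if (!all(u$class %in% c("single", "multi")))
    msg <- c(msg, "unit class must be 'single' or 'multi'")
  if (length(object@duration) != 1 || object@duration < 0)
    msg <- c(msg, "duration must be a single non-negative number")
  if (nrow(s) > 0) {
    if (any(s$time_s < 0) || any(s$time_s > object@duration))
      msg <- c(msg, "spike times must lie in [0, duration]")
    if (!all(s$unit_id %in% u$unit_id))
      msg <- c(msg, "spikes reference undeclared unit ids")
  }
  if (length(object@events) > 1 && any(diff(object@events) <= 0))
    msg <- c(msg, "event onsets must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a SpikeDataset
#'
#' @param units data.frame with columns \code{unit_id}, \code{class}.
#' @param spikes data.frame with columns \code{unit_id}, \code{time_s}.
#' @param events numeric vector of stimulus onset times (seconds).
#' @param duration recording duration in seconds.
#' @return A validated \linkS4class{SpikeDataset}.
#' @examples
#' ds <- SpikeDataset(units = data.frame(unit_id = 1L, class = "single"),
#'                    spikes = data.frame(unit_id = 1L, time_s = 0.5),
#'                    events = numeric(0), duration = 10)
#' @export
SpikeDataset <- function(units, spikes, events = numeric(0), duration) {
  units$unit_id <- as.integer(units$unit_id)
  units$class <- as.character(units$class)
  if (nrow(spikes) > 0) {
    spikes$unit_id <- as.integer(spikes$unit_id)
    spikes <- spikes[order(spikes$unit_id, spikes$time_s), , drop = FALSE]
    rownames(spikes) <- NULL
  }
  new("SpikeDataset", units = units,
      spikes = spikes[, c("unit_id", "time_s"), drop = FALSE],
      events = as.numeric(events), duration = as.numeric(duration))
}

#' @describeIn SpikeDataset-class unit table accessor
#' @param x a SpikeDataset
#' @export
unitTable <- function(x) x@units

#' @describeIn SpikeDataset-class spike table accessor
#' @export
spikeTable <- function(x) x@spikes

#' @describeIn SpikeDataset-class stimulus onset accessor
#' @export
eventTimes <- function(x) x@events

#' @describeIn SpikeDataset-class duration accessor (seconds)
#' @export
recordingDuration <- function(x) x@duration

#' Ids of single units in a dataset
#' @param x a SpikeDataset
#' @return integer vector of single-unit ids
#' @export
singleUnitIds <- function(x) x@units$unit_id[x@units$class == "single"]

setMethod("show", "SpikeDataset", function(object) {
  cat("SpikeDataset:", nrow(object@units), "units (",
      sum(object@units$class == "single"), "single,",
      sum(object@units$class == "multi"), "multi ),",
      nrow(object@spikes), "spikes,", length(object@events),
      "events,", object@duration, "s\n")
})

#' IsingModel: pairwise maximum-entropy model of an ensemble
#'
#' Biases \code{h} and symmetric zero-diagonal couplings \code{J} for one
#' ensemble of N units in one epoch, under the energy convention
#' \deqn{E(\sigma) = -\sum_i h_i\sigma_i - \tfrac12\sum_{ij}J_{ij}\sigma_i\sigma_j}
#' with \eqn{\sigma_i \in \{-1,+1\}} and Boltzmann pattern probabilities
#' \eqn{P(\sigma) = e^{-E(\sigma)}/Z}.
#'
#' @slot h numeric length-N vector of intrinsic biases.
#' @slot J numeric N x N symmetric coupling matrix, zero diagonal.
#' @slot unitIds integer ids of the ensemble units (defines ordering).
#' @slot epoch integer epoch label (NA if unset).
#' @export
setClass("IsingModel",
  representation(h = "numeric", J = "matrix", unitIds = "integer",
                 epoch = "integer"))

setValidity("IsingModel", function(object) {
  msg <- character()
  N <- length(object@h)
  if (!all(dim(object@J) == c(N, N))) msg <- c(msg, "J must be N x N")
  else {
    if (max(abs(object@J - t(object@J))) > 1e-10)
      msg <- c(msg, "J must be symmetric")
    if (any(abs(diag(object@J)) > 1e-12))
      msg <- c(msg, "diag(J) must be zero")
  }
  if (length(object@unitIds) != N)
    msg <- c(msg, "unitIds must have length N")
  if (length(msg)) msg else TRUE
})

#' Construct an IsingModel
#'
#' @param h numeric vector of biases.
#' @param J symmetric coupling matrix with zero diagonal (defaults to zeros,
#'   i.e. an independent model).
#' @param unitIds integer unit ids (default \code{seq_along(h)}).
#' @param epoch epoch label.
#' @return An \linkS4class{IsingModel}.
#' @examples
#' m <- IsingModel(h = c(0.5, -0.2), J = matrix(c(0, 0.1, 0.1, 0), 2))
#' @export
IsingModel <- function(h, J = NULL, unitIds = seq_along(h), epoch = NA_integer_) {
  N <- length(h)
  if (is.null(J)) J <- matrix(0, N, N)
  new("IsingModel", h = as.numeric(h), J = as.matrix(J),
      unitIds = as.integer(unitIds), epoch = as.integer(epoch))
}

#' @describeIn IsingModel-class bias accessor
#' @param x an IsingModel
#' @export
biases <- function(x) x@h

#' @describeIn IsingModel-class coupling matrix accessor
#' @export
couplings <- function(x) x@J

#' @describeIn IsingModel-class number of units
#' @export
ensembleSize <- function(x) length(x@h)

setMethod("show", "IsingModel", function(object) {
  cat("IsingModel: N =", length(object@h),
      if (!is.na(object@epoch)) paste0("(epoch ", object@epoch, ")"), "\n")
  cat("  h in [", round(min(object@h), 3), ",", round(max(object@h), 3),
      "]; |J| max =", round(max(abs(object@J)), 3), "\n")
})

#' Flatten model parameters to the canonical ordering
#'
#' Returns \code{[h1..hN, J12, J13, ..., J(N-1)N]}: the biases followed by
#' the row-major upper triangle of the couplings. This ordering matches the
#' observable vector used by the Fisher information matrix.
#'
#' @param model an \linkS4class{IsingModel}.
#' @return numeric vector of length N + N(N-1)/2.
#' @export
paramVector <- function(model) {
  N <- length(model@h)
  c(model@h, t(model@J)[lower.tri(model@J)])
}

#' Rebuild an IsingModel from a flat parameter vector
#'
#' Inverse of \code{\link{paramVector}}.
#' @param omega flat parameter vector, canonical ordering.
#' @param unitIds,epoch passed to \code{\link{IsingModel}}.
#' @export
modelFromParamVector <- function(omega, unitIds = NULL, epoch = NA_integer_) {
  L <- length(omega)
  N <- (sqrt(8 * L + 1) - 1) / 2
  if (abs(N - round(N)) > 1e-9)
    stop("length ", L, " is not N + N(N-1)/2 for any integer N")
  N <- as.integer(round(N))
  h <- omega[seq_len(N)]
  J <- matrix(0, N, N)
  pm <- pairIndexMap(N)
  for (k in seq_len(nrow(pm))) {
    J[pm$i[k], pm$j[k]] <- J[pm$j[k], pm$i[k]] <- omega[N + k]
  }
  if (is.null(unitIds)) unitIds <- seq_len(N)
  IsingModel(h, J, unitIds = unitIds, epoch = epoch)
}

#' FimResult: Fisher information matrix with eigen-decomposition
#'
#' The FIM of a pairwise maximum-entropy model is the covariance matrix of
#' the observable vector \code{[sigma_1..sigma_N, sigma_1 sigma_2, ...]}
#' under the model distribution. Eigenvalues are stored in descending order;
#' eigenvectors are unit norm with the sign fixed so the largest-magnitude
#' component is positive.
#'
#' @slot fim numeric symmetric matrix (L x L, L = N + N(N-1)/2).
#' @slot values eigenvalues, descending.
#' @slot vectors eigenvectors as columns, matching \code{values}.
#' @slot epoch epoch label.
#' @slot method \code{"exact"} or \code{"metropolis"}.
#' @export
setClass("FimResult",
  representation(fim = "matrix", values = "numeric", vectors = "matrix",
                 epoch = "integer", method = "character"))

setValidity("FimResult", function(object) {
  msg <- character()
  L <- nrow(object@fim)
  if (ncol(object@fim) != L) msg <- c(msg, "fim must be square")
  if (max(abs(object@fim - t(object@fim))) > 1e-8)
    msg <- c(msg, "fim must be symmetric")
  if (length(object@values) != L || !all(dim(object@vectors) == c(L, L)))
    msg <- c(msg, "eigenpairs must match fim dimension")
  if (is.unsorted(rev(object@values))) msg <- c(msg, "eigenvalues must be descending")
  if (min(object@values) < -1e-8) msg <- c(msg, "fim must be PSD up to 1e-8")
  if (length(msg)) msg else TRUE
})

#' @describeIn FimResult-class the matrix itself
#' @param x a FimResult
#' @export
fimMatrix <- function(x) x@fim

#' @describeIn FimResult-class eigenvalues (descending)
#' @export
fimEigenvalues <- function(x) x@values

#' @describeIn FimResult-class eigenvectors (columns, matching eigenvalues)
#' @export
fimEigenvectors <- function(x) x@vectors

setMethod("show", "FimResult", function(object) {
  v <- object@values
  cat("FimResult:", nrow(object@fim), "parameters;",
      "eigenvalue range [", signif(min(v), 3), ",", signif(max(v), 3), "]\n")
})

#' FitResult: outcome of a maximum-entropy fit
#'
#' @slot model the fitted \linkS4class{IsingModel}.
#' @slot converged logical.
#' @slot iterations iterations used.
#' @slot discrepancy final max-abs moment discrepancy.
#' @slot targetRates empirical \eqn{\langle\sigma_i\rangle}.
#' @slot targetPairs empirical \eqn{\langle\sigma_i\sigma_j\rangle} (matrix).
#' @slot momentMethod \code{"exact"} or \code{"metropolis"}.
#' @export
setClass("FitResult",
  representation(model = "IsingModel", converged = "logical",
                 iterations = "integer", discrepancy = "numeric",
                 targetRates = "numeric", targetPairs = "matrix",
                 momentMethod = "character"))

#' @describeIn FitResult-class fitted model accessor
#' @param x a FitResult
#' @export
fittedModel <- function(x) x@model

#' @describeIn FitResult-class convergence flag
#' @export
isConverged <- function(x) x@converged

setMethod("show", "FitResult", function(object) {
  cat("FitResult: N =", length(object@model@h),
      "| converged:", object@converged,
      "| iterations:", object@iterations,
      "| max moment error:", signif(object@discrepancy, 3), "\n")
})
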