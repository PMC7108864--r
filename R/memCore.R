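# Pairwise maximum-entropy (Ising) core: exact Boltzmann distributions,
# Metropolis sampling, moment matching by gradient descent, and
# divergence-based goodness-of-fit. Pattern distributions are plain numeric
# vectors of length 2^N in the canonical order of patternMatrix().

#' Energy of a pattern under an Ising model
#'
#' \deqn{E(\sigma) = -\sum_i h_i\sigma_i - \tfrac12\sum_{ij}J_{ij}\sigma_i\sigma_j}
#'
#' @param model an \linkS4class{IsingModel}.
#' @param pattern a -1/+1 vector of length N.
#' @return the scalar energy.
#' @examples
#' energy(IsingModel(h = 0.5), +1)  # -0.5
#' @export
energy <- function(model, pattern) {
  if (length(pattern) != length(model@h)) stop("pattern has wrong length")
  if (!all(pattern %in% c(-1, 1))) stop("pattern must be -1/+1")
  -sum(model@h * pattern) - 0.5 * drop(pattern %*% model@J %*% pattern)
}

.energies <- function(model, patterns) {
  # energies of many patterns at once (rows of `patterns`)
  drop(-(patterns %*% model@h) -
         0.5 * rowSums((patterns %*% model@J) * patterns))
}

#' Exact Boltzmann distribution of an Ising model
#'
#' Enumerates all 2^N patterns and returns \eqn{P(\sigma)=e^{-E(\sigma)}/Z}
#' in canonical pattern order. Energies are shifted by their minimum before
#' exponentiation, so the result is invariant to adding a constant to all
#' energies and stable for large parameters.
#'
#' @param model an \linkS4class{IsingModel} with N <= 20.
#' @return numeric vector of 2^N probabilities summing to 1.
#' @export
boltzmannDistribution <- function(model) {
  N <- length(model@h)
  if (N > 20)
    stop("exact enumeration limited to N <= 20; use metropolisSample() for larger N")
  E <- .energies(model, patternMatrix(N))
  w <- exp(-(E - min(E)))
  as.numeric(w / sum(w))
}

#' Model moments: activation rates and pairwise moments
#'
#' Expectations \eqn{\langle\sigma_i\rangle} and
#' \eqn{\langle\sigma_i\sigma_j\rangle} under the model, either exactly
#' (pattern enumeration, N <= 20) or from a Metropolis sample.
#'
#' @param model an \linkS4class{IsingModel}.
#' @param method \code{"exact"} or \code{"metropolis"}.
#' @param nSamples Metropolis sample count (default 100000).
#' @param seed RNG seed for the Metropolis route.
#' @return list with \code{rates} (length N) and \code{pairs} (N x N
#'   symmetric matrix, unit diagonal).
#' @export
modelMoments <- function(model, method = c("exact", "metropolis"),
                         nSamples = 100000, seed = NULL) {
  method <- match.arg(method)
  if (method == "exact") {
    N <- length(model@h)
    P <- patternMatrix(N)
    p <- boltzmannDistribution(model)
    rates <- drop(p %*% P)
    pairs <- crossprod(P, P * p)
    diag(pairs) <- 1
    list(rates = rates, pairs = pairs)
  } else {
    if (nSamples < 1000) warning("fewer than 1000 Metropolis samples")
    empiricalMoments(metropolisSample(model, nSamples, seed = seed))
  }
}

#' Metropolis Monte Carlo sampling of Ising patterns
#'
#' Single-site-flip Metropolis chain: one sweep proposes N flips at
#' uniformly chosen sites with acceptance \eqn{\min(1, e^{-\Delta E})}; one
#' pattern is recorded per sweep after a burn-in of \code{burnin} sweeps.
#' The initial pattern is uniform random. Deterministic under \code{seed}.
#'
#' @param model an \linkS4class{IsingModel}.
#' @param nSamples number of recorded patterns.
#' @param seed integer seed (NULL: continue the caller's RNG stream).
#' @param burnin discarded initial sweeps (default 1000).
#' @return a nSamples x N matrix of -1/+1 patterns with attribute
#'   \code{unitIds}.
#' @export
metropolisSample <- function(model, nSamples, seed = NULL, burnin = 1000) {
  if (nSamples < 1) stop("nSamples must be >= 1")
  samples <- withSeed(seed,
    .metropolis_chain(model@h, model@J, as.integer(nSamples),
                      as.integer(burnin)))
  attr(samples, "unitIds") <- model@unitIds
  samples
}

#' Empirical moments of pattern samples
#'
#' @param samples a samples x N matrix of -1/+1 patterns.
#' @return list with \code{rates} and \code{pairs} as in
#'   \code{\link{modelMoments}}.
#' @export
empiricalMoments <- function(samples) {
  if (nrow(samples) < 1) stop("need at least one sample")
  list(rates = colMeans(samples),
       pairs = crossprod(samples) / nrow(samples))
}

#' Empirical pattern distribution
#'
#' Relative frequencies over the 2^N canonical patterns; unobserved
#' patterns get probability 0.
#'
#' @param samples a samples x N matrix of -1/+1 patterns (N <= 20).
#' @return numeric vector of 2^N probabilities.
#' @export
empiricalDistribution <- function(samples) {
  N <- ncol(samples)
  if (N > 20) stop("empirical distribution limited to N <= 20")
  tabulate(patternIndex(samples), nbins = 2^N) / nrow(samples)
}

.clipRates <- function(rates, eps = 1e-4) {
  clipped <- pmin(pmax(rates, -1 + eps), 1 - eps)
  if (any(clipped != rates))
    message("degenerate unit(s) (always silent/active): rates clipped before atanh")
  clipped
}

.momentsOf <- function(model, momentMethod, nMc) {
  if (momentMethod == "exact") modelMoments(model, "exact")
  else empiricalMoments(metropolisSample(model, nMc))
}

.fitLoop <- function(targets, unitIds, epoch, alpha, tol, maxIter,
                     momentMethod, nMc, pairwise) {
  N <- length(targets$rates)
  h <- atanh(.clipRates(targets$rates))
  J <- matrix(0, N, N)
  up <- upper.tri(J)
  iter <- 0L
  repeat {
    model <- IsingModel(h, J, unitIds = unitIds, epoch = epoch)
    mm <- .momentsOf(model, momentMethod, nMc)
    dh <- mm$rates - targets$rates
    dJ <- mm$pairs - targets$pairs
    disc <- max(abs(dh), if (pairwise) abs(dJ[up]) else 0)
    if (disc < tol || iter >= maxIter) break
    # simultaneous gradient-descent updates, learning rate alpha
    h <- h - alpha * dh
    if (pairwise) {
      J <- J - alpha * dJ
      diag(J) <- 0
    }
    iter <- iter + 1L
  }
  new("FitResult", model = model, converged = disc < tol,
      iterations = iter, discrepancy = disc,
      targetRates = targets$rates, targetPairs = targets$pairs,
      momentMethod = momentMethod)
}

#' Fit a pairwise maximum-entropy model by gradient descent
#'
#' Matches the empirical activation rates and pairwise moments of the
#' samples by iterating simultaneous updates
#' \eqn{h_i \leftarrow h_i - \alpha(\langle\sigma_i\rangle_{model} -
#' \langle\sigma_i\rangle_{data})} and likewise for \eqn{J_{ij}}, starting
#' from the independent solution (\code{h = atanh} of clipped rates,
#' \code{J = 0}). Stops when the max-abs discrepancy over all N + N(N-1)/2
#' constrained moments drops below \code{tol}, or after \code{maxIter}
#' updates (then \code{converged} is FALSE).
#'
#' @param samples a samples x N matrix of -1/+1 patterns.
#' @param alpha learning rate (default 0.1).
#' @param tol moment tolerance (default 0.005).
#' @param maxIter maximum updates (default 100).
#' @param momentMethod \code{"exact"} (N <= 20) or \code{"metropolis"}.
#' @param nMc Metropolis samples per moment evaluation (default 100000).
#' @param seed RNG seed (used by the Metropolis route).
#' @return a \linkS4class{FitResult}.
#' @export
fitPairwise <- function(samples, alpha = 0.1, tol = 0.005, maxIter = 100,
                        momentMethod = c("exact", "metropolis"),
                        nMc = 100000, seed = NULL) {
  momentMethod <- match.arg(momentMethod)
  targets <- empiricalMoments(samples)
  unitIds <- attr(samples, "unitIds")
  if (is.null(unitIds)) unitIds <- seq_len(ncol(samples))
  epoch <- attr(samples, "epoch")
  if (is.null(epoch)) epoch <- NA_integer_
  withSeed(seed,
    .fitLoop(targets, unitIds, epoch, alpha, tol, maxIter,
             momentMethod, nMc, pairwise = TRUE))
}

#' Fit an independent maximum-entropy model (J = 0)
#'
#' Only the activation rates are constrained; couplings stay at zero. With
#' exact moments the solution is \code{h = atanh(rates)} and the fit
#' converges immediately.
#'
#' @inheritParams fitPairwise
#' @return a \linkS4class{FitResult} whose model has \code{J = 0}.
#' @export
fitIndependent <- function(samples, alpha = 0.1, tol = 0.005, maxIter = 100,
                           momentMethod = c("exact", "metropolis"),
                           nMc = 100000, seed = NULL) {
  momentMethod <- match.arg(momentMethod)
  targets <- empiricalMoments(samples)
  unitIds <- attr(samples, "unitIds")
  if (is.null(unitIds)) unitIds <- seq_len(ncol(samples))
  epoch <- attr(samples, "epoch")
  if (is.null(epoch)) epoch <- NA_integer_
  withSeed(seed,
    .fitLoop(targets, unitIds, epoch, alpha, tol, maxIter,
             momentMethod, nMc, pairwise = FALSE))
}

#' Kullback-Leibler divergence between pattern distributions (nats)
#'
#' \eqn{D_{KL}(P_1;P_2)=\sum_x P_1(x)\log(P_1(x)/P_2(x))}. Terms with
#' \eqn{P_1(x)=0} contribute 0; if \eqn{P_1} puts mass where \eqn{P_2} has
#' none the divergence is \code{Inf}.
#'
#' @param p1,p2 probability vectors of equal length.
#' @return the divergence in nats.
#' @export
klDivergence <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("distributions must have equal length")
  sel <- p1 > 0
  if (any(p2[sel] == 0)) return(Inf)
  sum(p1[sel] * log(p1[sel] / p2[sel]))
}

#' Jensen-Shannon divergence between pattern distributions (nats)
#'
#' \eqn{D_{JS}(P_1;P_2)=\tfrac12 D_{KL}(P_1;M)+\tfrac12 D_{KL}(P_2;M)} with
#' \eqn{M=(P_1+P_2)/2}; symmetric, finite, bounded by \eqn{\log 2}.
#'
#' @param p1,p2 probability vectors of equal length.
#' @return the divergence in nats.
#' @export
jsDivergence <- function(p1, p2) {
  m <- (p1 + p2) / 2
  0.5 * klDivergence(p1, m) + 0.5 * klDivergence(p2, m)
}

#' Kullback-Leibler ratio of pairwise over independent model fit
#'
#' \eqn{R = (D_1 - D_2)/D_1} with \eqn{D_k = D_{KL}(P_{data}; P_{model_k})}
#' for the independent (k = 1) and pairwise (k = 2) models. R approaches 1
#' when the pairwise model captures all structure the independent model
#' misses, and 0 when it adds nothing.
#'
#' @param pData empirical pattern distribution.
#' @param pIndependent independent-model distribution.
#' @param pPairwise pairwise-model distribution.
#' @return list with \code{R}, \code{D1} and \code{D2}; \code{R} is NA when
#'   \eqn{D_1 = 0} (data already independent-model distributed).
#' @export
klRatio <- function(pData, pIndependent, pPairwise) {
  D1 <- klDivergence(pData, pIndependent)
  D2 <- klDivergence(pData, pPairwise)
  R <- if (D1 == 0) NA_real_ else (D1 - D2) / D1
  list(R = R, D1 = D1, D2 = D2)
}

#' Serialize an Ising model (with fit metadata) to JSON
#'
#' @param fit a \linkS4class{FitResult} or \linkS4class{IsingModel}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
writeModelJson <- function(fit, path) {
  model <- if (is(fit, "FitResult")) fit@model else fit
  obj <- list(N = length(model@h), unit_ids = model@unitIds,
              h = model@h, J = model@J)
  if (!is.na(model@epoch)) obj$epoch <- model@epoch
  if (is(fit, "FitResult"))
    obj <- c(obj, list(converged = fit@converged, iterations = fit@iterations,
                       max_moment_error = fit@discrepancy,
                       moment_method = fit@momentMethod))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an Ising model from JSON written by \code{\link{writeModelJson}}
#'
#' @param path source file.
#' @return an \linkS4class{IsingModel}.
#' @export
readModelJson <- function(path) {
  obj <- jsonlite::fromJSON(path)
  IsingModel(obj$h, obj$J, unitIds = obj$unit_ids,
             epoch = if (is.null(obj$epoch)) NA_integer_ else obj$epoch)
}
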