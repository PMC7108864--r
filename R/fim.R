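# Fisher information matrices and stiff/sloppy sensitivity measures.
# For the pairwise maximum-entropy model the FIM equals the covariance of
# the observable vector x = [sigma_1..sigma_N, sigma_i sigma_j ...] under
# the model distribution; its leading eigenvectors are the stiff parameter
# combinations.

.eigenFixed <- function(F) {
  e <- eigen(F, symmetric = TRUE)
  vals <- e$values
  if (min(vals) < -1e-8)
    warning("FIM not PSD beyond tolerance; negative eigenvalues floored at 0")
  vals <- pmax(vals, 0)
  vecs <- e$vectors
  for (k in seq_len(ncol(vecs))) {           # sign: largest-|.| component > 0
    if (vecs[which.max(abs(vecs[, k])), k] < 0) vecs[, k] <- -vecs[, k]
  }
  list(values = vals, vectors = vecs)
}

#' Fisher information matrix of an Ising model
#'
#' Computes \eqn{FIM_{kl} = \langle x_k x_l\rangle - \langle x_k\rangle
#' \langle x_l\rangle} — the covariance of the observable vector under the
#' model — either exactly by pattern enumeration (N <= 20) or from a
#' Metropolis sample, together with its eigen-decomposition (descending
#' eigenvalues, sign-fixed orthonormal eigenvectors).
#'
#' @param model an \linkS4class{IsingModel}.
#' @param method \code{"exact"} or \code{"metropolis"}.
#' @param nSteps recorded Metropolis sweeps for the sampling route
#'   (default 500000).
#' @param seed RNG seed for the sampling route.
#' @return a \linkS4class{FimResult}.
#' @export
computeFim <- function(model, method = c("exact", "metropolis"),
                       nSteps = 500000, seed = NULL) {
  method <- match.arg(method)
  N <- length(model@h)
  if (method == "exact") {
    P <- patternMatrix(N)
    X <- observableVector(P)
    p <- boltzmannDistribution(model)
    mu <- drop(p %*% X)
    F <- crossprod(X, X * p) - tcrossprod(mu)
  } else {
    samples <- metropolisSample(model, nSteps, seed = seed)
    L <- N + N * (N - 1) / 2
    S1 <- numeric(L)
    S2 <- matrix(0, L, L)
    idx <- split(seq_len(nSteps), ceiling(seq_len(nSteps) / 50000))
    for (ch in idx) {                         # chunked: keeps memory modest
      Xc <- observableVector(samples[ch, , drop = FALSE])
      S1 <- S1 + colSums(Xc)
      S2 <- S2 + crossprod(Xc)
    }
    mu <- S1 / nSteps
    F <- S2 / nSteps - tcrossprod(mu)
    F <- (F + t(F)) / 2
  }
  e <- .eigenFixed(F)
  new("FimResult", fim = F, values = e$values, vectors = e$vectors,
      epoch = model@epoch, method = method)
}

#' Project epoch parameter vectors onto one epoch's FIM eigenvectors
#'
#' Raw (uncentered) projections \eqn{\nu_{t,k}\cdot\Omega(t')} for every
#' other epoch t' and every rank k.
#'
#' @param omegas matrix of flat parameter vectors, one row per epoch
#'   (see \code{\link{paramVector}}).
#' @param fimAtT the \linkS4class{FimResult} of the reference epoch.
#' @param t reference epoch row index (its row is excluded).
#' @return a (NE-1) x L matrix of projections, columns ordered by rank.
#' @export
projectParameters <- function(omegas, fimAtT, t) {
  omegas[-t, , drop = FALSE] %*% fimEigenvectors(fimAtT)
}

.popVar <- function(x) mean(x^2) - mean(x)^2  # population (1/n) variance

#' Variance of parameter projections as a function of eigenvector rank
#'
#' For each reference epoch t, the parameters of all other epochs are
#' projected onto the FIM eigenvectors at t and the variance of the
#' projections (population variance, so the 2-epoch case is defined) is
#' taken per rank; the profile is then averaged over reference epochs.
#' A rising profile means parameters drift along sloppy dimensions.
#'
#' @param fims list of \linkS4class{FimResult}, one per epoch.
#' @param omegas matrix of flat parameter vectors, one row per epoch.
#' @return numeric vector of length L: mean projection variance per rank.
#' @export
projectionVarianceByRank <- function(fims, omegas) {
  nE <- nrow(omegas)
  if (nE < 2) stop("need at least 2 epochs")
  profiles <- vapply(seq_len(nE), function(t) {
    proj <- projectParameters(omegas, fims[[t]], t)
    apply(proj, 2, .popVar)
  }, numeric(ncol(omegas)))
  rowMeans(profiles)
}

#' Ensemble sensitivity from the first FIM eigenvector
#'
#' \eqn{s_{ne,i} = \frac{1}{N_E}\sum_t |\nu_{t,1}(i)|}: each parameter's
#' average absolute contribution to the stiffest direction.
#'
#' @param fims list of \linkS4class{FimResult}, one per epoch.
#' @return numeric vector of length L.
#' @export
sensitivityFirstEig <- function(fims) {
  v1 <- vapply(fims, function(f) abs(fimEigenvectors(f)[, 1]),
               numeric(nrow(fimMatrix(fims[[1]]))))
  rowMeans(v1)
}

#' Ensemble sensitivity weighted over all eigenvectors
#'
#' \eqn{s^w_{ne,i} = \frac{1}{N_E}\sum_t \sum_k a_{t,k}|\nu_{t,k}(i)| /
#' \sum_k a_{t,k}}: contributions to every eigenvector, weighted by the
#' associated eigenvalues.
#'
#' @param fims list of \linkS4class{FimResult}, one per epoch.
#' @return numeric vector of length L.
#' @export
sensitivityWeighted <- function(fims) {
  per <- vapply(fims, function(f) {
    a <- fimEigenvalues(f)
    drop(abs(fimEigenvectors(f)) %*% a) / sum(a)
  }, numeric(nrow(fimMatrix(fims[[1]]))))
  rowMeans(per)
}

#' Aggregate ensemble sensitivities over the whole population
#'
#' The population index set I holds all Npop single units and all
#' Npop(Npop-1)/2 unit pairs. Each ensemble's length-L sensitivity vector
#' contributes its h-entries to the corresponding units and its J-entries
#' to the corresponding pairs; the population sensitivity of an element is
#' the mean over the ensembles covering it. Elements never covered are NA.
#'
#' @param sneMatrix Q x L matrix: one ensemble sensitivity vector per row
#'   (from \code{\link{sensitivityFirstEig}} or
#'   \code{\link{sensitivityWeighted}}).
#' @param ensembles list of Q sorted unit-id vectors (as from
#'   \code{\link{sampleEnsembles}}).
#' @param populationUnits all Npop single-unit ids.
#' @return data.frame with one row per element of I: \code{element}
#'   (\code{"u:<id>"} or \code{"p:<id1>-<id2>"}), \code{kind}
#'   (\code{unit}/\code{pair}), \code{i}, \code{j}, \code{s},
#'   \code{coverage}.
#' @export
aggregatePopulationSensitivity <- function(sneMatrix, ensembles,
                                           populationUnits) {
  populationUnits <- sort(populationUnits)
  npop <- length(populationUnits)
  pm <- pairIndexMap(npop)
  elems <- data.frame(
    element = c(paste0("u:", populationUnits),
                paste0("p:", populationUnits[pm$i], "-", populationUnits[pm$j])),
    kind = c(rep("unit", npop), rep("pair", nrow(pm))),
    i = c(populationUnits, populationUnits[pm$i]),
    j = c(rep(NA_integer_, npop), populationUnits[pm$j]))
  acc <- setNames(numeric(nrow(elems)), elems$element)
  cov <- setNames(integer(nrow(elems)), elems$element)
  for (q in seq_along(ensembles)) {
    u <- sort(ensembles[[q]])
    keys <- paramKeys(u)
    acc[keys] <- acc[keys] + sneMatrix[q, ]
    cov[keys] <- cov[keys] + 1L
  }
  elems$s <- ifelse(cov > 0, acc / pmax(cov, 1L), NA_real_)
  elems$coverage <- as.integer(cov)
  elems
}

#' Population element keys for an ensemble's parameter ordering
#'
#' @param sortedUnits sorted unit ids of one ensemble.
#' @return character keys \code{"u:<id>"} then \code{"p:<i>-<j>"} matching
#'   the canonical parameter ordering.
#' @export
paramKeys <- function(sortedUnits) {
  pm <- pairIndexMap(length(sortedUnits))
  c(paste0("u:", sortedUnits),
    paste0("p:", sortedUnits[pm$i], "-", sortedUnits[pm$j]))
}

#' Median split of sensitivities into sloppy and stiff classes
#'
#' Elements below the median are sloppy, above it stiff; elements exactly
#' at the median join the sloppy class. NA sensitivities stay unlabelled.
#'
#' @param s numeric sensitivities.
#' @return character vector of \code{"sloppy"}/\code{"stiff"}/NA.
#' @export
medianSplit <- function(s) {
  ok <- !is.na(s)
  if (!any(ok)) return(rep(NA_character_, length(s)))
  med <- median(s[ok])
  if (all(s[ok] == med))
    warning("all sensitivities equal; every element labelled sloppy")
  out <- rep(NA_character_, length(s))
  out[ok] <- ifelse(s[ok] <= med, "sloppy", "stiff")
  out
}

#' Stationary surrogates: repeated refits of one fixed model
#'
#' Draws NE independent Metropolis samples of \code{nPatterns} patterns
#' from a single reference model, refits a pairwise model to each, and
#' computes each refit's FIM. All parameter fluctuation across the NE
#' surrogate epochs is therefore model-estimation error, the null against
#' which genuine parameter drift is judged.
#'
#' @param model the reference \linkS4class{IsingModel}.
#' @param nE number of surrogate epochs.
#' @param nPatterns patterns per surrogate epoch (default 5000).
#' @param seed integer seed.
#' @param alpha,tol,maxIter fitting controls (see \code{\link{fitPairwise}}).
#' @param fimMethod FIM method for the refits (default exact).
#' @return list with \code{fits}, \code{fims}, and \code{omegas}
#'   (nE x L matrix of refit parameter vectors).
#' @export
makeStationarySurrogates <- function(model, nE, nPatterns = 5000, seed = 1,
                                     alpha = 0.1, tol = 0.005, maxIter = 100,
                                     fimMethod = "exact") {
  withSeed(seed, {
    fits <- vector("list", nE)
    fims <- vector("list", nE)
    for (t in seq_len(nE)) {
      samples <- metropolisSample(model, nPatterns)
      attr(samples, "unitIds") <- model@unitIds
      attr(samples, "epoch") <- t
      fits[[t]] <- fitPairwise(samples, alpha = alpha, tol = tol,
                               maxIter = maxIter, momentMethod = "exact")
      fims[[t]] <- computeFim(fittedModel(fits[[t]]), method = fimMethod)
    }
    omegas <- t(vapply(fits, function(f) paramVector(fittedModel(f)),
                       numeric(length(paramVector(model)))))
    list(fits = fits, fims = fims, omegas = omegas)
  })
}

#' Split-half reliability of the sensitivity measure
#'
#' Pearson correlation between sensitivities computed from the first and
#' second halves of the epochs. With \code{ensembles} and
#' \code{populationUnits} supplied, the comparison is at the population
#' level over covered elements; otherwise over one ensemble's L parameters.
#'
#' @param fimsPerEnsemble list (length Q) of per-epoch
#'   \linkS4class{FimResult} lists.
#' @param ensembles optional list of sorted unit-id vectors.
#' @param populationUnits optional vector of all single-unit ids.
#' @return the correlation coefficient.
#' @export
splitHalfSensitivityReliability <- function(fimsPerEnsemble, ensembles = NULL,
                                            populationUnits = NULL) {
  nE <- length(fimsPerEnsemble[[1]])
  first <- seq_len(floor(nE / 2))
  second <- setdiff(seq_len(nE), first)
  sHalf <- function(idx) {
    m <- t(vapply(fimsPerEnsemble,
                  function(fims) sensitivityFirstEig(fims[idx]),
                  numeric(nrow(fimMatrix(fimsPerEnsemble[[1]][[1]])))))
    if (is.null(ensembles)) drop(m)
    else aggregatePopulationSensitivity(m, ensembles, populationUnits)$s
  }
  s1 <- sHalf(first)
  s2 <- sHalf(second)
  ok <- !is.na(s1) & !is.na(s2)
  cor(s1[ok], s2[ok])
}
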