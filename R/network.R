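# Functional-connectivity graph: significance-thresholded mean pairwise
# correlations, betweenness centrality, and neuron-to-population coupling.

#' Build the significant-correlation graph
#'
#' For each unit pair, the NE per-epoch Pearson correlations are tested
#' against zero (one-sample t-test) with Bonferroni correction over all
#' pairs; an (unweighted, sign-agnostic) edge is placed where the corrected
#' p is below \code{alpha}. A pair whose correlation series has zero
#' variance but nonzero mean is treated as significant, with a warning.
#'
#' @param corSeries NE x Npairs matrix of per-epoch correlations, columns
#'   ordered as \code{\link{pairIndexMap}} over the sorted units.
#' @param units sorted unit ids (graph nodes).
#' @param alpha family-wise significance level (default 0.05).
#' @return list with \code{adjacency} (binary symmetric matrix),
#'   \code{edges} (data.frame i, j, mean_r, p_corrected) and \code{graph}
#'   (an igraph object).
#' @export
buildGraph <- function(corSeries, units, alpha = 0.05) {
  nE <- nrow(corSeries)
  if (nE < 3) stop("need at least 3 epochs to test correlations")
  npop <- length(units)
  pm <- pairIndexMap(npop)
  nTests <- nrow(pm)
  pRaw <- vapply(seq_len(nTests), function(k) {
    v <- corSeries[, k]
    v <- v[!is.na(v)]
    if (length(v) < 3) return(NA_real_)
    if (sd(v) == 0) {
      if (mean(v) != 0) {
        warning("zero-variance nonzero correlation series: treated as significant")
        return(0)
      }
      return(1)
    }
    t.test(v, mu = 0)$p.value
  }, numeric(1))
  pCorr <- pmin(pRaw * nTests, 1)
  adj <- matrix(0L, npop, npop, dimnames = list(units, units))
  sig <- !is.na(pCorr) & pCorr < alpha
  adj[cbind(pm$i[sig], pm$j[sig])] <- 1L
  adj <- adj + t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(adjacency = adj,
       edges = data.frame(i = units[pm$i], j = units[pm$j],
                          mean_r = colMeans(corSeries, na.rm = TRUE),
                          p_corrected = pCorr)[sig, , drop = FALSE],
       graph = g)
}

#' Betweenness centrality of the functional graph
#'
#' \eqn{BC(i) = \sum_{k\neq i\neq l} p(kl;i)/p(kl)} over unordered node
#' pairs, with unweighted shortest paths; disconnected pairs contribute 0.
#'
#' @param graphResult output of \code{\link{buildGraph}} (or an igraph
#'   object).
#' @return named numeric vector of BC per node.
#' @export
betweenness <- function(graphResult) {
  g <- if (igraph::is_igraph(graphResult)) graphResult else graphResult$graph
  igraph::betweenness(g, directed = FALSE, normalized = FALSE)
}

#' Neuron-to-population coupling
#'
#' Per epoch, the Pearson correlation between a unit's -1/+1 train and the
#' number of co-active other single units per bin (the unit itself
#' excluded), averaged over epochs.
#'
#' @param rasters list of per-epoch -1/+1 rasters (units x bins, from
#'   \code{\link{binarize}} over single units).
#' @return named numeric vector: mean coupling per unit.
#' @export
populationCoupling <- function(rasters) {
  units <- rownames(rasters[[1]])
  perEpoch <- vapply(rasters, function(r) {
    active <- r == 1
    totals <- colSums(active)
    vapply(seq_len(nrow(r)), function(i) {
      others <- totals - active[i, ]
      if (sd(r[i, ]) == 0 || sd(others) == 0) return(NA_real_)
      cor(r[i, ], others)
    }, numeric(1))
  }, numeric(length(units)))
  setNames(rowMeans(perEpoch, na.rm = TRUE), units)
}

#' Stiff vs sloppy separation for topology and activity measures
#'
#' For each supplied per-unit (or per-pair) quantity, computes the
#' ROC/AUC between the stiff and sloppy classes with a permutation
#' p-value; also reports the correlation between betweenness centrality
#' and firing rate when both are present.
#'
#' @param quantities named list of numeric vectors, all aligned with
#'   \code{labels}.
#' @param labels character vector of \code{"stiff"}/\code{"sloppy"}/NA.
#' @param nPerm permutations (default 1000).
#' @param seed RNG seed.
#' @return list with \code{auc} (data.frame quantity, AUC, p, n_sloppy,
#'   n_stiff) and \code{bc_rate_correlation} (NA if not computable).
#' @export
topologyClassComparison <- function(quantities, labels, nPerm = 1000,
                                    seed = 1) {
  rows <- lapply(names(quantities), function(nm) {
    v <- quantities[[nm]]
    ok <- !is.na(v) & !is.na(labels)
    roc <- rocAuc(v[ok], labels[ok])
    p <- permutationTest(v[ok], labels[ok], nPerm = nPerm, seed = seed)
    data.frame(quantity = nm, AUC = roc$auc, p = p,
               n_sloppy = roc$n_sloppy, n_stiff = roc$n_stiff)
  })
  bcr <- if (all(c("BC", "rate") %in% names(quantities))) {
    ok <- !is.na(quantities$BC) & !is.na(quantities$rate)
    if (sum(ok) >= 3 && sd(quantities$BC[ok]) > 0 && sd(quantities$rate[ok]) > 0)
      cor(quantities$BC[ok], quantities$rate[ok]) else NA_real_
  } else NA_real_
  list(auc = do.call(rbind, rows), bc_rate_correlation = bcr)
}
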