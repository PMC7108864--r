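#' Index map between pair parameters and unit pairs
#'
#' Pair parameters (couplings J_ij) are ordered row-major over the upper
#' triangle: (1,2), (1,3), ..., (1,N), (2,3), ..., (N-1,N). This map pins
#' the ordering shared by \code{\link{paramVector}},
#' \code{\link{observableVector}} and the FIM.
#'
#' @param N ensemble size.
#' @return data.frame with columns \code{i}, \code{j} (i < j) and
#'   \code{index} (position within the pair block).
#' @examples
#' pairIndexMap(3)  # (1,2), (1,3), (2,3)
#' @export
pairIndexMap <- function(N) {
  if (N < 2) return(data.frame(i = integer(0), j = integer(0), index = integer(0)))
  i <- rep(seq_len(N - 1), times = (N - 1):1)
  j <- unlist(lapply(seq_len(N - 1), function(a) (a + 1):N))
  data.frame(i = i, j = j, index = seq_along(i))
}

#' Enumerate all 2^N patterns in canonical order
#'
#' Canonical order is binary counting with -1 as 0 and +1 as 1, unit 1 the
#' most significant bit: row 1 is all -1, row 2^N is all +1.
#'
#' @param N number of units (N <= 20).
#' @return a 2^N x N matrix of -1/+1 values.
#' @export
patternMatrix <- function(N) {
  if (N > 20) stop("pattern enumeration limited to N <= 20")
  codes <- 0:(2^N - 1)
  bits <- sapply(seq_len(N), function(i) bitwAnd(codes %/% 2^(N - i), 1L))
  matrix(2L * bits - 1L, ncol = N)
}

#' Canonical index of patterns
#'
#' @param patterns matrix of -1/+1 rows (or a single pattern vector).
#' @return 1-based indices into the canonical pattern order.
#' @export
patternIndex <- function(patterns) {
  if (is.null(dim(patterns))) patterns <- matrix(patterns, nrow = 1)
  N <- ncol(patterns)
  bits <- (patterns + 1) / 2
  as.integer(bits %*% 2^((N - 1):0)) + 1L
}

#' Observable vector(s) for patterns
#'
#' Maps a pattern sigma to
#' \code{x = [sigma_1..sigma_N, sigma_1 sigma_2, sigma_1 sigma_3, ...]},
#' the sufficient statistics of the pairwise maximum-entropy model, in the
#' ordering of \code{\link{pairIndexMap}}.
#'
#' @param patterns a -1/+1 pattern vector, or a matrix with one pattern per
#'   row.
#' @return a vector of length N + N(N-1)/2, or a matrix with one such row
#'   per pattern.
#' @export
observableVector <- function(patterns) {
  single <- is.null(dim(patterns))
  if (single) patterns <- matrix(patterns, nrow = 1)
  if (!all(patterns %in% c(-1, 1))) stop("patterns must be -1/+1")
  pm <- pairIndexMap(ncol(patterns))
  x <- cbind(patterns, patterns[, pm$i, drop = FALSE] * patterns[, pm$j, drop = FALSE])
  colnames(x) <- NULL
  if (single) x[1, ] else x
}

#' Human-readable labels for the canonical parameter ordering
#'
#' @param unitIds unit ids of the ensemble, in ensemble order.
#' @return character vector: \code{"h:<id>"} for biases then
#'   \code{"J:<id1>-<id2>"} for couplings.
#' @export
paramLabels <- function(unitIds) {
  N <- length(unitIds)
  pm <- pairIndexMap(N)
  c(paste0("h:", unitIds),
    paste0("J:", unitIds[pm$i], "-", unitIds[pm$j]))
}
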