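# ROC/AUC separation between sloppy and stiff classes, with permutation
# testing. The AUC is the Mann-Whitney rank statistic with half-credit for
# ties; AUC = 1 means every stiff value exceeds every sloppy value.

#' Area under the ROC curve separating stiff from sloppy values
#'
#' Computed as the normalized rank-sum statistic, equivalent to sweeping a
#' threshold over both class distributions: AUC = P(X_stiff > X_sloppy) +
#' 0.5 P(X_stiff = X_sloppy). Values near 1 mean the stiff class dominates,
#' near 0 the sloppy class, 0.5 indistinguishable.
#'
#' @param values numeric vector.
#' @param labels character vector of \code{"sloppy"}/\code{"stiff"}.
#' @return list with \code{auc}, \code{n_sloppy}, \code{n_stiff}.
#' @export
rocAuc <- function(values, labels) {
  stiff <- labels == "stiff"
  n1 <- sum(stiff); n0 <- sum(!stiff)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")
  r <- rank(values)               # midranks give half-credit for ties
  auc <- (sum(r[stiff]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = auc, n_sloppy = n0, n_stiff = n1)
}

#' Permutation p-value for an AUC
#'
#' Labels are randomly reassociated with the values \code{nPerm} times;
#' the two-sided p-value is
#' \eqn{p = (1 + \#\{|AUC_{perm} - 0.5| \ge |AUC_{obs} - 0.5|\})/(n_{perm}+1)}.
#'
#' @param values numeric vector.
#' @param labels character \code{"sloppy"}/\code{"stiff"} labels.
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return the p-value.
#' @export
permutationTest <- function(values, labels, nPerm = 1000, seed = 1) {
  obs <- abs(rocAuc(values, labels)$auc - 0.5)
  exceed <- withSeed(seed, sum(vapply(seq_len(nPerm), function(i)
    abs(rocAuc(values, sample(labels))$auc - 0.5) >= obs, logical(1))))
  (1 + exceed) / (nPerm + 1)
}
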