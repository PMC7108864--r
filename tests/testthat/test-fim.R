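test_that("FIM equals the observable covariance under the model", {
  # zero model: unit variances 1 on the h-block, everything uncorrelated
  f0 <- computeFim(IsingModel(h = rep(0, 4)))
  expect_equal(fimMatrix(f0), diag(10))
  # random N = 4 models vs the enumeration oracle
  set.seed(8)
  for (rep in 1:3) {
    h <- rnorm(4, -0.5, 0.5)
    J <- matrix(0, 4, 4); J[upper.tri(J)] <- rnorm(6, 0, 0.3); J <- J + t(J)
    f <- computeFim(IsingModel(h, J))
    expect_equal(fimMatrix(f), enumFim(h, J), tolerance = 1e-12)
    # eigenpairs: descending, orthonormal, PSD
    v <- fimEigenvalues(f)
    expect_true(all(diff(v) <= 1e-12))
    expect_gte(min(v), 0)
    V <- fimEigenvectors(f)
    expect_equal(crossprod(V), diag(10), tolerance = 1e-8)
  }
  # Metropolis FIM approximates the exact one
  m <- randomIsingModel(5, seed = 4)
  fx <- computeFim(m)
  fs <- computeFim(m, "metropolis", nSteps = 60000, seed = 3)
  expect_lt(max(abs(fimMatrix(fx) - fimMatrix(fs))), 0.05)
})

test_that("KL divergence between nearby models is the FIM quadratic form", {
  m <- randomIsingModel(4, hRange = c(-1, 0), jSd = 0.2, seed = 5)
  f <- computeFim(m)
  omega <- paramVector(m)
  set.seed(6)
  for (rep in 1:3) {
    delta <- rnorm(10)
    delta <- delta / sqrt(sum(delta^2)) * 1e-3
    m2 <- modelFromParamVector(omega + delta)
    dkl <- klDivergence(boltzmannDistribution(m), boltzmannDistribution(m2))
    quad <- 0.5 * drop(delta %*% fimMatrix(f) %*% delta)
    expect_lt(abs(dkl - quad) / quad, 0.05)
  }
  # slope-2 scaling: DKL drops ~100-fold when the step shrinks 10-fold
  delta <- rep(1e-3 / sqrt(10), 10)
  d1 <- klDivergence(boltzmannDistribution(m),
                     boltzmannDistribution(modelFromParamVector(omega + delta)))
  d2 <- klDivergence(boltzmannDistribution(m),
                     boltzmannDistribution(modelFromParamVector(omega + delta / 10)))
  expect_equal(d1 / d2, 100, tolerance = 2)
})

test_that("parameter projections obey orthonormality and the variance rules", {
  m <- randomIsingModel(4, seed = 9)
  f <- computeFim(m)
  V <- fimEigenvectors(f)
  omegas <- rbind(V[, 1], V[, 1], V[, 1])   # three epochs at nu_1
  proj <- projectParameters(omegas, f, t = 1)
  expect_equal(proj[1, ], c(1, rep(0, 9)), tolerance = 1e-8)
  # constant parameters give zero variance at every rank
  expect_equal(projectionVarianceByRank(list(f, f, f), omegas),
               rep(0, 10))
  # two epochs: population variance keeps the profile defined
  om2 <- rbind(rnorm(10), rnorm(10))
  pv <- projectionVarianceByRank(list(f, f), om2)
  expect_length(pv, 10)
  expect_true(all(pv >= 0))
  # drift injected along the last eigenvector loads the last rank
  omD <- t(sapply(seq(-1, 1, length.out = 9), function(a) a * V[, 10]))
  pvD <- projectionVarianceByRank(rep(list(f), 9), omD)
  expect_equal(which.max(pvD), 10)
  # naive-loop oracle for a random series
  set.seed(10)
  omR <- matrix(rnorm(50), 5, 10)
  fims <- rep(list(f), 5)
  pvPkg <- projectionVarianceByRank(fims, omR)
  pvLoop <- numeric(10)
  for (t in 1:5) for (k in 1:10) {
    pr <- sapply(setdiff(1:5, t), function(u) sum(V[, k] * omR[u, ]))
    pvLoop[k] <- pvLoop[k] + (mean(pr^2) - mean(pr)^2) / 5
  }
  expect_equal(pvPkg, pvLoop, tolerance = 1e-12)
})

test_that("sensitivity measures average eigenvector contributions", {
  # single epoch with nu_1 = e_3
  m <- randomIsingModel(3, seed = 2)
  f <- computeFim(m)
  e3 <- diag(6)[, 3]
  fake <- new("FimResult", fim = fimMatrix(f),
              values = sort(c(5, rep(1, 5)), decreasing = TRUE),
              vectors = cbind(e3, diag(6)[, -3]),
              epoch = 1L, method = "exact")
  expect_equal(sensitivityFirstEig(list(fake)), e3)
  # hand-averaged two-epoch case
  fake2 <- new("FimResult", fim = fimMatrix(f),
               values = sort(c(5, rep(1, 5)), decreasing = TRUE),
               vectors = cbind(diag(6)[, 1], diag(6)[, -1]),
               epoch = 2L, method = "exact")
  expect_equal(sensitivityFirstEig(list(fake, fake2)),
               (e3 + diag(6)[, 1]) / 2)
  # weighted sensitivity: dominant first eigenvalue recovers the
  # first-eigenvector measure; equal eigenvalues average all columns
  V <- fimEigenvectors(f)
  big <- new("FimResult", fim = fimMatrix(f),
             values = c(1e8, rep(1, 5)) / 1, vectors = V,
             epoch = 1L, method = "exact")
  expect_equal(sensitivityWeighted(list(big)), abs(V[, 1]),
               tolerance = 1e-6)
  flat <- new("FimResult", fim = fimMatrix(f),
              values = rep(2, 6), vectors = V, epoch = 1L, method = "exact")
  expect_equal(sensitivityWeighted(list(flat)), rowMeans(abs(V)))
  # each component of s_ne lies in [0, 1]
  s <- sensitivityFirstEig(list(f))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("population aggregation covers units and pairs correctly", {
  # L formula: Npop = 72 gives 72 + 2556 elements
  agg <- aggregatePopulationSensitivity(
    matrix(1, 1, 3), list(c(5, 9)), populationUnits = c(5, 9, 11))
  expect_equal(nrow(aggregatePopulationSensitivity(
    matrix(1, 1, 2628)[, 1:3, drop = FALSE], list(c(1, 2)), 1:2)), 3)
  popTable <- aggregatePopulationSensitivity(
    matrix(seq_len(3), 1, 3), list(c(5, 9)), populationUnits = c(5, 9, 11))
  # ensemble (5,9): h-entries map to units 5 and 9, J-entry to pair 5-9
  expect_equal(popTable$s[popTable$element == "u:5"], 1)
  expect_equal(popTable$s[popTable$element == "u:9"], 2)
  expect_equal(popTable$s[popTable$element == "p:5-9"], 3)
  expect_true(is.na(popTable$s[popTable$element == "u:11"]))
  expect_equal(popTable$coverage[popTable$element == "p:5-11"], 0)
  # a unit in exactly one ensemble inherits that ensemble's value;
  # a unit in two ensembles gets their mean
  agg2 <- aggregatePopulationSensitivity(
    rbind(c(1, 1, 1), c(3, 3, 3)), list(c(1, 2), c(2, 3)), 1:3)
  expect_equal(agg2$s[agg2$element == "u:1"], 1)
  expect_equal(agg2$s[agg2$element == "u:2"], 2)
  expect_equal(agg2$coverage[agg2$element == "u:2"], 2)
  # L for Npop = 72
  full <- aggregatePopulationSensitivity(matrix(1, 1, 55),
                                         list(sort(sample(1:72, 10))), 1:72)
  expect_equal(nrow(full), 72 + 72 * 71 / 2)
  # empirical pair coverage tracks the sampling fraction
  set.seed(12)
  ens <- sampleEnsembles(1:81, N = 10, Q = 20, seed = 2)
  cov81 <- aggregatePopulationSensitivity(matrix(0, 20, 55),
                                          ens$ensembles, 1:81)
  frac <- mean(cov81$coverage[cov81$kind == "pair"] > 0)
  expected <- 1 - (1 - 45 / 3240)^20
  expect_equal(frac, expected, tolerance = 0.25)
})

test_that("median split labels by rank with sloppy ties", {
  expect_equal(medianSplit(c(1, 2, 3, 4)),
               c("sloppy", "sloppy", "stiff", "stiff"))
  expect_warning(lab <- medianSplit(rep(2, 5)), "equal")
  expect_true(all(lab == "sloppy"))
  s <- runif(20)
  expect_equal(medianSplit(s), medianSplit(exp(5 * s)))  # monotone invariant
  expect_equal(medianSplit(c(1, NA, 3))[2], NA_character_)
})

test_that("stationary surrogates reproduce the reference model on average", {
  m <- randomIsingModel(4, seed = 3)
  ss <- makeStationarySurrogates(m, nE = 8, nPatterns = 3000, seed = 4,
                                 maxIter = 500)
  expect_length(ss$fits, 8)
  # under the standard controls the moment tolerance leaves a bounded,
  # systematic parameter offset along sloppy directions
  expect_lt(max(abs(colMeans(ss$omegas) - paramVector(m))), 0.2)
  # tightening the tolerance removes it: bias within sampling error
  tight <- makeStationarySurrogates(m, nE = 12, nPatterns = 3000, seed = 4,
                                    tol = 5e-4, maxIter = 5000)
  dev <- colMeans(tight$omegas) - paramVector(m)
  se <- apply(tight$omegas, 2, sd) / sqrt(12)
  expect_lt(max(abs(dev) / pmax(3 * se, 0.02)), 1)
  expect_identical(
    makeStationarySurrogates(m, nE = 2, nPatterns = 500, seed = 9)$omegas,
    makeStationarySurrogates(m, nE = 2, nPatterns = 500, seed = 9)$omegas)
})

test_that("split-half sensitivity reliability hits its reference points", {
  m <- randomIsingModel(3, seed = 5)
  f <- computeFim(m)
  # identical halves correlate perfectly
  expect_equal(splitHalfSensitivityReliability(list(list(f, f))), 1)
})
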