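test_that("energy matches the explicit Ising sum", {
  N <- 3
  m0 <- IsingModel(h = rep(0, N))
  P <- patternMatrix(N)
  for (r in 1:8) expect_equal(energy(m0, P[r, ]), 0)
  expect_equal(energy(IsingModel(h = 0.5), +1), -0.5)
  set.seed(42)
  for (rep in 1:5) {
    h <- rnorm(N)
    J <- matrix(0, N, N); J[upper.tri(J)] <- rnorm(3); J <- J + t(J)
    m <- IsingModel(h, J)
    s <- sample(c(-1, 1), N, replace = TRUE)
    expect_equal(energy(m, s), bruteEnergy(h, J, s))
  }
  expect_error(energy(m0, c(1, -1)), "length")
})

test_that("Boltzmann distribution equals enumeration and closed forms", {
  # zero parameters: uniform over the 2^10 = 1024 patterns
  u <- boltzmannDistribution(IsingModel(h = rep(0, 10)))
  expect_length(u, 1024)
  expect_equal(u, rep(1 / 1024, 1024))
  # N = 1 closed form
  p <- boltzmannDistribution(IsingModel(h = 0.5))
  expect_equal(p[2], 1 / (1 + exp(-1)), tolerance = 1e-12)
  # random N = 4 models vs the expand.grid enumeration oracle
  set.seed(7)
  for (rep in 1:3) {
    h <- rnorm(4); J <- matrix(0, 4, 4)
    J[upper.tri(J)] <- rnorm(6, 0, 0.5); J <- J + t(J)
    expect_equal(boltzmannDistribution(IsingModel(h, J)),
                 enumDistribution(h, J), tolerance = 1e-12)
  }
  # invariance to constant energy shifts comes with normalization
  expect_equal(sum(boltzmannDistribution(IsingModel(h = rnorm(6) + 50))), 1)
  expect_error(boltzmannDistribution(IsingModel(h = rep(0, 21))),
               "metropolisSample")
})

test_that("model moments: closed forms and Metropolis agreement", {
  mm <- modelMoments(IsingModel(h = rep(0, 4)))
  expect_equal(mm$rates, rep(0, 4))
  expect_equal(mm$pairs - diag(4), matrix(0, 4, 4))
  expect_equal(modelMoments(IsingModel(h = 0.5))$rates, tanh(0.5))
  # metropolis moments within Monte Carlo error of exact ones
  m <- randomIsingModel(5, seed = 2)
  ex <- modelMoments(m, "exact")
  mc <- modelMoments(m, "metropolis", nSamples = 1e5, seed = 9)
  se <- sqrt((1 - ex$rates^2) / 1e5)
  expect_true(all(abs(mc$rates - ex$rates) < pmax(3 * 5 * se, 0.02)))
  expect_lt(max(abs(mc$pairs - ex$pairs)), 0.03)
  expect_warning(modelMoments(m, "metropolis", nSamples = 500), "1000")
})

test_that("Metropolis sampling is seeded and converges to the Boltzmann law", {
  strong <- IsingModel(h = rep(10, 4))
  s <- metropolisSample(strong, 500, seed = 1)
  expect_gt(mean(s == 1), 0.999)
  m <- randomIsingModel(5, seed = 3)
  expect_identical(metropolisSample(m, 200, seed = 5),
                   metropolisSample(m, 200, seed = 5))
  # empirical vs exact distribution at N = 5
  samp <- metropolisSample(m, 1e5, seed = 11)
  djs <- jsDivergence(empiricalDistribution(samp), boltzmannDistribution(m))
  expect_lt(djs, 0.01)
  # and the divergence shrinks as the sample grows
  djsSmall <- jsDivergence(empiricalDistribution(samp[1:2000, ]),
                           boltzmannDistribution(m))
  expect_lt(djs, djsSmall)
})

test_that("empirical moments and distributions match hand computation", {
  silent <- matrix(-1, 10, 3)
  em <- empiricalMoments(silent)
  expect_equal(em$rates, rep(-1, 3))
  expect_equal(em$pairs, matrix(1, 3, 3))
  alt <- rbind(c(1, -1), c(-1, 1), c(1, -1), c(-1, 1))
  expect_equal(empiricalMoments(alt)$pairs[1, 2], -1)
  toy <- rbind(c(1, 1), c(1, -1), c(-1, -1), c(1, 1))
  em2 <- empiricalMoments(toy)
  expect_equal(em2$rates, c(0.5, 0))
  expect_equal(em2$pairs[1, 2], 0.5)
  d <- empiricalDistribution(toy)
  expect_equal(sum(d), 1)
  expect_equal(d[patternIndex(c(1, 1))], 0.5)
  expect_equal(d[patternIndex(c(-1, -1))], 0.25)
  onePat <- matrix(rep(c(1, -1), 5), 5, 2, byrow = TRUE)
  expect_equal(max(empiricalDistribution(onePat)), 1)
})

test_that("pairwise fit matches moments and recovers ground truth", {
  # independent data leave the couplings near zero
  ind <- IsingModel(h = runif(6, -1.5, -0.5))
  sampI <- metropolisSample(ind, 5000, seed = 21)
  fitI <- fitPairwise(sampI, maxIter = 500)
  expect_lt(max(abs(couplings(fittedModel(fitI)))), 0.15)
  # recovery at N = 5 with exact moments
  gt <- randomIsingModel(5, seed = 13)
  samp <- metropolisSample(gt, 5000, seed = 14)
  fit <- fitPairwise(samp, maxIter = 500)
  expect_true(isConverged(fit))
  expect_lt(fit@discrepancy, 0.005)
  # converged fit reproduces its own target moments within tol
  mm <- modelMoments(fittedModel(fit))
  expect_lt(max(abs(mm$rates - fit@targetRates)), 0.005)
  expect_lt(max(abs(mm$pairs - fit@targetPairs)[upper.tri(mm$pairs)]), 0.005)
  expect_gt(cor(paramVector(gt), paramVector(fittedModel(fit))), 0.9)
  # parameter count for N = 10
  expect_length(paramVector(randomIsingModel(10, seed = 1)), 55)
  expect_equal(paramVector(modelFromParamVector(paramVector(gt))),
               paramVector(gt))
})

test_that("independent fit solves h = atanh(rates) and factorizes", {
  samp <- metropolisSample(IsingModel(h = c(0.4, -0.6, 0.1)), 20000, seed = 2)
  fit <- fitIndependent(samp)
  expect_true(isConverged(fit))
  m <- fittedModel(fit)
  expect_equal(couplings(m), matrix(0, 3, 3))
  expect_equal(biases(m), atanh(empiricalMoments(samp)$rates),
               tolerance = 0.02)
  # distribution factorizes over units
  p <- boltzmannDistribution(m)
  pi1 <- 1 / (1 + exp(-2 * biases(m)))          # P(sigma_i = +1)
  P <- patternMatrix(3)
  pFac <- apply(P, 1, function(s) prod(ifelse(s == 1, pi1, 1 - pi1)))
  expect_equal(p, unname(pFac), tolerance = 1e-10)
  # degenerate all-silent unit is clipped, with a message
  silent <- cbind(matrix(sample(c(-1, 1), 200, TRUE), 100, 2), -1)
  expect_message(fitIndependent(silent), "clipped")
})

test_that("divergences satisfy their defining identities", {
  p <- c(0.2, 0.3, 0.5); q <- c(0.3, 0.3, 0.4)
  expect_equal(klDivergence(p, p), 0)
  expect_equal(klDivergence(c(1, 0), c(0.5, 0.5)), log(2))
  expect_equal(klDivergence(c(0.5, 0.5), c(1, 0)), Inf)
  set.seed(3)
  for (rep in 1:10) {
    a <- runif(8); a <- a / sum(a)
    b <- runif(8); b <- b / sum(b)
    expect_gte(klDivergence(a, b), 0)
    expect_equal(jsDivergence(a, b), jsDivergence(b, a))
    expect_true(jsDivergence(a, b) >= 0 && jsDivergence(a, b) <= log(2))
  }
  expect_equal(jsDivergence(p, p), 0)
  expect_equal(jsDivergence(c(1, 0), c(0, 1)), log(2))
})

test_that("KL ratio spans its 0-1 range at the reference cases", {
  pd <- c(0.4, 0.1, 0.1, 0.4)
  pi <- rep(0.25, 4)
  expect_equal(klRatio(pd, pi, pd)$R, 1)       # pairwise perfect
  expect_equal(klRatio(pd, pi, pi)$R, 0)       # pairwise no better
  expect_true(is.na(klRatio(pd, pd, pd)$R))    # D1 = 0 flagged
})

test_that("model JSON serialization round-trips", {
  m <- randomIsingModel(4, seed = 6)
  path <- file.path(withr::local_tempdir(), "model.json")
  writeModelJson(m, path)
  back <- readModelJson(path)
  expect_equal(biases(back), biases(m))
  expect_equal(couplings(back), couplings(m))
})
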