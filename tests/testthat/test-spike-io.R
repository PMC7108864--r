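test_that("pattern ordering utilities agree with the canonical convention", {
  pm <- pairIndexMap(4)
  expect_equal(pm$i, c(1, 1, 1, 2, 2, 3))
  expect_equal(pm$j, c(2, 3, 4, 3, 4, 4))
  P <- patternMatrix(3)
  expect_equal(nrow(P), 8)
  expect_equal(P[1, ], c(-1L, -1L, -1L))          # all-silent first
  expect_equal(P[8, ], c(1L, 1L, 1L))
  expect_equal(P[5, ], c(1L, -1L, -1L))           # unit 1 most significant
  expect_equal(patternIndex(P), 1:8)              # round trip
  # observable vector: pair entries are products of the unit entries
  set.seed(1)
  for (r in 1:5) {
    s <- sample(c(-1, 1), 6, replace = TRUE)
    x <- observableVector(s)
    pm6 <- pairIndexMap(6)
    expect_equal(x[6 + pm6$index], s[pm6$i] * s[pm6$j])
  }
  expect_equal(observableVector(c(1, -1)), c(1, -1, -1))
})

test_that("spike tables round-trip through disk and handle empty cases", {
  ds <- toyDataset()
  path <- file.path(withr::local_tempdir(), "toy.csv")
  writeSpikeTable(ds, path)
  back <- readSpikeTable(path)
  expect_equal(nrow(spikeTable(back)), 3)
  expect_equal(nrow(unitTable(back)), 3)
  expect_equal(eventTimes(back), eventTimes(ds))
  expect_equal(recordingDuration(back), 10)
  expect_equal(spikeTable(back)$time_s, spikeTable(ds)$time_s,
               tolerance = 1e-9)

  # zero-spike dataset: header-only spikes table, still readable
  empty <- SpikeDataset(units = data.frame(unit_id = 1L, class = "single"),
                        spikes = data.frame(unit_id = integer(0),
                                            time_s = numeric(0)),
                        duration = 5)
  p2 <- file.path(withr::local_tempdir(), "empty.csv")
  writeSpikeTable(empty, p2)
  back2 <- readSpikeTable(p2)
  expect_equal(nrow(spikeTable(back2)), 0)
  expect_equal(nrow(unitTable(back2)), 1)

  # determinism: same dataset written twice is byte-identical
  g <- generateDataset(generatorConfig(nSingle = 10, nMulti = 2,
                                       duration = 150), seed = 1)
  pa <- file.path(withr::local_tempdir(), "a.csv")
  pb <- file.path(withr::local_tempdir(), "b.csv")
  writeSpikeTable(g$dataset, pa)
  writeSpikeTable(g$dataset, pb)
  expect_identical(readBin(pa, "raw", 1e7), readBin(pb, "raw", 1e7))
  # and the round trip is the identity on what binarization sees
  ga <- readSpikeTable(pa)
  expect_equal(spikeTable(ga)$unit_id, spikeTable(g$dataset)$unit_id)
  expect_equal(spikeTable(ga)$time_s, spikeTable(g$dataset)$time_s,
               tolerance = 1e-5)

  expect_error(suppressWarnings(readSpikeTable(tempfile())), "cannot open")
})

test_that("read validation rejects malformed tables", {
  bad <- file.path(withr::local_tempdir(), "bad.csv")
  writeLines(c("unit,when", "1,0.5"), bad)
  expect_error(readSpikeTable(bad), "format error")
  neg <- file.path(withr::local_tempdir(), "neg.csv")
  writeLines(c("unit_id,time_s,class", "1,-0.5,single"), neg)
  expect_error(readSpikeTable(neg), "validation error")
})

test_that("epoch segmentation places pre-stimulus windows correctly", {
  ds <- SpikeDataset(units = data.frame(unit_id = 1L, class = "single"),
                     spikes = data.frame(unit_id = 1L, time_s = 50),
                     events = c(0.5, seq(2.5, 197.5, by = 2.5)),
                     duration = 200)
  ew <- segmentEpochs(ds)
  expect_equal(nrow(ew$epochs), 2)
  expect_equal(ew$epochs$t_start, c(0, 100))
  # epochs tile [0, 200) disjointly
  expect_equal(ew$epochs$t_end[1], ew$epochs$t_start[2])
  # the event at 0.5 s would need a window starting at -1 s: dropped
  expect_false(0.5 %in% ew$windows[[1]]$onset)
  # every window ends exactly at its event onset and is 1.5 s long
  for (t in 1:2) {
    w <- ew$windows[[t]]
    expect_equal(w$w_end, w$onset)
    expect_equal(w$w_end - w$w_start, rep(1.5, nrow(w)))
    expect_true(all(w$w_start >= ew$epochs$t_start[t]))
  }
  # events in [0,100) belong to epoch 1 only
  expect_true(all(ew$events[[1]] < 100))
  expect_true(all(ew$events[[2]] >= 100))

  # 12 events in one epoch give 12 windows and 18 s of spontaneous time
  ds12 <- SpikeDataset(units = data.frame(unit_id = 1L, class = "single"),
                       spikes = data.frame(unit_id = integer(0),
                                           time_s = numeric(0)),
                       events = seq(5, 82, by = 7), duration = 100)
  ew12 <- segmentEpochs(ds12)
  expect_equal(nrow(ew12$windows[[1]]), 12)
  expect_equal(sum(ew12$windows[[1]]$w_end - ew12$windows[[1]]$w_start), 18)

  # an epoch with no events is flagged
  dsNo <- SpikeDataset(units = data.frame(unit_id = 1L, class = "single"),
                       spikes = data.frame(unit_id = integer(0),
                                           time_s = numeric(0)),
                       events = c(150.5), duration = 200)
  ewNo <- segmentEpochs(dsNo)
  expect_true(ewNo$epochs$flagged[1])
  expect_false(ewNo$epochs$flagged[2])
})

test_that("binarization marks occupied bins and rejects ragged windows", {
  ds <- toyDataset()
  w <- data.frame(w_start = 0, w_end = 1.5)
  r <- binarize(ds, w, units = 1:2)
  expect_equal(dim(r), c(2, 150))
  expect_true(all(r %in% c(-1L, 1L)))
  # unit 1 spiked at 0.005 (bin 1) and 0.012 (bin 2); unit 2 at 0.011 (bin 2)
  expect_equal(unname(r[1, 1:3]), c(1L, 1L, -1L))
  expect_equal(unname(r[2, 1:3]), c(-1L, 1L, -1L))
  expect_equal(sum(r == 1), 3)
  # spike-free unit in a 1.5-s window: 150 bins, all -1
  r3 <- binarize(ds, w, units = 3)
  expect_equal(sum(r3 == 1), 0)
  # two spikes in one bin collapse to a single +1
  ds2 <- SpikeDataset(units = data.frame(unit_id = 1L, class = "single"),
                      spikes = data.frame(unit_id = c(1L, 1L),
                                          time_s = c(0.003, 0.007)),
                      duration = 1)
  r2 <- binarize(ds2, data.frame(w_start = 0, w_end = 0.02))
  expect_equal(unname(r2[1, ]), c(1L, -1L))
  # window not a multiple of dt is an error, not a silent truncation
  expect_error(binarize(ds, data.frame(w_start = 0, w_end = 0.015)),
               "multiple of dt")
})

test_that("pattern extraction preserves spike presence and ordering", {
  g <- generateDataset(generatorConfig(nSingle = 12, nMulti = 0,
                                       duration = 150), seed = 2)
  ew <- segmentEpochs(g$dataset)
  r <- binarize(g$dataset, ew$windows[[1]], units = 1:12)
  pats <- extractPatterns(r, c(3, 1, 7))
  expect_equal(ncol(pats), 3)
  expect_equal(nrow(pats), ncol(r))
  # coordinate k of each pattern is the raster row of ensemble unit k
  expect_equal(pats[, 1], unname(r["3", ]))
  expect_equal(pats[, 2], unname(r["1", ]))
  expect_error(extractPatterns(r, c(1, 99)), "unknown unit")
  # 29 windows of 1.5 s in one epoch give 29 x 150 = 4350 patterns
  ds29 <- SpikeDataset(units = data.frame(unit_id = 1L, class = "single"),
                       spikes = data.frame(unit_id = integer(0),
                                           time_s = numeric(0)),
                       events = seq(2, 98, length.out = 29), duration = 100)
  ew29 <- segmentEpochs(ds29)
  r29 <- binarize(ds29, ew29$windows[[1]], units = 1)
  expect_equal(ncol(r29), 4350)
  expect_true(all(extractPatterns(r29, 1) == -1))
})

test_that("ensemble sampling is uniform, seeded and validated", {
  expect_error(sampleEnsembles(1:5, N = 10, Q = 1), "at least 10")
  one <- sampleEnsembles(1:10, N = 10, Q = 1, seed = 7)
  expect_equal(one$ensembles[[1]], 1:10)
  rat1 <- sampleEnsembles(1:81, N = 10, Q = 20, seed = 3)
  expect_length(rat1$ensembles, 20)
  for (e in rat1$ensembles) {
    expect_length(unique(e), 10)
    expect_true(all(e %in% 1:81))
  }
  expect_identical(sampleEnsembles(1:81, N = 10, Q = 20, seed = 3), rat1)
})
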