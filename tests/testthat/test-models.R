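test_that("architecture pinning: parameter counts match the printed sizes exactly", {
  expect_identical(countParameters(classifierSpec()), 65156L)
  expect_identical(countParameters(regressorSpec()), 44033L)
  ## 9-class head swaps 516 head parameters for 128*9 + 9
  expect_identical(countParameters(classifierSpec(nClasses = 9)),
                   65156L - 516L + (128L * 9L + 9L))
  ## any spec edit that changes a pinned dimension breaks the count
  expect_false(countParameters(classifierSpec(nFilters = 16)) == 65156L)
  expect_false(countParameters(regressorSpec(hidden = c(128, 64, 32))) ==
                 44033L)
})

test_that("classifier logits have nClasses entries for any window length >= 17", {
  spec <- classifierSpec()
  params <- gazeStrain:::withSeed(1, gazeStrain:::.inceptionInitParams(spec))
  bn <- gazeStrain:::.inceptionInitBnState(spec)
  for (Tlen in c(17, 33, 100)) {
    X <- array(rnorm(10 * Tlen * 3), c(10, Tlen, 3))
    fw <- gazeStrain:::.inceptionForward(X, params, spec, bn)
    expect_equal(dim(fw$logits), c(4, 3))
    expect_true(all(is.finite(fw$logits)))
  }
})

test_that("analytic gradients match finite differences on a tiny network", {
  spec <- classifierSpec(inChannels = 3, nFilters = 2, kernelSizes = c(5, 3, 3),
                         depth = 2, nClasses = 3)
  params <- gazeStrain:::withSeed(3, gazeStrain:::.inceptionInitParams(spec))
  bn <- gazeStrain:::.inceptionInitBnState(spec)
  set.seed(4)
  X <- array(rnorm(3 * 20 * 4), c(3, 20, 4))
  y <- c(1L, 2L, 3L, 1L)
  lossAt <- function(p) {
    fw <- gazeStrain:::.inceptionForward(X, p, spec,
                                         gazeStrain:::.inceptionInitBnState(spec),
                                         training = TRUE)
    gazeStrain:::.softmaxCE(fw$logits, y)$loss
  }
  fw <- gazeStrain:::.inceptionForward(X, params, spec, bn, training = TRUE)
  ls <- gazeStrain:::.softmaxCE(fw$logits, y)
  grads <- gazeStrain:::.inceptionBackward(fw, params, spec, ls$dlogits)
  eps <- 1e-6
  for (nm in c("b1.branch1.W", "b1.bottleneck.W", "b2.mp.W", "b1.bn.gamma",
               "head.W", "head.b")) {
    idx <- c(1L, length(params[[nm]]))  # first and last scalar
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("serialized 32-bit weight payloads match parameter count x 4 bytes", {
  ds <- simulateWindowDataset(48, nSubjects = 2, seed = 21,
                              directions = c("up", "right"))
  wn <- normalizeWindows(ds$expanded, fitNormalization(ds$expanded))
  m <- trainClassifier(wn, cfg = trainConfig(epochs = 1, seed = 1))
  f <- tempfile()
  serializeWeights(m, f)
  nPar <- countParameters(m)
  expect_identical(file.size(f), 4 * nPar)

  feats <- extractRegressionFeatures(wn)
  r <- trainRegressor(feats, windowAngles(wn), cfg = trainConfig(epochs = 2))
  f2 <- tempfile()
  serializeWeights(r, f2)
  expect_identical(file.size(f2), 4 * 44033)
  unlink(c(f, f2))
})

test_that("polarity rule decodes clean windows and is antisymmetric", {
  s <- cleanSensor()
  recs <- lapply(c("up", "down", "right", "left"), eventRecording,
                 angle = 12, sensor = s)
  for (i in seq_along(recs)) {
    w <- segmentWindows(highpassFilter(recs[[i]]))
    expect_equal(polarityClassify(w), windowLabels(w))
    ## negating the window flips the vertical/horizontal class
    neg <- windowSet(-windowData(w), w@samplingRate)
    flipped <- c(up = "down", down = "up", right = "left", left = "right")
    expect_equal(polarityClassify(neg),
                 unname(flipped[windowLabels(w)]))
  }
  zero <- windowSet(array(0, c(3, 100, 1)), 50)
  expect_equal(polarityClassify(zero), "uncertain")
})

test_that("DTW cost equals the brute-force dynamic program on short sequences", {
  expect_equal(dtwDistance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtwDistance(c(0, 1, 2), c(0, 2)), 1)
  expect_equal(dtwDistance(c(0, 0), c(4.5, 4.5)), 9)
  set.seed(7)
  for (rep in 1:25) {
    a <- round(rnorm(sample(2:6, 1)), 2)
    b <- round(rnorm(sample(2:6, 1)), 2)
    expect_equal(dtwDistance(a, b), bruteForceDtw(a, b))
    expect_equal(dtwDistance(a, b), dtwDistance(b, a))  # symmetry
  }
  ## multichannel cost is the sum of per-channel costs
  A <- rbind(c(0, 1, 2), c(1, 1, 1))
  B <- rbind(c(0, 2, 2), c(1, 2, 1))
  expect_equal(dtwDistance(A, B),
               dtwDistance(A[1, ], B[1, ]) + dtwDistance(A[2, ], B[2, ]))
  expect_error(dtwDistance(numeric(), 1), "non-empty")
})

test_that("KNN-DTW votes among nearest neighbours with distance tie-break", {
  mk <- function(v) array(rep(v, each = 1), c(1, length(v), 1))
  tr <- windowSet(array(c(0, 0, 0, 1, 1, 1, 5, 5, 5, 6, 6, 6),
                        c(1, 3, 4)), 50,
                  labels = c("a", "a", "b", "b"))
  ## query identical to a training sample
  q1 <- windowSet(mk(c(5, 5, 5)), 50)
  expect_equal(knnDtwClassify(tr, q1, k = 1), "b")
  ## k = n with balanced votes: the strictly nearer class wins the tie
  q2 <- windowSet(mk(c(0.4, 0.4, 0.4)), 50)
  expect_equal(knnDtwClassify(tr, q2, k = 4), "a")
  expect_error(knnDtwClassify(tr, q1, k = 9), "k must lie")
  empty <- windowSet(array(0, c(1, 3, 0)), 50)
  expect_error(knnDtwClassify(empty, q1, k = 1), "empty")
})

test_that("regression features are the signed channel extrema", {
  zero <- windowSet(array(0, c(10, 50, 2)), 50)
  expect_true(all(extractRegressionFeatures(zero) == 0))

  set.seed(9)
  w <- windowSet(array(rnorm(10 * 50 * 3), c(10, 50, 3)), 50)
  fe <- extractRegressionFeatures(w)
  expect_equal(dim(fe), c(3, 10))
  ## by definition: value of largest magnitude per channel
  for (ch in 1:10) {
    x <- windowData(w)[ch, , 2]
    expect_equal(unname(fe[2, ch]), x[which.max(abs(x))])
  }
  ## positive homogeneity
  w3 <- windowSet(2.5 * windowData(w), 50)
  expect_equal(extractRegressionFeatures(w3), 2.5 * fe)

  ## physiology: clean upward window has a negative 90-degree extremum
  up <- segmentWindows(highpassFilter(eventRecording("up", sensor = cleanSensor())))
  feUp <- extractRegressionFeatures(expandToTenChannels(up))
  expect_lt(feUp[1, 3], 0)
})

test_that("classifier evaluation reports consistent confusion metrics", {
  ds <- simulateWindowDataset(160, nSubjects = 2, seed = 13,
                              sensor = sensorSpec(noiseSd = 2e-4),
                              directions = c("up", "right"))
  wn <- normalizeWindows(ds$expanded, fitNormalization(ds$expanded))
  m <- trainClassifier(wn, cfg = trainConfig(epochs = 6, seed = 1,
                                             batchSize = 32))
  rep <- evaluateClassifier(m, wn)
  expect_true(rep@accuracy >= 0 && rep@accuracy <= 1)
  truth <- windowLabels(wn)
  expect_equal(unname(rowSums(rep@confusion)),
               as.numeric(table(factor(truth, sort(unique(truth))))))
  expect_equal(sum(rep@perClass$support), nWindows(wn))
  expect_error(evaluateClassifier(m, wn[integer()]), "empty")
})
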