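test_that("the regressor recovers a noise-free linear angle mapping", {
  ## sanity benchmark for capacity: dropout (a noise regularizer) off
  set.seed(5)
  v <- rnorm(10)
  ang <- runif(220, 5, 15)
  feats <- outer(ang, v) * 0.02
  r <- trainRegressor(feats[1:160, ], ang[1:160],
                      spec = regressorSpec(dropout = 0),
                      cfg = trainConfig(epochs = 300, seed = 2))
  mae <- mean(abs(predictRegressor(r, feats[161:220, ]) - ang[161:220]))
  expect_lt(mae, 0.2)

  expect_error(trainRegressor(feats[1:10, ], ang[1:10]), "at least 20")
  expect_error(trainRegressor(feats[1:30, 1:5], ang[1:30]), "spec wants")
})

test_that("the coordinate-output regressor minimizes gaze-point distance", {
  set.seed(6)
  v1 <- rnorm(10)
  v2 <- rnorm(10)
  xy <- cbind(runif(150, -15, 15), runif(150, -15, 15))
  feats <- (xy[, 1] %o% v1 + xy[, 2] %o% v2) * 0.01
  r <- trainRegressor(feats[1:120, ], xy[1:120, ],
                      spec = regressorSpec(outputDim = 2, dropout = 0),
                      cfg = trainConfig(epochs = 400, seed = 3))
  pred <- predictRegressor(r, feats[121:150, ])
  dist <- sqrt(rowSums((pred - xy[121:150, ])^2))
  expect_lt(mean(dist), 1)
})

test_that("two well-separated classes are learned to perfect held-out accuracy", {
  ds <- simulateWindowDataset(200, nSubjects = 2, seed = 3,
                              sensor = sensorSpec(noiseSd = 5e-5),
                              directions = c("up", "right"))
  wn <- normalizeWindows(ds$expanded, fitNormalization(ds$expanded))
  split <- withr::with_seed(1, sample(200))
  tr <- sort(split[1:150])
  te <- sort(split[151:200])
  m <- trainClassifier(wn[tr], cfg = trainConfig(epochs = 8, seed = 1))
  expect_equal(evaluateClassifier(m, wn[te])@accuracy, 1)
  ## training curves are logged per epoch
  expect_equal(nrow(m$history), 8)
  expect_true(all(c("loss", "accuracy", "macro_f1") %in% names(m$history)))

  oneClass <- wn[windowLabels(wn) == "up"]
  expect_error(trainClassifier(oneClass), "2 classes")
})

test_that("seeded training is reproducible run to run", {
  ds <- simulateWindowDataset(60, nSubjects = 1, seed = 9,
                              directions = c("up", "left"))
  wn <- normalizeWindows(ds$expanded, fitNormalization(ds$expanded))
  cfg <- trainConfig(epochs = 3, seed = 7)
  m1 <- trainClassifier(wn, cfg = cfg)
  m2 <- trainClassifier(wn, cfg = cfg)
  expect_identical(m1$params, m2$params)

  fe <- extractRegressionFeatures(wn)
  r1 <- trainRegressor(fe, windowAngles(wn), cfg = trainConfig(epochs = 5, seed = 2))
  r2 <- trainRegressor(fe, windowAngles(wn), cfg = trainConfig(epochs = 5, seed = 2))
  expect_identical(r1$params, r2$params)
})

## small shared bundle for the end-to-end and calibration contracts
e2eBundle <- local({
  ds <- simulateWindowDataset(360, nSubjects = 3, seed = 17,
                              directions = c("up", "down", "right", "left"))
  trainDirectionModels(ds$expanded,
                       clsCfg = trainConfig(epochs = 8, batchSize = 64,
                                            seed = 1),
                       regCfg = trainConfig(epochs = 150, seed = 1))
})

test_that("end-to-end decoding routes windows to the predicted class regressor", {
  rec <- eventRecording("up", angle = 10, seed = 31)
  out <- predictEndToEnd(rec, e2eBundle)
  expect_equal(nrow(out), 1)
  expect_equal(out$direction, "up")
  expect_lt(abs(out$angle - 10), 2)
  expect_equal(out$onset, rec@annotations$onset)

  ## an empty recording decodes to an empty table
  flat <- generateRecording(emptyAnnotations(), duration = 5, seed = 1)
  expect_equal(nrow(predictEndToEnd(flat, e2eBundle)), 0)

  ## a predicted gaze class without a regressor is a hard error
  broken <- e2eBundle
  broken$regressors$up <- NULL
  expect_error(predictEndToEnd(rec, broken), "no regressor")
})

test_that("artifact windows classify as the merged ninth class and get no angle", {
  ds <- simulateWindowDataset(300, nSubjects = 2, seed = 23,
                              directions = c("up", "down"),
                              artifactFraction = 0.3)
  m <- mergeArtifactLabels(ds$expanded)
  bundle <- trainDirectionModels(m,
                                 clsCfg = trainConfig(epochs = 8,
                                                      batchSize = 64,
                                                      seed = 1),
                                 regCfg = trainConfig(epochs = 120, seed = 1))
  expect_true("blink_expression" %in% bundle$classifier$classes)
  expect_false("blink_expression" %in% names(bundle$regressors))

  ev <- gazeEvents(c(2, 4.5), c("up", "blink"), angle = 10)
  rec <- generateRecording(ev, duration = 7, seed = 3)
  out <- predictEndToEnd(rec, bundle)
  expect_equal(nrow(out), 2)
  blinkRow <- out[out$onset == 4.5, ]
  expect_equal(blinkRow$direction, "blink_expression")
  expect_true(is.na(blinkRow$angle))
  expect_false(is.na(out$angle[out$onset == 2]))
})

test_that("few-shot calibration enforces the 2-5 sample contract and copies models", {
  ds <- simulateWindowDataset(60, nSubjects = 1, seed = 41)
  w <- ds$expanded
  labs <- windowLabels(w)
  pick <- function(k) unlist(lapply(c("up", "down", "right", "left"),
                                    function(d) which(labs == d)[seq_len(k)]))
  ## 1 sample per position: too few; 6: too many
  expect_error(fewShotCalibrate(e2eBundle, w[pick(1)], regEpochs = 5),
               "2-5 samples")
  expect_error(fewShotCalibrate(e2eBundle, w[pick(6)], regEpochs = 5),
               "2-5 samples")

  before <- e2eBundle$classifier$params$head.W
  ad <- fewShotCalibrate(e2eBundle, w[pick(3)], clsEpochs = 3,
                         regEpochs = 10, seed = 1)
  ## the original bundle is untouched; the adapted copy has moved
  expect_identical(e2eBundle$classifier$params$head.W, before)
  expect_false(identical(ad$classifier$params$head.W, before))
  expect_false(identical(ad$regressors$up$params$W4,
                         e2eBundle$regressors$up$params$W4))
  ## seeded: repeating the calibration reproduces the adapted weights
  ad2 <- fewShotCalibrate(e2eBundle, w[pick(3)], clsEpochs = 3,
                          regEpochs = 10, seed = 1)
  expect_identical(ad$classifier$params, ad2$classifier$params)
})

test_that("model checkpoints restore predictions exactly", {
  f <- tempfile(fileext = ".rds")
  saveModelCheckpoint(e2eBundle, f)
  back <- loadModelCheckpoint(f)
  rec <- eventRecording("right", angle = 8, seed = 51)
  expect_identical(predictEndToEnd(rec, back), predictEndToEnd(rec, e2eBundle))
  expect_error(loadModelCheckpoint(system.file("extdata",
    "hess_left_normal_synthetic.json", package = "gazeStrain")))
  unlink(f)
})
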