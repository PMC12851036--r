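## End-to-end pipeline: dataset synthesis, model-bundle training,
## window -> (direction, angle) prediction, few-shot subject calibration.

#' Simulate a labeled window dataset
#'
#' Convenience wrapper composing the simulator and the preprocessing
#' chain: generates a seeded subject cohort, high-pass filters each
#' recording, cuts event-centered windows and expands them to the
#' 10-channel model input. The event schedule guarantees no window is
#' clipped at a recording edge, so the dataset has exactly `nWindows`
#' windows, class-balanced over `directions`.
#'
#' @param nWindows total number of windows.
#' @param nSubjects subjects to spread the events over.
#' @param seed integer seed.
#' @param sensor,priors simulator specification.
#' @param directions gaze directions (plus artifacts via
#'   `artifactFraction`).
#' @param angleRange gaze-angle range, degrees.
#' @param gainJitter per-subject log-gain SD.
#' @param artifactFraction fraction of extra blink/expression events.
#' @param windowSeconds window length, seconds.
#' @param cutoff high-pass cutoff, Hz.
#' @return list with `expanded` (10-channel [WindowSet-class]) and
#'   `raw` (filtered 3-channel [WindowSet-class]) sharing labels,
#'   angles and subjects.
#' @export
simulateWindowDataset <- function(nWindows, nSubjects = 7, seed = 1,
                                  sensor = sensorSpec(),
                                  priors = defaultDirectionPriors(),
                                  directions = c("up", "down", "right", "left"),
                                  angleRange = c(5, 15), gainJitter = 0.15,
                                  artifactFraction = 0, windowSeconds = 2,
                                  cutoff = 0.5) {
  perSubj <- ceiling(nWindows / nSubjects)
  recs <- generateCohort(nSubjects = nSubjects, gainJitter = gainJitter,
                         eventsPerSubject = perSubj, seed = seed,
                         sensor = sensor, priors = priors,
                         directions = directions, angleRange = angleRange,
                         artifactFraction = artifactFraction)
  raws <- lapply(recs, function(r)
    segmentWindows(highpassFilter(r, cutoff), windowSeconds = windowSeconds))
  raw <- .bindWindowSets(raws)
  if (nWindows < nWindows(raw)) {
    keep <- withSeed(seed + 1L, sample(nWindows(raw), nWindows))
    raw <- raw[sort(keep)]
  }
  list(expanded = expandToTenChannels(raw), raw = raw)
}

.bindWindowSets <- function(sets) {
  sets <- Filter(function(s) nWindows(s) > 0L, sets)
  .assert(length(sets) > 0L, "no non-empty window sets to bind")
  d1 <- dim(sets[[1L]]@data)
  total <- sum(vapply(sets, nWindows, 0L))
  data <- array(0, c(d1[1L], d1[2L], total))
  at <- 0L
  for (s in sets) {
    n <- nWindows(s)
    data[, , (at + 1L):(at + n)] <- s@data
    at <- at + n
  }
  windowSet(data, sets[[1L]]@samplingRate,
            unlist(lapply(sets, windowLabels)),
            unlist(lapply(sets, windowAngles)),
            unlist(lapply(sets, windowSubjects)),
            unlist(lapply(sets, function(s) s@onsets)),
            sets[[1L]]@channelIds)
}

#' Train the full direction + angle model bundle
#'
#' Fits the per-channel normalization scale on the training windows,
#' trains the direction classifier on the normalized set, and trains
#' one independent MLP angle regressor per gaze-direction class, each
#' fitted only to its own class's samples. Artifact classes (blink /
#' expression) get no regressor.
#'
#' @param windows labeled 10-channel [WindowSet-class] with angles
#'   (unnormalized; scaling is fitted here and stored on the bundle).
#' @param clsSpec optional [ClassifierSpec-class].
#' @param clsCfg classifier [TrainConfig-class].
#' @param regSpec [RegressorSpec-class] shared by all regressors.
#' @param regCfg regressor [TrainConfig-class]; regressors are cheap,
#'   so their default epoch budget is larger than the classifier's.
#' @return a `gsModels` bundle: `classifier`, `regressors` (named by
#'   direction), `scale`.
#' @export
trainDirectionModels <- function(windows, clsSpec = NULL,
                                 clsCfg = trainConfig(),
                                 regSpec = regressorSpec(),
                                 regCfg = trainConfig(epochs = 150)) {
  scale <- fitNormalization(windows)
  wn <- normalizeWindows(windows, scale)
  classifier <- trainClassifier(wn, spec = clsSpec, cfg = clsCfg)
  feats <- extractRegressionFeatures(wn)
  labs <- windowLabels(wn)
  regressors <- list()
  for (dir in intersect(classifier$classes, gazeDirections())) {
    sel <- labs == dir & !is.na(windowAngles(wn))
    regressors[[dir]] <- trainRegressor(feats[sel, , drop = FALSE],
                                        windowAngles(wn)[sel],
                                        spec = regSpec, cfg = regCfg,
                                        direction = dir)
  }
  structure(list(classifier = classifier, regressors = regressors,
                 scale = scale),
            class = "gsModels")
}

#' Decode a recording end to end
#'
#' High-pass filters the recording, cuts event-centered windows,
#' expands and normalizes them, classifies each window, and routes it
#' to the regressor of its *predicted* class for angle estimation (the
#' deployment contract). Blink/expression predictions yield no angle.
#'
#' @param recording a [StrainRecording-class] with event annotations
#'   (onsets locate the windows; labels are not used).
#' @param models a `gsModels` bundle from [trainDirectionModels()].
#' @param windowSeconds,cutoff preprocessing settings; must match the
#'   training recipe.
#' @return data frame with `onset`, `direction`, `angle` (degrees; `NA`
#'   for the artifact class), one row per decoded window.
#' @export
predictEndToEnd <- function(recording, models, windowSeconds = 2,
                            cutoff = 0.5) {
  .assert(inherits(models, "gsModels"), "models must be a gsModels bundle")
  raw <- segmentWindows(highpassFilter(recording, cutoff),
                        windowSeconds = windowSeconds)
  if (nWindows(raw) == 0L)
    return(data.frame(onset = numeric(), direction = character(),
                      angle = numeric(), stringsAsFactors = FALSE))
  wn <- normalizeWindows(expandToTenChannels(raw), models$scale)
  pred <- as.character(predictClassifier(models$classifier, wn))
  feats <- extractRegressionFeatures(wn)
  angle <- rep(NA_real_, length(pred))
  for (dir in unique(pred)) {
    if (dir %in% c(artifactKinds(), "blink_expression")) next
    reg <- models$regressors[[dir]]
    .assert(!is.null(reg), "no regressor for predicted class '%s'", dir)
    sel <- pred == dir
    angle[sel] <- predictRegressor(reg, feats[sel, , drop = FALSE])
  }
  data.frame(onset = wn@onsets, direction = pred, angle = angle,
             stringsAsFactors = FALSE)
}

#' Merge blink and expression labels into one artifact class
#'
#' The nine-category direction model treats blinking and facial
#' expressions as a single ninth class; this relabels both artifact
#' kinds to `"blink_expression"` so the eight gaze directions plus the
#' merged artifact class give nine classes.
#'
#' @param windows a labeled [WindowSet-class].
#' @return the relabeled [WindowSet-class].
#' @export
mergeArtifactLabels <- function(windows) {
  labs <- windowLabels(windows)
  labs[labs %in% artifactKinds()] <- "blink_expression"
  windowSet(windows@data, windows@samplingRate, labs,
            windowAngles(windows), windowSubjects(windows),
            windows@onsets, windows@channelIds)
}

#' Overall and per-direction angle MAE
#'
#' @param predicted,truth angle vectors in degrees (NA pairs dropped).
#' @param direction optional per-sample direction labels.
#' @return list with `overall` MAE and named `perDirection` MAEs.
#' @export
angleMAE <- function(predicted, truth, direction = NULL) {
  ok <- is.finite(predicted) & is.finite(truth)
  err <- abs(predicted[ok] - truth[ok])
  per <- if (!is.null(direction)) {
    vapply(split(err, direction[ok]), mean, 0)
  } else setNames(numeric(), character())
  list(overall = mean(err), perDirection = per)
}

## continue Adam training of an existing classifier on a fixed set
.fineTuneClassifier <- function(model, wn, lr, epochs, seed) {
  X <- windowData(wn)
  y <- match(windowLabels(wn), model$classes)
  .assert(!anyNA(y), "calibration labels outside the model's classes")
  withSeed(seed, {
    params <- model$params
    bnStates <- model$bnStates
    opt <- .adamInit(params)
    for (epoch in seq_len(epochs)) {
      fw <- .inceptionForward(X, params, model$spec, bnStates,
                              training = TRUE)
      bnStates <- fw$bnStates
      ls <- .softmaxCE(fw$logits, y)
      grads <- .inceptionBackward(fw, params, model$spec, ls$dlogits)
      st <- .adamStep(params, grads, opt, lr)
      params <- st$params
      opt <- st$state
    }
    model$params <- params
    model$bnStates <- bnStates
    model
  })
}

.fineTuneRegressor <- function(model, feats, targets, lr, epochs, seed) {
  Xs <- t((t(as.matrix(feats)) - model$xCenter) / model$xScale)
  Ys <- (targets - model$yCenter) / model$yScale
  withSeed(seed, {
    params <- model$params
    opt <- .adamInit(params)
    Xb <- t(Xs)
    Tb <- matrix(Ys, nrow = model$spec@outputDim)
    for (epoch in seq_len(epochs)) {
      fw <- .mlpForward(Xb, params, model$spec, training = TRUE)
      err <- fw$out - Tb
      dOut <- 2 * err / length(err)
      grads <- .mlpBackward(fw, params, model$spec, dOut)
      st <- .adamStep(params, grads, opt, lr)
      params <- st$params
      opt <- st$state
    }
    model$params <- params
    model
  })
}

#' Few-shot subject calibration
#'
#' Adapts a trained model bundle to a new subject from 2-5 labeled
#' windows per cardinal gaze position: all weights of the classifier
#' and of each per-direction regressor are fine-tuned (full-batch Adam)
#' at a tenth of the base learning rate for a small fixed epoch budget.
#' The input bundle is not modified; an adapted copy is returned.
#'
#' @param models a `gsModels` bundle.
#' @param calibration labeled 10-channel [WindowSet-class] with angles
#'   (unnormalized), 2-5 windows per gaze direction known to the
#'   classifier.
#' @param clsEpochs classifier fine-tuning epoch budget (full-batch
#'   steps).
#' @param regEpochs per-regressor fine-tuning epoch budget (regressors
#'   are tiny, so their budget is larger).
#' @param seed RNG seed for dropout during fine-tuning.
#' @return the adapted `gsModels` bundle.
#' @export
fewShotCalibrate <- function(models, calibration, clsEpochs = 25,
                             regEpochs = 600, seed = 1) {
  .assert(inherits(models, "gsModels"), "models must be a gsModels bundle")
  labs <- windowLabels(calibration)
  dirs <- intersect(models$classifier$classes, gazeDirections())
  counts <- table(factor(labs, dirs))
  bad <- names(counts)[counts < 2 | counts > 5]
  .assert(length(bad) == 0L,
          "calibration needs 2-5 samples per position; '%s' has %d",
          if (length(bad)) bad[1L] else "", if (length(bad)) counts[bad[1L]] else 0L)
  baseLr <- models$classifier$cfg@learningRate
  wn <- normalizeWindows(calibration, models$scale)
  adapted <- models
  adapted$classifier <- .fineTuneClassifier(models$classifier, wn,
                                            lr = 0.1 * baseLr,
                                            epochs = clsEpochs, seed = seed)
  feats <- extractRegressionFeatures(wn)
  for (dir in names(models$regressors)) {
    sel <- labs == dir
    if (!any(sel)) next
    adapted$regressors[[dir]] <-
      .fineTuneRegressor(models$regressors[[dir]],
                         feats[sel, , drop = FALSE],
                         windowAngles(wn)[sel],
                         lr = 0.1 * baseLr, epochs = regEpochs,
                         seed = seed + match(dir, names(models$regressors)))
  }
  adapted
}
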