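## Direction classifier (Inception-style 1-D CNN) and per-direction MLP
## angle regressors: construction, training, prediction, evaluation,
## checkpointing.

#' Count trainable parameters
#'
#' Exact count of trainable scalars of an architecture specification or
#' a trained model: convolution weights (bias-free), normalization
#' affine pairs, and dense weights and biases. The pinned defaults give
#' 65,156 for the 4-class classifier and 44,033 for the scalar-output
#' regressor.
#'
#' @param spec a [ClassifierSpec-class], [RegressorSpec-class], or a
#'   trained model returned by [trainClassifier()] / [trainRegressor()].
#' @return integer parameter count.
#' @examples
#' countParameters(classifierSpec())  # 65156
#' countParameters(regressorSpec())   # 44033
#' @export
setGeneric("countParameters", function(spec) standardGeneric("countParameters"))

#' @rdname countParameters
#' @export
setMethod("countParameters", "ClassifierSpec", function(spec) {
  params <- withSeed(1L, .inceptionInitParams(spec))
  sum(vapply(params, length, 0L))
})

#' @rdname countParameters
#' @export
setMethod("countParameters", "RegressorSpec", function(spec) {
  params <- withSeed(1L, .mlpInitParams(spec))
  sum(vapply(params, length, 0L))
})

#' @rdname countParameters
#' @export
setMethod("countParameters", "ANY", function(spec) {
  .assert(is.list(spec) && !is.null(spec$params),
          "not a model specification or trained model")
  sum(vapply(spec$params, length, 0L))
})

## shared classification metrics
.classMetrics <- function(truth, pred, classes) {
  conf <- table(factor(truth, classes), factor(pred, classes))
  conf <- matrix(conf, length(classes), length(classes),
                 dimnames = list(truth = classes, predicted = classes))
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = mean(truth == pred),
       perClass = data.frame(class = classes, precision = prec, recall = rec,
                             f1 = f1, support = as.numeric(rowSums(conf)),
                             row.names = NULL),
       confusion = conf)
}

.stratifiedHoldout <- function(y, fraction) {
  idxVal <- integer()
  if (fraction > 0) {
    for (k in sort(unique(y))) {
      ik <- which(y == k)
      nv <- floor(fraction * length(ik))
      if (nv > 0) idxVal <- c(idxVal, sample(ik, nv))
    }
  }
  list(train = setdiff(seq_along(y), idxVal), val = sort(idxVal))
}

.classifierLogits <- function(model, X, idx = seq_len(dim(X)[3L]),
                              batch = 256L) {
  out <- matrix(0, model$spec@nClasses, length(idx))
  for (s in seq(1L, length(idx), by = batch)) {
    ib <- idx[s:min(s + batch - 1L, length(idx))]
    fw <- .inceptionForward(X[, , ib, drop = FALSE], model$params,
                            model$spec, model$bnStates, training = FALSE)
    out[, s:(s + length(ib) - 1L)] <- fw$logits
  }
  out
}

#' Train the Inception-style direction classifier
#'
#' Seeded Adam training with a cosine-decayed learning rate; the split
#' into training and validation folds is stratified by class. Given the
#' same data, configuration and seed (on a fixed thread count) two runs
#' produce identical weights.
#'
#' @param windows labeled [WindowSet-class] (10 channels after
#'   [expandToTenChannels()], typically normalized).
#' @param spec a [ClassifierSpec-class]; default derives `nClasses`
#'   from the labels present.
#' @param cfg a [TrainConfig-class].
#' @return a `gsClassifier` model list: `spec`, `params`, `bnStates`,
#'   `classes`, `history` (per-epoch loss / accuracy / macro-F1), `cfg`.
#' @export
trainClassifier <- function(windows, spec = NULL, cfg = trainConfig()) {
  labs <- windowLabels(windows)
  .assert(!anyNA(labs), "all windows must be labeled")
  classes <- sort(unique(labs))
  .assert(length(classes) >= 2L,
          "training set must contain at least 2 classes")
  d <- dim(windows@data)
  if (is.null(spec))
    spec <- classifierSpec(inChannels = d[1L], nClasses = length(classes))
  .assert(spec@nClasses == length(classes),
          "spec has %d classes but data has %d", spec@nClasses,
          length(classes))
  .assert(spec@inChannels == d[1L],
          "spec expects %d channels but windows have %d", spec@inChannels,
          d[1L])
  .assert(d[2L] >= max(spec@kernelSizes),
          "window length %d shorter than largest kernel %d", d[2L],
          max(spec@kernelSizes))
  X <- windowData(windows)
  y <- match(labs, classes)

  withSeed(cfg@seed, {
    params <- .inceptionInitParams(spec)
    bnStates <- .inceptionInitBnState(spec)
    split <- .stratifiedHoldout(y, cfg@valFraction)
    opt <- .adamInit(params)
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       accuracy = numeric(), macro_f1 = numeric())
    model <- list(spec = spec, params = params, bnStates = bnStates,
                  classes = classes, cfg = cfg)
    for (epoch in seq_len(cfg@epochs)) {
      lr <- .lrAt(cfg, epoch)
      ord <- sample(split$train)
      epLoss <- 0
      for (s in seq(1L, length(ord), by = cfg@batchSize)) {
        ib <- ord[s:min(s + cfg@batchSize - 1L, length(ord))]
        fw <- .inceptionForward(X[, , ib, drop = FALSE], params, spec,
                                bnStates, training = TRUE)
        bnStates <- fw$bnStates
        ls <- .softmaxCE(fw$logits, y[ib])
        grads <- .inceptionBackward(fw, params, spec, ls$dlogits)
        st <- .adamStep(params, grads, opt, lr)
        params <- st$params
        opt <- st$state
        epLoss <- epLoss + ls$loss * length(ib)
      }
      model$params <- params
      model$bnStates <- bnStates
      evalIdx <- if (length(split$val)) split$val else split$train
      pr <- max.col(t(.classifierLogits(model, X, evalIdx)),
                    ties.method = "first")
      mets <- .classMetrics(classes[y[evalIdx]], classes[pr], classes)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     loss = epLoss / length(ord),
                                     accuracy = mets$accuracy,
                                     macro_f1 = mean(mets$perClass$f1)))
    }
    model$history <- hist
    structure(model, class = "gsClassifier")
  })
}

#' Predict direction labels
#'
#' @param model a `gsClassifier` from [trainClassifier()].
#' @param windows a [WindowSet-class] with the model's channel count.
#' @return character vector of predicted labels, with the class
#'   probability matrix attached as attribute `"probs"`.
#' @export
predictClassifier <- function(model, windows) {
  .assert(inherits(model, "gsClassifier"), "model is not a gsClassifier")
  X <- windowData(windows)
  logits <- .classifierLogits(model, X)
  mx <- apply(logits, 2L, max)
  ez <- exp(sweep(logits, 2L, mx))
  probs <- sweep(ez, 2L, colSums(ez), "/")
  rownames(probs) <- model$classes
  pred <- model$classes[max.col(t(logits), ties.method = "first")]
  attr(pred, "probs") <- probs
  pred
}

#' Evaluate a classifier on labeled windows
#'
#' @param model a `gsClassifier`.
#' @param windows labeled [WindowSet-class] (non-empty).
#' @return an [EvalReport-class]; confusion-matrix rows (truth) sum to
#'   the per-class sample counts.
#' @export
evaluateClassifier <- function(model, windows) {
  .assert(nWindows(windows) > 0L, "cannot evaluate on an empty window set")
  truth <- windowLabels(windows)
  .assert(!anyNA(truth), "all windows must be labeled for evaluation")
  pred <- as.character(predictClassifier(model, windows))
  classes <- sort(union(model$classes, unique(truth)))
  mets <- .classMetrics(truth, pred, classes)
  new("EvalReport", accuracy = mets$accuracy, perClass = mets$perClass,
      confusion = mets$confusion, mae = NA_real_,
      maePerDirection = setNames(numeric(), character()))
}

#' Signed channel extrema as regression features
#'
#' For each window and each channel, the value of largest magnitude
#' (signed), ordered as in the ten-channel expansion. The map is
#' positively homogeneous: scaling a window scales its features.
#'
#' @param windows a [WindowSet-class].
#' @return numeric matrix `[windows x channels]`.
#' @export
extractRegressionFeatures <- function(windows) {
  d <- dim(windows@data)
  feats <- matrix(0, d[3L], d[1L],
                  dimnames = list(NULL, windows@channelIds))
  for (ch in seq_len(d[1L])) {
    M <- matrix(windows@data[ch, , ], d[2L], d[3L])
    idx <- max.col(t(abs(M)), ties.method = "first")
    feats[, ch] <- M[cbind(idx, seq_len(d[3L]))]
  }
  feats
}

#' Train one per-direction angle regressor
#'
#' Fits the four-layer MLP to the samples of a single direction class
#' (the deployment contract: one independent regressor per class,
#' fitted only to that class's samples). Scalar mode minimizes squared
#' angle error; coordinate mode (`outputDim = 2`) minimizes the
#' Euclidean distance between predicted and target gaze points.
#' Features and targets are standardized internally (transform stored
#' on the model).
#'
#' @param features numeric matrix `[samples x inputDim]` from
#'   [extractRegressionFeatures()].
#' @param targets angle vector (degrees), or `[samples x 2]` gaze-point
#'   matrix in coordinate mode; at least 20 samples.
#' @param spec a [RegressorSpec-class].
#' @param cfg a [TrainConfig-class] (regressors are cheap; a larger
#'   epoch budget than the classifier's is typical).
#' @param direction optional class label stored on the model.
#' @return a `gsRegressor` model list.
#' @export
trainRegressor <- function(features, targets, spec = regressorSpec(),
                           cfg = trainConfig(), direction = NA_character_) {
  features <- as.matrix(features)
  Yt <- if (is.matrix(targets)) targets else matrix(targets, ncol = 1L)
  .assert(nrow(features) >= 20L,
          "need at least 20 samples per direction class, got %d",
          nrow(features))
  .assert(nrow(Yt) == nrow(features), "features/targets length mismatch")
  .assert(ncol(Yt) == spec@outputDim, "targets have %d columns, spec wants %d",
          ncol(Yt), spec@outputDim)
  .assert(ncol(features) == spec@inputDim,
          "features have %d columns, spec wants %d", ncol(features),
          spec@inputDim)
  xc <- colMeans(features)
  xs <- apply(features, 2L, stats::sd)
  xs[xs <= 0 | !is.finite(xs)] <- 1
  yc <- colMeans(Yt)
  ys <- apply(Yt, 2L, stats::sd)
  ys[ys <= 0 | !is.finite(ys)] <- 1
  Xs <- t((t(features) - xc) / xs)   # [n x p]
  Ys <- t((t(Yt) - yc) / ys)

  withSeed(cfg@seed, {
    params <- .mlpInitParams(spec)
    opt <- .adamInit(params)
    hist <- data.frame(epoch = integer(), loss = numeric())
    n <- nrow(Xs)
    for (epoch in seq_len(cfg@epochs)) {
      lr <- .lrAt(cfg, epoch)
      ord <- sample(n)
      epLoss <- 0
      for (s in seq(1L, n, by = cfg@batchSize)) {
        ib <- ord[s:min(s + cfg@batchSize - 1L, n)]
        Xb <- t(Xs[ib, , drop = FALSE])          # [p x B]
        Tb <- t(Ys[ib, , drop = FALSE])          # [q x B]
        fw <- .mlpForward(Xb, params, spec, training = TRUE)
        if (spec@outputDim == 1L) {
          err <- fw$out - Tb
          loss <- mean(err^2)
          dOut <- 2 * err / length(err)
        } else {
          diff <- fw$out - Tb
          dist <- sqrt(colSums(diff^2) + 1e-12)
          loss <- mean(dist)
          dOut <- sweep(diff, 2L, dist, "/") / length(dist)
        }
        grads <- .mlpBackward(fw, params, spec, dOut)
        st <- .adamStep(params, grads, opt, lr)
        params <- st$params
        opt <- st$state
        epLoss <- epLoss + loss * length(ib)
      }
      hist <- rbind(hist, data.frame(epoch = epoch, loss = epLoss / n))
    }
    structure(list(spec = spec, params = params, xCenter = xc, xScale = xs,
                   yCenter = yc, yScale = ys, history = hist, cfg = cfg,
                   direction = direction),
              class = "gsRegressor")
  })
}

#' Predict angles (or gaze points) from features
#'
#' @param model a `gsRegressor`.
#' @param features matrix `[samples x inputDim]`.
#' @return numeric vector of angles (degrees) in scalar mode, or a
#'   `[samples x 2]` matrix in coordinate mode.
#' @export
predictRegressor <- function(model, features) {
  .assert(inherits(model, "gsRegressor"), "model is not a gsRegressor")
  features <- as.matrix(features)
  Xs <- t((t(features) - model$xCenter) / model$xScale)
  fw <- .mlpForward(t(Xs), model$params, model$spec, training = FALSE)
  out <- t(fw$out * model$yScale + model$yCenter)
  if (model$spec@outputDim == 1L) as.numeric(out) else out
}

#' Serialize model weights as 32-bit floats
#'
#' Writes all trainable parameters, in layer order, as a raw
#' little-endian float32 payload; the file size is the parameter count
#' times 4 bytes (the wearable deployment budget).
#'
#' @param model a `gsClassifier` or `gsRegressor`.
#' @param path output file.
#' @return invisibly, the number of bytes written.
#' @export
serializeWeights <- function(model, path) {
  vals <- unlist(model$params, use.names = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  invisible(4L * length(vals))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive holding the architecture specs,
#' weight arrays, normalization scales, class list and training seed --
#' enough to reproduce predictions exactly.
#'
#' @param models a model bundle (e.g. from [trainDirectionModels()]) or
#'   a single model.
#' @param path checkpoint file.
#' @return `loadModelCheckpoint` returns the restored object.
#' @export
saveModelCheckpoint <- function(models, path) {
  saveRDS(list(format = "gazeStrain-checkpoint-1", payload = models), path)
  invisible(path)
}

#' @rdname saveModelCheckpoint
#' @export
loadModelCheckpoint <- function(path) {
  obj <- readRDS(path)
  .assert(identical(obj$format, "gazeStrain-checkpoint-1"),
          "not a gazeStrain checkpoint: %s", path)
  obj$payload
}
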