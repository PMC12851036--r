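#' @import methods
NULL

## ---------------------------------------------------------------------------
## Sensor and simulator specifications
## ---------------------------------------------------------------------------

#' Strain-sensor specification
#'
#' Physical description of one strain-sensing array: the gauge factor
#' (slope of relative resistance change versus mechanical strain), the
#' maximal measurable strain, the sampling rate and the additive noise /
#' baseline-drift model. Defaults follow the characterized device: gauge
#' factor 0.169 with a measurement range up to 15 % strain.
#'
#' @slot gaugeFactor dimensionless slope of \eqn{\Delta R/R} vs strain.
#' @slot maxStrain maximal measurable strain (fraction, at most 0.15).
#' @slot samplingRate sampling rate in Hz.
#' @slot noiseSd additive white-noise SD in \eqn{\Delta R/R} units.
#' @slot driftAmplitude baseline-wander amplitude in \eqn{\Delta R/R} units.
#' @slot driftFrequency baseline-wander frequency in Hz (below 0.5).
#' @export
setClass("SensorSpec", representation(
  gaugeFactor = "numeric", maxStrain = "numeric", samplingRate = "numeric",
  noiseSd = "numeric", driftAmplitude = "numeric", driftFrequency = "numeric"
))

setValidity("SensorSpec", function(object) {
  msg <- character()
  if (!.isScalarNum(object@gaugeFactor) || object@gaugeFactor <= 0)
    msg <- c(msg, "gaugeFactor must be a positive scalar")
  if (!.isScalarNum(object@maxStrain) ||
      object@maxStrain <= 0 || object@maxStrain > 0.15)
    msg <- c(msg, "maxStrain must lie in (0, 0.15]")
  if (!.isScalarNum(object@samplingRate) || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be positive")
  if (!.isScalarNum(object@noiseSd) || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be non-negative")
  if (!.isScalarNum(object@driftAmplitude) || object@driftAmplitude < 0)
    msg <- c(msg, "driftAmplitude must be non-negative")
  if (!.isScalarNum(object@driftFrequency) ||
      object@driftFrequency < 0 || object@driftFrequency >= 0.5)
    msg <- c(msg, "driftFrequency must lie in [0, 0.5) Hz")
  if (length(msg)) msg else TRUE
})

#' @param gaugeFactor,maxStrain,samplingRate,noiseSd,driftAmplitude,driftFrequency
#'   see slots.
#' @return a validated `SensorSpec`.
#' @rdname SensorSpec-class
#' @examples
#' sensorSpec()                   # characterized-device defaults
#' sensorSpec(noiseSd = 0)        # noise-free idealization
#' @export
sensorSpec <- function(gaugeFactor = 0.169, maxStrain = 0.15,
                       samplingRate = 50, noiseSd = 0.001,
                       driftAmplitude = 0.002, driftFrequency = 0.2) {
  new("SensorSpec", gaugeFactor = gaugeFactor, maxStrain = maxStrain,
      samplingRate = samplingRate, noiseSd = noiseSd,
      driftAmplitude = driftAmplitude, driftFrequency = driftFrequency)
}

setMethod("show", "SensorSpec", function(object) {
  cat("SensorSpec: gauge factor", object@gaugeFactor,
      "| max strain", object@maxStrain,
      "| fs", object@samplingRate, "Hz",
      "| noise sd", object@noiseSd,
      "| drift", object@driftAmplitude, "@", object@driftFrequency, "Hz\n")
})

#' Direction-dependent strain coupling prior
#'
#' Signed coupling of one gaze direction onto the three sensing units,
#' together with the maximal eyelid strain reached at the reference
#' maximal gaze angle (18 degrees). Biomechanical structure encoded:
#' downward gaze strains the upper eyelid by at most 4 %, all other
#' directions by at most 11 %; for pure vertical directions the 0-degree
#' unit is near-silent (gain at most a tenth of the 90-degree unit), and
#' symmetrically for pure horizontal directions.
#'
#' @slot direction one of [gazeDirections()].
#' @slot unitGains signed coupling per unit, named `ch0, ch45, ch90`,
#'   magnitudes at most 1.
#' @slot maxEyelidStrain strain fraction at the 18-degree reference angle.
#' @export
setClass("DirectionPrior", representation(
  direction = "character", unitGains = "numeric", maxEyelidStrain = "numeric"
))

setValidity("DirectionPrior", function(object) {
  msg <- character()
  d <- object@direction
  g <- object@unitGains
  if (length(d) != 1L || !d %in% gazeDirections())
    msg <- c(msg, "direction must be one of the eight gaze directions")
  if (length(g) != 3L || any(!is.finite(g)) || any(abs(g) > 1))
    msg <- c(msg, "unitGains must be 3 finite values with |gain| <= 1")
  cap <- if (identical(d, "down")) 0.04 else 0.11
  if (!.isScalarNum(object@maxEyelidStrain) ||
      object@maxEyelidStrain <= 0 || object@maxEyelidStrain > cap + 1e-12)
    msg <- c(msg, sprintf("maxEyelidStrain must lie in (0, %.2f] for '%s'",
                          cap, d))
  if (length(g) == 3L && d %in% c("up", "down") &&
      abs(g[1L]) > 0.1 * abs(g[3L]) + 1e-12)
    msg <- c(msg, "vertical prior: |ch0 gain| must be <= 0.1 x |ch90 gain|")
  if (length(g) == 3L && d %in% c("right", "left") &&
      abs(g[3L]) > 0.1 * abs(g[1L]) + 1e-12)
    msg <- c(msg, "horizontal prior: |ch90 gain| must be <= 0.1 x |ch0 gain|")
  if (length(msg)) msg else TRUE
})

#' @param direction,unitGains,maxEyelidStrain see slots.
#' @rdname DirectionPrior-class
#' @export
directionPrior <- function(direction, unitGains, maxEyelidStrain) {
  ug <- as.numeric(unitGains)
  names(ug) <- channelNames()
  new("DirectionPrior", direction = direction, unitGains = ug,
      maxEyelidStrain = maxEyelidStrain)
}

setMethod("show", "DirectionPrior", function(object) {
  cat(sprintf("DirectionPrior '%s': gains (%+.3f, %+.3f, %+.3f), max strain %.3f\n",
              object@direction, object@unitGains[1L], object@unitGains[2L],
              object@unitGains[3L], object@maxEyelidStrain))
})

## ---------------------------------------------------------------------------
## Recording container
## ---------------------------------------------------------------------------

#' Three-channel eyelid-strain recording
#'
#' Timestamped relative-resistance signal of the three sensing units
#' (0/45/90 degrees) with gaze-event annotations and free-form subject
#' metadata. This is the system's raw input.
#'
#' @slot time time stamps (s), strictly increasing at `1/samplingRate`.
#' @slot channels numeric matrix, one column per unit (`ch0, ch45, ch90`),
#'   values are \eqn{\Delta R/R} (dimensionless).
#' @slot samplingRate Hz.
#' @slot annotations data frame of events (`onset`, `hold_duration`,
#'   `direction`, `angle_deg`, `ramp_time`, `kind`).
#' @slot subjectMeta free-form list (age group, sex, eyelid phenotype,
#'   per-subject gain multiplier, ...).
#' @export
setClass("StrainRecording", representation(
  time = "numeric", channels = "matrix", samplingRate = "numeric",
  annotations = "data.frame", subjectMeta = "list"
))

setValidity("StrainRecording", function(object) {
  msg <- character()
  n <- length(object@time)
  if (!is.numeric(object@channels) || ncol(object@channels) != 3L)
    msg <- c(msg, "channels must be a numeric matrix with 3 columns")
  else if (nrow(object@channels) != n)
    msg <- c(msg, "time and channels must have equal length")
  if (any(!is.finite(object@time)) || any(!is.finite(object@channels)))
    msg <- c(msg, "all values must be finite")
  if (!.isScalarNum(object@samplingRate) || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be positive")
  if (n >= 2L) {
    dt <- diff(object@time)
    if (any(dt <= 0))
      msg <- c(msg, "time must be strictly increasing")
    else if (max(abs(dt - 1 / object@samplingRate)) > 1e-6 / object@samplingRate)
      msg <- c(msg, "time must be uniform at 1/samplingRate")
  }
  if (length(msg)) msg else TRUE
})

#' @param time,channels,samplingRate,annotations,subjectMeta see slots.
#' @rdname StrainRecording-class
#' @export
strainRecording <- function(time, channels, samplingRate,
                            annotations = emptyAnnotations(),
                            subjectMeta = list()) {
  channels <- as.matrix(channels)
  colnames(channels) <- channelNames()
  new("StrainRecording", time = as.numeric(time), channels = channels,
      samplingRate = samplingRate, annotations = annotations,
      subjectMeta = subjectMeta)
}

#' Empty annotation table with the canonical columns
#' @return zero-row annotation data frame.
#' @export
emptyAnnotations <- function() {
  data.frame(onset = numeric(), hold_duration = numeric(),
             direction = character(), angle_deg = numeric(),
             ramp_time = numeric(), kind = character(),
             stringsAsFactors = FALSE)
}

setMethod("show", "StrainRecording", function(object) {
  cat(sprintf(
    "StrainRecording: %d samples x 3 channels @ %g Hz (%.1f s), %d annotated events\n",
    length(object@time), object@samplingRate,
    if (length(object@time)) diff(range(object@time)) else 0,
    nrow(object@annotations)))
  if (length(object@subjectMeta))
    cat("  subject:", paste(names(object@subjectMeta),
                            vapply(object@subjectMeta,
                                   function(x) paste(format(x), collapse = ","),
                                   ""), sep = "=", collapse = " "), "\n")
})

## ---------------------------------------------------------------------------
## Window containers
## ---------------------------------------------------------------------------

#' Set of fixed-length signal windows
#'
#' Windows cut around annotated gaze events, stored as a channels x time
#' x windows array with per-window direction label, gaze angle and
#' subject id. Raw windows carry 3 channels; after differential
#' expansion ([expandToTenChannels()]) they carry 10.
#'
#' @slot data numeric array `[channels, time, windows]`.
#' @slot samplingRate Hz.
#' @slot labels per-window direction label (or `NA`).
#' @slot angles per-window gaze angle in degrees (or `NA`).
#' @slot subjects per-window subject id.
#' @slot onsets source-event onsets in seconds (or `NA`).
#' @slot channelIds channel names, length `dim(data)[1]`.
#' @export
setClass("WindowSet", representation(
  data = "array", samplingRate = "numeric", labels = "character",
  angles = "numeric", subjects = "character", onsets = "numeric",
  channelIds = "character"
))

setValidity("WindowSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array [channels, time, windows]")
  else {
    if (length(object@channelIds) != d[1L])
      msg <- c(msg, "channelIds length must match channel dimension")
    if (length(object@labels) != d[3L] || length(object@angles) != d[3L] ||
        length(object@subjects) != d[3L] || length(object@onsets) != d[3L])
      msg <- c(msg, "labels, angles, subjects, onsets must match window count")
    if (any(!is.finite(object@data)))
      msg <- c(msg, "window values must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' @param data,samplingRate,labels,angles,subjects,onsets,channelIds
#'   see slots.
#' @rdname WindowSet-class
#' @export
windowSet <- function(data, samplingRate, labels = NULL, angles = NULL,
                      subjects = NULL, onsets = NULL, channelIds = NULL) {
  nw <- dim(data)[3L]
  if (is.null(labels)) labels <- rep(NA_character_, nw)
  if (is.null(angles)) angles <- rep(NA_real_, nw)
  if (is.null(subjects)) subjects <- rep(NA_character_, nw)
  if (is.null(onsets)) onsets <- rep(NA_real_, nw)
  if (is.null(channelIds)) channelIds <- paste0("c", seq_len(dim(data)[1L]))
  new("WindowSet", data = data, samplingRate = samplingRate,
      labels = as.character(labels), angles = as.numeric(angles),
      subjects = as.character(subjects), onsets = as.numeric(onsets),
      channelIds = channelIds)
}

#' @describeIn WindowSet-class number of windows.
#' @param x,object a `WindowSet`.
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' @rdname WindowSet-class
#' @export
setMethod("nWindows", "WindowSet", function(x) dim(x@data)[3L])

#' @describeIn WindowSet-class the data array.
#' @export
setGeneric("windowData", function(x) standardGeneric("windowData"))

#' @rdname WindowSet-class
#' @export
setMethod("windowData", "WindowSet", function(x) x@data)

#' @describeIn WindowSet-class per-window direction labels.
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))

#' @rdname WindowSet-class
#' @export
setMethod("windowLabels", "WindowSet", function(x) x@labels)

#' @describeIn WindowSet-class per-window gaze angles (degrees).
#' @export
setGeneric("windowAngles", function(x) standardGeneric("windowAngles"))

#' @rdname WindowSet-class
#' @export
setMethod("windowAngles", "WindowSet", function(x) x@angles)

#' @describeIn WindowSet-class per-window subject ids.
#' @export
setGeneric("windowSubjects", function(x) standardGeneric("windowSubjects"))

#' @rdname WindowSet-class
#' @export
setMethod("windowSubjects", "WindowSet", function(x) x@subjects)

#' @rdname WindowSet-class
#' @param i window indices (integer or logical).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "WindowSet", function(x, i, j, ..., drop = FALSE) {
  windowSet(x@data[, , i, drop = FALSE], x@samplingRate,
            x@labels[i], x@angles[i], x@subjects[i], x@onsets[i],
            x@channelIds)
})

setMethod("show", "WindowSet", function(object) {
  d <- dim(object@data)
  lab <- object@labels[!is.na(object@labels)]
  cat(sprintf("WindowSet: %d windows of %d channels x %d samples @ %g Hz\n",
              d[3L], d[1L], d[2L], object@samplingRate))
  if (length(lab)) {
    tab <- table(lab)
    cat("  labels:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
})

## ---------------------------------------------------------------------------
## Model specifications
## ---------------------------------------------------------------------------

#' Inception-style 1-D CNN classifier specification
#'
#' Architecture of the lightweight time-series direction classifier:
#' two inception blocks, each with a kernel-1 bottleneck to 32 channels,
#' three parallel length-preserving convolutions (kernels 17/7/3, 32
#' filters each, bias-free), a max-pool (kernel 3, stride 1) branch
#' followed by a kernel-1 convolution to 32 channels, concatenation to
#' 128 channels, affine batch normalization and a rectifier; then global
#' average pooling and an affine head. With 4 output classes the network
#' has exactly 65,156 trainable parameters.
#'
#' @slot inChannels input channels (10 after differential expansion).
#' @slot nFilters filters per branch (32).
#' @slot kernelSizes the three branch kernel sizes (17, 7, 3).
#' @slot depth number of inception blocks (2; no residual shortcuts).
#' @slot nClasses output classes (4 cardinal directions, or 9 with
#'   obliques plus the blink/expression class).
#' @export
setClass("ClassifierSpec", representation(
  inChannels = "numeric", nFilters = "numeric", kernelSizes = "numeric",
  depth = "numeric", nClasses = "numeric"
))

setValidity("ClassifierSpec", function(object) {
  msg <- character()
  if (object@inChannels < 1) msg <- c(msg, "inChannels must be >= 1")
  if (object@nFilters < 1) msg <- c(msg, "nFilters must be >= 1")
  if (length(object@kernelSizes) != 3L || any(object@kernelSizes < 1))
    msg <- c(msg, "kernelSizes must be 3 positive sizes")
  if (object@depth < 1) msg <- c(msg, "depth must be >= 1")
  if (object@nClasses < 2) msg <- c(msg, "nClasses must be >= 2")
  if (length(msg)) msg else TRUE
})

#' @param inChannels,nFilters,kernelSizes,depth,nClasses see slots.
#' @rdname ClassifierSpec-class
#' @examples
#' countParameters(classifierSpec())            # 65156
#' countParameters(classifierSpec(nClasses = 9))
#' @export
classifierSpec <- function(inChannels = 10, nFilters = 32,
                           kernelSizes = c(17, 7, 3), depth = 2,
                           nClasses = 4) {
  new("ClassifierSpec", inChannels = inChannels, nFilters = nFilters,
      kernelSizes = kernelSizes, depth = depth, nClasses = nClasses)
}

setMethod("show", "ClassifierSpec", function(object) {
  cat(sprintf(
    "ClassifierSpec: %d-ch input, %d filters, kernels (%s), depth %d, %d classes [%d parameters]\n",
    object@inChannels, object@nFilters,
    paste(object@kernelSizes, collapse = ","), object@depth,
    object@nClasses, countParameters(object)))
})

#' MLP angle-regressor specification
#'
#' A four-layer perceptron mapping the 10 signed channel extrema of an
#' expanded window to the gaze angle (scalar mode) or a gaze-point
#' coordinate pair (oblique mode). Hidden sizes 256/128/64 with biases
#' everywhere; with scalar output the network has exactly 44,033
#' trainable parameters.
#'
#' @slot inputDim input features (10).
#' @slot hidden hidden-layer widths (256, 128, 64).
#' @slot outputDim 1 (angle, degrees) or 2 (gaze-point coordinates).
#' @slot dropout dropout probability before the final affine layers.
#' @export
setClass("RegressorSpec", representation(
  inputDim = "numeric", hidden = "numeric", outputDim = "numeric",
  dropout = "numeric"
))

setValidity("RegressorSpec", function(object) {
  msg <- character()
  if (object@inputDim < 1) msg <- c(msg, "inputDim must be >= 1")
  if (length(object@hidden) < 1 || any(object@hidden < 1))
    msg <- c(msg, "hidden widths must be positive")
  if (!object@outputDim %in% c(1, 2))
    msg <- c(msg, "outputDim must be 1 or 2")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param inputDim,hidden,outputDim,dropout see slots.
#' @rdname RegressorSpec-class
#' @examples
#' countParameters(regressorSpec())   # 44033
#' @export
regressorSpec <- function(inputDim = 10, hidden = c(256, 128, 64),
                          outputDim = 1, dropout = 0.2) {
  new("RegressorSpec", inputDim = inputDim, hidden = hidden,
      outputDim = outputDim, dropout = dropout)
}

setMethod("show", "RegressorSpec", function(object) {
  cat(sprintf("RegressorSpec: %d -> %s -> %d, dropout %.2f [%d parameters]\n",
              object@inputDim, paste(object@hidden, collapse = "-"),
              object@outputDim, object@dropout, countParameters(object)))
})

#' Training configuration
#'
#' Optimization settings shared by the classifier and the regressors:
#' Adam with an adaptive learning rate starting at 0.001 decayed over
#' 20 epochs (cosine schedule), seeded for run-to-run reproducibility.
#'
#' @slot learningRate initial learning rate.
#' @slot epochs training epochs.
#' @slot batchSize minibatch size.
#' @slot seed RNG seed for init, shuffling and dropout.
#' @slot valFraction held-out validation fraction (stratified by class).
#' @slot lrSchedule `"cosine"` or `"constant"`.
#' @export
setClass("TrainConfig", representation(
  learningRate = "numeric", epochs = "numeric", batchSize = "numeric",
  seed = "numeric", valFraction = "numeric", lrSchedule = "character"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@epochs < 1) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
  if (object@valFraction < 0 || object@valFraction >= 1)
    msg <- c(msg, "valFraction must lie in [0, 1)")
  if (!object@lrSchedule %in% c("cosine", "constant"))
    msg <- c(msg, "lrSchedule must be 'cosine' or 'constant'")
  if (length(msg)) msg else TRUE
})

#' @param learningRate,epochs,batchSize,seed,valFraction,lrSchedule see slots.
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(learningRate = 0.001, epochs = 20, batchSize = 32,
                        seed = 1, valFraction = 0.2, lrSchedule = "cosine") {
  new("TrainConfig", learningRate = learningRate, epochs = epochs,
      batchSize = batchSize, seed = seed, valFraction = valFraction,
      lrSchedule = lrSchedule)
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf("TrainConfig: Adam lr %g (%s), %d epochs, batch %d, seed %d\n",
              object@learningRate, object@lrSchedule, object@epochs,
              object@batchSize, as.integer(object@seed)))
})

## ---------------------------------------------------------------------------
## Evaluation report
## ---------------------------------------------------------------------------

#' Classifier / regressor evaluation report
#'
#' @slot accuracy overall classification accuracy in \[0, 1\].
#' @slot perClass data frame with `class`, `precision`, `recall`, `f1`,
#'   `support`.
#' @slot confusion confusion matrix (rows = truth, columns = predicted);
#'   row sums equal per-class sample counts.
#' @slot mae overall regression MAE in degrees (`NA` if not evaluated).
#' @slot maePerDirection named per-direction MAE (degrees).
#' @export
setClass("EvalReport", representation(
  accuracy = "numeric", perClass = "data.frame", confusion = "matrix",
  mae = "numeric", maePerDirection = "numeric"
))

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: accuracy %.4f, macro-F1 %.4f",
              object@accuracy, mean(object@perClass$f1)))
  if (is.finite(object@mae)) cat(sprintf(", MAE %.3f deg", object@mae))
  cat("\n")
})
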