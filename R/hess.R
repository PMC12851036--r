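## Digitized Hess screen test: chart geometry, per-position deviation
## measurement, symmetry/size/position diagnosis rules, paretic-muscle
## localization, cover-uncover interpretation.

#' Hess screen geometry
#'
#' Tangent-plane screen geometry: adjacent grid lines are 5 degrees
#' apart when the patient sits half a meter away; the tested field
#' spans the nine cardinal positions at 15 degrees eccentricity.
#'
#' @slot viewingDistance meters (default 0.5).
#' @slot gridStep degrees between adjacent lines (5).
#' @slot innerFieldHalfWidth half-width of the tested field, degrees (15).
#' @export
setClass("HessGeometry", representation(
  viewingDistance = "numeric", gridStep = "numeric",
  innerFieldHalfWidth = "numeric"
))

setValidity("HessGeometry", function(object) {
  msg <- character()
  if (!.isScalarNum(object@viewingDistance) || object@viewingDistance <= 0)
    msg <- c(msg, "viewingDistance must be positive")
  if (!.isScalarNum(object@gridStep) || object@gridStep <= 0)
    msg <- c(msg, "gridStep must be positive")
  if (!.isScalarNum(object@innerFieldHalfWidth) ||
      object@innerFieldHalfWidth <= 0)
    msg <- c(msg, "innerFieldHalfWidth must be positive")
  if (length(msg)) msg else TRUE
})

#' @param viewingDistance,gridStep,innerFieldHalfWidth see slots.
#' @rdname HessGeometry-class
#' @export
hessGeometry <- function(viewingDistance = 0.5, gridStep = 5,
                         innerFieldHalfWidth = 15) {
  new("HessGeometry", viewingDistance = viewingDistance, gridStep = gridStep,
      innerFieldHalfWidth = innerFieldHalfWidth)
}

setMethod("show", "HessGeometry", function(object) {
  cat(sprintf("HessGeometry: %g m distance, %g-degree grid, %g-degree field\n",
              object@viewingDistance, object@gridStep,
              object@innerFieldHalfWidth))
})

## canonical position layout: id 1 = center, then clockwise from 'up'
.hessOuterOrder <- c("up", "up_right", "right", "down_right",
                     "down", "down_left", "left", "up_left")

#' Cardinal-position targets of the Hess chart
#'
#' @param geometry a [HessGeometry-class].
#' @return data frame `positionId` (1 center, 2-9 clockwise from up),
#'   `position`, `targetH`, `targetV` in degrees.
#' @export
hessTargets <- function(geometry = hessGeometry()) {
  e <- geometry@innerFieldHalfWidth
  hv <- list(up = c(0, e), up_right = c(e, e), right = c(e, 0),
             down_right = c(e, -e), down = c(0, -e), down_left = c(-e, -e),
             left = c(-e, 0), up_left = c(-e, e))
  data.frame(positionId = 1:9,
             position = c("center", .hessOuterOrder),
             targetH = c(0, vapply(.hessOuterOrder, function(p) hv[[p]][1L], 0)),
             targetV = c(0, vapply(.hessOuterOrder, function(p) hv[[p]][2L], 0)),
             stringsAsFactors = FALSE)
}

#' Gaze angle to screen coordinates and back
#'
#' Tangent projection onto the screen plane:
#' `x = d tan(h)`, `y = d tan(v)` with viewing distance `d`. The two
#' operations are exact inverses.
#'
#' @param horizontal,vertical gaze angles in degrees, |angle| < 90.
#' @param x,y screen coordinates in meters.
#' @param geometry a [HessGeometry-class].
#' @return `angleToScreen`: matrix with columns `x`, `y` (m);
#'   `screenToAngle`: matrix with columns `horizontal`, `vertical`
#'   (degrees).
#' @examples
#' angleToScreen(5, 0)  # x = 0.5 * tan(5 deg) = 0.043744 m
#' @export
angleToScreen <- function(horizontal, vertical, geometry = hessGeometry()) {
  .assert(all(abs(horizontal) < 90) && all(abs(vertical) < 90),
          "gaze angles must satisfy |angle| < 90 degrees")
  cbind(x = geometry@viewingDistance * tan(horizontal * pi / 180),
        y = geometry@viewingDistance * tan(vertical * pi / 180))
}

#' @rdname angleToScreen
#' @export
screenToAngle <- function(x, y, geometry = hessGeometry()) {
  cbind(horizontal = atan(x / geometry@viewingDistance) * 180 / pi,
        vertical = atan(y / geometry@viewingDistance) * 180 / pi)
}

#' Hess chart of one eye
#'
#' Measured gaze deviations of the tested eye at the nine cardinal
#' positions (mean over repeats), with the fellow eye fixating.
#'
#' @slot eye `"left"` or `"right"` (the tested eye).
#' @slot fixatingEye the fellow eye.
#' @slot points data frame: `positionId`, `position`, `targetH`,
#'   `targetV`, `measuredH`, `measuredV`, `n`, `dispersionH`,
#'   `dispersionV` (degrees).
#' @slot geometry a [HessGeometry-class].
#' @export
setClass("HessChart", representation(
  eye = "character", fixatingEye = "character", points = "data.frame",
  geometry = "HessGeometry"
))

setValidity("HessChart", function(object) {
  msg <- character()
  if (!object@eye %in% c("left", "right"))
    msg <- c(msg, "eye must be 'left' or 'right'")
  p <- object@points
  if (nrow(p) != 9L || anyDuplicated(p$positionId) ||
      !setequal(p$positionId, 1:9))
    msg <- c(msg, "chart must have exactly the 9 cardinal positions")
  else {
    tg <- hessTargets(object@geometry)
    if (!isTRUE(all.equal(p[order(p$positionId), c("targetH", "targetV")],
                          tg[, c("targetH", "targetV")],
                          check.attributes = FALSE)))
      msg <- c(msg, "targets must form the cardinal 3x3 grid")
    if (any(!is.finite(p$measuredH)) || any(!is.finite(p$measuredV)))
      msg <- c(msg, "measured deviations must be finite")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "HessChart", function(object) {
  cat(sprintf("HessChart (%s eye, %s fixating): area %.1f deg^2, mean shift (%+.2f, %+.2f) deg\n",
              object@eye, object@fixatingEye, chartArea(object),
              mean(object@points$measuredH - object@points$targetH),
              mean(object@points$measuredV - object@points$targetV)))
})

#' Build a Hess chart from per-position gaze measurements
#'
#' Averages repeated decoded gaze points per cardinal position (the
#' clinical protocol repeats the test, e.g. six times, and takes the
#' average) and records the per-position dispersion. All nine positions
#' must be measured at least once.
#'
#' @param measurements data frame with columns `position` (one of
#'   `center`, `up`, `up_right`, ..., or a `positionId` 1-9), `h`, `v`
#'   (decoded gaze, degrees); one row per repeat.
#' @param eye tested eye, `"left"` or `"right"`.
#' @param fixatingEye fellow eye; defaults to the other one.
#' @param geometry a [HessGeometry-class].
#' @return a [HessChart-class].
#' @export
buildHessChart <- function(measurements, eye,
                           fixatingEye = setdiff(c("left", "right"), eye),
                           geometry = hessGeometry()) {
  tg <- hessTargets(geometry)
  m <- measurements
  if (!"position" %in% names(m) && "positionId" %in% names(m))
    m$position <- tg$position[match(m$positionId, tg$positionId)]
  .assert(all(m$position %in% tg$position), "unknown position label")
  .assert(all(is.finite(m$h)) && all(is.finite(m$v)),
          "measured gaze must be finite")
  missing <- setdiff(tg$position, m$position)
  .assert(length(missing) == 0L,
          "missing measurements for %d position(s): %s", length(missing),
          paste(missing, collapse = ", "))
  agg <- function(f, col)
    vapply(tg$position, function(p) f(m[m$position == p, col]), 0)
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  pts <- data.frame(tg,
                    measuredH = agg(mean, "h"), measuredV = agg(mean, "v"),
                    n = vapply(tg$position,
                               function(p) sum(m$position == p), 0),
                    dispersionH = agg(sd0, "h"), dispersionV = agg(sd0, "v"),
                    row.names = NULL, stringsAsFactors = FALSE)
  new("HessChart", eye = eye, fixatingEye = fixatingEye, points = pts,
      geometry = geometry)
}

#' Area of the measured Hess field
#'
#' Planar polygon (shoelace) area of the eight outer measured points,
#' ordered by target bearing. Translation-invariant; scaling the chart
#' by `a` scales the area by `a^2`.
#'
#' @param chart a [HessChart-class].
#' @return area in square degrees.
#' @export
chartArea <- function(chart) {
  p <- chart@points
  outer <- p[match(.hessOuterOrder, p$position), ]
  x <- outer$measuredH
  y <- outer$measuredV
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

## action-field lookup: outer position -> muscle, per eye. Abduction is
## temporal (rightward for the right eye), adduction nasal; elevation in
## abduction isolates the superior rectus, elevation in adduction the
## inferior oblique, depression in abduction the inferior rectus,
## depression in adduction the superior oblique. Pure up/down map to the
## primary vertical movers.
.muscleLookup <- function(eye) {
  if (eye == "right") {
    c(right = "lateral rectus", left = "medial rectus",
      up_right = "superior rectus", up_left = "inferior oblique",
      down_right = "inferior rectus", down_left = "superior oblique",
      up = "superior rectus", down = "inferior rectus")
  } else {
    c(left = "lateral rectus", right = "medial rectus",
      up_left = "superior rectus", up_right = "inferior oblique",
      down_left = "inferior rectus", down_right = "superior oblique",
      up = "superior rectus", down = "inferior rectus")
  }
}

## horizontal shift sign -> eso/exo, resolved per eye side: temporal
## shift is exo, nasal is eso. For the right eye temporal = +H.
.horizontalLabel <- function(shiftH, eye, threshold) {
  if (abs(shiftH) < threshold) return("none")
  temporal <- if (eye == "right") shiftH > 0 else shiftH < 0
  if (temporal) "exo" else "eso"
}

.verticalLabel <- function(shiftV, threshold) {
  if (abs(shiftV) < threshold) return("none")
  if (shiftV > 0) "hyper" else "hypo"
}

## radial shortfall of the measured excursion toward each outer target
.underactions <- function(chart) {
  p <- chart@points
  outer <- p[match(.hessOuterOrder, p$position), ]
  tnorm <- sqrt(outer$targetH^2 + outer$targetV^2)
  ux <- outer$targetH / tnorm
  uy <- outer$targetV / tnorm
  u <- (outer$targetH - outer$measuredH) * ux +
    (outer$targetV - outer$measuredV) * uy
  data.frame(position = outer$position, underaction = u,
             muscle = unname(.muscleLookup(chart@eye)[outer$position]),
             stringsAsFactors = FALSE)
}

#' Strabismus diagnosis report
#'
#' @slot paralytic `TRUE` for paralytic (incomitant) strabismus.
#' @slot pareticEye `left`, `right` or `none`.
#' @slot horizontalDeviation `eso`, `exo` or `none`.
#' @slot verticalDeviation `hyper`, `hypo` or `none`.
#' @slot implicatedMuscles character like `"right medial rectus"`;
#'   non-empty iff paralytic.
#' @slot metrics list: chart areas (deg^2), area ratio, per-eye mean
#'   shifts (deg), ranked underaction table of the paretic eye.
#' @export
setClass("DiagnosisReport", representation(
  paralytic = "logical", pareticEye = "character",
  horizontalDeviation = "character", verticalDeviation = "character",
  implicatedMuscles = "character", metrics = "list"
))

setValidity("DiagnosisReport", function(object) {
  msg <- character()
  if (object@paralytic != (length(object@implicatedMuscles) > 0L))
    msg <- c(msg, "implicatedMuscles must be non-empty iff paralytic")
  if (!object@pareticEye %in% c("left", "right", "none"))
    msg <- c(msg, "pareticEye must be left/right/none")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DiagnosisReport", function(object) {
  cat("DiagnosisReport:",
      if (object@paralytic) "paralytic" else "non-paralytic", "strabismus\n")
  cat(sprintf("  paretic eye: %s | horizontal: %s | vertical: %s\n",
              object@pareticEye, object@horizontalDeviation,
              object@verticalDeviation))
  if (length(object@implicatedMuscles))
    cat("  implicated:", paste(object@implicatedMuscles, collapse = "; "),
        "\n")
  cat(sprintf("  areas %.1f / %.1f deg^2 (ratio %.3f)\n",
              object@metrics$areaLeft, object@metrics$areaRight,
              object@metrics$areaRatio))
})

#' Diagnosis thresholds
#'
#' The symmetry / size / position rules are threshold judgments; these
#' are the configurable cut-offs.
#'
#' @param areaRatio charts are asymmetric (paralytic) when
#'   min/max chart area falls below this (default 0.85).
#' @param shift minimal mean deviation, degrees, to call eso/exo or
#'   hyper/hypo (default 2).
#' @param underaction minimal radial shortfall, degrees, for the
#'   underaction ranking (default 2).
#' @return named list of thresholds.
#' @export
hessThresholds <- function(areaRatio = 0.85, shift = 2, underaction = 2) {
  list(areaRatio = areaRatio, shift = shift, underaction = underaction)
}

#' Rule-based strabismus diagnosis from a Hess chart pair
#'
#' Implements the clinical symmetry / size / position analysis:
#' (1) *symmetry* -- the pair is paralytic when the smaller-to-larger
#' chart-area ratio falls below the threshold; (2) *size* -- the
#' paretic eye is the one with the smaller field; (3) *position* -- the
#' mean measured-minus-target shift of the deviating eye is labeled
#' eso/exo (nasal/temporal resolved per eye side) and hyper/hypo;
#' (4) *muscle* -- the implicated extraocular muscle is the one whose
#' action field contains the position of maximal underaction (largest
#' radial shortfall) on the paretic eye. Only single-muscle
#' localization is automated; the full ranked underaction table is
#' returned in the metrics.
#'
#' @param left,right the two [HessChart-class]s (must share geometry).
#' @param thresholds from [hessThresholds()].
#' @return a [DiagnosisReport-class].
#' @export
diagnose <- function(left, right, thresholds = hessThresholds()) {
  .assert(left@eye == "left" && right@eye == "right",
          "pass the left-eye chart first, the right-eye chart second")
  .assert(isTRUE(all.equal(left@geometry, right@geometry)),
          "charts must share the same geometry")
  areaL <- chartArea(left)
  areaR <- chartArea(right)
  ratio <- min(areaL, areaR) / max(areaL, areaR)
  paralytic <- ratio < thresholds$areaRatio
  pareticEye <- if (!paralytic) "none" else
    if (areaR < areaL) "right" else "left"

  shift <- function(ch) c(H = mean(ch@points$measuredH - ch@points$targetH),
                          V = mean(ch@points$measuredV - ch@points$targetV))
  sL <- shift(left)
  sR <- shift(right)
  devEye <- if (paralytic) pareticEye else
    if (sum(sL^2) >= sum(sR^2)) "left" else "right"
  sDev <- if (devEye == "left") sL else sR
  hLab <- .horizontalLabel(sDev[["H"]], devEye, thresholds$shift)
  vLab <- .verticalLabel(sDev[["V"]], thresholds$shift)

  muscles <- character()
  ua <- NULL
  if (paralytic) {
    ua <- .underactions(if (pareticEye == "left") left else right)
    ua <- ua[order(-ua$underaction), ]
    muscles <- paste(pareticEye, ua$muscle[1L])
  }
  new("DiagnosisReport", paralytic = paralytic, pareticEye = pareticEye,
      horizontalDeviation = hLab, verticalDeviation = vLab,
      implicatedMuscles = muscles,
      metrics = list(areaLeft = areaL, areaRight = areaR, areaRatio = ratio,
                     meanShiftLeft = sL, meanShiftRight = sR,
                     underactions = ua, thresholds = thresholds))
}

#' Synthetic single-muscle palsy chart
#'
#' Generates the textbook Hess pattern of an isolated extraocular
#' muscle palsy: the measured point in the muscle's action field is
#' pulled radially toward the center (maximal underaction), its two
#' ring neighbours by half as much, and the whole chart is shifted by
#' the resting deviation the palsy produces (e.g. medial rectus palsy
#' leaves the eye exotropic, so the chart shifts temporally). Labelled
#' synthetic: these charts are generated patterns, not patient data.
#'
#' @param eye the paretic eye.
#' @param muscle one of the six extraocular muscles.
#' @param severity maximal underaction, degrees.
#' @param restShift resting-deviation shift, degrees.
#' @param geometry a [HessGeometry-class].
#' @return a [HessChart-class].
#' @export
generatePalsyChart <- function(eye, muscle, severity = 8, restShift = 3,
                               geometry = hessGeometry()) {
  lk <- .muscleLookup(eye)
  ## canonical (oblique-resolving) field of each muscle
  fields <- names(lk)[match(muscle, lk)]
  field <- setdiff(fields, c("up", "down"))[1L]
  if (is.na(field)) field <- fields[1L]
  .assert(!is.na(field), "unknown muscle '%s'", muscle)
  tg <- hessTargets(geometry)
  pts <- tg
  pts$h <- tg$targetH
  pts$v <- tg$targetV
  ring <- .hessOuterOrder
  fi <- match(field, ring)
  neigh <- ring[c((fi - 2L) %% 8L + 1L, fi %% 8L + 1L)]
  pull <- function(pos, amount) {
    i <- match(pos, pts$position)
    r <- sqrt(pts$targetH[i]^2 + pts$targetV[i]^2)
    pts$h[i] <<- pts$h[i] - amount * pts$targetH[i] / r
    pts$v[i] <<- pts$v[i] - amount * pts$targetV[i] / r
  }
  pull(field, severity)
  for (p in neigh) pull(p, severity / 2)
  ## resting deviation opposite the muscle's action
  shiftHV <- switch(muscle,
    "medial rectus" = c(if (eye == "right") restShift else -restShift, 0),
    "lateral rectus" = c(if (eye == "right") -restShift else restShift, 0),
    "superior rectus" = c(0, -restShift),
    "inferior rectus" = c(0, restShift),
    "superior oblique" = c(0, restShift),
    "inferior oblique" = c(0, -restShift),
    stop(sprintf("unknown muscle '%s'", muscle), call. = FALSE))
  m <- data.frame(position = pts$position, h = pts$h + shiftHV[1L],
                  v = pts$v + shiftHV[2L], stringsAsFactors = FALSE)
  buildHessChart(m, eye, geometry = geometry)
}

#' Cover-uncover test inference
#'
#' @slot tropiaPresent `TRUE` when a manifest deviation was detected.
#' @slot deviatingEye `left`, `right` or `none`.
#' @slot deviationType `eso`, `exo`, `hyper`, `hypo` or `none`.
#' @slot fixatingEye the covered fellow eye.
#' @export
setClass("TropiaInference", representation(
  tropiaPresent = "logical", deviatingEye = "character",
  deviationType = "character", fixatingEye = "character"
))

setValidity("TropiaInference", function(object) {
  if (object@tropiaPresent != (object@deviationType != "none"))
    "deviationType must be 'none' iff no tropia" else TRUE
})

setMethod("show", "TropiaInference", function(object) {
  if (object@tropiaPresent)
    cat(sprintf("TropiaInference: %stropia of the %s eye (%s eye fixating)\n",
                object@deviationType, object@deviatingEye,
                object@fixatingEye))
  else cat("TropiaInference: no manifest deviation detected\n")
})

#' Interpret a cover-uncover recording
#'
#' Detects a sustained directional deflection of the sensed eye that
#' begins within the covered interval and resolves at uncover: the
#' covered fellow eye stops fixating, so a deviating sensed eye makes a
#' refixation movement whose direction reveals the latent deviation.
#' An abduction (temporal) refixation means esotropia of the sensed
#' eye; adduction means exotropia; downward means hypertropia; upward
#' means hypotropia. The fixating eye is the covered fellow eye.
#'
#' @param recording filtered [StrainRecording-class] of the sensed eye.
#' @param coverIntervals data frame with `start`, `end` (seconds) of
#'   the fellow-eye cover; at least one interval, inside the recording.
#' @param eye which eye carries the sensor (`"left"` or `"right"`).
#' @param threshold minimal sustained deflection, relative-resistance
#'   units.
#' @return a [TropiaInference-class].
#' @export
coverUncoverInterpret <- function(recording, coverIntervals, eye,
                                  threshold = 1e-3) {
  .assert(is.data.frame(coverIntervals) && nrow(coverIntervals) >= 1L,
          "at least one cover interval is required")
  .assert(eye %in% c("left", "right"), "eye must be 'left' or 'right'")
  tt <- recording@time
  iv <- coverIntervals[1L, ]
  .assert(iv$start >= tt[1L] && iv$end <= tt[length(tt)] &&
            iv$end > iv$start, "cover interval outside the recording")
  fellow <- setdiff(c("left", "right"), eye)
  ## the refixation movement begins inside the cover interval; on an
  ## AC-coupled (high-pass filtered) channel its signature is the onset
  ## transient, so the decision uses the signed extremum in a short
  ## window after the first suprathreshold excursion
  inIv <- which(tt >= iv$start & tt <= iv$end)
  ch <- recording@channels[inIv, c(1L, 3L), drop = FALSE]
  cross <- which(abs(ch[, 1L]) >= threshold | abs(ch[, 2L]) >= threshold)
  if (!length(cross))
    return(new("TropiaInference", tropiaPresent = FALSE,
               deviatingEye = "none", deviationType = "none",
               fixatingEye = fellow))
  t0 <- tt[inIv[cross[1L]]]
  onset <- inIv[tt[inIv] >= t0 & tt[inIv] <= min(t0 + 0.5, iv$end)]
  ext <- function(x) x[which.max(abs(x))]
  m0 <- ext(recording@channels[onset, 1L])
  m90 <- ext(recording@channels[onset, 3L])
  gaze <- if (abs(m90) >= abs(m0)) {
    if (m90 < 0) "up" else "down"
  } else {
    if (m0 > 0) "right" else "left"
  }
  abductionDir <- if (eye == "left") "left" else "right"
  type <- switch(gaze,
                 up = "hypo", down = "hyper",
                 if (gaze == abductionDir) "eso" else "exo")
  new("TropiaInference", tropiaPresent = TRUE, deviatingEye = eye,
      deviationType = type, fixatingEye = fellow)
}

#' Plot a Hess chart
#'
#' Target grid with the measured field polygon, in the clinical layout.
#'
#' @param chart a [HessChart-class].
#' @param main plot title.
#' @return invisibly, `NULL`.
#' @export
plotHessChart <- function(chart, main = sprintf("%s eye", chart@eye)) {
  p <- chart@points
  e <- chart@geometry@innerFieldHalfWidth
  lim <- c(-e, e) * 1.5
  plot(NA, xlim = lim, ylim = lim, asp = 1, xlab = "horizontal (deg)",
       ylab = "vertical (deg)", main = main)
  graphics::abline(h = seq(-e, e, chart@geometry@gridStep),
                   v = seq(-e, e, chart@geometry@gridStep),
                   col = "grey85")
  graphics::points(p$targetH, p$targetV, pch = 3, col = "grey40")
  outer <- p[match(.hessOuterOrder, p$position), ]
  graphics::polygon(outer$measuredH, outer$measuredV, border = "red3")
  graphics::points(p$measuredH, p$measuredV, pch = 19, col = "red3")
  invisible(NULL)
}
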