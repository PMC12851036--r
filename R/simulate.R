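## Synthetic eyelid-strain signal generator.
##
## Encodes the reported strain-field conclusions only: direction-dependent
## polarity (upward gaze compresses the upper eyelid -> negative 90-degree
## unit signal), magnitudes growing linearly with gaze angle up to the
## 18-degree reference (at most 4 % strain looking down, 11 % otherwise),
## linear strain-to-resistance transduction, saccade-hold-return
## morphology, baseline wander, white noise, blink and expression
## artifacts. No finite-element computation is performed.

#' Linear strain-to-resistance transduction
#'
#' Maps eyelid strain to relative resistance change of a sensing unit,
#' \eqn{\Delta R/R = G \, \varepsilon}, with gauge factor `G` (default
#' 0.169). Sign-preserving and linear through the origin.
#'
#' @param strain strain fraction(s); magnitude must not exceed
#'   `sensor@maxStrain`.
#' @param sensor a [SensorSpec-class].
#' @return relative resistance change(s), same shape as `strain`.
#' @examples
#' strainToResistance(0.10, sensorSpec())  # 0.0169
#' @export
strainToResistance <- function(strain, sensor = sensorSpec()) {
  .assert(all(is.finite(strain)), "strain must be finite")
  bad <- abs(strain) > sensor@maxStrain + 1e-12
  if (any(bad))
    stop(sprintf("strain out of range: |%.4g| exceeds max measurable strain %.4g",
                 strain[which(bad)[1L]], sensor@maxStrain), call. = FALSE)
  sensor@gaugeFactor * strain
}

#' Default direction-coupling priors
#'
#' One [DirectionPrior-class] per gaze direction. Cardinal priors encode
#' the reported polarity and silence structure: `up` drives the
#' 90-degree unit negative (eyelid compression) with max strain 0.11,
#' `down` positive with max strain 0.04; `right`/`left` drive the
#' 0-degree unit positive/negative with max strain 0.11 while the
#' 90-degree unit stays near-silent. The 45-degree unit responds at 0.6
#' times the dominant unit's gain with matching sign. Oblique priors are
#' the vector combination of the two adjacent cardinal strain fields
#' (scaled by \eqn{1/\sqrt{2}}).
#'
#' @return named list of `DirectionPrior` objects, one per
#'   [gazeDirections()].
#' @export
defaultDirectionPriors <- function() {
  card <- list(
    up    = directionPrior("up",    c( 0.05, -0.6, -1.0), 0.11),
    down  = directionPrior("down",  c( 0.05,  0.6,  1.0), 0.04),
    right = directionPrior("right", c( 1.0,   0.6,  0.05), 0.11),
    left  = directionPrior("left",  c(-1.0,  -0.6,  0.05), 0.11)
  )
  obliq <- list(up_left = c("up", "left"), up_right = c("up", "right"),
                down_left = c("down", "left"), down_right = c("down", "right"))
  for (d in names(obliq)) {
    a <- card[[obliq[[d]][1L]]]; b <- card[[obliq[[d]][2L]]]
    v <- (a@unitGains * a@maxEyelidStrain +
          b@unitGains * b@maxEyelidStrain) / sqrt(2)
    m <- max(abs(v))
    card[[d]] <- directionPrior(d, v / m, m)
  }
  card[gazeDirections()]
}

## Raised-cosine ramp-hold-return profile in [0, 1]; zero outside the event.
.eventProfile <- function(t, onset, rampTime, holdDuration) {
  p <- numeric(length(t))
  r1 <- t >= onset & t < onset + rampTime
  p[r1] <- 0.5 * (1 - cos(pi * (t[r1] - onset) / rampTime))
  hl <- t >= onset + rampTime & t <= onset + rampTime + holdDuration
  p[hl] <- 1
  t2 <- onset + rampTime + holdDuration
  r2 <- t > t2 & t < t2 + rampTime
  p[r2] <- 0.5 * (1 + cos(pi * (t[r2] - t2) / rampTime))
  p
}

#' Build a gaze-event table
#'
#' Validates and assembles the annotation rows used by the simulator and
#' the segmenter. Directions may also be the artifact kinds `blink` and
#' `expression` (angle ignored for those).
#'
#' @param onset event onset(s), seconds, non-negative.
#' @param direction per-event direction or artifact kind.
#' @param angle gaze angle(s) in degrees, in \[0, 20\].
#' @param hold_duration hold time(s), seconds.
#' @param ramp_time saccade ramp time(s), seconds, positive.
#' @return annotation data frame (one row per event) with a `kind`
#'   column (`"gaze"`, `"blink"` or `"expression"`).
#' @export
gazeEvents <- function(onset, direction, angle = 10, hold_duration = 0.35,
                       ramp_time = 0.15) {
  n <- length(onset)
  ev <- data.frame(onset = as.numeric(onset),
                   hold_duration = rep_len(as.numeric(hold_duration), n),
                   direction = rep_len(as.character(direction), n),
                   angle_deg = rep_len(as.numeric(angle), n),
                   ramp_time = rep_len(as.numeric(ramp_time), n),
                   stringsAsFactors = FALSE)
  ok <- ev$direction %in% c(gazeDirections(), artifactKinds())
  .assert(all(ok), "unknown direction '%s'", ev$direction[!ok][1L])
  .assert(all(ev$onset >= 0), "onsets must be non-negative")
  .assert(all(ev$angle_deg >= 0 & ev$angle_deg <= 20),
          "angles must lie in [0, 20] degrees")
  .assert(all(ev$ramp_time > 0), "ramp_time must be positive")
  ev$kind <- ifelse(ev$direction %in% artifactKinds(), ev$direction, "gaze")
  ev$angle_deg[ev$kind != "gaze"] <- 0
  ev
}

#' Eyelid strain induced by one gaze event
#'
#' Ramp-hold-return strain profile on the three sensing units. During
#' the hold phase the strain on unit `u` is
#' `unitGains[u] * (angle / 18) * maxEyelidStrain`: linear in gaze angle
#' up to the 18-degree reference (18-20 degrees extrapolate linearly),
#' returning to zero after the return saccade.
#'
#' @param event one-row event data frame (see [gazeEvents()]).
#' @param prior the [DirectionPrior-class] for the event's direction.
#' @param t evaluation time(s), seconds.
#' @return `length(t) x 3` strain matrix (columns `ch0, ch45, ch90`).
#' @export
gazeToStrain <- function(event, prior, t) {
  .assert(is.data.frame(event) && nrow(event) == 1L,
          "event must be a single annotation row")
  .assert(identical(event$direction, prior@direction),
          "event direction '%s' does not match prior '%s'",
          event$direction, prior@direction)
  p <- .eventProfile(t, event$onset, event$ramp_time, event$hold_duration)
  amp <- (event$angle_deg / 18) * prior@maxEyelidStrain
  out <- outer(p, prior@unitGains * amp)
  colnames(out) <- channelNames()
  out
}

## amplitude (strain) of the largest directional event in a table
.maxDirectionalStrain <- function(events, priors) {
  gz <- events[events$kind == "gaze", , drop = FALSE]
  if (!nrow(gz)) return(0)
  max(vapply(seq_len(nrow(gz)), function(i) {
    pr <- priors[[gz$direction[i]]]
    (gz$angle_deg[i] / 18) * pr@maxEyelidStrain * max(abs(pr@unitGains))
  }, 0))
}

## blink: 0.3-s biphasic pulse, same polarity on all channels;
## expression: slow multi-channel half-sine over the event's hold time.
## Amplitudes are clipped to the sensor's max measurable strain.
.artifactStrain <- function(event, t, amp) {
  if (event$kind == "blink") {
    dur <- 0.3
    inwin <- t >= event$onset & t < event$onset + dur
    p <- numeric(length(t))
    p[inwin] <- sin(2 * pi * (t[inwin] - event$onset) / dur)
    gains <- c(1, 1, 1) * stats::runif(3, 0.7, 1)
  } else {
    dur <- max(event$hold_duration, 1)
    inwin <- t >= event$onset & t < event$onset + dur
    p <- numeric(length(t))
    p[inwin] <- sin(pi * (t[inwin] - event$onset) / dur)
    gains <- stats::runif(3, 0.3, 1) * sample(c(-1, 1), 3, replace = TRUE)
  }
  out <- outer(p, gains * amp)
  colnames(out) <- channelNames()
  out
}

#' Generate a synthetic strain recording
#'
#' Composes the per-event generative rules with measurement noise,
#' sinusoidal baseline wander and blink/expression artifacts into a
#' complete, annotated [StrainRecording-class]. Deterministic for a
#' given seed. Events must not overlap; blink/expression events inject
#' brief large-amplitude transients on all channels that follow no
#' directional polarity pattern. Total strain is clipped at the sensor's
#' max measurable strain before transduction, so the transduced signal
#' never exceeds `gaugeFactor * maxStrain` (artifact noise excepted by
#' at most the additive noise).
#'
#' @param events annotation data frame from [gazeEvents()].
#' @param sensor a [SensorSpec-class].
#' @param priors named list of [DirectionPrior-class] (one per direction).
#' @param duration recording length, seconds; must cover all events.
#' @param seed integer seed.
#' @param amplitudeScale per-subject multiplicative gain on directional
#'   strain (individual-difference model; default 1).
#' @param channelScale length-3 multiplicative gain per sensing unit
#'   (attachment-variability model: a misplaced array couples to each
#'   unit differently; default `c(1, 1, 1)`).
#' @param baselineOffset constant additive offset in \eqn{\Delta R/R}.
#' @param subjectMeta free-form metadata list stored on the recording.
#' @return a [StrainRecording-class].
#' @examples
#' ev <- gazeEvents(1, "up", angle = 10)
#' rec <- generateRecording(ev, duration = 4, seed = 1)
#' @export
generateRecording <- function(events, sensor = sensorSpec(),
                              priors = defaultDirectionPriors(),
                              duration = NULL, seed = 1,
                              amplitudeScale = 1, channelScale = c(1, 1, 1),
                              baselineOffset = 0, subjectMeta = list()) {
  events <- events[order(events$onset), , drop = FALSE]
  span <- function(e) {
    ifelse(e$kind == "blink", 0.3,
           ifelse(e$kind == "expression", pmax(e$hold_duration, 1),
                  2 * e$ramp_time + e$hold_duration))
  }
  ends <- events$onset + span(events)
  if (nrow(events) >= 2L) {
    ov <- which(events$onset[-1L] < ends[-nrow(events)] - 1e-9)
    .assert(length(ov) == 0L, "events %d and %d overlap", ov[1L], ov[1L] + 1L)
  }
  if (is.null(duration))
    duration <- if (nrow(events)) max(ends) + 1 else 1
  .assert(!nrow(events) || duration >= max(ends),
          "duration %.2f s does not cover all events", duration)

  fs <- sensor@samplingRate
  t <- seq(0, duration, by = 1 / fs)
  n <- length(t)
  strain <- matrix(0, n, 3L, dimnames = list(NULL, channelNames()))

  withSeed(seed, {
    base <- .maxDirectionalStrain(events, priors)
    ## no gaze events to set a directional scale: saturate the sensor
    artAmp <- if (base > 0) min(1.5 * base, sensor@maxStrain)
              else sensor@maxStrain
    for (i in seq_len(nrow(events))) {
      ev <- events[i, , drop = FALSE]
      if (ev$kind == "gaze") {
        pr <- priors[[ev$direction]]
        .assert(!is.null(pr), "no prior for direction '%s'", ev$direction)
        g <- gazeToStrain(ev, pr, t)
        strain <- strain + amplitudeScale *
          g * rep(channelScale, each = nrow(g))
      } else {
        strain <- strain + .artifactStrain(ev, t, artAmp)
      }
    }
    strain[strain > sensor@maxStrain] <- sensor@maxStrain
    strain[strain < -sensor@maxStrain] <- -sensor@maxStrain
    sig <- strainToResistance(strain, sensor)
    if (sensor@noiseSd > 0)
      sig <- sig + matrix(stats::rnorm(3L * n, 0, sensor@noiseSd), n, 3L)
    if (sensor@driftAmplitude > 0) {
      phase <- stats::runif(3L, 0, 2 * pi)
      for (ch in 1:3)
        sig[, ch] <- sig[, ch] + sensor@driftAmplitude *
          sin(2 * pi * sensor@driftFrequency * t + phase[ch])
    }
    sig <- sig + baselineOffset
    strainRecording(t, sig, fs, annotations = events,
                    subjectMeta = subjectMeta)
  })
}

#' Random event schedule
#'
#' Draws a balanced, shuffled, non-overlapping event sequence in the
#' motility-exam movement regime: amplitudes 5-15 degrees and brief
#' look-and-return movements recurring at 0.1-1 Hz. Holds are short
#' (0.25-0.45 s by default) because the decodable content of an
#' AC-coupled strain channel is the movement transient: a 0.5-Hz
#' high-pass removes any sustained fixation plateau, so the simulator
#' emulates the transient-dominated waveforms the device produces.
#' Uses the current RNG stream (wrap in a seeded context for
#' reproducibility).
#'
#' @param nEvents number of events.
#' @param directions directions to balance over.
#' @param angleRange gaze-angle range in degrees.
#' @param holdRange,gapRange hold / inter-event gap ranges, seconds.
#' @param rampTime saccade ramp time, seconds.
#' @param artifactFraction fraction of extra blink/expression events
#'   interleaved (for the 9-class regime).
#' @param startTime onset of the first event, seconds.
#' @return annotation data frame.
#' @export
randomGazeEvents <- function(nEvents, directions = c("up", "down", "right", "left"),
                             angleRange = c(5, 15), holdRange = c(0.25, 0.45),
                             gapRange = c(0.6, 1.4), rampTime = 0.15,
                             artifactFraction = 0, startTime = 1) {
  dirs <- sample(rep_len(directions, nEvents))
  nArt <- round(artifactFraction * nEvents)
  if (nArt > 0)
    dirs <- sample(c(dirs, sample(artifactKinds(), nArt, replace = TRUE)))
  n <- length(dirs)
  holds <- stats::runif(n, holdRange[1L], holdRange[2L])
  gaps <- stats::runif(n, gapRange[1L], gapRange[2L])
  spans <- ifelse(dirs == "blink", 0.3,
                  ifelse(dirs == "expression", pmax(holds, 1),
                         2 * rampTime + holds))
  onsets <- startTime + cumsum(c(0, (spans + gaps)[-n]))
  angles <- stats::runif(n, angleRange[1L], angleRange[2L])
  gazeEvents(onsets, dirs, angle = angles, hold_duration = holds,
             ramp_time = rampTime)
}

#' Generate a synthetic subject cohort
#'
#' Emulates the individual differences that motivate the learning
#' approach: each subject receives a fixed multiplicative gain
#' perturbation (log-normal with SD `gainJitter`) and a small baseline
#' offset applied to all of its events, recorded in `subjectMeta`
#' together with stratification attributes (age group, sex, eyelid
#' phenotype). With `gainJitter = 0` all subjects are statistically
#' identical generators.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param gainJitter SD of the per-subject log-gain.
#' @param eventsPerSubject gaze events per subject.
#' @param seed integer seed; the cohort is reproducible.
#' @param sensor,priors simulator specification.
#' @param directions,angleRange,artifactFraction passed to
#'   [randomGazeEvents()].
#' @return list of [StrainRecording-class], one per subject.
#' @export
generateCohort <- function(nSubjects = 7, gainJitter = 0.15,
                           eventsPerSubject = 40, seed = 1,
                           sensor = sensorSpec(),
                           priors = defaultDirectionPriors(),
                           directions = c("up", "down", "right", "left"),
                           angleRange = c(5, 15), artifactFraction = 0) {
  .assert(nSubjects >= 1, "nSubjects must be >= 1")
  withSeed(seed, {
    subjSeeds <- sample.int(2^31 - 2, nSubjects)
    lapply(seq_len(nSubjects), function(s) {
      gain <- exp(stats::rnorm(1, 0, gainJitter))
      offset <- stats::rnorm(1, 0, gainJitter * 0.002)
      meta <- list(subject_id = sprintf("S%02d", s),
                   gain = gain, baseline_offset = offset,
                   age_group = sample(c("<35", ">=35"), 1L),
                   sex = sample(c("F", "M"), 1L),
                   eyelid = sample(c("single", "double"), 1L))
      ev <- randomGazeEvents(eventsPerSubject, directions = directions,
                             angleRange = angleRange,
                             artifactFraction = artifactFraction)
      generateRecording(ev, sensor = sensor, priors = priors,
                        seed = subjSeeds[s], amplitudeScale = gain,
                        baselineOffset = offset, subjectMeta = meta)
    })
  })
}
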