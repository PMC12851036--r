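test_that("strain-to-resistance transduction is linear with gauge factor 0.169", {
  s <- sensorSpec()
  expect_equal(strainToResistance(0.10, s), 0.0169)
  expect_identical(strainToResistance(0, s), 0)
  expect_equal(strainToResistance(0.15, s), 0.02535)
  expect_equal(strainToResistance(-0.05, s), -0.169 * 0.05)
  expect_error(strainToResistance(0.16, s), "out of range")
})

test_that("sensor and prior specifications enforce their invariants", {
  expect_error(sensorSpec(gaugeFactor = -1), "gaugeFactor")
  expect_error(sensorSpec(maxStrain = 0.2), "maxStrain")
  expect_error(directionPrior("down", c(0.05, 0.6, 1), 0.11), "0.04")
  expect_error(directionPrior("up", c(0.5, 0.6, 1), 0.11), "ch0 gain")
  expect_error(directionPrior("sideways", c(0, 0, 1), 0.1), "direction")
  expect_error(gazeEvents(1, "up", angle = 25), "\\[0, 20\\]")
})

test_that("gaze-to-strain follows the hold-phase generative rule", {
  priors <- defaultDirectionPriors()
  ev <- gazeEvents(1, "up", angle = 18, hold_duration = 0.5)
  tHold <- 1 + 0.15 + 0.25  # mid-hold
  st <- gazeToStrain(ev, priors$up, tHold)
  expect_lt(st[, "ch90"], 0)                       # compression
  expect_lte(abs(st[, "ch0"]), 0.1 * abs(st[, "ch90"]))
  expect_equal(unname(abs(st[, "ch90"])), 0.11)    # full 18-degree strain

  ev0 <- gazeEvents(1, "up", angle = 0)
  expect_equal(as.numeric(gazeToStrain(ev0, priors$up, tHold)), c(0, 0, 0))

  ev10 <- gazeEvents(1, "up", angle = 10, hold_duration = 0.5)
  ev5 <- gazeEvents(1, "up", angle = 5, hold_duration = 0.5)
  expect_equal(gazeToStrain(ev10, priors$up, tHold),
               2 * gazeToStrain(ev5, priors$up, tHold))

  expect_error(gazeToStrain(ev, priors$down, tHold), "does not match")
})

test_that("polarity table: hold-phase signs follow the unit gains", {
  priors <- defaultDirectionPriors()
  for (d in gazeDirections()) {
    ev <- gazeEvents(1, d, angle = 12, hold_duration = 0.5)
    st <- gazeToStrain(ev, priors[[d]], 1.4)
    active <- abs(priors[[d]]@unitGains) > 1e-9
    expect_equal(sign(st[, active]),
                 sign(priors[[d]]@unitGains[active]),
                 ignore_attr = TRUE)
  }
  expect_true(sign(priors$up@unitGains["ch90"]) ==
                -sign(priors$down@unitGains["ch90"]))
  expect_true(sign(priors$right@unitGains["ch0"]) ==
                -sign(priors$left@unitGains["ch0"]))
})

test_that("peak signal magnitude increases strictly with gaze angle", {
  s <- cleanSensor()
  for (d in gazeDirections()) {
    peaks <- vapply(seq(2, 18, by = 4), function(a) {
      rec <- eventRecording(d, angle = a, sensor = s)
      max(abs(rec@channels))
    }, 0)
    expect_true(all(diff(peaks) > 0), label = sprintf("monotone for %s", d))
  }
})

test_that("strain magnitudes and transduced signals respect the caps", {
  s <- cleanSensor()
  priors <- defaultDirectionPriors()
  for (d in gazeDirections()) {
    cap <- if (d == "down") 0.04 else 0.11
    expect_lte(priors[[d]]@maxEyelidStrain, cap)
  }
  ## with blinks and maximal angles the transduced signal stays within
  ## gauge_factor x max_strain
  ev <- gazeEvents(c(1, 3, 5), c("up", "blink", "right"), angle = 18)
  rec <- generateRecording(ev, sensor = s, duration = 8, seed = 4)
  expect_lte(max(abs(rec@channels)), s@gaugeFactor * s@maxStrain + 1e-12)
})

test_that("recording generation composes events deterministically", {
  s <- cleanSensor()
  empty <- generateRecording(emptyAnnotations(), sensor = s, duration = 2,
                             seed = 1)
  expect_true(all(empty@channels == 0))

  up <- eventRecording("up", angle = 12, sensor = s)
  expect_lt(max(abs(up@channels[, "ch0"])),
            0.1 * max(abs(up@channels[, "ch90"])))

  a <- eventRecording("left", sensor = sensorSpec(), seed = 99)
  b <- eventRecording("left", sensor = sensorSpec(), seed = 99)
  expect_identical(a@channels, b@channels)

  ov <- gazeEvents(c(1, 1.2), c("up", "down"))
  expect_error(generateRecording(ov, duration = 5), "overlap")
  expect_error(generateRecording(gazeEvents(1, "up"), duration = 1),
               "does not cover")
})

test_that("blink and expression artifacts hit all channels without a prior polarity", {
  s <- cleanSensor()
  ev <- gazeEvents(c(1, 3), c("blink", "expression"), hold_duration = 1.5)
  rec <- generateRecording(ev, sensor = s, duration = 7, seed = 2,
                           priors = defaultDirectionPriors())
  ## artifact amplitude defaults to the sensor cap when no gaze events
  ## set a directional scale; all three channels must be excited
  blink <- rec@time >= 1 & rec@time < 1.3
  expect_true(all(apply(abs(rec@channels[blink, ]), 2, max) > 0))
  expr <- rec@time >= 3 & rec@time < 4.5
  expect_true(all(apply(abs(rec@channels[expr, ]), 2, max) > 0))
})

test_that("cohort generation is seeded and records subject metadata", {
  recs <- generateCohort(nSubjects = 7, eventsPerSubject = 4, seed = 5)
  expect_length(recs, 7)
  ids <- vapply(recs, function(r) r@subjectMeta$subject_id, "")
  expect_false(anyDuplicated(ids) > 0)
  expect_true(all(vapply(recs, function(r)
    all(c("gain", "age_group", "sex", "eyelid") %in% names(r@subjectMeta)),
    TRUE)))

  recs2 <- generateCohort(nSubjects = 7, eventsPerSubject = 4, seed = 5)
  expect_identical(lapply(recs, function(r) r@channels),
                   lapply(recs2, function(r) r@channels))

  flat <- generateCohort(nSubjects = 3, gainJitter = 0, eventsPerSubject = 2,
                         seed = 1)
  expect_true(all(vapply(flat, function(r) r@subjectMeta$gain, 0) == 1))
})
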