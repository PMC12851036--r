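test_that("tangent projection maps angles to screen coordinates and back", {
  g <- hessGeometry()
  expect_equal(as.numeric(angleToScreen(0, 0, g)), c(0, 0))
  ## 5 degrees at half a meter
  expect_equal(angleToScreen(5, 0, g)[1, "x"], 0.5 * tan(5 * pi / 180),
               ignore_attr = TRUE)
  expect_equal(angleToScreen(5, 0, g)[1, "x"], 0.043744, tolerance = 1e-4,
               ignore_attr = TRUE)
  ## round trip to numerical precision
  h <- c(-20, -5, 0, 12.5, 44)
  v <- c(10, -30, 0.1, 0, -1)
  sc <- angleToScreen(h, v, g)
  back <- screenToAngle(sc[, "x"], sc[, "y"], g)
  expect_lt(max(abs(back[, "horizontal"] - h)), 1e-9)
  expect_lt(max(abs(back[, "vertical"] - v)), 1e-9)
  sc2 <- angleToScreen(back[, "horizontal"], back[, "vertical"], g)
  expect_lt(max(abs(sc2 - sc)), 1e-12)
  expect_error(angleToScreen(90, 0, g), "< 90")
})

test_that("chart construction averages repeats and demands all nine positions", {
  tg <- hessTargets()
  perfect <- onTargetChart("left")
  expect_equal(perfect@points$measuredH, perfect@points$targetH)
  expect_equal(perfect@points$measuredV, perfect@points$targetV)

  ## six repeats with a deterministic spread: measured is their mean
  reps <- do.call(rbind, lapply(1:6, function(k)
    data.frame(position = tg$position, h = tg$targetH + (k - 3.5) * 0.2,
               v = tg$targetV - (k - 3.5) * 0.1)))
  ch <- buildHessChart(reps, "right")
  expect_equal(ch@points$measuredH, tg$targetH)
  expect_equal(ch@points$measuredV, tg$targetV)
  expect_true(all(ch@points$n == 6))
  expect_true(all(ch@points$dispersionH > 0))

  ## permutation invariance in repeat order
  perm <- reps[sample(nrow(reps)), ]
  expect_equal(buildHessChart(perm, "right")@points, ch@points)

  expect_error(buildHessChart(reps[reps$position != "up", ], "right"),
               "missing measurements")
})

test_that("chart area follows the shoelace rule with its invariances", {
  ch <- onTargetChart("left")
  p <- ch@points[match(c("up", "up_right", "right", "down_right", "down",
                         "down_left", "left", "up_left"),
                       ch@points$position), ]
  expect_equal(chartArea(ch), shoelaceOracle(p$measuredH, p$measuredV))
  expect_equal(chartArea(ch), 900)

  ## translation invariance
  tg <- hessTargets()
  shifted <- buildHessChart(data.frame(position = tg$position,
                                       h = tg$targetH + 4,
                                       v = tg$targetV - 2), "left")
  expect_equal(chartArea(shifted), chartArea(ch))

  ## scaling law
  half <- buildHessChart(data.frame(position = tg$position,
                                    h = tg$targetH * 0.5,
                                    v = tg$targetV * 0.5), "left")
  expect_equal(chartArea(half), 0.25 * chartArea(ch))
})

test_that("diagnosis applies the symmetry, size and position rules", {
  normal <- onTargetChart("left")
  ## Hess pattern of a right medial rectus palsy: right chart smaller,
  ## maximal underaction in adduction, mean temporal shift
  palsy <- generatePalsyChart("right", "medial rectus")
  rep <- diagnose(normal, palsy)
  expect_true(rep@paralytic)
  expect_equal(rep@pareticEye, "right")
  expect_equal(rep@horizontalDeviation, "exo")
  expect_equal(rep@implicatedMuscles, "right medial rectus")
  expect_lt(rep@metrics$areaRatio, 0.85)

  ## both charts on target: nothing to report
  none <- diagnose(onTargetChart("left"), onTargetChart("right"))
  expect_false(none@paralytic)
  expect_equal(none@pareticEye, "none")
  expect_equal(none@horizontalDeviation, "none")
  expect_equal(none@verticalDeviation, "none")
  expect_length(none@implicatedMuscles, 0)

  ## comitant case: left chart uniformly 5 degrees nasal (rightward for
  ## the left eye), equal areas -> non-paralytic left esotropia
  tg <- hessTargets()
  eso <- buildHessChart(data.frame(position = tg$position,
                                   h = tg$targetH + 5, v = tg$targetV),
                        "left")
  rep2 <- diagnose(eso, onTargetChart("right"))
  expect_false(rep2@paralytic)
  expect_equal(rep2@horizontalDeviation, "eso")
  expect_length(rep2@implicatedMuscles, 0)

  other <- generatePalsyChart("right", "medial rectus",
                              geometry = hessGeometry(viewingDistance = 1))
  expect_error(diagnose(normal, other), "geometry")
})

test_that("each single-muscle palsy chart recovers its generating muscle", {
  muscles <- c("medial rectus", "lateral rectus", "superior rectus",
               "inferior rectus", "superior oblique", "inferior oblique")
  for (eye in c("left", "right")) {
    fellow <- setdiff(c("left", "right"), eye)
    for (m in muscles) {
      palsy <- generatePalsyChart(eye, m)
      charts <- if (eye == "left")
        list(palsy, onTargetChart("right")) else
        list(onTargetChart("left"), palsy)
      rep <- diagnose(charts[[1]], charts[[2]])
      expect_true(rep@paralytic)
      expect_equal(rep@pareticEye, eye)
      expect_equal(rep@implicatedMuscles, paste(eye, m),
                   label = sprintf("%s %s", eye, m))
    }
  }
})

test_that("muscle lookup covers all eight outer positions uniquely per eye", {
  ring <- c("up", "up_right", "right", "down_right", "down", "down_left",
            "left", "up_left")
  for (eye in c("left", "right")) {
    lk <- gazeStrain:::.muscleLookup(eye)
    expect_setequal(names(lk), ring)
    expect_true(all(lk %in% c("medial rectus", "lateral rectus",
                              "superior rectus", "inferior rectus",
                              "superior oblique", "inferior oblique")))
    expect_false(anyNA(lk[ring]))
  }
})

test_that("diagnosis is mirror-consistent", {
  ## mirror the world left-right: swap eyes and negate horizontal axes
  mirrorChart <- function(chart, newEye) {
    p <- chart@points
    mirrored <- data.frame(
      position = chartMirrorPos(p$position),
      h = -p$measuredH, v = p$measuredV)
    buildHessChart(mirrored, newEye, geometry = chart@geometry)
  }
  chartMirrorPos <- function(pos) {
    swap <- c(center = "center", up = "up", down = "down",
              left = "right", right = "left",
              up_left = "up_right", up_right = "up_left",
              down_left = "down_right", down_right = "down_left")
    unname(swap[pos])
  }
  normal <- onTargetChart("left")
  palsy <- generatePalsyChart("right", "superior oblique")
  orig <- diagnose(normal, palsy)
  mirrored <- diagnose(mirrorChart(palsy, "left"),
                       mirrorChart(normal, "right"))
  expect_equal(mirrored@paralytic, orig@paralytic)
  expect_equal(mirrored@pareticEye, "left")           # swapped
  expect_equal(mirrored@horizontalDeviation, orig@horizontalDeviation)
  expect_equal(mirrored@verticalDeviation, orig@verticalDeviation)
  expect_equal(mirrored@metrics$areaRatio, orig@metrics$areaRatio)
})

test_that("cover-uncover interpretation maps refixation direction to tropia", {
  s <- cleanSensor()
  cover <- data.frame(start = 2, end = 5)
  ## left eye swings temporally (abduction = leftward) while the right
  ## eye is covered -> left esotropia, right eye fixating
  mkRec <- function(dir) {
    ev <- gazeEvents(2.5, dir, angle = 10, hold_duration = 2)
    highpassFilter(generateRecording(ev, sensor = s, duration = 8, seed = 1))
  }
  inf <- coverUncoverInterpret(mkRec("left"), cover, eye = "left")
  expect_true(inf@tropiaPresent)
  expect_equal(inf@deviationType, "eso")
  expect_equal(inf@deviatingEye, "left")
  expect_equal(inf@fixatingEye, "right")

  ## adduction deflection -> exotropia of the sensed eye
  inf2 <- coverUncoverInterpret(mkRec("right"), cover, eye = "left")
  expect_equal(inf2@deviationType, "exo")

  ## vertical refixations: downward movement reveals hypertropia
  inf3 <- coverUncoverInterpret(mkRec("down"), cover, eye = "left")
  expect_equal(inf3@deviationType, "hyper")
  inf4 <- coverUncoverInterpret(mkRec("up"), cover, eye = "left")
  expect_equal(inf4@deviationType, "hypo")

  ## flat signal during cover: no tropia
  flat <- highpassFilter(generateRecording(emptyAnnotations(), sensor = s,
                                           duration = 8, seed = 1))
  inf5 <- coverUncoverInterpret(flat, cover, eye = "left")
  expect_false(inf5@tropiaPresent)
  expect_equal(inf5@deviationType, "none")

  expect_error(coverUncoverInterpret(flat, cover[0, ], eye = "left"),
               "cover interval")
})
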