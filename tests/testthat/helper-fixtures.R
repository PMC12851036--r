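## Shared fixtures, built in code at test time.

## noise-free sensor for deterministic signal-shape checks
cleanSensor <- function(fs = 50) {
  sensorSpec(noiseSd = 0, driftAmplitude = 0, samplingRate = fs)
}

## single-event recording with generous padding around the event
eventRecording <- function(direction, angle = 10, sensor = sensorSpec(),
                           seed = 1, hold = 0.35, onset = 3) {
  ev <- gazeEvents(onset, direction, angle = angle, hold_duration = hold)
  generateRecording(ev, sensor = sensor, duration = onset + hold + 3,
                    seed = seed)
}

## an undeviated Hess chart (measured exactly on target)
onTargetChart <- function(eye, geometry = hessGeometry()) {
  tg <- hessTargets(geometry)
  buildHessChart(data.frame(position = tg$position, h = tg$targetH,
                            v = tg$targetV),
                 eye = eye, geometry = geometry)
}

## independent brute-force DTW oracle: plain recursive definition with
## memoisation, usable for sequences of length <= 6
bruteForceDtw <- function(a, b) {
  memo <- array(NA_real_, c(length(a), length(b)))
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    if (i == 0 || j == 0) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- abs(a[i] - b[j]) + min(rec(i - 1, j), rec(i, j - 1),
                                rec(i - 1, j - 1))
    memo[i, j] <<- v
    v
  }
  rec(length(a), length(b))
}

## independent shoelace oracle for polygon area
shoelaceOracle <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  abs(s) / 2
}

## two-way ANOVA mean-squares oracle via base aov
anovaMsOracle <- function(a, b) {
  n <- length(a)
  df <- data.frame(y = c(a, b),
                   subject = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  list(msr = tab["subject", "Mean Sq"],
       msc = tab["rater", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"])
}
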