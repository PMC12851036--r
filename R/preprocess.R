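## Preprocessing: zero-phase high-pass filtering, event-centered
## segmentation, ten-channel differential expansion, robust scaling.

#' Zero-phase high-pass filter
#'
#' Removes baseline wander with a 4th-order Butterworth high-pass
#' (default cutoff 0.5 Hz) applied forward-backward (`filtfilt`), so
#' event peaks are not time-shifted and the DC component is rejected.
#'
#' @param recording a [StrainRecording-class].
#' @param cutoff high-pass cutoff in Hz; must be below Nyquist/1.
#' @return the filtered [StrainRecording-class] (annotations and
#'   metadata preserved).
#' @export
highpassFilter <- function(recording, cutoff = 0.5) {
  fs <- recording@samplingRate
  .assert(fs > 2 * cutoff, "sampling rate %g Hz too low for cutoff %g Hz",
          fs, cutoff)
  bf <- signal::butter(4, cutoff / (fs / 2), type = "high")
  ch <- recording@channels
  for (j in seq_len(ncol(ch)))
    ch[, j] <- signal::filtfilt(bf, ch[, j])
  strainRecording(recording@time, ch, fs,
                  annotations = recording@annotations,
                  subjectMeta = recording@subjectMeta)
}

#' Cut event-centered windows from a recording
#'
#' One fixed-length window per annotated event, centered on the event
#' onset and carrying the event's direction label and gaze angle.
#' Windows that would extend past the recording edges are dropped. An
#' empty annotation table yields an empty window set (not an error).
#'
#' @param recording a [StrainRecording-class] (typically filtered).
#' @param annotations event table; defaults to the recording's own.
#' @param windowSeconds window length in seconds (must give at least 16
#'   samples).
#' @return a 3-channel [WindowSet-class].
#' @export
segmentWindows <- function(recording, annotations = recording@annotations,
                           windowSeconds = 2) {
  fs <- recording@samplingRate
  Tlen <- round(windowSeconds * fs)
  .assert(Tlen >= 16, "window of %g s x %g Hz has fewer than 16 samples",
          windowSeconds, fs)
  n <- length(recording@time)
  half <- Tlen %/% 2
  keep <- list(); labs <- character(); angs <- numeric(); ons <- numeric()
  subj <- if (!is.null(recording@subjectMeta$subject_id))
    recording@subjectMeta$subject_id else NA_character_
  for (i in seq_len(nrow(annotations))) {
    ctr <- round((annotations$onset[i] - recording@time[1L]) * fs) + 1L
    lo <- ctr - half; hi <- lo + Tlen - 1L
    if (lo < 1L || hi > n) next  # clipped at edge: dropped
    keep[[length(keep) + 1L]] <- t(recording@channels[lo:hi, , drop = FALSE])
    labs <- c(labs, annotations$direction[i])
    angs <- c(angs, annotations$angle_deg[i])
    ons <- c(ons, annotations$onset[i])
  }
  nw <- length(keep)
  data <- array(0, c(3L, Tlen, nw))
  for (i in seq_len(nw)) data[, , i] <- keep[[i]]
  windowSet(data, fs, labels = if (nw) labs else character(),
            angles = if (nw) angs else numeric(),
            subjects = rep(subj, nw),
            onsets = if (nw) ons else numeric(),
            channelIds = channelNames())
}

#' Ten-channel differential expansion
#'
#' Expands each 3-channel window to the 10-channel model input built
#' from channel differences and time differences: the three raw unit
#' signals `s0, s45, s90`; the pairwise channel differences `s0-s45`,
#' `s45-s90`, `s0-s90`; the lag-1 time differences of each unit
#' (zero-padded at the first sample); and the lag-K time difference of
#' the channel mean with `K = round(0.2 s x sampling rate)`, capturing a
#' longer deformation timescale. The expansion is linear.
#'
#' @param windows a 3-channel [WindowSet-class].
#' @param longLagSeconds lag of the channel-mean difference (default 0.2 s).
#' @return a 10-channel [WindowSet-class] (labels/angles/subjects
#'   carried through).
#' @export
expandToTenChannels <- function(windows, longLagSeconds = 0.2) {
  d <- dim(windows@data)
  .assert(d[1L] == 3L, "expected 3-channel windows, got %d channels", d[1L])
  Tlen <- d[2L]; nw <- d[3L]
  K <- max(1L, round(longLagSeconds * windows@samplingRate))
  out <- array(0, c(10L, Tlen, nw))
  x <- windows@data
  out[1:3, , ] <- x
  out[4L, , ] <- x[1L, , ] - x[2L, , ]
  out[5L, , ] <- x[2L, , ] - x[3L, , ]
  out[6L, , ] <- x[1L, , ] - x[3L, , ]
  if (Tlen > 1L)
    out[7:9, 2:Tlen, ] <- x[, 2:Tlen, , drop = FALSE] -
      x[, 1:(Tlen - 1L), , drop = FALSE]
  m <- (x[1L, , ] + x[2L, , ] + x[3L, , ]) / 3
  m <- matrix(m, Tlen, nw)  # guard nw == 1
  if (Tlen > K)
    out[10L, (K + 1L):Tlen, ] <- m[(K + 1L):Tlen, ] - m[1:(Tlen - K), ]
  windowSet(out, windows@samplingRate, windows@labels, windows@angles,
            windows@subjects, windows@onsets,
            channelIds = c("s0", "s45", "s90", "d0_45", "d45_90", "d0_90",
                           "dt0", "dt45", "dt90", "dtK_mean"))
}

#' Fit per-channel robust scales on a training set
#'
#' The scale of each channel is the 95th percentile of absolute signal
#' values over all training windows (falling back to 1 for an all-zero
#' channel). Scaling is division only -- no centering -- so the
#' positive/negative polarity that carries the physiology survives.
#'
#' @param windows the training [WindowSet-class].
#' @return numeric vector of positive per-channel scales.
#' @export
fitNormalization <- function(windows) {
  d <- dim(windows@data)
  sc <- vapply(seq_len(d[1L]), function(ch) {
    q <- stats::quantile(abs(windows@data[ch, , ]), 0.95, names = FALSE)
    if (q <= 0) 1 else q
  }, 0)
  names(sc) <- windows@channelIds
  sc
}

#' Apply per-channel scaling
#'
#' Channel-wise division by a stored training-set scale.
#'
#' @param windows a [WindowSet-class].
#' @param scale positive per-channel scale vector (from
#'   [fitNormalization()]).
#' @return the scaled [WindowSet-class].
#' @export
normalizeWindows <- function(windows, scale) {
  d <- dim(windows@data)
  .assert(length(scale) == d[1L], "scale length %d != %d channels",
          length(scale), d[1L])
  .assert(all(scale > 0), "scales must be positive")
  out <- windows@data / array(scale, d)  # recycles over channel dim
  windowSet(out, windows@samplingRate, windows@labels, windows@angles,
            windows@subjects, windows@onsets, windows@channelIds)
}
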