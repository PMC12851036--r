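## Reference classifiers the learned model is benchmarked against: the
## physiological polarity rule and k-nearest-neighbours with dynamic
## time warping.

#' Polarity-rule direction classifier
#'
#' Classifies each (filtered) 3-channel window from the signed extrema
#' of the vertical and horizontal units alone: if the 90-degree-unit
#' extremum dominates, negative means `up` (eyelid compression) and
#' positive means `down`; if the 0-degree-unit extremum dominates, the
#' sign maps to `right` (positive) / `left` (negative) under the
#' simulator convention. Below-threshold windows are `"uncertain"`.
#' The rule is antisymmetric: negating a window flips the class.
#'
#' @param windows a 3-channel [WindowSet-class].
#' @param threshold minimal extremum magnitude, relative-resistance
#'   units.
#' @return character vector of `up/down/right/left/uncertain`.
#' @export
polarityClassify <- function(windows, threshold = 5e-4) {
  d <- dim(windows@data)
  .assert(d[1L] == 3L, "polarity rule expects 3-channel windows")
  feats <- extractRegressionFeatures(windows)  # signed extrema
  e0 <- feats[, 1L]
  e90 <- feats[, 3L]
  out <- ifelse(pmax(abs(e0), abs(e90)) < threshold, "uncertain",
                ifelse(abs(e90) >= abs(e0),
                       ifelse(e90 < 0, "up", "down"),
                       ifelse(e0 > 0, "right", "left")))
  as.character(out)
}

#' Dynamic-time-warping alignment cost
#'
#' Standard dynamic-programming alignment cost with absolute-difference
#' local cost and match/insert/delete steps (unconstrained warping).
#' For multichannel inputs (matrices `[channels x time]`) the per-channel
#' costs are summed. Symmetric in its arguments.
#'
#' @param a,b numeric vectors, or matrices with equal channel counts;
#'   non-empty.
#' @return non-negative cost; 0 iff the sequences are identical.
#' @examples
#' dtwDistance(c(0, 1, 2), c(0, 2))  # 1
#' @export
dtwDistance <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- as.matrix(a); b <- as.matrix(b)
    .assert(nrow(a) == nrow(b), "channel counts differ (%d vs %d)",
            nrow(a), nrow(b))
    .assert(ncol(a) > 0 && ncol(b) > 0, "sequences must be non-empty")
    return(sum(vapply(seq_len(nrow(a)),
                      function(ch) .dtwCostC(a[ch, ], b[ch, ]), 0)))
  }
  .assert(length(a) > 0 && length(b) > 0, "sequences must be non-empty")
  .dtwCostC(as.numeric(a), as.numeric(b))
}

#' KNN-DTW direction classifier
#'
#' Majority vote among the `k` training windows nearest to each query
#' under multichannel DTW (sum of per-channel costs); ties are broken
#' in favour of the tied class with the smallest total distance.
#'
#' @param train labeled [WindowSet-class] (the reference set).
#' @param query [WindowSet-class] to classify.
#' @param k neighbours, at most the training-set size.
#' @return character vector of predicted labels.
#' @export
knnDtwClassify <- function(train, query, k = 5) {
  nTr <- nWindows(train)
  .assert(nTr > 0L, "training set is empty")
  .assert(k >= 1L && k <= nTr, "k must lie in [1, %d]", nTr)
  labs <- windowLabels(train)
  .assert(!anyNA(labs), "training windows must be labeled")
  nQ <- nWindows(query)
  out <- character(nQ)
  for (q in seq_len(nQ)) {
    qw <- query@data[, , q]
    dist <- vapply(seq_len(nTr),
                   function(i) dtwDistance(qw, train@data[, , i]), 0)
    nb <- order(dist)[seq_len(k)]
    votes <- table(labs[nb])
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) > 1L) {
      tot <- vapply(winners,
                    function(cl) sum(dist[nb][labs[nb] == cl]), 0)
      winners <- winners[which.min(tot)]
    }
    out[q] <- winners[1L]
  }
  out
}
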