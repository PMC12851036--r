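## Shared conventions: channel order, direction vocabulary, sign conventions.
## Single source of truth -- referenced by every module.

#' Channel and direction conventions
#'
#' The sensing array carries three units oriented at 0, 45 and 90 degrees;
#' channels are always ordered `ch0, ch45, ch90`. Direction labels are
#' head-centric: `up`/`down` refer to elevation/depression, `right`/`left`
#' to the subject's right/left. Sign conventions: upward gaze compresses
#' the upper eyelid, giving a *negative* 90-degree-unit signal; downward
#' gaze stretches it (positive). Leftward gaze drives the 0-degree unit
#' negative, rightward positive. Adduction/abduction are resolved per eye
#' side in the Hess and cover-uncover layers.
#'
#' @return `gazeDirections()` returns the eight gaze direction labels;
#'   `artifactKinds()` the two artifact labels; `channelNames()` the three
#'   raw channel names in canonical order.
#' @export
gazeDirections <- function() {
  c("up", "down", "right", "left",
    "up_left", "up_right", "down_left", "down_right")
}

#' @rdname gazeDirections
#' @export
artifactKinds <- function() c("blink", "expression")

#' @rdname gazeDirections
#' @export
channelNames <- function() c("ch0", "ch45", "ch90")

## Evaluate `code` under a temporary RNG state seeded with `seed`;
## the caller's RNG stream is untouched.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

## stopifnot with a formatted message
.assert <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = call.)
  invisible(TRUE)
}

.isScalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
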