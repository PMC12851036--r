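## Method-agreement statistics between wearable-derived deviations and
## a reference test: ICC(A,1) with F-based confidence interval,
## Bland-Altman bias and 95% limits of agreement, folded empirical
## cumulative distribution (mountain plot), subgroup stratification.

#' Agreement summary for one set of paired measurements
#'
#' @slot icc intraclass correlation point estimate (two-way random
#'   effects, absolute agreement, single measurement); may be negative
#'   for discordant data.
#' @slot iccLow,iccHigh 95% confidence bounds on the ICC.
#' @slot bias mean difference (method A minus method B), degrees.
#' @slot loaLow,loaHigh 95% limits of agreement, degrees.
#' @slot loaLowCI,loaHighCI approximate 95% confidence intervals on the
#'   limits themselves.
#' @slot n number of pairs.
#' @export
setClass("AgreementResult", representation(
  icc = "numeric", iccLow = "numeric", iccHigh = "numeric",
  bias = "numeric", loaLow = "numeric", loaHigh = "numeric",
  loaLowCI = "numeric", loaHighCI = "numeric", n = "numeric"
))

setMethod("show", "AgreementResult", function(object) {
  cat(sprintf("AgreementResult (n = %d):\n", as.integer(object@n)))
  cat(sprintf("  ICC(A,1) %.3f, 95%% CI (%.3f, %.3f)\n", object@icc,
              object@iccLow, object@iccHigh))
  cat(sprintf("  bias %+.3f, 95%% LoA (%.3f, %.3f)\n", object@bias,
              object@loaLow, object@loaHigh))
})

#' Intraclass correlation, absolute agreement, single measurement
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' computed from the two-way ANOVA mean squares (subjects x methods),
#' with the standard F-based 95% confidence interval. This is the
#' conventional form for method-comparison studies.
#'
#' @param a,b paired measurements of the two methods (length >= 3).
#' @param conf confidence level (default 0.95).
#' @return list with `icc`, `lower`, `upper`, the mean squares
#'   (`msr`, `msc`, `mse`) and `n`.
#' @export
iccAbsoluteAgreement <- function(a, b, conf = 0.95) {
  .assert(length(a) == length(b), "paired vectors must have equal length")
  n <- length(a)
  .assert(n >= 3L, "need at least 3 pairs, got %d", n)
  .assert(all(is.finite(a)) && all(is.finite(b)), "values must be finite")
  k <- 2
  X <- cbind(a, b)
  grand <- mean(X)
  rowm <- rowMeans(X)
  colm <- colMeans(X)
  .assert(stats::var(as.numeric(X)) > 0, "degenerate input: zero total variance")
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((X - grand)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  ## F-based interval (two-way random, absolute agreement, single rater)
  alpha <- 1 - conf
  fj <- msc / mse
  if (!is.finite(fj) || mse == 0) {
    lower <- upper <- icc
  } else {
    vn <- (k - 1) * (n - 1) *
      (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
    vd <- (n - 1) * k^2 * icc^2 * fj^2 +
      (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- vn / vd
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }
  list(icc = icc, lower = lower, upper = upper, msr = msr, msc = msc,
       mse = mse, n = n)
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences `d = a - b`: bias is `mean(d)`, the 95% limits of
#' agreement are `bias +/- 1.96 sd(d)`. Approximate 95% confidence
#' intervals on the limits use the standard variance of a limit,
#' `sd^2 (1/n + 1.96^2 / (2(n-1)))`.
#'
#' @param a,b paired measurements (length >= 2).
#' @return list with `bias`, `loaLow`, `loaHigh`, `loaLowCI`,
#'   `loaHighCI`, `sd`, and the per-pair `means` and `diffs` for
#'   plotting.
#' @export
blandAltman <- function(a, b) {
  .assert(length(a) == length(b), "paired vectors must have equal length")
  n <- length(a)
  .assert(n >= 2L, "need at least 2 pairs, got %d", n)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  loaLow <- bias - 1.96 * s
  loaHigh <- bias + 1.96 * s
  seLim <- sqrt(s^2 * (1 / n + 1.96^2 / (2 * (n - 1))))
  z <- stats::qnorm(0.975)
  list(bias = bias, loaLow = loaLow, loaHigh = loaHigh,
       loaLowCI = c(loaLow - z * seLim, loaLow + z * seLim),
       loaHighCI = c(loaHigh - z * seLim, loaHigh + z * seLim),
       sd = s, means = (a + b) / 2, diffs = d, n = n)
}

#' Folded empirical cumulative distribution (mountain plot)
#'
#' Folded percentiles `p* = min(p, 1 - p)` of the empirical CDF of the
#' differences, using the Hazen plotting position `(i - 0.5)/n`. The
#' folded curve peaks at the median and never exceeds 0.5.
#'
#' @param differences numeric vector (length >= 1).
#' @return data frame with `value` (sorted) and `folded`.
#' @export
foldedEcdf <- function(differences) {
  .assert(length(differences) >= 1L, "need at least one difference")
  v <- sort(differences)
  p <- (seq_along(v) - 0.5) / length(v)
  data.frame(value = v, folded = pmin(p, 1 - p))
}

.agreementRow <- function(a, b, stratum, minIcc = 3L, minCI = 5L) {
  n <- length(a)
  flagged <- n < minIcc
  icc <- c(icc = NA_real_, lower = NA_real_, upper = NA_real_)
  ba <- list(bias = NA_real_, loaLow = NA_real_, loaHigh = NA_real_)
  if (!flagged) {
    ic <- iccAbsoluteAgreement(a, b)
    icc <- c(icc = ic$icc,
             lower = if (n >= minCI) ic$lower else NA_real_,
             upper = if (n >= minCI) ic$upper else NA_real_)
    ba <- blandAltman(a, b)
  }
  data.frame(stratum = stratum, n = n, icc = icc[["icc"]],
             icc_low = icc[["lower"]], icc_high = icc[["upper"]],
             bias = ba$bias, loa_low = ba$loaLow, loa_high = ba$loaHigh,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Stratified agreement table
#'
#' Applies [iccAbsoluteAgreement()] and [blandAltman()] within each
#' stratum (e.g. direction, age group, sex, eyelid phenotype) and adds
#' a pooled row. Strata below the estimation minimum (3 pairs; 5 for
#' confidence intervals) are flagged, not silently dropped.
#'
#' @param pairs data frame with columns `method_a`, `method_b`.
#' @param strata optional factor/character vector (same length) of
#'   stratum labels; `NULL` gives only the pooled row.
#' @return data frame, one row per stratum plus `"pooled"`, with
#'   columns `stratum`, `n`, `icc`, `icc_low`, `icc_high`, `bias`,
#'   `loa_low`, `loa_high`, `flagged`.
#' @export
stratifiedAgreement <- function(pairs, strata = NULL) {
  .assert(all(c("method_a", "method_b") %in% names(pairs)),
          "pairs must have columns method_a and method_b")
  a <- pairs$method_a
  b <- pairs$method_b
  out <- .agreementRow(a, b, "pooled")
  if (!is.null(strata)) {
    .assert(length(strata) == length(a),
            "strata must match the number of pairs")
    for (s in sort(unique(as.character(strata)))) {
      sel <- strata == s
      out <- rbind(out, .agreementRow(a[sel], b[sel], s))
    }
  }
  rownames(out) <- NULL
  out
}

#' Agreement analysis of one set of pairs
#'
#' Convenience wrapper returning an [AgreementResult-class] combining
#' the ICC and Bland-Altman summaries.
#'
#' @param a,b paired measurements (length >= 3).
#' @return an [AgreementResult-class].
#' @export
agreementAnalysis <- function(a, b) {
  ic <- iccAbsoluteAgreement(a, b)
  ba <- blandAltman(a, b)
  new("AgreementResult", icc = ic$icc, iccLow = ic$lower,
      iccHigh = ic$upper, bias = ba$bias, loaLow = ba$loaLow,
      loaHigh = ba$loaHigh, loaLowCI = ba$loaLowCI,
      loaHighCI = ba$loaHighCI, n = length(a))
}

#' Mean-difference (Bland-Altman) plot
#'
#' @param a,b paired measurements.
#' @param main title.
#' @return invisibly, the [blandAltman()] summary.
#' @export
plotBlandAltman <- function(a, b, main = "Mean-difference plot") {
  ba <- blandAltman(a, b)
  plot(ba$means, ba$diffs, pch = 19, col = "grey30",
       xlab = "mean of methods (deg)", ylab = "difference (deg)",
       main = main)
  graphics::abline(h = ba$bias, col = "red3")
  graphics::abline(h = c(ba$loaLow, ba$loaHigh), col = "red3", lty = 2)
  invisible(ba)
}

#' Mountain (folded ECDF) plot
#'
#' @param differences numeric vector of paired differences.
#' @param main title.
#' @return invisibly, the [foldedEcdf()] table.
#' @export
plotMountain <- function(differences, main = "Folded empirical CDF") {
  fe <- foldedEcdf(differences)
  plot(fe$value, fe$folded, type = "b", pch = 19, col = "grey30",
       xlab = "difference (deg)", ylab = "folded percentile", main = main)
  graphics::abline(v = stats::median(differences), col = "red3", lty = 2)
  invisible(fe)
}
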