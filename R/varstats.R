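## Variability statistics: order-statistic quantiles, QCD, CV and per-bin
## profiles.  The quartile estimator is linear interpolation of order
## statistics (index h = (n - 1) p + 1), i.e. stats::quantile() type 7.

#' Quantile by linear interpolation of order statistics
#'
#' The index convention is \eqn{h = (n - 1) p + 1}: the quantile interpolates
#' linearly between the order statistics bracketing `h`.
#'
#' @param values Non-empty numeric vector.
#' @param p Probability (or probabilities) in [0, 1].
#' @return Quantile value(s).
#' @examples
#' linQuantile(c(1, 2, 3, 4, 5), 0.25)   # 2
#' linQuantile(c(2, 4, 6, 8), 0.75)      # 6.5
#' @export
linQuantile <- function(values, p) {
  if (!length(values)) stop("empty input")
  if (any(p < 0 | p > 1)) stop("'p' must be in [0, 1]")
  unname(quantile(values, p, type = 7, names = FALSE))
}

#' @describeIn qcd QCD of a numeric vector (n >= 4).
#' @export
setMethod("qcd", "numeric", function(x, ...) {
  if (length(x) < 4L) stop("need >= 4 values for quartiles")
  q <- linQuantile(x, c(0.25, 0.75))
  if (q[1] + q[2] <= 0)
    stop("QCD undefined: q1 + q3 = ", signif(q[1] + q[2], 4), " <= 0")
  (q[2] - q[1]) / (q[2] + q[1])
})

#' @describeIn qcd stored QCD of a summary.
#' @export
setMethod("qcd", "VariabilitySummary", function(x, ...) x@qcd)

#' @describeIn cv CV of a numeric vector (n >= 2, positive mean).
#' @export
setMethod("cv", "numeric", function(x, ...) {
  if (length(x) < 2L) stop("need >= 2 values")
  m <- mean(x)
  if (m <= 0) stop("CV undefined for non-positive mean")
  sd(x) / m
})

#' @describeIn cv stored CV of a summary.
#' @export
setMethod("cv", "VariabilitySummary", function(x, ...) x@cv)

#' Summarise the variability of a set of values
#'
#' @param values Numeric vector (n >= 4 for quartile statistics).
#' @return A [VariabilitySummary-class] object.  `qcd` is `NA` when
#'   q1 + q3 <= 0 and `cv` is `NA` when the mean is not positive.
#' @export
variabilitySummary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) stop("need >= 4 finite values")
  q <- linQuantile(values, c(0.25, 0.5, 0.75))
  m <- mean(values); s <- sd(values)
  new("VariabilitySummary", n = length(values),
      q1 = q[1], q2 = q[2], q3 = q[3],
      qcd = if (q[1] + q[3] > 0) (q[3] - q[1]) / (q[3] + q[1]) else NA_real_,
      cv = if (m > 0) s / m else NA_real_,
      mean = m, sd = s)
}

#' Per-length-bin variability profile
#'
#' Groups cells into length bins and summarises the given signal column per
#' bin.  Bins with fewer than `min_n` cells are reported in attribute
#' `"underpopulated"` but not summarised.  Background rows are excluded.
#'
#' @param tab Cell table.
#' @param values_col Name of the column to summarise (for example
#'   `"signal_HPG_corr"`).
#' @param binning A [LengthBinning-class] object.
#' @param min_n Minimum cells per reported bin (default 50).
#' @return A data.frame with columns `bin_centre_um`, `n`, `q1`, `q2`, `q3`,
#'   `qcd`, `cv`.
#' @export
binVariabilityProfile <- function(tab, values_col, binning = LengthBinning(),
                                  min_n = 50) {
  stopifnot(min_n >= 4)
  .checkChannel(tab, values_col)
  tab <- tab[!tab$is_background & is.finite(tab[[values_col]]), ,
             drop = FALSE]
  tab <- assignLengthBins(tab, binning)
  groups <- split(tab[[values_col]], tab$length_bin_um)
  counts <- lengths(groups)
  keep <- counts >= min_n
  if (!any(keep)) stop("no length bin holds >= ", min_n, " cells")
  rows <- lapply(names(groups)[keep], function(b) {
    s <- variabilitySummary(groups[[b]])
    data.frame(bin_centre_um = as.numeric(b), n = s@n, q1 = s@q1, q2 = s@q2,
               q3 = s@q3, qcd = s@qcd, cv = s@cv)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$bin_centre_um), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "underpopulated") <- as.numeric(names(groups)[!keep])
  out
}
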