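## Background correction, length binning and the two signal-normalisation
## schemes.  All functions consume and return the cell table; derived values
## are appended as new columns (signal_<ch>_scaled, _corr, _norm, _lennorm),
## never overwritten.

.signalCol <- function(channel) paste0("signal_", channel)

.checkChannel <- function(tab, col) {
  if (!col %in% names(tab)) stop("missing channel column '", col, "'")
  invisible(TRUE)
}

#' Scale signals by the median background intensity
#'
#' Divides each cell's total signal (sample and background rows alike) by the
#' median total signal of the background sample, putting experiments on a
#' common scale.  QCD and CV are invariant under this pure rescaling.
#'
#' @param tab Cell table with an `is_background` column.
#' @param channels Channels to scale (default `"HPG"`).
#' @return `tab` with appended `signal_<ch>_scaled` columns; the scale used is
#'   in attribute `"background_median"`.
#' @export
backgroundScale <- function(tab, channels = "HPG") {
  if (!any(tab$is_background)) stop("background sample is empty")
  meds <- numeric(0)
  for (ch in channels) {
    col <- .signalCol(ch)
    .checkChannel(tab, col)
    m <- median(tab[[col]][tab$is_background], na.rm = TRUE)
    if (!is.finite(m) || m <= 0)
      stop("non-positive background median for channel ", ch)
    tab[[paste0(col, "_scaled")]] <- tab[[col]] / m
    meds[ch] <- m
  }
  attr(tab, "background_median") <- meds
  tab
}

#' Bin-wise background subtraction
#'
#' For each 1-um length bin (or the binning given), the median scaled
#' background signal is computed on the background sample and subtracted from
#' each cell in that bin.  Bins with no background cells fall back to the
#' global background median (reported in attribute `"fallback_bins"`).
#' Negative corrected values are retained.
#'
#' @param tab Cell table with `signal_<ch>_scaled` columns (see
#'   [backgroundScale()]).
#' @param channels Channels to correct.
#' @param binning A [LengthBinning-class] object.
#' @return `tab` with appended `signal_<ch>_corr` columns.
#' @export
backgroundSubtractBinned <- function(tab, channels = "HPG",
                                     binning = LengthBinning()) {
  stopifnot(is(binning, "LengthBinning"))
  if (!any(tab$is_background)) stop("background sample is empty")
  w <- binning@width_um
  bin <- floor(tab$length_um / w)
  fallback <- character(0)
  for (ch in channels) {
    col <- paste0(.signalCol(ch), "_scaled")
    if (!col %in% names(tab))
      stop("column '", col, "' not found; run backgroundScale() first")
    bg <- tab$is_background
    med_by_bin <- tapply(tab[[col]][bg], bin[bg], median, na.rm = TRUE)
    global_med <- median(tab[[col]][bg], na.rm = TRUE)
    m <- med_by_bin[as.character(bin)]
    miss <- is.na(m)
    if (any(miss & !bg)) {
      fb <- sort(unique(bin[miss & !bg])) * w + w / 2
      fallback <- union(fallback, as.character(fb))
      message("channel ", ch, ": ", length(fb),
              " length bin(s) without background cells; ",
              "using the global background median")
    }
    m[miss] <- global_med
    tab[[paste0(.signalCol(ch), "_corr")]] <- tab[[col]] - as.numeric(m)
  }
  attr(tab, "fallback_bins") <- fallback
  tab
}

#' Length normalisation by OLS prediction
#'
#' Fits an ordinary least squares regression of signal on cell length
#' (intercept included, unweighted, background rows excluded) and divides
#' each observed signal by the signal predicted for its length.  Cells with a
#' non-positive predicted signal are set to `NA` and counted in attribute
#' `"n_excluded"`.
#'
#' @param tab Cell table.
#' @param channel Channel to normalise.
#' @param signal_col Column holding the signal to normalise; defaults to the
#'   raw `signal_<channel>`.
#' @return `tab` with an appended `<signal_col>_lennorm` column.
#' @export
lengthNormalizeOLS <- function(tab, channel = "HPG", signal_col = NULL) {
  if (is.null(signal_col)) signal_col <- .signalCol(channel)
  .checkChannel(tab, signal_col)
  use <- !tab$is_background & is.finite(tab[[signal_col]])
  if (sum(use) < 3L) stop("need >= 3 cells for the OLS fit")
  len <- tab$length_um[use]
  if (sd(len) == 0) stop("zero length variance: OLS fit is degenerate")
  fit <- lm(tab[[signal_col]][use] ~ len)
  pred <- rep(NA_real_, nrow(tab))
  pred[use] <- coef(fit)[1] + coef(fit)[2] * len
  bad <- use & pred <= 0
  out <- rep(NA_real_, nrow(tab))
  ok <- use & pred > 0
  out[ok] <- tab[[signal_col]][ok] / pred[ok]
  if (any(bad))
    message(sum(bad), " cell(s) with non-positive predicted signal excluded")
  tab[[paste0(signal_col, "_lennorm")]] <- out
  attr(tab, "n_excluded") <- sum(bad)
  attr(tab, "ols_coef") <- unname(coef(fit))
  tab
}

#' Per-length median normalisation
#'
#' Divides each signal by the cell length, then by the population median of
#' signal/length (background rows excluded from the median), so the
#' population median of the output is exactly 1.
#'
#' @param tab Cell table.
#' @param channel Channel to normalise.
#' @param signal_col Column holding the signal; defaults to the raw channel
#'   signal.
#' @return `tab` with an appended `<signal_col>_norm` column.
#' @export
perLengthMedianNormalize <- function(tab, channel = "HPG",
                                     signal_col = NULL) {
  if (is.null(signal_col)) signal_col <- .signalCol(channel)
  .checkChannel(tab, signal_col)
  per_len <- tab[[signal_col]] / tab$length_um
  use <- !tab$is_background & is.finite(per_len)
  m <- median(per_len[use])
  if (!is.finite(m) || m <= 0)
    stop("non-positive population median of signal/length")
  tab[[paste0(signal_col, "_norm")]] <- per_len / m
  tab
}

#' Assign cells to half-open length bins
#'
#' Bin edges sit at integer multiples of the bin width, bins are half-open
#' `[k w, (k+1) w)`, and the label is the bin centre, so the bins partition
#' the population: every cell falls in exactly one bin and the bin counts sum
#' to the table size.
#'
#' @param tab Cell table with positive `length_um`.
#' @param binning A [LengthBinning-class] object.
#' @return `tab` with an appended `length_bin_um` column (bin centre).
#' @examples
#' tab <- data.frame(length_um = c(7.0, 7.999, 12.3))
#' assignLengthBins(tab)$length_bin_um   # 7.5 7.5 12.5
#' @export
assignLengthBins <- function(tab, binning = LengthBinning()) {
  stopifnot(is(binning, "LengthBinning"))
  if (any(tab$length_um <= 0)) stop("lengths must be positive")
  w <- binning@width_um
  tab$length_bin_um <- floor(tab$length_um / w) * w + w / 2
  tab
}
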