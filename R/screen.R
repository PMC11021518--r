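## Replicate-thresholded QCD variability screen across strains, and paired
## replicate comparisons.

#' Per-strain, per-replicate QCD table
#'
#' Two conventions are supported, matching the two assays of the screen:
#' \describe{
#'   \item{`mean_signal`}{QCD of the per-cell mean signal (total signal
#'     divided by mask area) divided by the median value for the sample;
#'     background not subtracted (imaging-flow-cytometry convention).}
#'   \item{`length_normalized`}{QCD of the OLS length-normalised raw signal
#'     (see [lengthNormalizeOLS()]); background not subtracted (microscopy
#'     convention).}
#' }
#' The median division leaves the QCD unchanged (scale invariance); it is
#' applied so the returned per-cell values are also usable for density plots.
#'
#' @param tab Cell table with `strain_id` and `replicate` columns.
#' @param mode `"mean_signal"` or `"length_normalized"`.
#' @param channel Channel (default `"HPG"`).
#' @param min_cells Minimum cells per strain x replicate; undersized samples
#'   are excluded with a warning (default 100).
#' @return A data.frame with columns `strain_id`, `replicate`, `qcd`, `n`.
#' @export
strainQCDTable <- function(tab, mode = c("mean_signal", "length_normalized"),
                           channel = "HPG", min_cells = 100) {
  mode <- match.arg(mode)
  col <- .signalCol(channel)
  .checkChannel(tab, col)
  tab <- tab[!tab$is_background, , drop = FALSE]
  pieces <- split(tab, list(tab$strain_id, tab$replicate), drop = TRUE)
  rows <- lapply(pieces, function(sub) {
    if (nrow(sub) < min_cells) {
      warning("sample ", sub$strain_id[1], " replicate ", sub$replicate[1],
              " has ", nrow(sub), " cells (< ", min_cells, "); excluded")
      return(NULL)
    }
    vals <- if (mode == "mean_signal") {
      per_cell <- if ("area_px" %in% names(sub) && all(sub$area_px > 0))
        sub[[col]] / sub$area_px else sub[[col]]
      per_cell / median(per_cell)
    } else {
      lengthNormalizeOLS(sub, channel)[[paste0(col, "_lennorm")]]
    }
    vals <- vals[is.finite(vals)]
    data.frame(strain_id = sub$strain_id[1],
               replicate = sub$replicate[1],
               qcd = qcd(vals), n = length(vals),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no sample meets 'min_cells'")
  out <- out[order(out$strain_id, out$replicate), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag strains with atypical variability
#'
#' Compares each strain's mean QCD against the spread of wild-type replicate
#' QCDs: strains above `wt_mean + k * wt_sd` are flagged `"high"`, below
#' `wt_mean - k * wt_sd` `"low"`, otherwise `"none"` (sample SD, n - 1
#' denominator; k = 1.5 by default).
#'
#' @param qcd_tab Output of [strainQCDTable()].
#' @param wt_strain Label of the wild-type strain (default `"WT"`).
#' @param k Threshold in wild-type SDs (default 1.5).
#' @return A data.frame with one row per strain: `strain_id`, `n_replicates`,
#'   `qcd_mean`, `qcd_sd`, `wt_mean`, `wt_sd`, `flag`.
#' @export
flagVariability <- function(qcd_tab, wt_strain = "WT", k = 1.5) {
  wt <- qcd_tab$qcd[qcd_tab$strain_id == wt_strain]
  if (length(wt) < 2L)
    stop("need >= 2 wild-type replicates (SD undefined otherwise)")
  wt_mean <- mean(wt); wt_sd <- sd(wt)
  rows <- lapply(split(qcd_tab, qcd_tab$strain_id), function(sub) {
    m <- mean(sub$qcd)
    flag <- if (m > wt_mean + k * wt_sd) "high"
            else if (m < wt_mean - k * wt_sd) "low" else "none"
    data.frame(strain_id = sub$strain_id[1], n_replicates = nrow(sub),
               qcd_mean = m,
               qcd_sd = if (nrow(sub) > 1L) sd(sub$qcd) else NA_real_,
               wt_mean = wt_mean, wt_sd = wt_sd, flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired replicate comparison of QCD values
#'
#' Two-sided paired t-test on replicate-matched differences.  (The protocol
#' this mirrors labels the test "Welch's unequal variances paired t test";
#' Welch's correction applies to unpaired samples, so the paired test is the
#' default and an unpaired Welch test is available via `method = "welch"`.)
#' Zero-variance differences are degenerate: the statistic is reported as 0
#' (all differences zero) or signed infinity, with a warning.
#'
#' @param qcd_a,qcd_b Per-replicate values, replicate-matched, equal length
#'   >= 2.
#' @param method `"paired"` (default) or `"welch"` (unpaired, unequal
#'   variances).
#' @return List with `t`, `p`, `df` and `method`.
#' @export
pairedDifferenceTest <- function(qcd_a, qcd_b,
                                 method = c("paired", "welch")) {
  method <- match.arg(method)
  if (length(qcd_a) != length(qcd_b) || length(qcd_a) < 2L)
    stop("need replicate-matched vectors of equal length >= 2")
  if (method == "paired" && sd(qcd_a - qcd_b) == 0) {
    d <- (qcd_a - qcd_b)[1]
    warning("zero-variance differences: degenerate paired t statistic")
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else 0,
                df = length(qcd_a) - 1L, method = method))
  }
  tt <- if (method == "paired") t.test(qcd_a, qcd_b, paired = TRUE)
        else t.test(qcd_a, qcd_b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), method = method)
}
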