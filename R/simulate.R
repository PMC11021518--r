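## Synthetic single-cell pulse-labelling data.
##
## Each cell carries a latent log synthesis rate X(t): a stationary Gaussian
## process with SD s and stretched-exponential correlation, sampled on a
## 1-min grid restricted to the pulse windows (one Cholesky factorization of
## the grid correlation matrix, reused across cells).  True incorporation per
## pulse is mean_rate * integral of L(t) * exp(X(t) - s^2/2) over the window
## (trapezoidal); the observed signal adds lognormal multiplicative
## measurement noise and a lognormal background draw.

## deterministic 31-bit substream seed from the master seed and labels, so
## adding samples never perturbs existing ones
.substreamSeed <- function(seed, ...) {
  M <- 2147483563
  key <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% M
  as.integer((((seed %% M) * 48271) %% M + h) %% M + 1)
}

## steady-state age distribution of an exponentially growing population:
## density proportional to 2^(-a/T) on [0, T]; CDF F(a) = 2 (1 - 2^(-a/T))
.sampleAge <- function(n, generation_min, sampling = c("exponential",
                                                       "uniform")) {
  sampling <- match.arg(sampling)
  u <- runif(n)
  if (sampling == "uniform") u * generation_min
  else -generation_min * log2(1 - u / 2)
}

.cellLength <- function(growth, age_min) {
  growth@birth_length_um +
    (growth@division_length_um - growth@birth_length_um) *
    age_min / growth@generation_min
}

## rod (spherocylinder) area in pixels for a cell of given length
.rodAreaPx <- function(length_um, px_per_um, width_um = 3.5) {
  body <- pmax(length_um - width_um, 0) * width_um
  caps <- pi * (width_um / 2)^2
  as.integer(round((body + caps) * px_per_um^2))
}

#' Simulate one sample of single-cell pulse-labelling measurements
#'
#' Generates a table of cell records for one sample: ages drawn from the
#' steady-state age distribution of an exponentially growing population,
#' linear elongation from birth to division length, a stationary lognormal
#' rate process integrated over each pulse window, multiplicative measurement
#' noise and additive lognormal background per channel.  Cells whose
#' cell-cycle position at fixation falls in the final `binucleate_fraction`
#' of the cycle carry two nuclei.  Fixation is at the end of the last pulse
#' (or immediately, for background-only samples, which carry background draws
#' only).  Output is deterministic for a fixed seed.
#'
#' @param n_cells Number of cells (>= 1).
#' @param rate A [RateProcessParams-class] object.
#' @param growth A [GrowthParams-class] object.
#' @param meas A [MeasurementParams-class] object.
#' @param pulses List of [PulseScheme-class] objects, one per channel.
#' @param strain A [StrainSpec-class]; its `s_multiplier` scales the log-rate
#'   SD.
#' @param sample_id Sample label (default derived from strain and replicate).
#' @param replicate Replicate index.
#' @param seed Integer seed.
#' @param background_only Generate a background sample (cells fixed
#'   immediately after analogue addition: autofluorescence only).
#' @param age_sampling `"exponential"` (steady state, default) or
#'   `"uniform"`.
#' @param horizon_min Optional simulation horizon; pulses extending beyond it
#'   are an error.  Defaults to the last pulse end.
#' @return A data.frame with columns `cell_id`, `sample_id`, `strain_id`,
#'   `replicate`, `length_um`, `area_px`, `n_nuclei`, `is_background`,
#'   `signal_HPG`, `signal_AHA` (NA for unpulsed channels) and `age_min`.
#' @examples
#' wt <- wildTypeParams()
#' cells <- simulateCells(100, wt$rate, wt$growth, wt$meas,
#'                        list(PulseScheme("HPG", 0, 5)), seed = 1)
#' head(cells)
#' @export
simulateCells <- function(n_cells, rate, growth, meas, pulses,
                          strain = StrainSpec(), sample_id = NULL,
                          replicate = 1L, seed = 1L,
                          background_only = FALSE,
                          age_sampling = c("exponential", "uniform"),
                          horizon_min = NULL) {
  stopifnot(is(rate, "RateProcessParams"), is(growth, "GrowthParams"),
            is(meas, "MeasurementParams"), is(strain, "StrainSpec"))
  if (!is.numeric(n_cells) || n_cells < 1)
    stop("'n_cells' must be a positive integer")
  n_cells <- as.integer(n_cells)
  if (!length(pulses) || !all(vapply(pulses, is, logical(1), "PulseScheme")))
    stop("'pulses' must be a non-empty list of PulseScheme objects")
  chans <- vapply(pulses, function(p) p@channel, character(1))
  if (anyDuplicated(chans)) stop("one pulse per channel")
  ends <- vapply(pulses, function(p) p@start_min + p@duration_min, numeric(1))
  t_fix <- if (background_only) 0 else max(ends)
  if (!is.null(horizon_min) && any(ends > horizon_min))
    stop("pulse extends beyond the simulated horizon of ", horizon_min,
         " min")
  age_sampling <- match.arg(age_sampling)
  if (is.null(sample_id))
    sample_id <- paste0(strain@strain_id, "_r", replicate,
                        if (background_only) "_bg")

  set.seed(as.integer(seed))
  age <- .sampleAge(n_cells, growth@generation_min, age_sampling)
  s_eff <- rate@s * strain@s_multiplier

  signals <- matrix(NA_real_, n_cells, 2,
                    dimnames = list(NULL, c("HPG", "AHA")))
  if (!background_only) {
    tgrid <- sort(unique(unlist(lapply(pulses, function(p) {
      e <- p@start_min + p@duration_min
      unique(c(seq(p@start_min, e, by = 1), e))
    }))))
    if (s_eff > 0 && length(tgrid) > 1L) {
      U <- processCorrelationMatrix(rate, tgrid, chol = TRUE)
      X <- crossprod(U, matrix(rnorm(length(tgrid) * n_cells),
                               length(tgrid), n_cells)) * s_eff
    } else {
      X <- matrix(rnorm(length(tgrid) * n_cells) * 0, length(tgrid), n_cells)
      if (s_eff > 0) X[] <- rnorm(length(X)) * s_eff  # single-point grid
    }
    for (p in pulses) {
      e <- p@start_min + p@duration_min
      idx <- which(tgrid >= p@start_min - 1e-9 & tgrid <= e + 1e-9)
      tt <- tgrid[idx]
      w <- diff(tt); w <- c(w / 2, 0) + c(0, w / 2)   # trapezoid
      incorp <- numeric(n_cells)
      E <- exp(X[idx, , drop = FALSE] - s_eff^2 / 2)
      for (k in seq_along(idx))
        incorp <- incorp + w[k] * .cellLength(growth, age + tt[k]) * E[k, ]
      incorp <- incorp * rate@mean_rate
      eps <- if (meas@sigma_meas > 0)
        exp(rnorm(n_cells, 0, meas@sigma_meas) - meas@sigma_meas^2 / 2)
      else rep(1, n_cells)
      bg <- rlnorm(n_cells, log(meas@background_median),
                   meas@background_log_sd)
      signals[, p@channel] <- incorp * eps + bg
    }
  } else {
    for (p in pulses)
      signals[, p@channel] <- rlnorm(n_cells, log(meas@background_median),
                                     meas@background_log_sd)
  }

  len_fix <- .cellLength(growth, age + t_fix)
  phase <- pmin((age + t_fix) / growth@generation_min, 1)
  data.frame(
    cell_id = sprintf("%s_c%06d", sample_id, seq_len(n_cells)),
    sample_id = sample_id,
    strain_id = strain@strain_id,
    replicate = as.integer(replicate),
    length_um = len_fix,
    area_px = .rodAreaPx(len_fix, meas@px_per_um),
    n_nuclei = ifelse(phase > 1 - growth@binucleate_fraction, 2L, 1L),
    is_background = background_only,
    signal_HPG = signals[, "HPG"],
    signal_AHA = signals[, "AHA"],
    age_min = age,
    stringsAsFactors = FALSE)
}

#' Simulate a pulse experiment with its background sample
#'
#' Convenience wrapper: one labelled sample plus one background-only sample
#' (cells fixed immediately after analogue addition), on independent seed
#' substreams.
#'
#' @inheritParams simulateCells
#' @param n_background Number of background-sample cells.
#' @return Combined cell table; background rows have `is_background = TRUE`.
#' @export
simulatePulseExperiment <- function(n_cells, n_background = 2000,
                                    rate, growth, meas, pulses,
                                    strain = StrainSpec(), replicate = 1L,
                                    seed = 1L,
                                    age_sampling = c("exponential",
                                                     "uniform")) {
  age_sampling <- match.arg(age_sampling)
  samp <- simulateCells(n_cells, rate, growth, meas, pulses, strain,
                        replicate = replicate,
                        seed = .substreamSeed(seed, strain@strain_id,
                                              replicate, "cells"),
                        age_sampling = age_sampling)
  bg <- simulateCells(n_background, rate, growth, meas, pulses, strain,
                      replicate = replicate,
                      seed = .substreamSeed(seed, strain@strain_id,
                                            replicate, "background"),
                      background_only = TRUE, age_sampling = age_sampling)
  rbind(samp, bg)
}

#' Simulate a dual-pulse interval series
#'
#' One dual-pulse experiment per interval: an HPG pulse over minutes
#' `[0, pulse_min]` and an AHA pulse over `[interval, interval + pulse_min]`,
#' with independent seed substreams per interval.
#'
#' @param intervals Numeric vector of intervals between the two pulse starts
#'   (minutes, >= 0).
#' @param n_per_interval Cells per interval.
#' @param pulse_min Pulse duration (default 10 min, the dual-pulse protocol).
#' @inheritParams simulateCells
#' @return A cell table with an extra `interval_min` column.
#' @export
simulateDualPulseSeries <- function(intervals, n_per_interval, rate, growth,
                                    meas, pulse_min = 10,
                                    strain = StrainSpec(), seed = 1L) {
  stopifnot(all(intervals >= 0))
  out <- lapply(intervals, function(d) {
    tab <- simulateCells(n_per_interval, rate, growth, meas,
                         list(PulseScheme("HPG", 0, pulse_min),
                              PulseScheme("AHA", d, pulse_min)),
                         strain,
                         sample_id = paste0("dual_", d, "min"),
                         seed = .substreamSeed(seed, "dual", d))
    tab$interval_min <- d
    tab
  })
  do.call(rbind, out)
}

#' Simulate a multi-strain variability-screen dataset
#'
#' One sample per strain and replicate on independent seed substreams derived
#' from labels (adding strains never perturbs existing samples).
#' Replicate-level experimental variation is emulated by lognormal jitter of
#' the mean rate and the background median, so wild-type QCD has non-zero
#' spread across replicates.
#'
#' @param strains List of [StrainSpec-class] objects.  At least one strain
#'   with `s_multiplier = 1` and >= 2 replicates (the wild type) is required.
#' @inheritParams simulateCells
#' @param n_cells_per_sample Cells per strain x replicate sample.
#' @param replicate_cv Named numeric: CV of the replicate-level jitter on
#'   `mean_rate` and on `background_median`.
#' @return Combined cell table across all strain x replicate samples.
#' @export
simulateScreenDataset <- function(strains, rate, growth, meas, pulses,
                                  n_cells_per_sample, seed = 1L,
                                  replicate_cv = c(mean_rate = 0.05,
                                                   background = 0.1)) {
  ids <- vapply(strains, function(s) s@strain_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate strain_id in 'strains'")
  is_wt <- vapply(strains, function(s)
    s@s_multiplier == 1 && s@n_replicates >= 2L, logical(1))
  if (!any(is_wt))
    stop("need >= 1 wild-type strain (s_multiplier = 1, >= 2 replicates)")
  sd_mr <- sqrt(log1p(replicate_cv[["mean_rate"]]^2))
  sd_bg <- sqrt(log1p(replicate_cv[["background"]]^2))
  out <- lapply(strains, function(st) {
    reps <- lapply(seq_len(st@n_replicates), function(r) {
      set.seed(.substreamSeed(seed, st@strain_id, r, "jitter"))
      rate_r <- RateProcessParams(
        mean_rate = rate@mean_rate * exp(rnorm(1, 0, sd_mr) - sd_mr^2 / 2),
        s = rate@s, tau_min = rate@tau_min, beta = rate@beta)
      meas_r <- MeasurementParams(
        sigma_meas = meas@sigma_meas,
        background_median = meas@background_median *
          exp(rnorm(1, 0, sd_bg) - sd_bg^2 / 2),
        background_log_sd = meas@background_log_sd,
        px_per_um = meas@px_per_um)
      simulateCells(n_cells_per_sample, rate_r, growth, meas_r, pulses, st,
                    replicate = r,
                    seed = .substreamSeed(seed, st@strain_id, r, "cells"))
    })
    do.call(rbind, reps)
  })
  do.call(rbind, out)
}
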