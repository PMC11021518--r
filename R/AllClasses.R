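## S4 parameter and result classes.  Constructors share the class name
## (Bioconductor convention); slots are reached through accessors, not `@`.

#' Stationary log-rate process parameters
#'
#' Parameters of the latent per-cell synthesis-rate process: the log rate is a
#' stationary Gaussian process with stretched-exponential autocorrelation
#' \eqn{\rho(\Delta t) = \exp(-(\Delta t/\tau)^\beta)}.
#'
#' @slot mean_rate Mean synthesis rate, fluorescence-equivalent units per
#'   micrometre of cell length per minute.
#' @slot s Stationary standard deviation of the log rate (dimensionless).
#' @slot tau_min Autocorrelation timescale in minutes.
#' @slot beta Stretch exponent of the correlation kernel, in (0, 2].
#'
#' @examples
#' RateProcessParams(mean_rate = 100, s = 0.29, tau_min = 50, beta = 1.2)
#' @export RateProcessParams
#' @exportClass RateProcessParams
setClass("RateProcessParams",
  representation(mean_rate = "numeric", s = "numeric",
                 tau_min = "numeric", beta = "numeric"),
  prototype(mean_rate = 100, s = 0.29, tau_min = 50, beta = 1.2))

setValidity("RateProcessParams", function(object) {
  msg <- character()
  if (length(object@mean_rate) != 1L || !is.finite(object@mean_rate) ||
      object@mean_rate <= 0) msg <- c(msg, "'mean_rate' must be a positive number")
  if (length(object@s) != 1L || !is.finite(object@s) || object@s < 0)
    msg <- c(msg, "'s' must be a non-negative number")
  if (length(object@tau_min) != 1L || !is.finite(object@tau_min) ||
      object@tau_min <= 0) msg <- c(msg, "'tau_min' must be a positive number")
  if (length(object@beta) != 1L || !is.finite(object@beta) ||
      object@beta <= 0 || object@beta > 2)
    msg <- c(msg, "'beta' must lie in (0, 2] (kernel positive-definite)")
  if (length(msg)) msg else TRUE
})

#' @rdname RateProcessParams-class
#' @param mean_rate,s,tau_min,beta see slot documentation.
RateProcessParams <- function(mean_rate = 100, s = 0.29, tau_min = 50,
                              beta = 1.2) {
  new("RateProcessParams", mean_rate = as.numeric(mean_rate),
      s = as.numeric(s), tau_min = as.numeric(tau_min),
      beta = as.numeric(beta))
}

#' Cell growth and division parameters
#'
#' Linear elongation from birth to division length over one generation; the
#' final fraction of the cycle is flagged binucleate (two nuclei present
#' before septation), so the binucleate-exclusion filter has cells to remove.
#'
#' @slot birth_length_um Length at birth (micrometres).
#' @slot division_length_um Length at division (micrometres).
#' @slot generation_min Generation time (minutes).
#' @slot binucleate_fraction Final fraction of the cycle flagged binucleate,
#'   in [0, 1).
#' @export GrowthParams
#' @exportClass GrowthParams
setClass("GrowthParams",
  representation(birth_length_um = "numeric", division_length_um = "numeric",
                 generation_min = "numeric", binucleate_fraction = "numeric"),
  prototype(birth_length_um = 7.5, division_length_um = 15,
            generation_min = 250, binucleate_fraction = 0.12))

setValidity("GrowthParams", function(object) {
  msg <- character()
  if (object@birth_length_um <= 0)
    msg <- c(msg, "'birth_length_um' must be positive")
  if (object@division_length_um <= object@birth_length_um)
    msg <- c(msg, "'division_length_um' must exceed 'birth_length_um'")
  if (object@generation_min <= 0)
    msg <- c(msg, "'generation_min' must be positive")
  if (object@binucleate_fraction < 0 || object@binucleate_fraction >= 1)
    msg <- c(msg, "'binucleate_fraction' must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname GrowthParams-class
#' @param birth_length_um,division_length_um,generation_min,binucleate_fraction
#'   see slot documentation.
GrowthParams <- function(birth_length_um = 7.5, division_length_um = 15,
                         generation_min = 250, binucleate_fraction = 0.12) {
  new("GrowthParams", birth_length_um = as.numeric(birth_length_um),
      division_length_um = as.numeric(division_length_um),
      generation_min = as.numeric(generation_min),
      binucleate_fraction = as.numeric(binucleate_fraction))
}

#' Measurement and background parameters
#'
#' Per-channel multiplicative measurement noise is lognormal with log-SD
#' `sigma_meas`; background fluorescence (autofluorescence plus nonspecific
#' staining) is lognormal with the given median and log-SD.  The pixel scale
#' default (15.3609 px per micrometre) matches the imaging setup emulated by
#' [renderImages()].
#'
#' @slot sigma_meas SD of the log multiplicative measurement noise.
#' @slot background_median Median background total fluorescence (same units as
#'   signals).
#' @slot background_log_sd Log-SD of the background distribution.
#' @slot px_per_um Pixels per micrometre.
#' @export MeasurementParams
#' @exportClass MeasurementParams
setClass("MeasurementParams",
  representation(sigma_meas = "numeric", background_median = "numeric",
                 background_log_sd = "numeric", px_per_um = "numeric"),
  prototype(sigma_meas = 0.08, background_median = 1000,
            background_log_sd = 0.25, px_per_um = 15.3609))

setValidity("MeasurementParams", function(object) {
  msg <- character()
  if (object@sigma_meas < 0) msg <- c(msg, "'sigma_meas' must be >= 0")
  if (object@background_median <= 0)
    msg <- c(msg, "'background_median' must be positive")
  if (object@background_log_sd < 0)
    msg <- c(msg, "'background_log_sd' must be >= 0")
  if (object@px_per_um <= 0) msg <- c(msg, "'px_per_um' must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname MeasurementParams-class
#' @param sigma_meas,background_median,background_log_sd,px_per_um see slot
#'   documentation.
MeasurementParams <- function(sigma_meas = 0.08, background_median = 1000,
                              background_log_sd = 0.25,
                              px_per_um = 15.3609) {
  new("MeasurementParams", sigma_meas = as.numeric(sigma_meas),
      background_median = as.numeric(background_median),
      background_log_sd = as.numeric(background_log_sd),
      px_per_um = as.numeric(px_per_um))
}

#' Pulse-labelling scheme
#'
#' One analogue pulse: the channel ("HPG" or "AHA"), its start time relative
#' to the first analogue addition, and its duration.
#'
#' @slot channel "HPG" or "AHA".
#' @slot start_min Pulse start (minutes, >= 0).
#' @slot duration_min Pulse duration (minutes, > 0).
#' @examples
#' PulseScheme("HPG", start_min = 0, duration_min = 5)
#' @export PulseScheme
#' @exportClass PulseScheme
setClass("PulseScheme",
  representation(channel = "character", start_min = "numeric",
                 duration_min = "numeric"),
  prototype(channel = "HPG", start_min = 0, duration_min = 5))

setValidity("PulseScheme", function(object) {
  msg <- character()
  if (!object@channel %in% c("HPG", "AHA"))
    msg <- c(msg, "'channel' must be \"HPG\" or \"AHA\"")
  if (object@start_min < 0) msg <- c(msg, "'start_min' must be >= 0")
  if (object@duration_min <= 0) msg <- c(msg, "'duration_min' must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname PulseScheme-class
#' @param channel,start_min,duration_min see slot documentation.
PulseScheme <- function(channel = "HPG", start_min = 0, duration_min = 5) {
  new("PulseScheme", channel = as.character(channel),
      start_min = as.numeric(start_min), duration_min = as.numeric(duration_min))
}

#' Strain specification for the variability screen
#'
#' @slot strain_id Strain label.
#' @slot s_multiplier Multiplier applied to the wild-type log-rate SD; 1 for
#'   wild type, >1 for more variable strains, <1 for less variable ones.
#' @slot n_replicates Number of experimental replicates to simulate.
#' @export StrainSpec
#' @exportClass StrainSpec
setClass("StrainSpec",
  representation(strain_id = "character", s_multiplier = "numeric",
                 n_replicates = "integer"),
  prototype(strain_id = "WT", s_multiplier = 1, n_replicates = 1L))

setValidity("StrainSpec", function(object) {
  msg <- character()
  if (length(object@strain_id) != 1L || !nzchar(object@strain_id))
    msg <- c(msg, "'strain_id' must be a non-empty label")
  if (object@s_multiplier <= 0) msg <- c(msg, "'s_multiplier' must be > 0")
  if (object@n_replicates < 1L) msg <- c(msg, "'n_replicates' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname StrainSpec-class
#' @param strain_id,s_multiplier,n_replicates see slot documentation.
StrainSpec <- function(strain_id = "WT", s_multiplier = 1, n_replicates = 1L) {
  new("StrainSpec", strain_id = as.character(strain_id),
      s_multiplier = as.numeric(s_multiplier),
      n_replicates = as.integer(n_replicates))
}

#' Post-acquisition gating configuration
#'
#' Numeric gates applied to per-cell feature columns, mirroring imaging-flow
#' post-acquisition filters: cells are kept when `thickness_px` lies within
#' `[thickness_min_px, thickness_max_px]`, `width_px` does not exceed
#' `width_max_px`, `n_nuclei == 1` when `require_mononucleate` is set, and
#' every extra gate in `numeric_gates` (a named list of `c(lo, hi)` ranges,
#' names being table columns) is satisfied.  Instrument-specific features such
#' as focus quality are represented only as generic numeric gates on a
#' user-supplied column.
#'
#' @slot thickness_min_px,thickness_max_px Allowed range of the
#'   `thickness_px` feature.
#' @slot width_max_px Upper bound on the `width_px` feature.
#' @slot require_mononucleate Drop cells with `n_nuclei != 1`.
#' @slot numeric_gates Named list of `c(lo, hi)` ranges for extra columns.
#' @export GateConfig
#' @exportClass GateConfig
setClass("GateConfig",
  representation(thickness_min_px = "numeric", thickness_max_px = "numeric",
                 width_max_px = "numeric", require_mononucleate = "logical",
                 numeric_gates = "list"),
  prototype(thickness_min_px = 0, thickness_max_px = Inf, width_max_px = Inf,
            require_mononucleate = TRUE, numeric_gates = list()))

setValidity("GateConfig", function(object) {
  msg <- character()
  if (object@thickness_min_px >= object@thickness_max_px)
    msg <- c(msg, "'thickness_min_px' must be < 'thickness_max_px'")
  if (length(object@numeric_gates)) {
    if (is.null(names(object@numeric_gates)) ||
        any(!nzchar(names(object@numeric_gates))))
      msg <- c(msg, "'numeric_gates' must be a named list")
    if (any(!vapply(object@numeric_gates,
                    function(g) is.numeric(g) && length(g) == 2L, logical(1))))
      msg <- c(msg, "each numeric gate must be c(lo, hi)")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GateConfig-class
#' @param thickness_min_px,thickness_max_px,width_max_px,require_mononucleate,numeric_gates
#'   see slot documentation.
GateConfig <- function(thickness_min_px = 0, thickness_max_px = Inf,
                       width_max_px = Inf, require_mononucleate = TRUE,
                       numeric_gates = list()) {
  new("GateConfig", thickness_min_px = as.numeric(thickness_min_px),
      thickness_max_px = as.numeric(thickness_max_px),
      width_max_px = as.numeric(width_max_px),
      require_mononucleate = isTRUE(require_mononucleate),
      numeric_gates = numeric_gates)
}

#' Length binning scheme
#'
#' Half-open bins `[k w, (k+1) w)` with edges at integer multiples of the bin
#' width and labels at bin centres, so every cell maps to exactly one bin.
#'
#' @slot width_um Bin width in micrometres (default 1).
#' @export LengthBinning
#' @exportClass LengthBinning
setClass("LengthBinning", representation(width_um = "numeric"),
         prototype(width_um = 1))

setValidity("LengthBinning", function(object) {
  if (length(object@width_um) != 1L || !is.finite(object@width_um) ||
      object@width_um <= 0) "'width_um' must be a positive number" else TRUE
})

#' @rdname LengthBinning-class
#' @param width_um bin width in micrometres.
LengthBinning <- function(width_um = 1) {
  new("LengthBinning", width_um = as.numeric(width_um))
}

#' Variability summary of a set of values
#'
#' Quartiles, quartile coefficient of dispersion (QCD), coefficient of
#' variation (CV), mean, SD and sample size; see [variabilitySummary()].
#'
#' @slot n Number of values.
#' @slot q1,q2,q3 First, second and third quartiles.
#' @slot qcd (q3 - q1) / (q3 + q1), `NA` when q1 + q3 <= 0.
#' @slot cv SD / mean, `NA` when mean <= 0.
#' @slot mean,sd Sample mean and SD (n - 1 denominator).
#' @exportClass VariabilitySummary
setClass("VariabilitySummary",
  representation(n = "integer", q1 = "numeric", q2 = "numeric", q3 = "numeric",
                 qcd = "numeric", cv = "numeric", mean = "numeric",
                 sd = "numeric"))

setValidity("VariabilitySummary", function(object) {
  if (!is.na(object@q1) && !is.na(object@q3) &&
      (object@q1 > object@q2 || object@q2 > object@q3))
    "quartiles must satisfy q1 <= q2 <= q3" else TRUE
})

#' Fitted dual-pulse decorrelation model
#'
#' Result of [fitDecorrelation()]: the model
#' \eqn{R^2(\Delta t) = R^2_0 \exp(-2 (\Delta t/\tau)^\beta)} fitted to an
#' observed decay curve, together with the half-decay interval solved from
#' the fit.
#'
#' @slot r2_0 Fitted simultaneous-pulse \eqn{R^2}, in [0, 1].
#' @slot tau_hat_min Fitted timescale (minutes).
#' @slot beta_hat Fitted stretch exponent, in (0, 2].
#' @slot half_decay_min Interval at which the fitted \eqn{R^2} falls to half
#'   its simultaneous-pulse value.
#' @slot residual_sse Residual sum of squares of the fit.
#' @slot pulse_min Pulse duration used for window correction, or `NA` for the
#'   plain (uncorrected) model.
#' @slot boundary `TRUE` when a parameter ended on the search boundary.
#' @exportClass DecorrelationFit
setClass("DecorrelationFit",
  representation(r2_0 = "numeric", tau_hat_min = "numeric",
                 beta_hat = "numeric", half_decay_min = "numeric",
                 residual_sse = "numeric", pulse_min = "numeric",
                 boundary = "logical"))

setValidity("DecorrelationFit", function(object) {
  msg <- character()
  if (object@r2_0 < 0 || object@r2_0 > 1) msg <- c(msg, "'r2_0' must be in [0, 1]")
  if (object@tau_hat_min <= 0) msg <- c(msg, "'tau_hat_min' must be positive")
  if (object@beta_hat <= 0 || object@beta_hat > 2)
    msg <- c(msg, "'beta_hat' must be in (0, 2]")
  if (object@residual_sse < 0) msg <- c(msg, "'residual_sse' must be >= 0")
  if (length(msg)) msg else TRUE
})
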