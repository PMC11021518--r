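#' Quartile coefficient of dispersion
#'
#' QCD = (Q3 - Q1) / (Q3 + Q1), a scale-invariant, outlier-robust dispersion
#' measure.  Quartiles use linear interpolation of order statistics (index
#' h = (n - 1) p + 1).
#'
#' @param x A numeric vector (length >= 4) or a `VariabilitySummary`.
#' @param ... Unused.
#' @return The QCD as a single number.
#' @examples
#' qcd(c(1, 2, 3, 4, 5))   # (4 - 2) / (4 + 2)
#' @export
setGeneric("qcd", function(x, ...) standardGeneric("qcd"))

#' Coefficient of variation
#'
#' CV = sample SD (n - 1 denominator) divided by the mean.
#'
#' @param x A numeric vector (length >= 2, positive mean) or a
#'   `VariabilitySummary`.
#' @param ... Unused.
#' @return The CV as a single number.
#' @examples
#' cv(c(8, 10, 12))   # 0.2
#' @export
setGeneric("cv", function(x, ...) standardGeneric("cv"))

#' @describeIn DecorrelationFit-class fitted timescale (minutes).
#' @param object A `DecorrelationFit`.
#' @export
setGeneric("tauHat", function(object) standardGeneric("tauHat"))

#' @describeIn DecorrelationFit-class fitted stretch exponent.
#' @export
setGeneric("betaHat", function(object) standardGeneric("betaHat"))

#' @describeIn DecorrelationFit-class fitted simultaneous-pulse R-squared.
#' @export
setGeneric("r2Zero", function(object) standardGeneric("r2Zero"))

#' @describeIn DecorrelationFit-class half-decay interval (minutes).
#' @export
setGeneric("halfDecay", function(object) standardGeneric("halfDecay"))

#' @export
#' @describeIn DecorrelationFit-class accessors.
setMethod("tauHat", "DecorrelationFit", function(object) object@tau_hat_min)

#' @export
#' @describeIn DecorrelationFit-class accessors.
setMethod("betaHat", "DecorrelationFit", function(object) object@beta_hat)

#' @export
#' @describeIn DecorrelationFit-class accessors.
setMethod("r2Zero", "DecorrelationFit", function(object) object@r2_0)

#' @export
#' @describeIn DecorrelationFit-class accessors.
setMethod("halfDecay", "DecorrelationFit", function(object) object@half_decay_min)

setMethod("show", "RateProcessParams", function(object) {
  cat("RateProcessParams\n",
      "  mean_rate: ", object@mean_rate, " (units/um/min)\n",
      "  s (log-SD): ", signif(object@s, 4), "\n",
      "  tau: ", signif(object@tau_min, 4), " min   beta: ",
      signif(object@beta, 4), "\n", sep = "")
})

setMethod("show", "GrowthParams", function(object) {
  cat("GrowthParams: birth ", object@birth_length_um, " um -> division ",
      object@division_length_um, " um over ", object@generation_min,
      " min; binucleate fraction ", object@binucleate_fraction, "\n", sep = "")
})

setMethod("show", "MeasurementParams", function(object) {
  cat("MeasurementParams: sigma_meas ", signif(object@sigma_meas, 4),
      ", background median ", signif(object@background_median, 5),
      " (log-SD ", object@background_log_sd, "), scale ",
      object@px_per_um, " px/um\n", sep = "")
})

setMethod("show", "PulseScheme", function(object) {
  cat("PulseScheme: ", object@channel, " pulse, minutes ",
      object@start_min, "-", object@start_min + object@duration_min,
      "\n", sep = "")
})

setMethod("show", "StrainSpec", function(object) {
  cat("StrainSpec: ", object@strain_id, " (s x ", object@s_multiplier, ", ",
      object@n_replicates, " replicate(s))\n", sep = "")
})

setMethod("show", "VariabilitySummary", function(object) {
  cat("VariabilitySummary (n = ", object@n, ")\n",
      "  quartiles: ", signif(object@q1, 5), " / ", signif(object@q2, 5),
      " / ", signif(object@q3, 5), "\n",
      "  QCD: ", signif(object@qcd, 4), "   CV: ", signif(object@cv, 4),
      "\n", sep = "")
})

setMethod("show", "DecorrelationFit", function(object) {
  cat("DecorrelationFit: R2(dt) = ", signif(object@r2_0, 3),
      " * exp(-2 (dt/", signif(object@tau_hat_min, 4), ")^",
      signif(object@beta_hat, 3), ")\n",
      "  half-decay: ", signif(object@half_decay_min, 4), " min",
      if (!is.na(object@pulse_min)) paste0("  (", object@pulse_min,
                                           "-min pulse window correction)"),
      "\n", sep = "")
  if (object@boundary)
    cat("  note: a parameter ended on the search boundary\n")
})
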