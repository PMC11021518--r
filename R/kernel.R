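#' Stretched-exponential correlation kernel
#'
#' Autocorrelation of the latent log synthesis rate at lag `dt`:
#' \eqn{\rho(\Delta t) = \exp(-(\Delta t/\tau)^\beta)}.  Equals 1 at lag zero
#' and is strictly decreasing in the lag; \eqn{\beta = 1} recovers the
#' Ornstein-Uhlenbeck (single-exponential) kernel.
#'
#' @param params A [RateProcessParams-class] object.
#' @param dt Non-negative lag(s) in minutes (vectorised).
#' @return Correlation value(s) in (0, 1].
#' @examples
#' p <- RateProcessParams(tau_min = 65.2, beta = 1)
#' correlationKernel(p, 40)   # exp(-40/65.2) ~ 0.541
#' @export
correlationKernel <- function(params, dt) {
  stopifnot(is(params, "RateProcessParams"))
  validObject(params)
  if (any(!is.finite(dt)) || any(dt < 0))
    stop("'dt' must be non-negative and finite")
  exp(-(dt / params@tau_min)^params@beta)
}

#' Correlation matrix of the log-rate process on a time grid
#'
#' Builds the grid correlation matrix \eqn{C_{ij} = \rho(|t_i - t_j|)} and,
#' optionally, its (upper-triangular) Cholesky factor.  A small diagonal
#' jitter (at most 1e-8) is added only if plain factorization fails; for
#' \eqn{\beta \in (0, 2]} the kernel is positive-definite and grids of up to a
#' few hundred points factorize without appreciable jitter.
#'
#' @param params A [RateProcessParams-class] object.
#' @param times Numeric vector of time points (minutes).
#' @param chol Return the Cholesky factor instead of the matrix.
#' @return The correlation matrix, or its Cholesky factor when `chol = TRUE`
#'   (with the jitter used recorded in attribute `"jitter"`).
#' @export
processCorrelationMatrix <- function(params, times, chol = FALSE) {
  stopifnot(is.numeric(times), length(times) >= 1L)
  C <- correlationKernel(params, abs(outer(times, times, "-")))
  if (!chol) return(C)
  for (jit in c(0, 1e-12, 1e-10, 1e-8)) {
    U <- tryCatch(base::chol(C + diag(jit, nrow(C))), error = function(e) NULL)
    if (!is.null(U)) {
      attr(U, "jitter") <- jit
      return(U)
    }
  }
  stop("correlation matrix could not be factorized with jitter <= 1e-8")
}

## Value-scale covariance between two pulse-window averages of the
## mean-one lognormal fluctuation factor exp(X - s^2/2):
##   cov = mean over (t, u) in the two windows of exp(s^2 rho(|delta + t - u|)) - 1.
## Trapezoidal weights on a `step`-minute grid; exact for the jointly
## lognormal latent process up to quadrature error.
windowCovariance <- function(delta, pulse_min, tau, beta, s2, step = 0.25) {
  t1 <- seq(0, pulse_min, by = step)
  D <- abs(outer(t1, delta + t1, "-"))
  w <- rep(1, length(t1)); w[c(1L, length(t1))] <- 0.5
  W <- outer(w, w)
  sum(W * (expm1(s2 * exp(-(D / tau)^beta)))) / sum(W)
}
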