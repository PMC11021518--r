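## Dual-label decorrelation analysis: per-interval OLS R-squared,
## decorrelation-timescale fitting, ranked-group regression-to-the-mean
## trajectories.

#' Ordinary least squares fit
#'
#' Closed-form simple linear regression of `y` on `x` with
#' \eqn{R^2 = 1 - SSE/SST}.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), `x` non-degenerate.
#' @return List with `slope`, `intercept`, `r2` and `n`.
#' @examples
#' olsFit(c(1, 2, 3), c(2, 4, 9))   # slope 3.5, intercept -2, r2 ~ 0.942
#' @export
olsFit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 complete observations")
  if (sd(x) == 0) stop("degenerate x: zero variance")
  fit <- stats::lm.fit(cbind(1, x), y)
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r2 = 1 - sse / sst, n = length(x))
}

#' Dual-pulse R-squared decay curve
#'
#' For each interval between the HPG and AHA pulse starts, normalises both
#' channels as in the dual-pulse analysis (signal divided by cell length,
#' then by the population median of signal/length, per interval) and fits the
#' OLS regression of normalised AHA on normalised HPG.
#'
#' @param tab Cell table with an `interval_min` column (see
#'   [simulateDualPulseSeries()]) and both channel signals.  Pre-computed
#'   `signal_HPG_norm` / `signal_AHA_norm` columns are used when present.
#' @return A data.frame with columns `interval_min`, `r2`, `n`, in interval
#'   order.
#' @export
r2DecayCurve <- function(tab) {
  if (!"interval_min" %in% names(tab)) stop("missing 'interval_min' column")
  for (ch in c("HPG", "AHA")) .checkChannel(tab, .signalCol(ch))
  out <- lapply(sort(unique(tab$interval_min)), function(d) {
    sub <- tab[tab$interval_min == d & !tab$is_background, , drop = FALSE]
    for (ch in c("HPG", "AHA"))
      if (!paste0(.signalCol(ch), "_norm") %in% names(sub))
        sub <- perLengthMedianNormalize(sub, ch)
    fit <- olsFit(sub$signal_HPG_norm, sub$signal_AHA_norm)
    data.frame(interval_min = d, r2 = fit$r2, n = fit$n)
  })
  do.call(rbind, out)
}

## half-decay of R2(t) = r2_0 exp(-2 (t/tau)^beta): closed form for the plain
## model, root solve for the window-corrected one
.halfDecaySolve <- function(tau, beta, pulse_min = NULL) {
  if (is.null(pulse_min)) return(tau * (log(2) / 2)^(1 / beta))
  ratio <- function(t) .windowKernelRatio(t, pulse_min, tau, beta)^2 - 0.5
  uniroot(ratio, c(1e-3, 50 * tau), tol = 1e-10)$root
}

## small-s limit of windowCovariance ratio: mean kernel over the two windows
.windowKernelRatio <- function(delta, pulse_min, tau, beta, step = 0.5) {
  t1 <- seq(0, pulse_min, by = step)
  w <- rep(1, length(t1)); w[c(1L, length(t1))] <- 0.5
  W <- outer(w, w)
  avg <- function(d) {
    D <- abs(outer(t1, d + t1, "-"))
    sum(W * exp(-(D / tau)^beta)) / sum(W)
  }
  avg(delta) / avg(0)
}

#' Fit the decorrelation model to an R-squared decay curve
#'
#' Least-squares fit of \eqn{R^2(\Delta t) = R^2_0 \exp(-2(\Delta t/\tau)^\beta)}
#' over a \eqn{(\tau, \beta)} grid refined by local optimisation, with
#' \eqn{R^2_0} profiled out in closed form at each candidate.  When
#' `pulse_min` is given, the model instead uses the pulse-window-averaged
#' kernel ratio, which removes the upward timescale bias that finite pulse
#' windows induce; the plain model (default) matches the curve as printed.
#'
#' @param curve Data.frame with columns `interval_min` and `r2`, >= 3
#'   intervals including 0.
#' @param pulse_min Optional pulse duration (min) for window correction.
#' @return A [DecorrelationFit-class] object.
#' @examples
#' curve <- data.frame(interval_min = c(0, 20, 50),
#'                     r2 = c(0.85, 0.46, 0.12))
#' fitDecorrelation(curve)   # tau ~ 50.8 min, beta ~ 1.27
#' @export
fitDecorrelation <- function(curve, pulse_min = NULL) {
  stopifnot(all(c("interval_min", "r2") %in% names(curve)))
  curve <- curve[is.finite(curve$r2), , drop = FALSE]
  if (nrow(curve) < 3L || !any(curve$interval_min == 0))
    stop("need >= 3 intervals including 0")
  if (any(diff(curve$r2[order(curve$interval_min)]) > 0))
    warning("R-squared curve is not non-increasing in the interval")
  d <- curve$interval_min; r <- curve$r2
  pos <- d > 0

  model <- function(tau, beta) {
    w <- numeric(length(d))
    w[!pos] <- 1
    if (is.null(pulse_min)) {
      w[pos] <- exp(-2 * (d[pos] / tau)^beta)
    } else {
      w[pos] <- vapply(d[pos], function(x)
        .windowKernelRatio(x, pulse_min, tau, beta)^2, numeric(1))
    }
    w
  }
  sse <- function(tau, beta) {
    if (!is.finite(tau) || !is.finite(beta) || tau <= 0 ||
        beta <= 0 || beta >= 2) return(1e10)
    w <- model(tau, beta)
    r0 <- min(max(sum(w * r) / sum(w^2), 1e-6), 1)
    sum((r0 * w - r)^2)
  }
  grid <- expand.grid(tau = exp(seq(log(2), log(400), length.out = 30)),
                      beta = seq(0.25, 1.99, length.out = 25))
  vals <- mapply(sse, grid$tau, grid$beta)
  st <- grid[which.min(vals), ]
  o <- optim(c(log(st$tau), log(st$beta / (2 - st$beta))),
             function(p) sse(exp(p[1]), 2 / (1 + exp(-p[2]))),
             control = list(reltol = 1e-12, maxit = 500))
  tau <- exp(o$par[1]); beta <- 2 / (1 + exp(-o$par[2]))
  w <- model(tau, beta)
  r0 <- min(max(sum(w * r) / sum(w^2), 1e-6), 1)
  boundary <- tau < 2.05 || tau > 395 || beta < 0.26 || beta > 1.99
  if (boundary) warning("fit parameters at the search boundary")
  new("DecorrelationFit", r2_0 = r0, tau_hat_min = tau, beta_hat = beta,
      half_decay_min = .halfDecaySolve(tau, beta, pulse_min),
      residual_sse = o$value,
      pulse_min = if (is.null(pulse_min)) NA_real_ else pulse_min,
      boundary = boundary)
}

#' Rank cells into near-equal groups by signal
#'
#' Cells are sorted ascending by the given column (ties broken by `cell_id`
#' for determinism) and split into `n_groups` contiguous groups whose sizes
#' differ by at most one; when the count does not divide evenly, the extra
#' cells go to the lowest groups.
#'
#' @param tab Cell table (n >= `n_groups`).
#' @param values_col Column to rank on (for example `"signal_HPG_norm"`).
#' @param n_groups Number of groups (default 10).
#' @return Integer vector of group indices (1 = lowest), aligned with the
#'   rows of `tab`.
#' @export
rankGroups <- function(tab, values_col = "signal_HPG_norm", n_groups = 10L) {
  .checkChannel(tab, values_col)
  n <- nrow(tab)
  if (n < n_groups) stop("fewer cells than groups")
  ord <- order(tab[[values_col]], tab$cell_id)
  base <- n %/% n_groups; extra <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  grp <- integer(n)
  grp[ord] <- rep(seq_len(n_groups), times = sizes)
  grp
}

#' Ranked-group regression-to-the-mean trajectories
#'
#' Within each interval's sample, cells are ranked into groups on the
#' normalised HPG signal and the mean normalised AHA signal per group is
#' computed.  Because groups are re-formed per interval from independent
#' cells, an extreme group's mean approaches the per-interval population mean
#' as the interval grows.  The convergence time of a group is the earliest
#' interval on the simulated grid at which its absolute deviation from the
#' population mean first falls below `convergence_frac` of its deviation at
#' interval 0.
#'
#' @param tab Cell table with an `interval_min` column and both channels.
#' @param n_groups Number of ranked groups (default 10).
#' @param convergence_frac Fraction of the initial deviation defining
#'   convergence (default 1/3).
#' @return List with `trajectories` (interval_min, group, mean_norm_aha, n),
#'   `population` (per-interval population mean) and `convergence` (group,
#'   convergence_min; `NA` when never reached on the grid).
#' @export
groupTrajectories <- function(tab, n_groups = 10L, convergence_frac = 1 / 3) {
  if (!"interval_min" %in% names(tab)) stop("missing 'interval_min' column")
  intervals <- sort(unique(tab$interval_min))
  traj <- list(); popm <- numeric(length(intervals))
  for (i in seq_along(intervals)) {
    sub <- tab[tab$interval_min == intervals[i] & !tab$is_background, ,
               drop = FALSE]
    for (ch in c("HPG", "AHA"))
      if (!paste0(.signalCol(ch), "_norm") %in% names(sub))
        sub <- perLengthMedianNormalize(sub, ch)
    grp <- rankGroups(sub, "signal_HPG_norm", n_groups)
    means <- tapply(sub$signal_AHA_norm, grp, mean)
    ns <- tabulate(grp, n_groups)
    if (any(ns == 0L)) stop("empty group at interval ", intervals[i])
    popm[i] <- mean(sub$signal_AHA_norm)
    traj[[i]] <- data.frame(interval_min = intervals[i],
                            group = seq_len(n_groups),
                            mean_norm_aha = as.numeric(means), n = ns)
  }
  trajectories <- do.call(rbind, traj)
  population <- data.frame(interval_min = intervals, mean_norm_aha = popm)
  conv <- vapply(seq_len(n_groups), function(g) {
    dev <- trajectories$mean_norm_aha[trajectories$group == g] - popm
    d0 <- abs(dev[intervals == 0])
    if (!length(d0) || d0 == 0) return(NA_real_)
    hit <- which(abs(dev) < convergence_frac * d0)
    if (length(hit)) intervals[min(hit)] else NA_real_
  }, numeric(1))
  list(trajectories = trajectories, population = population,
       convergence = data.frame(group = seq_len(n_groups),
                                convergence_min = conv))
}
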