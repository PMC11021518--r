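test_that("OLS fit matches the closed-form oracle", {
  fit <- olsFit(c(1, 2, 3), c(2, 4, 9))
  oracle <- bruteOLS(c(1, 2, 3), c(2, 4, 9))
  expect_equal(fit$slope, 3.5, tolerance = 1e-12)
  expect_equal(fit$intercept, -2, tolerance = 1e-12)
  expect_equal(fit$r2, 1 - 1.5 / 26, tolerance = 1e-12)
  expect_equal(fit$r2, oracle$r2, tolerance = 1e-12)

  x <- seq(0, 1, length.out = 50)
  expect_equal(olsFit(x, 3 * x + 1)$r2, 1, tolerance = 1e-12)

  set.seed(8)
  expect_lt(olsFit(rnorm(10000), rnorm(10000))$r2, 0.01)
  expect_error(olsFit(rep(1, 5), 1:5), "degenerate")
})

test_that("decorrelation fit recovers a noiseless curve and the anchors", {
  tau <- 50.8; beta <- 1.27
  d <- seq(0, 110, by = 10)
  curve <- data.frame(interval_min = d,
                      r2 = 0.85 * exp(-2 * (d / tau)^beta))
  fit <- fitDecorrelation(curve)
  expect_equal(tauHat(fit), tau, tolerance = 0.01)
  expect_equal(betaHat(fit), beta, tolerance = 0.01)
  expect_equal(r2Zero(fit), 0.85, tolerance = 0.01)

  ## the three printed anchor points alone
  anchor_fit <- fitDecorrelation(
    data.frame(interval_min = c(0, 20, 50), r2 = c(0.85, 0.46, 0.12)))
  expect_equal(tauHat(anchor_fit), 50.85, tolerance = 0.02)
  expect_equal(betaHat(anchor_fit), 1.265, tolerance = 0.02)
  expect_equal(halfDecay(anchor_fit), 22.0, tolerance = 0.01)
  ## half-decay is consistent with the fitted parameters: R2(t_half) = r2_0/2
  t12 <- halfDecay(anchor_fit)
  expect_equal(r2Zero(anchor_fit) *
                 exp(-2 * (t12 / tauHat(anchor_fit))^betaHat(anchor_fit)),
               r2Zero(anchor_fit) / 2, tolerance = 1e-9)

  w <- capture_warnings(fitDecorrelation(
    data.frame(interval_min = c(0, 20, 50), r2 = c(0.5, 0.6, 0.2))))
  expect_true(any(grepl("non-increasing", w)))
  expect_error(fitDecorrelation(
    data.frame(interval_min = c(10, 20), r2 = c(0.5, 0.4))), "including 0")
})

test_that("R-squared decays monotonically in expectation across seeds", {
  wt <- wtParams()
  intervals <- c(0, 15, 35, 60)
  curves <- sapply(1:20, function(sd) {
    tab <- simulateDualPulseSeries(intervals, 1500, wt$rate, wt$growth,
                                   wt$meas, seed = 100 + sd)
    r2DecayCurve(tab)$r2
  })
  mean_curve <- rowMeans(curves)
  expect_true(all(diff(mean_curve) < 0))
  expect_lte(cor(intervals, mean_curve, method = "spearman"), -0.9)
})

test_that("ranked groups are contiguous, near-equal and deterministic", {
  set.seed(31)
  tab <- data.frame(cell_id = sprintf("c%03d", 1:100),
                    signal_HPG_norm = rlnorm(100, 0, 0.3))
  g <- rankGroups(tab)
  expect_equal(unname(table(g)), rep(10L, 10), ignore_attr = TRUE)
  expect_gt(mean(tab$signal_HPG_norm[g == 10]),
            mean(tab$signal_HPG_norm[g == 1]))
  ## 101 cells: the extra cell goes to the lowest group
  tab101 <- rbind(tab, data.frame(cell_id = "c101",
                                  signal_HPG_norm = 0.9))
  g101 <- rankGroups(tab101)
  expect_equal(as.integer(table(g101)), c(11L, rep(10L, 9)))
  ## permutation invariance: shuffled rows give the same assignment per cell
  perm <- sample(nrow(tab))
  g_perm <- rankGroups(tab[perm, ])
  expect_equal(g_perm[order(perm)], g)
  expect_error(rankGroups(tab[1:5, ]), "fewer cells")
})

test_that("group trajectories regress towards the population mean", {
  wt <- wtParams()
  tab <- simulateDualPulseSeries(c(0, 40, 150), 3000, wt$rate, wt$growth,
                                 wt$meas, seed = 77)
  gt <- groupTrajectories(tab)
  tr <- gt$trajectories
  at <- function(g, d) tr$mean_norm_aha[tr$group == g & tr$interval_min == d]
  pop <- function(d) gt$population$mean_norm_aha[gt$population$interval_min == d]
  ## simultaneous pulses preserve the ranking around the population mean
  expect_gt(at(10, 0), pop(0))
  expect_lt(at(1, 0), pop(0))
  expect_gt(at(10, 0), 1)
  expect_lt(at(1, 0), 1)
  ## far beyond tau, the extreme groups sit near the population mean
  expect_lt(abs(at(10, 150) - pop(150)), 0.05)
  expect_lt(abs(at(1, 150) - pop(150)), 0.05)
  ## deviations of the top group shrink with the interval
  dev10 <- abs(tr$mean_norm_aha[tr$group == 10] -
                 gt$population$mean_norm_aha)
  expect_true(all(diff(dev10) < 0))
})
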