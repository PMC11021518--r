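## tiny hand-built cell table: 4 sample cells + background cells
mkTab <- function(sig, bg_sig, lengths = NULL, bg_lengths = NULL) {
  n <- length(sig); m <- length(bg_sig)
  data.frame(
    cell_id = sprintf("c%03d", seq_len(n + m)),
    sample_id = rep(c("s", "bg"), c(n, m)),
    strain_id = "WT", replicate = 1L,
    length_um = c(if (is.null(lengths)) rep(10, n) else lengths,
                  if (is.null(bg_lengths)) rep(10, m) else bg_lengths),
    n_nuclei = 1L,
    is_background = rep(c(FALSE, TRUE), c(n, m)),
    signal_HPG = c(sig, bg_sig), signal_AHA = NA_real_)
}

test_that("background scaling divides by the background median", {
  tab <- mkTab(c(250, 300), c(90, 100, 110))
  out <- backgroundScale(tab)
  expect_equal(out$signal_HPG_scaled[1], 2.5)
  expect_equal(attr(out, "background_median")[["HPG"]], 100)
  ## QCD is invariant under the pure rescaling
  vals <- rlnorm(200, 1, 0.3)
  tab2 <- mkTab(vals, c(1, 1, 1, 1))
  out2 <- backgroundScale(tab2)
  expect_equal(qcd(out2$signal_HPG_scaled[!out2$is_background]), qcd(vals),
               tolerance = 1e-12)
  expect_error(backgroundScale(mkTab(1, numeric(0))), "empty")
})

test_that("bin-wise subtraction removes the per-bin background median", {
  tab <- mkTab(c(3.2, 3.2), c(1, 1, 1))
  tab$signal_HPG_scaled <- tab$signal_HPG   # already on background scale
  out <- backgroundSubtractBinned(tab)
  expect_equal(out$signal_HPG_corr[1], 2.2)
  ## self-subtraction: a sample equal to the background has per-bin median 0
  set.seed(2)
  vals <- rlnorm(400, 0, 0.3)
  tab2 <- mkTab(vals, vals, lengths = runif(400, 8, 12),
                bg_lengths = runif(400, 8, 12))
  tab2$length_um[1:400] <- tab2$length_um[401:800]  # same bins
  tab2 <- backgroundScale(tab2)
  out2 <- backgroundSubtractBinned(tab2)
  meds <- tapply(out2$signal_HPG_corr[!out2$is_background],
                 floor(out2$length_um[!out2$is_background]), median)
  expect_equal(as.numeric(meds), rep(0, length(meds)), tolerance = 1e-12)
  ## bins without background cells fall back to the global median
  tab3 <- mkTab(c(5, 5), c(1, 1, 1), lengths = c(9.5, 30.5),
                bg_lengths = c(9.4, 9.5, 9.6))
  tab3 <- backgroundScale(tab3)
  expect_message(out3 <- backgroundSubtractBinned(tab3), "global")
  expect_equal(attr(out3, "fallback_bins"), "30.5")
})

test_that("scaling then bin-wise subtraction recovers true incorporation", {
  wt <- wtParams()
  tab <- simulatePulseExperiment(20000, 4000, wt$rate, wt$growth, wt$meas,
                                 list(PulseScheme("HPG", 0, 5)), seed = 17)
  tab <- backgroundScale(tab)
  tab <- suppressMessages(backgroundSubtractBinned(tab))
  bgmed <- attr(tab, "background_median")[["HPG"]]
  got <- mean(tab$signal_HPG_corr[!tab$is_background]) * bgmed
  ## analytic mean true incorporation: mean_rate * P * E[L(age + P/2)]
  lbar <- 7.5 + 7.5 * (1 / log(2) - 1)
  truth <- 100 * 5 * (lbar + 7.5 * 2.5 / 250)
  expect_equal(got, truth, tolerance = 0.02)
})

test_that("OLS length normalisation divides by the predicted signal", {
  tab <- mkTab(2 * c(8, 10, 12, 14), numeric(0),
               lengths = c(8, 10, 12, 14))
  tab$is_background <- FALSE
  out <- lengthNormalizeOLS(tab)
  expect_equal(out$signal_HPG_lennorm, rep(1, 4), tolerance = 1e-12)

  ## closed-form oracle on three points
  tab2 <- mkTab(c(2, 4, 9), numeric(0), lengths = c(1, 2, 3))
  out2 <- lengthNormalizeOLS(tab2)
  expect_equal(attr(out2, "ols_coef"), c(-2, 3.5), tolerance = 1e-12)
  expect_equal(out2$signal_HPG_lennorm[3], 9 / 8.5, tolerance = 1e-12)

  ## de-trending: normalised signal has no residual length slope
  wt <- wtParams()
  big <- simulateCells(10000, wt$rate, wt$growth, wt$meas,
                       list(PulseScheme("HPG", 0, 5)), seed = 23)
  big <- lengthNormalizeOLS(big)
  fit <- olsFit(big$length_um, big$signal_HPG_lennorm)
  expect_lt(abs(fit$slope) * diff(range(big$length_um)), 0.02)

  expect_error(lengthNormalizeOLS(mkTab(c(1, 2, 3), numeric(0))), "variance")
})

test_that("per-length median normalisation has unit population median", {
  tab <- mkTab(rep(5, 4), numeric(0))
  out <- perLengthMedianNormalize(tab)
  expect_equal(out$signal_HPG_norm, rep(1, 4))

  tab2 <- mkTab(c(1, 2, 3), numeric(0), lengths = c(1, 1, 1))
  out2 <- perLengthMedianNormalize(tab2)
  expect_equal(out2$signal_HPG_norm, c(0.5, 1, 1.5))

  set.seed(4)
  tab3 <- mkTab(rlnorm(101, 2, 0.5), numeric(0),
                lengths = runif(101, 7, 15))
  expect_equal(median(perLengthMedianNormalize(tab3)$signal_HPG_norm), 1)
})

test_that("length bins are a half-open integer-aligned partition", {
  tab <- data.frame(length_um = c(7.0, 7.999, 8.0, 12.3))
  out <- assignLengthBins(tab)
  expect_equal(out$length_bin_um, c(7.5, 7.5, 8.5, 12.5))
  set.seed(6)
  tab2 <- data.frame(length_um = runif(500, 0.01, 20))
  out2 <- assignLengthBins(tab2, LengthBinning(2))
  expect_equal(sum(table(out2$length_bin_um)), 500)
  expect_true(all(abs(out2$length_um - out2$length_bin_um) <= 1))
  expect_error(LengthBinning(0), "positive")
  expect_error(assignLengthBins(data.frame(length_um = -1)), "positive")
})
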