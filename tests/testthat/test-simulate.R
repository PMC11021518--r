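pulse5 <- list(PulseScheme("HPG", 0, 5))

test_that("identical seeds give identical tables", {
  wt <- wtParams()
  a <- simulateCells(500, wt$rate, wt$growth, wt$meas, pulse5, seed = 42)
  b <- simulateCells(500, wt$rate, wt$growth, wt$meas, pulse5, seed = 42)
  expect_identical(a, b)
  c <- simulateCells(500, wt$rate, wt$growth, wt$meas, pulse5, seed = 43)
  expect_false(identical(a$signal_HPG, c$signal_HPG))
})

test_that("noise-free limit gives the deterministic growth integral", {
  growth <- GrowthParams()
  rate0 <- RateProcessParams(mean_rate = 100, s = 0, tau_min = 50, beta = 1.2)
  meas0 <- MeasurementParams(sigma_meas = 0, background_median = 500,
                             background_log_sd = 0)
  tab <- simulateCells(200, rate0, growth, meas0, pulse5, seed = 1)
  ## linear elongation makes the trapezoidal pulse integral exact:
  ## signal = mean_rate * P * L(age + P/2) + background
  slope <- (15 - 7.5) / 250
  len_mid <- 7.5 + slope * (tab$age_min + 2.5)
  expect_equal(tab$signal_HPG, 100 * 5 * len_mid + 500, tolerance = 1e-10)
  ## equal ages imply equal lengths and equal signals
  expect_equal(tab$length_um, 7.5 + slope * (tab$age_min + 5),
               tolerance = 1e-12)
})

test_that("empirical log-rate correlation recovers the kernel", {
  wt <- wtParams()
  ## two 1-min pulses, no measurement noise, negligible background:
  ## log(signal / length) differs from the latent log rate only by the
  ## 1-min window average
  meas0 <- MeasurementParams(sigma_meas = 0, background_median = 1e-9,
                             background_log_sd = 0)
  for (lag in c(10, 40)) {
    tab <- simulateCells(10000, wt$rate, wt$growth, meas0,
                         list(PulseScheme("HPG", 0, 1),
                              PulseScheme("AHA", lag, 1)),
                         seed = lag)
    r <- cor(log(tab$signal_HPG / tab$length_um),
             log(tab$signal_AHA / tab$length_um))
    expect_equal(r, correlationKernel(wt$rate, lag), tolerance = 0.03)
  }
})

test_that("ages follow the steady-state exponential age distribution", {
  wt <- wtParams()
  tab <- simulateCells(20000, wt$rate, wt$growth, wt$meas, pulse5, seed = 9)
  expect_equal(mean(tab$age_min) / 250, 1 / log(2) - 1, tolerance = 0.02)
  ## binucleate flag covers the final fraction of the cycle at fixation
  frac2 <- mean(tab$n_nuclei == 2L)
  a_star <- 0.88 * 250 - 5
  expected <- 1 - 2 * (1 - 2^(-a_star / 250))
  expect_equal(frac2, expected, tolerance = 0.015)

  unif <- simulateCells(20000, wt$rate, wt$growth, wt$meas, pulse5,
                        seed = 9, age_sampling = "uniform")
  expect_equal(mean(unif$age_min) / 250, 0.5, tolerance = 0.02)
})

test_that("background-only samples carry background draws only", {
  wt <- wtParams()
  bg <- simulateCells(5000, wt$rate, wt$growth, wt$meas, pulse5, seed = 3,
                      background_only = TRUE)
  expect_true(all(bg$is_background))
  expect_equal(median(bg$signal_HPG), wt$meas@background_median,
               tolerance = 0.05)
  ## fixed immediately: lengths at the age drawn, not at pulse end
  expect_equal(bg$length_um, 7.5 + (7.5 / 250) * bg$age_min,
               tolerance = 1e-12)
})

test_that("simulation inputs are validated", {
  wt <- wtParams()
  expect_error(simulateCells(0, wt$rate, wt$growth, wt$meas, pulse5),
               "positive")
  expect_error(simulateCells(10, wt$rate, wt$growth, wt$meas, list()),
               "non-empty")
  expect_error(simulateCells(10, wt$rate, wt$growth, wt$meas,
                             c(pulse5, pulse5)), "one pulse per channel")
  expect_error(simulateCells(10, wt$rate, wt$growth, wt$meas, pulse5,
                             horizon_min = 3), "horizon")
})

test_that("screen datasets use label-derived substreams", {
  wt <- wtParams()
  base <- list(StrainSpec("WT", 1, 2), StrainSpec("mutA", 1.4, 1))
  more <- c(base, list(StrainSpec("mutB", 0.7, 1)))
  t1 <- simulateScreenDataset(base, wt$rate, wt$growth, wt$meas, pulse5,
                              150, seed = 5)
  t2 <- simulateScreenDataset(more, wt$rate, wt$growth, wt$meas, pulse5,
                              150, seed = 5)
  ## adding a strain never perturbs existing samples
  expect_identical(t1, t2[t2$strain_id %in% c("WT", "mutA"), ])
  ## determinism
  t3 <- simulateScreenDataset(base, wt$rate, wt$growth, wt$meas, pulse5,
                              150, seed = 5)
  expect_identical(t1, t3)
  ## replicate jitter gives replicates different signal scales
  med <- tapply(t1$signal_HPG[t1$strain_id == "WT"],
                t1$replicate[t1$strain_id == "WT"], median)
  expect_gt(abs(diff(med)), 0)

  expect_error(simulateScreenDataset(
    list(StrainSpec("WT", 1, 2), StrainSpec("WT", 1, 2)),
    wt$rate, wt$growth, wt$meas, pulse5, 150), "duplicate")
  expect_error(simulateScreenDataset(
    list(StrainSpec("mutA", 1.4, 3)),
    wt$rate, wt$growth, wt$meas, pulse5, 150), "wild-type")
})
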