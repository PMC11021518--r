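test_that("per-strain QCD is invariant under the median division", {
  set.seed(21)
  vals <- rlnorm(300, 5, 0.3)
  tab <- data.frame(cell_id = sprintf("c%03d", 1:300), sample_id = "s",
                    strain_id = "WT", replicate = 1L,
                    length_um = runif(300, 8, 14), n_nuclei = 1L,
                    is_background = FALSE, signal_HPG = vals,
                    signal_AHA = NA_real_,
                    area_px = rep(1000L, 300))
  q <- strainQCDTable(tab, "mean_signal")
  expect_equal(q$qcd, qcd(vals / median(vals)), tolerance = 1e-12)
  expect_equal(q$qcd, qcd(vals), tolerance = 1e-12)   # scale invariance
  ## identical replicate data have zero QCD spread
  tab2 <- tab; tab2$replicate <- 2L
  tab2$cell_id <- sprintf("d%03d", 1:300)
  f <- flagVariability(strainQCDTable(rbind(tab, tab2), "mean_signal"))
  expect_equal(f$qcd_sd, 0)
  small <- tab[1:50, ]
  small$replicate <- 3L
  small$cell_id <- sprintf("e%03d", 1:50)
  expect_warning(q3 <- strainQCDTable(rbind(tab, small), "mean_signal"),
                 "excluded")
  expect_equal(q3$replicate, 1L)
})

test_that("strains with higher log-rate SD have higher QCD in expectation", {
  wt <- wtParams()
  tab <- simulateScreenDataset(
    list(StrainSpec("WT", 1, 3), StrainSpec("wide", 1.5, 3)),
    wt$rate, wt$growth, wt$meas, list(PulseScheme("HPG", 0, 5)),
    600, seed = 13)
  q <- strainQCDTable(tab, "mean_signal")
  expect_gt(mean(q$qcd[q$strain_id == "wide"]),
            mean(q$qcd[q$strain_id == "WT"]))
  ## both QCD conventions agree on the direction of the effect
  q2 <- strainQCDTable(tab, "length_normalized")
  expect_gt(mean(q2$qcd[q2$strain_id == "wide"]),
            mean(q2$qcd[q2$strain_id == "WT"]))
})

test_that("flags follow the wild-type mean +/- k SD thresholds", {
  qtab <- data.frame(strain_id = rep(c("WT", "mid", "hi", "lo"),
                                     c(4, 1, 1, 1)),
                     replicate = c(1:4, 1, 1, 1),
                     qcd = c(0.19, 0.20, 0.21, 0.20, NA, NA, NA),
                     n = 500)
  wt_mean <- mean(qtab$qcd[1:4]); wt_sd <- sd(qtab$qcd[1:4])
  qtab$qcd[5] <- wt_mean
  qtab$qcd[6] <- wt_mean + 2 * wt_sd
  qtab$qcd[7] <- wt_mean - 2 * wt_sd
  f <- flagVariability(qtab)
  expect_equal(f$flag[f$strain_id == "mid"], "none")
  expect_equal(f$flag[f$strain_id == "hi"], "high")
  expect_equal(f$flag[f$strain_id == "lo"], "low")
  expect_equal(unique(f$wt_sd), wt_sd)
  expect_error(flagVariability(qtab[4:7, ]), "wild-type")
})

test_that("null strains are flagged at the rate implied by 5-replicate
           threshold estimation", {
  ## a null strain's QCD is exchangeable with a wild-type replicate's, so
  ## the flag rate is P(|t_4| > 1.5 / sqrt(1 + 1/5)) ~ 0.24 under
  ## normality, well above the nominal 2*Phi(-1.5) = 0.134 tail mass
  wt <- wtParams()
  expected <- 2 * pt(-1.5 / sqrt(1.2), df = 4)
  strains <- list(StrainSpec("WT", 1, 5), StrainSpec("null1", 1, 1),
                  StrainSpec("null2", 1, 1))
  hits <- sapply(1:25, function(sd) {
    tab <- simulateScreenDataset(strains, wt$rate, wt$growth, wt$meas,
                                 list(PulseScheme("HPG", 0, 5)), 400,
                                 seed = 400 + sd)
    f <- flagVariability(strainQCDTable(tab, "mean_signal"), "WT")
    f$flag[f$strain_id != "WT"] != "none"
  })
  rate <- mean(hits)   # 50 Bernoulli draws
  expect_lt(abs(rate - expected), 3 * sqrt(expected * (1 - expected) / 50) +
              0.05)
})

test_that("paired replicate comparison matches the closed-form t", {
  expect_warning(res0 <- pairedDifferenceTest(c(1, 2, 3), c(1, 2, 3)),
                 "degenerate")
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  expect_warning(res1 <- pairedDifferenceTest(c(2, 3, 4), c(1, 2, 3)),
                 "degenerate")
  expect_equal(res1$t, Inf)
  expect_equal(res1$p, 0)

  d <- c(0.5, 0.7, 0.6, 0.4, 0.8)
  a <- c(1.1, 1.4, 1.2, 1.0, 1.5); b <- a - d
  res <- pairedDifferenceTest(a, b)
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 4), tolerance = 1e-12)
  ## unpaired Welch option
  resw <- pairedDifferenceTest(a, b, method = "welch")
  expect_equal(resw$t, unname(t.test(a, b)$statistic), tolerance = 1e-12)
  expect_error(pairedDifferenceTest(1:3, 1:4), "equal length")
})
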