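test_that("sliding features: sinusoid AC at half period, lengths, masks", {
  t <- 1:300
  x <- 10 + 5 * sin(2 * pi * t / 30)
  f <- sliding_features(x, window = 150, lag = 15, bins = 8)
  expect_equal(nrow(f), 300 - 150 + 1)
  # lag 15 is half the period: the estimator's maximum anticorrelation.
  # The truncated numerator runs over window - lag terms while the
  # denominator covers the full window, so the attainable value is
  # -(window - lag)/window = -0.9, not -1.
  expect_true(all(abs(f$ac + (150 - 15) / 150) < 0.02))
  expect_true(all(f$ami >= 0))
  expect_equal(f$max_nc_wl, rep(max(x), nrow(f)), tolerance = 1e-9)

  suppressMessages(fc <- sliding_features(rep(4, 160), window = 150,
                                          lag = 15))
  expect_true(all(is.na(fc$ac)))
  expect_true(all(fc$ami == 0))

  expect_error(sliding_features(x, window = 400), class = "mcml_error_data")
  expect_error(sliding_features(x, window = 150, lag = 150),
               class = "mcml_error_parameter")
})

test_that("dynamic scaling formulas and bounds", {
  f <- tibble::tibble(date = as.Date("2021-01-01") + 0:2,
                      nc = c(40, 30, 100),
                      ac = c(0, -1, 0.5),
                      ami = c(1.2, 0.3, 2),
                      max_nc_wl = c(100, 50, 200))
  sc <- dynamic_scale(f)
  expect_equal(sc$ac_scaled, c((0 + 1) * 50, 0, 1.5 * 100))
  expect_equal(sc$ami_scaled, c(1.2 * 50, 0.3 * 25, 2 * 100))
  expect_equal(sc$nc_out, f$nc)
  # bounds: ac_scaled in [0, max_nc_wl], ami_scaled >= 0
  expect_true(all(sc$ac_scaled >= 0 & sc$ac_scaled <= f$max_nc_wl))
  norm <- dynamic_scale(f, normalize_nc = TRUE)
  expect_equal(norm$nc_out, f$nc / f$max_nc_wl)
  expect_true(all(norm$nc_out >= 0 & norm$nc_out <= 1))
})

test_that("arbitrary per-axis constants form a group action", {
  f <- dynamic_scale(tibble::tibble(date = as.Date("2021-01-01") + 0:1,
                                    nc = c(10, 20), ac = c(0.2, -0.4),
                                    ami = c(1, 2), max_nc_wl = c(20, 20)))
  expect_equal(arbitrary_scale(f), f, ignore_attr = TRUE)
  doubled <- arbitrary_scale(f, ami = 2)
  expect_equal(doubled$ami_scaled, 2 * f$ami_scaled)
  expect_equal(attr(doubled, "extra_factors")[["ami"]], 2)
  back <- arbitrary_scale(doubled, ami = 0.5)
  expect_equal(back$ami_scaled, f$ami_scaled, tolerance = 1e-12)
  expect_error(arbitrary_scale(f, ac = -1), class = "mcml_error_parameter")
})

test_that("local Lyapunov exponents: closed forms and masking", {
  # gap doubles, then stays
  lam <- local_lyapunov_pair(c(0, 0, 0), c(1, 2, 2))
  expect_equal(lam, c(log(2), 0))
  # exponentially growing gap returns the rate at every step
  t <- 0:20
  lam2 <- local_lyapunov_pair(rep(0, 21), 1e-6 * exp(0.3 * t))
  expect_equal(lam2, rep(0.3, 20), tolerance = 1e-10)
  # zero denominator is masked; vanishing numerator masked with warning
  expect_warning(lam3 <- local_lyapunov_pair(c(0, 0, 1), c(1, 1, 1)),
                 class = "mcml_warning_degenerate")
  expect_true(is.na(lam3[2]))
  lam4 <- local_lyapunov_pair(c(1, 1, 2), c(1, 2, 4))
  expect_true(is.na(lam4[1]))  # zero initial gap
  expect_error(local_lyapunov_pair(1:3, 1:4), class = "mcml_error_parameter")
})

test_that("chaotic logistic-map pair recovers lambda near log 2", {
  tr <- gen_logistic_map(n = 30, r = 4, x0 = 0.2, gap = 1e-9)
  lam <- local_lyapunov_pair(tr$x, tr$y)
  expect_gt(mean(lam[1:20]), 0.5)
  expect_lt(mean(lam[1:20]), 0.9)
})

test_that("MLE is the per-day max over the three pairwise exponents", {
  withr::with_seed(14, {
    sc <- dynamic_scale(tibble::tibble(
      date = as.Date("2021-01-01") + 0:19,
      nc = abs(rnorm(20, 50, 20)), ac = runif(20, -1, 1),
      ami = runif(20, 0, 2), max_nc_wl = abs(rnorm(20, 60, 5))))
  })
  ly <- max_lyapunov(sc)
  expect_equal(nrow(ly), 19)
  for (t in 1:19) {
    vals <- c(ly$lambda_nc_ac[t], ly$lambda_ac_ami[t], ly$lambda_ami_nc[t])
    if (all(is.na(vals))) {
      expect_true(is.na(ly$mle[t]))
    } else {
      expect_equal(ly$mle[t], max(vals, na.rm = TRUE))
      expect_true(all(ly$mle[t] >= vals[!is.na(vals)]))
    }
  }
  # nc/ac gap doubles (4 -> 8) while the other two pairs shrink: MLE = log 2
  sc2 <- dynamic_scale(tibble::tibble(
    date = as.Date("2021-01-01") + 0:1,
    nc = c(10, 10), ac = c(0, -2 / 3), ami = c(7 / 3, 1.5),
    max_nc_wl = c(12, 12)))
  ly2 <- max_lyapunov(sc2)
  expect_equal(ly2$lambda_nc_ac, log(2), tolerance = 1e-12)
  expect_lt(ly2$lambda_ac_ami, 0)
  expect_lt(ly2$lambda_ami_nc, 0)
  expect_equal(ly2$mle, log(2), tolerance = 1e-12)
})

test_that("first differences approximate the derivative day-by-day", {
  expect_equal(first_difference(c(1, 3, 2)), c(2, -1))
  expect_equal(first_difference(rep(7, 5)), rep(0, 4))
  x <- rnorm(40)
  expect_equal(sum(first_difference(x)), x[40] - x[1], tolerance = 1e-12)
})

test_that("peak/spike alignment: self, shifted and monotone cases", {
  n <- 240
  nc <- pulse_train(n, centers = c(60, 130, 200))
  # identical trains: every lead is zero
  al <- peak_spike_alignment(nc, nc)
  expect_equal(nrow(al), 3)
  expect_true(all(al$lead_days == 0))
  # spikes 5 days ahead of every peak
  mle <- c(nc[6:n], rep(0, 5))
  al2 <- peak_spike_alignment(nc, mle)
  expect_true(all(al2$lead_days == 5))
  # the literal nearest rule agrees here (5 is the closest spike)
  al2n <- peak_spike_alignment(nc, mle, prefer = "nearest")
  expect_equal(al2n$lead_days, al2$lead_days)
  # monotone series has no interior maxima
  al3 <- peak_spike_alignment(seq_len(100), pulse_train(100, 50))
  expect_equal(nrow(al3), 0)
  # spikes beyond the window are left unmatched, not mismatched
  far <- c(rep(0, 30), nc[1:(n - 30)])
  al4 <- peak_spike_alignment(nc, far, max_lead_days = 10)
  expect_true(any(is.na(al4$lead_days)))
})

test_that("feature-space plots build without evaluation errors", {
  s <- preset_series("two-wave", seed = 2)
  sc <- dynamic_scale(sliding_features(s, window = 150, lag = 15))
  expect_s3_class(plot_feature_space(sc, "nc", "ac"), "ggplot")
  ly <- max_lyapunov(sc)
  expect_s3_class(plot_mle(ly, sc), "ggplot")
  expect_error(plot_feature_space(sc, "nc", "bogus"),
               class = "mcml_error_parameter")
})
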