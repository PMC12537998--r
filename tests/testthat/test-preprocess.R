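# Continuous-to-clean-epochs chain.

test_that("linear detrending matches closed-form least squares", {
  n <- 500
  t0 <- seq_len(n)
  line <- 2 + 0.03 * t0
  expect_lt(max(abs(detrend_linear(rbind(line)))), 1e-9)
  expect_identical(detrend_linear(matrix(0, 2, 10)), matrix(0, 2, 10))
  # line + sine: result equals residuals of an explicit lm fit
  x <- line + sin(2 * pi * 5 * t0 / 250)
  expect_equal(as.vector(detrend_linear(rbind(x))),
               unname(resid(lm(x ~ t0))), tolerance = 1e-9)
  expect_error(detrend_linear(matrix(1, 2, 1)), "2 samples")
})

test_that("zero-phase band-pass matches the squared Butterworth magnitude", {
  fs <- 250
  tt <- seq(0, 20, by = 1 / fs)
  mid <- 2000:3000                       # away from filter edge transients
  gain_at <- function(f) {
    s <- sin(2 * pi * f * tt)
    y <- bandpass_filter(s, fs)
    sqrt(mean(y[mid]^2) / mean(s[mid]^2))
  }
  # analytic oracle: squared (forward-backward) order-4 Butterworth band
  # magnitude with prewarped analog edges
  warp <- function(f) tan(pi * f / fs)
  analytic <- function(f) {
    w <- warp(f); w1 <- warp(0.2); w2 <- warp(20)
    om <- (w^2 - w1 * w2) / (w * (w2 - w1))   # band-pass transform
    (1 / (1 + om^8))                           # |H|^2 of order-4 prototype
  }
  expect_gt(gain_at(5), 0.95)
  expect_lte(gain_at(5), 1.0 + 1e-4)
  expect_equal(gain_at(5), analytic(5), tolerance = 0.02)
  expect_gt(-20 * log10(gain_at(50)), 40)     # >= 40 dB attenuation
  expect_equal(bandpass_filter(rep(0, 1000), fs), rep(0, 1000))
  expect_error(bandpass_filter(tt, fs, low = 30, high = 20), "band edges")
  # commutes with channel permutation
  set.seed(1)
  x <- matrix(rnorm(2 * 600), 2, 600)
  expect_equal(bandpass_filter(x, fs)[2:1, ],
               bandpass_filter(x[2:1, ], fs), tolerance = 1e-10)
})

test_that("segmentation uses half-open windows and drops edge events", {
  fs <- 250
  sig <- matrix(rnorm(3 * fs * 30), 3)
  ev <- structure(list(onsets = c(0.1, 5, 10, 29.9),
                       labels = c("a", "b", "a", "b")),
                  class = "event_schedule")
  expect_warning(ep <- segment_epochs(sig, ev, fs = fs), "dropped 2")
  expect_equal(dim(ep$data), c(2, 3, 300))      # 1.2 s at 250 Hz
  expect_identical(ep$labels, c("b", "a"))
  # epochs reproduce the raw samples
  s0 <- round((5 - 0.2) * fs)
  expect_equal(ep$data[1, , ], sig[, (s0 + 1):(s0 + 300)])
  ev2 <- structure(list(onsets = -5, labels = "a"),
                   class = "event_schedule")
  expect_error(segment_epochs(sig, ev2, fs = fs), "no events")
})

test_that("channel rejection flags variance outliers scale-freely", {
  set.seed(1)
  arr <- array(rnorm(20 * 32 * 100), c(20, 32, 100))
  arr[, 7, ] <- arr[, 7, ] * 100
  ep <- toy_epochs(data = arr)
  expect_identical(reject_channels(ep), "ch7")
  # scale invariance (uV vs mV)
  ep_mv <- ep; ep_mv$data <- ep$data / 1000
  expect_identical(reject_channels(ep_mv), "ch7")
  # permutation invariance
  perm <- c(7, 1:6, 8:32)
  ep_p <- toy_epochs(data = arr[, perm, , drop = FALSE])
  ep_p$channels <- paste0("ch", perm)
  expect_identical(reject_channels(ep_p), "ch7")
  # identical channels: zero spread handled as no outliers
  flat <- array(rep(rnorm(100), each = 5 * 6), c(5, 6, 100))
  expect_identical(reject_channels(toy_epochs(data = flat)), character(0))
})

test_that("epoch rejection removes spike epochs and conserves counts", {
  set.seed(2)
  arr <- array(rnorm(20 * 5 * 100), c(20, 5, 100))
  arr[4, 2, 50] <- 500
  ep <- toy_epochs(data = arr, labels = rep(c("x", "y"), 10))
  r <- reject_epochs(ep)
  expect_identical(r$dropped, 4L)
  expect_equal(n_trials(r$epochs) + length(r$dropped), 20)
  expect_identical(r$epochs$labels, rep(c("x", "y"), 10)[-4])
  # identical epochs: zero spread, none removed
  one <- array(rnorm(4 * 50), c(1, 4, 50))
  hom <- toy_epochs(data = array(rep(one, each = 10), c(10, 4, 50)))
  expect_length(reject_epochs(hom)$dropped, 0)
  expect_error(reject_epochs(toy_epochs(n_trials = 2)), "3 epochs")
})

test_that("FASTER metrics identify reference-correlated and odd components", {
  set.seed(5)
  n <- 5000
  comps <- matrix(rnorm(9 * n), 9, n)
  eog <- comps[3, ] * 0.995 + rnorm(n, 0, 0.1)
  met <- faster_component_metrics(comps, eog = eog, fs = 250)
  expect_identical(names(met), c("component", "max_ref_cor", "kurtosis",
                                 "hurst", "power_gradient",
                                 "median_gradient", "flagged"))
  expect_gt(met$max_ref_cor[3], 0.99)
  expect_true(met$flagged[3])
  expect_lt(max(met$max_ref_cor[-3]), 0.1)
  # white-noise components: Hurst near 1/2, excess kurtosis near 0
  expect_true(all(abs(met$hurst[-3] - 0.5) < 0.1))
  expect_true(all(abs(met$kurtosis[-3]) < 0.2))
  # constant component: metrics zeroed with a warning
  cc <- rbind(comps[1:3, ], 0)
  expect_warning(m2 <- faster_component_metrics(cc, fs = 250), "constant")
  expect_equal(unlist(m2[4, 2:6]), c(max_ref_cor = 0, kurtosis = 0,
                                     hurst = 0, power_gradient = 0,
                                     median_gradient = 0))
})

test_that("rescaled-range Hurst estimate agrees with an independent oracle", {
  skip_if_not_installed("pracma")
  set.seed(6)
  x <- cumsum(rnorm(8192))      # random walk: H ~ 1 (clipped near it)
  w <- rnorm(8192)              # white noise: H ~ 0.5
  hw <- flowprobe:::.hurst_rs(w)
  hx <- flowprobe:::.hurst_rs(x)
  expect_equal(hw, 0.5, tolerance = 0.1)
  expect_gt(hx, 0.85)
  expect_equal(hw, pracma::hurstexp(w, display = FALSE)$Hs,
               tolerance = 0.12)
})

test_that("baseline correction zeroes the window mean and is idempotent", {
  cfg <- simulation_config(n_trials_per_condition = 3, noise_sd = 4)
  ep <- simulate_epochs(cfg, "flow")
  bc <- baseline_correct(ep)
  sel <- bc$times >= -0.2 & bc$times < 0
  expect_lt(max(abs(apply(bc$data[, , sel], c(1, 2), mean))), 1e-10)
  expect_equal(baseline_correct(bc)$data, bc$data, tolerance = 1e-12)
  # constant epochs map to zero
  cst <- toy_epochs(data = array(7, c(2, 3, 50)))
  expect_equal(max(abs(baseline_correct(cst)$data)), 0)
  expect_error(baseline_correct(ep, window = c(-5, -4)), "outside")
})

test_that("the full preprocessing chain yields clean CSD epochs", {
  cfg <- simulation_config(noise_sd = 4, n_trials_per_condition = 12,
                           blink_rate = 6, seed = 13)
  mon <- build_standard_montage()
  ses <- simulate_continuous_session(cfg, "underload", subject = 1)
  out <- preprocess_session(ses, mon, csd = TRUE)
  ep <- out$epochs
  expect_s3_class(ep, "eeg_epochs")
  expect_identical(ep$units, "csd")
  expect_true(all(is.finite(ep$data)))
  expect_true(all(ep$labels == "oddball"))
  expect_lte(n_trials(ep), 12)
  expect_true(all(c("segmented", "baseline", "csd") %in% ep$history))
  expect_identical(out$log$band, c(0.2, 20))
})
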