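# Multitaper spectral analysis: taper construction, density calibration,
# band statistics and the spectrogram.

test_that("DPSS tapers are orthonormal and band-concentrated", {
  tap <- dpss_tapers(2000, nw = 5, k = 9)
  expect_equal(crossprod(tap), diag(9), tolerance = 1e-10,
               ignore_attr = TRUE)
  # in-band energy concentration of the leading taper
  X <- Mod(fft(c(tap[, 1], rep(0, 6000))))^2
  W <- 5 / 2000
  inband <- sum(X[1:ceiling(W * 8000)])
  expect_gt(inband / (sum(X) / 2), 0.999)
})

test_that("the PSD is Parseval-consistent and flat for white noise", {
  set.seed(12)
  ratios <- flat <- numeric(20)
  for (i in 1:20) {
    x <- rnorm(20000)
    ps <- multitaper_psd(x, fs = 1000)
    df <- diff(ps$frequency[1:2])
    flat[i] <- sum(ps$power) * df / var(x)
    sel1 <- ps$frequency >= 4 & ps$frequency <= 12
    sel2 <- ps$frequency >= 100 & ps$frequency <= 300
    ratios[i] <- mean(ps$power[sel1]) / mean(ps$power[sel2])
  }
  expect_true(all(abs(flat - 1) < 0.05))      # Parseval within 5 percent
  expect_gt(mean(ratios), 0.8)                # spectral flatness
  expect_lt(mean(ratios), 1.25)
})

test_that("a noisy sinusoid peaks at its frequency", {
  set.seed(4)
  t <- (0:19999) / 1000
  x <- sin(2 * pi * 8 * t) + 0.1 * rnorm(length(t))
  ps <- multitaper_psd(x, fs = 1000)
  pk <- peak_frequency(ps, band = c(1, 50))
  expect_equal(as.numeric(pk), 8, tolerance = 0.05)
  expect_true(attr(pk, "dominant"))
})

test_that("peak detection flags flat spectra and resolves a delta spectrum", {
  f <- seq(0, 500, by = 0.1)
  flat <- structure(data.frame(frequency = f, power = rep(1, length(f))),
                    class = c("power_spectrum", "data.frame"))
  pk <- peak_frequency(flat, band = c(1, 50))
  expect_false(attr(pk, "dominant"))
  delta <- flat
  delta$power[abs(f - 10) < 0.001] <- 500
  expect_equal(as.numeric(peak_frequency(delta, band = c(1, 50))), 10,
               tolerance = 0.05)
  expect_error(peak_frequency(flat, band = c(600, 700)), "empty")
})

test_that("theta ratio: white noise near the band-width fraction, line at 1", {
  set.seed(9)
  r <- vapply(1:10, function(i) theta_ratio(multitaper_psd(rnorm(20000))), 0)
  expect_equal(mean(r), 8 / 299, tolerance = 0.5)
  f <- seq(0, 500, by = 0.1)
  line <- structure(data.frame(frequency = f,
                               power = ifelse(abs(f - 8) < 0.05, 1000, 1e-9)),
                    class = c("power_spectrum", "data.frame"))
  expect_equal(theta_ratio(line), 1, tolerance = 1e-3)
  short <- structure(data.frame(frequency = seq(0, 100, 0.1), power = 1),
                     class = c("power_spectrum", "data.frame"))
  expect_error(theta_ratio(short), "does not cover")
})

test_that("band powers are width-normalised", {
  set.seed(2)
  bp <- Reduce(`+`, lapply(1:20, function(i)
    band_powers(multitaper_psd(rnorm(20000))))) / 20
  expect_true(max(bp) / min(bp) < 1.25) # flat density: all four equal
  f <- seq(0, 500, by = 0.1)
  line <- structure(data.frame(frequency = f,
                               power = ifelse(abs(f - 8) < 0.05, 1000, 0)),
                    class = c("power_spectrum", "data.frame"))
  bp2 <- band_powers(line)
  expect_gt(bp2[["theta"]], 0)
  expect_equal(unname(bp2[c("delta", "beta")]), c(0, 0))
})

test_that("the spectrogram is stationary for noise and tracks a chirp", {
  set.seed(6)
  sg <- spectrogram(rnorm(20000), fs = 1000, window = 2000)
  colm <- colMeans(sg$power)
  fit <- summary(lm(colm ~ seq_along(colm)))
  expect_gt(fit$coefficients[2, 4], 0.01) # no trend at alpha = 0.01
  # chirp 2 -> 20 Hz over 20 s: ridge increases monotonically
  t <- (0:19999) / 1000
  chirp <- sin(2 * pi * (2 * t + (18 / 40) * t^2))
  sg2 <- spectrogram(chirp, fs = 1000, window = 2000)
  ridge <- sg2$frequency[apply(sg2$power, 2, which.max)]
  expect_true(all(diff(ridge) > 0))
})

test_that("time-averaged spectrogram matches the whole-trace PSD", {
  set.seed(8)
  x <- as.numeric(stats::filter(rnorm(20000), rep(1 / 4, 4), sides = 1))
  x[1:3] <- 0
  ps <- multitaper_psd(x, fs = 1000)
  sg <- spectrogram(x, fs = 1000, window = 2000)
  avg <- rowMeans(sg$power)
  sel <- sg$frequency >= 1 & sg$frequency <= 20
  psd_i <- approx(ps$frequency, ps$power, xout = sg$frequency[sel])$y
  expect_equal(mean(avg[sel] / psd_i), 1, tolerance = 0.2)
})

test_that("decimation preserves band power and halts aliasing", {
  set.seed(3)
  t <- (0:199999) / 10000 # 20 s at 10 kHz
  x <- sin(2 * pi * 8 * t) + 0.05 * rnorm(length(t))
  tr <- list(t = t * 1000, V = x)
  d <- decimate_trace(tr, fs_out = 1000)
  expect_equal(d$fs, 1000)
  expect_equal(length(d$V), 20000)
  ps <- multitaper_psd(d$V, fs = 1000)
  expect_equal(as.numeric(peak_frequency(ps, c(1, 50))), 8, tolerance = 0.1)
})
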