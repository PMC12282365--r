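# Constructed-signal oracles for the functional-domain detectors.

biphasic <- function(centres_ms, amps = rep(1, length(centres_ms)), fs = FS,
                     dur_ms = 200, width_ms = 5, kind = "bipolar") {
  t <- seq(0, dur_ms - 1000 / fs, by = 1000 / fs)
  x <- rep(0, length(t))
  for (i in seq_along(centres_ms)) {
    a <- (t - centres_ms[i]) / width_ms
    x <- x - amps[i] * a * exp(-0.5 * a^2)
  }
  egm_trace(x, fs, kind, qrs_on = 1, qrs_end = length(t),
            t_end = length(t))
}

test_that("LAT is the latest qualifying deflection (midpoint of the swing)", {
  expect_equal(detect_lat(biphasic(50)), 50, tolerance = 1)
  # two equal deflections: the later one wins
  expect_equal(detect_lat(biphasic(c(40, 70))), 70, tolerance = 1)
  # a trailing deflection below 20% of peak-to-peak does not count
  expect_equal(detect_lat(biphasic(c(40, 70), amps = c(1, 0.05))), 40,
               tolerance = 1)
  flat <- egm_trace(rep(0, 400), FS, "bipolar", 1, 200)
  expect_true(is.na(detect_lat(flat)))
})

test_that("RT is the maximum T-wave upslope", {
  tr <- make_trace("unipolar", lat_ms = 60, rt_ms = 300)
  expect_equal(detect_rt(tr), 300, tolerance = 1)

  # monotone-decreasing T window: the least-negative slope is still defined
  t <- seq(0, 399, by = 1000 / FS)
  x <- -t / 400
  x[t >= 350] <- x[t >= 350] - 0.5 * (t[t >= 350] - 350) / 50  # steeper late
  dec <- egm_trace(x, FS, "unipolar", qrs_on = 1,
                   qrs_end = round(0.1 * length(x)), t_end = length(x))
  expect_false(is.na(detect_rt(dec)))
  expect_lt(detect_rt(dec), 350)

  # two T-wave candidates: the steeper upslope wins
  t2 <- make_trace("unipolar", rt_ms = 250, a_t = 0.2)
  tg <- (seq_along(t2$samples) - 1) / FS * 1000
  t2$samples <- t2$samples + 0.6 * exp(-0.5 * ((tg - (320 + 24)) / 24)^2)
  expect_equal(detect_rt(t2), 320, tolerance = 2)
})

test_that("ARI = RT - LAT, with negative values flagged but retained", {
  expect_equal(compute_ari(320, 40), 280)
  expect_equal(compute_ari(100, 100), 0)
  expect_true(is.na(compute_ari(NA_real_, 40)))
  expect_warning(v <- compute_ari(30, 40), "negative")
  expect_equal(v, -10)
})

test_that("EGM duration spans the first-to-last threshold crossing", {
  fs <- FS
  n <- round(0.4 * fs)
  x <- rep(0, n)
  on <- round(0.1 * fs); off <- round(0.18 * fs)  # 80 ms burst
  x[on:off] <- 1
  tr <- egm_trace(x, fs, "bipolar", 1, n)
  expect_equal(egm_duration(tr, seq_len(n)), 80, tolerance = 2 * 1000 / fs)

  expect_equal(egm_duration(egm_trace(rep(0, 100), fs, "bipolar", 1, 50),
                            1:100), 0)

  # two bursts at 0-20 and 60-80 ms: duration is 80 ms, not 40
  x2 <- rep(0, n)
  x2[1:round(0.02 * fs)] <- 1
  x2[round(0.06 * fs):round(0.08 * fs)] <- -1
  tr2 <- egm_trace(x2, fs, "bipolar", 1, n)
  expect_equal(egm_duration(tr2, seq_len(n)), 80, tolerance = 3 * 1000 / fs)
})

test_that("amplitude is peak-to-peak", {
  tr <- egm_trace(c(0.7, -0.3, 0.1, 0), 1000, "bipolar", 1, 3)
  expect_equal(amplitude(tr, 1:4), 1.0)
  expect_equal(amplitude(egm_trace(rep(2, 10), 1000, "bipolar", 1, 5), 1:10), 0)
  t <- seq(0, 1, by = 1 / FS)
  s <- egm_trace(0.8 * sin(2 * pi * 20 * t), FS, "bipolar", 1, 100)
  expect_equal(amplitude(s, seq_along(t)), 1.6, tolerance = 0.01)
})

test_that("deflection count applies the 20% depth rule and is scale-invariant", {
  t <- seq(0, 0.4, by = 1 / FS)
  troughs <- function(depths) {
    x <- rep(0, length(t))
    cents <- c(0.1, 0.2, 0.3)
    for (i in seq_along(depths)) {
      x <- x - depths[i] * exp(-0.5 * ((t - cents[i]) / 0.008)^2)
    }
    x + 0.5 * exp(-0.5 * ((t - 0.05) / 0.008)^2)  # positive lobe, ptp = 1
  }
  tr <- egm_trace(troughs(c(0.5, 0.3, 0.1)), FS, "bipolar", 1, length(t))
  expect_equal(count_deflections(tr, seq_along(t)), 2L)

  tr10 <- tr; tr10$samples <- 10 * tr$samples
  expect_equal(count_deflections(tr10, seq_along(t)),
               count_deflections(tr, seq_along(t)))

  mono <- egm_trace(seq(0.1, 1, length.out = 300), FS, "bipolar", 1, 200)
  expect_equal(count_deflections(mono, 1:300), 0L)

  expect_equal(count_deflections(biphasic(50), 1:200), 1L)
})

test_that("slope statistics match analytic derivatives", {
  fs <- 1000
  ramp <- egm_trace(seq(0, 1, length.out = 1001), fs, "bipolar", 1, 500)
  s <- slope_stats(ramp, 1:1001)
  expect_equal(unname(s["max"]), 1e-3 * fs / 1000, tolerance = 1e-9)
  expect_equal(unname(s["max"]), unname(s["mean"]), tolerance = 1e-9)

  con <- egm_trace(rep(1, 100), fs, "bipolar", 1, 50)
  expect_equal(unname(slope_stats(con, 1:100)), c(0, 0))

  t <- seq(0, 1, by = 1 / FS)
  a <- 0.5; f <- 12
  sine <- egm_trace(a * sin(2 * pi * f * t), FS, "bipolar", 1, 100)
  expect_equal(unname(slope_stats(sine, seq_along(t))["max"]),
               2 * pi * f * a / 1000, tolerance = 0.01 * 2 * pi * f * a / 1000)
})

test_that("features are invariant to time shift within the window", {
  tr1 <- biphasic(60, dur_ms = 400)
  tr2 <- biphasic(160, dur_ms = 400)
  w <- 1:length(tr1$samples)
  expect_equal(amplitude(tr1, w), amplitude(tr2, w), tolerance = 1e-3)
  expect_equal(slope_stats(tr1, w), slope_stats(tr2, w), tolerance = 1e-2)
  expect_equal(count_deflections(tr1, w), count_deflections(tr2, w))
})
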