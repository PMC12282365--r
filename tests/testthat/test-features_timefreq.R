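tone <- function(freq, fs = FS, dur_ms = 400, kind = "bipolar", amp = 1) {
  t <- seq(0, dur_ms / 1000 - 1 / fs, by = 1 / fs)
  n <- length(t)
  egm_trace(amp * sin(2 * pi * freq * t), fs, kind,
            qrs_on = 1, qrs_end = round(n / 2),
            t_end = if (kind == "unipolar") n else n)
}

test_that("SPWVD localizes a pure tone within one frequency bin", {
  tf <- spwvd(tone(30))
  marg <- rowSums(tf)
  f_peak <- attr(tf, "freqs_hz")[which.max(marg)]
  expect_lte(abs(f_peak - 30), attr(tf, "df_hz") + 1e-9)
})

test_that("SPWVD conserves energy within 2% on seeded random signals", {
  for (s in 1:8) {
    x <- withr::with_seed(s, rnorm(814))
    tr <- egm_trace(x, FS, "bipolar", 1, 400)
    tf <- spwvd(tr)
    expect_lt(abs(attr(tf, "energy_ratio") - 1), 0.02)
    # after normalization the integral equals the (band-limited) signal energy
    tot <- sum(tf) * attr(tf, "dt_s") * attr(tf, "df_hz")
    expect_gt(tot, 0)
  }
})

test_that("a chirp's ridge frequency increases over time", {
  fs <- FS
  t <- seq(0, 0.4 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * (10 * t + (50 / 0.4 / 2) * t^2))  # 10 -> 60 Hz
  tf <- spwvd(egm_trace(x, fs, "bipolar", 1, 400))
  ridge <- apply(tf, 2, which.max)
  inner <- ridge[seq(round(0.1 * length(ridge)), round(0.9 * length(ridge)))]
  expect_gt(cor(seq_along(inner), inner, method = "spearman"), 0.95)
})

test_that("band energies: fractions sum to one and low tones land low", {
  tr <- tone(10, kind = "unipolar")
  tf <- spwvd(tr)
  qrs_ms <- c(0, 200)
  be <- band_energies(tf, qrs_ms, channel_bands("unipolar"))
  expect_equal(sum(be$fractions), 1, tolerance = 1e-9)
  expect_gte(be$fractions[1], 0.9)   # 10 Hz lies in the 0-20 band
  expect_true(all(be$fractions >= 0 & be$fractions <= 1))

  z <- egm_trace(rep(0, 814), FS, "unipolar", 1, 300, 700)
  tfz <- spwvd(z)
  bez <- band_energies(tfz, c(150, 340), channel_bands("unipolar"))
  expect_equal(bez$total, 0)
  expect_true(all(is.na(bez$fractions)))
})

test_that("fractional energies are scale-invariant; totals scale quadratically", {
  tr1 <- tone(55); tr3 <- tone(55, amp = 3)
  b1 <- band_energies(spwvd(tr1), c(0, 200), channel_bands("bipolar"))
  b3 <- band_energies(spwvd(tr3), c(0, 200), channel_bands("bipolar"))
  expect_equal(b1$fractions, b3$fractions, tolerance = 1e-6)
  expect_equal(b3$total / b1$total, 9, tolerance = 0.01)
})

test_that("central frequency is the PSD centre of mass", {
  n <- length(tone(40)$samples)
  tr <- tone(40)
  expect_equal(central_frequency(tr, seq_len(n)), 40, tolerance = FS / n + 1)

  t <- seq(0, 0.4 - 1 / FS, by = 1 / FS)
  two <- egm_trace(sin(2 * pi * 20 * t) + sin(2 * pi * 60 * t), FS, "bipolar",
                   1, 400)
  expect_equal(central_frequency(two, seq_along(t)), 40, tolerance = 2)

  noise <- withr::with_seed(3, rnorm(8138))
  wn <- egm_trace(noise, FS, "unipolar", 1, 4000, 8138)
  expect_equal(central_frequency(wn, 1:8138), 40, tolerance = 4)  # B/2, B = 80

  z <- egm_trace(rep(0, 200), FS, "bipolar", 1, 100)
  expect_true(is.na(central_frequency(z, 1:200)))
})

test_that("spectral peak count follows the prominence rule", {
  n <- length(tone(40)$samples)
  expect_equal(spectral_peaks(tone(40), seq_len(n)), 1L)

  t <- seq(0, 0.4 - 1 / FS, by = 1 / FS)
  two <- egm_trace(sin(2 * pi * 20 * t) + sin(2 * pi * 60 * t), FS, "bipolar",
                   1, 400)
  expect_equal(spectral_peaks(two, seq_along(t)), 2L)

  z <- egm_trace(rep(0, 200), FS, "bipolar", 1, 100)
  expect_equal(spectral_peaks(z, 1:200), 0L)
})

test_that("time-frequency features tile 2 windows x 4 bands per channel", {
  reg <- build_registry()
  tfq <- reg[reg$domain == "timefreq", ]
  for (chan in c("bipolar", "unipolar")) {
    fr <- tfq[tfq$channel == chan &
                !tfq$name %in% c("EB_QRS_0_160", "EB_P_0_160",
                                 "RU_QRS_0_80", "RU_T_0_80"), ]
    expect_equal(nrow(fr), 8L)
    cnt <- table(fr$window)
    expect_equal(unname(as.integer(cnt[c("QRS", "post")])), c(4L, 4L))
  }
})

test_that("short traces are rejected", {
  expect_error(spwvd(egm_trace(rnorm(50), FS, "bipolar", 1, 25)), "64")
  expect_error(central_frequency(tone(40), 1:16), "32")
})
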