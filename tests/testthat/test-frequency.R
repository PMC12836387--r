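test_that("constant series give a flat tachogram and zero spectrum", {
  nn <- nn_series(rep(500, 800))
  raw <- resample_tachogram(nn, detrend = FALSE)
  expect_true(all(abs(raw$values - 500) < 1e-6))
  det <- resample_tachogram(nn)
  expect_true(all(abs(det$values) < 1e-6))
  psd <- estimate_psd(det)
  expect_true(all(psd$density < 1e-12))
  sp <- band_powers(psd)
  expect_true(all(c(sp$tp, sp$ulf, sp$vlf, sp$lf, sp$hf) < 1e-12))
  # an identically-zero spectrum flags all normalized indices as missing
  zero <- structure(list(fs = 4, t0 = 0, values = rep(0, 2400),
                         detrended = TRUE, n_bridged_gaps = 0L),
                    class = "even_tachogram")
  sp0 <- band_powers(estimate_psd(zero))
  expect_true(is.na(sp0$n_hf) && is.na(sp0$n_lf) && is.na(sp0$lf_hf))
  expect_identical(sp0$tp, 0)
})

test_that("resampling preconditions are enforced", {
  nn <- nn_series(rep(500, 800))
  expect_error(resample_tachogram(nn, fs = 0.5), "fs must exceed")
  expect_error(resample_tachogram(nn_series(rep(500, 100))), "5 minutes")
  expect_error(resample_tachogram(nn_series(c(500, 500))), "at least 3")
})

test_that("interpolated tachogram tracks the generating modulation", {
  cfg <- autonomic_config(mean_rr = 500, a_hf = 0, a_lf = 0.08, f_lf = 0.09,
                          noise_sd = 0, duration = 1200, phase_lf = 0.7)
  nn <- filter_nn(generate_beats(cfg, seed = 13))
  tach <- resample_tachogram(nn)
  grid <- tach$t0 + (seq_along(tach$values) - 1) / tach$fs
  # an interval reports the average rate over its span: compare the tachogram
  # with the (negated) rate modulation at each interval's midpoint
  ref <- -sin(2 * pi * 0.09 * (grid - 0.25) + 0.7)
  expect_gt(stats::cor(tach$values, ref), 0.99)
})

test_that("discrete Parseval holds exactly for the periodogram", {
  for (s in 1:5) {
    nn <- random_nn(1500, seed = s)
    tach <- resample_tachogram(nn)
    psd <- estimate_psd(tach, "periodogram")
    total <- sum(psd$density) * psd$df
    expect_equal(total, mean(tach$values^2), tolerance = 1e-9)
  }
})

test_that("a pure sinusoid peaks within one bin of its frequency", {
  fs <- 4
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  tach <- structure(list(fs = fs, t0 = 0, values = 40 * sin(2 * pi * 0.3 * t),
                         detrended = TRUE, n_bridged_gaps = 0L),
                    class = "even_tachogram")
  psd <- estimate_psd(tach, "periodogram")
  peak <- psd$freqs[which.max(psd$density)]
  expect_lte(abs(peak - 0.3), psd$df)
  expect_error(estimate_psd(tach, "multitaper"))
})

test_that("band powers are additive and normalizations consistent", {
  for (s in 1:10) {
    nn <- random_nn(1500, seed = 100 + s)
    sp <- spectral_indices(nn)
    expect_equal(sp$tp, sp$ulf + sp$vlf + sp$lf + sp$hf, tolerance = 1e-12)
    expect_equal(sp$n_hf + sp$n_lf, 1, tolerance = 1e-12)
    expect_equal(sp$lf_hf, sp$lf / sp$hf, tolerance = 1e-12)
    expect_true(all(c(sp$ulf, sp$vlf, sp$lf, sp$hf) >= 0))
  }
})

test_that("moving the modulation from 0.10 to 0.30 Hz moves the band power", {
  mk <- function(f, band) {
    cfg <- autonomic_config(mean_rr = 500, a_hf = 0.1, f_hf = 0.3, a_lf = 0.1,
                            f_lf = 0.09, noise_sd = 0, duration = 1800,
                            phase_hf = 0, phase_lf = 0)
    if (f < 0.15) cfg$a_hf <- 0 else cfg$a_lf <- 0
    if (f < 0.15) cfg$f_lf <- f else cfg$f_hf <- f
    sp <- spectral_indices(filter_nn(generate_beats(cfg, seed = 31)))
    sp[[band]] / (sp$lf + sp$hf)
  }
  expect_gt(mk(0.10, "lf"), 0.9)
  expect_gt(mk(0.30, "hf"), 0.9)
})

test_that("welch mode reduces variance and reports hybrid ULF", {
  nn <- filter_nn(generate_beats(autonomic_config(duration = 3600), seed = 17))
  spw <- spectral_indices(nn, method = "welch")
  spp <- spectral_indices(nn, method = "periodogram")
  expect_true(spw$hybrid)
  expect_equal(spw$ulf, spp$ulf, tolerance = 1e-12)
  expect_equal(spw$tp, spw$ulf + spw$vlf + spw$lf + spw$hf, tolerance = 1e-12)
  # same physiology, comparable band split
  expect_equal(spw$n_hf, spp$n_hf, tolerance = 0.1)
})

test_that("long gaps are bridged linearly, not splined", {
  on <- c(seq(0.5, 200, by = 0.5), seq(230, 430.5, by = 0.5))
  vals <- c(rep(500, 400), rep(600, 402))
  nn <- nn_series(vals, onsets = on,
                  gap_before = c(rep(FALSE, 400), TRUE, rep(FALSE, 401)))
  tach <- resample_tachogram(nn, detrend = FALSE)
  expect_identical(tach$n_bridged_gaps, 1L)
  grid <- tach$t0 + (seq_along(tach$values) - 1) / tach$fs
  inside <- grid > 200 & grid < 230
  # linear bridge between (200, 500) and (230, 600)
  expect_lt(max(abs(tach$values[inside] -
                      (500 + (grid[inside] - 200) / 30 * 100))), 1e-6)
})
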