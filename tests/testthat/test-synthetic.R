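test_that("constant-rate IPFM is an exact metronome", {
  cfg <- autonomic_config(mean_rr = 500, a_hf = 0, a_lf = 0, noise_sd = 0,
                          duration = 10)
  b <- generate_beats(cfg, seed = 1)
  expect_length(b$times, 20L)
  expect_lt(max(abs(b$times - seq(0.5, 10, by = 0.5))) * 1000, 0.01)
  expect_true(all(b$labels == "N"))
})

test_that("beat count scales linearly with duration", {
  mk <- function(dur) autonomic_config(mean_rr = 520, a_hf = 0.1, a_lf = 0.04,
                                       noise_sd = 0, duration = dur,
                                       phase_hf = 1, phase_lf = 2)
  n1 <- length(generate_beats(mk(1800), seed = 3)$times)
  n2 <- length(generate_beats(mk(3600), seed = 3)$times)
  expect_lte(abs(n2 - 2 * n1), 1)
})

test_that("configuration invariants are enforced", {
  expect_error(autonomic_config(a_hf = 0.5, a_lf = 0.4, noise_sd = 0.05),
               "rate stays positive")
  expect_error(autonomic_config(f_hf = 0.1), "f_hf")
  expect_error(autonomic_config(f_lf = 0.2), "f_lf")
  expect_error(autonomic_config(sympatho_shift = 1.5), "sympatho_shift")
  expect_error(autonomic_config(mean_rr = -5))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- autonomic_config(duration = 300)
  expect_identical(generate_beats(cfg, seed = 7), generate_beats(cfg, seed = 7))
  expect_false(identical(generate_beats(cfg, seed = 7)$times,
                         generate_beats(cfg, seed = 8)$times))
})

test_that("single-sinusoid modulation concentrates power in its band", {
  # HF-only modulation: downstream PSD peak and >=90% of (VLF+LF+HF) in HF
  cfg <- autonomic_config(mean_rr = 500, a_hf = 0.1, f_hf = 0.25, a_lf = 0,
                          noise_sd = 0, duration = 3600)
  nn <- filter_nn(generate_beats(cfg, seed = 11))
  sp <- spectral_indices(nn)
  expect_gt(sp$hf / (sp$vlf + sp$lf + sp$hf), 0.90)
  psd <- estimate_psd(resample_tachogram(nn))
  peak <- psd$freqs[which.max(psd$density)]
  expect_gt(peak, 0.15)
  expect_lt(peak, 0.40)
})

test_that("artifact injection with zero rates is the identity", {
  b <- generate_beats(autonomic_config(duration = 300), seed = 2)
  out <- inject_artifacts(b, artifact_config(ectopic_rate = 0, missed_rate = 0),
                          seed = 5)
  expect_identical(out$times, b$times)
  expect_identical(out$labels, b$labels)
})

test_that("ectopic flag counts follow the binomial rate", {
  b <- beat_series(cumsum(rep(0.5, 1001)))
  cfg <- artifact_config(ectopic_rate = 0.01)
  flagged <- vapply(1:200, function(s) {
    sum(inject_artifacts(b, cfg, seed = s)$labels == "E")
  }, numeric(1))
  # mean of 200 draws from Binomial(~1000, 0.01): within 5 SE of 10
  expect_lt(abs(mean(flagged) - 10), 5 * sqrt(1000 * 0.01 * 0.99 / 200))
  expect_true(all(vapply(1:20, function(s) {
    out <- inject_artifacts(b, cfg, seed = s)
    all(diff(out$times) > 0)
  }, logical(1))))
})

test_that("non-perturbed beats keep their normal label", {
  b <- generate_beats(autonomic_config(duration = 300), seed = 4)
  out <- inject_artifacts(b, artifact_config(ectopic_rate = 0.05), seed = 9)
  expect_setequal(unique(out$labels), c("N", "E"))
  # unshifted beats are exactly the original times
  expect_true(all(out$times[out$labels == "N"] %in% b$times))
})

test_that("cohort generation is deterministic and respects the design", {
  cfg <- autonomic_config(duration = 300)
  cohort <- generate_cohort(cfg, shift = 0.8, n_subjects = 3, seed = 21)
  expect_length(cohort, 3L)
  expect_identical(cohort,
                   generate_cohort(cfg, shift = 0.8, n_subjects = 3, seed = 21))
  # shift = 0: Pre and Post share the config, differ only by noise path
  null_cohort <- generate_cohort(cfg, shift = 0, n_subjects = 2, seed = 22)
  for (s in null_cohort) {
    expect_equal(mean(diff(s$pre$times)), mean(diff(s$post$times)),
                 tolerance = 0.05)
  }
})

test_that("median SD1/SD2 is non-increasing in the sympathovagal shift", {
  cfg <- autonomic_config(duration = 900)
  med <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 1.0), function(rho) {
    cfg$sympatho_shift <- rho
    ratios <- vapply(1:20, function(s) {
      poincare_indices(filter_nn(generate_beats(cfg, seed = 1000 + s)))$sd1_sd2
    }, numeric(1))
    stats::median(ratios)
  }, numeric(1))
  expect_true(all(diff(med) <= 0))
})

test_that("beat series round-trip through CSV and RR exports", {
  b <- generate_beats(autonomic_config(duration = 300), seed = 6)
  csv <- tempfile(fileext = ".csv")
  write_beats(b, csv)
  b2 <- read_beats(csv)
  expect_equal(b2$times, b$times, tolerance = 1e-9)
  expect_identical(b2$labels, b$labels)
  rr <- tempfile(fileext = ".txt")
  write_rr(b, rr)
  b3 <- read_beats(rr)
  # an RR list of n-1 intervals yields n-1 beats, so n-2 derived intervals
  expect_equal(diff(b3$times), diff(b$times)[-1], tolerance = 1e-9)
})
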