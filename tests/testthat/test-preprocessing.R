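test_that("read_beats parses annotation CSVs and detects bad rows", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("time_s,label", "0.5,N", "1.0,N", "1.6,N"), f)
  b <- read_beats(f)
  expect_length(b$times, 3L)
  expect_equal(diff(b$times) * 1000, c(500, 600))

  writeLines(c("time_s,label", "0.5,N", "1.0,N", "0.9,N"), f)
  expect_error(read_beats(f), "row 3")

  writeLines(character(0), f)
  expect_error(read_beats(f), "empty")
})

test_that("read_beats converts plain RR lists to cumulative beat times", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("500", "500", "500"), f)
  b <- read_beats(f)
  expect_equal(b$times, c(0.5, 1.0, 1.5))
  expect_true(all(b$labels == "N"))
  expect_identical(b$record_start_clock, "00:00")
})

test_that("select_window applies wall-clock arithmetic with day indices", {
  b <- beat_series(seq(60, 16 * 3600, by = 60), record_start_clock = "20:00")
  w <- select_window(b, "00:00", "08:00", start_day = 1, end_day = 1)
  expect_gte(min(w$times), 4 * 3600)
  expect_lt(max(w$times), 12 * 3600)
  # full-record window is the identity on times
  full <- select_window(b, "20:00", "13:00", start_day = 0, end_day = 1)
  expect_identical(full$times, b$times)
  # zero-length and out-of-record windows fail loudly
  expect_error(select_window(b, "03:00", "03:00", 1, 1), "empty selection")
  expect_error(select_window(b, "00:00", "08:00", 5, 5), "empty selection")
})

test_that("clean synthetic series pass the default filter untouched", {
  nn <- filter_nn(generate_beats(autonomic_config(duration = 600), seed = 3))
  expect_identical(nn$n_rejected, 0L)
  expect_false(any(nn$gap_before))
})

test_that("filtering rejects intervals adjacent to injected ectopics", {
  cfg <- autonomic_config(duration = 600)
  art <- artifact_config(ectopic_rate = 0.01)
  frac <- vapply(1:50, function(s) {
    dirty <- inject_artifacts(generate_beats(cfg, seed = s), art, seed = s)
    nn <- filter_nn(dirty)
    ect <- which(dirty$labels == "E")
    if (length(ect) == 0L) return(1)
    # ground-truth-perturbed intervals: those ending or starting at an ectopic
    perturbed_onsets <- dirty$times[c(ect, ect + 1L)]
    perturbed_onsets <- perturbed_onsets[!is.na(perturbed_onsets)]
    mean(!perturbed_onsets %in% nn$onsets)
  }, numeric(1))
  expect_gte(mean(frac >= 0.9), 0.9)
})

test_that("filter_nn enforces bounds, step rule and minimum data", {
  b <- beat_series(c(0, 0.5, 1.0, 3.5, 4.0, 4.5))  # one 2500 ms dropout
  nn <- filter_nn(b, filter_rules())
  expect_identical(nn$n_rejected, 1L)
  expect_true(any(nn$gap_before))
  # relative step rule catches an unlabeled premature beat
  b2 <- beat_series(c(0, 0.5, 1.0, 1.3, 2.0, 2.5, 3.0))
  nn2 <- filter_nn(b2, filter_rules())
  expect_gte(nn2$n_rejected, 1L)
  all_art <- beat_series(c(0, 0.5, 1.0), labels = rep("A", 3))
  expect_error(filter_nn(all_art), "insufficient NN data")
})

test_that("filter_nn is idempotent", {
  dirty <- inject_artifacts(generate_beats(autonomic_config(duration = 600),
                                           seed = 5),
                            artifact_config(ectopic_rate = 0.02), seed = 5)
  nn1 <- filter_nn(dirty)
  nn2 <- filter_nn(nn1)
  expect_identical(nn2$intervals, nn1$intervals)
  expect_identical(nn2$onsets, nn1$onsets)
  expect_identical(nn2$gap_before, nn1$gap_before)
  expect_identical(nn2$n_rejected, nn1$n_rejected)
})

test_that("window selection and filtering commute with a time shift", {
  b <- generate_beats(autonomic_config(duration = 3600 * 5,
                                       record_start_clock = "22:00"), seed = 8)
  shift <- 3600  # one hour later on the record clock, one hour earlier start
  b_shift <- beat_series(b$times + shift, b$labels,
                         record_start_clock = "21:00")
  w1 <- select_window(b, "23:00", "02:00", 0, 1)
  w2 <- select_window(b_shift, "23:00", "02:00", 0, 1)
  nn1 <- filter_nn(w1)
  nn2 <- filter_nn(w2)
  expect_equal(nn2$intervals, nn1$intervals, tolerance = 1e-9)
  expect_equal(nn2$onsets, nn1$onsets + shift, tolerance = 1e-9)
  expect_identical(nn2$gap_before, nn1$gap_before)
  expect_identical(nn2$n_rejected, nn1$n_rejected)
})
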