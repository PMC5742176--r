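test_that("EEG CSV reader validates structure and round-trips exactly", {
  td <- withr::local_tempdir()
  toy <- file.path(td, "toy.csv")
  writeLines(c("Fp1_uV,Fp2_uV", "1.5,2.5", "2,3", "0,1"), toy)
  rec <- read_eeg_csv(toy, fs = 250)
  expect_length(rec$channels$Fp1, 3)
  expect_equal(rec$channels$Fp2, c(2.5, 3, 1))

  # writer -> reader is bit-exact
  orig <- synth_eeg(20, blink_times = c(4, 12), seed = 9)
  p <- file.path(td, "rt.csv")
  write_eeg_csv(orig, p)
  back <- read_eeg_csv(p)
  expect_identical(back$channels$Fp1, orig$channels$Fp1)
  expect_identical(back$channels$Fp2, orig$channels$Fp2)
  expect_equal(back$fs, orig$fs, tolerance = 1e-9)

  # missing channel column
  bad <- file.path(td, "bad.csv")
  writeLines(c("Fp1_uV", "1", "2"), bad)
  expect_error(read_eeg_csv(bad, fs = 250), "Fp2_uV")
  # non-numeric cells
  nn <- file.path(td, "nn.csv")
  writeLines(c("Fp1_uV,Fp2_uV", "1,a", "2,3"), nn)
  expect_error(read_eeg_csv(nn, fs = 250), "non-numeric")
  # empty file
  ef <- file.path(td, "empty.csv")
  writeLines("Fp1_uV,Fp2_uV", ef)
  expect_error(read_eeg_csv(ef, fs = 250), "empty")
})

test_that("noiseless blinks are recovered exactly", {
  truth <- c(10, 25, 40, 55, 70)
  rec <- synth_eeg(90, truth, noise_sd = 0)
  ev <- detect_blinks(rec)
  expect_equal(nrow(ev), 5)
  expect_true(all(abs(ev$peak_time - truth) <= 0.020))
  expect_true(all(ev$channel_support == "Fp1+Fp2"))
  expect_true(!is.unsorted(ev$peak_time))
  expect_true(all(diff(ev$peak_time) >= 0.250))
})

test_that("flat signal yields no events; short recordings error", {
  rec <- eeg_recording(numeric(5000), numeric(5000), fs = 250)
  ev <- detect_blinks(rec)
  expect_equal(nrow(ev), 0)
  short <- eeg_recording(numeric(1000), numeric(1000), fs = 250)
  expect_error(detect_blinks(short), "too short")
})

test_that("detection is amplitude-scale equivariant", {
  rec <- synth_eeg(120, session_blink_times(120, seed = 4), noise_sd = 15,
                   seed = 4)
  ev1 <- detect_blinks(rec, min_amplitude = 10)
  scaled <- eeg_recording(rec$channels$Fp1 * 37, rec$channels$Fp2 * 37,
                          fs = rec$fs)
  ev2 <- detect_blinks(scaled, min_amplitude = 10 * 37)
  expect_equal(ev1$peak_time, ev2$peak_time)
})

test_that("event count is non-increasing in the threshold multiplier", {
  rec <- synth_eeg(300, session_blink_times(300, seed = 8),
                   noise_sd = 25, seed = 8)
  counts <- vapply(c(2, 3, 4, 5), function(k)
    nrow(detect_blinks(rec, threshold_k = k, min_amplitude = 0)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection recovers the generating intervals on clean EEG", {
  truth <- session_blink_times(200, rate = 20, seed = 5)
  rec <- synth_eeg(200, truth, noise_sd = 0)
  brv <- build_brv(detect_blinks(rec))
  expect_equal(length(brv), length(truth) - 1)
  expect_true(all(abs(as.numeric(brv) - diff(truth)) <= 1 / rec$fs))
})

test_that("detection stays accurate in pink background noise", {
  f1 <- vapply(1:5, function(s) {
    truth <- session_blink_times(300, rate = 18, seed = s)
    rec <- synth_eeg(300, truth, template_amplitude = 100, noise_sd = 15,
                     seed = 100 + s)
    detection_f1(detect_blinks(rec)$peak_time, truth, tol = 0.1)
  }, numeric(1))
  expect_gte(mean(f1), 0.95)
})

test_that("interval stacking is exact arithmetic", {
  ev <- data.frame(peak_time = c(10.0, 12.5, 16.0), amplitude = 1:3)
  brv <- build_brv(ev)
  expect_equal(as.numeric(brv), c(2.5, 3.5))
  # telescoping
  tt <- sort(runif(20, 0, 100))
  brv2 <- build_brv(data.frame(peak_time = tt))
  expect_length(brv2, 19)
  expect_equal(sum(brv2), tt[20] - tt[1])
  expect_error(build_brv(data.frame(peak_time = 1)), "insufficient")
})

test_that("blink rate is blinks per minute", {
  ev <- function(n) data.frame(peak_time = as.numeric(seq_len(n)),
                               amplitude = rep(1, n))
  expect_equal(blink_rate(ev(90), 300), 18)
  expect_equal(blink_rate(ev(0), 300), 0)
  expect_equal(blink_rate(ev(183), 600), 18.3)
})

test_that("QC threshold is boundary-inclusive", {
  mk <- function(n) brv_series(rep(1, n))
  expect_false(qc_filter(mk(5), 30)$passed)
  expect_true(qc_filter(mk(90), 30)$passed)
  expect_true(qc_filter(mk(30), 30)$passed)
  expect_match(qc_filter(mk(5), 30)$reason, "short")
})
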