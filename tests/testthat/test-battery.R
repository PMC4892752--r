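test_that("battery defines the 12 tasks with the published design", {
  bat <- build_battery()
  expect_length(bat, 12)
  expect_setequal(names(bat), c(paste0("p", 1:4), paste0("r", 1:4),
                                paste0("m", 1:4)))
  domains <- vapply(bat, `[[`, "", "domain")
  expect_equal(as.vector(table(domains)[c("pitch", "rhythm", "timbre")]),
               c(4L, 4L, 4L))
  for (id in c("p3", "p4")) {
    expect_equal(bat[[id]]$paradigm, "fixed_same_different")
    expect_equal(bat[[id]]$n_trials, 40L)
  }
  adaptive <- battery_task_ids(bat, c("adaptive_2AFC", "adaptive_3AFC"))
  expect_length(adaptive, 10)
  expect_true(all(vapply(bat[adaptive], `[[`, 0L, "n_trials") == 50L))
  expect_setequal(log_tasks(), c("p1", "r1", "r2", "m2", "m3"))
  dir <- task_directions()
  expect_false(any(dir[c("p3", "p4")]))
  expect_true(all(dir[setdiff(names(dir), c("p3", "p4"))]))
  # 3AFC tasks carry chance level 1/3
  expect_equal(bat$r3$guess_rate, 1 / 3)
  expect_equal(bat$p1$guess_rate, 0.5)
})

test_that("pure-tone synthesis has the right length, RMS and bounds", {
  w <- synth_pure_tone(tone_spec(500, 100), 44100)
  expect_length(w, 4410)
  expect_length(synth_pure_tone(tone_spec(500, 250), 44100), 11025)
  # un-ramped full-scale sinusoid: RMS = peak / sqrt(2)
  w2 <- synth_pure_tone(tone_spec(500, 1000, level = 0, ramp = 0), 44100)
  expect_equal(sqrt(mean(w2^2)), 1 / sqrt(2), tolerance = 1e-3)
  expect_lte(max(abs(w2)), 1)
  expect_error(synth_pure_tone(tone_spec(500, 100), 1000), "aliasing")
  expect_error(tone_spec(500, 100, ramp = 60), "exceed")
})

test_that("basic pitch trials implement the semitone arithmetic", {
  set.seed(11)
  tr <- make_pitch_trial("p1", 0)
  expect_true(tr$undecidable)
  expect_equal(tr$pairs[[1]], tr$pairs[[2]])

  # 1-semitone change scales frequency by 2^(1/12)
  found <- replicate(20, {
    t1 <- make_pitch_trial("p1", 1)
    tgt <- t1$pairs[[t1$target]]
    abs(tgt[2] / tgt[1] - 2^(t1$direction / 12)) < 1e-12
  })
  expect_true(all(found))

  same_by_dir <- replicate(50, {
    t2 <- make_pitch_trial("p2", 1)
    (t2$answer == "same") == (t2$directions[1] == t2$directions[2])
  })
  expect_true(all(same_by_dir))
  expect_error(make_pitch_trial("p1", -1), ">= 0")
})

test_that("local changes preserve and global changes violate the contour", {
  set.seed(7)
  for (i in 1:1000) {
    t3 <- make_pitch_sequence_trial("p3", same = FALSE)
    expect_identical(t3$contour_reference, t3$contour_comparison)
    expect_false(isTRUE(all.equal(t3$reference, t3$comparison)))
    t4 <- make_pitch_sequence_trial("p4", same = FALSE)
    expect_false(identical(t4$contour_reference, t4$contour_comparison))
  }
  ts <- make_pitch_sequence_trial("p3", same = TRUE)
  expect_identical(ts$reference, ts$comparison)
})

test_that("rhythm trials implement the stated interval constructions", {
  set.seed(3)
  t2 <- make_rhythm_trial("r2", 400, 25)
  target <- t2$onsets[[t2$target]]
  expect_equal(diff(target), c(400, 400, 500, 400))
  # timing conservation: total duration exceeds reference by ioi * delta/100
  ref <- t2$onsets[[3 - t2$target]]
  expect_equal(max(target) - max(ref), 400 * 25 / 100, tolerance = 1e-9)

  t1 <- make_rhythm_trial("r1", 500, 0)
  expect_true(t1$undecidable)
  expect_equal(t1$onsets[[1]], t1$onsets[[2]])
  expect_error(make_rhythm_trial("r1", 200, 10), "\\[300, 600\\]")

  for (task in c("r3", "r4")) {
    tr <- make_rhythm_trial(task, 400, 30)
    expect_length(tr$onsets, 3)
    expect_true(all(vapply(tr$onsets, length, 0L) == 7))
    expect_true(all(vapply(tr$onsets, function(o) all(diff(o) > 0), NA)))
    # exactly one sequence differs from the reference
    same_as_ref <- vapply(tr$onsets, identical, NA, tr$onsets[[1]])
    expect_equal(sum(!same_as_ref), 1L)
    expect_equal(which(!same_as_ref), tr$odd)
  }
  # strongly metrical reference has onsets on every beat, weak does not
  r3 <- make_rhythm_trial("r3", 400, 10)$onsets[[1]]
  r4 <- make_rhythm_trial("r4", 400, 10)$onsets[[1]]
  beats <- 400 * 0:3
  expect_true(all(beats %in% r3))
  expect_false(all(beats %in% r4))
})

test_that("FM synthesis degenerates correctly and has the right sidebands", {
  sr <- 8000
  spec0 <- modulation_spec(500, fm_rate = 2, fm_depth = 0)
  w0 <- synth_modulated("m1", spec0, sr)
  t <- (seq_along(w0) - 1) / sr
  ramp <- audbat:::raised_cosine_envelope(length(w0), round(0.01 * sr))
  expect_lt(max(abs(w0 - 0.9 * sin(2 * pi * 500 * t) * ramp)), 1e-9)

  spec <- modulation_spec(500, fm_rate = 40, fm_depth = 0.2)
  w <- synth_modulated("m2", spec, sr)
  expect_lte(max(abs(w)), 1)
  amp <- Mod(stats::fft(w))[1:(length(w) / 2)]
  hz <- (seq_along(amp) - 1) * sr / length(w)
  band <- function(f) max(amp[abs(hz - f) < 2])
  noise <- stats::median(amp)
  expect_gt(band(460), 20 * noise)
  expect_gt(band(540), 20 * noise)
  expect_gt(band(500), 20 * noise)
  expect_error(synth_modulated("m1", modulation_spec(500, 7, 0.1), sr),
               "fm_rate")

  # ripples: depth 0 reproduces the flat-envelope reference
  rs <- modulation_spec(500, ripple_density = 1, ripple_rate = 4,
                        fm_depth = 0)
  expect_identical(synth_modulated("m3", rs, 16000),
                   synth_modulated("m3", rs, 16000))
  rd <- modulation_spec(500, ripple_density = 1, ripple_rate = 4,
                        fm_depth = 0.9)
  wd <- synth_modulated("m3", rd, 16000)
  expect_lte(max(abs(wd)), 1)
  expect_gt(max(abs(wd - synth_modulated("m3", rs, 16000))), 1e-3)
})

test_that("battery serializes to JSON and stimuli to WAV", {
  js <- battery_json()
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_length(parsed, 12)
  expect_equal(parsed$p1$n_trials, 50)
  f <- tempfile(fileext = ".wav")
  write_wav(synth_pure_tone(tone_spec(500, 50), 8000), f, 8000)
  con <- file(f, "rb")
  hdr <- readChar(con, 4)
  close(con)
  expect_equal(hdr, "RIFF")
})
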