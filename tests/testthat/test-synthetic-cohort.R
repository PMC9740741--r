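test_that("protocol table matches the shuttle-test design", {
  p <- shuttle_protocol()
  expect_equal(nrow(p), 15)
  expect_equal(p$speed_kmh[1], 0)
  expect_true(all(diff(p$speed_kmh[-1]) > 0))
  expect_equal(p$duration_s, c(180, rep(90, 14)))
})

test_that("cohort generation returns the configured number of recordings", {
  co <- tiny_cohort()
  expect_length(co, 3)
  expect_equal(vapply(co, `[[`, "", "test_type"),
               c("track", "track", "treadmill"), ignore_attr = TRUE)
  big <- cohort_config()  # default study conditions
  expect_equal(big$n_track + big$n_treadmill, 110)
  expect_equal(round(big$fraction_100hz * 110), 39)
})

test_that("identical seeds give bit-identical cohorts", {
  a <- generate_cohort(tiny_config(), seed = 9)
  b <- generate_cohort(tiny_config(), seed = 9)
  expect_identical(a, b)
  c2 <- generate_cohort(tiny_config(), seed = 10)
  expect_false(identical(a[[1]]$x, c2[[1]]$x))
})

test_that("stage 1 is 180 s of Standing and annotations cover every sample", {
  co <- generate_cohort(cohort_config(n_track = 1, n_treadmill = 0),
                        seed = 3)
  rec <- co[[1]]
  n1 <- sum(rec$stage == 1)
  expect_equal(n1, 180 * rec$sampling_rate)
  expect_true(all(rec$class[rec$stage == 1] == "Standing"))
  expect_length(rec$class, length(rec$x))
  expect_length(rec$stage, length(rec$x))
  expect_true(!is.unsorted(rec$stage))
})

test_that("configuration errors are rejected", {
  expect_error(cohort_config(n_track = -1), "non-negative")
  expect_error(cohort_config(fraction_100hz = 1.5), "0, 1")
  expect_error(synth_stage_signal(-1, "Walking", 10, 50,
                                  draw_subject_params(tiny_config(), "s"),
                                  "track"),
               "non-negative")
})

test_that("label assignment follows the stage rules", {
  stages <- c(1, 1, 2, 5, 8, 9, 12)
  expect_equal(assign_labels(stages, "binary"),
               c("Standing", "Standing", "Walking", "Walking", "Walking",
                 NA, NA))
  expect_equal(assign_labels(stages, "tertiary", jog_onset_stage = 8),
               c("Standing", "Standing", "Walking", "Walking", "Jogging",
                 "Jogging", "Jogging"))
  expect_error(assign_labels(stages, "tertiary", jog_onset_stage = 6),
               ">= 7")
  expect_error(assign_labels(stages, "tertiary"), "jog_onset_stage")
})

test_that("standing is quiet, walking periodic, jogging larger", {
  set.seed(11)
  params <- draw_subject_params(tiny_config(), "subj")
  st <- synth_stage_signal(0, "Standing", 60, 50, params, "treadmill")
  expect_equal(mean(st$y), 1, tolerance = 0.02)
  bound <- 1.6 * params$sway_amplitude + 4 * params$noise_sd
  expect_lt(stats::sd(st$y), bound)
  wa <- synth_stage_signal(5.5, "Walking", 60, 50, params, "treadmill")
  jo <- synth_stage_signal(5.5, "Jogging", 60, 50, params, "treadmill")
  expect_gt(stats::sd(jo$y), stats::sd(wa$y))
})

test_that("per-class vertical SD is ordered on every generated recording", {
  for (rec in tiny_cohort()) {
    rec50 <- downsample_to_50(rec)
    sds <- tapply(rec50$y, rec50$class, stats::sd)
    expect_lt(sds[["Standing"]], sds[["Walking"]])
    if ("Jogging" %in% names(sds))
      expect_lt(sds[["Walking"]], sds[["Jogging"]])
  }
})

test_that("walking stage spectrum peaks at the configured step frequency", {
  set.seed(21)
  cfg <- tiny_config()
  params <- draw_subject_params(cfg, "spec")
  speed <- 4.3
  f_expected <- params$walk_freq_intercept + params$walk_freq_slope * speed
  sig <- synth_stage_signal(speed, "Walking", 90, 50, params, "treadmill")
  y <- sig$y - mean(sig$y)
  n <- length(y)
  p <- Mod(stats::fft(y))^2
  k <- which.max(p[2:floor(n / 2)])
  f_peak <- k * 50 / n
  expect_lt(abs(f_peak - f_expected), 50 / n + 1e-9)  # within one FFT bin
})

test_that("roughly the configured fraction of recordings is at 100 Hz", {
  co <- generate_cohort(cohort_config(n_track = 8, n_treadmill = 2),
                        seed = 2)
  rates <- vapply(co, `[[`, 0, "sampling_rate")
  expect_equal(sum(rates == 100), round(39 / 110 * 10))
})

test_that("cohort CSV round-trips through write and read", {
  rec <- short_recording()
  tmp <- tempfile(fileext = ".csv")
  write_recording_csv(rec, tmp)
  back <- read_raw_csv(tmp, test_type = "treadmill")
  expect_equal(back$sampling_rate, 50)
  expect_lt(max(abs(back$x - rec$x)), 1e-6)  # 1e-6 g absolute
  expect_lt(max(abs(back$y - rec$y)), 1e-6)
  expect_equal(back$stage, rec$stage)
  expect_equal(back$class, rec$class)
  unlink(tmp)
})

test_that("malformed CSV rows are reported with their line", {
  rec <- short_recording()
  tmp <- tempfile(fileext = ".csv")
  write_recording_csv(rec, tmp)
  lines <- readLines(tmp)
  lines[5] <- sub("^([^,]*),[^,]*", "\\1,not_a_number", lines[5])
  writeLines(lines, tmp)
  expect_error(read_raw_csv(tmp), "line 5")
  unlink(tmp)
})

test_that("cohort manifest records the recording metadata", {
  co <- tiny_cohort()
  dir <- tempfile()
  write_cohort(co[1], dir, seed = 42)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 42)
  expect_equal(man$recordings[[1]]$source_id, co[[1]]$source_id)
  expect_equal(man$recordings[[1]]$sampling_rate, co[[1]]$sampling_rate)
  unlink(dir, recursive = TRUE)
})
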