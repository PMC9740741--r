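test_that("filter design has order + 1 taps and rejects bad specs", {
  spec <- fir_highpass_spec(fs = 50, cutoff = 0.5, order = 1000)
  expect_length(spec$b, 1001)
  expect_error(fir_highpass_spec(order = 999), "even")
  expect_error(fir_highpass_spec(fs = 50, cutoff = 30), "fs/2")
})

test_that("frequency response: DC rejected, 5 Hz passed within 1%", {
  spec <- fir_highpass_spec()
  H <- function(f) abs(sum(spec$b * exp(-2i * pi * f / 50 * (0:1000))))
  expect_lt(H(0), 1e-3)
  expect_lt(abs(H(5) - 1), 0.01)
})

test_that("constant input filters to zero and output is trimmed symmetrically", {
  rec <- short_recording()
  n <- length(rec$x)
  rec$x <- rep(1, n)
  spec <- fir_highpass_spec()
  out <- highpass_filter(rec, spec)
  expect_length(out$x, n - 1000)
  expect_length(out$stage, n - 1000)
  expect_lt(max(abs(out$x)), 1e-3)
  expect_equal(out$stage, rec$stage[501:(n - 500)])
})

test_that("5 Hz sinusoid passes the high-pass nearly unchanged and aligned", {
  fs <- 50
  n <- 4000
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 5 * t)
  rec <- structure(list(source_id = "s", test_type = "track",
                        sampling_rate = fs, x = x, y = x, z = x,
                        stage = rep(1L, n), class = rep("Standing", n)),
                   class = "raw_recording")
  out <- highpass_filter(rec, fir_highpass_spec())
  expect_equal(out$x, x[501:(n - 500)], tolerance = 0.01)
})

test_that("filtering is linear and errors on too-short input", {
  spec <- fir_highpass_spec()
  rec <- short_recording()
  rec2 <- rec
  rec2$x <- 3 * rec$x; rec2$y <- 3 * rec$y; rec2$z <- 3 * rec$z
  a <- highpass_filter(rec, spec)
  b <- highpass_filter(rec2, spec)
  expect_equal(b$x, 3 * a$x, tolerance = 1e-9)
  tiny <- rec
  keep <- 1:900
  tiny$x <- tiny$x[keep]; tiny$y <- tiny$y[keep]; tiny$z <- tiny$z[keep]
  tiny$stage <- tiny$stage[keep]; tiny$class <- tiny$class[keep]
  expect_error(highpass_filter(tiny, spec), "shorter")
})

test_that("50 Hz recordings pass through the downsampler unchanged", {
  rec <- short_recording(fs = 50)
  expect_identical(downsample_to_50(rec), rec)
})

test_that("100 Hz recordings are halved and tones survive decimation", {
  fs <- 100
  n <- 2000
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 5 * t)
  rec <- structure(list(source_id = "s", test_type = "track",
                        sampling_rate = fs, x = x, y = x, z = x,
                        stage = rep(1L, n), class = rep("Standing", n)),
                   class = "raw_recording")
  out <- downsample_to_50(rec)
  expect_equal(out$sampling_rate, 50)
  expect_equal(length(out$x), n / 2)
  expect_length(out$stage, n / 2)
  p <- Mod(stats::fft(out$x - mean(out$x)))^2
  k <- which.max(p[2:(length(out$x) / 2)])
  expect_equal(k * 50 / length(out$x), 5, tolerance = 0.1)
  bad <- rec; bad$sampling_rate <- 200
  expect_error(downsample_to_50(bad), "unsupported")
})

test_that("window counts follow floor((L - 100)/50) + 1 per label run", {
  mk <- function(stages) {
    n <- length(stages)
    structure(list(source_id = "m", test_type = "track",
                   sampling_rate = 50, x = stats::rnorm(n),
                   y = stats::rnorm(n), z = stats::rnorm(n),
                   stage = stages,
                   class = ifelse(stages == 1, "Standing", "Walking")),
              class = "raw_recording")
  }
  expect_equal(nrow(segment_windows(mk(rep(1L, 300)))$meta), 5)
  expect_equal(nrow(segment_windows(mk(rep(1L, 100)))$meta), 1)
  expect_equal(nrow(segment_windows(mk(rep(1L, 99)))$meta), 0)
  # two runs: 230 -> 3 windows, 170 -> 2 windows; boundary never crossed
  ws <- segment_windows(mk(c(rep(1L, 230), rep(2L, 170))))
  expect_equal(nrow(ws$meta), 5)
  expect_equal(sum(ws$meta$stage == 1), 3)
  expect_true(all(table(ws$meta$stage, ws$meta$class)[cbind(c("1", "2"),
                c("Standing", "Walking"))] > 0))
  expect_equal(ncol(ws$x), 100)
})

test_that("windows are contiguous slices of the source signal", {
  rec <- short_recording()
  rec$filtered <- TRUE
  ws <- segment_windows(rec)
  # every window row must appear contiguously in the recording
  for (j in sample(nrow(ws$meta), 5)) {
    hit <- FALSE
    target <- ws$x[j, ]
    starts <- which(rec$x == target[1])
    for (s in starts) {
      if (s + 99 <= length(rec$x) &&
          isTRUE(all.equal(rec$x[s:(s + 99)], target))) hit <- TRUE
    }
    expect_true(hit)
  }
  expect_true(all(tapply(ws$meta$class, ws$meta$stage,
                         function(cl) length(unique(cl))) == 1))
})

test_that("50% overlap roughly doubles the window count", {
  rec <- short_recording()
  n50 <- nrow(segment_windows(rec, overlap = 0.5)$meta)
  n0 <- nrow(segment_windows(rec, overlap = 0)$meta)
  expect_gte(n50, 2 * n0 - 3)  # -1 per label run
  expect_error(segment_windows(rec, window_seconds = 1.33), "integer")
  expect_error(segment_windows(rec, overlap = 1), "overlap")
})
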