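test_that("basic statistics match their definitions", {
  s <- basic_stats(c(1, 2, 3, 4))
  expect_equal(s[["mean"]], 2.5)
  expect_equal(s[["median"]], 2.5)
  expect_equal(s[["sd"]], stats::sd(1:4))
  cw <- basic_stats(rep(7, 10))
  expect_equal(cw[["sd"]], 0)
  expect_equal(cw[["p25"]], 7)
  expect_equal(cw[["p75"]], 7)
  # independent order-statistic oracle for the percentiles of 1..100
  x <- sample(100)
  s2 <- basic_stats(x)
  srt <- sort(x)
  oracle <- function(p) {
    h <- p * 99 + 1
    srt[floor(h)] + (h - floor(h)) * (srt[ceiling(h)] - srt[floor(h)])
  }
  expect_equal(s2[["p25"]], oracle(0.25))
  expect_equal(s2[["p75"]], oracle(0.75))
  expect_error(basic_stats(1), "at least 2")
})

test_that("moments are standardized central moments", {
  expect_equal(moments(c(-1, 0, 1))[["skew"]], 0)
  m <- moments(c(0, 0, 0, 1))
  expect_equal(m[["skew"]], 0.09375 / 0.1875^1.5, tolerance = 1e-12)
  expect_equal(m[["skew"]], 1.154701, tolerance = 1e-6)
  expect_true(all(is.na(moments(rep(3, 10)))))
  # kurtosis of a long normal sample is near 3
  set.seed(1)
  expect_equal(moments(stats::rnorm(1e5))[["kurt"]], 3, tolerance = 0.1)
})

test_that("principal frequency finds the dominant tone", {
  t <- (1:100) / 50
  expect_equal(principal_frequency(sin(2 * pi * 5 * t), 50), 5)
  mix <- sin(2 * pi * 3 * t) + 2 * sin(2 * pi * 10 * t)
  expect_equal(principal_frequency(mix, 50), 10)
  expect_equal(principal_frequency(rep(0, 100), 50), 0)
  # white-noise window: agree with an independent periodogram argmax
  set.seed(2)
  x <- stats::rnorm(100)
  p <- Mod(stats::fft(x))^2 / 100
  k <- which.max(p[2:51])
  expect_equal(principal_frequency(x, 50), k * 50 / 100)
})

test_that("spectral energy equals the Parseval identity", {
  expect_equal(spectral_energy(c(1, 0, 0, 0)), 4)
  expect_equal(spectral_energy(rep(0, 100)), 0)
  set.seed(3)
  x <- stats::rnorm(100)
  expect_equal(spectral_energy(x), 100 * sum(x^2), tolerance = 1e-9)
})

test_that("LZ76 scanning parser agrees with known parses", {
  s <- as.integer(strsplit("0001101001000101", "")[[1]])
  expect_equal(accelgait:::.lz76_count(s), 6)
  expect_equal(lz76_oracle(s), 6)
  expect_equal(lz_complexity(rep(1, 100) + 0), 2 * log2(100) / 100)
  # balanced random +-1 windows have near-maximal normalised complexity
  # (bounds frozen from a 500-draw Monte-Carlo with the oracle-validated
  # parser: observed range 1.00-1.33 at n = 100)
  set.seed(4)
  vals <- replicate(30, lz_complexity(sample(rep(c(-1, 1), 50))))
  expect_true(all(vals >= 0.8 & vals <= 1.4))
  # median binarisation collapses two-valued windows whose minority
  # value is the larger one to the all-ones string
  expect_equal(lz_complexity(c(rep(-1, 51), rep(1, 49))),
               2 * log2(100) / 100)
})

test_that("CTM counts first-difference pairs inside the radius", {
  expect_equal(ctm(rep(2, 50)), 1)
  expect_equal(ctm(rep(c(0, 1), 25)), 0)
  # N = 4 gives denominator 2: one of two pairs inside
  expect_equal(ctm(c(0, 0, 0, 1), rho = 0.5), 0.5)
  expect_error(ctm(c(1, 2)), "at least 3")
})

test_that("correlation dimension behaves like a dimension estimate", {
  t <- (1:1000) / 100
  d2 <- correlation_dimension(sin(2 * pi * 5 * t))
  expect_gt(d2, 0.7)
  expect_lt(d2, 1.3)
  expect_true(is.na(correlation_dimension(rep(1, 100))))
  # correlation sums are non-decreasing in r
  set.seed(5)
  cs <- correlation_sums(stats::rnorm(100))
  expect_true(all(diff(cs$C) >= 0))
})

test_that("wavelet energies conserve signal energy and basic cases", {
  expect_equal(unname(dwt_features(rep(0, 100))), rep(0, 6))
  imp <- c(1, rep(0, 99))
  e <- dwt_features(imp)
  expect_equal(sum(e[c("dwt_d1", "dwt_d2", "dwt_d3", "dwt_a3")]), 1,
               tolerance = 1e-12)
  set.seed(6)
  x <- stats::rnorm(100)
  e2 <- dwt_features(x)
  expect_equal(sum(e2[c("dwt_d1", "dwt_d2", "dwt_d3", "dwt_a3")]),
               sum(x^2), tolerance = 1e-9)
})

test_that("batch extraction agrees with the per-window functions", {
  ws <- segment_windows(highpass_filter(short_recording()))
  ft <- extract_features(ws)
  expect_equal(ncol(ft$features), 54)
  expect_equal(colnames(ft$features), feature_columns())
  params <- nonlinear_params()
  for (j in sample(nrow(ft$features), 4)) {
    w <- ws$y[j, ]
    expect_equal(ft$features[[j, "y_mean"]], unname(basic_stats(w)["mean"]))
    expect_equal(ft$features[[j, "y_p75"]], unname(basic_stats(w)["p75"]))
    expect_equal(ft$features[[j, "y_sd"]], unname(basic_stats(w)["sd"]))
    expect_equal(ft$features[[j, "y_skew"]], unname(moments(w)["skew"]))
    expect_equal(ft$features[[j, "y_kurt"]], unname(moments(w)["kurt"]))
    expect_equal(ft$features[[j, "y_pfreq"]], principal_frequency(w, 50))
    expect_equal(ft$features[[j, "y_senergy"]], spectral_energy(w))
    expect_equal(ft$features[[j, "y_lz"]], lz_complexity(w))
    expect_equal(ft$features[[j, "y_ctm"]], ctm(w, 0.1))
    d2 <- correlation_dimension(w, params)
    if (is.na(d2)) expect_true(is.na(ft$features[[j, "y_d2"]]))
    else expect_equal(ft$features[[j, "y_d2"]], d2)
    expect_equal(unname(ft$features[j, grep("^y_dwt",
                                            colnames(ft$features))]),
                 unname(dwt_features(w)))
  }
})

test_that("each axis block only depends on its own axis", {
  ws <- segment_windows(highpass_filter(short_recording()))
  ft <- extract_features(ws)
  swapped <- ws
  swapped$x <- ws$z
  swapped$z <- ws$x
  ft2 <- extract_features(swapped)
  ycols <- grep("^y_", colnames(ft$features))
  expect_equal(ft2$features[, ycols], ft$features[, ycols])
  expect_equal(ft2$features[, grep("^x_", colnames(ft$features))],
               ft$features[, grep("^z_", colnames(ft$features))],
               ignore_attr = TRUE)
})

test_that("features scale as expected under signal scaling", {
  set.seed(7)
  x <- stats::rnorm(100)
  a <- 3.7
  linear <- c("mean", "median", "sd", "p25", "p75")
  b1 <- basic_stats(x)
  b2 <- basic_stats(a * x)
  expect_equal(b2[linear], a * b1[linear], tolerance = 1e-12)
  expect_equal(moments(a * x), moments(x), tolerance = 1e-12)
  expect_equal(lz_complexity(a * x), lz_complexity(x))
  expect_equal(ctm(a * x, rho = a * 0.1), ctm(x, rho = 0.1))
  d2a <- correlation_dimension(x)
  d2b <- correlation_dimension(a * x)
  expect_equal(d2a, d2b, tolerance = 1e-6)
})

test_that("constant windows are flagged invalid but kept in the table", {
  ws <- segment_windows(highpass_filter(short_recording()))
  ws$x[3, ] <- 0  # degenerate axis window
  ft <- extract_features(ws)
  expect_false(ft$meta$valid[3])
  expect_equal(nrow(ft$features), nrow(ws$meta))
  # determinism: identical windows give identical vectors
  ws$x[5, ] <- ws$x[4, ]; ws$y[5, ] <- ws$y[4, ]; ws$z[5, ] <- ws$z[4, ]
  ft2 <- extract_features(ws)
  expect_identical(ft2$features[4, ], ft2$features[5, ])
})

test_that("vertical SD and spectral energy separate Standing from Jogging", {
  ft <- tiny_feature_table()
  cls <- ft$meta$class
  if (all(c("Standing", "Jogging") %in% cls)) {
    for (col in c("y_sd", "y_senergy")) {
      expect_gt(min(ft$features[cls == "Jogging", col]),
                max(ft$features[cls == "Standing", col]))
    }
  }
})
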