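#' Nonlinear feature parameters
#'
#' Tunable parameters of the three nonlinear features. The CTM radius
#' defaults to 0.1 g (chosen to stay informative across both slow and
#' fast stages); the Lempel-Ziv binarisation threshold is the window
#' median; the correlation-dimension estimator uses embedding dimension
#' 5, delay 1 sample, 20 log-spaced radii between the 5th and 95th
#' percentile of pairwise embedded distances, and selects the widest
#' scaling region whose local log-log slopes stay within 0.2 of their
#' mean (at least 5 radii).
#'
#' @param ctm_rho CTM radius (g).
#' @param d2_embedding,d2_delay Embedding dimension and delay (samples).
#' @param d2_n_radii Number of radii in the grid.
#' @param d2_slope_tol Local-slope tolerance defining the scaling region.
#' @param d2_min_points Minimum number of radii in a scaling region.
#' @return List of class `nonlinear_params`.
#' @export
nonlinear_params <- function(ctm_rho = 0.1, d2_embedding = 5, d2_delay = 1,
                             d2_n_radii = 20, d2_slope_tol = 0.2,
                             d2_min_points = 5) {
  stopifnot(ctm_rho > 0, d2_embedding >= 2, d2_delay >= 1)
  structure(as.list(environment()), class = "nonlinear_params")
}

#' Names of the 18 per-axis features
#'
#' In identifier order: mean, median, standard deviation, 25th and 75th
#' percentiles, skewness, kurtosis, principal frequency, spectral
#' energy, Lempel-Ziv complexity, central tendency measure, correlation
#' dimension, then the six wavelet energies (detail level 1,
#' approximation level 1, detail levels 2-3, approximation levels 2-3).
#'
#' @return Character vector of length 18.
#' @export
feature_names <- function() {
  c("mean", "median", "sd", "p25", "p75", "skew", "kurt",
    "pfreq", "senergy", "lz", "ctm", "d2",
    "dwt_d1", "dwt_a1", "dwt_d2", "dwt_d3", "dwt_a2", "dwt_a3")
}

#' Column names of the 54-dimensional feature vector
#'
#' Axis-major concatenation: the 18 features of the x axis, then y,
#' then z (e.g. `x_mean`, ..., `z_dwt_a3`).
#'
#' @return Character vector of length 54.
#' @export
feature_columns <- function() {
  as.vector(t(outer(c("x", "y", "z"), feature_names(), paste, sep = "_")))
}

#' Basic distributional statistics of one window
#'
#' Mean, sample median, standard deviation (n - 1 denominator) and the
#' 25th/75th percentiles by linear interpolation of order statistics
#' (type 7).
#'
#' @param x Numeric window (length >= 2).
#' @return Named numeric vector `mean`, `median`, `sd`, `p25`, `p75`.
#' @export
basic_stats <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  c(mean = mean(x), median = stats::median(x), sd = stats::sd(x),
    p25 = q[1], p75 = q[2])
}

#' Skewness and kurtosis of one window
#'
#' Standardised central moments: skewness m3 / m2^(3/2) and kurtosis
#' m4 / m2^2 (so a normal sample has kurtosis near 3). Undefined for a
#' constant window (returns `NA`, which invalidates the window for
#' feature sets containing the moments).
#'
#' @param x Numeric window.
#' @return Named numeric vector `skew`, `kurt` (NA when sd is zero).
#' @export
moments <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(c(skew = NA_real_, kurt = NA_real_))
  c(skew = mean((x - m)^3) / m2^1.5, kurt = mean((x - m)^4) / m2^2)
}

#' Principal frequency of one window
#'
#' Frequency of the maximum-power FFT bin over (0, fs/2], with power
#' |fft(x)|^2 / n. The DC bin is excluded (the windows are high-pass
#' filtered, so it carries no signal); ties break toward the lower
#' frequency. An all-zero window returns 0.
#'
#' @param x Numeric window (length >= 4).
#' @param fs Sampling frequency in Hz.
#' @return Frequency in Hz.
#' @export
principal_frequency <- function(x, fs) {
  n <- length(x)
  if (n < 4) stop("window too short", call. = FALSE)
  if (all(x == 0)) return(0)
  p <- Mod(stats::fft(x))^2 / n
  k <- seq_len(floor(n / 2))          # bins 1 .. n/2 (DC excluded)
  k[which.max(p[k + 1])] * fs / n
}

#' Spectral energy of one window
#'
#' Sum of squared FFT coefficient magnitudes over all n bins
#' (unnormalised forward transform, so this equals n times the signal
#' energy by Parseval's identity).
#'
#' @param x Numeric window.
#' @return Non-negative energy.
#' @export
spectral_energy <- function(x) sum(Mod(stats::fft(x))^2)

#' Normalised Lempel-Ziv complexity of one window
#'
#' The window is coarse-grained to a binary string (1 where the sample
#' is at or above the window median, 0 below), parsed left to right with
#' the Lempel-Ziv 1976 exhaustive-history algorithm to count the number
#' of distinct production words c(n), and normalised as
#' c(n) * log2(n) / n. The normalised value approaches 1 for long random
#' sequences but carries a sizeable finite-size excess at n = 100, where
#' balanced random strings score roughly 1.0-1.4.
#'
#' @param x Numeric window (length >= 2).
#' @return Normalised complexity.
#' @export
lz_complexity <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  s <- as.integer(x >= stats::median(x))
  .lz76_count(s) * log2(n) / n
}

#' Central tendency measure of one window
#'
#' Fraction of points of the first-difference scatter plot
#' (x(n+1) - x(n), x(n+2) - x(n+1)) falling strictly inside a circle of
#' radius `rho` around the origin; the denominator is N - 2. Near 1 for
#' quiescent signals, near 0 for large successive changes.
#'
#' @param x Numeric window (length >= 3).
#' @param rho Radius (same units as `x`).
#' @return Proportion in \[0, 1\].
#' @export
ctm <- function(x, rho = 0.1) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  d <- diff(x)
  mean(sqrt(d[-1]^2 + d[-(n - 1)]^2) < rho)
}

#' Grassberger-Procaccia correlation dimension of one window
#'
#' Delay-embeds the window, computes correlation sums C(r) over a
#' log-spaced radius grid, and fits the slope of log C(r) against log r
#' over an automatically selected scaling region (see
#' [nonlinear_params()]). Estimation fails (returns `NA`) for
#' degenerate or near-constant windows with no valid scaling region;
#' a failed window is flagged invalid for feature sets that include
#' the correlation dimension.
#'
#' @param x Numeric window.
#' @param params A [nonlinear_params()].
#' @return Estimate, or `NA` on failure.
#' @export
correlation_dimension <- function(x, params = nonlinear_params()) {
  .d2_rows(matrix(x, nrow = 1), params$d2_embedding, params$d2_delay,
           params$d2_n_radii, params$d2_slope_tol, params$d2_min_points)[1]
}

#' Correlation-sum curve of one window
#'
#' Returns the radius grid and correlation sums C(r) used by
#' [correlation_dimension()], for inspection of the scaling region.
#'
#' @inheritParams correlation_dimension
#' @return List with vectors `r` and `C` (empty for degenerate input).
#' @export
correlation_sums <- function(x, params = nonlinear_params()) {
  .d2_curve(as.numeric(x), params$d2_embedding, params$d2_delay,
            params$d2_n_radii)
}

# ---- Daubechies-2 DWT with periodization -----------------------------

# Orthonormal one-level analysis matrices for even length n; odd-length
# inputs are zero-padded to even length by the caller (zero padding adds
# no energy, so coefficient energy exactly equals signal energy).
.db2_level_matrices <- function(n) {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- rev(h) * c(1, -1, 1, -1)
  nh <- n / 2
  A <- matrix(0, nh, n)
  D <- matrix(0, nh, n)
  for (k in seq_len(nh)) {
    cols <- ((2 * (k - 1) + 0:3) %% n) + 1
    A[k, cols] <- A[k, cols] + h
    D[k, cols] <- D[k, cols] + g
  }
  list(A = A, D = D)
}

.dwt_cache <- new.env(parent = emptyenv())
.db2_matrices <- function(n) {
  key <- as.character(n)
  if (is.null(.dwt_cache[[key]]))
    .dwt_cache[[key]] <- .db2_level_matrices(n)
  .dwt_cache[[key]]
}

# One analysis level applied to windows in rows; zero-pads odd lengths.
.dwt_step_rows <- function(w) {
  n <- ncol(w)
  if (n %% 2 == 1) {
    w <- cbind(w, 0)
    n <- n + 1
  }
  mats <- .db2_matrices(n)
  list(a = w %*% t(mats$A), d = w %*% t(mats$D))
}

#' Wavelet energy features of one window
#'
#' Three-level discrete wavelet transform with the Daubechies-2 mother
#' wavelet and periodized (circular) boundary handling; odd-length
#' approximations are zero-padded to even length before the next level
#' so the transform stays exactly energy-preserving. Returns the energy
#' (sum of squared coefficients) of the detail and approximation bands
#' at each level, in identifier order: detail level 1, approximation
#' level 1, detail level 2, detail level 3, approximation level 2,
#' approximation level 3.
#'
#' @param x Numeric window (length >= 8).
#' @return Named numeric vector of 6 energies.
#' @export
dwt_features <- function(x) {
  if (length(x) < 8) stop("window too short for 3 DWT levels", call. = FALSE)
  m <- matrix(x, nrow = 1)
  l1 <- .dwt_step_rows(m)
  l2 <- .dwt_step_rows(l1$a)
  l3 <- .dwt_step_rows(l2$a)
  c(dwt_d1 = sum(l1$d^2), dwt_a1 = sum(l1$a^2),
    dwt_d2 = sum(l2$d^2), dwt_d3 = sum(l3$d^2),
    dwt_a2 = sum(l2$a^2), dwt_a3 = sum(l3$a^2))
}

# ---- batch extraction ------------------------------------------------

# All 18 features for windows stored in the rows of `w` (vectorised
# across windows; agrees with the per-window functions above).
.axis_features <- function(w, fs, params) {
  n <- nrow(w)
  len <- ncol(w)
  out <- matrix(NA_real_, n, 18, dimnames = list(NULL, feature_names()))
  mu <- rowMeans(w)
  cent <- w - mu
  m2 <- rowMeans(cent^2)
  out[, "mean"] <- mu
  q <- .row_quantiles(w, c(0.25, 0.5, 0.75))
  out[, "median"] <- q[, 2]
  out[, "p25"] <- q[, 1]
  out[, "p75"] <- q[, 3]
  out[, "sd"] <- sqrt(rowSums(cent^2) / (len - 1))
  ok <- m2 > 0
  out[ok, "skew"] <- rowMeans(cent[ok, , drop = FALSE]^3) / m2[ok]^1.5
  out[ok, "kurt"] <- rowMeans(cent[ok, , drop = FALSE]^4) / m2[ok]^2
  ft <- stats::mvfft(t(w))                   # len x n, windows in columns
  pw <- Mod(ft)^2
  out[, "senergy"] <- colSums(pw)
  kmax <- floor(len / 2)
  pos <- pw[1 + seq_len(kmax), , drop = FALSE]
  best <- apply(pos, 2, which.max)
  out[, "pfreq"] <- best * fs / len
  out[out[, "senergy"] == 0, "pfreq"] <- 0
  out[, "lz"] <- .lz76_norm_rows(w)
  d1 <- w[, -1, drop = FALSE] - w[, -len, drop = FALSE]
  out[, "ctm"] <- rowMeans(sqrt(d1[, -1, drop = FALSE]^2 +
                                  d1[, -(len - 1), drop = FALSE]^2) <
                             params$ctm_rho)
  out[, "d2"] <- .d2_rows(w, params$d2_embedding, params$d2_delay,
                          params$d2_n_radii, params$d2_slope_tol,
                          params$d2_min_points)
  l1 <- .dwt_step_rows(w)
  l2 <- .dwt_step_rows(l1$a)
  l3 <- .dwt_step_rows(l2$a)
  out[, "dwt_d1"] <- rowSums(l1$d^2)
  out[, "dwt_a1"] <- rowSums(l1$a^2)
  out[, "dwt_d2"] <- rowSums(l2$d^2)
  out[, "dwt_d3"] <- rowSums(l3$d^2)
  out[, "dwt_a2"] <- rowSums(l2$a^2)
  out[, "dwt_a3"] <- rowSums(l3$a^2)
  out
}

#' Extract the 54-dimensional feature matrix from a window set
#'
#' Computes the 18 per-axis features for every window and concatenates
#' them axis-major (all x features, then y, then z). A window is
#' flagged invalid (`valid = FALSE`) when any axis has an undefined
#' moment (constant window) or a failed correlation-dimension estimate;
#' invalid windows are retained in the output and excluded later only
#' by feature sets that use the affected identifiers.
#'
#' @param windows A `window_set` (see [segment_windows()]).
#' @param params A [nonlinear_params()].
#' @param fs Sampling frequency of the windows (Hz).
#' @return A list of class `feature_table`: numeric matrix `features`
#'   (windows x 54), data.frame `meta` (with `valid` flag appended).
#' @export
extract_features <- function(windows, params = nonlinear_params(), fs = 50) {
  fx <- .axis_features(windows$x, fs, params)
  fy <- .axis_features(windows$y, fs, params)
  fz <- .axis_features(windows$z, fs, params)
  feats <- cbind(fx, fy, fz)
  colnames(feats) <- feature_columns()
  frag <- c("skew", "kurt", "d2")
  bad <- rowSums(is.na(feats[, as.vector(outer(c("x_", "y_", "z_"), frag,
                                               paste0)), drop = FALSE])) > 0
  meta <- windows$meta
  meta$valid <- !bad
  structure(list(features = feats, meta = meta), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d windows x %d features, %d valid>\n",
              nrow(x$features), ncol(x$features), sum(x$meta$valid)))
  invisible(x)
}

#' Write a feature table to CSV
#'
#' Columnar layout: `source_id`, `window_index`, `stage`, `class`,
#' `valid`, then the 54 named feature columns.
#'
#' @param ft A `feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(ft, path) {
  utils::write.csv(cbind(ft$meta, as.data.frame(ft$features)), path,
                   row.names = FALSE)
  invisible(path)
}
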