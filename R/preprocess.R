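#' High-pass FIR filter specification
#'
#' Designs the gravity-removal filter: a Hamming-window FIR high-pass
#' with cut-off 0.5 Hz and order 1000 (1001 taps). The order must be
#' even so the group delay (order/2 samples) is an integer and can be
#' compensated exactly.
#'
#' @param fs Sampling frequency in Hz.
#' @param cutoff Cut-off frequency in Hz (must be below `fs/2`).
#' @param order Filter order (even).
#' @return List of class `filter_spec` with the tap vector `b`.
#' @export
fir_highpass_spec <- function(fs = 50, cutoff = 0.5, order = 1000) {
  if (order %% 2 != 0) stop("filter order must be even", call. = FALSE)
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie in (0, fs/2)", call. = FALSE)
  b <- signal::fir1(order, cutoff / (fs / 2), type = "high",
                    window = signal::hamming(order + 1))
  structure(list(fs = fs, cutoff = cutoff, order = order,
                 b = as.numeric(b)),
            class = "filter_spec")
}

# FFT-based FIR filtering with group-delay compensation. Returns the
# time-aligned output for input indices (order/2 + 1) .. (N - order/2):
# one filter length of edge-contaminated samples is trimmed in total,
# half from each end.
.fir_apply_trimmed <- function(x, b, order) {
  y <- signal::fftfilt(b, x)          # causal, length N, delay order/2
  n <- length(x)
  half <- order / 2
  y[(order + 1):n]                    # aligned sample t = y[t + half]
}

#' High-pass filter a recording
#'
#' Applies the FIR high-pass to each axis with group-delay compensation
#' so the output stays time-aligned with the stage/class annotations,
#' then trims one filter length of contaminated samples symmetrically
#' (order/2 from each end), trimming annotations in lockstep. The output
#' is zero-mean to numerical tolerance (gravity and DC removed).
#'
#' @param rec A `raw_recording` (at the spec's sampling rate).
#' @param spec A [fir_highpass_spec()]; defaults to the 0.5 Hz / order
#'   1000 design at the recording's rate.
#' @return A filtered `raw_recording`, shorter by `order` samples.
#' @export
highpass_filter <- function(rec, spec = NULL) {
  if (is.null(spec)) spec <- fir_highpass_spec(fs = rec$sampling_rate)
  if (spec$fs != rec$sampling_rate)
    stop("filter designed for ", spec$fs, " Hz but recording is ",
         rec$sampling_rate, " Hz", call. = FALSE)
  n <- length(rec$x)
  if (n <= spec$order)
    stop("recording shorter than filter order + 1 samples", call. = FALSE)
  half <- spec$order / 2
  keep <- (half + 1):(n - half)
  out <- rec
  out$x <- .fir_apply_trimmed(rec$x, spec$b, spec$order)
  out$y <- .fir_apply_trimmed(rec$y, spec$b, spec$order)
  out$z <- .fir_apply_trimmed(rec$z, spec$b, spec$order)
  out$stage <- rec$stage[keep]
  out$class <- rec$class[keep]
  out$filtered <- TRUE
  out
}

#' Downsample a 100 Hz recording to 50 Hz
#'
#' 100 Hz recordings are low-pass filtered at 0.8 x the target Nyquist
#' (20 Hz) with a Hamming FIR (order 200, delay-compensated) and then
#' decimated by two; stage and class annotations are decimated in
#' lockstep. 50 Hz recordings are returned unchanged.
#'
#' @param rec A `raw_recording` at 50 or 100 Hz.
#' @return A `raw_recording` at 50 Hz.
#' @export
downsample_to_50 <- function(rec) {
  if (rec$sampling_rate == 50) return(rec)
  if (rec$sampling_rate != 100)
    stop("unsupported sampling rate: ", rec$sampling_rate, call. = FALSE)
  order <- 200
  b <- signal::fir1(order, 0.8 * 25 / 50, type = "low",
                    window = signal::hamming(order + 1))
  n <- length(rec$x)
  lp <- function(x) {
    # delay-compensated low-pass; edges padded by reflection to keep length
    xp <- c(rev(x[1:(order / 2)]), x, rev(x[(n - order / 2 + 1):n]))
    y <- signal::fftfilt(as.numeric(b), xp)
    y[(order + 1):(order + n)]
  }
  idx <- seq(1, n, by = 2)
  out <- rec
  out$x <- lp(rec$x)[idx]
  out$y <- lp(rec$y)[idx]
  out$z <- lp(rec$z)[idx]
  out$stage <- rec$stage[idx]
  out$class <- rec$class[idx]
  out$sampling_rate <- 50
  out
}

#' Segment a filtered recording into overlapping labelled windows
#'
#' Splits each axis into fixed-length windows (2 s = 100 samples at
#' 50 Hz) with 50% overlap (hop of 50 samples). Windows are emitted only
#' inside contiguous runs sharing a single stage (and therefore a single
#' class): windows straddling a stage boundary are dropped, so every
#' window has an unambiguous label. A run of length L yields
#' `floor((L - wl)/hop) + 1` windows when `L >= wl`, else none.
#'
#' @param rec A (filtered) `raw_recording`.
#' @param window_seconds Window duration (default 2 s).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @return A list of class `window_set`: matrices `x`, `y`, `z`
#'   (windows in rows) and a data.frame `meta` with `source_id`,
#'   `window_index`, `stage`, `class`.
#' @export
segment_windows <- function(rec, window_seconds = 2, overlap = 0.5) {
  fs <- rec$sampling_rate
  wl <- window_seconds * fs
  if (abs(wl - round(wl)) > 1e-9)
    stop("window_seconds * fs must be an integer number of samples",
         call. = FALSE)
  wl <- as.integer(round(wl))
  if (overlap < 0 || overlap >= 1)
    stop("overlap must lie in [0, 1)", call. = FALSE)
  hop <- wl * (1 - overlap)
  if (abs(hop - round(hop)) > 1e-9)
    stop("window length times (1 - overlap) must be an integer",
         call. = FALSE)
  hop <- as.integer(round(hop))

  runs <- rle(rec$stage)
  ends <- cumsum(runs$lengths)
  starts_run <- ends - runs$lengths + 1
  win_starts <- integer(0)
  for (i in seq_along(runs$lengths)) {
    L <- runs$lengths[i]
    if (L >= wl)
      win_starts <- c(win_starts,
                      seq(starts_run[i], starts_run[i] + L - wl, by = hop))
  }
  nw <- length(win_starts)
  idx <- outer(win_starts, 0:(wl - 1L), `+`)
  take <- function(v) matrix(v[idx], nrow = nw, ncol = wl)
  ws <- list(
    x = take(rec$x), y = take(rec$y), z = take(rec$z),
    meta = data.frame(
      source_id = rep(rec$source_id, nw),
      window_index = seq_len(nw),
      stage = rec$stage[win_starts],
      class = rec$class[win_starts],
      stringsAsFactors = FALSE
    )
  )
  class(ws) <- "window_set"
  ws
}

#' Combine window sets from several recordings
#'
#' @param ... `window_set` objects (or one list of them).
#' @return A single `window_set`.
#' @export
bind_windows <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "window_set"))
    sets <- sets[[1]]
  out <- list(
    x = do.call(rbind, lapply(sets, `[[`, "x")),
    y = do.call(rbind, lapply(sets, `[[`, "y")),
    z = do.call(rbind, lapply(sets, `[[`, "z")),
    meta = do.call(rbind, lapply(sets, `[[`, "meta"))
  )
  rownames(out$meta) <- NULL
  class(out) <- "window_set"
  out
}

#' Preprocess a cohort end to end
#'
#' Downsamples 100 Hz recordings, high-pass filters, segments into
#' overlapping windows, and pools the windows of all recordings.
#'
#' @param cohort List of `raw_recording`s.
#' @param cutoff,order Filter parameters (see [fir_highpass_spec()]).
#' @param window_seconds,overlap Windowing parameters.
#' @return A pooled `window_set`.
#' @export
preprocess_cohort <- function(cohort, cutoff = 0.5, order = 1000,
                              window_seconds = 2, overlap = 0.5) {
  spec <- fir_highpass_spec(fs = 50, cutoff = cutoff, order = order)
  sets <- lapply(cohort, function(r) {
    r <- downsample_to_50(r)
    r <- highpass_filter(r, spec)
    segment_windows(r, window_seconds, overlap)
  })
  bind_windows(sets)
}
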