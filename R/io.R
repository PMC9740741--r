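#' Write one recording to CSV
#'
#' One row per sample with header `timestamp,x,y,z,stage,class`,
#' ISO-8601 timestamps and accelerations in g printed with six decimal
#' places.
#'
#' @param rec A `raw_recording`.
#' @param path Output file path.
#' @param start_time POSIXct start of the recording.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path,
                                start_time = as.POSIXct("2022-01-01 09:00:00",
                                                        tz = "UTC")) {
  n <- length(rec$x)
  secs <- (seq_len(n) - 1) / rec$sampling_rate
  ts <- format(start_time, "%Y-%m-%dT%H:%M:%S")
  frac <- secs - floor(secs)
  ts_full <- paste0(
    format(start_time + floor(secs), "%Y-%m-%dT%H:%M:%S"),
    sprintf(".%03d", round(frac * 1000) %% 1000)
  )
  df <- data.frame(
    timestamp = ts_full,
    x = sprintf("%.6f", rec$x),
    y = sprintf("%.6f", rec$y),
    z = sprintf("%.6f", rec$z),
    stage = rec$stage,
    class = rec$class
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a raw recording from CSV
#'
#' Parses the dialect written by [write_recording_csv()]. The sampling
#' rate is inferred from the median timestamp spacing unless supplied;
#' inconsistent spacing (any delta off by more than 10% of the median)
#' is a format error, and non-numeric acceleration values are parse
#' errors reported with their line number.
#'
#' @param path CSV file path.
#' @param source_id Identifier to attach (defaults to file name).
#' @param test_type,sampling_rate Optional metadata overrides (e.g. from
#'   a cohort manifest).
#' @return A `raw_recording`.
#' @export
read_raw_csv <- function(path, source_id = NULL, test_type = "track",
                         sampling_rate = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("timestamp", "x", "y", "z", "stage", "class")
  if (!all(need %in% names(df)))
    stop("malformed header: expected columns ", paste(need, collapse = ","),
         call. = FALSE)
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("parse error: non-numeric %s at line %d", col,
                   bad[1] + 1L), call. = FALSE)
    df[[col]] <- v
  }
  if (is.null(sampling_rate)) {
    tt <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
    dt <- diff(as.numeric(tt))
    md <- stats::median(dt)
    if (any(abs(dt - md) > 0.1 * md + 1e-6))
      stop("format error: inconsistent timestamp spacing", call. = FALSE)
    sampling_rate <- round(1 / md)
  }
  if (!sampling_rate %in% c(50, 100))
    stop("unsupported sampling rate: ", sampling_rate, call. = FALSE)
  rec <- list(
    source_id = if (is.null(source_id)) sub("\\.csv$", "", basename(path))
                else source_id,
    test_type = test_type,
    sampling_rate = sampling_rate,
    x = df$x, y = df$y, z = df$z,
    stage = as.integer(df$stage),
    class = df$class,
    jog_onset_stage = NA_integer_,
    max_stage = max(as.integer(df$stage))
  )
  class(rec) <- "raw_recording"
  rec
}

#' Write a cohort to disk
#'
#' One CSV per recording plus a JSON manifest recording source id, test
#' type, sampling rate, jog onset, final stage and the master seed.
#'
#' @param cohort List of `raw_recording`s.
#' @param dir Output directory (created if needed).
#' @param seed Master seed to record in the manifest.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(cohort, function(r) {
    list(source_id = r$source_id, test_type = r$test_type,
         sampling_rate = r$sampling_rate,
         jog_onset_stage = r$jog_onset_stage, max_stage = r$max_stage,
         file = paste0(r$source_id, ".csv"))
  })
  for (r in cohort)
    write_recording_csv(r, file.path(dir, paste0(r$source_id, ".csv")))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = seed, recordings = manifest), mpath,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
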