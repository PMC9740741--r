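#' Cohort generation configuration
#'
#' Parameters of the synthetic shuttle-test cohort. Defaults emulate the
#' study conditions the pipeline assumes: 80 track and 30 treadmill
#' recordings (110 sources), 39/110 of recordings sampled at 100 Hz (the
#' rest at 50 Hz), jog onset drawn per subject from stages 7--9, and a
#' max-stage distribution under which only a small minority of subjects
#' complete all 15 stages.
#'
#' Gait signals are a sum of three harmonics of a subject-specific step
#' frequency that rises linearly with belt/track speed (walking roughly
#' 1.6--2.2 Hz, jogging roughly 2.4--3.0 Hz), with axis-specific amplitude
#' ratios, a +1 g gravity offset on the vertical axis, Gaussian sensor
#' noise, low-frequency postural sway while standing, and medial/lateral
#' turning bursts every 20 m of simulated distance on the track.
#'
#' All distribution parameters are explicit so that any of them can be
#' overridden; units are g, Hz, and km/h throughout.
#'
#' @param n_track,n_treadmill Number of track / treadmill recordings.
#' @param fraction_100hz Fraction of recordings sampled at 100 Hz (the
#'   rest at 50 Hz); `round(fraction_100hz * n)` recordings are chosen.
#' @param walk_freq_intercept_mean,walk_freq_intercept_sd Per-subject
#'   walking step-frequency intercept (Hz at 0 km/h).
#' @param walk_freq_slope_mean,walk_freq_slope_sd Walking step-frequency
#'   slope (Hz per km/h).
#' @param jog_freq_intercept_mean,jog_freq_intercept_sd,jog_freq_slope_mean,jog_freq_slope_sd
#'   Same for jogging.
#' @param amp_scale_mean,amp_scale_sd Vertical gait amplitude per unit
#'   speed (g per km/h), truncated below at `amp_scale_min`.
#' @param amp_scale_min Lower truncation for the amplitude scale.
#' @param jog_amp_meanlog,jog_amp_sdlog Log-normal parameters of the
#'   discontinuous jogging amplitude factor, truncated below at
#'   `jog_amp_min`.
#' @param jog_amp_min Lower truncation for the jog amplitude factor.
#' @param sway_amp_mean,sway_amp_sd Standing sway amplitude (g).
#' @param noise_sd_mean,noise_sd_sd Sensor white-noise SD (g).
#' @param jog_onset_stages Stages a subject may first jog at (>= 7).
#' @param max_stage_probs Probabilities of a subject's final stage being
#'   8, 9, ..., 15.
#' @param harmonic_weights Relative amplitudes of the step-frequency
#'   harmonics (fundamental first).
#' @param axis_amp_ratio Amplitude of the anterior/posterior (x) and
#'   medial/lateral (z) gait component relative to vertical (y).
#' @param turn_interval_m Track turn spacing in metres (cone-to-cone).
#' @param turn_amp Amplitude (g) of the medial/lateral turning burst.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_track = 80,
                          n_treadmill = 30,
                          fraction_100hz = 39 / 110,
                          walk_freq_intercept_mean = 1.35,
                          walk_freq_intercept_sd = 0.08,
                          walk_freq_slope_mean = 0.107,
                          walk_freq_slope_sd = 0.012,
                          jog_freq_intercept_mean = 1.55,
                          jog_freq_intercept_sd = 0.10,
                          jog_freq_slope_mean = 0.14,
                          jog_freq_slope_sd = 0.015,
                          amp_scale_mean = 0.075,
                          amp_scale_sd = 0.012,
                          amp_scale_min = 0.04,
                          jog_amp_meanlog = log(1.6),
                          jog_amp_sdlog = 0.09,
                          jog_amp_min = 1.2,
                          sway_amp_mean = 0.02,
                          sway_amp_sd = 0.005,
                          noise_sd_mean = 0.03,
                          noise_sd_sd = 0.005,
                          jog_onset_stages = 7:9,
                          max_stage_probs = c(0.10, 0.15, 0.20, 0.20,
                                              0.15, 0.10, 0.06, 0.04),
                          harmonic_weights = c(1, 0.4, 0.2),
                          axis_amp_ratio = c(x = 0.45, z = 0.25),
                          turn_interval_m = 20,
                          turn_amp = 0.15) {
  if (n_track < 0 || n_treadmill < 0)
    stop("recording counts must be non-negative", call. = FALSE)
  if (fraction_100hz < 0 || fraction_100hz > 1)
    stop("fraction_100hz must lie in [0, 1]", call. = FALSE)
  if (any(jog_onset_stages < 7))
    stop("jog onset stages must be >= 7", call. = FALSE)
  if (length(max_stage_probs) != 8 || any(max_stage_probs < 0))
    stop("max_stage_probs must be 8 non-negative probabilities (stages 8-15)",
         call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

# Stable 31-bit string hash (polynomial rolling hash) used to derive
# independent per-recording RNG substreams from the master seed.
.string_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

#' Draw per-subject gait parameters
#'
#' Samples one subject's gait model parameters from the cohort
#' configuration using the current RNG state.
#'
#' @param config A [cohort_config()].
#' @param subject_id Identifier string.
#' @param sampling_rate 50 or 100 (Hz).
#' @return List of class `subject_params`.
#' @export
draw_subject_params <- function(config, subject_id, sampling_rate = 50) {
  stopifnot(sampling_rate %in% c(50, 100))
  p <- list(
    subject_id = subject_id,
    walk_freq_intercept = stats::rnorm(1, config$walk_freq_intercept_mean,
                                       config$walk_freq_intercept_sd),
    walk_freq_slope = stats::rnorm(1, config$walk_freq_slope_mean,
                                   config$walk_freq_slope_sd),
    jog_freq_intercept = stats::rnorm(1, config$jog_freq_intercept_mean,
                                      config$jog_freq_intercept_sd),
    jog_freq_slope = stats::rnorm(1, config$jog_freq_slope_mean,
                                  config$jog_freq_slope_sd),
    amp_scale = max(config$amp_scale_min,
                    stats::rnorm(1, config$amp_scale_mean,
                                 config$amp_scale_sd)),
    jog_amp_factor = max(config$jog_amp_min,
                         stats::rlnorm(1, config$jog_amp_meanlog,
                                       config$jog_amp_sdlog)),
    sway_amplitude = max(0.005, stats::rnorm(1, config$sway_amp_mean,
                                             config$sway_amp_sd)),
    noise_sd = max(0.01, stats::rnorm(1, config$noise_sd_mean,
                                      config$noise_sd_sd)),
    jog_onset_stage = sample(config$jog_onset_stages, 1),
    max_stage = sample(8:15, 1, prob = config$max_stage_probs),
    sampling_rate = sampling_rate,
    harmonic_weights = config$harmonic_weights,
    axis_amp_ratio = config$axis_amp_ratio,
    turn_interval_m = config$turn_interval_m,
    turn_amp = config$turn_amp
  )
  class(p) <- "subject_params"
  p
}

#' Synthesize one protocol stage of triaxial acceleration
#'
#' Generates `duration` seconds of triaxial signal for a single stage.
#' Standing stages are a +1 g vertical gravity offset plus low-frequency
#' (< 0.8 Hz) postural sway and white noise. Walking and jogging stages
#' add a periodic gait waveform: three harmonics of the subject's
#' speed-dependent step frequency, with jogging carrying a higher
#' fundamental and a discontinuously larger vertical amplitude than
#' walking at the same speed. Track recordings receive an extra
#' medial/lateral burst at every simulated 20 m turn.
#'
#' Axis convention: x anterior/posterior, y vertical (carries gravity),
#' z medial/lateral; all units g.
#'
#' @param speed Stage speed in km/h (>= 0).
#' @param activity `"Standing"`, `"Walking"` or `"Jogging"`.
#' @param duration Stage duration in seconds.
#' @param fs Sampling frequency, 50 or 100 Hz.
#' @param params A `subject_params` list.
#' @param test_type `"track"` or `"treadmill"`.
#' @return List with numeric vectors `x`, `y`, `z` of length
#'   `duration * fs`.
#' @export
synth_stage_signal <- function(speed, activity, duration, fs, params,
                               test_type = c("track", "treadmill")) {
  test_type <- match.arg(test_type)
  if (speed < 0) stop("speed must be non-negative", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  stopifnot(fs %in% c(50, 100))
  n <- round(duration * fs)
  t <- seq_len(n) / fs
  noise <- function() stats::rnorm(n, 0, params$noise_sd)

  if (activity == "Standing") {
    sway <- function(scale) {
      a <- params$sway_amplitude * scale
      a * sin(2 * pi * 0.25 * t + stats::runif(1, 0, 2 * pi)) +
        0.6 * a * sin(2 * pi * 0.45 * t + stats::runif(1, 0, 2 * pi))
    }
    return(list(x = sway(0.8) + noise(),
                y = 1 + sway(1) + noise(),
                z = sway(0.8) + noise()))
  }

  jogging <- activity == "Jogging"
  f0 <- if (jogging) {
    params$jog_freq_intercept + params$jog_freq_slope * speed
  } else {
    params$walk_freq_intercept + params$walk_freq_slope * speed
  }
  amp_y <- params$amp_scale * speed * if (jogging) params$jog_amp_factor else 1
  gait <- function(amp) {
    w <- params$harmonic_weights
    out <- numeric(n)
    for (h in seq_along(w)) {
      out <- out + amp * w[h] * sin(2 * pi * h * f0 * t +
                                      stats::runif(1, 0, 2 * pi))
    }
    out
  }
  x <- gait(amp_y * params$axis_amp_ratio[["x"]]) + noise()
  y <- 1 + gait(amp_y) + noise()
  z <- gait(amp_y * params$axis_amp_ratio[["z"]]) + noise()

  if (test_type == "track" && speed > 0) {
    # one medial/lateral burst per 20 m shuttle turn, alternating direction
    turn_period <- params$turn_interval_m / (speed / 3.6)
    turn_times <- seq(turn_period / 2, duration, by = turn_period)
    sgn <- 1
    for (tc in turn_times) {
      z <- z + sgn * params$turn_amp *
        exp(-(t - tc)^2 / (2 * 0.2^2)) * sin(2 * pi * 1.2 * (t - tc))
      sgn <- -sgn
    }
  }
  list(x = x, y = y, z = z)
}

#' Assign activity class labels from stage annotations
#'
#' Two labelling schemes are used. The binary scheme is protocol-wide:
#' stage 1 is Standing and stages 2--8 are Walking; samples beyond stage 8
#' get `NA` (they are outside the binary task). The tertiary scheme is
#' per-recording: stage 1 Standing, stages 2 to `jog_onset_stage - 1`
#' Walking, and every stage from `jog_onset_stage` onwards Jogging.
#'
#' @param stage Integer vector of per-sample stage indices.
#' @param task `"tertiary"` or `"binary"`.
#' @param jog_onset_stage First jogging stage (>= 7); required for the
#'   tertiary task. A value above the recorded stages means the subject
#'   never jogged.
#' @return Character vector of class labels (with `NA` outside the task).
#' @export
assign_labels <- function(stage, task = c("tertiary", "binary"),
                          jog_onset_stage = NULL) {
  task <- match.arg(task)
  if (task == "binary") {
    lab <- rep(NA_character_, length(stage))
    lab[stage == 1] <- "Standing"
    lab[stage >= 2 & stage <= 8] <- "Walking"
    return(lab)
  }
  if (is.null(jog_onset_stage))
    stop("tertiary labelling needs jog_onset_stage", call. = FALSE)
  if (jog_onset_stage < 7)
    stop("jog_onset_stage must be >= 7", call. = FALSE)
  lab <- rep("Walking", length(stage))
  lab[stage == 1] <- "Standing"
  lab[stage >= jog_onset_stage] <- "Jogging"
  lab
}

#' Generate one synthetic shuttle-test recording
#'
#' Runs the protocol from stage 1 to the subject's final stage, labelling
#' samples with the tertiary scheme (the binary labels are derivable from
#' the stage annotation at any time via [assign_labels()]).
#'
#' @param config A [cohort_config()].
#' @param source_id Recording identifier.
#' @param test_type `"track"` or `"treadmill"`.
#' @param sampling_rate 50 or 100 Hz.
#' @param seed Integer seed for this recording's RNG substream.
#' @return List of class `raw_recording` with fields `source_id`,
#'   `test_type`, `sampling_rate`, `x`, `y`, `z`, `stage`, `class`,
#'   `jog_onset_stage`, `max_stage`.
#' @export
generate_recording <- function(config, source_id, test_type,
                               sampling_rate = 50, seed = 1L) {
  set.seed(seed)
  params <- draw_subject_params(config, source_id, sampling_rate)
  proto <- shuttle_protocol()
  stages <- proto[proto$stage <= params$max_stage, ]
  xs <- ys <- zs <- vector("list", nrow(stages))
  stage_ann <- vector("list", nrow(stages))
  for (i in seq_len(nrow(stages))) {
    st <- stages$stage[i]
    cls <- assign_labels(st, "tertiary",
                         jog_onset_stage = params$jog_onset_stage)
    sig <- synth_stage_signal(stages$speed_kmh[i], cls,
                              stages$duration_s[i], sampling_rate,
                              params, test_type)
    xs[[i]] <- sig$x; ys[[i]] <- sig$y; zs[[i]] <- sig$z
    stage_ann[[i]] <- rep(st, length(sig$x))
  }
  stage_vec <- unlist(stage_ann)
  rec <- list(
    source_id = source_id,
    test_type = test_type,
    sampling_rate = sampling_rate,
    x = unlist(xs), y = unlist(ys), z = unlist(zs),
    stage = stage_vec,
    class = assign_labels(stage_vec, "tertiary",
                          jog_onset_stage = params$jog_onset_stage),
    jog_onset_stage = params$jog_onset_stage,
    max_stage = params$max_stage
  )
  class(rec) <- "raw_recording"
  rec
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording %s: %s, %d Hz, %d samples, stages 1-%d, jog onset %d>\n",
              x$source_id, x$test_type, x$sampling_rate, length(x$x),
              x$max_stage, x$jog_onset_stage))
  invisible(x)
}

#' Generate a synthetic shuttle-test cohort
#'
#' Deterministically generates `n_track + n_treadmill` labelled
#' recordings. Each recording has its own RNG substream derived from the
#' master seed and a stable hash of its source id, so identical seeds
#' give bit-identical cohorts and individual recordings can be
#' regenerated in isolation.
#'
#' @param config A [cohort_config()].
#' @param seed Master integer seed.
#' @return List of `raw_recording` objects of length
#'   `n_track + n_treadmill`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_track = 2, n_treadmill = 1), seed = 1)
#' length(cohort)
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_track + config$n_treadmill
  ids <- c(sprintf("track_%02d", seq_len(config$n_track)),
           sprintf("treadmill_%02d", seq_len(config$n_treadmill)))
  types <- c(rep("track", config$n_track),
             rep("treadmill", config$n_treadmill))
  set.seed(seed)
  n100 <- round(config$fraction_100hz * n)
  idx100 <- if (n100 > 0) sample(n, n100) else integer(0)
  rates <- rep(50, n)
  rates[idx100] <- 100
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    sub_seed <- (as.numeric(seed) + .string_hash(ids[i])) %% 2147483647
    cohort[[i]] <- generate_recording(config, ids[i], types[i], rates[i],
                                      seed = as.integer(sub_seed))
  }
  cohort
}
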