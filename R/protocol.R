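#' Incremental shuttle-test stage protocol
#'
#' Fifteen-stage incremental protocol used for both the track and the
#' treadmill tests: three minutes of quiet standing at stage 1 (0 km/h),
#' then 1.5 minutes per stage at strictly increasing speeds from
#' 2.4 km/h up to 10.4 km/h.
#'
#' @return A data.frame with columns `stage` (1--15), `speed_kmh` and
#'   `duration_s` (180 s for stage 1, 90 s otherwise).
#' @export
#' @examples
#' shuttle_protocol()
shuttle_protocol <- function() {
  data.frame(
    stage = 1:15,
    speed_kmh = c(0, 2.4, 3.0, 3.6, 4.3, 4.9, 5.5, 6.1,
                  6.7, 7.3, 7.9, 8.5, 9.1, 9.8, 10.4),
    duration_s = c(180, rep(90, 14))
  )
}

#' Activity class labels
#'
#' Canonical class order used throughout: Standing, Walking, Jogging.
#' @return Character vector of the three class names.
#' @export
activity_classes <- function() c("Standing", "Walking", "Jogging")
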