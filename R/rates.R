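#' Discharge rates and irritative zone
#'
#' Computes, per unit (channel or region), the detector event rate inside
#' the analysis windows around the selected markers, the rate normalized by
#' the patient's maximum, and the irritative-zone flag: a unit belongs to
#' the irritative zone when its rate exceeds 1/10 of the maximum rate
#' across units.
#'
#' @param detected_events data.frame of detector-style events (`time_s`,
#'   `label`).
#' @param marker_times Times (s) of the selected discharge markers.
#' @param window_s Two-element window around each marker (default the
#'   time-frequency epoch, `c(-2, 3)`).
#' @param units Optional unit labels to report (defaults to the labels seen
#'   in the events).
#' @return data.frame with `unit`, `rate_per_min`, `normalized_rate` and
#'   `iz` flag; the maximum normalized rate is 1.
#' @export
rates_and_iz <- function(detected_events, marker_times, window_s = c(-2, 3),
                         units = NULL) {
  if (nrow(detected_events) == 0L) stop("no detected events")
  if (length(marker_times) == 0L) stop("zero total analysis time")
  if (is.null(units)) units <- unique(detected_events$label)
  total_min <- length(marker_times) * diff(window_s) / 60
  in_window <- vapply(detected_events$time_s, function(t) {
    any(t >= marker_times + window_s[1] & t <= marker_times + window_s[2])
  }, logical(1))
  ev <- detected_events[in_window, , drop = FALSE]
  counts <- vapply(units, function(u) sum(ev$label == u), numeric(1))
  rate <- counts / total_min
  mx <- max(rate)
  norm <- if (mx > 0) rate / mx else rate
  data.frame(unit = units, rate_per_min = rate, normalized_rate = norm,
             iz = rate > mx / 10, stringsAsFactors = FALSE,
             row.names = NULL)
}
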