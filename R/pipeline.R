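# End-to-end per-trial analysis: track conditioning, event detection,
# bout classification, EMG bursts, coupling.

#' Analyze one trial end to end
#'
#' Runs the full chain on a pose track and EMG recording:
#' likelihood-gated interpolation; moving-average smoothing; fin-extension
#' metric and 0.05 L event detection per side; left-right synchronicity;
#' body-wave metrics (on the unsmoothed track) and bout classification;
#' COM velocity from the smoothed track; EMG filtering, spike and burst
#' detection; event-burst-velocity coupling records and event positions.
#'
#' @param pose A `pose_track`.
#' @param emg An `emg_recording`, or NULL to skip all EMG steps.
#' @param meta A `trial_meta`.
#' @param threshold Event threshold in L units, default 0.05.
#' @param window Velocity/association window in s, default 0.2.
#' @param window_fraction Smoothing window as fraction of frame rate.
#' @param likelihood_floor,max_gap Passed to [interpolate_untracked()].
#' @param ... Passed to [detect_bursts()].
#' @return List with `events` (both sides, with synchronicity, positions and
#'   zones), `bout` (`behavior_bout`), `metrics` (`body_wave_metrics`),
#'   `velocity`, `bursts`, `coupling`.
#' @export
analyze_trial <- function(pose, emg, meta, threshold = 0.05, window = 0.2,
                          window_fraction = 0.2, likelihood_floor = 0.9,
                          max_gap = 5, ...) {
  L <- meta$body_length_L
  pose <- interpolate_untracked(pose, floor = likelihood_floor,
                                max_gap = max_gap)
  sm <- smooth_track(pose, window_fraction)
  per_side <- lapply(c("left", "right"), function(s) {
    ext <- fin_extension_distance(sm, s, L)
    detect_extension_events(ext, sm$times, threshold = threshold, side = s)
  })
  sync <- label_synchronicity(per_side[[1]], per_side[[2]])
  events <- rbind(sync$left, sync$right)
  events <- events[base::order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  vel <- com_velocity(sm)
  metrics <- body_wave_metrics(pose, L)
  bout <- classify_bout(metrics, vel$forward, vel$times, L)
  if (nrow(events) > 0) {
    pos <- lapply(seq_len(nrow(events)), function(i)
      event_position(events[i, ], pose))
    events$x <- vapply(pos, `[[`, numeric(1), "x")
    events$y <- vapply(pos, `[[`, numeric(1), "y")
    events$zone <- vapply(pos, `[[`, character(1), "zone")
  }
  bursts <- if (!is.null(emg)) detect_bursts(emg, ...)
            else data.frame(channel = character(), onset = numeric(),
                            offset = numeric(), n_spikes = integer(),
                            mean_spike_amplitude = numeric())
  coupling <- couple_events(events, vel$forward, vel$lateral, vel$times,
                            bursts, behavior = bout$label, window = window)
  list(events = events, bout = bout, metrics = metrics, velocity = vel,
       bursts = bursts, coupling = coupling)
}
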