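# Fin-extension event detection, synchronicity, bout classification,
# event position relative to the cylinder.

#' Detect fin-extension events by the 0.05 L threshold rule
#'
#' An extension event is a maximal run of frames whose (smoothed) extension is
#' at or above `threshold` body lengths. Runs separated by gaps shorter than
#' `merge_gap` frames are merged, then runs shorter than `min_duration` frames
#' are discarded. Intervals are half-open: onset is the time of the first
#' above-threshold frame, offset the time of the first frame after the run.
#' `t_max` is the earliest argmax within the run.
#'
#' Frames with NA extension (untracked or degenerate base) never join a run.
#'
#' @param extension Numeric vector, extension in L units (smoothed).
#' @param times Time vector, uniformly sampled.
#' @param threshold Event threshold in L units, default 0.05.
#' @param min_duration Minimum run length in frames, default 3.
#' @param merge_gap Runs separated by fewer than this many below-threshold
#'   frames are merged, default 2.
#' @param side Label stored with each event.
#' @return Data frame with columns side, onset, offset, t_max,
#'   peak_extension, onset_idx, offset_idx (1-based frame indices; offset_idx
#'   is one past the last event frame).
#' @export
detect_extension_events <- function(extension, times, threshold = 0.05,
                                    min_duration = 3, merge_gap = 2,
                                    side = "left") {
  if (length(extension) != length(times)) stopf("extension/times mismatch")
  check_uniform_times(times, tol = 1e-6, what = "extension times")
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  above <- !is.na(extension) & extension >= threshold
  n <- length(above)
  empty <- data.frame(side = character(), onset = numeric(),
                      offset = numeric(), t_max = numeric(),
                      peak_extension = numeric(), onset_idx = integer(),
                      offset_idx = integer(), stringsAsFactors = FALSE)
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by short gaps
  if (nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap < merge_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  runs <- runs[runs$end - runs$start + 1L >= min_duration, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)
  out <- lapply(seq_len(nrow(runs)), function(i) {
    i0 <- runs$start[i]; i1 <- runs$end[i]
    seg <- extension[i0:i1]
    imax <- i0 + which.max(seg) - 1L   # earliest argmax on ties
    data.frame(side = side, onset = times[i0],
               offset = if (i1 < n) times[i1 + 1L] else times[n] + dt,
               t_max = times[imax], peak_extension = extension[imax],
               onset_idx = i0, offset_idx = i1 + 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Label left-right synchronicity of fin-extension events
#'
#' Two events (one per side) are simultaneous when their overlap is at least
#' `overlap_fraction` of the shorter event's duration. Pairing is greedy by
#' largest overlap, each event used at most once; unpaired events are
#' asynchronous.
#'
#' @param left_events,right_events Event data frames from
#'   [detect_extension_events()], sorted by onset, non-overlapping within a
#'   side.
#' @param overlap_fraction Required overlap as a fraction of the shorter
#'   event, default 0.5.
#' @return A list with `left`, `right` (the inputs plus `synchronicity` and
#'   `pair_id` columns) and `pairs` (data frame of paired indices with their
#'   overlap in seconds).
#' @export
label_synchronicity <- function(left_events, right_events,
                                overlap_fraction = 0.5) {
  for (ev in list(left_events, right_events)) {
    if (nrow(ev) > 1) {
      if (is.unsorted(ev$onset)) stopf("events must be sorted by onset")
      if (any(ev$onset[-1] < ev$offset[-nrow(ev)]))
        stopf("overlapping events within one side")
    }
  }
  nl <- nrow(left_events); nr <- nrow(right_events)
  cand <- expand.grid(li = seq_len(nl), ri = seq_len(nr))
  if (nrow(cand) > 0) {
    cand$overlap <- interval_overlap(
      left_events$onset[cand$li], left_events$offset[cand$li],
      right_events$onset[cand$ri], right_events$offset[cand$ri])
    shorter <- pmin(left_events$offset[cand$li] - left_events$onset[cand$li],
                    right_events$offset[cand$ri] - right_events$onset[cand$ri])
    cand <- cand[cand$overlap >= overlap_fraction * shorter &
                   cand$overlap > 0, , drop = FALSE]
    cand <- cand[order(-cand$overlap, cand$li, cand$ri), , drop = FALSE]
  }
  used_l <- logical(nl); used_r <- logical(nr)
  pairs <- data.frame(li = integer(), ri = integer(), overlap = numeric())
  for (k in seq_len(nrow(cand))) {
    li <- cand$li[k]; ri <- cand$ri[k]
    if (!used_l[li] && !used_r[ri]) {
      used_l[li] <- TRUE; used_r[ri] <- TRUE
      pairs <- rbind(pairs, cand[k, ])
    }
  }
  add_labels <- function(ev, used, which_col) {
    if (nrow(ev) == 0) {
      ev$synchronicity <- character(0); ev$pair_id <- integer(0)
      return(ev)
    }
    ev$synchronicity <- ifelse(used, "synchronous", "asynchronous")
    ev$pair_id <- NA_integer_
    if (nrow(pairs) > 0)
      ev$pair_id[pairs[[which_col]]] <- seq_len(nrow(pairs))
    ev
  }
  list(left = add_labels(left_events, used_l, "li"),
       right = add_labels(right_events, used_r, "ri"),
       pairs = pairs)
}

#' Classify a swimming bout as Karman gaiting, braking, or other
#'
#' Karman-gait criteria (all five must hold):
#' \enumerate{
#'   \item station holding: |net x drift| <= `drift_tol` (in L) over the bout;
#'   \item a traveling wave along the body (nonzero phase slope, not
#'     rigid-body sway);
#'   \item large lateral displacement: tail peak-to-peak > 0.5 L;
#'   \item long body wavelength: > 1 L;
#'   \item no transient small-amplitude high-frequency tail beats.
#' }
#' Braking criteria (all four must hold):
#' \enumerate{
#'   \item net upstream drift (net x drift < -`drift_tol` L);
#'   \item a forward (upstream, negative) velocity excursion below `-v_tol`
#'     followed within 0.5 s by a rise above `+v_tol`;
#'   \item no sustained tail oscillation at a dominant frequency for more
#'     than half the bout;
#'   \item no whole-body undulation (lateral displacement <= 0.5 L).
#' }
#'
#' @param metrics A `body_wave_metrics` for the bout.
#' @param forward Forward (x) COM velocity, cm s^-1.
#' @param times Time vector matching `forward`.
#' @param L Body length in cm.
#' @param drift_tol Station-holding tolerance in L units, default 0.1.
#' @param v_tol Velocity excursion threshold in cm s^-1, default 1.
#' @return A list of class `behavior_bout`: `label`, `start`, `end`,
#'   `criteria_flags` (named logicals `kg1`..`kg5`, `br1`..`br4`).
#' @export
classify_bout <- function(metrics, forward, times, L,
                          drift_tol = 0.1, v_tol = 1) {
  if (length(times) < 2 || (max(times) - min(times)) < 1)
    stopf("bout must cover at least 1 s")
  kg <- c(
    kg1 = abs(metrics$net_drift) <= drift_tol * L,
    kg2 = isTRUE(metrics$oscillation) && !isTRUE(metrics$rigid_body),
    kg3 = isTRUE(metrics$lateral_displacement > 0.5),
    kg4 = isTRUE(metrics$wavelength > 1),
    kg5 = !isTRUE(metrics$has_transient_highfreq_tailbeats))
  br <- c(
    br1 = metrics$net_drift < -drift_tol * L,
    br2 = has_brake_excursion(forward, times, v_tol),
    br3 = !sustained_oscillation(metrics),
    br4 = isTRUE(metrics$lateral_displacement <= 0.5))
  label <- if (all(kg)) "karman_gait" else if (all(br)) "braking" else "other"
  structure(list(label = label, start = min(times), end = max(times),
                 criteria_flags = c(kg, br)),
            class = "behavior_bout")
}

# a local minimum below -v_tol followed within 0.5 s by a rise above +v_tol
has_brake_excursion <- function(forward, times, v_tol) {
  low <- which(forward < -v_tol)
  if (length(low) == 0) return(FALSE)
  for (i in low) {
    after <- which(times > times[i] & times <= times[i] + 0.5)
    if (any(forward[after] > v_tol)) return(TRUE)
  }
  FALSE
}

# sustained periodic tail oscillation: a declared spectral oscillation that
# is not rigid-body sway and has meaningful amplitude
sustained_oscillation <- function(metrics) {
  isTRUE(metrics$oscillation) && isTRUE(metrics$lateral_displacement > 0.1)
}

#' Position of an event relative to the cylinder, with zone label
#'
#' Reports the landmark position (snout, midline point 1, by default) at the
#' time of maximal fin extension and assigns a zone: `suction_zone` when
#' x is in (0, `suction_x`] cm and |y| <= `suction_y` cm, `wake` when x is in
#' (`suction_x`, `wake_x`] cm, else `outside`.
#'
#' @param event One-row event data frame (needs `t_max`).
#' @param track A `pose_track` covering `t_max`.
#' @param landmark Bodypart used for position, default `"midline_1"`.
#' @param suction_x,suction_y,wake_x Zone bounds in cm.
#' @return List with `x`, `y` (cm) and `zone`.
#' @export
event_position <- function(event, track, landmark = "midline_1",
                           suction_x = 15, suction_y = 3, wake_x = 30) {
  t <- event$t_max
  if (t < min(track$times) - 1e-9 || t > max(track$times) + 1e-9)
    stopf("event t_max outside the track")
  i <- which.min(abs(track$times - t))
  x <- track$x[i, landmark]; y <- track$y[i, landmark]
  zone <- if (x > 0 && x <= suction_x && abs(y) <= suction_y) "suction_zone"
          else if (x > suction_x && x <= wake_x) "wake"
          else "outside"
  list(x = unname(x), y = unname(y), zone = zone)
}
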