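# Shared fixtures and independent oracles used across test files.

test_meta <- function(...) {
  trial_meta(body_length_L = 21.7, flow_speed_U = 65, ...)
}

# Build a pose_track where every bodypart sits at a fixed point, optionally
# overriding individual bodypart coordinate columns.
flat_track <- function(n = 60, frame_rate = 150, x0 = 10, y0 = 0,
                       override_x = list(), override_y = list(),
                       likelihood = NULL) {
  bp <- pose_bodyparts()
  x <- matrix(x0, n, 17, dimnames = list(NULL, bp))
  y <- matrix(y0, n, 17, dimnames = list(NULL, bp))
  for (nm in names(override_x)) x[, nm] <- override_x[[nm]]
  for (nm in names(override_y)) y[, nm] <- override_y[[nm]]
  pose_track(x, y, likelihood, frame_rate = frame_rate)
}

# Brute-force shrinking-window moving average (independent of smooth_series).
oracle_moving_average <- function(v, w) {
  n <- length(v)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w %/% 2L
  sapply(seq_len(n), function(i) {
    lo <- max(1L, i - half_lo); hi <- min(n, i + half_hi)
    mean(v[lo:hi])
  })
}

# Exhaustive-scan event detector: independent re-derivation of the
# threshold/merge/min-duration rules, sample by sample.
oracle_detect_events <- function(extension, times, threshold = 0.05,
                                 min_duration = 3, merge_gap = 2) {
  above <- !is.na(extension) & extension >= threshold
  n <- length(above)
  dt <- times[2] - times[1]
  # collect maximal runs by linear scan
  runs <- list()
  i <- 1
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  # merge across short gaps
  merged <- list()
  for (r in runs) {
    m <- length(merged)
    if (m > 0 && r[1] - merged[[m]][2] - 1 < merge_gap) {
      merged[[m]][2] <- r[2]
    } else merged[[length(merged) + 1]] <- r
  }
  merged <- Filter(function(r) r[2] - r[1] + 1 >= min_duration, merged)
  if (length(merged) == 0)
    return(data.frame(onset = numeric(), offset = numeric(),
                      t_max = numeric()))
  do.call(rbind, lapply(merged, function(r) {
    seg <- extension[r[1]:r[2]]
    data.frame(onset = times[r[1]],
               offset = if (r[2] < n) times[r[2] + 1] else times[n] + dt,
               t_max = times[r[1] + which.max(seg) - 1])
  }))
}

# Interval-intersection synchrony oracle for a single left/right pair.
oracle_pair_synchronous <- function(l_on, l_off, r_on, r_off, frac = 0.5) {
  ov <- max(0, min(l_off, r_off) - max(l_on, r_on))
  shorter <- min(l_off - l_on, r_off - r_on)
  ov > 0 && ov >= frac * shorter
}

# Gap-scan burst grouping oracle.
oracle_group_bursts <- function(times, max_gap = 0.05, refractory = 0.002) {
  if (length(times) == 0)
    return(data.frame(onset = numeric(), offset = numeric(),
                      n_spikes = integer()))
  groups <- list(times[1])
  for (t in times[-1]) {
    g <- groups[[length(groups)]]
    if (t - g[length(g)] <= max_gap) {
      groups[[length(groups)]] <- c(g, t)
    } else groups[[length(groups) + 1]] <- t
  }
  do.call(rbind, lapply(groups, function(g) {
    data.frame(onset = g[1],
               offset = if (length(g) == 1) g[1] + refractory else g[length(g)],
               n_spikes = length(g))
  }))
}

# One-row event stub for coupling tests.
stub_event <- function(t_max, side = "left", onset = t_max - 0.5,
                       offset = t_max + 0.5) {
  data.frame(side = side, onset = onset, offset = offset, t_max = t_max,
             peak_extension = 0.15, stringsAsFactors = FALSE)
}

burst_row <- function(channel, onset, offset) {
  data.frame(channel = channel, onset = onset, offset = offset,
             n_spikes = 5L, mean_spike_amplitude = 10)
}
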