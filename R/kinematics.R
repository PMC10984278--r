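# Smoothing, the fin-extension metric, COM velocity, body-wave metrics.

#' Moving-average smoothing with shrinking edge windows
#'
#' Centered moving average whose window is `round(window_fraction *
#' frame_rate)` samples (20% of frame rate by default, i.e. 30 frames at
#' 150 fps). At the edges the window shrinks to the available samples, so the
#' output has the input's length. This attenuates extrema (a conservative
#' estimate of maxima/minima) and has sinc-like gain: an oscillation at
#' frequency f is scaled by roughly sinc(f * w / frame_rate).
#'
#' @param values Numeric vector (a uniformly sampled series).
#' @param frame_rate Samples per second.
#' @param window_fraction Window size as a fraction of the frame rate,
#'   default 0.2.
#' @return Numeric vector, same length.
#' @export
smooth_series <- function(values, frame_rate, window_fraction = 0.2) {
  w <- max(1L, as.integer(round(window_fraction * frame_rate)))
  n <- length(values)
  if (n < w) stopf("series of length %d shorter than smoothing window %d", n, w)
  half_lo <- (w - 1L) %/% 2L   # samples before center
  half_hi <- w %/% 2L          # samples after center (even w leans forward)
  vapply(seq_len(n), function(i) {
    mean(values[max(1L, i - half_lo):min(n, i + half_hi)])
  }, numeric(1))
}

#' Smooth every tracked point of a pose track
#'
#' @param track A `pose_track`.
#' @inheritParams smooth_series
#' @return A `pose_track` with smoothed x and y.
#' @export
smooth_track <- function(track, window_fraction = 0.2) {
  for (j in seq_len(ncol(track$x))) {
    track$x[, j] <- smooth_series(track$x[, j], track$frame_rate,
                                  window_fraction)
    track$y[, j] <- smooth_series(track$y[, j], track$frame_rate,
                                  window_fraction)
  }
  track
}

#' Fin extension: perpendicular tip-to-base distance in body lengths
#'
#' The extension of a pectoral fin is the perpendicular distance from the fin
#' tip (fin point 3) to the fin base — the infinite line through fin points 1
#' and 5 — divided by body length L. The absolute distance is used, so the
#' metric is non-negative and invariant under rigid motion of the three
#' points. Frames where the base points are closer than 1e-6 cm are returned
#' as NA (degenerate base).
#'
#' @param track A `pose_track` (smooth it first for event detection).
#' @param side `"left"` or `"right"`.
#' @param L Body length in cm.
#' @return Numeric vector of extensions in L units, one per frame.
#' @export
fin_extension_distance <- function(track, side = c("left", "right"), L) {
  side <- match.arg(side)
  pre <- if (side == "left") "Lfin_" else "Rfin_"
  p1x <- track$x[, paste0(pre, 1)]; p1y <- track$y[, paste0(pre, 1)]
  p3x <- track$x[, paste0(pre, 3)]; p3y <- track$y[, paste0(pre, 3)]
  p5x <- track$x[, paste0(pre, 5)]; p5y <- track$y[, paste0(pre, 5)]
  bx <- p5x - p1x; by <- p5y - p1y
  blen <- sqrt(bx^2 + by^2)
  # |cross((p5-p1), (p3-p1))| / |p5-p1|
  d <- abs(bx * (p3y - p1y) - by * (p3x - p1x)) / blen
  d[blen < 1e-6] <- NA_real_
  d / L
}

#' Center-of-mass velocity from the third midline point
#'
#' The third midline point (pectoral fin girdle region) proxies the center of
#' mass. Velocities are central differences of its (already smoothed) x and y
#' positions; the endpoints use one-sided differences. Under the package's
#' coordinate convention, negative forward velocity is upstream motion toward
#' the cylinder.
#'
#' @param track A `pose_track`, smoothed.
#' @return A list with `times`, `forward` (x-velocity, cm s^-1) and
#'   `lateral` (y-velocity, cm s^-1).
#' @export
com_velocity <- function(track) {
  n <- nrow(track$x)
  if (n < 3) stopf("need at least 3 frames for velocity estimation")
  deriv <- function(p) {
    dt <- 1 / track$frame_rate
    v <- numeric(n)
    v[1] <- (p[2] - p[1]) / dt
    v[n] <- (p[n] - p[n - 1]) / dt
    v[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (2 * dt)
    v
  }
  list(times = track$times,
       forward = deriv(track$x[, "midline_3"]),
       lateral = deriv(track$y[, "midline_3"]))
}

# Phase of a sinusoid at frequency f in a uniformly sampled signal,
# by least-squares projection onto cos/sin.
phase_at_freq <- function(values, times, f) {
  c1 <- cos(2 * pi * f * times); s1 <- sin(2 * pi * f * times)
  a <- sum(values * c1) / sum(c1^2)
  b <- sum(values * s1) / sum(s1^2)
  list(phase = atan2(-a, b), amplitude = sqrt(a^2 + b^2))
}

#' Body-wave metrics of a swimming bout
#'
#' Characterizes whole-body undulation from the seven midline points:
#' \itemize{
#'   \item `tailbeat_frequency`: dominant spectral peak of the tail-tip
#'     lateral signal (Hz);
#'   \item `lateral_displacement`: peak-to-peak tail-tip lateral excursion
#'     in L units;
#'   \item `wavelength`: body wavelength in L units, from the slope of the
#'     per-point oscillation phase against arclength at the dominant
#'     frequency (lambda = 2*pi / |d phase / d s|);
#'   \item `net_drift`: x displacement of midline point 3 over the bout (cm);
#'   \item `has_transient_highfreq_tailbeats`: TRUE when more than 10% of the
#'     bout shows more tail energy above 1.5x the dominant frequency than in
#'     the dominant band;
#'   \item `oscillation`: FALSE when no spectral peak rises above the noise
#'     floor (wavelength undefined);
#'   \item `rigid_body`: TRUE when all points oscillate in phase (phase slope
#'     ~ 0), in which case the wavelength is reported as `Inf`.
#' }
#'
#' Pass unsmoothed positions: the 0.2 s moving-average smoother strongly
#' attenuates 2-5 Hz oscillation (gain ~0.5 at 3 Hz, 0 at 5 Hz) and would
#' mask the very undulation these metrics quantify.
#'
#' @param track A `pose_track` covering at least 1 s.
#' @param L Body length in cm.
#' @param peak_snr Floor on the ratio of the dominant spectral peak to the
#'   mean spectral power for an oscillation to be declared, default 10; the
#'   effective threshold grows with spectrum size to hold the white-noise
#'   false-alarm rate near 1%.
#' @return A list of class `body_wave_metrics`.
#' @export
body_wave_metrics <- function(track, L, peak_snr = 10) {
  n <- nrow(track$x)
  fs <- track$frame_rate
  if (n < fs) stopf("need at least 1 s of data for body-wave metrics")
  tail_y <- track$y[, "midline_7"]
  tail_y <- tail_y - mean(tail_y)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  spec <- Mod(stats::fft(tail_y * hann))^2
  half <- 2:(floor(n / 2))        # skip DC
  freqs <- (half - 1) * fs / n
  pk <- which.max(spec[half])
  f0 <- freqs[pk]
  nb <- length(half)
  # sub-bin refinement: quadratic interpolation on the log spectrum
  if (pk > 1 && pk < length(half)) {
    lv <- log(spec[half][(pk - 1):(pk + 1)] + .Machine$double.xmin)
    den <- lv[1] - 2 * lv[2] + lv[3]
    if (is.finite(den) && den < 0) {
      delta <- 0.5 * (lv[1] - lv[3]) / den
      if (abs(delta) <= 0.5) f0 <- f0 + delta * fs / n
    }
  }
  # Fisher-g style periodicity call: for white noise the spectral ordinates
  # are ~exponential, so P(max/mean > x) ~ nb * exp(-x); the threshold keeps
  # the false-alarm rate near 1%. peak_snr is a floor for tiny spectra.
  peak_ratio <- spec[half][pk] / mean(spec[half])
  oscillation <- peak_ratio > max(peak_snr, log(nb / 0.01))
  net_drift <- unname(track$x[n, "midline_3"] - track$x[1, "midline_3"])
  out <- list(tailbeat_frequency = NA_real_, lateral_displacement = NA_real_,
              wavelength = NA_real_, net_drift = net_drift,
              has_transient_highfreq_tailbeats = FALSE,
              oscillation = oscillation, rigid_body = FALSE)
  class(out) <- "body_wave_metrics"
  out$lateral_displacement <- (max(tail_y) - min(tail_y)) / L
  if (!oscillation) return(out)
  out$tailbeat_frequency <- f0
  # phase per midline point at f0, against arclength along the body
  mid <- paste0("midline_", 1:7)
  sx <- colMeans(track$x[, mid]); sy <- colMeans(track$y[, mid])
  arc <- c(0, cumsum(sqrt(diff(sx)^2 + diff(sy)^2)))
  ph <- vapply(mid, function(bp) {
    yy <- track$y[, bp] - mean(track$y[, bp])
    phase_at_freq(yy, track$times, f0)$phase
  }, numeric(1))
  ph <- unwrap_phase(ph)
  fit <- stats::lm(ph ~ arc)
  slope <- unname(stats::coef(fit)[2])
  slope_se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  if (!is.finite(slope) || abs(slope) < 2 * slope_se ||
      abs(slope) * L < 0.2) {   # < 0.2 rad phase lag over a body length
    out$rigid_body <- TRUE
    out$wavelength <- Inf
  } else {
    out$wavelength <- (2 * pi / abs(slope)) / L
  }
  out$has_transient_highfreq_tailbeats <-
    highfreq_tailbeat_fraction(tail_y, fs, f0) > 0.10
  out
}

# fraction of the bout in which tail energy above 1.5*f0 exceeds the
# dominant-band energy, from short-time spectra in ~0.5 s windows
highfreq_tailbeat_fraction <- function(tail_y, fs, f0) {
  win <- max(16L, as.integer(round(0.5 * fs)))
  n <- length(tail_y)
  if (n < win) return(0)
  starts <- seq(1L, n - win + 1L, by = max(1L, win %/% 2L))
  flagged <- vapply(starts, function(s) {
    seg <- tail_y[s:(s + win - 1L)]
    seg <- seg - mean(seg)
    sp <- Mod(stats::fft(seg))^2
    half <- 2:(floor(win / 2))
    fr <- (half - 1) * fs / win
    dom <- fr >= 0.5 * f0 & fr <= 1.5 * f0
    hi <- fr > 1.5 * f0
    sum(sp[half][hi]) > sum(sp[half][dom])
  }, logical(1))
  mean(flagged)
}

unwrap_phase <- function(p) {
  for (i in seq_along(p)[-1]) {
    while (p[i] - p[i - 1] > pi) p[i] <- p[i] - 2 * pi
    while (p[i] - p[i - 1] < -pi) p[i] <- p[i] + 2 * pi
  }
  p
}
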