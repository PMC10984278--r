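# Internal helpers shared across modules.

#' Canonical bodypart labels for a ventral-view pose table
#'
#' Seven midline points (snout to caudal fin tip) plus five points per
#' pectoral fin, in the fixed column order the pose reader expects.
#'
#' @return Character vector of 17 bodypart labels.
#' @export
pose_bodyparts <- function() {
  c(paste0("midline_", 1:7), paste0("Lfin_", 1:5), paste0("Rfin_", 1:5))
}

#' Canonical EMG channel names
#'
#' @return Character vector: left/right abductor and adductor.
#' @export
emg_channels <- function() {
  c("L_abductor", "L_adductor", "R_abductor", "R_adductor")
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_uniform_times <- function(times, tol = 1e-6, what = "times") {
  if (length(times) < 2) return(invisible(TRUE))
  dt <- diff(times)
  if (any(dt <= 0)) stopf("%s must be strictly increasing", what)
  if (max(dt) - min(dt) > tol) {
    stopf("%s are not uniformly sampled (max deviation %.3g s)", what,
          max(dt) - min(dt))
  }
  invisible(TRUE)
}

# overlap length between closed interval [a1, a2] and [b1, b2]
interval_overlap <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}

# TRUE when interval [a1, a2] intersects window [w1, w2) with positive or
# touching measure under the half-open convention used for association
# windows: the burst must reach strictly past w1 and start strictly before w2.
overlaps_window <- function(a1, a2, w1, w2) {
  a2 > w1 & a1 < w2
}
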