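# Reading pose and EMG files, constructing trial containers, writing results.

#' Trial metadata
#'
#' Holds the per-trial constants every downstream computation needs: fish body
#' length L, the free-stream flow speed U, the cylinder diameter D, camera and
#' EMG sampling rates, and the cylinder center in image coordinates.
#'
#' The coordinate convention throughout the package: the cylinder center is
#' (0, 0); x increases downstream; y is lateral (positive toward the fish's
#' right in the ventral view). Forward (upstream) body motion therefore has
#' negative x-velocity.
#'
#' @param body_length_L Fish total length in cm (> 0).
#' @param flow_speed_U Flow speed in cm s^-1, within [0, 200].
#' @param cylinder_diameter_D Cylinder diameter in cm (> 0).
#' @param frame_rate Video frame rate in frames s^-1 (> 0).
#' @param emg_rate EMG sampling rate in samples s^-1 (> 0).
#' @param cylinder_origin Numeric (x, y): cylinder center in the raw
#'   coordinates of the pose file (same units as the file, typically px).
#' @param fish_id,trial_id Labels.
#' @return An object of class `trial_meta`.
#' @export
trial_meta <- function(body_length_L, flow_speed_U, cylinder_diameter_D = 5,
                       frame_rate = 150, emg_rate = 5000,
                       cylinder_origin = c(0, 0),
                       fish_id = "fish1", trial_id = "trial1") {
  if (!is.numeric(body_length_L) || body_length_L <= 0)
    stopf("body_length_L must be > 0")
  if (!is.numeric(flow_speed_U) || flow_speed_U < 0 || flow_speed_U > 200)
    stopf("flow_speed_U must lie in [0, 200] cm/s")
  if (cylinder_diameter_D <= 0) stopf("cylinder_diameter_D must be > 0")
  if (frame_rate <= 0) stopf("frame_rate must be > 0")
  if (emg_rate <= 0) stopf("emg_rate must be > 0")
  if (length(cylinder_origin) != 2) stopf("cylinder_origin must be (x, y)")
  structure(
    list(body_length_L = body_length_L, flow_speed_U = flow_speed_U,
         cylinder_diameter_D = cylinder_diameter_D, frame_rate = frame_rate,
         emg_rate = emg_rate, cylinder_origin = as.numeric(cylinder_origin),
         fish_id = fish_id, trial_id = trial_id),
    class = "trial_meta")
}

#' Construct a pose track
#'
#' @param x,y,likelihood Numeric matrices, frames x bodyparts, with column
#'   names equal to `pose_bodyparts()`. Coordinates in cm relative to the
#'   cylinder center.
#' @param frame_rate Frames per second.
#' @param times Optional time vector; defaults to `(0:(n-1)) / frame_rate`.
#' @return Object of class `pose_track`.
#' @export
pose_track <- function(x, y, likelihood = NULL, frame_rate, times = NULL) {
  bp <- pose_bodyparts()
  x <- as.matrix(x); y <- as.matrix(y)
  if (is.null(likelihood)) {
    likelihood <- matrix(1, nrow(x), ncol(x), dimnames = dimnames(x))
  }
  likelihood <- as.matrix(likelihood)
  if (!identical(colnames(x), bp) || !identical(colnames(y), bp) ||
      !identical(colnames(likelihood), bp))
    stopf("pose matrices must have the 17 canonical bodypart columns in order")
  if (nrow(x) != nrow(y) || nrow(x) != nrow(likelihood))
    stopf("x, y, likelihood must have the same number of frames")
  if (any(likelihood < 0 | likelihood > 1, na.rm = TRUE))
    stopf("likelihoods must lie in [0, 1]")
  if (is.null(times)) times <- (seq_len(nrow(x)) - 1) / frame_rate
  check_uniform_times(times, tol = 1e-9, what = "pose times")
  structure(list(times = times, x = x, y = y, likelihood = likelihood,
                 frame_rate = frame_rate),
            class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames at %g fps (%.2f s), 17 bodyparts\n",
              nrow(x$x), x$frame_rate, nrow(x$x) / x$frame_rate))
  invisible(x)
}

#' Construct an EMG recording
#'
#' @param channels Numeric matrix, samples x 4, columns `emg_channels()`.
#'   Amplifier units.
#' @param emg_rate Samples per second.
#' @param times Optional time vector.
#' @return Object of class `emg_recording`.
#' @export
emg_recording <- function(channels, emg_rate, times = NULL) {
  channels <- as.matrix(channels)
  if (!identical(colnames(channels), emg_channels()))
    stopf("EMG channels must be exactly: %s",
          paste(emg_channels(), collapse = ", "))
  if (is.null(times)) times <- (seq_len(nrow(channels)) - 1) / emg_rate
  if (length(times) != nrow(channels))
    stopf("times and channels lengths differ")
  check_uniform_times(times, tol = 1e-6, what = "EMG times")
  structure(list(times = times, channels = channels, emg_rate = emg_rate),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples at %g Hz (%.2f s), 4 channels\n",
              nrow(x$channels), x$emg_rate, nrow(x$channels) / x$emg_rate))
  invisible(x)
}

#' Read a DeepLabCut-dialect pose CSV
#'
#' Expects the three-row DeepLabCut header (scorer / bodyparts / coords) with
#' x, y, likelihood triplets for each of the 17 canonical bodyparts, then one
#' row per frame. Raw coordinates (typically pixels) are mapped to cm with
#' `pixel_to_cm` and translated so the cylinder center (`meta$cylinder_origin`,
#' in raw units) sits at (0, 0).
#'
#' @param path CSV path.
#' @param meta A `trial_meta`.
#' @param pixel_to_cm Scale factor, cm per raw coordinate unit.
#' @param name_map Optional named character vector mapping file bodypart
#'   labels to the canonical labels, e.g. `c(snout = "midline_1")`.
#' @return A `pose_track` in cm, times from row index / frame_rate.
#' @export
read_pose_csv <- function(path, meta, pixel_to_cm = 1, name_map = NULL) {
  if (!file.exists(path)) stopf("pose file not found: %s", path)
  hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                         colClasses = "character")
  body <- utils::read.csv(path, header = FALSE, skip = 3,
                          colClasses = "character")
  bp_row <- as.character(unlist(hdr[2, -1]))
  coord_row <- as.character(unlist(hdr[3, -1]))
  if (!is.null(name_map)) {
    hit <- bp_row %in% names(name_map)
    bp_row[hit] <- unname(name_map[bp_row[hit]])
  }
  need <- pose_bodyparts()
  have <- unique(bp_row)
  missing <- setdiff(need, have)
  if (length(missing) > 0)
    stopf("pose file missing bodypart column(s): %s",
          paste(missing, collapse = ", "))
  frame_idx <- suppressWarnings(as.numeric(body[[1]]))
  if (anyDuplicated(frame_idx)) stopf("duplicate frame index in pose file")
  n <- nrow(body)
  get_col <- function(bp, coord) {
    j <- which(bp_row == bp & coord_row == coord)
    if (length(j) != 1)
      stopf("pose file missing bodypart column(s): %s (%s)", bp, coord)
    v <- suppressWarnings(as.numeric(body[[j + 1]]))
    bad <- which(!is.na(body[[j + 1]]) & body[[j + 1]] != "" & is.na(v))
    if (length(bad) > 0)
      stopf("non-numeric value in column %s/%s at data row %d", bp, coord,
            bad[1])
    v
  }
  x <- sapply(need, get_col, coord = "x")
  y <- sapply(need, get_col, coord = "y")
  lik <- sapply(need, get_col, coord = "likelihood")
  dim(x) <- dim(y) <- dim(lik) <- c(n, length(need))
  colnames(x) <- colnames(y) <- colnames(lik) <- need
  x <- (x - meta$cylinder_origin[1]) * pixel_to_cm
  y <- (y - meta$cylinder_origin[2]) * pixel_to_cm
  pose_track(x, y, lik, frame_rate = meta$frame_rate)
}

#' Write a pose track as a DeepLabCut-dialect CSV
#'
#' Inverse of [read_pose_csv()]: coordinates are mapped back to raw units via
#' the same affine transform (divide by `pixel_to_cm`, add the cylinder
#' origin), so read-then-write round-trips.
#'
#' @inheritParams read_pose_csv
#' @param track A `pose_track`.
#' @param scorer Scorer label for the first header row.
#' @export
write_pose_csv <- function(track, path, meta, pixel_to_cm = 1,
                           scorer = "finwake") {
  bp <- pose_bodyparts()
  n <- nrow(track$x)
  cols <- vector("list", 1 + 3 * length(bp))
  cols[[1]] <- 0:(n - 1)
  hdr1 <- c("scorer", rep(scorer, 3 * length(bp)))
  hdr2 <- c("bodyparts", rep(bp, each = 3))
  hdr3 <- c("coords", rep(c("x", "y", "likelihood"), length(bp)))
  for (i in seq_along(bp)) {
    cols[[3 * i - 1]] <- track$x[, bp[i]] / pixel_to_cm + meta$cylinder_origin[1]
    cols[[3 * i]]     <- track$y[, bp[i]] / pixel_to_cm + meta$cylinder_origin[2]
    cols[[3 * i + 1]] <- track$likelihood[, bp[i]]
  }
  m <- do.call(cbind, lapply(cols, function(v) format(v, digits = 15,
                                                      scientific = FALSE,
                                                      trim = TRUE)))
  out <- rbind(hdr1, hdr2, hdr3, m)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plain-CSV EMG export
#'
#' Expects a `time` column plus the four channel columns named as in
#' `emg_channels()`. Non-uniform sampling (beyond 1e-6 s) is rejected.
#'
#' @param path CSV path.
#' @param meta A `trial_meta`; `meta$emg_rate` is cross-checked against the
#'   timestamps.
#' @return An `emg_recording`.
#' @export
read_emg_csv <- function(path, meta) {
  if (!file.exists(path)) stopf("EMG file not found: %s", path)
  d <- utils::read.csv(path, check.names = FALSE)
  if (ncol(d) < 2) stopf("EMG file must have a time column plus channels")
  if (!"time" %in% names(d)) stopf("EMG file missing 'time' column")
  missing <- setdiff(emg_channels(), names(d))
  if (length(missing) > 0)
    stopf("EMG file missing channel(s): %s", paste(missing, collapse = ", "))
  times <- d$time
  check_uniform_times(times, tol = 1e-6, what = "EMG times")
  ch <- as.matrix(d[, emg_channels(), drop = FALSE])
  emg_recording(ch, emg_rate = meta$emg_rate, times = times)
}

#' Write an EMG recording to CSV
#' @param rec An `emg_recording`.
#' @param path Output path.
#' @export
write_emg_csv <- function(rec, path) {
  d <- data.frame(time = rec$times, rec$channels, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate low-likelihood pose points
#'
#' Points with likelihood below `floor` are treated as untracked. Gaps of at
#' most `max_gap` frames are filled by linear interpolation; longer gaps stay
#' NA, and the affected frame ranges should be excluded from event detection.
#' This is the automated surrogate for manual outlier correction.
#'
#' @param track A `pose_track`.
#' @param floor Likelihood floor, default 0.9.
#' @param max_gap Longest gap (frames) to interpolate, default 5.
#' @return A `pose_track` with interpolated coordinates; likelihoods of
#'   filled points are set to `floor`.
#' @export
interpolate_untracked <- function(track, floor = 0.9, max_gap = 5) {
  fill <- function(v, bad) {
    r <- rle(bad)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      if (i1 - i0 + 1 > max_gap || i0 == 1 || i1 == length(v)) {
        v[i0:i1] <- NA
      } else {
        v[i0:i1] <- v[i0 - 1] +
          (v[i1 + 1] - v[i0 - 1]) * seq_len(i1 - i0 + 1) / (i1 - i0 + 2)
      }
    }
    v
  }
  for (j in seq_len(ncol(track$x))) {
    bad <- track$likelihood[, j] < floor
    if (any(bad)) {
      track$x[, j] <- fill(track$x[, j], bad)
      track$y[, j] <- fill(track$y[, j], bad)
      track$likelihood[bad, j] <- floor
    }
  }
  track
}

#' Write tidy result tables
#'
#' Emits one CSV per entity type: `events.csv`, `bouts.csv`, `bursts.csv`,
#' `coupling.csv`, `summary.csv`. Empty inputs produce header-only files.
#' Rewriting to the same directory is idempotent.
#'
#' @param results A list with any of `events`, `bouts`, `bursts`, `coupling`,
#'   `summary` data frames (missing ones are written as header-only).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the vector of written paths.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  templates <- list(
    events = data.frame(fish_id = character(), trial_id = character(),
                        side = character(), onset = numeric(),
                        offset = numeric(), t_max = numeric(),
                        peak_extension = numeric(), x = numeric(),
                        y = numeric(), zone = character()),
    bouts = data.frame(fish_id = character(), trial_id = character(),
                       label = character(), start = numeric(),
                       end = numeric()),
    bursts = data.frame(fish_id = character(), trial_id = character(),
                        channel = character(), onset = numeric(),
                        offset = numeric(), n_spikes = integer(),
                        mean_spike_amplitude = numeric()),
    coupling = data.frame(),
    summary = data.frame())
  paths <- character(0)
  for (nm in names(templates)) {
    d <- results[[nm]]
    if (is.null(d) || nrow(as.data.frame(d)) == 0) {
      d <- if (nrow(templates[[nm]]) == 0 && is.null(d)) templates[[nm]]
           else if (is.null(d)) templates[[nm]] else as.data.frame(d)
    }
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(d), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
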