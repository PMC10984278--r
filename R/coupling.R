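# Joining kinematic events to velocity changes and EMG bursts; pre/post
# statistics; activation-pattern classification; cohort summaries.

#' Pre/post velocity change around maximal fin extension
#'
#' Means of a velocity series over the 0.2 s windows on either side of the
#' time of maximal extension: pre over [t_max - window, t_max), post over
#' (t_max, t_max + window]. A window truncated by the recording edge is still
#' computed (with `truncated = TRUE`) when at least half of it is present,
#' otherwise NA.
#'
#' @param event One-row event data frame (needs `t_max`).
#' @param values Velocity series, cm s^-1.
#' @param times Matching time vector.
#' @param window Window length in s, default 0.2.
#' @return List with `pre`, `post`, `pre_truncated`, `post_truncated`.
#' @export
velocity_change <- function(event, values, times, window = 0.2) {
  t <- event$t_max
  if (t < min(times) || t > max(times)) stopf("event t_max outside the series")
  win_mean <- function(lo, hi, open_left) {
    inside <- if (open_left) times > lo & times <= hi
              else times >= lo & times < hi
    avail <- (min(max(times), hi) - max(min(times), lo)) / (hi - lo)
    if (avail < 0.5 || !any(inside))
      return(list(mean = NA_real_, truncated = TRUE))
    list(mean = mean(values[inside]), truncated = avail < 1 - 1e-9)
  }
  pre <- win_mean(t - window, t, open_left = FALSE)
  post <- win_mean(t, t + window, open_left = TRUE)
  list(pre = pre$mean, post = post$mean,
       pre_truncated = pre$truncated, post_truncated = post$truncated)
}

#' Pre/post paired test: KS normality check, then Student's t-test
#'
#' Differences d = post - pre are standardized and checked against a
#' standard normal with a one-sample Kolmogorov-Smirnov test; the velocity
#' change itself is tested with a paired two-tailed Student's t-test.
#' With zero-variance differences the t statistic is undefined: the result
#' is flagged degenerate and significance is decided by exact inequality of
#' pre and post.
#'
#' @param pairs Data frame with `pre` and `post` columns (n >= 2, finite).
#' @param alpha Significance level, default 0.05.
#' @return List of class `pre_post_test`: n, pre_mean, post_mean, ks_p,
#'   t_stat, t_p, significant, degenerate.
#' @export
pre_post_test <- function(pairs, alpha = 0.05) {
  pairs <- pairs[is.finite(pairs$pre) & is.finite(pairs$post), , drop = FALSE]
  n <- nrow(pairs)
  if (n < 2) stopf("need at least 2 complete pairs")
  d <- pairs$post - pairs$pre
  out <- list(n = n, pre_mean = mean(pairs$pre), post_mean = mean(pairs$post),
              ks_p = NA_real_, t_stat = NA_real_, t_p = NA_real_,
              significant = NA, degenerate = FALSE)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      out$t_stat <- 0; out$t_p <- 1; out$significant <- FALSE
    } else {
      out$degenerate <- TRUE
      out$significant <- TRUE     # constant nonzero shift
    }
    class(out) <- "pre_post_test"
    return(out)
  }
  z <- (d - mean(d)) / stats::sd(d)
  out$ks_p <- suppressWarnings(stats::ks.test(z, "pnorm")$p.value)
  tt <- stats::t.test(pairs$post, pairs$pre, paired = TRUE)
  out$t_stat <- unname(tt$statistic)
  out$t_p <- tt$p.value
  out$significant <- tt$p.value < alpha
  class(out) <- "pre_post_test"
  out
}

#' Muscle activity associated with a fin-extension event
#'
#' Flags, per muscle (ipsilateral/contralateral x abductor/adductor), whether
#' any EMG burst overlaps the onset window [t_max - window, t_max) or the
#' offset window (t_max, t_max + window], and records the durations of
#' overlapping bursts.
#'
#' @param event One-row event data frame (needs `t_max` and `side`).
#' @param bursts Burst data frame from [group_bursts()]/[detect_bursts()].
#' @param window Association window in s, default 0.2.
#' @return List with `onset` and `offset` (named logicals ipsi_abd,
#'   ipsi_add, contra_abd, contra_add, any), and `burst_durations`
#'   (durations of bursts overlapping either window).
#' @export
muscle_association <- function(event, bursts, window = 0.2) {
  t <- event$t_max
  ipsi <- if (event$side == "left") "L" else "R"
  contra <- if (event$side == "left") "R" else "L"
  role <- function(prefix, mus) paste0(prefix, "_", mus)
  chans <- c(ipsi_abd = role(ipsi, "abductor"),
             ipsi_add = role(ipsi, "adductor"),
             contra_abd = role(contra, "abductor"),
             contra_add = role(contra, "adductor"))
  win_flags <- function(w1, w2) {
    fl <- vapply(chans, function(ch) {
      b <- bursts[bursts$channel == ch, , drop = FALSE]
      nrow(b) > 0 && any(overlaps_window(b$onset, b$offset, w1, w2))
    }, logical(1))
    c(fl, any = any(fl))
  }
  onset <- win_flags(t - window, t)
  offset <- win_flags(t, t + window)
  in_any <- overlaps_window(bursts$onset, bursts$offset, t - window, t) |
    overlaps_window(bursts$onset, bursts$offset, t, t + window)
  list(onset = onset, offset = offset,
       burst_durations = bursts$offset[in_any] - bursts$onset[in_any])
}

#' Classify the activation pattern of each fin-movement phase
#'
#' Splits the event at the time of maximal extension into an abduction phase
#' [onset, t_max] and an adduction phase [t_max, offset]. For each phase the
#' ipsilateral muscles overlapping it decide the pattern:
#' \itemize{
#'   \item agonist only (abductor during abduction, adductor during
#'     adduction): `active_*`;
#'   \item neither muscle: `passive_*` (e.g. vortex-driven fin movement);
#'   \item antagonist only: `resistive_*` (muscle braking the movement);
#'   \item both: `active_*` with `co_contraction = TRUE`.
#' }
#'
#' @param event One-row event data frame (`side`, `onset`, `offset`,
#'   `t_max`).
#' @param bursts Burst data frame.
#' @return List with `abduction`, `adduction` (pattern labels, NA for a
#'   zero-length phase) and `co_contraction` (named logical pair).
#' @export
classify_activation_pattern <- function(event, bursts) {
  ipsi <- if (event$side == "left") "L" else "R"
  abd <- paste0(ipsi, "_abductor"); add <- paste0(ipsi, "_adductor")
  phase_overlap <- function(ch, p1, p2) {
    b <- bursts[bursts$channel == ch, , drop = FALSE]
    nrow(b) > 0 && any(interval_overlap(b$onset, b$offset, p1, p2) > 0)
  }
  classify <- function(p1, p2, movement) {
    if (p2 <= p1) return(list(pattern = NA_character_, co = FALSE))
    agonist <- if (movement == "abduction") abd else add
    antagonist <- if (movement == "abduction") add else abd
    ag <- phase_overlap(agonist, p1, p2)
    an <- phase_overlap(antagonist, p1, p2)
    if (ag && an) list(pattern = paste0("active_", movement), co = TRUE)
    else if (ag) list(pattern = paste0("active_", movement), co = FALSE)
    else if (an) list(pattern = paste0("resistive_", movement), co = FALSE)
    else list(pattern = paste0("passive_", movement), co = FALSE)
  }
  a <- classify(event$onset, event$t_max, "abduction")
  d <- classify(event$t_max, event$offset, "adduction")
  list(abduction = a$pattern, adduction = d$pattern,
       co_contraction = c(abduction = a$co, adduction = d$co))
}

#' Build coupling records for a set of events
#'
#' Joins each fin-extension event to its velocity change, synchronicity
#' label, muscle-association flags and activation patterns.
#'
#' @param events Event data frame with `synchronicity` column (from
#'   [label_synchronicity()]).
#' @param forward,lateral COM velocity series, cm s^-1.
#' @param times Velocity time base.
#' @param bursts Burst data frame.
#' @param behavior Bout label attached to every record.
#' @param window Association/velocity window in s, default 0.2.
#' @return Data frame, one row per event, with velocity means, per-muscle
#'   activity flags, burst-duration summary and pattern labels.
#' @export
couple_events <- function(events, forward, lateral, times, bursts,
                          behavior, window = 0.2) {
  if (nrow(events) == 0) return(data.frame())
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    vf <- velocity_change(ev, forward, times, window)
    vl <- velocity_change(ev, lateral, times, window)
    ma <- muscle_association(ev, bursts, window)
    pat <- classify_activation_pattern(ev, bursts)
    data.frame(
      behavior = behavior, side = ev$side, onset = ev$onset,
      offset = ev$offset, t_max = ev$t_max,
      peak_extension = ev$peak_extension,
      synchronicity = ev$synchronicity,
      pre_forward = vf$pre, post_forward = vf$post,
      pre_lateral = vl$pre, post_lateral = vl$post,
      onset_ipsi_abd = ma$onset[["ipsi_abd"]],
      onset_ipsi_add = ma$onset[["ipsi_add"]],
      onset_contra_abd = ma$onset[["contra_abd"]],
      onset_contra_add = ma$onset[["contra_add"]],
      onset_any = ma$onset[["any"]],
      offset_ipsi_abd = ma$offset[["ipsi_abd"]],
      offset_ipsi_add = ma$offset[["ipsi_add"]],
      offset_contra_abd = ma$offset[["contra_abd"]],
      offset_contra_add = ma$offset[["contra_add"]],
      offset_any = ma$offset[["any"]],
      mean_burst_duration = if (length(ma$burst_durations) > 0)
        mean(ma$burst_durations) else NA_real_,
      pattern_abduction = pat$abduction,
      pattern_adduction = pat$adduction,
      co_contraction = any(pat$co_contraction),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize a cohort of coupling records
#'
#' Per behavior: synchronous/asynchronous counts and fractions; fractions of
#' events with any-muscle, ipsilateral-only, and no muscle activity in the
#' onset and offset windows; mean and s.e.m. of burst durations; pre/post
#' velocity tests (forward for braking; lateral, by extended side, for
#' Karman gaiting).
#'
#' @param records Coupling data frame from [couple_events()] (possibly
#'   row-bound over trials).
#' @param alpha Significance level for the velocity tests.
#' @return List with `synchronicity`, `activity`, `durations` data frames
#'   and `velocity_tests` (list of `pre_post_test` results).
#' @export
summarize_coupling <- function(records, alpha = 0.05) {
  if (is.null(records) || nrow(records) == 0) {
    return(list(synchronicity = data.frame(), activity = data.frame(),
                durations = data.frame(), velocity_tests = list()))
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  by_beh <- split(records, records$behavior)
  sync <- do.call(rbind, lapply(names(by_beh), function(b) {
    r <- by_beh[[b]]
    ns <- sum(r$synchronicity == "synchronous")
    data.frame(behavior = b, n_events = nrow(r), n_synchronous = ns,
               n_asynchronous = nrow(r) - ns,
               frac_synchronous = ns / nrow(r),
               frac_asynchronous = 1 - ns / nrow(r))
  }))
  act <- do.call(rbind, lapply(names(by_beh), function(b) {
    r <- by_beh[[b]]
    ipsi_on <- r$onset_ipsi_abd | r$onset_ipsi_add
    ipsi_off <- r$offset_ipsi_abd | r$offset_ipsi_add
    data.frame(behavior = b,
               frac_onset_any = mean(r$onset_any),
               frac_offset_any = mean(r$offset_any),
               frac_onset_ipsi = mean(ipsi_on),
               frac_offset_ipsi = mean(ipsi_off),
               frac_no_activity = mean(!r$onset_any & !r$offset_any))
  }))
  dur <- do.call(rbind, lapply(names(by_beh), function(b) {
    d <- by_beh[[b]]$mean_burst_duration
    d <- d[is.finite(d)]
    data.frame(behavior = b, n = length(d),
               mean_burst_duration = if (length(d) > 0) mean(d) else NA_real_,
               sem_burst_duration = if (length(d) > 1) sem(d) else NA_real_)
  }))
  tests <- list()
  if ("braking" %in% names(by_beh)) {
    r <- by_beh[["braking"]]
    p <- data.frame(pre = r$pre_forward, post = r$post_forward)
    if (sum(stats::complete.cases(p)) >= 2)
      tests$braking_forward <- pre_post_test(p, alpha)
  }
  if ("karman_gait" %in% names(by_beh)) {
    r <- by_beh[["karman_gait"]]
    for (s in c("left", "right")) {
      rs <- r[r$side == s, , drop = FALSE]
      p <- data.frame(pre = rs$pre_lateral, post = rs$post_lateral)
      if (sum(stats::complete.cases(p)) >= 2)
        tests[[paste0("kg_lateral_", s)]] <- pre_post_test(p, alpha)
    }
  }
  list(synchronicity = sync, activity = act, durations = dur,
       velocity_tests = tests)
}
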