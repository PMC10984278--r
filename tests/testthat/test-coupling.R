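# Velocity windows, pre/post statistics, muscle association, activation
# patterns, cohort summaries.

test_that("velocity windows average the 0.2 s on each side of t_max", {
  t <- (0:599) / 150
  ev <- stub_event(t_max = 2)
  z <- velocity_change(ev, rep(0, 600), t)
  expect_equal(c(z$pre, z$post), c(0, 0))
  expect_false(z$pre_truncated)
  v3 <- velocity_change(ev, rep(3, 600), t)
  expect_equal(c(v3$pre, v3$post), c(3, 3))
  # step: pre window sees only the old level, post only the new
  step <- ifelse(t < 2, -4, 3)
  vs <- velocity_change(ev, step, t)
  expect_equal(vs$pre, -4)
  expect_equal(vs$post, 3)
  # window truncated by the record edge: computed but flagged when >= 50%
  near_start <- velocity_change(stub_event(t_max = 0.15), rep(2, 600), t)
  expect_true(near_start$pre_truncated)
  expect_equal(near_start$pre, 2)
  at_start <- velocity_change(stub_event(t_max = 0.05), rep(2, 600), t)
  expect_true(is.na(at_start$pre))
  expect_error(velocity_change(stub_event(t_max = 99), rep(0, 600), t),
               "outside")
})

test_that("paired pre/post test matches closed-form t arithmetic", {
  same <- data.frame(pre = c(1, 2, 3), post = c(1, 2, 3))
  r0 <- pre_post_test(same)
  expect_equal(r0$t_stat, 0)
  expect_equal(r0$t_p, 1)
  expect_false(r0$significant)
  # differences {1,1,1,2}: t = mean/ (sd/sqrt(4)) = 1.25 / 0.25 = 5
  p <- data.frame(pre = c(0, 0, 0, 0), post = c(1, 1, 1, 2))
  r <- pre_post_test(p)
  expect_equal(r$t_stat, 5)
  expect_equal(r$n, 4)
  expect_true(is.finite(r$ks_p))
  expect_error(pre_post_test(data.frame(pre = 1, post = 2)), "2 complete")
  # constant nonzero shift: degenerate, decided by exact inequality
  d <- pre_post_test(data.frame(pre = c(0, 1), post = c(2, 3)))
  expect_true(d$degenerate)
  expect_true(d$significant)
})

test_that("muscle association flags follow the 0.2 s windows", {
  ev <- stub_event(t_max = 5, side = "left")
  m1 <- muscle_association(ev, burst_row("L_abductor", 4.90, 4.95))
  expect_true(m1$onset[["ipsi_abd"]])
  expect_true(m1$onset[["any"]])
  expect_false(m1$offset[["ipsi_abd"]])
  # burst ending 0.25 s before t_max: outside the onset window
  m2 <- muscle_association(ev, burst_row("L_abductor", 4.5, 4.75))
  expect_false(any(m2$onset))
  # spanning burst hits both windows; right-side burst is contralateral
  m3 <- muscle_association(ev, burst_row("R_adductor", 4.95, 5.05))
  expect_true(m3$onset[["contra_add"]])
  expect_true(m3$offset[["contra_add"]])
  expect_false(m3$onset[["ipsi_abd"]])
  expect_equal(m3$burst_durations, 0.1, tolerance = 1e-12)
})

test_that("association flags are monotone in window length", {
  set.seed(51)
  for (rep in 1:30) {
    ev <- stub_event(t_max = 5, side = sample(c("left", "right"), 1))
    b <- burst_row(sample(emg_channels(), 1),
                   runif(1, 4.4, 5.4), runif(1, 5.4, 5.9))
    small <- muscle_association(ev, b, window = 0.1)
    big <- muscle_association(ev, b, window = 0.4)
    expect_true(all(big$onset >= small$onset))
    expect_true(all(big$offset >= small$offset))
  }
})

test_that("activation patterns reproduce the full 6-class truth table", {
  # phases of a left-fin event: abduction [4, 5], adduction [5, 6]
  ev <- stub_event(t_max = 5, side = "left", onset = 4, offset = 6)
  abd_b <- burst_row("L_abductor", 4.3, 4.7)    # inside abduction phase
  add_b <- burst_row("L_adductor", 5.3, 5.7)    # inside adduction phase
  abd_late <- burst_row("L_abductor", 5.3, 5.7) # abductor during adduction
  add_early <- burst_row("L_adductor", 4.3, 4.7)

  cases <- list(
    # agonist only in each phase: canonical active abduction then adduction
    list(bursts = rbind(abd_b, add_b),
         abd = "active_abduction", add = "active_adduction",
         co = c(FALSE, FALSE)),
    # no ipsilateral activity at all: fully passive (vortex-driven fin)
    list(bursts = burst_row("R_abductor", 4.3, 4.7),
         abd = "passive_abduction", add = "passive_adduction",
         co = c(FALSE, FALSE)),
    # antagonist only: resistive in both phases
    list(bursts = rbind(add_early, abd_late),
         abd = "resistive_abduction", add = "resistive_adduction",
         co = c(FALSE, FALSE)),
    # both muscles in both phases: active with co-contraction (braking-like)
    list(bursts = rbind(abd_b, add_early, abd_late, add_b),
         abd = "active_abduction", add = "active_adduction",
         co = c(TRUE, TRUE)))
  for (cs in cases) {
    got <- classify_activation_pattern(ev, cs$bursts)
    expect_equal(got$abduction, cs$abd)
    expect_equal(got$adduction, cs$add)
    expect_equal(unname(got$co_contraction), cs$co)
  }
  # a zero-length phase is unclassified
  inst <- stub_event(t_max = 4, side = "left", onset = 4, offset = 6)
  expect_true(is.na(classify_activation_pattern(inst, abd_b)$abduction))
})

test_that("cohort summaries reproduce synchronicity count arithmetic", {
  mk_rec <- function(n, sync, behavior, side = "left") {
    data.frame(behavior = behavior, side = side, onset = 1, offset = 2,
               t_max = 1.5, peak_extension = 0.1,
               synchronicity = rep(sync, n),
               pre_forward = rnorm(n), post_forward = rnorm(n),
               pre_lateral = rnorm(n), post_lateral = rnorm(n),
               onset_ipsi_abd = FALSE, onset_ipsi_add = FALSE,
               onset_contra_abd = FALSE, onset_contra_add = FALSE,
               onset_any = FALSE,
               offset_ipsi_abd = FALSE, offset_ipsi_add = FALSE,
               offset_contra_abd = FALSE, offset_contra_add = FALSE,
               offset_any = FALSE, mean_burst_duration = NA_real_,
               pattern_abduction = "passive_abduction",
               pattern_adduction = "passive_adduction",
               co_contraction = FALSE)
  }
  set.seed(52)
  records <- rbind(mk_rec(9, "synchronous", "braking"),
                   mk_rec(4, "asynchronous", "braking"),
                   mk_rec(35, "synchronous", "karman_gait"),
                   mk_rec(237, "asynchronous", "karman_gait"))
  s <- summarize_coupling(records)
  braking <- s$synchronicity[s$synchronicity$behavior == "braking", ]
  expect_equal(braking$n_events, 13)
  expect_equal(braking$frac_synchronous, 9 / 13)
  kg <- s$synchronicity[s$synchronicity$behavior == "karman_gait", ]
  expect_equal(kg$n_events, 272)
  expect_equal(kg$frac_asynchronous, 237 / 272)
  # all records passive: zero any-muscle activity everywhere
  expect_true(all(s$activity$frac_onset_any == 0))
  expect_true(all(s$activity$frac_no_activity == 1))
  empty <- summarize_coupling(data.frame())
  expect_equal(nrow(empty$synchronicity), 0)
})

test_that("planted activation-pattern frequencies are recovered at cohort scale", {
  set.seed(53)
  n <- 200
  p_passive <- 0.5
  is_passive <- runif(n) < p_passive
  recs <- lapply(seq_len(n), function(i) {
    t0 <- 10 * i
    ev <- stub_event(t_max = t0, side = "left", onset = t0 - 0.5,
                     offset = t0 + 0.5)
    bursts <- if (is_passive[i]) {
      data.frame(channel = character(), onset = numeric(),
                 offset = numeric(), n_spikes = integer(),
                 mean_spike_amplitude = numeric())
    } else {
      rbind(burst_row("L_abductor", t0 - 0.4, t0 - 0.1),
            burst_row("L_adductor", t0 + 0.1, t0 + 0.4))
    }
    pat <- classify_activation_pattern(ev, bursts)
    ma <- muscle_association(ev, bursts)
    data.frame(pattern_abduction = pat$abduction,
               onset_any = ma$onset[["any"]])
  })
  recs <- do.call(rbind, recs)
  frac_passive <- mean(recs$pattern_abduction == "passive_abduction")
  ci_half <- 1.96 * sqrt(p_passive * (1 - p_passive) / n)
  expect_lt(abs(frac_passive - p_passive), ci_half)
  # association flags agree with the planted activity
  expect_equal(recs$onset_any, !is_passive)
})
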