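test_that("domain formulas for the pulse volume equal volume-law differences", {
  art <- artery_model(a = 0.11, b = 0.03, Va0 = 0.3)
  Pt <- seq(-100, 100, by = 0.25)
  for (PP in c(10, 40, 80)) {
    dv <- pulse_volume(Pt, PP, art)
    ref <- artery_volume(Pt + PP, art) - artery_volume(Pt, art)
    expect_lt(max(abs(dv - ref)), 1e-12)
  }
  # continuity across the two domain boundaries
  for (Pt0 in c(-40, 0)) {
    expect_lt(abs(pulse_volume(Pt0 - 1e-9, 40, art) -
                    pulse_volume(Pt0 + 1e-9, 40, art)), 1e-9)
  }
  expect_lt(pulse_volume(-200, 1e-9, art), 1e-9)   # PP -> 0 limit
  expect_error(pulse_volume(0, -1, art), "positive")
})

test_that("pulse-volume slope extrema sit at systolic and diastolic pressure", {
  art <- artery_model(a = 0.11, b = 0.03, Va0 = 0.3)
  PP <- 40
  Pt <- seq(-80, 40, by = 0.01)
  dv <- pulse_volume(Pt, PP, art)
  # maximum swing occurs strictly inside Domain 2
  expect_gt(Pt[which.max(dv)], -PP)
  expect_lt(Pt[which.max(dv)], 0)
  # slope of the swing w.r.t. nadir pressure: max at Pt = -PP (cuff = SBP),
  # min at Pt = 0 (cuff = DBP)
  sl <- diff(dv) / diff(Pt)
  mid <- Pt[-1] - 0.005
  expect_lt(abs(mid[which.max(sl)] - (-PP)), 0.05)
  expect_lt(abs(mid[which.min(sl)] - 0), 0.05)
})

test_that("semi-log regression recovers constants exactly from log-linear data", {
  # head beats exactly k1*exp(-a*P), tail beats exactly k3*exp(b*P)
  a <- 0.11; b <- 0.03
  P <- seq(145, 40, by = -2)
  amp <- ifelse(P > 110, 5 * exp(-a * (P - 110)),
                ifelse(P < 75, 4.2 * exp(b * (P - 75)), 5 - abs(P - 95) / 50))
  env <- envelope_from_beats(P, amp)
  fs <- fit_stiffness(env)
  expect_equal(fs$a_hat, a, tolerance = 1e-10)
  expect_equal(fs$b_hat, b, tolerance = 1e-10)
  expect_equal(fs$diagnostics$slope1, -a, tolerance = 1e-10)
  expect_equal(fs$diagnostics$slope3, b, tolerance = 1e-10)
  expect_gte(fs$diagnostics$n_head, 3)
  expect_gte(fs$diagnostics$n_tail, 3)
  # too few beats in a range is a named error
  tiny <- envelope_from_beats(c(100, 95, 90, 85, 80, 75),
                              c(1, 5, 6, 5.9, 5.8, 5.7))
  expect_error(fit_stiffness(tiny), "head|tail")
})

test_that("regression ranges follow the onset, 1/3 and 2/3 peak-height rules", {
  env <- cached_run("normal")$envelope
  fs <- fit_stiffness(env)
  d <- fs$diagnostics
  beats <- env$beats
  peak <- max(beats$amp)
  # head spans the onset (>= 10% of peak) through the first beat at peak/3
  head_beats <- beats[beats$P_beat >= d$head_P_range[1] &
                        beats$P_beat <= d$head_P_range[2], ]
  expect_gte(head_beats$amp[1], 0.10 * peak)
  expect_true(all(utils::head(head_beats$amp, -1) < peak / 3))
  expect_gte(utils::tail(head_beats$amp, 1), peak / 3)
  # beats just above the head range sit below the onset threshold
  pre <- beats[beats$P_beat > d$head_P_range[2], ]
  expect_true(all(pre$amp < 0.10 * peak))
  # every tail beat except the first is below 2*peak/3
  tail_beats <- beats[beats$P_beat <= d$tail_P_range[2], ]
  expect_gte(tail_beats$amp[1], 2 * peak / 3)
  expect_true(all(tail_beats$amp[-1] < 2 * peak / 3))
  # regressing from the very first beat is available and close on clean data
  fs0 <- fit_stiffness(env, onset_frac = 0)
  expect_equal(fs0$a_hat, fs$a_hat, tolerance = 0.02)
})

test_that("predicted envelope is the pulse volume scaled by cuff stiffness", {
  P <- seq(40, 145, by = 0.5)
  art <- artery_model(a = 0.11, b = 0.03, Va0 = 1)
  yhat <- predicted_envelope(P, 120, 80, 0.11, 0.03, cuff_model(V0 = 300))
  ref <- pulse_volume(80 - P, 40, art) * (P + 760) / 300
  expect_equal(yhat, ref, tolerance = 1e-12)
  # vanishing pulse pressure gives a vanishing envelope
  expect_lt(max(predicted_envelope(P, 100 + 1e-8, 100, 0.11, 0.03)), 1e-6)
  expect_error(predicted_envelope(P, 80, 90, 0.11, 0.03), "exceed")
  # peak strictly between DBP and SBP
  Pfine <- seq(80, 120, by = 0.1)
  yfine <- predicted_envelope(Pfine, 120, 80, 0.11, 0.03)
  i <- which.max(yfine)
  expect_gt(Pfine[i], 80); expect_lt(Pfine[i], 120)
})

test_that("sum of squares is zero at truth and scale-invariant", {
  env <- synth_envelope(120, 80, 0.11, 0.03)
  expect_equal(sum_of_squares(env, 120, 80, 0.11, 0.03), 0)
  expect_gt(sum_of_squares(env, 110, 70, 0.11, 0.03), 0)
  env2 <- envelope_from_beats(env$beats$P_beat, env$beats$amp * 37.5)
  for (cand in list(c(120, 80), c(110, 70), c(130, 90))) {
    expect_equal(sum_of_squares(env, cand[1], cand[2], 0.11, 0.03),
                 sum_of_squares(env2, cand[1], cand[2], 0.11, 0.03),
                 tolerance = 1e-12)
  }
})

test_that("misfit grows for displaced test pressures on the simulated envelope", {
  run <- cached_run("normal")
  est <- run$estimate
  ss_true <- sum_of_squares(run$envelope, 120, 80, est$a_hat, est$b_hat)
  expect_gt(sum_of_squares(run$envelope, 110, 70, est$a_hat, est$b_hat), ss_true)
  expect_gt(sum_of_squares(run$envelope, 130, 90, est$a_hat, est$b_hat), ss_true)
})

test_that("grid search recovers generating pressures exactly from model envelopes", {
  for (truth in list(c(120, 80), c(140, 60), c(110, 90))) {
    env <- synth_envelope(truth[1], truth[2], 0.11, 0.03)
    est <- estimate_pressures(env, stiffness = list(a_hat = 0.11, b_hat = 0.03))
    expect_equal(est$SBP_hat, truth[1])
    expect_equal(est$DBP_hat, truth[2])
    expect_equal(est$ss_min, 0, tolerance = 1e-20)
  }
})

test_that("estimate respects grid bounds, bracketing and determinism", {
  run <- cached_run("normal")
  est <- run$estimate
  expect_gt(est$SBP_hat, est$DBP_hat)
  expect_gte(est$SBP_hat, run$envelope$P_max)
  expect_lte(est$DBP_hat, run$envelope$P_max)
  expect_true(all(diff(est$grid$SBP) == 1))
  expect_lte(min(est$grid$DBP), min(run$envelope$beats$P_beat))
  expect_gte(max(est$grid$SBP), max(run$envelope$beats$P_beat))
  est2 <- estimate_pressures(run$envelope, run$scenario$cuff)
  expect_identical(est$SBP_hat, est2$SBP_hat)
  expect_identical(est$DBP_hat, est2$DBP_hat)
  expect_identical(est$ss_surface, est2$ss_surface)
})

test_that("the SS surface has a single local-minimum basin on clean data", {
  ss <- cached_run("normal")$estimate$ss_surface
  n_min <- 0L
  for (i in seq_len(nrow(ss))) {
    for (j in seq_len(ncol(ss))) {
      v <- ss[i, j]
      if (!is.finite(v)) next
      nb <- c(if (i > 1) ss[i - 1, j], if (i < nrow(ss)) ss[i + 1, j],
              if (j > 1) ss[i, j - 1], if (j < ncol(ss)) ss[i, j + 1])
      nb <- nb[is.finite(nb)]
      if (length(nb) > 0 && all(v < nb)) n_min <- n_min + 1L
    }
  }
  expect_identical(n_min, 1L)
})

test_that("small seeded measurement noise barely moves the estimates", {
  sc <- builtin_scenarios()$normal
  for (seed in c(11, 12)) {
    rec <- simulate_run(sc$artery, sc$cuff, sc$waveform,
                        noise_sd = 0.02, seed = seed)
    est <- estimate_pressures(extract_envelope(highpass_filter(rec)), sc$cuff)
    expect_lte(abs(est$SBP_hat - 120), 3)
    expect_lte(abs(est$DBP_hat - 80), 3)
  }
})
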