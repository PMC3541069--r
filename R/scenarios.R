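#' Construct a named simulation scenario
#'
#' Bundles a true pressure waveform, artery model and cuff model, plus the
#' optional noise settings, under a label. Scenario defaults are the
#' standard normal conditions: 120/80 mmHg at 80 beats/min, artery
#' `a = 0.11`, `b = 0.03` per mmHg with `Va0 = 0.3` ml, and a 300 ml cuff
#' deflated from 150 mmHg at 3 mmHg/s.
#'
#' @param name Scenario label.
#' @param SBP,DBP True systolic/diastolic pressure, mmHg.
#' @param f_bpm Heart rate in beats per minute (converted to Hz internally).
#' @param a,b Artery stiffness constants, 1/mmHg.
#' @param Va0 Artery zero-pressure volume, ml.
#' @param V0,P0,r Cuff volume (ml), starting pressure (mmHg) and deflation
#'   rate (mmHg/s).
#' @param noise_sd Gaussian measurement-noise SD on cuff pressure, mmHg.
#' @param seed Noise seed.
#' @return A `bp_scenario` list with elements `name`, `waveform`, `artery`,
#'   `cuff`, `noise_sd`, `seed`.
#' @export
scenario <- function(name, SBP = 120, DBP = 80, f_bpm = 80,
                     a = 0.11, b = 0.03, Va0 = 0.3,
                     V0 = 300, P0 = 150, r = 3,
                     noise_sd = 0, seed = NULL) {
  structure(
    list(name = name,
         waveform = pressure_waveform(SBP, DBP, f_bpm / 60),
         artery = artery_model(a = a, b = b, Va0 = Va0),
         cuff = cuff_model(V0 = V0, P0 = P0, r = r),
         noise_sd = noise_sd, seed = seed),
    class = "bp_scenario"
  )
}

#' @export
print.bp_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': %g/%g mmHg, a = %.4g, b = %.4g /mmHg\n",
              x$name, x$waveform$SBP, x$waveform$DBP,
              x$artery$a, x$artery$b))
  invisible(x)
}

#' Built-in validation scenarios
#'
#' The five stress scenarios of the validation suite. All share the
#' standard cuff and heart rate; stiffness variants keep 120/80 mmHg and
#' scale both artery constants by the factor 1.44 (halved stiffness
#' multiplies `a` and `b` by 1.44, doubled stiffness divides by 1.44, a
#' proportional change in both constants scaling the compliance at every
#' pressure); pulse-pressure variants keep normal stiffness and halve
#' (110/90) or double (140/60) the 40 mmHg pulse pressure about the
#' 100 mmHg mid-level.
#'
#' @return Named list of five [scenario()] objects: `normal`,
#'   `twice_stiffness`, `half_stiffness`, `half_pp`, `twice_pp`.
#' @export
builtin_scenarios <- function() {
  k <- 1.44
  list(
    normal          = scenario("normal"),
    twice_stiffness = scenario("twice_stiffness", a = 0.11 / k, b = 0.03 / k),
    half_stiffness  = scenario("half_stiffness", a = 0.11 * k, b = 0.03 * k),
    half_pp         = scenario("half_pp", SBP = 110, DBP = 90),
    twice_pp        = scenario("twice_pp", SBP = 140, DBP = 60)
  )
}

#' Simulate a scenario and extract its oscillation envelope
#'
#' Convenience pipeline: [simulate_run()], [highpass_filter()],
#' [extract_envelope()].
#'
#' @param sc A [scenario()].
#' @param ... Passed to [simulate_run()] (e.g. `duration`, `dt`,
#'   `sample_rate`).
#' @return A list with the filtered `recording` and the `envelope`.
#' @export
run_scenario <- function(sc, ...) {
  stopifnot(inherits(sc, "bp_scenario"))
  rec <- simulate_run(sc$artery, sc$cuff, sc$waveform,
                      noise_sd = sc$noise_sd, seed = sc$seed, ...)
  rec <- highpass_filter(rec)
  list(recording = rec, envelope = extract_envelope(rec))
}

#' Interpolated envelope amplitudes at the true pressures (characteristic ratios)
#'
#' The classical fixed-ratio oscillometric algorithm assumes the envelope
#' amplitude at systolic pressure (rising side) and diastolic pressure
#' (falling side) are fixed fractions of the peak amplitude. This function
#' measures those fractions for a simulated run where the truth is known,
#' by linear interpolation of the beat-wise envelope at cuff pressure
#' equal to SBP (on the rising, high-pressure side of the peak) and DBP
#' (on the falling, low-pressure side).
#'
#' @param env A `bp_envelope`.
#' @param truth A [pressure_waveform()] carrying the true SBP/DBP, or a
#'   [scenario()].
#' @return Named numeric vector `c(systolic_ratio, diastolic_ratio)` in
#'   percent of peak amplitude.
#' @export
characteristic_ratios <- function(env, truth) {
  stopifnot(inherits(env, "bp_envelope"))
  if (inherits(truth, "bp_scenario")) truth <- truth$waveform
  stopifnot(inherits(truth, "pressure_waveform"))
  beats <- env$beats
  i_peak <- which.max(beats$amp)
  rising <- beats[seq_len(i_peak), ]              # earlier beats: higher P
  falling <- beats[seq(i_peak, nrow(beats)), ]
  if (truth$SBP > max(rising$P_beat) || truth$SBP < min(rising$P_beat)) {
    stop("true SBP outside the rising-side envelope pressure support")
  }
  if (truth$DBP > max(falling$P_beat) || truth$DBP < min(falling$P_beat)) {
    stop("true DBP outside the falling-side envelope pressure support")
  }
  amp_s <- stats::approx(rising$P_beat, rising$amp, xout = truth$SBP)$y
  amp_d <- stats::approx(falling$P_beat, falling$amp, xout = truth$DBP)$y
  c(systolic_ratio = 100 * amp_s / env$peak_amp,
    diastolic_ratio = 100 * amp_d / env$peak_amp)
}

#' Fixed characteristic-ratio baseline estimator
#'
#' The classical maximum-amplitude algorithm: systolic pressure is read off
#' where the rising side of the envelope crosses `sys_ratio` of the peak
#' amplitude and diastolic pressure where the falling side crosses
#' `dia_ratio`, using linear interpolation between adjacent beats. The
#' conventional ratios are about 50\% (systolic) and 70\% (diastolic).
#' Provided as the comparison baseline for the model-based estimator; the
#' fixed ratios are known to break down when arterial stiffness or pulse
#' pressure deviate from normal.
#'
#' @param env A `bp_envelope`.
#' @param sys_ratio,dia_ratio Fractions of peak amplitude.
#' @return Named numeric vector `c(SBP_hat, DBP_hat)` in mmHg.
#' @export
fixed_ratio_estimate <- function(env, sys_ratio = 0.5, dia_ratio = 0.7) {
  stopifnot(inherits(env, "bp_envelope"))
  beats <- env$beats
  i_peak <- which.max(beats$amp)
  thr_s <- sys_ratio * env$peak_amp
  thr_d <- dia_ratio * env$peak_amp

  # rising side: last crossing of the systolic threshold before the peak
  SBP_hat <- NA_real_
  for (i in seq_len(i_peak - 1L)) {
    lo <- beats$amp[i] < thr_s; hi <- beats$amp[i + 1L] >= thr_s
    if (lo && hi) {
      SBP_hat <- stats::approx(beats$amp[i:(i + 1L)],
                               beats$P_beat[i:(i + 1L)], xout = thr_s)$y
    }
  }
  # falling side: first crossing of the diastolic threshold after the peak
  DBP_hat <- NA_real_
  for (i in seq(i_peak, nrow(beats) - 1L)) {
    hi <- beats$amp[i] >= thr_d; lo <- beats$amp[i + 1L] < thr_d
    if (hi && lo) {
      DBP_hat <- stats::approx(beats$amp[i:(i + 1L)],
                               beats$P_beat[i:(i + 1L)], xout = thr_d)$y
      break
    }
  }
  if (is.na(SBP_hat) || is.na(DBP_hat)) {
    stop("envelope does not cross the fixed-ratio thresholds")
  }
  c(SBP_hat = SBP_hat, DBP_hat = DBP_hat)
}

#' Run the validation suite over a set of scenarios
#'
#' For each scenario: simulate noise-free, filter, extract the envelope,
#' fit the stiffness constants and run the grid-search pressure estimate;
#' also compute the fixed characteristic-ratio baseline for comparison.
#' A failure in one scenario is recorded in its row and does not stop the
#' suite.
#'
#' @param scenarios List of [scenario()] objects (default
#'   [builtin_scenarios()]).
#' @param grid_step Candidate grid spacing, mmHg.
#' @param ... Passed to [simulate_run()].
#' @return A `bp_validation` object: list with `results` (one row per
#'   scenario: truth, estimates, errors, baseline) and `summary` (max
#'   absolute errors and the RMSE of the pressure estimates under two
#'   conventions: `rmse = sqrt(mean(err^2))` and
#'   `rmse_alt = sqrt(sum(err^2))/n`).
#' @export
run_validation <- function(scenarios = builtin_scenarios(), grid_step = 1,
                           ...) {
  stopifnot(length(scenarios) > 0)
  rows <- lapply(scenarios, function(sc) {
    out <- data.frame(
      scenario = sc$name,
      true_SBP = sc$waveform$SBP, true_DBP = sc$waveform$DBP,
      true_a = sc$artery$a, true_b = sc$artery$b,
      SBP_hat = NA_real_, DBP_hat = NA_real_,
      a_hat = NA_real_, b_hat = NA_real_,
      SBP_err = NA_real_, DBP_err = NA_real_,
      ratio_SBP_hat = NA_real_, ratio_DBP_hat = NA_real_,
      error = NA_character_, stringsAsFactors = FALSE
    )
    tryCatch({
      run <- run_scenario(sc, ...)
      est <- estimate_pressures(run$envelope, sc$cuff, grid_step = grid_step)
      out$SBP_hat <- est$SBP_hat; out$DBP_hat <- est$DBP_hat
      out$a_hat <- est$a_hat; out$b_hat <- est$b_hat
      out$SBP_err <- est$SBP_hat - sc$waveform$SBP
      out$DBP_err <- est$DBP_hat - sc$waveform$DBP
      base <- tryCatch(fixed_ratio_estimate(run$envelope),
                       error = function(e) c(NA_real_, NA_real_))
      out$ratio_SBP_hat <- base[1]; out$ratio_DBP_hat <- base[2]
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  err <- c(results$SBP_err, results$DBP_err)
  err <- err[!is.na(err)]
  summary <- list(
    n_scenarios = nrow(results),
    n_failed = sum(!is.na(results$error)),
    max_abs_SBP_err = max(abs(results$SBP_err), na.rm = TRUE),
    max_abs_DBP_err = max(abs(results$DBP_err), na.rm = TRUE),
    rmse = sqrt(mean(err^2)),
    rmse_alt = sqrt(sum(err^2)) / length(err)
  )
  structure(list(results = results, summary = summary),
            class = "bp_validation")
}

#' @export
print.bp_validation <- function(x, ...) {
  cat("Oscillometric estimator validation suite\n")
  print(x$results[, c("scenario", "true_SBP", "true_DBP",
                      "SBP_hat", "DBP_hat", "a_hat", "b_hat")],
        row.names = FALSE, digits = 4)
  cat(sprintf("max |SBP err| = %g, max |DBP err| = %g mmHg; RMSE = %.3g (sqrt(SSE)/n = %.3g)\n",
              x$summary$max_abs_SBP_err, x$summary$max_abs_DBP_err,
              x$summary$rmse, x$summary$rmse_alt))
  invisible(x)
}
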