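#' Simulate an oscillometric cuff deflation run
#'
#' Integrates the coupled cuff-artery system through a deflation run with the
#' forward Euler method. The cuff pressure obeys
#' \deqn{dP/dt = -r + \frac{P_0 + 760 - r t}{V_0} \frac{dV_a}{dt}}
#' where the artery filling rate follows from the chain rule applied to the
#' bi-exponential volume law,
#' \eqn{dV_a/dt = C_a(P_t) (dP_a/dt + r)}, with the compliance branch chosen
#' by the sign of the transmural pressure. The transmural pressure driving
#' the artery uses the smooth deflation ramp `P0 - r*t`: the artery responds
#' to the prevailing difference between blood pressure and cuff pressure,
#' the superimposed sub-mmHg cuff oscillations being negligible by
#' comparison. With no artery (`Va0 = 0`) the run reduces exactly to the
#' linear deflation `P0 - r*t`.
#'
#' Integration runs at a fine internal step `dt` (default 0.5 ms) to resolve
#' the stiff exponential collapse branch under first-order Euler; the stored
#' recording is decimated to `sample_rate`.
#'
#' The bleed valve is modelled as rate-controlled: automatic devices regulate
#' deflation so the smooth (beat-averaged) cuff pressure falls at the nominal
#' rate `r`. The integrated artery term contains, besides the pulsatile
#' oscillations, a slow secular component (the artery steadily fills as the
#' cuff deflates, re-pressurising the cuff by a few mmHg over a run); a
#' constant-rate valve absorbs that component. Accordingly the stored
#' pressure is `P0 - r*t` plus the pulsatile part of the artery contribution,
#' obtained by removing its one-beat moving average.
#'
#' @param artery An [artery_model()].
#' @param cuff A [cuff_model()].
#' @param waveform A [pressure_waveform()].
#' @param duration Run length in seconds. The default 40 s takes a 150 mmHg
#'   cuff to 30 mmHg at the standard 3 mmHg/s bleed rate.
#' @param dt Internal Euler step, seconds. Must satisfy
#'   `dt <= 1/(20 * f)`.
#' @param sample_rate Output sampling rate, Hz. Must be an integer divisor
#'   of `1/dt`.
#' @param noise_sd Standard deviation of optional additive white Gaussian
#'   measurement noise on the stored pressure samples, mmHg. Default 0
#'   (noise-free).
#' @param seed Integer seed for the noise generator; ignored when
#'   `noise_sd = 0`.
#' @return A `bp_recording`: list with fields `t` (s), `P` (gauge cuff
#'   pressure, mmHg), `osc` (filtered oscillations; `NULL` until
#'   [highpass_filter()] is applied), `sample_rate`, and `meta` holding the
#'   scenario parameters.
#' @examples
#' rec <- simulate_run(artery_model(), cuff_model(), pressure_waveform(120, 80))
#' range(rec$P)
#' @export
simulate_run <- function(artery, cuff, waveform,
                         duration = 40, dt = 5e-4, sample_rate = 100,
                         noise_sd = 0, seed = NULL) {
  stopifnot(inherits(artery, "artery_model") || is.null(artery),
            inherits(cuff, "cuff_model"),
            inherits(waveform, "pressure_waveform"))
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")
  if (dt > 1 / (20 * waveform$f)) {
    stop("dt must be at most 1/(20*f) to resolve the waveform harmonics")
  }
  dec <- 1 / (sample_rate * dt)
  if (abs(dec - round(dec)) > 1e-8) {
    stop("sample_rate must be an integer divisor of 1/dt")
  }
  dec <- round(dec)

  P0 <- cuff$P0; r <- cuff$r; V0 <- cuff$V0; Patm <- cuff$P_atm
  n <- floor(duration / dt)
  tt <- (0:n) * dt

  ramp <- P0 - r * tt
  if (is.null(artery) || artery$Va0 == 0) {
    P <- ramp
  } else {
    # artery responds to the smooth deflation, not the sub-mmHg oscillations
    Pt <- waveform_pressure(tt, waveform) - ramp
    Ca <- artery_compliance(Pt, artery)
    dVadt <- Ca * (waveform_derivative(tt, waveform) + r)
    rhs <- -r + (P0 + Patm - r * tt) / V0 * dVadt
    # rhs is independent of the state, so forward Euler is a running sum
    P <- P0 + dt * c(0, cumsum(rhs[-(n + 1)]))
    # rate-controlled valve: keep only the pulsatile part of the artery term
    resid <- P - ramp
    w <- round(1 / (waveform$f * dt))
    if (w %% 2 == 0) w <- w + 1L
    trend <- as.numeric(stats::filter(resid, rep(1 / w, w), sides = 2))
    h <- (w - 1L) %/% 2L
    trend[seq_len(h)] <- trend[h + 1L]
    trend[seq(length(trend) - h + 1L, length(trend))] <- trend[length(trend) - h]
    P <- ramp + (resid - trend)
  }

  if (any(P <= 0)) {
    cut <- which(P <= 0)[1] - 1L
    warning("cuff pressure reached zero at t = ", signif(tt[cut], 4),
            " s; truncating run")
    P <- P[seq_len(cut)]
    tt <- tt[seq_len(cut)]
  }
  if (any(!is.finite(P))) stop("simulation diverged (non-finite cuff pressure)")

  keep <- seq(1L, length(P), by = dec)
  t_out <- tt[keep]
  P_out <- P[keep]

  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    P_out <- P_out + stats::rnorm(length(P_out), sd = noise_sd)
  }

  structure(
    list(
      t = t_out, P = P_out, osc = NULL, sample_rate = sample_rate,
      meta = list(
        SBP = waveform$SBP, DBP = waveform$DBP, f = waveform$f,
        a = if (is.null(artery)) NA_real_ else artery$a,
        b = if (is.null(artery)) NA_real_ else artery$b,
        Va0 = if (is.null(artery)) 0 else artery$Va0,
        V0 = V0, P0 = P0, r = r,
        duration = duration, dt = dt,
        noise_sd = noise_sd, seed = if (is.null(seed)) NA_integer_ else seed
      )
    ),
    class = "bp_recording"
  )
}

#' @export
print.bp_recording <- function(x, ...) {
  cat(sprintf("Oscillometric recording: %d samples at %g Hz (%.4g-%.4g s)\n",
              length(x$t), x$sample_rate, x$t[1], x$t[length(x$t)]))
  cat(sprintf("  cuff pressure %.4g down to %.4g mmHg\n",
              max(x$P), min(x$P)))
  cat(if (is.null(x$osc)) "  oscillations: not yet filtered\n"
      else "  oscillations: filtered\n")
  invisible(x)
}

#' High-pass filter a cuff pressure recording
#'
#' Emulates the analog high-pass filter of an automatic oscillometric
#' instrument by a moving-average subtraction: the oscillation signal at
#' time `t` is the mean cuff pressure over the centred window
#' `[t - dt/2, t + dt/2]`, where `dt` is one beat period, minus the pressure
#' at `t`. A centred full-period mean removes both the linear deflation ramp
#' and the slowly varying baseline while retaining the cardiac-frequency
#' oscillations (sign-inverted). Samples within half a beat period of either
#' end of the record are left undefined (`NA`).
#'
#' The window length in samples is rounded to the nearest odd integer so the
#' window is symmetric; at the default 100 Hz sampling and 80 beats/min the
#' window covers exactly one beat period (75 samples).
#'
#' @param rec A `bp_recording` from [simulate_run()] or [read_recording()].
#' @param beat_period Beat period in seconds; defaults to `1/f` from the
#'   recording metadata.
#' @return The recording with its `osc` field filled in.
#' @export
highpass_filter <- function(rec, beat_period = NULL) {
  stopifnot(inherits(rec, "bp_recording"))
  if (is.null(beat_period)) {
    if (is.null(rec$meta$f) || is.na(rec$meta$f)) {
      stop("beat_period missing and no cardiac frequency in metadata")
    }
    beat_period <- 1 / rec$meta$f
  }
  w <- round(beat_period * rec$sample_rate)
  if (w %% 2 == 0) w <- w + 1L
  if (w > length(rec$P)) stop("recording shorter than one beat period")
  ma <- as.numeric(stats::filter(rec$P, rep(1 / w, w), sides = 2))
  rec$osc <- ma - rec$P
  rec
}

#' Extract the beat-wise oscillation amplitude envelope
#'
#' Segments the filtered oscillation signal into consecutive one-beat
#' windows and records, for each complete beat, the peak-to-trough
#' oscillation amplitude (maximum minus minimum of the filtered signal) and
#' a representative cuff pressure (the mean cuff pressure over the beat).
#' Beats containing any unfiltered (`NA`) samples near the record ends are
#' dropped.
#'
#' Two segmentation modes are available. `"phase"` (default, for simulated
#' data where the waveform phase is known) uses fixed windows
#' `[k/f, (k+1)/f)` from the start of the record. `"zero_crossing"` (for
#' external recordings) segments at ascending zero crossings of the
#' oscillation signal, enforcing a minimum separation of half a beat period.
#'
#' @param rec A filtered `bp_recording` (run [highpass_filter()] first; it
#'   is applied automatically if `osc` is missing and the beat period is
#'   known).
#' @param beat_period Beat period in seconds; defaults to `1/f` from
#'   metadata.
#' @param align Beat segmentation mode, `"phase"` or `"zero_crossing"`.
#' @return A `bp_envelope`: list with `beats` (data frame of `beat`,
#'   `P_beat`, `amp`), `peak_amp` and `P_max` (cuff pressure of the
#'   largest-amplitude beat).
#' @export
extract_envelope <- function(rec, beat_period = NULL,
                             align = c("phase", "zero_crossing")) {
  stopifnot(inherits(rec, "bp_recording"))
  align <- match.arg(align)
  if (is.null(beat_period)) {
    if (is.null(rec$meta$f) || is.na(rec$meta$f)) {
      stop("beat_period missing and no cardiac frequency in metadata")
    }
    beat_period <- 1 / rec$meta$f
  }
  if (is.null(rec$osc)) rec <- highpass_filter(rec, beat_period)

  if (align == "phase") {
    idx <- floor((rec$t - rec$t[1]) / beat_period)
    groups <- split(seq_along(rec$t), idx)
    n_full <- round(beat_period * rec$sample_rate)
    groups <- Filter(function(g) length(g) >= n_full, groups)
  } else {
    groups <- .segment_zero_crossings(rec, beat_period)
  }

  rows <- lapply(groups, function(g) {
    o <- rec$osc[g]
    if (anyNA(o)) return(NULL)
    c(P_beat = mean(rec$P[g]), amp = max(o) - min(o))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) < 3L) stop("fewer than 3 complete beats in recording")
  beats <- data.frame(
    beat = seq_along(rows),
    P_beat = vapply(rows, `[[`, numeric(1), "P_beat"),
    amp = vapply(rows, `[[`, numeric(1), "amp"),
    row.names = NULL
  )
  i_max <- which.max(beats$amp)
  structure(
    list(beats = beats,
         peak_amp = beats$amp[i_max],
         P_max = beats$P_beat[i_max]),
    class = "bp_envelope"
  )
}

#' Build an envelope object from beat-wise data
#'
#' Constructs a `bp_envelope` directly from per-beat cuff pressures and
#' oscillation amplitudes, e.g. for envelope data obtained outside the
#' package or synthesised from the closed-form model.
#'
#' @param P_beat Representative cuff pressure per beat, mmHg, in beat order
#'   (strictly decreasing during a deflation).
#' @param amp Oscillation amplitude per beat, mmHg (non-negative).
#' @return A `bp_envelope`.
#' @export
envelope_from_beats <- function(P_beat, amp) {
  stopifnot(length(P_beat) == length(amp), length(amp) >= 3L,
            all(is.finite(P_beat)), all(amp >= 0))
  beats <- data.frame(beat = seq_along(amp), P_beat = P_beat, amp = amp)
  i_max <- which.max(beats$amp)
  structure(
    list(beats = beats, peak_amp = beats$amp[i_max],
         P_max = beats$P_beat[i_max]),
    class = "bp_envelope"
  )
}

# ascending zero crossings of osc, at least half a beat period apart
.segment_zero_crossings <- function(rec, beat_period) {
  o <- rec$osc
  ok <- which(!is.na(o))
  cross <- ok[-length(ok)][o[ok[-length(ok)]] < 0 & o[ok[-1]] >= 0]
  if (length(cross) < 2L) stop("too few oscillation zero crossings detected")
  min_sep <- 0.5 * beat_period * rec$sample_rate
  keep <- cross[1]
  for (c_i in cross[-1]) {
    if (c_i - keep[length(keep)] >= min_sep) keep <- c(keep, c_i)
  }
  if (length(keep) < 2L) stop("too few oscillation zero crossings detected")
  mapply(function(from, to) seq(from, to - 1L),
         keep[-length(keep)], keep[-1], SIMPLIFY = FALSE)
}

#' @export
print.bp_envelope <- function(x, ...) {
  cat(sprintf("Oscillation envelope: %d beats, peak %.4g mmHg at cuff pressure %.4g mmHg\n",
              nrow(x$beats), x$peak_amp, x$P_max))
  invisible(x)
}
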