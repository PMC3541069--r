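#' Construct an arterial pressure waveform
#'
#' A three-harmonic Fourier series used as the forcing function of the
#' simulator:
#' \deqn{P_a(t) = DBP + 0.5 PP + 0.36 PP (\sin\omega t +
#'   \tfrac12 \sin 2\omega t + \tfrac14 \sin 3\omega t)}
#' with pulse pressure `PP = SBP - DBP` and angular frequency
#' `omega = 2*pi*f`. Its mean over a cardiac cycle is `DBP + 0.5*PP`, the
#' mid-level arterial pressure; its extremes are within about 0.05 mmHg of
#' the nominal SBP and DBP for typical pulse pressures.
#'
#' @param SBP Systolic pressure, mmHg.
#' @param DBP Diastolic pressure, mmHg. Must be below `SBP`.
#' @param f Cardiac frequency in Hz (beats per second). The default 4/3 Hz
#'   corresponds to 80 beats/min.
#' @return An object of class `pressure_waveform` with fields `SBP`, `DBP`,
#'   `PP`, `f` and `omega`.
#' @examples
#' w <- pressure_waveform(120, 80)
#' waveform_pressure(0, w)  # 100 mmHg: the mid-level pressure
#' @export
pressure_waveform <- function(SBP, DBP, f = 80 / 60) {
  stopifnot(is.numeric(SBP), is.numeric(DBP), is.numeric(f))
  if (SBP <= DBP) stop("SBP must exceed DBP")
  if (f <= 0) stop("cardiac frequency must be positive")
  structure(
    list(SBP = SBP, DBP = DBP, PP = SBP - DBP, f = f, omega = 2 * pi * f),
    class = "pressure_waveform"
  )
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf("Arterial pressure waveform: %g/%g mmHg at %.4g beats/min\n",
              x$SBP, x$DBP, 60 * x$f))
  invisible(x)
}

#' Arterial pressure at time t
#'
#' @param t Time in seconds. Vectorised.
#' @param waveform A [pressure_waveform()].
#' @return Arterial pressure in mmHg.
#' @export
waveform_pressure <- function(t, waveform) {
  stopifnot(inherits(waveform, "pressure_waveform"))
  w <- waveform$omega
  waveform$DBP + 0.5 * waveform$PP +
    0.36 * waveform$PP *
      (sin(w * t) + 0.5 * sin(2 * w * t) + 0.25 * sin(3 * w * t))
}

#' Time derivative of the arterial pressure waveform
#'
#' Exact analytic derivative of [waveform_pressure()]:
#' \eqn{0.36 PP \omega (\cos\omega t + \cos 2\omega t +
#' \tfrac34 \cos 3\omega t)}.
#'
#' @inheritParams waveform_pressure
#' @return dPa/dt in mmHg/s.
#' @export
waveform_derivative <- function(t, waveform) {
  stopifnot(inherits(waveform, "pressure_waveform"))
  w <- waveform$omega
  0.36 * waveform$PP * w *
    (cos(w * t) + cos(2 * w * t) + 0.75 * cos(3 * w * t))
}
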