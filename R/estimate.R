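#' Artery volume change over one pulse
#'
#' Volume taken up by the artery segment as transmural pressure swings from
#' its diastolic nadir `Pt` up to `Pt + PP` over one heartbeat. Three
#' transmural-pressure regimes arise during a deflation run:
#' \itemize{
#'   \item Domain 1 (`Pt + PP < 0`): the whole swing is on the collapse
#'     branch — the head of the envelope, cuff pressure above systolic.
#'   \item Domain 2 (`Pt < 0 <= Pt + PP`): the swing straddles zero — cuff
#'     pressure between systolic and diastolic, where oscillations are
#'     largest.
#'   \item Domain 3 (`Pt >= 0`): the whole swing is on the distension
#'     branch — the tail, cuff pressure below diastolic.
#' }
#' Each regime has its own closed form; all three agree with
#' `artery_volume(Pt + PP) - artery_volume(Pt)` and are continuous across
#' the boundaries.
#'
#' @param Pt Transmural pressure at the diastolic nadir, mmHg. Vectorised.
#' @param PP Pulse pressure, mmHg (positive).
#' @param artery An [artery_model()].
#' @return Pulse volume change in ml.
#' @export
pulse_volume <- function(Pt, PP, artery) {
  stopifnot(inherits(artery, "artery_model"))
  if (PP <= 0) stop("pulse pressure must be positive")
  a <- artery$a; b <- artery$b; Va0 <- artery$Va0
  top <- Pt + PP
  out <- numeric(length(Pt))
  d1 <- top < 0
  d2 <- Pt < 0 & top >= 0
  d3 <- Pt >= 0
  out[d1] <- Va0 * (exp(a * top[d1]) - exp(a * Pt[d1]))
  out[d2] <- Va0 * (1 + (a / b) * (1 - exp(-b * top[d2])) - exp(a * Pt[d2]))
  out[d3] <- Va0 * ((a / b) * (1 - exp(-b * top[d3])) -
                      (a / b) * (1 - exp(-b * Pt[d3])))
  out
}

#' Recover artery stiffness constants from an oscillation envelope
#'
#' In the head of the envelope (cuff pressure well above systolic, Domain 1)
#' the beat amplitude is proportional to \eqn{e^{-aP}}, so an ordinary
#' least-squares fit of `log(amp)` on cuff pressure has slope `-a`. In the
#' tail (cuff pressure below diastolic, Domain 3) the amplitude is
#' proportional to \eqn{e^{bP}} and the semi-log slope is `+b`.
#'
#' With `ranges = "height"` (default) the head region runs from the
#' envelope onset — the first rising-side beat reaching `onset_frac` of the
#' peak amplitude, below which beats carry no usable signal — up to the
#' first beat reaching one third of the peak, and the tail region from the
#' last beat at or above two thirds of the peak on the falling side to the
#' end. With `ranges = "inflection"` the regions are bounded instead by the
#' points of maximal (rising) and maximal-negative (falling) envelope slope
#' in the pressure domain; the height thresholds are the deterministic,
#' noise-robust default.
#'
#' @param env A `bp_envelope` from [extract_envelope()].
#' @param ranges Region selection rule, `"height"` or `"inflection"`.
#' @param onset_frac Envelope-onset threshold as a fraction of peak
#'   amplitude; rising-side beats below it are excluded from the head
#'   regression (default 0.10). Set to 0 to regress from the very first
#'   beat.
#' @return List with `a_hat`, `b_hat` (1/mmHg) and `diagnostics`: the
#'   number of beats and pressure range used in each regression, the raw
#'   slopes (`slope1`, `slope3`), the intercepts (`ln_k1`, `ln_k3`), and
#'   the count of non-positive-amplitude beats dropped.
#' @export
fit_stiffness <- function(env, ranges = c("height", "inflection"),
                          onset_frac = 0.10) {
  stopifnot(inherits(env, "bp_envelope"))
  ranges <- match.arg(ranges)
  beats <- env$beats
  usable <- is.finite(beats$amp) & beats$amp > 0
  n_dropped <- sum(!usable)
  beats <- beats[usable, , drop = FALSE]
  if (nrow(beats) < 6L) stop("too few usable beats for stiffness regression")

  peak <- max(beats$amp)
  i_peak <- which.max(beats$amp)

  if (ranges == "height") {
    rising <- beats$amp[seq_len(i_peak)]
    onset <- which(rising >= onset_frac * peak)[1]
    reach <- which(rising >= peak / 3)
    if (length(reach) == 0L) stop("no rising-side beat reaches 1/3 of peak")
    head_idx <- seq(onset, reach[1])
    fall <- seq(i_peak, nrow(beats))
    above <- fall[beats$amp[fall] >= 2 * peak / 3]
    tail_idx <- seq(above[length(above)], nrow(beats))
  } else {
    # bound regions by the envelope's slope extrema in the pressure domain
    dP <- diff(beats$P_beat); dA <- diff(beats$amp)
    slope <- dA / dP                        # P decreases with beat index
    rising <- seq_len(i_peak - 1L)
    head_idx <- seq_len(which.min(slope[rising]))
    falling <- seq(i_peak, nrow(beats) - 1L)
    tail_idx <- seq(falling[which.max(slope[falling])] + 1L, nrow(beats))
  }

  if (length(head_idx) < 3L) {
    stop("head (rising-side) regression range has fewer than 3 beats")
  }
  if (length(tail_idx) < 3L) {
    stop("tail (falling-side) regression range has fewer than 3 beats")
  }

  hd <- beats[head_idx, ]
  tl <- beats[tail_idx, ]
  fit1 <- stats::lm(log(amp) ~ P_beat, data = hd)
  fit3 <- stats::lm(log(amp) ~ P_beat, data = tl)
  s1 <- unname(stats::coef(fit1)[2])
  s3 <- unname(stats::coef(fit3)[2])

  list(
    a_hat = -s1,
    b_hat = s3,
    diagnostics = list(
      n_head = nrow(hd), n_tail = nrow(tl),
      head_P_range = range(hd$P_beat), tail_P_range = range(tl$P_beat),
      slope1 = s1, slope3 = s3,
      ln_k1 = unname(stats::coef(fit1)[1]),
      ln_k3 = unname(stats::coef(fit3)[1]),
      n_dropped = n_dropped, ranges = ranges
    )
  )
}

#' Model-predicted oscillation amplitude at a cuff pressure
#'
#' For candidate systolic/diastolic pressures and fitted stiffness
#' constants, the predicted cuff pressure oscillation amplitude at cuff
#' pressure `P` is the artery pulse volume divided by the cuff compliance:
#' \deqn{\hat y(P) = [V_a(SBP - P) - V_a(DBP - P)] \cdot (P + 760)/V_0.}
#' Absolute scale depends on `Va0/V0`, but only the shape matters once the
#' envelope is amplitude-normalised, so the artery volume is evaluated with
#' unit `Va0`.
#'
#' @param P Cuff pressure, mmHg. Vectorised.
#' @param SBP_test,DBP_test Candidate systolic/diastolic pressures, mmHg.
#' @param a_hat,b_hat Stiffness constants, 1/mmHg.
#' @param cuff Optional [cuff_model()] supplying `V0`; with the default
#'   `NULL`, `V0 = 1` (the factor cancels under normalisation).
#' @return Predicted amplitude (arbitrary units proportional to mmHg).
#' @export
predicted_envelope <- function(P, SBP_test, DBP_test, a_hat, b_hat,
                               cuff = NULL) {
  if (SBP_test <= DBP_test) stop("SBP_test must exceed DBP_test")
  V0 <- if (is.null(cuff)) 1 else cuff$V0
  Patm <- if (is.null(cuff)) 760 else cuff$P_atm
  unit <- artery_model(a = a_hat, b = b_hat, Va0 = 1)
  pulse_volume(DBP_test - P, SBP_test - DBP_test, unit) * (P + Patm) / V0
}

#' Sum-of-squares misfit between observed and predicted envelopes
#'
#' Both envelopes are normalised by their own peak over the observed beats'
#' cuff pressures, so the statistic is independent of `Va0`, `V0` and any
#' overall amplitude scale:
#' \deqn{SS = \sum_{beats} (y/y_{max} - \hat y / \hat y_{max})^2.}
#'
#' @inheritParams predicted_envelope
#' @param env A `bp_envelope`.
#' @return The dimensionless sum of squares; `Inf` if the predicted
#'   envelope is degenerate (zero peak).
#' @export
sum_of_squares <- function(env, SBP_test, DBP_test, a_hat, b_hat,
                           cuff = NULL) {
  stopifnot(inherits(env, "bp_envelope"))
  beats <- env$beats
  if (nrow(beats) == 0L || env$peak_amp <= 0) {
    stop("envelope is empty or has non-positive peak amplitude")
  }
  yhat <- predicted_envelope(beats$P_beat, SBP_test, DBP_test,
                             a_hat, b_hat, cuff)
  yhat_max <- max(yhat)
  if (!is.finite(yhat_max) || yhat_max <= 0) return(Inf)
  sum((beats$amp / env$peak_amp - yhat / yhat_max)^2)
}

#' Estimate systolic and diastolic pressure from an oscillation envelope
#'
#' The full inverse algorithm: stiffness constants are recovered from the
#' envelope by semi-log regression ([fit_stiffness()]), then the
#' sum-of-squares misfit ([sum_of_squares()]) is evaluated over a
#' two-dimensional grid of candidate (DBP, SBP) pairs and the minimiser is
#' returned. Diastolic candidates span from 10 mmHg below the lowest beat
#' pressure up to the envelope peak pressure; systolic candidates from the
#' peak pressure to 10 mmHg above the highest beat pressure (the envelope
#' peak lies between diastolic and systolic pressure, classically at mean
#' arterial pressure). Grid values are integer multiples of `grid_step`.
#' Ties are broken deterministically: smallest pulse pressure
#' `SBP - DBP`, then smallest SBP.
#'
#' @param env A `bp_envelope`.
#' @param cuff Optional [cuff_model()]; only affects the (cancelling)
#'   amplitude scale.
#' @param grid_step Candidate grid spacing, mmHg (default 1).
#' @param expand Margin beyond the observed beat pressure range, mmHg.
#' @param stiffness Optional list with `a_hat` and `b_hat` to reuse a
#'   previous [fit_stiffness()] result.
#' @param ranges Passed to [fit_stiffness()].
#' @return A `bp_estimate`: list with `SBP_hat`, `DBP_hat`, `a_hat`,
#'   `b_hat`, `ss_min`, the full `ss_surface` matrix (rows SBP, columns
#'   DBP), the candidate `grid`, and regression `diagnostics`.
#' @export
estimate_pressures <- function(env, cuff = NULL, grid_step = 1,
                               expand = 10, stiffness = NULL,
                               ranges = "height") {
  stopifnot(inherits(env, "bp_envelope"))
  if (is.null(stiffness)) stiffness <- fit_stiffness(env, ranges = ranges)
  a_hat <- stiffness$a_hat
  b_hat <- stiffness$b_hat
  if (a_hat <= 0 || b_hat <= 0) {
    stop("stiffness regression produced non-positive constants (a_hat = ",
         signif(a_hat, 3), ", b_hat = ", signif(b_hat, 3), ")")
  }

  P <- env$beats$P_beat
  dbp_cand <- seq(ceiling((min(P) - expand) / grid_step) * grid_step,
                  floor(env$P_max / grid_step) * grid_step, by = grid_step)
  sbp_cand <- seq(ceiling(env$P_max / grid_step) * grid_step,
                  floor((max(P) + expand) / grid_step) * grid_step,
                  by = grid_step)
  if (length(dbp_cand) == 0L || length(sbp_cand) == 0L) {
    stop("empty candidate grid: envelope pressure support too narrow")
  }

  ss <- matrix(NA_real_, nrow = length(sbp_cand), ncol = length(dbp_cand),
               dimnames = list(SBP = sbp_cand, DBP = dbp_cand))
  for (j in seq_along(dbp_cand)) {
    for (i in seq_along(sbp_cand)) {
      if (sbp_cand[i] > dbp_cand[j]) {
        ss[i, j] <- sum_of_squares(env, sbp_cand[i], dbp_cand[j],
                                   a_hat, b_hat, cuff)
      }
    }
  }
  if (all(!is.finite(ss))) stop("no feasible candidate pair on the grid")

  feas <- which(is.finite(ss), arr.ind = TRUE)
  vals <- ss[feas]
  best <- feas[vals == min(vals), , drop = FALSE]
  if (nrow(best) > 1L) {
    pp <- sbp_cand[best[, 1]] - dbp_cand[best[, 2]]
    best <- best[order(pp, sbp_cand[best[, 1]])[1], , drop = FALSE]
  }
  SBP_hat <- sbp_cand[best[1, 1]]
  DBP_hat <- dbp_cand[best[1, 2]]

  structure(
    list(SBP_hat = SBP_hat, DBP_hat = DBP_hat,
         a_hat = a_hat, b_hat = b_hat,
         ss_min = min(vals), ss_surface = ss,
         grid = list(SBP = sbp_cand, DBP = dbp_cand, step = grid_step),
         diagnostics = stiffness$diagnostics),
    class = "bp_estimate"
  )
}

#' @export
print.bp_estimate <- function(x, ...) {
  cat("Oscillometric pressure estimate\n")
  cat(sprintf("  SBP/DBP = %g/%g mmHg (SS = %.4g)\n",
              x$SBP_hat, x$DBP_hat, x$ss_min))
  cat(sprintf("  stiffness a = %.4g, b = %.4g /mmHg\n", x$a_hat, x$b_hat))
  invisible(x)
}
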