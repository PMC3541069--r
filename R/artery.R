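#' Derive the collapse-branch stiffness constant from the collapse pressure
#'
#' The artery segment is modelled with a bi-exponential pressure-volume law.
#' On the collapse branch (negative transmural pressure) the volume is
#' \eqn{V_a = V_{a0} e^{a P_t}}. The constant \eqn{a} follows from the
#' collapse pressure \eqn{P_c}, defined as the (negative) transmural pressure
#' at which the segment volume has fallen to 10\% of its zero-pressure
#' volume: \eqn{a = \ln(0.1) / P_c}.
#'
#' @param Pc Collapse pressure in mmHg. Must be strictly negative.
#' @return Stiffness constant `a` in 1/mmHg (positive).
#' @examples
#' derive_a(-20)   # approximately 0.115, printed as 0.11 to 2 s.f.
#' @export
derive_a <- function(Pc) {
  stopifnot(is.numeric(Pc), length(Pc) == 1L, is.finite(Pc))
  if (Pc >= 0) {
    stop("collapse pressure `Pc` must be negative (got ", Pc, ")")
  }
  log(0.1) / Pc
}

#' Derive the distension-branch stiffness constant from mid-pressure compliance
#'
#' On the distension branch (non-negative transmural pressure) the dynamic
#' compliance is \eqn{dV_a/dP_t = a V_{a0} e^{-b P_t}}. Given the measured
#' compliance \eqn{C_n} at a mid-level arterial pressure \eqn{P_{mid}}
#' (halfway between systolic and diastolic), the constant is
#' \eqn{b = -\ln(C_n / (a V_{a0})) / P_{mid}}.
#'
#' @param Cn Compliance at mid-level pressure, ml/mmHg. Must satisfy
#'   `0 < Cn < a * Va0` for a positive `b`.
#' @param a Collapse-branch stiffness constant, 1/mmHg.
#' @param Va0 Artery segment volume at zero transmural pressure, ml.
#' @param Pmid Mid-level arterial pressure, mmHg (positive).
#' @return Stiffness constant `b` in 1/mmHg (positive).
#' @examples
#' derive_b(0.0016, 0.11, 0.3, 100)  # approximately 0.030
#' @export
derive_b <- function(Cn, a, Va0, Pmid) {
  stopifnot(is.numeric(Cn), is.numeric(a), is.numeric(Va0), is.numeric(Pmid))
  if (Cn <= 0 || a <= 0 || Va0 <= 0 || Pmid <= 0) {
    stop("`Cn`, `a`, `Va0` and `Pmid` must all be positive")
  }
  if (Cn >= a * Va0) {
    stop("`Cn` must be smaller than a*Va0 = ", a * Va0,
         " for a positive distension constant")
  }
  -log(Cn / (a * Va0)) / Pmid
}

#' Construct a bi-exponential artery segment model
#'
#' Represents the compressed artery segment under the cuff. Volume follows
#' one exponential branch for collapse (transmural pressure `Pt < 0`) and a
#' decelerating exponential branch for distension (`Pt >= 0`), continuous in
#' both volume and compliance at `Pt = 0`.
#'
#' If `a` or `b` is `NULL` it is derived from the physiologic inputs:
#' `a` from the collapse pressure `Pc` via [derive_a()], and `b` from the
#' mid-pressure compliance `Cn` via [derive_b()]. The standard normal values
#' used throughout the validation suite are `a = 0.11`, `b = 0.03` per mmHg
#' with `Va0 = 0.3` ml.
#'
#' @param a Collapse-branch stiffness constant, 1/mmHg, or `NULL` to derive.
#' @param b Distension-branch stiffness constant, 1/mmHg, or `NULL` to derive.
#' @param Va0 Zero-pressure segment volume, ml.
#' @param Pc Collapse pressure, mmHg (negative); used when `a` is `NULL`.
#' @param Cn Mid-pressure compliance, ml/mmHg; used when `b` is `NULL`.
#' @param Pmid Mid-level arterial pressure, mmHg; used when `b` is `NULL`.
#' @return An object of class `artery_model`.
#' @examples
#' artery_model()                      # standard normal artery
#' artery_model(a = NULL, b = NULL)    # constants derived from Pc, Cn, Pmid
#' @export
artery_model <- function(a = 0.11, b = 0.03, Va0 = 0.3,
                         Pc = -20, Cn = 0.0016, Pmid = 100) {
  if (is.null(a)) a <- derive_a(Pc)
  if (is.null(b)) b <- derive_b(Cn, a, Va0, Pmid)
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(Va0),
            length(a) == 1L, length(b) == 1L, length(Va0) == 1L)
  if (a <= 0 || b <= 0 || Va0 <= 0) {
    stop("artery model requires a > 0, b > 0, Va0 > 0")
  }
  structure(
    list(a = a, b = b, Va0 = Va0, Pc = Pc, Cn = Cn, Pmid = Pmid),
    class = "artery_model"
  )
}

#' @export
print.artery_model <- function(x, ...) {
  cat("Bi-exponential artery segment model\n")
  cat(sprintf("  a   = %.5g /mmHg (collapse branch)\n", x$a))
  cat(sprintf("  b   = %.5g /mmHg (distension branch)\n", x$b))
  cat(sprintf("  Va0 = %.4g ml (zero-pressure volume)\n", x$Va0))
  invisible(x)
}

#' Artery segment volume at a transmural pressure
#'
#' Evaluates the bi-exponential pressure-volume law:
#' \eqn{V_a = V_{a0} e^{a P_t}} for \eqn{P_t < 0} and
#' \eqn{V_a = V_{a0} (1 + (a/b)(1 - e^{-b P_t}))} for \eqn{P_t \ge 0}.
#' The two branches meet continuously at `Pt = 0` with value `Va0`; the
#' distension branch saturates at `Va0 * (1 + a/b)`.
#'
#' @param Pt Transmural pressure (arterial minus cuff), mmHg. Vectorised.
#' @param artery An [artery_model()].
#' @return Volume in ml, same length as `Pt`.
#' @export
artery_volume <- function(Pt, artery) {
  stopifnot(inherits(artery, "artery_model"))
  a <- artery$a; b <- artery$b; Va0 <- artery$Va0
  ifelse(Pt < 0,
         Va0 * exp(a * Pt),
         Va0 * (1 + (a / b) * (1 - exp(-b * Pt))))
}

#' Dynamic compliance of the artery segment
#'
#' The derivative of [artery_volume()] with respect to transmural pressure:
#' \eqn{a V_{a0} e^{a P_t}} for \eqn{P_t < 0} and
#' \eqn{a V_{a0} e^{-b P_t}} for \eqn{P_t \ge 0}. Both branches equal
#' `a * Va0` at `Pt = 0`, so the compliance is continuous across collapse
#' and distension.
#'
#' @inheritParams artery_volume
#' @return Compliance dVa/dPt in ml/mmHg, same length as `Pt`.
#' @export
artery_compliance <- function(Pt, artery) {
  stopifnot(inherits(artery, "artery_model"))
  a <- artery$a; b <- artery$b; Va0 <- artery$Va0
  ifelse(Pt < 0,
         a * Va0 * exp(a * Pt),
         a * Va0 * exp(-b * Pt))
}
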