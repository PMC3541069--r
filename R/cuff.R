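#' Construct a pneumatic cuff model
#'
#' After inflation the outer cuff wall is effectively rigid, so the cuff's
#' compliance comes entirely from the sealed air it contains and follows from
#' Boyle's law. `V0` is the cuff air volume between heartbeats; the default
#' 300 ml corresponds to a 30 cm x 10 cm x 1 cm adult arm cuff. The cuff is
#' inflated to `P0` (gauge mmHg) and vented through a bleed valve at a
#' constant rate `r`.
#'
#' @param V0 Cuff air volume, ml.
#' @param P0 Cuff pressure at the onset of deflation, mmHg gauge.
#' @param r Deflation (bleed) rate, mmHg/s.
#' @return An object of class `cuff_model`. The atmospheric offset is fixed
#'   at 760 mmHg.
#' @examples
#' cuff_model()  # 300 ml cuff, 150 mmHg start, 3 mmHg/s bleed
#' @export
cuff_model <- function(V0 = 300, P0 = 150, r = 3) {
  stopifnot(is.numeric(V0), is.numeric(P0), is.numeric(r))
  if (V0 <= 0 || P0 <= 0 || r <= 0) {
    stop("cuff model requires V0 > 0, P0 > 0, r > 0")
  }
  structure(list(V0 = V0, P0 = P0, r = r, P_atm = 760), class = "cuff_model")
}

#' @export
print.cuff_model <- function(x, ...) {
  cat("Pneumatic cuff model\n")
  cat(sprintf("  V0 = %.4g ml, P0 = %.4g mmHg, r = %.4g mmHg/s\n",
              x$V0, x$P0, x$r))
  invisible(x)
}

#' Dynamic compliance of the sealed cuff
#'
#' From Boyle's law for the fixed mass of air in the cuff over one heartbeat,
#' \eqn{C_{cuff} = V_0 / (P + 760)} for gauge cuff pressure `P` in mmHg.
#' The cuff becomes more compliant as it deflates.
#'
#' @param P Gauge cuff pressure, mmHg. Vectorised. Must exceed -760.
#' @param cuff A [cuff_model()].
#' @return Compliance in ml/mmHg.
#' @export
cuff_compliance <- function(P, cuff) {
  stopifnot(inherits(cuff, "cuff_model"))
  if (any(P <= -cuff$P_atm)) {
    stop("absolute cuff pressure must be positive (gauge P > -760 mmHg)")
  }
  cuff$V0 / (P + cuff$P_atm)
}
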