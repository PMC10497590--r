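#' Spoiled gradient-echo (SPGR) steady-state signal
#'
#' Ernst steady-state magnitude signal of a spoiled gradient-recalled echo
#' acquisition, with mono-exponential T2* decay at the echo time:
#' \deqn{S = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha}
#'       e^{-TE \cdot R_2^*}, \qquad E_1 = e^{-TR \cdot R_1}.}
#'
#' @param m0 Equilibrium magnetization (arbitrary units).
#' @param flip_deg Nominal flip angle in degrees, in (0, 90].
#' @param tr_ms Repetition time, ms.
#' @param r1 Longitudinal relaxation rate, s\eqn{^{-1}}.
#' @param te_ms Echo time, ms (default 0: no transverse decay).
#' @param r2star Effective transverse relaxation rate, s\eqn{^{-1}}.
#' @param b1 Transmit-field factor scaling the achieved flip angle
#'   (1 = nominal).
#' @return Signal in the units of \code{m0}. Vectorised over any argument.
#' @examples
#' spgr_signal(1000, flip_deg = 30, tr_ms = 19, r1 = 1)  # ~62.6
#' @export
spgr_signal <- function(m0, flip_deg, tr_ms, r1, te_ms = 0, r2star = 0,
                        b1 = 1) {
  if (any(flip_deg <= 0) || any(flip_deg > 90))
    stop("flip angle must be in (0, 90] degrees")
  if (any(tr_ms <= 0)) stop("TR must be positive")
  a <- b1 * flip_deg * pi / 180
  e1 <- exp(-(tr_ms / 1000) * r1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a)) * exp(-(te_ms / 1000) * r2star)
}

#' Inversion-recovery signal (magnitude)
#'
#' Forward model for a spin-echo inversion-recovery acquisition used as the
#' gold-standard R1 reference for B1+ calibration:
#' \deqn{S = |M_0 (1 - (1 + \epsilon) e^{-TI \cdot R_1})|}
#' with inversion efficiency \eqn{\epsilon} (1 = ideal adiabatic pulse).
#'
#' @param m0 Equilibrium magnetization.
#' @param ti_ms Inversion time, ms; non-negative.
#' @param r1 Longitudinal relaxation rate, s\eqn{^{-1}}.
#' @param inv_efficiency Inversion efficiency in [0, 1]; default 1.
#' @return Magnitude signal; vectorised.
#' @examples
#' ir_signal(100, ti_ms = 500, r1 = 1)  # ~21.3
#' ir_signal(100, ti_ms = 1000 * log(2), r1 = 1)  # null point, ~0
#' @export
ir_signal <- function(m0, ti_ms, r1, inv_efficiency = 1) {
  if (any(ti_ms < 0)) stop("TI must be non-negative")
  if (any(inv_efficiency < 0) || any(inv_efficiency > 1))
    stop("inversion efficiency must be in [0, 1]")
  abs(m0 * (1 - (1 + inv_efficiency) * exp(-(ti_ms / 1000) * r1)))
}
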