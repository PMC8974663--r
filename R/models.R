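# Lumped-parameter models of aortic input impedance.
#
# FWK2 replaces the ideal capacitor of the two-element Windkessel with a
# fractional-order capacitor (constant-phase element) of impedance
# 1 / (C_alpha * (j*w)^alpha), 0 < alpha <= 1, so that
#   Z_fwk2(w) = Rp / (1 + Rp * C_alpha * (j*w)^alpha).
# (j*w)^alpha is evaluated on the principal branch, w^alpha * exp(j*alpha*pi/2);
# negative frequencies are never evaluated directly (conjugate symmetry is the
# caller's responsibility).

check_omega <- function(omega, allow_zero = TRUE) {
  if (any(!is.finite(omega))) abort_fracwk("omega must be finite", "precondition")
  if (allow_zero) {
    if (any(omega < 0)) abort_fracwk("omega must be >= 0", "precondition")
  } else {
    if (any(omega <= 0)) abort_fracwk("omega must be > 0", "precondition")
  }
  invisible(omega)
}

# (j*w)^alpha on the principal branch; exact jw for alpha == 1 so that the
# integer-order models are reproduced to machine precision.
s_alpha <- function(omega, alpha) {
  if (alpha == 1) return(1i * omega)
  omega^alpha * exp(1i * alpha * pi / 2)
}

#' Fractional-order two-element Windkessel impedance
#'
#' `Z(w) = Rp / (1 + Rp * C_alpha * (j*w)^alpha)`, the input impedance of a
#' peripheral resistance in parallel with a fractional-order capacitor. At
#' `w = 0` it returns `Rp` exactly; with `alpha = 1` it reduces to the
#' classical two-element Windkessel.
#'
#' @param omega Angular frequency (rad/s), vectorized, `>= 0`.
#' @param rp Peripheral resistance (mmHg s/ml), `> 0`.
#' @param c_alpha Pseudo-capacitance (ml/mmHg/s^(1-alpha)), `> 0`.
#' @param alpha Fractional differentiation order, `> 0` (physiological range
#'   0--1; `alpha = 1` is the ideal capacitor).
#' @return Complex impedance (mmHg s/ml), same length as `omega`.
#' @export
#' @examples
#' impedance_fwk2(c(0, 1, 2 * pi), rp = 1.2, c_alpha = 1, alpha = 0.6)
impedance_fwk2 <- function(omega, rp, c_alpha, alpha) {
  stopifnot(rp > 0, c_alpha > 0, alpha > 0)
  check_omega(omega)
  rp / (1 + rp * c_alpha * s_alpha(omega, alpha))
}

#' Two-element Windkessel impedance
#'
#' `Z(w) = Rp / (1 + j*w*Rp*C)`: peripheral resistance in parallel with an
#' ideal capacitor.
#'
#' @inheritParams impedance_fwk2
#' @param c Total arterial compliance (ml/mmHg), `> 0`.
#' @return Complex impedance, same length as `omega`.
#' @export
impedance_wk2 <- function(omega, rp, c) {
  stopifnot(rp > 0, c > 0)
  check_omega(omega)
  rp / (1 + 1i * omega * rp * c)
}

#' Three-element Windkessel impedance
#'
#' `Z(w) = Zc + Rp / (1 + j*w*Rp*C)`: a characteristic impedance in series
#' with the two-element cell. The DC value is `Zc + Rp`.
#'
#' @inheritParams impedance_wk2
#' @param zc Characteristic impedance (mmHg s/ml), `> 0`.
#' @return Complex impedance, same length as `omega`.
#' @export
impedance_wk3 <- function(omega, zc, rp, c) {
  stopifnot(zc > 0, rp > 0, c > 0)
  check_omega(omega)
  zc + rp / (1 + 1i * omega * rp * c)
}

#' Viscoelastic Windkessel impedance
#'
#' Peripheral resistance in parallel with a Voigt cell (dashpot resistance
#' `Rd` in series with a static compliance `C_vw`):
#' `Z(w) = Rp * (1 + j*w*Rd*C_vw) / (1 + j*w*(Rp + Rd)*C_vw)`. The DC value
#' is `Rp`. With matched coefficients this is the same one-zero/one-pole
#' family as the three-element Windkessel.
#'
#' @inheritParams impedance_wk2
#' @param rd Voigt dashpot resistance (mmHg s/ml), `> 0`.
#' @param c_vw Static compliance (ml/mmHg), `> 0`.
#' @return Complex impedance, same length as `omega`.
#' @export
impedance_vwk <- function(omega, rp, rd, c_vw) {
  stopifnot(rp > 0, rd > 0, c_vw > 0)
  check_omega(omega)
  # parallel combination of Rp with (Rd + 1/(j*w*C_vw))
  rp * (1 + 1i * omega * rd * c_vw) / (1 + 1i * omega * (rp + rd) * c_vw)
}

#' Evaluate any supported model's impedance
#'
#' Dispatcher over the four model tags with parameters given as a named list:
#' `fwk2` needs `rp, c_alpha, alpha`; `wk2` needs `rp, c`; `wk3` needs
#' `zc, rp, c`; `vwk` needs `rp, rd, c_vw`.
#'
#' @param omega Angular frequency (rad/s), vectorized.
#' @param model One of `"fwk2"`, `"wk2"`, `"wk3"`, `"vwk"`.
#' @param params Named list of physical parameters for `model`.
#' @return Complex impedance, same length as `omega`.
#' @export
model_impedance <- function(omega, model, params) {
  switch(match.arg(model, wk_models()),
    fwk2 = impedance_fwk2(omega, params$rp, params$c_alpha, params$alpha),
    wk2 = impedance_wk2(omega, params$rp, params$c),
    wk3 = impedance_wk3(omega, params$zc, params$rp, params$c),
    vwk = impedance_vwk(omega, params$rp, params$rd, params$c_vw)
  )
}

#' Supported Windkessel model tags
#' @return Character vector of model tags.
#' @export
wk_models <- function() c("fwk2", "wk2", "wk3", "vwk")

#' Closed-form FWK2 impedance modulus and phase
#'
#' Evaluates the fractional one-pole transfer function
#' `H(w) = G / (1 + tau_alpha * (j*w)^alpha)` in polar form:
#' \deqn{|H| = G / \sqrt{[1 + w^a \tau \cos(a\pi/2)]^2 + [w^a \tau \sin(a\pi/2)]^2}}
#' with phase the negated four-quadrant arctangent of
#' `w^a tau sin(a pi/2)` over `1 + w^a tau cos(a pi/2)`. For
#' `alpha` in (0, 1] the phase lies in `(-alpha*pi/2, 0]`; at `w = 0` the
#' modulus is `G` and the phase 0.
#'
#' @param omega Angular frequency (rad/s), vectorized, `>= 0`.
#' @param gain DC gain `G` (mmHg s/ml), `> 0`.
#' @param tau_alpha Fractional time constant `tau_alpha = Rp * C_alpha`
#'   (s^alpha), `> 0`.
#' @param alpha Fractional order, `> 0`.
#' @return Tibble with columns `omega`, `modulus`, `phase_rad`.
#' @export
fwk2_modulus_phase <- function(omega, gain, tau_alpha, alpha) {
  stopifnot(gain > 0, tau_alpha > 0, alpha > 0)
  check_omega(omega)
  wa <- omega^alpha * tau_alpha
  re_den <- 1 + wa * cos(alpha * pi / 2)
  im_den <- wa * sin(alpha * pi / 2)
  tibble(
    omega = omega,
    modulus = gain / sqrt(re_den^2 + im_den^2),
    phase_rad = -atan2(im_den, re_den)
  )
}

#' Dynamic compliance of the fractional-order capacitor
#'
#' The pseudo-capacitance translates into an equivalent ordinary capacitance
#' that is complex and frequency-dependent:
#' `C_F(w) = C_alpha * w^beta * [cos(beta*pi/2) + j*sin(beta*pi/2)]` with
#' `beta = alpha - 1`. Its modulus follows a power law `w^(alpha-1)`,
#' decreasing with frequency for `alpha < 1`; at `alpha = 1` it reduces to
#' the real, frequency-independent `C_alpha`.
#'
#' @param omega Angular frequency (rad/s), `> 0` when `alpha < 1` (the power
#'   law is singular at DC).
#' @param c_alpha Pseudo-capacitance, `> 0`.
#' @param alpha Fractional order, `> 0`.
#' @return Complex capacitance (ml/mmHg), same length as `omega`.
#' @export
foc_compliance <- function(omega, c_alpha, alpha) {
  stopifnot(c_alpha > 0, alpha > 0)
  if (alpha == 1) {
    check_omega(omega)
    return(rep(complex(real = c_alpha), length(omega)))
  }
  if (any(omega == 0)) {
    abort_fracwk("FOC compliance has a power-law singularity at omega = 0 for alpha < 1", "domain")
  }
  check_omega(omega, allow_zero = FALSE)
  beta <- alpha - 1
  c_alpha * omega^beta * complex(real = cos(beta * pi / 2), imaginary = sin(beta * pi / 2))
}

#' Dynamic compliance of the Voigt cell
#'
#' `C_c(w) = C_vw / (1 + j*w*Rd*C_vw)`: the series resistance makes the
#' apparent compliance complex and frequency-dependent; at `w = 0` (or
#' `Rd -> 0`) it is the static compliance `C_vw`.
#'
#' @param omega Angular frequency (rad/s), `>= 0`.
#' @param c_vw Static compliance (ml/mmHg), `> 0`.
#' @param rd Dashpot resistance (mmHg s/ml), `>= 0` (`rd = 0` is the
#'   ideal-capacitor limit, reached e.g. by boundary fits of purely elastic
#'   data).
#' @return Complex compliance (ml/mmHg), same length as `omega`.
#' @export
voigt_compliance <- function(omega, c_vw, rd) {
  stopifnot(c_vw > 0, rd >= 0)
  check_omega(omega)
  c_vw / (1 + 1i * omega * rd * c_vw)
}

#' Impedance of an identifiable transfer function
#'
#' Evaluates the observational (coefficient) form shared by all four models:
#' `H(w) = G * (1 + a1 * j*w) / (1 + b1 * (j*w)^alpha)`, with `a1 = 0` for
#' the one-pole forms (FWK2, WK2) and `alpha = 1` for the integer-order
#' models (WK2, WK3, VWK).
#'
#' @param omega Angular frequency (rad/s), vectorized, `>= 0`.
#' @param coeffs Named list with `gain`, `a1`, `b1`, `alpha`.
#' @return Complex impedance, same length as `omega`.
#' @export
tf_impedance <- function(omega, coeffs) {
  check_omega(omega)
  coeffs$gain * (1 + coeffs$a1 * 1i * omega) / (1 + coeffs$b1 * s_alpha(omega, coeffs$alpha))
}
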