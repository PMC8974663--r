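# Calibration of Windkessel impedance models against an empirical spectrum.
#
# All models share the identifiable form H(w) = G (1 + a1 jw)/(1 + b1 (jw)^a).
# The gain G is fixed to the DC impedance (mean pressure over mean flow) and
# never optimized; the remaining observational coefficients are estimated by
# bounded Levenberg-Marquardt on the gain-normalized residual vector, whose
# root-sum-square is exactly the NRMSE objective reported in the metrics.

as_z <- function(x) {
  if (is.complex(x)) x else spectrum_z(x)
}

#' DC gain of an impedance spectrum
#'
#' `G = Z(0)`, the ratio of mean pressure to mean flow — the total peripheral
#' resistance. The gain is fixed by this identity during fitting, never
#' optimized.
#'
#' @param spectrum An impedance spectrum tibble (harmonic 0 first) or a
#'   complex vector whose first element is `Z(0)`.
#' @return Positive scalar gain (mmHg s/ml).
#' @export
compute_gain <- function(spectrum) {
  z0 <- as_z(spectrum)[1]
  g <- Re(z0)
  if (!is.finite(g) || g <= 0) {
    abort_fracwk("DC impedance (gain) must be positive and finite", "data")
  }
  g
}

#' Normalized root mean square error between impedance spectra
#'
#' The calibration objective: the square root of the summed squared real- and
#' imaginary-part residuals over harmonics 0..N, divided by `(N+1) * G`. The
#' divisor sits outside the radical, so this is a gain-normalized
#' root-sum-square, not an RMS; published magnitudes (~1e-2) depend on this
#' convention.
#'
#' @param observed Impedance spectrum tibble or complex vector (harmonics 0..N).
#' @param predicted Model-predicted spectrum or complex vector, same length.
#' @param gain Normalizing DC gain `G > 0`.
#' @return Non-negative scalar.
#' @export
nrmse <- function(observed, predicted, gain) {
  z <- as_z(observed)
  zh <- as_z(predicted)
  if (length(z) != length(zh)) {
    abort_fracwk("observed and predicted spectra must have the same harmonic count", "usage")
  }
  stopifnot(gain > 0)
  n1 <- length(z)
  sqrt(sum((Re(z) - Re(zh))^2 + (Im(z) - Im(zh))^2)) / (n1 * gain)
}

#' Per-harmonic modulus deviations
#'
#' `D_i = (|Zhat_i| - |Z_i|) / |Z_i| * 100` for each retained harmonic. When
#' the gain is fixed to `Z(0)`, `D_0` is identically zero.
#'
#' @inheritParams nrmse
#' @return Tibble with columns `harmonic` (0..N) and `d_pct`.
#' @export
harmonic_deviations <- function(observed, predicted) {
  z <- Mod(as_z(observed))
  zh <- Mod(as_z(predicted))
  if (length(z) != length(zh)) {
    abort_fracwk("observed and predicted spectra must have the same harmonic count", "usage")
  }
  if (any(z == 0)) abort_fracwk("zero impedance modulus at a retained harmonic", "degenerate")
  tibble(harmonic = seq_along(z) - 1L, d_pct = (zh - z) / z * 100)
}

#' Mean modulus deviation
#'
#' Arithmetic mean of the per-harmonic deviations `D_i` over harmonics 0..N
#' (divisor `N+1`).
#'
#' @inheritParams nrmse
#' @return Scalar percentage.
#' @export
deviation <- function(observed, predicted) {
  mean(harmonic_deviations(observed, predicted)$d_pct)
}

#' L2 relative errors of impedance modulus and phase
#'
#' `100 * ||x - xhat||_2 / ||x||_2` computed separately for the modulus
#' vector and the phase vector over harmonics 0..N. Phases are principal
#' values in radians by default; set `unwrap = TRUE` to remove 2*pi jumps
#' before the norm, or `degrees = TRUE` to convert (the ratio is unaffected
#' by a pure unit change).
#'
#' @inheritParams nrmse
#' @param degrees Convert phases to degrees before the norm.
#' @param unwrap Unwrap phase sequences before the norm.
#' @return One-row tibble with `re_moduli_pct` and `re_phase_pct`;
#'   `re_phase_pct` is `NA` when the observed phase vector has zero norm
#'   (all-real spectrum), an undefined-phase sentinel rather than an error.
#' @export
relative_errors <- function(observed, predicted, degrees = FALSE, unwrap = FALSE) {
  z <- as_z(observed)
  zh <- as_z(predicted)
  if (length(z) != length(zh)) {
    abort_fracwk("observed and predicted spectra must have the same harmonic count", "usage")
  }
  mod_z <- Mod(z)
  mod_zh <- Mod(zh)
  if (sum(mod_z^2) == 0) abort_fracwk("zero-norm modulus vector", "degenerate")
  re_mod <- 100 * sqrt(sum((mod_z - mod_zh)^2)) / sqrt(sum(mod_z^2))
  ph_z <- wrap_phase(Arg(z))
  ph_zh <- wrap_phase(Arg(zh))
  if (unwrap) {
    ph_z <- unwrap_phase(ph_z)
    ph_zh <- unwrap_phase(ph_zh)
  }
  if (degrees) {
    ph_z <- ph_z * 180 / pi
    ph_zh <- ph_zh * 180 / pi
  }
  denom <- sqrt(sum(ph_z^2))
  re_ph <- if (denom == 0) NA_real_ else 100 * sqrt(sum((ph_z - ph_zh)^2)) / denom
  tibble(re_moduli_pct = re_mod, re_phase_pct = re_ph)
}

#' Full goodness-of-fit metric suite
#'
#' NRMSE, L2 relative errors of moduli and phase, and mean modulus deviation
#' for an (observed, predicted) spectrum pair.
#'
#' @inheritParams nrmse
#' @inheritParams relative_errors
#' @return One-row tibble with `nrmse`, `re_moduli_pct`, `re_phase_pct`,
#'   `deviation_pct`.
#' @export
impedance_metrics <- function(observed, predicted, gain,
                              degrees = FALSE, unwrap = FALSE) {
  dplyr::bind_cols(
    tibble(nrmse = nrmse(observed, predicted, gain)),
    relative_errors(observed, predicted, degrees = degrees, unwrap = unwrap),
    tibble(deviation_pct = deviation(observed, predicted))
  )
}

#' Map physical parameters to observational transfer-function coefficients
#'
#' Forward maps: FWK2 `G = Rp, b1 = tau_alpha = Rp*C_alpha`; WK2
#' `G = Rp, b1 = Rp*C`; WK3 `G = Zc + Rp, b1 = Rp*C, a1 = Zc*Rp*C/(Zc+Rp)`;
#' VWK `G = Rp, a1 = Rd*C_vw, b1 = (Rp+Rd)*C_vw`.
#'
#' @param model Model tag.
#' @param params Named list of physical parameters (see [model_impedance()]).
#' @return Named list `gain, a1, b1, alpha`.
#' @export
coeffs_from_params <- function(model, params) {
  switch(match.arg(model, wk_models()),
    fwk2 = list(
      gain = params$rp, a1 = 0,
      b1 = params$rp * params$c_alpha, alpha = params$alpha
    ),
    wk2 = list(gain = params$rp, a1 = 0, b1 = params$rp * params$c, alpha = 1),
    wk3 = list(
      gain = params$zc + params$rp,
      a1 = params$zc * params$rp * params$c / (params$zc + params$rp),
      b1 = params$rp * params$c, alpha = 1
    ),
    vwk = list(
      gain = params$rp, a1 = params$rd * params$c_vw,
      b1 = (params$rp + params$rd) * params$c_vw, alpha = 1
    )
  )
}

#' Extract physical parameters from fitted coefficients
#'
#' Inverse maps of [coeffs_from_params()]: FWK2 `Rp = G, C_alpha = b1/G,
#' alpha = alpha`; WK2 `Rp = G, C = b1/G`; WK3 `Zc = G*a1/b1, Rp = G - Zc,
#' C = b1/Rp`; VWK `Rp = G, C_vw = (b1 - a1)/G, Rd = a1/C_vw`. The zero-pole
#' models are realizable only when `a1 < b1` (the zero must lie above the
#' pole); a violation raises a non-physical-parameter error so the caller
#' can retain the fit while flagging the extraction.
#'
#' @param model Model tag.
#' @param coeffs Named list `gain, a1, b1, alpha` (positive).
#' @return Named list of physical parameters.
#' @export
params_from_coeffs <- function(model, coeffs) {
  g <- coeffs$gain
  a1 <- coeffs$a1 %||% 0
  b1 <- coeffs$b1
  switch(match.arg(model, wk_models()),
    fwk2 = list(rp = g, c_alpha = b1 / g, alpha = coeffs$alpha),
    wk2 = list(rp = g, c = b1 / g),
    wk3 = {
      if (a1 >= b1) {
        abort_fracwk("WK3 realizability violated: requires a1 < b1 (Zc < G)", "nonphysical")
      }
      zc <- g * a1 / b1
      rp <- g - zc
      list(zc = zc, rp = rp, c = b1 / rp)
    },
    vwk = {
      if (a1 >= b1) {
        abort_fracwk("VWK realizability violated: requires a1 < b1", "nonphysical")
      }
      c_vw <- (b1 - a1) / g
      list(rp = g, rd = a1 / c_vw, c_vw = c_vw)
    }
  )
}

#' Calibration configuration
#'
#' @param n_harmonics Harmonic count for the spectrum (default 20).
#' @param multistart Number of deterministic initial points (>= 1; default 3).
#' @param alpha_starts Initial fractional orders tried for FWK2.
#' @param alpha_upper Upper bound on alpha during fitting (default
#'   unconstrained; the lower bound is always 0).
#' @param max_iter Maximum optimizer iterations per start.
#' @param ftol,ptol Objective / parameter convergence tolerances of the
#'   Levenberg-Marquardt steps.
#' @param seed Integer seed for any randomized start perturbations.
#' @return A list of class `fracwk_fit_config`.
#' @export
fit_config <- function(n_harmonics = 20, multistart = 3,
                       alpha_starts = c(0.3, 0.5, 0.8),
                       alpha_upper = Inf, max_iter = 400,
                       ftol = 1e-14, ptol = 1e-14, seed = 1L) {
  stopifnot(n_harmonics >= 1, multistart >= 1)
  structure(
    list(
      n_harmonics = n_harmonics, multistart = multistart,
      alpha_starts = alpha_starts, alpha_upper = alpha_upper,
      max_iter = max_iter, ftol = ftol, ptol = ptol, seed = seed
    ),
    class = "fracwk_fit_config"
  )
}

# First-harmonic moment match for the WK2 time constant: 1/Z1 = (1 + jw1 tau)/G.
estimate_tau0 <- function(z, omega, gain) {
  if (length(z) < 2) return(1)
  tau0 <- gain * Im(1 / z[2]) / omega[2]
  if (!is.finite(tau0) || tau0 <= 0) 1 else tau0
}

# Deterministic multistart grid per model family.
default_starts <- function(model, tau0, config) {
  scales <- c(1, 0.3, 3, 0.1, 10)
  starts <- switch(model,
    fwk2 = {
      grid <- expand.grid(alpha = config$alpha_starts, scale = scales)
      lapply(seq_len(nrow(grid)), function(i) {
        c(b1 = tau0 * grid$scale[i], alpha = grid$alpha[i])
      })
    },
    wk2 = lapply(scales, function(s) c(b1 = tau0 * s)),
    lapply(c(0.05, 0.1, 0.02, 0.2, 0.01), function(f) {
      c(a1 = f * tau0, b1 = tau0)
    })
  )
  utils::head(starts, max(config$multistart, 1L))
}

coeffs_from_theta <- function(model, theta, gain) {
  if (model == "fwk2") {
    list(gain = gain, a1 = 0, b1 = theta[["b1"]], alpha = theta[["alpha"]])
  } else if (model == "wk2") {
    list(gain = gain, a1 = 0, b1 = theta[["b1"]], alpha = 1)
  } else {
    list(gain = gain, a1 = theta[["a1"]], b1 = theta[["b1"]], alpha = 1)
  }
}

#' Fit a Windkessel model to an impedance spectrum
#'
#' Fixes the gain to the DC impedance, then estimates the remaining
#' observational coefficients (FWK2: `tau_alpha, alpha`; WK2: `tau`;
#' WK3/VWK: `a1, b1`) by bounded Levenberg-Marquardt minimization of the
#' gain-normalized residual vector, whose root-sum-square is exactly the
#' NRMSE objective. All coefficients are constrained positive; `alpha` is
#' unbounded above by default. A deterministic multistart (time constant
#' seeded by a first-harmonic moment match, several scale factors and, for
#' FWK2, several initial fractional orders) guards against local minima; the
#' best-objective start is returned.
#'
#' @param spectrum An impedance spectrum tibble from [impedance_spectrum()].
#' @param model One of `"fwk2"`, `"wk2"`, `"wk3"`, `"vwk"`.
#' @param config A [fit_config()].
#' @return An object of class `wk_fit`: a list with the model tag, fitted
#'   `coeffs`, extracted physical `params` (with `physical = FALSE` and a
#'   warning if the realizability inequality fails), the observed and
#'   predicted spectra, per-harmonic `deviations`, a one-row `metrics`
#'   tibble, the `objective` value and convergence diagnostics.
#' @export
#' @examples
#' rec <- synthesize_pressure(
#'   generate_flow_pulse(hr = 60, sv = 83),
#'   model = "fwk2", params = list(rp = 1.1, c_alpha = 1.0, alpha = 0.5)
#' )
#' fit <- fit_model(impedance_spectrum(rec), "fwk2")
#' glance(fit)
fit_model <- function(spectrum, model, config = fit_config()) {
  model <- match.arg(model, wk_models())
  z <- spectrum_z(spectrum)
  omega <- spectrum$omega
  gain <- compute_gain(spectrum)
  n1 <- length(z)

  residual_fn <- function(theta) {
    zh <- tf_impedance(omega, coeffs_from_theta(model, theta, gain))
    c(Re(z) - Re(zh), Im(z) - Im(zh)) / (n1 * gain)
  }

  tau0 <- estimate_tau0(z, omega, gain)
  starts <- default_starts(model, tau0, config)
  upper <- function(theta) {
    u <- rep(Inf, length(theta))
    names(u) <- names(theta)
    if ("alpha" %in% names(u)) u[["alpha"]] <- config$alpha_upper
    u
  }

  runs <- lapply(starts, function(theta0) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = theta0, fn = residual_fn,
        lower = rep(0, length(theta0)), upper = upper(theta0),
        control = minpack.lm::nls.lm.control(
          maxiter = config$max_iter, ftol = config$ftol,
          ptol = config$ptol, gtol = 0
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    theta <- fit$par
    obj <- nrmse(z, tf_impedance(omega, coeffs_from_theta(model, theta, gain)), gain)
    # MINPACK success codes: 1-3 tolerance tests, 4 gradient orthogonality
    list(theta = theta, objective = obj, info = fit$info, converged = fit$info %in% 1:4)
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0) {
    abort_fracwk("all optimizer starts failed", "convergence")
  }
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "objective"))]]
  if (!any(vapply(runs, `[[`, logical(1), "converged"))) {
    abort_fracwk(
      "no optimizer start converged",
      "convergence",
      best_iterate = best
    )
  }

  coeffs <- coeffs_from_theta(model, best$theta, gain)
  params <- tryCatch(params_from_coeffs(model, coeffs), fracwk_error_nonphysical = function(e) NULL)
  physical <- !is.null(params)
  if (!physical) {
    rlang::warn(paste0(model, " fit retained but parameter extraction is non-physical"))
  }

  zh <- tf_impedance(omega, coeffs)
  predicted <- tibble(
    harmonic = spectrum$harmonic, freq_hz = spectrum$freq_hz, omega = omega,
    real = Re(zh), imag = Im(zh), modulus = Mod(zh), phase_rad = wrap_phase(Arg(zh))
  )
  structure(
    list(
      model = model,
      coeffs = coeffs,
      params = params,
      physical = physical,
      gain = gain,
      spectrum = spectrum,
      predicted = predicted,
      deviations = harmonic_deviations(z, zh),
      metrics = impedance_metrics(z, zh, gain),
      objective = best$objective,
      converged = best$converged,
      n_starts = length(runs),
      n_converged = sum(vapply(runs, `[[`, logical(1), "converged"))
    ),
    class = "wk_fit"
  )
}

unit_table <- c(
  gain = "mmHg.s/ml", a1 = "s", b1 = "s^alpha", alpha = "-",
  rp = "mmHg.s/ml", c_alpha = "ml/mmHg/s^(1-alpha)", c = "ml/mmHg",
  zc = "mmHg.s/ml", rd = "mmHg.s/ml", c_vw = "ml/mmHg"
)

#' @exportS3Method generics::tidy
tidy.wk_fit <- function(x, ...) {
  co <- tibble(
    term = names(x$coeffs),
    estimate = unlist(x$coeffs),
    kind = "coefficient"
  )
  pa <- if (x$physical) {
    tibble(term = names(x$params), estimate = unlist(x$params), kind = "physical")
  } else {
    tibble(term = character(), estimate = numeric(), kind = character())
  }
  out <- dplyr::bind_rows(co, pa)
  out$unit <- unname(unit_table[out$term])
  out
}

#' @exportS3Method generics::glance
glance.wk_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble(model = x$model, gain = x$gain),
    x$metrics,
    tibble(
      converged = x$converged,
      n_starts = x$n_starts,
      n_converged = x$n_converged,
      physical = x$physical
    )
  )
}

#' @export
print.wk_fit <- function(x, ...) {
  cat("<wk_fit> model:", x$model, "\n")
  cat("  gain (fixed):", format(x$gain, digits = 6), "mmHg.s/ml\n")
  cat(
    "  coefficients:",
    paste(names(x$coeffs), format(unlist(x$coeffs), digits = 6), sep = "=", collapse = ", "),
    "\n"
  )
  if (x$physical) {
    cat(
      "  physical:",
      paste(names(x$params), format(unlist(x$params), digits = 6), sep = "=", collapse = ", "),
      "\n"
    )
  } else {
    cat("  physical: extraction flagged non-physical\n")
  }
  m <- x$metrics
  cat(sprintf(
    "  NRMSE %.3e | Re_moduli %.2f%% | Re_phase %s%% | Deviation %.2f%%\n",
    m$nrmse, m$re_moduli_pct,
    ifelse(is.na(m$re_phase_pct), "NA", sprintf("%.2f", m$re_phase_pct)),
    m$deviation_pct
  ))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.wk_fit <- function(object, ...) {
  obs <- dplyr::mutate(object$spectrum, source = "observed")
  fitted <- dplyr::mutate(object$predicted, source = "fitted")
  long <- tidyr::pivot_longer(
    dplyr::bind_rows(obs, fitted),
    cols = c("modulus", "phase_rad"),
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$freq_hz, y = .data$value, colour = .data$source)) +
    ggplot2::geom_point(data = function(d) d[d$source == "observed", ]) +
    ggplot2::geom_line(data = function(d) d[d$source == "fitted", ]) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = "frequency (Hz)", y = NULL, colour = NULL,
      title = paste0("Aortic input impedance fit (", object$model, ")")
    )
}
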