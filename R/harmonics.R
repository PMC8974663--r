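# Fourier harmonic decomposition of periodic waveforms and construction of
# the empirical aortic input impedance spectrum, harmonic by harmonic.
#
# Convention: y(t) = mean + sum_n amp[n] * cos(n * w0 * t + phase[n]),
# w0 = 2*pi/T. Harmonic 0 carries the mean (phase 0); phases are principal
# values in (-pi, pi].

#' Fourier harmonic decomposition of a periodic waveform
#'
#' Decomposes one column of a single-cycle record into its mean value plus
#' cosine harmonics at multiples of the cardiac fundamental `w0 = 2*pi/T`,
#' via the FFT. A pure input `A*cos(n*w0*t + phi)` yields `amp = A`,
#' `phase = phi` at harmonic `n`.
#'
#' @param data Data frame with a uniform `time_s` column covering one period.
#' @param value Column to decompose (tidy-eval, e.g. `pressure_mmHg`).
#' @param n_harmonics Number of harmonics to retain (default 20, covering the
#'   frequency band of physiological interest up to 20x the heart rate).
#'
#' @return A tibble with columns `harmonic` (0..N), `freq_hz`, `omega`
#'   (rad/s), `amp` and `phase` (radians, in (-pi, pi]); harmonic 0 holds the
#'   signal mean with phase 0. The heart period is attached as attribute
#'   `"period"`.
#' @export
#' @examples
#' t <- seq(0, 0.995, by = 0.005)
#' d <- tibble::tibble(time_s = t, p = 2 + 3 * cos(2 * pi * t + 0.7))
#' decompose(d, p, n_harmonics = 5)
decompose <- function(data, value, n_harmonics = 20) {
  y <- dplyr::pull(data, {{ value }})
  if (anyNA(y)) abort_fracwk("waveform contains missing samples", "data")
  n <- length(y)
  if (n_harmonics < 1) abort_fracwk("n_harmonics must be >= 1", "precondition")
  if (n_harmonics > floor((n - 1) / 2)) {
    abort_fracwk(
      paste0(
        "n_harmonics = ", n_harmonics, " exceeds the Nyquist limit ",
        floor((n - 1) / 2), " for ", n, " samples"
      ),
      "precondition"
    )
  }
  period <- record_period(data)
  w0 <- 2 * pi / period
  # One-sided cosine-series coefficients from the DFT: bin n holds
  # (amp/2) * exp(1i * phase) for 0 < n < n/2.
  spec <- stats::fft(y) / n
  idx <- seq_len(n_harmonics) + 1L
  amp <- c(Re(spec[1]), 2 * Mod(spec[idx]))
  phase <- c(0, wrap_phase(Arg(spec[idx])))
  out <- tibble(
    harmonic = 0:n_harmonics,
    freq_hz = (0:n_harmonics) * w0 / (2 * pi),
    omega = (0:n_harmonics) * w0,
    amp = amp,
    phase = phase
  )
  attr(out, "period") <- period
  out
}

#' Resynthesize a band-limited waveform from its harmonic series
#'
#' Inverse of [decompose()]: evaluates
#' `mean + sum_n amp[n] * cos(n * w0 * t + phase[n])` on an arbitrary time
#' grid. Exact (to rounding) for signals band-limited to the retained
#' harmonics.
#'
#' @param series A harmonic series tibble from [decompose()].
#' @param time_s Time points (seconds) at which to evaluate.
#' @return Numeric vector of samples.
#' @export
resynthesize <- function(series, time_s) {
  stopifnot(all(c("harmonic", "omega", "amp", "phase") %in% names(series)))
  # harmonic 0 contributes amp * cos(0) = mean, so one sum covers all terms
  vapply(
    time_s,
    function(t) sum(series$amp * cos(series$omega * t + series$phase)),
    numeric(1)
  )
}

#' Empirical aortic input impedance from pressure and flow harmonics
#'
#' Forms the impedance spectrum `Z[n] = P(jnw0) / Q(jnw0)` harmonic by
#' harmonic: `Z[0]` is the ratio of mean pressure to mean flow (the total
#' peripheral resistance), and for `n >= 1` the modulus is the ratio of
#' pressure to flow amplitudes and the phase the difference of their phase
#' angles, wrapped to (-pi, pi].
#'
#' @param pressure Harmonic series of the pressure waveform ([decompose()]).
#' @param flow Harmonic series of the flow waveform; must share the
#'   fundamental frequency and harmonic count with `pressure`.
#' @param amplitude_floor Relative floor below which a flow harmonic is
#'   considered degenerate: flow amplitudes smaller than
#'   `amplitude_floor * max(flow amp[1..N])` raise an error naming the
#'   offending harmonic, since the pressure/flow ratio is then meaningless.
#'
#' @return An impedance spectrum: tibble with columns `harmonic`, `freq_hz`,
#'   `omega`, `real`, `imag`, `modulus`, `phase_rad`; heart period as
#'   attribute `"period"`.
#' @export
impedance_from_harmonics <- function(pressure, flow, amplitude_floor = 1e-12) {
  if (nrow(pressure) != nrow(flow)) {
    abort_fracwk("pressure and flow series must have the same harmonic count", "usage")
  }
  if (max(abs(pressure$omega - flow$omega)) > 1e-9 * max(flow$omega)) {
    abort_fracwk("pressure and flow series must share the fundamental frequency", "usage")
  }
  q_mean <- flow$amp[1]
  if (q_mean == 0) abort_fracwk("mean flow is zero; impedance undefined at DC", "degenerate")
  n_idx <- which(flow$harmonic >= 1)
  q_amp <- flow$amp[n_idx]
  floor_abs <- amplitude_floor * max(q_amp)
  bad <- flow$harmonic[n_idx][q_amp < floor_abs]
  if (length(bad) > 0) {
    abort_fracwk(
      paste0(
        "flow amplitude below floor at harmonic(s) ",
        paste(bad, collapse = ", "), "; impedance ratio degenerate"
      ),
      "degenerate"
    )
  }
  z <- complex(real = numeric(nrow(pressure)))
  z[1] <- complex(real = pressure$amp[1] / q_mean)
  z[n_idx] <- (pressure$amp[n_idx] / q_amp) *
    exp(1i * (pressure$phase[n_idx] - flow$phase[n_idx]))
  out <- tibble(
    harmonic = pressure$harmonic,
    freq_hz = pressure$freq_hz,
    omega = pressure$omega,
    real = Re(z),
    imag = Im(z),
    modulus = Mod(z),
    phase_rad = wrap_phase(Arg(z))
  )
  attr(out, "period") <- attr(pressure, "period") %||% (2 * pi / pressure$omega[2])
  out
}

#' Empirical impedance spectrum of a hemodynamic record
#'
#' Convenience pipeline: decomposes pressure and flow to `n_harmonics`
#' harmonics and forms their ratio with [impedance_from_harmonics()].
#'
#' @param record A `hemodynamic_record`.
#' @inheritParams decompose
#' @inheritParams impedance_from_harmonics
#' @return An impedance spectrum tibble (see [impedance_from_harmonics()]).
#' @export
impedance_spectrum <- function(record, n_harmonics = 20, amplitude_floor = 1e-12) {
  validate_record(record)
  p <- decompose(record, .data$pressure_mmHg, n_harmonics)
  q <- decompose(record, .data$flow_ml_s, n_harmonics)
  impedance_from_harmonics(p, q, amplitude_floor)
}

#' Complex impedance vector of a spectrum table
#'
#' @param spectrum An impedance spectrum tibble (or any model-predicted
#'   spectrum with `real` and `imag` columns).
#' @return Complex vector, one element per harmonic.
#' @export
spectrum_z <- function(spectrum) {
  complex(real = spectrum$real, imaginary = spectrum$imag)
}

#' Write an impedance spectrum to CSV
#'
#' Columns: `harmonic,freq_hz,modulus,phase_rad,real,imag`.
#'
#' @param spectrum An impedance spectrum tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  out <- spectrum[, c("harmonic", "freq_hz", "modulus", "phase_rad", "real", "imag")]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
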