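# Fixtures built in code: synthetic records, band-limited signals and
# model-generated impedance spectra.

# Uniform half-open grid of one period.
time_grid <- function(period, n) seq(0, period - period / n, length.out = n)

# Record with sinusoidal pressure/flow at given extrema.
sinus_record <- function(period = 1, n = 200,
                         p_max = 120, p_min = 70,
                         q_mean = 90, q_amp = 80) {
  t <- time_grid(period, n)
  w0 <- 2 * pi / period
  hemodynamic_record(
    t,
    (p_max + p_min) / 2 + (p_max - p_min) / 2 * cos(w0 * t),
    q_mean + q_amp * sin(w0 * t)
  )
}

# Band-limited random signal with known harmonic content.
random_band_limited <- function(period, n, n_harmonics, seed = 1) {
  set.seed(seed)
  t <- time_grid(period, n)
  w0 <- 2 * pi / period
  amp <- runif(n_harmonics, 0.5, 3)
  phase <- runif(n_harmonics, -pi, pi)
  y <- 5 + Reduce(`+`, lapply(seq_len(n_harmonics), function(k) {
    amp[k] * cos(k * w0 * t + phase[k])
  }))
  list(t = t, y = y, amp = amp, phase = phase, mean = 5, w0 = w0)
}

# Impedance spectrum tibble from a complex vector on harmonics 0..N.
make_spectrum <- function(omega, z, period = 2 * pi / omega[2]) {
  out <- tibble::tibble(
    harmonic = seq_along(omega) - 1L,
    freq_hz = omega / (2 * pi),
    omega = omega,
    real = Re(z),
    imag = Im(z),
    modulus = Mod(z),
    phase_rad = Arg(z)
  )
  attr(out, "period") <- period
  out
}

# Noiseless model-generated spectrum at harmonics 0..N of fundamental w0.
model_spectrum <- function(model, params, w0 = 2 * pi, n_harmonics = 20) {
  omega <- (0:n_harmonics) * w0
  make_spectrum(omega, model_impedance(omega, model, params))
}
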