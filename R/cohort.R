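# Synthetic virtual cohort: stylized ascending-aorta flow pulses paired with
# pressure synthesized through a chosen ground-truth impedance model, so that
# every pipeline stage (decomposition, spectrum, calibration, reporting) is
# testable offline. Pressure synthesis is purely frequency-domain (periodic
# steady state), which is exact for periodic inputs and avoids any
# fractional-order time stepping.

#' Generate a stylized aortic flow pulse
#'
#' Half-sine systolic ejection of duration `ejection_fraction * T`, zero flow
#' in diastole, with the peak scaled so that the analytic cycle integral
#' equals the stroke volume exactly: `peak = SV * pi / (2 * duration)`.
#'
#' @param hr Heart rate (beats/min); the period is `T = 60 / hr`.
#' @param sv Stroke volume (ml).
#' @param ejection_fraction Fraction of the cycle spent in ejection, in (0, 1)
#'   (default 0.33, a typical systolic fraction at rest).
#' @param n_samples Samples per cycle on the half-open grid (default 256).
#' @return A tibble with `time_s` and `flow_ml_s` covering one period.
#' @export
#' @examples
#' pulse <- generate_flow_pulse(hr = 60, sv = 100, ejection_fraction = 0.33)
#' max(pulse$flow_ml_s) # ~ 100 * pi / (2 * 0.33)
generate_flow_pulse <- function(hr, sv, ejection_fraction = 0.33, n_samples = 256) {
  stopifnot(hr > 0, sv > 0, n_samples >= 8)
  if (ejection_fraction <= 0 || ejection_fraction >= 1) {
    abort_fracwk("ejection_fraction must lie strictly between 0 and 1", "precondition")
  }
  period <- 60 / hr
  dur <- ejection_fraction * period
  peak <- sv * pi / (2 * dur)
  t <- seq(0, period - period / n_samples, length.out = n_samples)
  q <- ifelse(t < dur, peak * sin(pi * t / dur), 0)
  tibble(time_s = t, flow_ml_s = q)
}

#' Synthesize pressure from flow through an impedance model
#'
#' Decomposes the flow into `n_harmonics` harmonics, multiplies each flow
#' harmonic by the model impedance at that frequency
#' (`P(jn w0) = Z(jn w0) * Q(jn w0)`, with `P0 = Z(0) * Q0` at DC), optionally
#' perturbs the pressure harmonics with i.i.d. complex Gaussian noise, and
#' reconstructs the band-limited pressure waveform on the flow's time grid.
#' The result is the exact periodic steady-state response of the model.
#'
#' @param flow A tibble with `time_s` and `flow_ml_s` (e.g. from
#'   [generate_flow_pulse()]), or a full record whose flow column is used.
#' @param model Ground-truth model tag (see [wk_models()]).
#' @param params Named list of physical parameters for `model`.
#' @param n_harmonics Harmonics used for synthesis (default 20).
#' @param noise_sigma Noise level as a fraction of the first pressure
#'   harmonic's amplitude; each perturbed harmonic receives independent
#'   Gaussian noise of that standard deviation on its real and imaginary
#'   parts (harmonics 1..N; the mean is left exact so the DC gain stays
#'   identifiable). Default 0 (noiseless).
#' @param subject_id Optional label forwarded to the record.
#' @return A `hemodynamic_record` with the synthesized `pressure_mmHg`.
#' @export
synthesize_pressure <- function(flow, model, params, n_harmonics = 20,
                                noise_sigma = 0, subject_id = NULL) {
  stopifnot(noise_sigma >= 0)
  q <- decompose(flow, .data$flow_ml_s, n_harmonics)
  z <- model_impedance(q$omega, model, params)
  # complex flow harmonics under the cosine-series convention
  qc <- q$amp * exp(1i * q$phase)
  pc <- z * qc
  if (noise_sigma > 0) {
    sd_abs <- noise_sigma * Mod(pc[2])
    idx <- 2:length(pc)
    pc[idx] <- pc[idx] + complex(
      real = stats::rnorm(length(idx), 0, sd_abs),
      imaginary = stats::rnorm(length(idx), 0, sd_abs)
    )
  }
  p_series <- tibble(
    harmonic = q$harmonic,
    freq_hz = q$freq_hz,
    omega = q$omega,
    amp = c(Re(pc[1]), Mod(pc[-1])),
    phase = c(0, wrap_phase(Arg(pc[-1])))
  )
  attr(p_series, "period") <- attr(q, "period")
  pressure <- resynthesize(p_series, flow$time_s)
  hemodynamic_record(flow$time_s, pressure, flow$flow_ml_s, subject_id = subject_id)
}

#' Specification of a synthetic virtual cohort
#'
#' Defines the heart-rate / stroke-volume grid, the ground-truth model and
#' its parameter sampling ranges, and the synthesis settings. The defaults
#' emulate the structure of the in-silico virtual adult population: heart
#' rates of 53, 63 and 72 beats/min crossed with stroke volumes of 66, 83 and
#' 100 ml, giving cardiac outputs spanning roughly 3.5 to 7.2 l/min.
#'
#' Default parameter ranges: `rp` uniform on \[0.7, 1.5\] mmHg s/ml;
#' `alpha` uniform on \[0.3, 0.6\] (spanning reported per-subject estimates
#' of 0.33--0.52); the time constant `tau = rp * c` uniform on \[0.5, 2\] s,
#' from which the compliance-like parameter is derived; for WK3 `zc` uniform
#' on \[0.03, 0.08\] and for VWK `rd` uniform on \[0.02, 0.06\] mmHg s/ml.
#'
#' @param hr Heart-rate levels (beats/min).
#' @param sv Stroke-volume levels (ml).
#' @param model Ground-truth model tag.
#' @param ranges Named list of `c(lower, upper)` sampling ranges; recognized
#'   names: `rp`, `alpha`, `tau` (time constant `rp * c`), `zc`, `rd`.
#' @param subjects_per_cell Subjects drawn per (hr, sv) cell.
#' @param n_harmonics Harmonics used in pressure synthesis.
#' @param noise_sigma Per-harmonic pressure noise (fraction of the first
#'   harmonic amplitude); see [synthesize_pressure()].
#' @param ejection_fraction Systolic fraction of the flow pulse.
#' @param n_samples Samples per cycle.
#' @param seed Integer RNG seed; cohorts are fully deterministic given the
#'   spec.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(hr = c(53, 63, 72), sv = c(66, 83, 100),
                        model = "fwk2",
                        ranges = list(
                          rp = c(0.7, 1.5), alpha = c(0.3, 0.6),
                          tau = c(0.5, 2), zc = c(0.03, 0.08),
                          rd = c(0.02, 0.06)
                        ),
                        subjects_per_cell = 1, n_harmonics = 20,
                        noise_sigma = 0, ejection_fraction = 0.33,
                        n_samples = 256, seed = 1L) {
  if (length(hr) == 0 || length(sv) == 0) {
    abort_fracwk("heart-rate and stroke-volume sets must be non-empty", "precondition")
  }
  stopifnot(all(hr > 0), all(sv > 0), noise_sigma >= 0, subjects_per_cell >= 1)
  model <- match.arg(model, wk_models())
  structure(
    list(
      hr = hr, sv = sv, model = model, ranges = ranges,
      subjects_per_cell = subjects_per_cell, n_harmonics = n_harmonics,
      noise_sigma = noise_sigma, ejection_fraction = ejection_fraction,
      n_samples = n_samples, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

sample_params <- function(model, ranges) {
  u <- function(r) stats::runif(1, r[1], r[2])
  rp <- u(ranges$rp)
  tau <- u(ranges$tau)
  switch(model,
    fwk2 = list(rp = rp, c_alpha = tau / rp, alpha = u(ranges$alpha)),
    wk2 = list(rp = rp, c = tau / rp),
    wk3 = list(zc = u(ranges$zc), rp = rp, c = tau / rp),
    vwk = list(rp = rp, rd = u(ranges$rd), c_vw = tau / rp)
  )
}

#' Generate a synthetic virtual cohort
#'
#' Draws ground-truth parameters per subject, builds the flow pulse for each
#' (heart rate, stroke volume) cell and synthesizes the paired pressure
#' through the ground-truth model. Deterministic under the spec's seed; the
#' caller's RNG state is left untouched.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per virtual subject: `subject_id`, `hr`,
#'   `sv`, `cell`, `model`, `params` (list-column of ground-truth parameter
#'   lists), `noise_sigma` and `record` (list-column of
#'   `hemodynamic_record`s).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(subjects_per_cell = 1, seed = 42))
#' dplyr::summarise(
#'   dplyr::rowwise(cohort),
#'   co = extract_features(record)$co
#' )
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- expand.grid(
    rep = seq_len(spec$subjects_per_cell),
    sv = spec$sv, hr = spec$hr
  )[, c("hr", "sv", "rep")]
  with_preserved_seed(spec$seed, {
    rows <- purrr::pmap(grid, function(hr, sv, rep) {
      params <- sample_params(spec$model, spec$ranges)
      flow <- generate_flow_pulse(hr, sv, spec$ejection_fraction, spec$n_samples)
      id <- sprintf("hr%02d_sv%03d_r%02d", as.integer(hr), as.integer(sv), rep)
      rec <- synthesize_pressure(
        flow, spec$model, params,
        n_harmonics = spec$n_harmonics,
        noise_sigma = spec$noise_sigma,
        subject_id = id
      )
      tibble(
        subject_id = id, hr = hr, sv = sv,
        cell = sprintf("hr%02d_sv%03d", as.integer(hr), as.integer(sv)),
        model = spec$model, params = list(params),
        noise_sigma = spec$noise_sigma, record = list(rec)
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Write a cohort to disk
#'
#' Emits a manifest TSV (`subject_id, hr, sv, model, true_params_json,
#' noise_sigma, seed`) plus one waveform CSV per subject in the canonical
#' record dialect.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest (informational).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- dplyr::mutate(
    dplyr::select(cohort, "subject_id", "hr", "sv", "model", "noise_sigma"),
    true_params_json = purrr::map_chr(
      cohort$params,
      ~ jsonlite::toJSON(.x, auto_unbox = TRUE, digits = NA)
    ),
    seed = seed
  )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  purrr::walk2(
    cohort$record, cohort$subject_id,
    ~ write_record(.x, file.path(dir, paste0(.y, ".csv")))
  )
  invisible(file.path(dir, "manifest.tsv"))
}
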