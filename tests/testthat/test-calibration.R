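test_that("gain is read from the DC impedance and must be positive", {
  spec <- make_spectrum(c(0, 2 * pi), c(1.25 + 0i, 0.8 - 0.1i))
  expect_equal(compute_gain(spec), 1.25)
  # ratio of mean pressure to mean flow
  expect_equal(compute_gain(c(complex(real = 93.33 / 83.33), 0.5 + 0i)),
    93.33 / 83.33,
    tolerance = 1e-12
  )
  bad <- make_spectrum(c(0, 2 * pi), c(-0.1 + 0i, 0.8 - 0.1i))
  expect_error(compute_gain(bad), class = "fracwk_error_data")
})

test_that("NRMSE follows the gain-normalized root-sum-square convention", {
  z <- complex(real = c(1.2, 0.8, 0.4), imaginary = c(0, -0.3, -0.2))
  expect_equal(nrmse(z, z, 1.2), 0)
  # single-harmonic hand computation: sqrt(1) / (1 * 2) = 0.5
  expect_equal(nrmse(2 + 0i, 1 + 0i, 2), 0.5)
  # brute-force loop oracle on a random 21-harmonic pair
  set.seed(4)
  za <- complex(real = rnorm(21), imaginary = rnorm(21))
  zb <- za + complex(real = rnorm(21, sd = 0.1), imaginary = rnorm(21, sd = 0.1))
  g <- 1.7
  acc <- 0
  for (i in 1:21) {
    acc <- acc + (Re(za[i]) - Re(zb[i]))^2 + (Im(za[i]) - Im(zb[i]))^2
  }
  expect_equal(nrmse(za, zb, g), sqrt(acc) / (21 * g), tolerance = 1e-12)
  expect_error(nrmse(za, zb[1:10], g), class = "fracwk_error_usage")
})

test_that("modulus deviations and their mean behave as relative percentages", {
  z <- complex(real = c(1.5, 0.9, 0.5), imaginary = c(0, -0.4, -0.3))
  expect_equal(harmonic_deviations(z, z)$d_pct, rep(0, 3))
  expect_equal(deviation(z, z), 0)
  # uniform 1.2x modulus inflation -> 20% everywhere
  expect_equal(harmonic_deviations(z, 1.2 * z)$d_pct, rep(20, 3), tolerance = 1e-12)
  expect_equal(deviation(z, 1.2 * z), 20, tolerance = 1e-12)
  # mean of the per-harmonic loop oracle
  set.seed(5)
  zh <- z * runif(3, 0.8, 1.3)
  d_oracle <- vapply(1:3, function(i) (Mod(zh[i]) - Mod(z[i])) / Mod(z[i]) * 100, numeric(1))
  expect_equal(deviation(z, zh), mean(d_oracle), tolerance = 1e-12)
})

test_that("L2 relative errors match hand computations", {
  z <- complex(modulus = c(1, 1), argument = c(-0.2, -0.3))
  zh <- complex(modulus = c(1.1, 0.9), argument = c(-0.2, -0.3))
  re <- relative_errors(z, zh)
  expect_equal(re$re_moduli_pct, 100 * sqrt(0.02) / sqrt(2), tolerance = 1e-12)
  expect_equal(re$re_phase_pct, 0)
  # constant phase shift against known phases
  zh2 <- complex(modulus = c(1, 1), argument = c(-0.2, -0.3) + 0.1)
  re2 <- relative_errors(z, zh2)
  expect_equal(
    re2$re_phase_pct,
    100 * sqrt(0.1^2 + 0.1^2) / sqrt(0.2^2 + 0.3^2),
    tolerance = 1e-12
  )
  # all-real spectrum: undefined phase error is a sentinel, not an exception
  re3 <- relative_errors(c(1 + 0i, 2 + 0i), c(1 + 0i, 2.1 + 0i))
  expect_true(is.na(re3$re_phase_pct))
})

test_that("coefficient/parameter maps round-trip for every model", {
  expect_equal(
    params_from_coeffs("fwk2", list(gain = 2, a1 = 0, b1 = 1, alpha = 0.5)),
    list(rp = 2, c_alpha = 0.5, alpha = 0.5)
  )
  cases <- list(
    list(model = "fwk2", params = list(rp = 1.3, c_alpha = 0.7, alpha = 0.44)),
    list(model = "wk2", params = list(rp = 0.9, c = 1.8)),
    list(model = "wk3", params = list(zc = 0.05, rp = 1.0, c = 1.2)),
    list(model = "vwk", params = list(rp = 1.2, rd = 0.04, c_vw = 1.5))
  )
  for (cs in cases) {
    back <- params_from_coeffs(cs$model, coeffs_from_params(cs$model, cs$params))
    expect_equal(back, cs$params, tolerance = 1e-12)
  }
  expect_error(
    params_from_coeffs("vwk", list(gain = 1, a1 = 2, b1 = 1, alpha = 1)),
    class = "fracwk_error_nonphysical"
  )
  expect_error(
    params_from_coeffs("wk3", list(gain = 1, a1 = 2, b1 = 1, alpha = 1)),
    class = "fracwk_error_nonphysical"
  )
})

test_that("noiseless spectra are recovered to high precision", {
  truth <- list(rp = 1.2, c_alpha = 0.9, alpha = 0.55)
  spec <- model_spectrum("fwk2", truth, w0 = 2 * pi / 0.95)
  fit <- fit_model(spec, "fwk2")
  expect_lt(abs(fit$params$rp - truth$rp) / truth$rp, 1e-6)
  expect_lt(abs(fit$params$c_alpha - truth$c_alpha) / truth$c_alpha, 1e-6)
  expect_lt(abs(fit$params$alpha - truth$alpha) / truth$alpha, 1e-6)
  expect_lt(fit$metrics$nrmse, 1e-10)
  expect_true(fit$converged)
})

test_that("fitting the fractional model to integer-order data drives alpha to 1", {
  spec <- model_spectrum("wk2", list(rp = 1, c = 1.5))
  fit <- fit_model(spec, "fwk2")
  expect_lt(abs(fit$params$alpha - 1), 1e-4)
  expect_lt(abs(fit$params$c_alpha - 1.5), 1e-4)
})

test_that("WK3 and VWK fits of the same spectrum have identical objectives", {
  spec <- model_spectrum("wk3", list(zc = 0.06, rp = 1.1, c = 1.4))
  f3 <- fit_model(spec, "wk3")
  fv <- fit_model(spec, "vwk")
  expect_lt(abs(f3$metrics$nrmse - fv$metrics$nrmse), 1e-10)
  expect_lt(f3$metrics$nrmse, 1e-10)
  # and both recover the generating triple through their own parameterizations
  expect_equal(f3$params$zc, 0.06, tolerance = 1e-5)
  expect_equal(f3$params$rp, 1.1, tolerance = 1e-5)
  expect_equal(f3$params$c, 1.4, tolerance = 1e-5)
})

test_that("the two-element fit can never beat the fractional fit it nests in", {
  for (a in c(0.4, 0.6, 0.8)) {
    spec <- model_spectrum("fwk2", list(rp = 1.1, c_alpha = 0.8, alpha = a))
    f_frac <- fit_model(spec, "fwk2")
    f_int <- fit_model(spec, "wk2")
    expect_gte(f_int$metrics$nrmse, f_frac$metrics$nrmse)
  }
})

test_that("fitted fractional phase never exceeds zero", {
  rec <- synthesize_pressure(
    generate_flow_pulse(63, 83), "wk3", list(zc = 0.05, rp = 1.0, c = 1.3)
  )
  fit <- fit_model(impedance_spectrum(rec), "fwk2")
  expect_true(all(fit$predicted$phase_rad <= 0))
  w_dense <- seq(0, 500, length.out = 2000)
  mp <- fwk2_modulus_phase(w_dense, fit$coeffs$gain, fit$coeffs$b1, fit$coeffs$alpha)
  expect_true(all(mp$phase_rad <= 0))
})

test_that("broom methods expose coefficients, parameters and metrics", {
  spec <- model_spectrum("fwk2", list(rp = 1.2, c_alpha = 0.9, alpha = 0.5))
  fit <- fit_model(spec, "fwk2")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "kind", "unit") %in% names(td)))
  expect_true(all(c("rp", "c_alpha", "alpha") %in% td$term))
  gl <- glance(fit)
  expect_equal(gl$model, "fwk2")
  expect_true(all(c("nrmse", "re_moduli_pct", "re_phase_pct", "deviation_pct") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})
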