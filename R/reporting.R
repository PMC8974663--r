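# Aggregation and reporting: per-record multi-model fits, cohort-level
# goodness-of-fit summaries grouped by heart rate, and the dynamic-compliance
# comparison across models evaluated at the heart pulsation.

#' Fit several Windkessel models to one record
#'
#' Runs the full pipeline (harmonic decomposition, empirical impedance
#' spectrum, calibration) for each requested model. All models share the same
#' DC gain, fixed by the spectrum.
#'
#' @param record A `hemodynamic_record`.
#' @param models Character vector of model tags (default all four).
#' @param config A [fit_config()]; its `n_harmonics` sets the spectrum size.
#' @return A tibble with one row per model: glance columns (gain, metric
#'   suite, convergence), coefficient columns (`a1`, `b1`, `alpha`), a JSON
#'   string of the extracted physical parameters, and the full `wk_fit`
#'   object in the `fit` list-column.
#' @export
fit_record <- function(record, models = wk_models(), config = fit_config()) {
  spectrum <- impedance_spectrum(record, n_harmonics = config$n_harmonics)
  fits <- purrr::map(models, ~ fit_model(spectrum, .x, config))
  dplyr::bind_cols(
    dplyr::bind_rows(purrr::map(fits, glance)),
    tibble(
      a1 = purrr::map_dbl(fits, ~ .x$coeffs$a1),
      b1 = purrr::map_dbl(fits, ~ .x$coeffs$b1),
      alpha = purrr::map_dbl(fits, ~ .x$coeffs$alpha),
      params_json = purrr::map_chr(
        fits,
        ~ if (.x$physical) {
          as.character(jsonlite::toJSON(.x$params, auto_unbox = TRUE, digits = NA))
        } else {
          NA_character_
        }
      ),
      fit = fits
    )
  )
}

#' Fit models to every subject of a cohort
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param models Model tags to fit.
#' @param config A [fit_config()].
#' @return A long tibble: one row per subject x model, carrying `subject_id`,
#'   `hr`, `sv` and all [fit_record()] columns.
#' @export
fit_cohort <- function(cohort, models = wk_models(), config = fit_config()) {
  rows <- purrr::pmap(
    list(cohort$record, cohort$subject_id, cohort$hr, cohort$sv),
    function(record, subject_id, hr, sv) {
      res <- tryCatch(
        fit_record(record, models, config),
        error = function(e) {
          rlang::warn(paste0("subject ", subject_id, " excluded: ", conditionMessage(e)))
          NULL
        }
      )
      if (is.null(res)) return(NULL)
      dplyr::bind_cols(tibble(subject_id = subject_id, hr = hr, sv = sv), res)
    }
  )
  dropped <- sum(vapply(rows, is.null, logical(1)))
  out <- dplyr::bind_rows(Filter(Negate(is.null), rows))
  attr(out, "n_excluded") <- dropped
  out
}

#' Heart-rate-group summary of the goodness-of-fit metrics
#'
#' Aggregates per-subject fits into mean and standard deviation of NRMSE,
#' modulus and phase relative errors and mean deviation, per heart-rate
#' group and model — one row per heart-rate group, columns
#' `{model}_{metric}_{mean,sd}`.
#'
#' @param fits Long tibble from [fit_cohort()].
#' @return A wide tibble, one row per `hr` group.
#' @export
cohort_benchmark <- function(fits) {
  long <- tidyr::pivot_longer(
    dplyr::select(
      fits, "hr", "model", "nrmse", "re_moduli_pct", "re_phase_pct",
      "deviation_pct"
    ),
    cols = c("nrmse", "re_moduli_pct", "re_phase_pct", "deviation_pct"),
    names_to = "metric", values_to = "value"
  )
  agg <- dplyr::summarise(
    dplyr::group_by(long, .data$hr, .data$model, .data$metric),
    mean = mean(.data$value),
    sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), 0),
    n = dplyr::n(),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    agg,
    id_cols = "hr",
    names_from = c("model", "metric"),
    values_from = c("mean", "sd"),
    names_glue = "{model}_{metric}_{.value}"
  )
  n_per_group <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(fits, .data$hr, .data$subject_id), .data$hr),
    n = dplyr::n(), .groups = "drop"
  )
  dplyr::left_join(wide, n_per_group, by = "hr")
}

#' Write a benchmark summary TSV
#'
#' @param summary Wide tibble from [cohort_benchmark()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(summary, path) {
  readr::write_tsv(summary, path, progress = FALSE)
  invisible(path)
}

ols_line <- function(x, y) {
  fit <- stats::lm(y ~ x)
  # noiseless self-consistency checks legitimately produce perfect fits
  s <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = s$r.squared
  )
}

#' Dynamic-compliance comparison across models
#'
#' For every subject fitted with all four models, evaluates the
#' fractional-order capacitor's complex compliance `C_F` and the Voigt
#' cell's dynamic compliance `C_c` at the subject's heart pulsation
#' `w_h = 2*pi/T`, collects the static compliances of WK2, WK3 and VWK, and
#' regresses each pairing by ordinary least squares (as in the scatter-plot
#' comparison of compliance estimates): `|C_F|` against `C_W2`, `C_W3`,
#' `C_VW` and `|C_c|`, and the real and imaginary parts of `C_F` against
#' those of `C_c`.
#'
#' @param fits Long tibble from [fit_cohort()] containing all four models
#'   per subject; each subject's heart pulsation is taken from its fitted
#'   spectrum's fundamental.
#' @return A list of class `compliance_comparison` with `subjects` (one row
#'   per subject: `omega_h`, `cf_mod`, `cf_re`, `cf_im`, `c_w2`, `c_w3`,
#'   `c_vw`, `cc_mod`, `cc_re`, `cc_im`) and `regressions` (one row per
#'   pairing: `pairing`, `slope`, `intercept`, `r_squared`). With fewer than
#'   3 subjects the regression table is empty and a warning is issued.
#' @export
compliance_comparison <- function(fits) {
  needed <- wk_models()
  per_subject <- purrr::map(
    split(fits, fits$subject_id),
    function(d) {
      if (!all(needed %in% d$model)) return(NULL)
      get_fit <- function(m) d$fit[[which(d$model == m)[1]]]
      f_fwk2 <- get_fit("fwk2")
      f_wk2 <- get_fit("wk2")
      f_wk3 <- get_fit("wk3")
      f_vwk <- get_fit("vwk")
      if (!all(f_fwk2$physical, f_wk2$physical, f_wk3$physical, f_vwk$physical)) {
        return(NULL)
      }
      omega_h <- f_fwk2$spectrum$omega[2]
      cf <- foc_compliance(omega_h, f_fwk2$params$c_alpha, f_fwk2$params$alpha)
      cc <- voigt_compliance(omega_h, f_vwk$params$c_vw, f_vwk$params$rd)
      tibble(
        subject_id = d$subject_id[1],
        omega_h = omega_h,
        cf_mod = Mod(cf), cf_re = Re(cf), cf_im = Im(cf),
        c_w2 = f_wk2$params$c,
        c_w3 = f_wk3$params$c,
        c_vw = f_vwk$params$c_vw,
        cc_mod = Mod(cc), cc_re = Re(cc), cc_im = Im(cc)
      )
    }
  )
  subjects <- dplyr::bind_rows(Filter(Negate(is.null), per_subject))
  pairings <- list(
    cf_mod_vs_c_w2 = c("c_w2", "cf_mod"),
    cf_mod_vs_c_w3 = c("c_w3", "cf_mod"),
    cf_mod_vs_c_vw = c("c_vw", "cf_mod"),
    cf_re_vs_cc_re = c("cc_re", "cf_re"),
    cf_im_vs_cc_im = c("cc_im", "cf_im"),
    cf_mod_vs_cc_mod = c("cc_mod", "cf_mod")
  )
  if (nrow(subjects) < 3) {
    rlang::warn("fewer than 3 complete subjects; compliance regressions skipped")
    regressions <- tibble(
      pairing = character(), slope = numeric(),
      intercept = numeric(), r_squared = numeric()
    )
  } else {
    regressions <- dplyr::bind_rows(purrr::imap(
      pairings,
      function(cols, name) {
        dplyr::bind_cols(
          tibble(pairing = name),
          ols_line(subjects[[cols[1]]], subjects[[cols[2]]])
        )
      }
    ))
  }
  structure(
    list(subjects = subjects, regressions = regressions),
    class = "compliance_comparison"
  )
}

#' @export
print.compliance_comparison <- function(x, ...) {
  cat("<compliance_comparison>", nrow(x$subjects), "subjects\n")
  print(x$regressions)
  invisible(x)
}

#' Scatter plot of a compliance pairing
#'
#' @param comparison A [compliance_comparison()] result.
#' @param x,y Column names of `comparison$subjects` to plot (defaults:
#'   WK2 compliance against the FOC compliance modulus at the heart
#'   pulsation).
#' @return A ggplot object with the OLS line overlaid.
#' @export
plot_compliance <- function(comparison, x = "c_w2", y = "cf_mod") {
  d <- comparison$subjects
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(
      x = paste0(x, " (ml/mmHg)"), y = paste0(y, " (ml/mmHg)"),
      title = "Dynamic compliance at the heart pulsation"
    )
}

#' Write per-model fit results for one record
#'
#' Emits a JSON file (coefficients, physical parameters with unit strings,
#' metrics) and a one-row-per-model TSV suitable for cohort aggregation.
#'
#' @param fits Tibble from [fit_record()].
#' @param dir Output directory.
#' @param stem File stem for the outputs.
#' @return Paths of the written files, invisibly.
#' @export
write_fit_results <- function(fits, dir, stem = "fit") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- dplyr::select(fits, -"fit")
  tsv_path <- file.path(dir, paste0(stem, ".tsv"))
  readr::write_tsv(tsv, tsv_path, progress = FALSE)
  json_path <- file.path(dir, paste0(stem, ".json"))
  payload <- purrr::map(fits$fit, function(f) {
    list(
      model = f$model,
      coefficients = f$coeffs,
      physical_parameters = if (f$physical) f$params else NULL,
      units = as.list(unit_table[names(f$params %||% f$coeffs)]),
      metrics = as.list(f$metrics),
      converged = f$converged
    )
  })
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(tsv_path, json_path))
}
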