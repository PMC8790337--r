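# Constant-flow perfusion QC: transducer calibration, outflow facility,
# eye inclusion gating and drug-response detection.
#
# The perfusion model infuses synthetic aqueous humour at a constant
# 2.4 ul/min while a transducer monitors pressure at the cannulation
# point. For an enucleated eye (no episcleral venous pressure) outflow
# facility is C = Flow / IOP. Eyes qualify for study when facility stays
# inside a species range (pig 0.18-0.35, human 0.18-0.40 ul/min/mmHg)
# over a stable window.

#' Calibrate a pressure transducer
#'
#' Least-squares line mapping transducer voltage to pressure against a
#' reference manometer.
#'
#' @param voltages transducer output in volts (>= 2 distinct values).
#' @param reference_pressures reference pressures in mmHg, same length.
#' @return an object of class `calibration_curve` with `slope`
#'   (mmHg per volt), `intercept` (mmHg) and `r_squared`.
#' @examples
#' cal <- calibrate_transducer(c(0, 1, 2), c(0, 10, 20))
#' predict(cal, 1.5)  # 15 mmHg
#' @export
calibrate_transducer <- function(voltages, reference_pressures) {
  stopifnot(is.numeric(voltages), is.numeric(reference_pressures),
            length(voltages) == length(reference_pressures))
  if (length(voltages) < 2 || length(unique(voltages)) < 2) {
    stopf("calibration requires at least 2 distinct voltages")
  }
  fit <- stats::lm(reference_pressures ~ voltages)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((reference_pressures - mean(reference_pressures))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "calibration_curve")
}

#' @export
predict.calibration_curve <- function(object, voltages, ...) {
  object$intercept + object$slope * voltages
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Transducer calibration: P[mmHg] = %.4g * V + %.4g (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Outflow facility of an enucleated eye
#'
#' C = Flow / IOP, the simplified facility formula for enucleated eyes
#' (no episcleral venous pressure term). Homogeneous in flow.
#'
#' @param flow infusion rate in ul/min (>= 0).
#' @param pressure intraocular pressure in mmHg (> 0).
#' @return facility in ul/min/mmHg.
#' @examples
#' outflow_facility(2.4, 12)  # 0.2
#' @export
outflow_facility <- function(flow, pressure) {
  stopifnot(is.numeric(flow), is.numeric(pressure))
  if (any(!is.finite(pressure)) || any(pressure <= 0)) {
    stopf("pressure must be positive; mask transient non-positive samples upstream")
  }
  flow / pressure
}

#' Perfusion record for one eye
#'
#' A pressure time series at constant infusion flow, with the element-wise
#' facility series derived on construction. Transient non-positive
#' pressures (e.g. during aqueous sampling the port depressurises) yield
#' missing facility values rather than errors.
#'
#' @param eye_id label for the eye.
#' @param species one of `"pig"`, `"human"`, `"cyno"`.
#' @param flow_rate infusion rate in ul/min (> 0).
#' @param times_min sampling times in minutes, strictly increasing.
#' @param pressures_mmhg pressures in mmHg, same length as `times_min`.
#' @return an object of class `perfusion_record`.
#' @export
perfusion_record <- function(eye_id, species = c("pig", "human", "cyno"),
                             flow_rate, times_min, pressures_mmhg) {
  species <- match.arg(species)
  stopifnot(is.numeric(times_min), is.numeric(pressures_mmhg),
            length(times_min) == length(pressures_mmhg))
  if (length(flow_rate) != 1 || !is.finite(flow_rate) || flow_rate <= 0) {
    stopf("flow_rate must be a single positive value")
  }
  if (length(times_min) < 2 || any(diff(times_min) <= 0)) {
    stopf("times must be strictly increasing with >= 2 samples")
  }
  fac <- ifelse(is.finite(pressures_mmhg) & pressures_mmhg > 0,
                flow_rate / pressures_mmhg, NA_real_)
  structure(list(eye_id = as.character(eye_id), species = species,
                 flow_rate = flow_rate, times = times_min,
                 pressures = pressures_mmhg, facility_series = fac),
            class = "perfusion_record")
}

#' @export
print.perfusion_record <- function(x, ...) {
  ok <- is.finite(x$facility_series)
  cat(sprintf("Perfusion record %s (%s): %d samples over %.1f min at %.2g ul/min\n",
              x$eye_id, x$species, length(x$times), diff(range(x$times)), x$flow_rate))
  if (any(ok)) {
    cat(sprintf("  facility: mean %.3f, range [%.3f, %.3f] ul/min/mmHg (%d masked)\n",
                mean(x$facility_series[ok]), min(x$facility_series[ok]),
                max(x$facility_series[ok]), sum(!ok)))
  }
  invisible(x)
}

#' @export
plot.perfusion_record <- function(x, ...) {
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  graphics::plot(x$times, x$pressures, type = "l", xlab = "time (min)",
                 ylab = "IOP (mmHg)", ...)
  graphics::plot(x$times, x$facility_series, type = "l", xlab = "time (min)",
                 ylab = "facility (ul/min/mmHg)", ...)
  invisible(x)
}

#' Facility time series of a perfusion record
#'
#' Element-wise C = Flow / IOP at the record's constant flow; non-positive
#' pressures are masked as `NA`.
#'
#' @param record a [perfusion_record()].
#' @return numeric vector of facilities (ul/min/mmHg).
#' @export
facility_series <- function(record) {
  stopifnot(inherits(record, "perfusion_record"))
  record$facility_series
}

#' Inclusion criteria for perfused eyes
#'
#' Facility window plus stability rule gating which eyes enter a study.
#' Presets: `species = "pig"` gives 0.18-0.35 ul/min/mmHg; `"human"` the
#' expanded 0.18-0.40 range. Stability is judged over the final
#' `stability_window` minutes (default 30, the stable-perfusion window):
#' max - min facility must not exceed `max_relative_drift` (default 10%)
#' of the window mean.
#'
#' @param species optional preset, `"pig"`, `"human"` or `"cyno"` (cyno
#'   uses the human range).
#' @param facility_min,facility_max facility bounds in ul/min/mmHg.
#' @param stability_window_min window length in minutes.
#' @param max_relative_drift allowed (max - min)/mean within the window.
#' @return an object of class `inclusion_criteria`.
#' @export
inclusion_criteria <- function(species = NULL, facility_min = 0.18,
                               facility_max = 0.35, stability_window_min = 30,
                               max_relative_drift = 0.10) {
  if (!is.null(species)) {
    species <- match.arg(species, c("pig", "human", "cyno"))
    if (species %in% c("human", "cyno")) facility_max <- 0.40
  }
  if (!(facility_min > 0 && facility_min < facility_max)) {
    stopf("need 0 < facility_min < facility_max")
  }
  structure(list(facility_min = facility_min, facility_max = facility_max,
                 stability_window_min = stability_window_min,
                 max_relative_drift = max_relative_drift,
                 species = species),
            class = "inclusion_criteria")
}

#' Gate a perfusion record against inclusion criteria
#'
#' An eye passes when, over the final stability window, every facility
#' sample lies inside the species range and the relative drift
#' (max - min over mean) does not exceed the criterion. All violated
#' rules are reported.
#'
#' @param record a [perfusion_record()].
#' @param criteria an [inclusion_criteria()] object.
#' @return a list with `pass` (logical) and `reasons` (character vector,
#'   empty on pass).
#' @export
check_inclusion <- function(record, criteria) {
  stopifnot(inherits(record, "perfusion_record"),
            inherits(criteria, "inclusion_criteria"))
  span <- diff(range(record$times))
  if (span < criteria$stability_window_min) {
    stopf("record spans %.1f min, shorter than the %.0f min stability window",
          span, criteria$stability_window_min)
  }
  t_end <- max(record$times)
  in_window <- record$times >= t_end - criteria$stability_window_min
  fac <- record$facility_series[in_window]
  fac_ok <- fac[is.finite(fac)]
  reasons <- character(0)
  if (length(fac_ok) < 2) {
    reasons <- c(reasons, "insufficient valid facility samples in stability window")
  } else {
    if (any(fac_ok < criteria$facility_min)) {
      reasons <- c(reasons, sprintf("facility below lower bound %.2f (min %.3f)",
                                    criteria$facility_min, min(fac_ok)))
    }
    if (any(fac_ok > criteria$facility_max)) {
      reasons <- c(reasons, sprintf("facility above upper bound %.2f (max %.3f)",
                                    criteria$facility_max, max(fac_ok)))
    }
    drift <- (max(fac_ok) - min(fac_ok)) / mean(fac_ok)
    if (drift > criteria$max_relative_drift) {
      reasons <- c(reasons, sprintf("facility drift %.1f%% exceeds %.1f%% of window mean",
                                    100 * drift, 100 * criteria$max_relative_drift))
    }
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Outflow-facility response to a treatment
#'
#' Contralateral-controlled fold change in facility around an intervention
#' (e.g. cytochalasin D injected into the treated eye's anterior chamber):
#' (treated post/pre ratio) / (control post/pre ratio). Pre means are
#' taken over `baseline_window_min` minutes before `intervention_time_min`;
#' post means over all samples after it.
#'
#' @param treated,control [perfusion_record()] objects for the treated and
#'   contralateral control eye.
#' @param intervention_time_min time of the intervention (minutes).
#' @param baseline_window_min baseline window length before the
#'   intervention (minutes).
#' @return fold change (dimensionless; 1 = no differential response).
#' @export
facility_response <- function(treated, control, intervention_time_min,
                              baseline_window_min = 30) {
  stopifnot(inherits(treated, "perfusion_record"),
            inherits(control, "perfusion_record"))
  ratio_one <- function(rec) {
    pre_idx <- rec$times < intervention_time_min &
      rec$times >= intervention_time_min - baseline_window_min
    post_idx <- rec$times > intervention_time_min
    if (!any(pre_idx) || !any(post_idx)) {
      stopf("record %s does not cover the baseline window and post period", rec$eye_id)
    }
    pre <- mean(rec$facility_series[pre_idx], na.rm = TRUE)
    post <- mean(rec$facility_series[post_idx], na.rm = TRUE)
    if (!is.finite(pre) || pre == 0) stopf("zero or undefined baseline facility")
    post / pre
  }
  ratio_one(treated) / ratio_one(control)
}
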