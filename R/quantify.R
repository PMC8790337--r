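# Microbead quantification: stock arithmetic, fluorescence standard
# curves, plate-sample inversion, percent-of-injected normalisation,
# anterior dispersion-rate regression and species scaling ratios.

#' Microbeads per millilitre from a solids suspension
#'
#' beads/ml = 6 S 1e12 / (rho pi phi^3), for a suspension of solids
#' concentration S (g/ml) of polymer density rho (g/ml) divided into
#' spheres of diameter phi (um). The 1e12 converts um^3 to ml.
#'
#' Note: the vendor-stated stock concentrations in [fluosphere_specs()]
#' are *not* reproduced by this formula at S = 0.02 g/ml, rho = 1.055
#' g/ml; the two are kept as independent sources (the formula as an
#' operation, the vendor values as data) and the discrepancy is
#' documented rather than resolved.
#'
#' @param S solids concentration in g/ml (>= 0).
#' @param rho polymer density in g/ml (> 0).
#' @param phi bead diameter in um (> 0).
#' @return bead number concentration in beads/ml.
#' @examples
#' beads_per_ml(0.02, 1.055, 2)  # ~4.5e9
#' @export
beads_per_ml <- function(S, rho, phi) {
  stopifnot(is.numeric(S), is.numeric(rho), is.numeric(phi))
  if (any(S < 0)) stopf("solids concentration must be non-negative")
  if (any(rho <= 0) || any(phi <= 0)) stopf("density and diameter must be positive")
  6 * S * 1e12 / (rho * pi * phi^3)
}

#' Bead specification
#'
#' Physical constants for one fluorescent microbead product.
#'
#' @param diameter_phi_um bead diameter in um.
#' @param channel fluorescence channel, `"green"` or `"red"`.
#' @param solids_fraction_S suspension solids in g/ml (in (0, 1)).
#' @param polymer_density_rho polymer density in g/ml.
#' @param stock_concentration vendor-stated stock in beads/ml.
#' @return an object of class `bead_spec`.
#' @seealso [fluosphere_specs()] for the reference products.
#' @export
bead_spec <- function(diameter_phi_um, channel = c("green", "red"),
                      solids_fraction_S = 0.02, polymer_density_rho = 1.055,
                      stock_concentration) {
  channel <- match.arg(channel)
  stopifnot(diameter_phi_um > 0, polymer_density_rho > 0,
            solids_fraction_S > 0, solids_fraction_S < 1,
            stock_concentration > 0)
  structure(list(diameter_phi_um = diameter_phi_um, channel = channel,
                 solids_fraction_S = solids_fraction_S,
                 polymer_density_rho = polymer_density_rho,
                 stock_concentration = stock_concentration),
            class = "bead_spec")
}

#' Reference FluoSphere bead specifications
#'
#' The two polystyrene microbead products used for anterior dispersion
#' profiling: 20 nm green (stock 4.143e13 beads/ml) and 2000 nm red
#' (stock 1.326e8 beads/ml), both 2% solids, polymer specific gravity
#' 1.055 (near-neutral buoyancy in physiological fluids). Stock values
#' are vendor-stated data, not derived from [beads_per_ml()].
#'
#' @return a named list of two [bead_spec()] objects, `green` and `red`.
#' @export
fluosphere_specs <- function() {
  list(
    green = bead_spec(0.02, "green", 0.02, 1.055, 4.143e13),
    red = bead_spec(2, "red", 0.02, 1.055, 1.326e8)
  )
}

#' Beads delivered by an intravitreal injection
#'
#' Dose = stock concentration x injected volume x mix fraction. The
#' reference protocol injects 50 ul of a 1:1 (green:red) mix of the two
#' stocks, so each channel contributes at `mix_fraction = 0.5`.
#'
#' @param spec a [bead_spec()].
#' @param injected_volume_ul injected volume in ul.
#' @param mix_fraction fraction of the injectate that is this stock,
#'   in (0, 1].
#' @return number of beads injected.
#' @examples
#' injected_dose(fluosphere_specs()$green, 50, 0.5)  # ~1.04e12 beads
#' @export
injected_dose <- function(spec, injected_volume_ul, mix_fraction = 0.5) {
  stopifnot(inherits(spec, "bead_spec"), injected_volume_ul >= 0,
            mix_fraction > 0, mix_fraction <= 1)
  spec$stock_concentration * injected_volume_ul * mix_fraction / 1000
}

#' Serial dilution series
#'
#' Geometric series stock/factor^k, k = 1..n, for standard-curve plates.
#'
#' @param stock starting concentration (beads/ml).
#' @param factor dilution factor per step (> 1).
#' @param n number of dilutions (>= 1).
#' @return strictly decreasing numeric vector of length `n`.
#' @export
make_dilution_series <- function(stock, factor, n) {
  stopifnot(stock > 0, factor > 1, n >= 1)
  stock / factor^seq_len(n)
}

#' Fit a fluorescence standard curve
#'
#' Ordinary least-squares line reading = slope * concentration +
#' intercept, fitted with a free intercept (plate readers have background
#' fluorescence).
#'
#' @param concentrations standard concentrations in beads/ml (>= 3 points,
#'   >= 2 distinct).
#' @param readings fluorescence readings (a.u.), same length.
#' @param channel optional channel label carried on the curve.
#' @return an object of class `standard_curve` with `slope` (a.u. per
#'   beads/ml), `intercept` (a.u.), `r_squared`, and the data.
#' @export
fit_standard_curve <- function(concentrations, readings, channel = NULL) {
  stopifnot(is.numeric(concentrations), is.numeric(readings),
            length(concentrations) == length(readings))
  if (any(concentrations < 0)) stopf("standard concentrations must be non-negative")
  if (length(concentrations) < 3) stopf("standard curve needs >= 3 points")
  if (length(unique(concentrations)) < 2) {
    stopf("standard curve needs >= 2 distinct concentrations")
  }
  fit <- stats::lm(readings ~ concentrations)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((readings - mean(readings))^2)
  structure(list(channel = channel,
                 concentrations = concentrations, readings = readings,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve%s: reading = %.4g * conc + %.4g (r^2 = %.4f, n = %d)\n",
              if (is.null(x$channel)) "" else paste0(" [", x$channel, "]"),
              x$slope, x$intercept, x$r_squared, length(x$readings)))
  invisible(x)
}

#' @export
plot.standard_curve <- function(x, ...) {
  graphics::plot(x$concentrations, x$readings, xlab = "concentration (beads/ml)",
                 ylab = "fluorescence (a.u.)", ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Invert a plate reading to a bead concentration
#'
#' (reading - intercept) / slope, clamped at zero: readings at or below
#' the fitted background are reported as concentration 0 with a
#' `below_background` flag (attribute) rather than as negative
#' concentrations.
#'
#' @param curve a usable [fit_standard_curve()] result (positive slope).
#' @param reading fluorescence reading(s) in a.u.
#' @return concentration(s) in beads/ml with logical attribute
#'   `below_background`.
#' @export
reading_to_concentration <- function(curve, reading) {
  stopifnot(inherits(curve, "standard_curve"), is.numeric(reading))
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    stopf("unusable standard curve: slope must be positive")
  }
  conc <- (reading - curve$intercept) / curve$slope
  below <- conc <= 0 & reading <= curve$intercept
  conc[conc < 0] <- 0
  structure(conc, below_background = below)
}

#' Percent of injected dose present in a compartment
#'
#' 100 x concentration x compartment volume / dose. The compartment
#' (anterior chamber) volume is a required per-species input -- roughly
#' 250-300 ul for pig and human eyes -- with no silent default.
#'
#' @param concentration bead concentration in beads/ml.
#' @param compartment_volume_ul compartment volume in ul.
#' @param dose injected beads (> 0), e.g. from [injected_dose()].
#' @return percentage of the injected dose.
#' @examples
#' percent_injected(1e10, 250, injected_dose(fluosphere_specs()$green, 50))
#' @export
percent_injected <- function(concentration, compartment_volume_ul, dose) {
  stopifnot(is.numeric(concentration), all(compartment_volume_ul > 0))
  if (any(!is.finite(dose)) || any(dose <= 0)) stopf("dose must be positive")
  100 * concentration * (compartment_volume_ul / 1000) / dose
}

#' Anterior dispersion rate from timed aqueous samples
#'
#' Least-squares slope of anterior-chamber bead concentration versus time
#' (beads/ml/h), the quantity used to compare particle sizes and species.
#' By default only the sampled time points enter the fit (the reference
#' analysis uses the 2 h and 4 h samples); `anchor_origin = TRUE`
#' additionally includes an implicit (0 h, 0) point.
#'
#' @param samples data frame with numeric columns `time_h` and
#'   `concentration` (beads/ml), optionally a `channel` column.
#' @param channel optional channel to filter on.
#' @param anchor_origin include a (0, 0) anchor point in the fit.
#' @param species,size optional labels carried on the estimate.
#' @return an object of class `dispersion_estimate` with `rate`
#'   (beads/ml/h), `intercept` (beads/ml) and `n_points`.
#' @export
dispersion_rate <- function(samples, channel = NULL, anchor_origin = FALSE,
                            species = NULL, size = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("time_h", "concentration") %in% names(samples)))
  if (!is.null(channel) && "channel" %in% names(samples)) {
    samples <- samples[samples$channel == channel, , drop = FALSE]
  }
  t <- samples$time_h
  y <- samples$concentration
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (anchor_origin) {
    t <- c(0, t); y <- c(0, y)
  }
  if (length(t) < 2 || length(unique(t)) < 2) {
    stopf("dispersion rate needs >= 2 distinct time points")
  }
  fit <- stats::lm(y ~ t)
  structure(list(species = species, size = size,
                 rate = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_points = length(t)),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  lab <- paste(c(x$species, x$size), collapse = " ")
  cat(sprintf("Anterior dispersion rate%s: %s beads/ml/h (n = %d, intercept %s)\n",
              if (nzchar(lab)) paste0(" [", lab, "]") else "",
              fmt_signif(x$rate, 3), x$n_points, fmt_signif(x$intercept, 3)))
  invisible(x)
}

#' Species (or condition) fold ratio of dispersion rates
#'
#' rate_a / rate_b. The reference 20 nm comparison is 1.62e10 (pig)
#' over 6.15e9 (human) = 2.63-fold.
#'
#' @param rate_a,rate_b [dispersion_rate()] estimates or bare numeric
#'   rates; `rate_b` must be positive.
#' @return dimensionless fold ratio.
#' @export
species_fold_ratio <- function(rate_a, rate_b) {
  val <- function(x) if (inherits(x, "dispersion_estimate")) x$rate else as.numeric(x)
  a <- val(rate_a); b <- val(rate_b)
  if (!is.finite(b) || b <= 0) stopf("denominator rate must be positive")
  a / b
}
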