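# Poroelastic scaling of an intravitreal injection.
#
# An ITV bolus of radius a inside a vitreous globe of radius R0 relaxes by
# driving Darcy flow through the vitreous (hydraulic permeability kappa)
# under the injection overpressure P0. Three scalars summarise the
# transient: the advection time constant tau, the Darcy velocity scale V0,
# and the transport length L0 = tau * V0 over which injected fluid can be
# carried before the pressure transient dissipates.
#
# Internal unit regime is CGS (cm, s, dyn); clinical units (microlitres,
# mmHg) enter only through the explicit converters below.

# 1 mmHg in dyn cm^-2, from 101325 Pa / 760 mmHg = 133.322 Pa expressed in CGS.
MMHG_DYN_CM2 <- 1333.22

# Version tag for the tau formula actually implemented (see
# advection_time_constant): denominator a*kappa*P0, no factor 3.
FORMULA_VERSION <- "tau-akP0-v1"

#' Convert pressure from mmHg to CGS units
#'
#' Multiplies by the exact constant 1333.22 dyn cm^-2 per mmHg
#' (101325 Pa / 760, expressed in CGS). Sign is preserved, so gauge
#' pressures below ambient are allowed.
#'
#' @param pressure pressure in mmHg (numeric, any sign).
#' @return pressure in dyn cm^-2.
#' @examples
#' mmhg_to_cgs(50)   # ~6.7e4 dyn cm^-2
#' @export
mmhg_to_cgs <- function(pressure) {
  stopifnot(is.numeric(pressure), all(is.finite(pressure)))
  pressure * MMHG_DYN_CM2
}

#' Convert pressure from CGS units to mmHg
#' @param pressure pressure in dyn cm^-2.
#' @return pressure in mmHg.
#' @export
cgs_to_mmhg <- function(pressure) {
  stopifnot(is.numeric(pressure), all(is.finite(pressure)))
  pressure / MMHG_DYN_CM2
}

#' Radius of the injected bolus
#'
#' Radius of the sphere with the same volume as the injected dose:
#' a = (3 V / 4 pi)^(1/3), with V converted from microlitres to cm^3.
#' A 50 microlitre injection gives a = 0.23 cm (2 s.f.).
#'
#' @param volume_ul injected volume in microlitres (> 0).
#' @return bolus radius in cm.
#' @examples
#' injection_radius(50)  # 0.2285 cm
#' @export
injection_radius <- function(volume_ul) {
  stopifnot(is.numeric(volume_ul))
  if (any(!is.finite(volume_ul)) || any(volume_ul <= 0)) {
    stopf("injection volume must be positive and finite")
  }
  (3 * volume_ul * 1e-3 / (4 * pi))^(1 / 3)
}

#' Injection overpressure from ocular rigidity
#'
#' Lower-bound estimate of the initial injection overpressure P0: the globe
#' stiffens by roughly 1 mmHg per microlitre of added volume (ocular
#' rigidity), so a bolus of `volume_ul` raises IOP by at least
#' volume * rigidity. Returned in CGS units for direct use in the
#' poroelastic formulas.
#'
#' @param volume_ul injected volume in microlitres (>= 0).
#' @param rigidity_mmhg_per_ul ocular rigidity in mmHg per microlitre
#'   (default 1, the standard whole-globe value).
#' @return overpressure in dyn cm^-2 (a lower bound on P0).
#' @examples
#' injection_overpressure(50)  # ~6.7e4 dyn cm^-2 (50 mmHg)
#' @export
injection_overpressure <- function(volume_ul, rigidity_mmhg_per_ul = 1) {
  stopifnot(is.numeric(volume_ul), is.numeric(rigidity_mmhg_per_ul))
  if (any(volume_ul < 0)) stopf("injection volume must be non-negative")
  if (any(rigidity_mmhg_per_ul <= 0)) stopf("ocular rigidity must be positive")
  mmhg_to_cgs(volume_ul * rigidity_mmhg_per_ul)
}

#' Poroelastic parameter set
#'
#' Bundles the five quantities controlling the injection transient, in CGS
#' units: fluid volume fraction `f` (~1 for the highly porous vitreous),
#' vitreous radius `R0` (1.2 cm for porcine or human eyes), bolus radius
#' `a`, hydraulic permeability `kappa` (8.4e-8 cm^4 dyn^-1 s^-1, bovine
#' vitreous measurement) and initial overpressure `P0`. `a` and `P0` may
#' instead be derived from an injected volume (and ocular rigidity) via
#' [injection_radius()] and [injection_overpressure()].
#'
#' @param f fluid volume fraction, in (0, 1].
#' @param R0 vitreous radius in cm.
#' @param kappa hydraulic permeability in cm^4 dyn^-1 s^-1.
#' @param a bolus radius in cm (0 < a <= R0), or `NULL` to derive from
#'   `injection_volume_ul`.
#' @param P0 injection overpressure in dyn cm^-2 (>= 0), or `NULL` to derive
#'   from `injection_volume_ul` and `rigidity_mmhg_per_ul`.
#' @param injection_volume_ul injected volume in microlitres, used when `a`
#'   or `P0` is not given directly.
#' @param rigidity_mmhg_per_ul ocular rigidity used to derive `P0`.
#' @return an object of class `poroelastic_params`.
#' @examples
#' # the printed reference configuration: 50 ul injection, lower-bound P0
#' p <- poroelastic_params(injection_volume_ul = 50)
#' transport_scales(p)
#' @export
poroelastic_params <- function(f = 1, R0 = 1.2, kappa = 8.4e-8,
                               a = NULL, P0 = NULL,
                               injection_volume_ul = NULL,
                               rigidity_mmhg_per_ul = 1) {
  if (is.null(a)) {
    if (is.null(injection_volume_ul)) stopf("supply either `a` or `injection_volume_ul`")
    a <- injection_radius(injection_volume_ul)
  }
  if (is.null(P0)) {
    if (is.null(injection_volume_ul)) stopf("supply either `P0` or `injection_volume_ul`")
    P0 <- injection_overpressure(injection_volume_ul, rigidity_mmhg_per_ul)
  }
  stopifnot(length(f) == 1, length(R0) == 1, length(a) == 1,
            length(kappa) == 1, length(P0) == 1)
  if (!is.finite(f) || f <= 0 || f > 1) stopf("f must be in (0, 1]")
  if (!is.finite(R0) || R0 <= 0) stopf("R0 must be positive")
  if (!is.finite(a) || a <= 0 || a > R0) stopf("a must satisfy 0 < a <= R0")
  if (!is.finite(kappa) || kappa <= 0) stopf("kappa must be positive")
  if (!is.finite(P0) || P0 < 0) stopf("P0 must be non-negative")
  structure(list(f = f, R0 = R0, a = a, kappa = kappa, P0 = P0),
            class = "poroelastic_params")
}

#' @export
print.poroelastic_params <- function(x, ...) {
  cat("Poroelastic parameters (CGS):\n")
  cat(sprintf("  f     = %g            (fluid volume fraction)\n", x$f))
  cat(sprintf("  R0    = %g cm         (vitreous radius)\n", x$R0))
  cat(sprintf("  a     = %g cm      (bolus radius)\n", signif(x$a, 4)))
  cat(sprintf("  kappa = %g cm^4/(dyn s)\n", x$kappa))
  cat(sprintf("  P0    = %g dyn/cm^2  (%s mmHg)\n", signif(x$P0, 4),
              fmt_signif(cgs_to_mmhg(x$P0), 3)))
  invisible(x)
}

#' Advection time constant of the injection transient
#'
#' tau = f (R0 - a)^3 / (a kappa P0): the characteristic time over which
#' the injection-driven trans-vitreal flow persists. With the reference
#' inputs (f = 1, R0 = 1.2 cm, a = 0.23 cm, kappa = 8.4e-8, P0 = 6.7e4
#' dyn cm^-2) this evaluates to 705 s.
#'
#' Degenerate boundaries return defined sentinels rather than erroring,
#' since parameter sweeps legitimately touch them: `P0 = 0` gives `Inf`
#' (no driving pressure, the transient never relaxes); `a = R0` gives 0
#' (no vitreous shell to traverse).
#'
#' @param params a [poroelastic_params()] object.
#' @return time constant in seconds.
#' @export
advection_time_constant <- function(params) {
  stopifnot(inherits(params, "poroelastic_params"))
  with(params, {
    if (a == R0) return(0)
    if (P0 == 0) return(Inf)
    f * (R0 - a)^3 / (a * kappa * P0)
  })
}

#' Darcy velocity scale of the injection transient
#'
#' V0 = kappa P0 / R0: the order of magnitude of the fluid velocity induced
#' in the vitreous by a local pressure elevation P0 over a region of size
#' R0 (Darcy's law). Reference inputs give 4.7e-3 cm s^-1.
#'
#' @inheritParams advection_time_constant
#' @return velocity in cm s^-1.
#' @export
darcy_velocity <- function(params) {
  stopifnot(inherits(params, "poroelastic_params"))
  with(params, kappa * P0 / R0)
}

#' Transport length scale of the injection transient
#'
#' L0 = tau * V0: the distance fluid can be advected before the pressure
#' transient dissipates. Algebraically P0 cancels
#' (L0 = f (R0 - a)^3 / (a R0)), but the value is computed as the product
#' of [advection_time_constant()] and [darcy_velocity()] so the tau
#' sentinels propagate (`P0 = 0` yields `NaN` from `Inf * 0`). Reference
#' inputs give 3.3 cm -- larger than the eye, supporting bidirectional
#' dispersion of injected material.
#'
#' @inheritParams advection_time_constant
#' @return length in cm.
#' @export
transport_length <- function(params) {
  advection_time_constant(params) * darcy_velocity(params)
}

#' Transport scales summary
#'
#' Computes all three scaling quantities (tau, V0, L0) for a parameter set.
#'
#' @inheritParams advection_time_constant
#' @return an object of class `transport_scales` with fields `tau` (s),
#'   `V0` (cm s^-1), `L0` (cm) and the input `params`.
#' @examples
#' p <- poroelastic_params(a = 0.23, P0 = 6.7e4)
#' s <- transport_scales(p)
#' s$tau  # 705 s at 3 s.f.
#' @export
transport_scales <- function(params) {
  structure(list(tau = advection_time_constant(params),
                 V0 = darcy_velocity(params),
                 L0 = transport_length(params),
                 params = params),
            class = "transport_scales")
}

#' @export
print.transport_scales <- function(x, digits = 2, ...) {
  cat("Intravitreal injection transport scales:\n")
  cat(sprintf("  tau = %s s       (advection time constant)\n",
              fmt_signif(x$tau, max(digits, 3))))
  cat(sprintf("  V0  = %s cm/s  (Darcy velocity scale)\n", fmt_signif(x$V0, digits)))
  cat(sprintf("  L0  = %s cm      (transport length)\n", fmt_signif(x$L0, digits)))
  invisible(x)
}

#' Machine-readable transport report
#'
#' Report of the scaling analysis: full-precision values plus 2-s.f.
#' display strings, the inputs, and the formula version tag.
#'
#' @inheritParams advection_time_constant
#' @return a list suitable for JSON serialisation.
#' @export
transport_report <- function(params) {
  s <- transport_scales(params)
  list(
    tau_s = s$tau,
    V0_cm_s = s$V0,
    L0_cm = s$L0,
    display = list(tau_s = fmt_signif(s$tau, 3),
                   V0_cm_s = fmt_signif(s$V0, 2),
                   L0_cm = fmt_signif(s$L0, 2)),
    inputs = unclass(params),
    formula_version = FORMULA_VERSION
  )
}
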