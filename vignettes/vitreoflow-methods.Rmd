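---
title: "vitreoflow: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vitreoflow: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitreoflow)
```

# The problem

Intravitreally (ITV) injected drug formulations do not stay where they are
put. Particles can migrate anteriorly, accumulate in the anterior chamber
(AC) and block aqueous drainage, raising intraocular pressure. vitreoflow
implements the quantitative analysis layer of an organotypic whole-globe
perfusion approach to this problem: perfused enucleated eyes receive an ITV
injection of sized fluorescent microbeads (20 nm and 2000 nm) or drug
suspensions, the AC is sampled over 4 h, and bead or particle flux is
quantified. A closed-form poroelastic scaling analysis explains why injected
material can disperse across the whole eye in tens of minutes.

# Poroelastic scaling of an injection

An injected bolus of radius $a$ inside a vitreous globe of radius $R_0$
creates an overpressure $P_0$ that drives Darcy flow through the vitreous
(hydraulic permeability $\kappa$, fluid fraction $f$). Three scales
summarise the transient:

$$\tau = \frac{f\,(R_0-a)^3}{a\,\kappa\,P_0}, \qquad
  V_0 = \frac{\kappa P_0}{R_0}, \qquad
  L_0 = \tau\,V_0 = \frac{f\,(R_0-a)^3}{a\,R_0}.$$

Defaults and units (all CGS internally; public entry points accept
microlitres and mmHg through explicit converters, 1 mmHg = 1333.22
dyn cm$^{-2}$ from 101325 Pa / 760):

| symbol | meaning | default | why |
|---|---|---|---|
| $f$ | fluid volume fraction | 1 | the vitreous is ~99% water |
| $R_0$ | vitreous radius | 1.2 cm | porcine/human globe |
| $a$ | bolus radius | from volume: $(3V/4\pi)^{1/3}$, 0.23 cm at 50 µl | equal-volume sphere |
| $\kappa$ | hydraulic permeability | 8.4e-8 cm$^4$ dyn$^{-1}$ s$^{-1}$ | bovine vitreous measurement |
| $P_0$ | injection overpressure | volume × 1 mmHg/µl (50 mmHg for 50 µl) | ocular rigidity; a lower bound |

```{r}
p <- poroelastic_params(a = 0.23, P0 = 6.7e4)
transport_scales(p)
```

**Formula reconstruction.** The $\tau$ expression is sometimes typeset
flattened ("f (Ro−a)3aκPo"). The implemented form, with denominator
$a\kappa P_0$ and no factor 3, is fixed by the printed worked value: the
quoted inputs give 705 s with this form and 235 s with a $3a$ denominator.
The package records the choice as `formula_version = "tau-akP0-v1"` in
every transport report. Whether the source consolidation theory carries a
factor 3 remains flagged, not guessed.

**Degenerate inputs.** $P_0 = 0$ returns $\tau = \infty$ (and `NaN` for
$L_0$, since the sentinel propagates through the product); $a = R_0$
returns $\tau = L_0 = 0$. These are defined sentinels, not errors, because
parameter sweeps legitimately touch them.

## The numerical oracle, and why it has two clocks

`simulate_relaxation()` provides an independent numerical check of the
scaling. It returns two time scales, and the distinction matters:

- **Consolidation clock.** The quasi-static pressure-diffusion problem
  $\partial_t p = (\kappa K_\mathrm{eff}/f)\nabla^2 p$ with
  $K_\mathrm{eff} = P_0$ (the only pressure scale available) is solved by
  explicit finite differences on $r \in [0, R_0]$, with $p = P_0$ in the
  bolus initially and $p = 0$ at the outer boundary. The fitted
  exponential decay of the mean bolus overpressure is the *consolidation*
  time. Eigenanalysis of the spherical problem shows this mode scales as
  $\sim 4a/(\pi^2 (R_0-a))\cdot\tau$ — roughly 10–30 times shorter than
  $\tau$ near the reference configuration. Pressure diffuses much faster
  than fluid is advected; a pressure-decay fit therefore *cannot* validate
  an advection time, no matter how the solver is tuned.
- **Advection clock (the comparator).** $\tau$ is an advection time: how
  long injected fluid keeps moving, and how far. Its numerical
  counterpart is the transit time of a fluid tracer from the bolus
  surface to the outer boundary under the quasi-steady Darcy field
  $v(r) = \kappa P_0 / (r^2(1/a - 1/R_0))$, evaluated by Simpson
  quadrature of $\int_a^{R_0} f/v(r)\,dr$ (`darcy_transit_time()`).
  Analytically this equals
  $f(1/a - 1/R_0)(R_0^3 - a^3)/(3\kappa P_0)$, i.e.
  $\tau \cdot (1 + x + x^2)/(3(1-x))$ with $x = a/R_0$ — between
  one-third of $\tau$ and $\tau$ for all realistic geometries, with the
  same parameter scaling in $f$, $\kappa$ and $P_0$ exactly.

`fitted_time` is the advection clock; it is the quantity compared against
$\tau$ in the factor-of-5 agreement tests. The consolidation clock is
reported alongside as a diagnostic of the field solve. Both are
order-of-magnitude validators; neither reproduces the full poroelastic
solution for a finite elastic-shelled globe, which is out of scope.

```{r}
prof <- simulate_relaxation(p, n_radii = 32, n_times = 16)
prof
```

# Perfusion quality control

Enucleated eyes are perfused with synthetic aqueous humour at a constant
2.4 µl min$^{-1}$ (average aqueous turnover). With no episcleral venous
pressure ex vivo, outflow facility is simply $C = F/\mathrm{IOP}$
(µl min$^{-1}$ mmHg$^{-1}$); there is deliberately no EVP term anywhere in
the package. Eyes qualify when facility stays inside the species range —
pig 0.18–0.35, human (and cynomolgus) expanded to 0.18–0.40 — over a
stable window.

Two QC conventions are the package's own, since the protocol states none:

- **Stability**: over the final 30 min (the stable-perfusion window),
  max − min facility must not exceed 10% of the window mean.
- **Masking**: transient non-positive pressures (aqueous sampling
  depressurises the port) yield missing facility values, not errors.

Drug response (`facility_response()`) is the contralateral-controlled fold
change: (treated post/pre facility) / (control post/pre), matching how a
cytochalasin-D viability check is read out.

# Bead quantification

Stock arithmetic: beads/ml $= 6 S \times 10^{12} / (\rho \pi \phi^3)$ for
solids $S$ (g/ml), polymer density $\rho$ (g/ml), diameter $\phi$ (µm).
The vendor-stated stock concentrations used for dosing (green 20 nm:
4.143e13; red 2000 nm: 1.326e8 beads/ml) are **not** reproduced by this
formula at $S = 0.02$, $\rho = 1.055$ (discrepancies of order 10–100×).
The package stores the vendor values as data (`fluosphere_specs()`) and
keeps the formula as an independent operation; the inconsistency is
documented, not resolved.

Standard curves are fitted with a free intercept — plate readers have
background fluorescence, and the protocol does not state a through-origin
fit. Readings at or below the fitted background invert to concentration 0
with a `below_background` flag rather than to negative concentrations.

The anterior **dispersion rate** is the least-squares slope of AC
concentration versus time. The default fits only the sampled time points
(the reference analysis uses the 2 h and 4 h samples); `anchor_origin =
TRUE` optionally adds an implicit (0, 0). Percent-of-injected conversion
requires an explicit AC volume — pig/human ≈ 250–300 µl is a literature
convention, not a measured quantity here, so there is no silent default.

# Particle imaging

Counting follows the simple protocol it emulates: global threshold (fixed,
or Otsu on request), 8-connected components, regions below 4 px discarded
as shot noise, equivalent diameter $\phi = s\sqrt{4A/\pi}$ for area $A$
(px) and pixel size $s$ (µm). Touching particles are **not** split (no
watershed); this is a documented limitation consistent with the simple
counting it mirrors. Summaries require at least three images per sample
(counts averaged, diameters pooled); lowering the minimum warns. Since no
TIFF reader is installed in the supported environment, images are
exchanged as grayscale PNG or in-memory matrices.

# The synthetic world

The generators emulate each measurement process so every stage is testable
without wet-lab data. Defaults are the stated experimental conditions where
they exist, and fixed conventions where they do not:

- **Pressure traces**: $P(t) = F/C + \text{drift}\cdot t + $ AR(1) noise
  (coefficient 0.8, stationary sd 0.3 mmHg by default) — smooth
  physiological noise; 240 min at 2.4 µl min$^{-1}$.
- **Bead kinetics**: a two-compartment mass balance. The vitreous depot
  loses beads at first-order $k$; the AC (250 µl) receives them; sampling
  at 2 h and 4 h withdraws 30 µl of mixed fluid, refilled bead-free.
  Bead number is conserved exactly in the noiseless model (vitreous + AC
  + washed out + sampled = dose), and the analytic propagation is tested
  against an independent fine-step Euler integration.
- **Bead washout defaults to zero.** Fluid turns over at the infusion
  rate (0.58 h$^{-1}$), but the observed AC accumulation is near-linear
  over 0–4 h, which is incompatible with beads leaving at the fluid
  turnover rate; histologically, beads reaching the outflow tissues are
  retained in the meshwork. The washout term is fully implemented and
  tested at nonzero rates, but the default world has none.
- **Sampling dilution is real and uncorrected**: withdrawing 30 µl of a
  250 µl AC at 2 h depresses the noiseless 4 h point, so the generating
  rate (the noiseless-model regression slope, returned as ground truth)
  is ≈ 0.88 of the undisturbed limit $k\,\mathrm{dose}/V_{AC}$. The two
  coincide as the sample volume vanishes, and parameter-recovery tests
  compare against each in its own regime.
- **Species presets** (`reference_transfer_model()`) choose $k$ per
  channel so the noiseless world reproduces the reported rate magnitudes
  (pig 20 nm ~1.6e10, human 20 nm ~6e9, 2000 nm ~1e3 beads ml$^{-1}$
  h$^{-1}$) at a 250 µl AC — a ~10$^6$–10$^7$-fold size contrast.
- **Plate readings**: mean-one multiplicative lognormal noise on the
  line, the plate-reader convention.
- **Micrographs**: non-overlapping disks (≥ 2 px background gap, so
  planted objects never touch under 8-connectivity), lognormal diameters
  (median 15 µm for a milled 10–20 µm suspension, 7.5 µm for a 5–10 µm
  one), additive Gaussian noise at the stated SNR over a 0.5 background
  offset, clipped at zero.

All generators fan a single seed into per-stage substreams and are
bit-reproducible given (parameters, seed).

What a green test does and does not establish: recovery tests show the
estimators are unbiased and precise *under these noise models and this
compartmental abstraction*. Real eyes add vitreous heterogeneity,
convection from the corneal temperature gradient, reservoir-refill
artefacts, spectral crosstalk between fluorophores and particle
aggregation — none of which the generators model, and none of which a
passing suite certifies.

# Known limitations

- The scaling analysis treats an infinite porous medium; a finite globe
  bounded by an elastic shell (scleral expansion, global pressure rise)
  is explicitly out of scope.
- Hindered transport of particles and macromolecules is not modelled;
  $L_0$ bounds fluid, not particle, displacement.
- No constant-pressure perfusion mode, no EVP, no circadian IOP models.
- No spectral unmixing; each fluorescence channel is treated
  independently.
- Touching particles count as one region.
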