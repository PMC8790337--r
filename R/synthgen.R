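# Seeded generators emulating each measurement stage: stable pressure
# traces, two-compartment vitreous-to-anterior-chamber bead transfer with
# timed aqueous sampling, plate-reader fluorescence, and particle
# micrographs with planted ground truth.
#
# Noise models (none are stated by the measurement protocols; these are
# the field conventions): AR(1) for pressure (physiological smoothness),
# mean-one multiplicative lognormal for fluorescence and concentration
# measurements (plate-reader convention), additive Gaussian for images.
# All generators are reproducible given (parameters, seed).

#' Simulate a constant-flow pressure trace
#'
#' P(t) = flow / true_facility + drift * t + AR(1) noise, the signature of
#' a stable perfusion at constant infusion. Returned as a
#' [perfusion_record()] so the QC stage consumes it directly.
#'
#' @param true_facility generating outflow facility in ul/min/mmHg (> 0).
#' @param flow infusion rate in ul/min.
#' @param duration_min trace length in minutes.
#' @param dt_min sampling interval in minutes.
#' @param noise_sd_mmhg stationary standard deviation of the AR(1) noise.
#' @param drift_mmhg_per_h linear pressure drift.
#' @param ar_coef AR(1) coefficient in [0, 1).
#' @param seed RNG seed (`NULL` uses the current stream).
#' @param eye_id,species record labels.
#' @return a [perfusion_record()].
#' @examples
#' rec <- simulate_pressure_trace(0.25, seed = 1)
#' mean(rec$pressures)  # ~ 2.4 / 0.25 = 9.6 mmHg
#' @export
simulate_pressure_trace <- function(true_facility, flow = 2.4,
                                    duration_min = 240, dt_min = 1,
                                    noise_sd_mmhg = 0, drift_mmhg_per_h = 0,
                                    ar_coef = 0.8, seed = NULL,
                                    eye_id = "synthetic", species = "pig") {
  stopifnot(true_facility > 0, flow > 0, duration_min > 0, dt_min > 0,
            ar_coef >= 0, ar_coef < 1)
  times <- seq(0, duration_min, by = dt_min)
  n <- length(times)
  noise <- with_seed(seed, {
    if (noise_sd_mmhg > 0) {
      e <- numeric(n)
      e[1] <- stats::rnorm(1, 0, noise_sd_mmhg)
      innov_sd <- noise_sd_mmhg * sqrt(1 - ar_coef^2)
      z <- stats::rnorm(n - 1, 0, innov_sd)
      for (i in seq_len(n - 1)) e[i + 1] <- ar_coef * e[i] + z[i]
      e
    } else numeric(n)
  })
  pressures <- flow / true_facility + drift_mmhg_per_h * times / 60 + noise
  perfusion_record(eye_id, species, flow, times, pressures)
}

#' Two-compartment bead transfer model
#'
#' The generating world for anterior bead kinetics: a vitreous depot loses
#' beads to the anterior chamber at first-order rate `k_transfer` (h^-1);
#' the AC (volume `ac_volume_ul`) is diluted by bead-carrying outflow at
#' `washout_rate`; each aqueous sampling removes `sample_volume` of mixed
#' fluid (replaced by bead-free synthetic aqueous humour). Bead number is
#' conserved exactly in the noiseless model.
#'
#' The default `washout_rate = 0` reflects the observed near-linear 0-4 h
#' AC accumulation: microbeads reaching the outflow tissues are retained
#' in the meshwork on this horizon rather than cleared, so the effective
#' bead washout is negligible even though fluid turns over at the
#' infusion rate. Nonzero washout is fully supported.
#'
#' @param injected_dose named numeric vector of beads per channel (e.g.
#'   `c(green = 1.04e12, red = 3.3e6)`).
#' @param k_transfer named numeric vector of transfer rates (h^-1), same
#'   names as `injected_dose`, all >= 0.
#' @param ac_volume_ul anterior chamber volume in ul (> 0; 250 is the
#'   pig/human literature convention).
#' @param washout_rate bead-carrying outflow in ul/min (>= 0).
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise on sampled concentrations.
#' @param seed RNG seed.
#' @return an object of class `transfer_model`.
#' @seealso [reference_transfer_model()] for species presets matching the
#'   reported dispersion-rate magnitudes.
#' @export
transfer_model <- function(injected_dose, k_transfer, ac_volume_ul = 250,
                           washout_rate = 0, noise_cv = 0.05, seed = NULL) {
  stopifnot(is.numeric(injected_dose), is.numeric(k_transfer),
            length(injected_dose) == length(k_transfer))
  if (is.null(names(injected_dose))) names(injected_dose) <- paste0("ch", seq_along(injected_dose))
  if (is.null(names(k_transfer))) names(k_transfer) <- names(injected_dose)
  stopifnot(identical(sort(names(injected_dose)), sort(names(k_transfer))))
  if (any(k_transfer < 0)) stopf("k_transfer must be non-negative")
  if (ac_volume_ul <= 0) stopf("ac_volume_ul must be positive")
  if (washout_rate < 0) stopf("washout_rate must be non-negative")
  structure(list(injected_dose = injected_dose,
                 k_transfer = k_transfer[names(injected_dose)],
                 ac_volume_ul = ac_volume_ul, washout_rate = washout_rate,
                 noise_cv = noise_cv, seed = seed),
            class = "transfer_model")
}

#' Reference transfer-model presets by species
#'
#' Doses from the 50 ul 1:1 injection of the reference bead stocks
#' ([fluosphere_specs()]); transfer rates chosen so the noiseless
#' generating world reproduces the reported dispersion-rate magnitudes
#' (pig 20 nm ~1.6e10, human 20 nm ~6e9, 2000 nm ~1e3 beads/ml/h) at a
#' 250 ul anterior chamber.
#'
#' @param species `"pig"` or `"human"`.
#' @param noise_cv,seed passed to [transfer_model()].
#' @return a [transfer_model()].
#' @export
reference_transfer_model <- function(species = c("pig", "human"),
                                     noise_cv = 0.05, seed = NULL) {
  species <- match.arg(species)
  specs <- fluosphere_specs()
  dose <- c(green = injected_dose(specs$green, 50, 0.5),
            red = injected_dose(specs$red, 50, 0.5))
  ac <- 250
  rates <- switch(species,
                  pig = c(green = 1.62e10, red = 2.45e3),
                  human = c(green = 6.15e9, red = 3.59e3))
  k <- rates * (ac / 1000) / dose
  transfer_model(dose, k, ac_volume_ul = ac, noise_cv = noise_cv, seed = seed)
}

# Analytic propagation of (N_v, N_a) over dt hours with transfer k (h^-1)
# and washout turnover q (h^-1); returns the new state plus the exact
# washed-out increment from the channel mass balance.
propagate_compartments <- function(Nv, Na, k, q, dt) {
  Nv1 <- Nv * exp(-k * dt)
  Na1 <- if (abs(q - k) > 1e-12 * max(q, k, 1e-30)) {
    Na * exp(-q * dt) + k * Nv * (exp(-k * dt) - exp(-q * dt)) / (q - k)
  } else {
    Na * exp(-k * dt) + k * Nv * dt * exp(-k * dt)
  }
  washed_inc <- (Nv - Nv1) - (Na1 - Na)
  list(Nv = Nv1, Na = Na1, washed_inc = washed_inc)
}

#' Simulate timed aqueous sampling of bead transfer kinetics
#'
#' Runs the two-compartment mass balance of a [transfer_model()] and
#' samples the anterior chamber at `sample_times_h`. Each sample measures
#' the current AC concentration (with mean-one lognormal noise at the
#' model's `noise_cv`), then removes `sample_volume_ul` of mixed fluid --
#' beads leave in proportion and the volume is refilled bead-free, so the
#' remaining concentration drops by `(1 - sample_volume/ac_volume)`.
#'
#' Ground truth is attached as attribute `truth`: per channel the
#' noiseless concentrations, the generating rate (`rate_true`, the
#' noiseless least-squares slope at the sample times), its small-k
#' undisturbed-limit approximation `rate_small_k = k * dose / ac volume`,
#' and the exact bead budget (`conservation`: vitreous + AC + washed +
#' sampled = dose).
#'
#' @param model a [transfer_model()].
#' @param sample_times_h strictly increasing sampling times in hours.
#' @param sample_volume_ul volume withdrawn per sample in ul (< AC volume).
#' @return data frame with columns `channel`, `time_h`, `volume_ul`,
#'   `concentration` (measured, beads/ml) and `concentration_true`, with
#'   attribute `truth`.
#' @export
simulate_transfer_kinetics <- function(model, sample_times_h = c(2, 4),
                                       sample_volume_ul = 30) {
  stopifnot(inherits(model, "transfer_model"))
  if (any(diff(sample_times_h) <= 0) || any(sample_times_h < 0)) {
    stopf("sample times must be non-negative and strictly increasing")
  }
  if (sample_volume_ul < 0 || sample_volume_ul >= model$ac_volume_ul) {
    stopf("sample volume must be in [0, ac_volume)")
  }
  V <- model$ac_volume_ul
  q <- model$washout_rate * 60 / V     # washout turnover, h^-1
  channels <- names(model$injected_dose)
  rows <- list()
  truth_channels <- list()
  conservation <- list()

  for (ch in channels) {
    k <- model$k_transfer[[ch]]
    dose <- model$injected_dose[[ch]]
    Nv <- dose; Na <- 0; washed <- 0; sampled <- 0; t_now <- 0
    c_true <- numeric(length(sample_times_h))
    for (i in seq_along(sample_times_h)) {
      st <- propagate_compartments(Nv, Na, k, q, sample_times_h[i] - t_now)
      Nv <- st$Nv; Na <- st$Na; washed <- washed + st$washed_inc
      t_now <- sample_times_h[i]
      c_true[i] <- Na * 1000 / V                 # beads/ml
      samp_beads <- Na * sample_volume_ul / V
      sampled <- sampled + samp_beads
      Na <- Na - samp_beads
    }
    rate_true <- if (length(sample_times_h) >= 2) {
      unname(stats::coef(stats::lm(c_true ~ sample_times_h))[2])
    } else NA_real_
    truth_channels[[ch]] <- list(concentration_true = c_true,
                                 rate_true = rate_true,
                                 rate_small_k = k * dose / (V / 1000))
    conservation[[ch]] <- data.frame(channel = ch, vitreous = Nv, ac = Na,
                                     washed = washed, sampled = sampled,
                                     dose = dose)
    rows[[ch]] <- data.frame(channel = ch, time_h = sample_times_h,
                             volume_ul = sample_volume_ul,
                             concentration_true = c_true)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$concentration <- with_seed(model$seed, {
    if (model$noise_cv > 0) {
      sdlog <- sqrt(log(1 + model$noise_cv^2))
      out$concentration_true *
        stats::rlnorm(nrow(out), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else out$concentration_true
  })
  out <- out[, c("channel", "time_h", "volume_ul", "concentration",
                 "concentration_true")]
  attr(out, "truth") <- list(channels = truth_channels,
                             conservation = do.call(rbind, conservation))
  out
}

#' Simulate plate-reader fluorescence readings
#'
#' reading = (slope * concentration + intercept) * mean-one lognormal
#' noise at coefficient of variation `noise_cv`.
#'
#' @param true_concentrations bead concentrations in beads/ml.
#' @param curve_slope fluorescence per beads/ml (> 0).
#' @param curve_intercept background fluorescence (a.u.).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed RNG seed.
#' @return numeric vector of readings (a.u.).
#' @export
simulate_plate_readings <- function(true_concentrations, curve_slope,
                                    curve_intercept = 0, noise_cv = 0,
                                    seed = NULL) {
  stopifnot(is.numeric(true_concentrations), curve_slope > 0, noise_cv >= 0)
  line <- curve_slope * true_concentrations + curve_intercept
  with_seed(seed, {
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      line * stats::rlnorm(length(line), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else line
  })
}

#' Simulate a particle micrograph with planted ground truth
#'
#' Places `n_particles` non-overlapping disks (rejection sampling) with
#' lognormal equivalent diameters on a uniform background, then adds
#' Gaussian noise. Signal amplitude is 1 above a background offset of
#' 0.5, with noise standard deviation `1/snr`, so `snr` is the plateau
#' contrast over the noise scale; negative excursions are clipped at 0
#' (negligible for snr >= 5). Ground-truth centres and diameters are
#' attached as attribute `truth`.
#'
#' Diameter regimes of interest: median 15 um (sigma ~0.15) emulates a
#' milled 10-20 um suspension; median 7.5 um emulates a 5-10 um one.
#'
#' @param n_particles number of disks (>= 0).
#' @param median_diameter_um median of the lognormal diameter law (um).
#' @param sigma_log lognormal shape (sd of log diameter).
#' @param image_px image side in pixels (square image).
#' @param pixel_size_um pixel size in um.
#' @param snr plateau signal-to-noise ratio; `Inf` for noiseless.
#' @param seed RNG seed.
#' @param max_tries placement attempts per disk before a packing error.
#' @return a [particle_image()] with attribute `truth` (data frame of
#'   `row`, `col` in px and `diameter_um`).
#' @export
simulate_particle_field <- function(n_particles, median_diameter_um = 15,
                                    sigma_log = 0.15, image_px = 256,
                                    pixel_size_um = 0.65, snr = 10,
                                    seed = NULL, max_tries = 200) {
  stopifnot(n_particles >= 0, median_diameter_um > 0, image_px >= 16,
            pixel_size_um > 0, snr > 0)
  background <- 0.5
  amplitude <- 1
  res <- with_seed(seed, {
    diam <- if (n_particles > 0) {
      stats::rlnorm(n_particles, meanlog = log(median_diameter_um), sdlog = sigma_log)
    } else numeric(0)
    r_px <- diam / 2 / pixel_size_um
    centres <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n_particles)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- stats::runif(2, min = r_px[i] + 1, max = image_px - r_px[i] - 1)
        if (nrow(centres) == 0) { ok <- TRUE } else {
          d2 <- (centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2
          # >= 2 px background between disks: pixelated masks can protrude
          # up to ~1 px, and an 8-connected labeller must never see planted
          # objects touch
          ok <- all(d2 > (r_px[seq_len(nrow(centres))] + r_px[i] + 2)^2)
        }
        if (ok) { centres <- rbind(centres, cand); placed <- TRUE; break }
      }
      if (!placed) stopf("could not place %d non-overlapping particles in a %d px image",
                         n_particles, image_px)
    }
    img <- matrix(background, image_px, image_px)
    for (i in seq_len(n_particles)) {
      lo_r <- max(1, floor(centres[i, 1] - r_px[i])); hi_r <- min(image_px, ceiling(centres[i, 1] + r_px[i]))
      lo_c <- max(1, floor(centres[i, 2] - r_px[i])); hi_c <- min(image_px, ceiling(centres[i, 2] + r_px[i]))
      rr <- lo_r:hi_r; cc <- lo_c:hi_c
      d2 <- outer((rr - centres[i, 1])^2, (cc - centres[i, 2])^2, `+`)
      sub <- img[rr, cc]
      sub[d2 <= r_px[i]^2] <- background + amplitude
      img[rr, cc] <- sub
    }
    if (is.finite(snr)) {
      img <- img + matrix(stats::rnorm(image_px^2, 0, amplitude / snr),
                          image_px, image_px)
    }
    img[img < 0] <- 0
    list(img = img, centres = centres, diam = diam)
  })
  out <- particle_image(res$img, pixel_size_um)
  attr(out, "truth") <- data.frame(
    row = if (n_particles) res$centres[, 1] else numeric(0),
    col = if (n_particles) res$centres[, 2] else numeric(0),
    diameter_um = res$diam)
  out
}
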