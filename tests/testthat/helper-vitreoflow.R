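# Shared fixtures and small oracles, all built in code.

# Reference poroelastic configuration: 50 ul injection, lower-bound P0.
ref_params <- function(...) {
  args <- list(f = 1, R0 = 1.2, kappa = 8.4e-8, a = 0.23, P0 = 6.7e4)
  over <- list(...)
  args[names(over)] <- over
  do.call(poroelastic_params, args)
}

# Random valid parameter set for property sweeps.
random_params <- function() {
  R0 <- runif(1, 0.8, 2)
  poroelastic_params(f = runif(1, 0.5, 1), R0 = R0, kappa = 10^runif(1, -8.5, -7),
                     a = runif(1, 0.1, 0.6 * R0), P0 = 10^runif(1, 4, 5.5))
}

# Exact pixel disk (no noise) centred in an image, for detector oracles.
exact_disk_image <- function(radii_px, image_px = 128, pixel_size_um = 1,
                             centres = NULL) {
  img <- matrix(0, image_px, image_px)
  if (is.null(centres)) {
    centres <- cbind(seq(image_px / 4, 3 * image_px / 4,
                         length.out = length(radii_px)),
                     seq(image_px / 4, 3 * image_px / 4,
                         length.out = length(radii_px)))
  }
  for (i in seq_along(radii_px)) {
    rr <- seq_len(image_px)
    d2 <- outer((rr - centres[i, 1])^2, (rr - centres[i, 2])^2, `+`)
    img[d2 <= radii_px[i]^2] <- 1
  }
  particle_image(img, pixel_size_um)
}

# Match detections to planted ground truth by centroid distance; returns
# recall and precision.
recall_precision <- function(det, truth, pixel_size_um, tol_px = NULL) {
  if (is.null(tol_px)) tol_px <- pmax(3, truth$diameter_um / 2 / pixel_size_um)
  matched_truth <- logical(nrow(truth))
  matched_det <- logical(det$count)
  for (i in seq_len(nrow(truth))) {
    if (det$count == 0) break
    d <- sqrt((det$centroids[, 1] - truth$row[i])^2 +
                (det$centroids[, 2] - truth$col[i])^2)
    j <- which.min(d)
    if (d[j] <= tol_px[i] && !matched_det[j]) {
      matched_truth[i] <- TRUE
      matched_det[j] <- TRUE
    }
  }
  list(recall = mean(matched_truth),
       precision = if (det$count > 0) mean(matched_det) else 1)
}

# Full measurement chain for one seed: kinetics for n_eyes, plate
# simulation of standards + samples, curve fit, inversion, regression.
# Returns recovered rate / generating (noiseless-model) rate.
end_to_end_rate_recovery <- function(seed, n_eyes = 6, noise_cv = 0.05,
                                     species = "pig") {
  base <- reference_transfer_model(species, noise_cv = 0)
  specs <- fluosphere_specs()
  conc_meas <- unlist(lapply(seq_len(n_eyes), function(i) {
    m <- transfer_model(base$injected_dose, base$k_transfer,
                        ac_volume_ul = base$ac_volume_ul,
                        washout_rate = base$washout_rate,
                        noise_cv = noise_cv, seed = seed * 1000 + i)
    kin <- simulate_transfer_kinetics(m)
    kin$concentration[kin$channel == "green"]
  }))
  stds <- make_dilution_series(specs$green$stock_concentration * 0.5, 4, 10)
  std_read <- simulate_plate_readings(stds, 2e-9, 5, noise_cv,
                                      seed = seed * 1000 + 990)
  curve <- fit_standard_curve(stds, std_read, channel = "green")
  smp_read <- simulate_plate_readings(conc_meas, 2e-9, 5, noise_cv,
                                      seed = seed * 1000 + 991)
  conc_hat <- reading_to_concentration(curve, smp_read)
  est <- dispersion_rate(data.frame(time_h = rep(c(2, 4), n_eyes),
                                    concentration = as.numeric(conc_hat)))
  truth <- attr(simulate_transfer_kinetics(
    transfer_model(base$injected_dose, base$k_transfer,
                   ac_volume_ul = base$ac_volume_ul,
                   washout_rate = base$washout_rate, noise_cv = 0)), "truth")
  est$rate / truth$channels$green$rate_true
}
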