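# Particle detection, counting and equivalent-diameter sizing from
# grayscale micrographs of drug suspensions (spotted coverslips imaged
# under 488 nm excitation autofluorescence).
#
# Detection is deliberately simple, matching the counting procedure it
# emulates: global threshold (fixed or Otsu), 8-connected components,
# small-area rejection. Touching particles are not split.

#' Particle micrograph
#'
#' A grayscale intensity grid with its physical pixel size.
#'
#' @param pixels numeric matrix of non-negative finite intensities.
#' @param pixel_size_um physical size of one pixel in um (> 0).
#' @return an object of class `particle_image`.
#' @export
particle_image <- function(pixels, pixel_size_um) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    stopf("intensities must be finite and non-negative")
  }
  if (length(pixel_size_um) != 1 || !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stopf("pixel_size_um must be a single positive value")
  }
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "particle_image")
}

#' @export
print.particle_image <- function(x, ...) {
  cat(sprintf("Particle image: %d x %d px at %.3g um/px (%.0f x %.0f um)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              nrow(x$pixels) * x$pixel_size_um, ncol(x$pixels) * x$pixel_size_um))
  invisible(x)
}

#' Otsu threshold of an intensity grid
#'
#' Histogram-based threshold maximising between-class variance; the
#' automatic alternative to a fixed global threshold.
#'
#' @param pixels numeric matrix or vector of intensities.
#' @param n_bins histogram resolution.
#' @return threshold on the intensity scale of `pixels`.
#' @export
otsu_threshold <- function(pixels, n_bins = 256) {
  x <- as.numeric(pixels)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# 8-connected component labelling by iterative minimum-label propagation.
# Foreground pixels start with their linear index; each sweep replaces a
# pixel's label with the minimum over its 8-neighbourhood, so the smallest
# index floods each component. Converges in O(component diameter) sweeps.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  lab[mask] <- which(mask)
  if (!any(mask)) return(matrix(0L, nr, nc))
  pad_shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    out
  }
  repeat {
    new <- lab
    for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                   c(0, 1), c(1, -1), c(1, 0), c(1, 1))) {
      new <- pmin(new, pad_shift(lab, d[1], d[2]))
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nr, nc)
  ids <- sort(unique(lab[mask]))
  out[mask] <- match(lab[mask], ids)
  out
}

#' Detect particles in a micrograph
#'
#' Thresholds the image (foreground = intensity > threshold), labels
#' 8-connected components, and drops regions smaller than `min_area_px`
#' (shot-noise suppression). An empty foreground is a valid result of
#' zero regions, not an error. Detection counts are invariant under
#' uniform intensity rescaling when the threshold is rescaled identically.
#'
#' @param image a [particle_image()].
#' @param threshold intensity threshold, or `"otsu"` for automatic
#'   selection via [otsu_threshold()].
#' @param min_area_px minimum region area in pixels (default 4).
#' @return an object of class `particle_regions`: `labels` (integer
#'   matrix, 0 = background), `count`, `areas_px`, `centroids` (row/col,
#'   px), `diameters_um` (equivalent diameters) and `threshold`.
#' @export
detect_particles <- function(image, threshold = "otsu", min_area_px = 4) {
  stopifnot(inherits(image, "particle_image"))
  px <- image$pixels
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(px)
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  rng <- range(px)
  if (threshold < rng[1] - abs(rng[1]) - 1 || threshold > rng[2]) {
    # allow thresholds anywhere below max; above max just yields no regions
  }
  mask <- px > threshold
  labels <- label_components(mask)
  n_raw <- max(labels)
  if (n_raw == 0) {
    return(structure(list(labels = labels, count = 0L,
                          areas_px = numeric(0),
                          centroids = matrix(numeric(0), ncol = 2),
                          diameters_um = numeric(0), threshold = threshold,
                          pixel_size_um = image$pixel_size_um),
                     class = "particle_regions"))
  }
  areas <- tabulate(labels[labels > 0], nbins = n_raw)
  keep <- which(areas >= min_area_px)
  relab <- integer(n_raw)
  relab[keep] <- seq_along(keep)
  fg <- labels > 0
  labels[fg] <- relab[labels[fg]]
  idx <- which(labels > 0, arr.ind = TRUE)
  lab_v <- labels[labels > 0]
  centroids <- if (length(keep)) {
    cbind(row = as.numeric(tapply(idx[, 1], lab_v, mean)),
          col = as.numeric(tapply(idx[, 2], lab_v, mean)))
  } else matrix(numeric(0), ncol = 2)
  areas_kept <- areas[keep]
  structure(list(labels = labels, count = length(keep),
                 areas_px = areas_kept, centroids = centroids,
                 diameters_um = if (length(keep))
                   equivalent_diameter(areas_kept, image$pixel_size_um)
                 else numeric(0),
                 threshold = threshold, pixel_size_um = image$pixel_size_um),
            class = "particle_regions")
}

#' @export
print.particle_regions <- function(x, ...) {
  cat(sprintf("Detected %d particle(s) at threshold %.4g\n", x$count, x$threshold))
  if (x$count > 0) {
    cat(sprintf("  equivalent diameter: mean %.2f um, median %.2f um\n",
                mean(x$diameters_um), stats::median(x$diameters_um)))
  }
  invisible(x)
}

#' Equivalent diameter of a detected region
#'
#' Diameter of the circle with the same area as the region:
#' pixel_size * sqrt(4 area / pi).
#'
#' @param area_px region area in pixels (> 0).
#' @param pixel_size_um pixel size in um.
#' @return equivalent diameter in um.
#' @examples
#' equivalent_diameter(100, 0.5)  # 5.64 um
#' @export
equivalent_diameter <- function(area_px, pixel_size_um) {
  stopifnot(is.numeric(area_px), pixel_size_um > 0)
  if (any(area_px <= 0)) stopf("region area must be positive")
  pixel_size_um * sqrt(4 * area_px / pi)
}

#' Summarise particle counts and sizes across images
#'
#' Per-image counts are averaged and equivalent-diameter distributions
#' pooled, following the rule that particles are counted from at least
#' three images per sample and averaged. Fewer images than `min_images`
#' is an error unless the minimum is explicitly lowered, which warns.
#'
#' @param images list of [particle_image()] objects.
#' @param threshold intensity threshold or `"otsu"` (per image).
#' @param min_area_px minimum region area in pixels.
#' @param min_images required number of images (default 3).
#' @return an object of class `particle_stats`: `count` (mean per-image
#'   count), `counts_per_image`, pooled `diameters_um`,
#'   `mean_diameter_um`, `median_diameter_um`, `n_images`.
#' @export
summarize_particles <- function(images, threshold = "otsu", min_area_px = 4,
                                min_images = 3) {
  stopifnot(is.list(images), all(vapply(images, inherits, TRUE, "particle_image")))
  if (min_images < 3) warnf("fewer than 3 images per sample is below the standard rule")
  if (length(images) < min_images) {
    stopf("need >= %d images per sample, got %d", min_images, length(images))
  }
  dets <- lapply(images, detect_particles, threshold = threshold,
                 min_area_px = min_area_px)
  counts <- vapply(dets, `[[`, numeric(1), "count")
  diams <- unlist(lapply(dets, `[[`, "diameters_um"))
  structure(list(count = mean(counts), counts_per_image = counts,
                 diameters_um = diams,
                 mean_diameter_um = if (length(diams)) mean(diams) else NA_real_,
                 median_diameter_um = if (length(diams)) stats::median(diams) else NA_real_,
                 n_images = length(images)),
            class = "particle_stats")
}

#' @export
print.particle_stats <- function(x, ...) {
  cat(sprintf("Particle summary over %d images: %.1f particles/image\n",
              x$n_images, x$count))
  cat(sprintf("  equivalent diameter: mean %.2f um, median %.2f um (n = %d)\n",
              x$mean_diameter_um, x$median_diameter_um, length(x$diameters_um)))
  invisible(x)
}

#' Read a grayscale micrograph from PNG
#'
#' Multi-channel images are averaged to grayscale. Intensities are on the
#' PNG scale in [0, 1].
#'
#' @param path PNG file path.
#' @param pixel_size_um physical pixel size in um.
#' @return a [particle_image()].
#' @export
read_image_png <- function(path, pixel_size_um) {
  arr <- png::readPNG(path)
  px <- if (length(dim(arr)) == 3) apply(arr[, , seq_len(min(3, dim(arr)[3])), drop = FALSE],
                                         c(1, 2), mean) else arr
  particle_image(px, pixel_size_um)
}

#' Write a micrograph to grayscale PNG
#'
#' Intensities are clipped to [0, 1] for the 8-bit PNG encoding; analysis
#' should be run on the in-memory matrix when exact values matter.
#'
#' @param image a [particle_image()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  stopifnot(inherits(image, "particle_image"))
  px <- pmin(pmax(image$pixels, 0), 1)
  png::writePNG(px, path)
  invisible(path)
}
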