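# Shared fixtures, built in code.

# ideal (noiseless) model image on a centered grid, with render_image-style
# geometry attributes
ideal_model_image <- function(model, max_r = 250, pixel = 3) {
  n <- round(2 * max_r / pixel)
  xs <- -max_r + (seq_len(n) - 0.5) * pixel
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(xs, n, n)
  img <- model_density(model, X, Y)
  attr(img, "xlim") <- c(-max_r, max_r)
  attr(img, "ylim") <- c(-max_r, max_r)
  attr(img, "pixel_size") <- pixel
  img
}

# localization table of one synthetic ring site (one blink per molecule,
# fixed per-record precision)
ring_site_table <- function(n = 300, r_out = 70, dr = 30, precision = 15,
                            center = c(0, 0), shape = "ring") {
  spec <- structure_spec(shape, center = center, r_out = r_out, dr = dr,
                         n_molecules = n)
  man <- ground_truth_manifest(list(spec), n_frames = 100)
  emit_localizations(man, emission_model(mean_blinks = 1,
                                         precision_mean = precision,
                                         precision_sd = 0))
}

# uniform-disk cell footprint
disk_points <- function(n, center, radius) {
  r <- radius * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  cbind(center[1] + r * cos(a), center[2] + r * sin(a))
}

simple_table <- function(x, y, frame = 1L, photons = 1000, precision = 10,
                         sigma = 130, bg = 0) {
  localization_table(frame = frame, x_nm = x, y_nm = y, photons = photons,
                     bg = bg, sigma_nm = sigma, precision_nm = precision)
}
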