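## synthetic_data: ground-truth structures, localization tables, raw frames
## and diffraction-limited marker stacks with known parameters, so that every
## downstream stage can be tested by parameter recovery.

#' Ground-truth structure specification
#'
#' Describes one endocytic-site-like structure: a ring (annulus with a
#' central hole), a patch (filled disk, `dr >= r_out`), or a dome
#' (hemisphere of radius `r_out` projected onto the membrane plane).
#'
#' @param shape one of `"ring"`, `"patch"`, `"dome"`.
#' @param center numeric length-2, site center in nm.
#' @param r_out outer radius, nm (> 0).
#' @param dr rim thickness, nm (> 0). Patches have `dr >= r_out`.
#' @param n_molecules number of labelled molecules (>= 1).
#' @param dome_height dome height, nm; defaults to `r_out` (hemisphere).
#' @return an object of class `structure_spec`.
#' @export
structure_spec <- function(shape, center = c(0, 0), r_out, dr = r_out,
                           n_molecules, dome_height = r_out) {
  if (!is.character(shape) || length(shape) != 1L ||
      !shape %in% c("ring", "patch", "dome")) {
    stopf("'shape' must be one of \"ring\", \"patch\", \"dome\"")
  }
  check_number(r_out, "r_out", 0, strict = TRUE)
  check_number(dr, "dr", 0, strict = TRUE)
  check_number(n_molecules, "n_molecules", 1)
  if (shape == "patch" && dr < r_out) {
    stopf("a patch requires dr >= r_out (filled disk); got dr=%g, r_out=%g",
          dr, r_out)
  }
  if (length(center) != 2L || !all(is.finite(center))) {
    stopf("'center' must be a finite 2-vector (nm)")
  }
  structure(list(shape = shape, center = as.numeric(center),
                 r_out = r_out, dr = dr,
                 n_molecules = as.integer(n_molecules),
                 dome_height = dome_height),
            class = "structure_spec")
}

#' Emission model for simulated photoswitching
#'
#' Phenomenological model of mMaple-like blinking: each molecule emits a
#' geometric number of blinks (support >= 1, mean `mean_blinks`) in a run of
#' consecutive frames, with probability `blink_gap_prob` of a 1-frame dark
#' gap between successive blinks. Each blink is displaced from the true
#' molecule position by an isotropic Gaussian whose per-blink standard
#' deviation (the localization precision) is drawn from a Gaussian
#' (`precision_mean`, `precision_sd`) truncated below at 1 nm.
#'
#' @param mean_blinks mean blinks per molecule (> 0).
#' @param blink_gap_prob probability of a single-frame gap inside a blink run.
#' @param precision_mean,precision_sd per-blink localization precision
#'   distribution, nm; floor 1 nm.
#' @param psf_sigma PSF standard deviation used when rendering frames, nm.
#' @param photons_mean mean photons per blink.
#' @param background_rate spurious background localizations per square
#'   micrometre of field (over the whole acquisition).
#' @return an object of class `emission_model`.
#' @export
emission_model <- function(mean_blinks = 3, blink_gap_prob = 0.2,
                           precision_mean = 15, precision_sd = 5,
                           psf_sigma = 130, photons_mean = 1000,
                           background_rate = 0) {
  check_number(mean_blinks, "mean_blinks", 0, strict = TRUE)
  check_number(blink_gap_prob, "blink_gap_prob", 0)
  if (blink_gap_prob > 1) stopf("'blink_gap_prob' must be a probability")
  check_number(precision_mean, "precision_mean", 0)
  check_number(precision_sd, "precision_sd", 0)
  check_number(psf_sigma, "psf_sigma", 0, strict = TRUE)
  check_number(photons_mean, "photons_mean", 0, strict = TRUE)
  check_number(background_rate, "background_rate", 0)
  structure(list(mean_blinks = mean_blinks, blink_gap_prob = blink_gap_prob,
                 precision_mean = precision_mean, precision_sd = precision_sd,
                 psf_sigma = psf_sigma, photons_mean = photons_mean,
                 background_rate = background_rate),
            class = "emission_model")
}

#' Sample true molecule positions for one structure
#'
#' Draws exactly `n_molecules` positions from the normalized structure
#' density with zero blur (true molecule positions are noiseless; blur
#' enters later through the emission model). Rings and patches use the
#' annular density, i.e. uniform area density on the annulus
#' `max(0, r_out - dr) <= R <= r_out`; domes are uniform on a hemisphere of
#' radius `r_out` and orthographically projected onto the plane.
#'
#' @param spec a [structure_spec()].
#' @param seed optional integer seed (local to this call).
#' @return an `n_molecules` x 2 matrix of positions, nm.
#' @export
sample_structure <- function(spec, seed = NULL) {
  if (!inherits(spec, "structure_spec")) {
    stopf("'spec' must be a structure_spec object")
  }
  with_seed(seed, {
    n <- spec$n_molecules
    if (spec$shape == "dome") {
      ## uniform on hemisphere: cos(polar angle) uniform in (0, 1]
      u <- stats::runif(n)
      phi <- stats::runif(n, 0, 2 * pi)
      s <- sqrt(pmax(0, 1 - u^2))          # sin(polar) ; u = cos(polar)
      xy <- spec$r_out * cbind(s * cos(phi), s * sin(phi))
    } else {
      r_in <- max(0, spec$r_out - spec$dr)
      r <- sqrt(stats::runif(n, r_in^2, spec$r_out^2))
      phi <- stats::runif(n, 0, 2 * pi)
      xy <- cbind(r * cos(phi), r * sin(phi))
    }
    sweep(xy, 2, spec$center, "+")
  })
}

#' Assemble a ground-truth manifest
#'
#' Samples molecule positions for every site and records the per-frame drift
#' trajectory and the true diffraction-limited marker amplitude per site.
#'
#' @param sites list of [structure_spec()] objects.
#' @param n_frames number of camera frames the manifest covers.
#' @param drift_per_frame numeric length-2: linear drift per frame (nm); or
#'   an `n_frames` x 2 matrix giving the full trajectory.
#' @param gfp_amplitudes non-negative true marker amplitudes, one per site.
#' @param seed optional integer seed.
#' @return an object of class `gt_manifest` with elements `sites`,
#'   `molecule_positions`, `drift_trajectory`, `gfp_true_amplitudes`.
#' @export
ground_truth_manifest <- function(sites, n_frames,
                                  drift_per_frame = c(0, 0),
                                  gfp_amplitudes = rep(0, length(sites)),
                                  seed = NULL) {
  if (!length(sites) || !all(vapply(sites, inherits, TRUE, "structure_spec"))) {
    stopf("'sites' must be a non-empty list of structure_spec objects")
  }
  check_number(n_frames, "n_frames", 1)
  n_frames <- as.integer(n_frames)
  if (is.matrix(drift_per_frame)) {
    drift <- drift_per_frame
    if (nrow(drift) != n_frames) stopf("drift trajectory must have n_frames rows")
  } else {
    drift <- outer(seq_len(n_frames) - 1L, as.numeric(drift_per_frame))
  }
  if (length(gfp_amplitudes) != length(sites) || any(gfp_amplitudes < 0)) {
    stopf("'gfp_amplitudes' must be non-negative, one per site")
  }
  with_seed(seed, {
    pos <- lapply(sites, sample_structure)
    structure(list(sites = sites, molecule_positions = pos,
                   drift_trajectory = drift,
                   gfp_true_amplitudes = as.numeric(gfp_amplitudes),
                   n_frames = n_frames),
              class = "gt_manifest")
  })
}

## truncated-normal precision draw, floor 1 nm
draw_precision <- function(n, mean, sd) {
  if (sd <= 0) return(rep(max(mean, 1), n))
  p <- stats::rnorm(n, mean, sd)
  while (any(bad <- p < 1)) p[bad] <- stats::rnorm(sum(bad), mean, sd)
  p
}

#' Emit a localization table from a ground-truth manifest
#'
#' Every molecule blinks a geometric number of times in a run of frames
#' starting at a uniformly drawn frame (1-frame gaps occur with probability
#' `blink_gap_prob`); each blink is displaced by an isotropic Gaussian with
#' its own drawn precision; per-frame drift is added; spurious background
#' localizations uniform over `field_nm` are appended. The returned table
#' carries the true per-record precision in `precision_nm`.
#'
#' @param manifest a [ground_truth_manifest()].
#' @param model an [emission_model()].
#' @param n_frames number of frames (defaults to the manifest's).
#' @param field_nm numeric length-2 field size (nm), used for the uniform
#'   background; required when `background_rate > 0`.
#' @param seed optional integer seed.
#' @return a localization table; attribute `"site_id"` holds the generating
#'   site index per record (0 = background).
#' @export
emit_localizations <- function(manifest, model, n_frames = manifest$n_frames,
                               field_nm = NULL, seed = NULL) {
  if (!inherits(manifest, "gt_manifest")) stopf("'manifest' must be a gt_manifest")
  if (!inherits(model, "emission_model")) stopf("'model' must be an emission_model")
  check_number(n_frames, "n_frames", 1)
  n_frames <- as.integer(n_frames)
  drift <- manifest$drift_trajectory
  if (nrow(drift) < n_frames) stopf("drift trajectory shorter than n_frames")
  with_seed(seed, {
    pos <- do.call(rbind, manifest$molecule_positions)
    site_of_mol <- rep.int(seq_along(manifest$molecule_positions),
                           vapply(manifest$molecule_positions, nrow, 1L))
    n_mol <- nrow(pos)
    n_blinks <- stats::rgeom(n_mol, 1 / model$mean_blinks) + 1L
    mol_id <- rep.int(seq_len(n_mol), n_blinks)
    total <- sum(n_blinks)
    ## frame of each blink: run of consecutive frames with occasional gaps
    start <- sample.int(n_frames, n_mol, replace = TRUE)
    steps <- 1L + stats::rbinom(total, 1L, model$blink_gap_prob)
    offs <- stats::ave(steps, mol_id, FUN = cumsum) - steps
    frame <- pmin(start[mol_id] + offs, n_frames)
    prec <- draw_precision(total, model$precision_mean, model$precision_sd)
    xy <- pos[mol_id, , drop = FALSE] +
      cbind(stats::rnorm(total, 0, prec), stats::rnorm(total, 0, prec)) +
      drift[frame, , drop = FALSE]
    photons <- stats::rpois(total, model$photons_mean)
    site_id <- site_of_mol[mol_id]
    ## spurious background localizations, uniform over the field
    if (model$background_rate > 0) {
      if (is.null(field_nm)) stopf("'field_nm' is required when background_rate > 0")
      area_um2 <- prod(field_nm) / 1e6
      n_bg <- stats::rpois(1, model$background_rate * area_um2)
      if (n_bg > 0) {
        frame <- c(frame, sample.int(n_frames, n_bg, replace = TRUE))
        xy <- rbind(xy, cbind(stats::runif(n_bg, 0, field_nm[1]),
                              stats::runif(n_bg, 0, field_nm[2])))
        prec <- c(prec, draw_precision(n_bg, model$precision_mean,
                                       model$precision_sd))
        photons <- c(photons, stats::rpois(n_bg, model$photons_mean))
        site_id <- c(site_id, rep(0L, n_bg))
      }
    }
    ord <- order(frame)
    out <- localization_table(frame = frame[ord], x_nm = xy[ord, 1],
                              y_nm = xy[ord, 2], photons = photons[ord],
                              bg = 0, sigma_nm = model$psf_sigma,
                              precision_nm = prec[ord], channel = 1L)
    attr(out, "site_id") <- site_id[ord]
    out
  })
}

#' Render raw camera frames from a localization table
#'
#' Each blink contributes a pixel-integrated 2D Gaussian (standard deviation
#' `sigma_nm` of the record) scaled to its photon count, on top of a
#' constant background; Poisson noise is applied per pixel unless
#' `noiseless = TRUE`.
#'
#' @param table localization table (positions must lie inside the frame).
#' @param camera list with `pixelsize_nm`, `width_px`, `height_px`, and
#'   `background` (photons per pixel per frame).
#' @param n_frames number of frames to render (defaults to `max(frame)`).
#' @param noiseless logical; skip the Poisson step.
#' @param seed optional integer seed.
#' @return numeric array `height_px x width_px x n_frames` of photon counts.
#' @export
render_frames <- function(table, camera, n_frames = NULL, noiseless = FALSE,
                          seed = NULL) {
  check_loc_columns(table)
  p <- camera$pixelsize_nm
  check_number(p, "pixelsize_nm", 0, strict = TRUE)
  W <- as.integer(camera$width_px); H <- as.integer(camera$height_px)
  bgc <- if (is.null(camera$background)) 0 else camera$background
  if (is.null(n_frames)) n_frames <- if (nrow(table)) max(table$frame) else 1L
  if (nrow(table) &&
      (any(table$x_nm < 0 | table$x_nm > W * p) ||
       any(table$y_nm < 0 | table$y_nm > H * p))) {
    stopf("all localizations must lie inside the frame bounds")
  }
  stack <- array(bgc, dim = c(H, W, n_frames))
  xe <- (0:W) * p; ye <- (0:H) * p                 # pixel edges, nm
  for (k in seq_len(nrow(table))) {
    s <- table$sigma_nm[k]
    wx <- diff(stats::pnorm(xe, table$x_nm[k], s))
    wy <- diff(stats::pnorm(ye, table$y_nm[k], s))
    f <- table$frame[k]
    stack[, , f] <- stack[, , f] + table$photons[k] * outer(wy, wx)
  }
  if (!noiseless) {
    with_seed(seed, {
      stack[] <- stats::rpois(length(stack), stack)
    })
  }
  stack
}

#' Simulate a diffraction-limited marker z-stack
#'
#' Each site renders as an isotropic 2D Gaussian spot whose width grows and
#' whose peak amplitude decays away from focus
#' (`sigma(dz) = psf_sigma * sqrt(1 + (dz/z_range)^2)`, amplitude scaled by
#' `(psf_sigma/sigma(dz))^2` so the integrated intensity is conserved).
#' Overlapping neighbours add linearly.
#'
#' @param sites data.frame or matrix with columns x (nm), y (nm), amplitude
#'   (peak counts at focus).
#' @param layout list: `n_slices`, `step_nm`, `psf_sigma_nm`, `pixelsize_nm`,
#'   `width_px`, `height_px`, `background`, optional `z_range_nm` (depth
#'   scale of defocus, default 400) and `focus_slice` (default the middle).
#' @param noiseless logical; skip Poisson noise (default TRUE).
#' @param seed optional integer seed.
#' @return object of class `gfp_stack`: list with `data`
#'   (`height x width x n_slices` array), `layout`, and `focus_slice`.
#' @export
gen_gfp_stack <- function(sites, layout, noiseless = TRUE, seed = NULL) {
  ns <- as.integer(layout$n_slices)
  if (is.na(ns) || ns < 1L) stopf("'n_slices' must be >= 1")
  p <- layout$pixelsize_nm
  check_number(p, "pixelsize_nm", 0, strict = TRUE)
  W <- as.integer(layout$width_px); H <- as.integer(layout$height_px)
  bgc <- if (is.null(layout$background)) 0 else layout$background
  zr <- if (is.null(layout$z_range_nm)) 400 else layout$z_range_nm
  focus <- if (is.null(layout$focus_slice)) (ns + 1L) %/% 2L else
    as.integer(layout$focus_slice)
  sites <- as.data.frame(sites)
  names(sites)[1:3] <- c("x", "y", "amplitude")
  stack <- array(bgc, dim = c(H, W, ns))
  xe <- (0:W) * p; ye <- (0:H) * p
  s0 <- layout$psf_sigma_nm
  for (z in seq_len(ns)) {
    dz <- (z - focus) * layout$step_nm
    sz <- s0 * sqrt(1 + (dz / zr)^2)
    for (k in seq_len(nrow(sites))) {
      ## peak-amplitude parameterization: value at the spot center
      amp <- sites$amplitude[k] * (s0 / sz)^2
      wx <- diff(stats::pnorm(xe, sites$x[k], sz))
      wy <- diff(stats::pnorm(ye, sites$y[k], sz))
      stack[, , z] <- stack[, , z] +
        amp * (2 * pi * sz^2 / p^2) * outer(wy, wx)
    }
  }
  if (!noiseless) with_seed(seed, stack[] <- stats::rpois(length(stack), stack))
  structure(list(data = stack, layout = layout, focus_slice = focus),
            class = "gfp_stack")
}
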