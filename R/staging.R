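## staging_timeline: order fixed-cell snapshots in pseudo-time. The
## diffraction-limited intensity of a marker protein (e.g. Sla2, Abp1,
## Rvs167) at each superresolved site grows during its recruitment phase,
## so binning sites by marker intensity approximates early -> late ordering.

#' Marker intensity of one site from a diffraction-limited z-stack
#'
#' Maximum-projects the 7 z-slices around the focal plane, subtracts a
#' level-3 wavelet background, and fits the projected image with the sum of
#' three isotropic Gaussians: the first fixed at the mapped site center,
#' the second and third with free centers constrained to lie at least
#' `min_separation` (350 nm) from the first and from each other, to absorb
#' partially overlapping signal from proximal sites. Returns the amplitude
#' of the first Gaussian. If the fit fails, the background-subtracted peak
#' value at the site center is returned with a flag.
#'
#' @param stack a `gfp_stack` (>= 7 slices) from [gen_gfp_stack()] or an
#'   equivalent list with `data`, `layout`, `focus_slice`.
#' @param site_center length-2 site center in superresolution coordinates,
#'   nm.
#' @param transform optional `projective_transform` mapping superresolution
#'   to stack coordinates (NULL = identity).
#' @param psf_sigma_nm width of the fitted Gaussians, nm (default: the
#'   stack layout's `psf_sigma_nm`).
#' @param min_separation constraint distance for the neighbour Gaussians,
#'   nm (default 350).
#' @param n_project number of central slices in the projection (default 7).
#' @return list: `amplitude` (Gaussian 1), `neighbour_amplitudes`,
#'   `neighbour_centers`, `fit_ok`.
#' @export
gfp_site_intensity <- function(stack, site_center, transform = NULL,
                               psf_sigma_nm = NULL, min_separation = 350,
                               n_project = 7L) {
  dat <- stack$data
  ns <- dim(dat)[3]
  if (ns < n_project) stopf("stack must have at least %d slices", n_project)
  layout <- stack$layout
  if (is.null(psf_sigma_nm)) psf_sigma_nm <- layout$psf_sigma_nm
  p <- layout$pixelsize_nm
  ctr <- if (is.null(transform)) as.numeric(site_center)
         else as.numeric(apply_transform(transform, rbind(site_center)))
  ## max projection of the central slices around focus
  focus <- stack$focus_slice
  half <- (n_project - 1L) %/% 2L
  idx <- (focus - half):(focus + half)
  idx <- idx[idx >= 1L & idx <= ns]
  proj <- apply(dat[, , idx, drop = FALSE], c(1, 2), max)
  bgless <- proj - wavelet_background(proj, 3L)
  xs <- pixel_centers(ncol(proj), p)
  ys <- pixel_centers(nrow(proj), p)
  X <- matrix(xs, nrow(proj), ncol(proj), byrow = TRUE)
  Y <- matrix(ys, nrow(proj), ncol(proj))
  ## slice sigmas and amplitude factors of the projection (defocus model of
  ## the stack layout; for a plain 2D image this reduces to one Gaussian)
  zr <- if (is.null(layout$z_range_nm)) 400 else layout$z_range_nm
  step <- if (is.null(layout$step_nm)) 0 else layout$step_nm
  dz <- (idx - focus) * step
  sz <- psf_sigma_nm * sqrt(1 + (dz / zr)^2)
  xe <- (0:ncol(proj)) * p; ye <- (0:nrow(proj)) * p
  ## template = unit-amplitude spot as imaged (pixel-integrated, max
  ## projection over the same slices), minus its own wavelet background:
  ## the background subtraction applied to the data removes part of each
  ## spot too, and being linear it acts identically on the templates
  slice_templates <- function(cx, cy) {
    lapply(sz, function(s) {
      wx <- diff(stats::pnorm(xe, cx, s)); wy <- diff(stats::pnorm(ye, cy, s))
      (psf_sigma_nm / s)^2 * (2 * pi * s^2 / p^2) * outer(wy, wx)
    })
  }
  g_raw <- function(cx, cy) Reduce(pmax, slice_templates(cx, cy))
  g <- function(cx, cy) {
    raw <- g_raw(cx, cy)
    raw - wavelet_background(raw, 3L)
  }
  ## fallback value: background-subtracted peak at the mapped center
  ci <- pixel_index(ctr[1], p); ri <- pixel_index(ctr[2], p)
  peak_val <- if (ri >= 1 && ri <= nrow(proj) && ci >= 1 && ci <= ncol(proj))
    bgless[ri, ci] else 0
  ## amplitudes are solved linearly for given neighbour centers
  amps_for <- function(c2, c3) {
    B <- cbind(as.vector(g(ctr[1], ctr[2])),
               as.vector(g(c2[1], c2[2])),
               as.vector(g(c3[1], c3[2])))
    a <- tryCatch(stats::coef(stats::lm.fit(B, as.vector(bgless))),
                  error = function(e) NULL)
    if (is.null(a) || any(!is.finite(a))) return(NULL)
    pmax(a, 0)
  }
  obj <- function(th) {
    c2 <- th[1:2]; c3 <- th[3:4]
    d12 <- sqrt(sum((c2 - ctr)^2)); d13 <- sqrt(sum((c3 - ctr)^2))
    d23 <- sqrt(sum((c2 - c3)^2))
    pen <- sum(pmax(min_separation - c(d12, d13, d23), 0)^2) * 1e4
    a <- amps_for(c2, c3)
    if (is.null(a)) return(1e12)
    B <- a[1] * g(ctr[1], ctr[2]) + a[2] * g(c2[1], c2[2]) +
      a[3] * g(c3[1], c3[2])
    sum((bgless - B)^2) + pen
  }
  ## init: residual peaks outside the separation radius, else defaults
  resid <- bgless - peak_val * g(ctr[1], ctr[2])
  D2 <- (X - ctr[1])^2 + (Y - ctr[2])^2
  resid[D2 < min_separation^2] <- -Inf
  i1 <- which.max(resid)
  c2_0 <- c(X[i1], Y[i1])
  resid[(X - c2_0[1])^2 + (Y - c2_0[2])^2 < min_separation^2] <- -Inf
  i2 <- which.max(resid)
  c3_0 <- c(X[i2], Y[i2])
  opt <- tryCatch(
    stats::optim(c(c2_0, c3_0), obj, method = "Nelder-Mead",
                 control = list(maxit = 600, reltol = 1e-9)),
    error = function(e) NULL)
  if (is.null(opt)) {
    return(list(amplitude = peak_val, neighbour_amplitudes = c(0, 0),
                neighbour_centers = rbind(c2_0, c3_0), fit_ok = FALSE))
  }
  a <- amps_for(opt$par[1:2], opt$par[3:4])
  if (is.null(a)) {
    return(list(amplitude = peak_val, neighbour_amplitudes = c(0, 0),
                neighbour_centers = rbind(c2_0, c3_0), fit_ok = FALSE))
  }
  ## Max-projection noise-bias correction. Pixelwise max over noisy slices
  ## is inflated (Jensen): E[max_z Pois(mu_z)] > max_z mu_z, about
  ## +0.8 sd at the spot center, i.e. a few percent of the amplitude at
  ## moderate SNR. The inflation is computed analytically from the fitted
  ## spot model under the Poisson/normal approximation and scaled by an
  ## empirical dispersion estimate, so noiseless stacks are untouched.
  centers <- list(ctr, opt$par[1:2], opt$par[3:4])
  tmpl_f <- lapply(centers, function(cc) g(cc[1], cc[2]))
  model_f <- a[1] * tmpl_f[[1]] + a[2] * tmpl_f[[2]] + a[3] * tmpl_f[[3]]
  bg0 <- stats::median(proj)
  mu_z <- lapply(seq_along(sz), function(zi) {
    m <- matrix(bg0, nrow(proj), ncol(proj))
    for (k in 1:3) {
      m <- m + a[k] * slice_templates(centers[[k]][1], centers[[k]][2])[[zi]]
    }
    m
  })
  mu_max <- Reduce(pmax, mu_z)
  ## dispersion: residual variance relative to the Poisson prediction
  resid2 <- (bgless - model_f)^2
  phi <- stats::median(resid2 / pmax(mu_max, 1)) / 0.455
  phi <- min(max(phi, 0), 1)
  if (phi > 0.05) {
    ## E[max] - max by numeric integration of the normal order statistic
    sd_ref <- sqrt(pmax(mu_max, 1))
    tgrid <- seq(-4, 8, by = 0.25)
    bias <- matrix(0, nrow(proj), ncol(proj))
    for (t in tgrid) {
      Ft <- matrix(1, nrow(proj), ncol(proj))
      tv <- mu_max + t * sd_ref
      for (zi in seq_along(mu_z)) {
        Ft <- Ft * stats::pnorm((tv - mu_z[[zi]]) /
                                  sqrt(pmax(mu_z[[zi]], 1e-9)))
      }
      ## E[max] - mu_max = int [(1 - F(t)) - 1(t < mu_max)] dt
      bias <- bias + ((1 - Ft) - (t < 0)) * 0.25 * sd_ref
    }
    bias <- pmax(bias, 0)
    bgless2 <- bgless - phi * (bias - wavelet_background(bias, 3L))
    B <- vapply(tmpl_f, as.vector, numeric(length(proj)))
    a2 <- tryCatch(stats::coef(stats::lm.fit(B, as.vector(bgless2))),
                   error = function(e) NULL)
    if (!is.null(a2) && all(is.finite(a2))) a <- pmax(a2, 0)
  }
  list(amplitude = unname(a[1]), neighbour_amplitudes = unname(a[2:3]),
       neighbour_centers = rbind(opt$par[1:2], opt$par[3:4]), fit_ok = TRUE)
}

#' Stage sites by marker intensity
#'
#' Excludes sites brighter than `exclude_factor` (1.5) times the 80th
#' percentile of intensities (overlapping signal from more than two sites,
#' typically in small buds). From the remaining sites, those below
#' `no_factor` (0.1) times the post-exclusion 80th percentile form the
#' `"no"` marker bin; the rest are sorted by intensity and split into three
#' contiguous equal-count bins `"low"`, `"med"`, `"high"` (remainders go to
#' the lower bins). Quantiles use the linear-interpolation (type 7)
#' convention.
#'
#' @param intensities numeric site intensities (>= 4 sites).
#' @param exclude_factor exclusion multiple of the 80th percentile.
#' @param no_factor "no marker" multiple of the post-exclusion 80th
#'   percentile.
#' @return data.frame with `intensity`, `bin` (factor no/low/med/high, NA
#'   for excluded), `excluded_overlap`; attribute `"p80"` holds the
#'   post-exclusion 80th percentile.
#' @export
stage_sites <- function(intensities, exclude_factor = 1.5, no_factor = 0.1) {
  x <- as.numeric(intensities)
  if (length(x) < 4L) stopf("at least 4 sites are required for staging")
  p80_all <- stats::quantile(x, 0.8, type = 7, names = FALSE)
  excluded <- x > exclude_factor * p80_all
  if (all(excluded)) stopf("all sites excluded by the overlap rule")
  p80 <- stats::quantile(x[!excluded], 0.8, type = 7, names = FALSE)
  bin <- rep(NA_character_, length(x))
  is_no <- if (p80 <= 0) !excluded else !excluded & x < no_factor * p80
  bin[is_no] <- "no"
  rest <- which(!excluded & !is_no)
  if (length(rest)) {
    ord <- rest[order(x[rest], rest)]
    n <- length(ord)
    base <- n %/% 3L; extra <- n %% 3L
    sizes <- base + c(extra >= 1L, extra >= 2L, 0L)  # remainders to lower bins
    lab <- rep(c("low", "med", "high"), times = sizes)
    bin[ord] <- lab
  }
  out <- data.frame(intensity = x,
                    bin = factor(bin, levels = c("no", "low", "med", "high")),
                    excluded_overlap = excluded)
  attr(out, "p80") <- p80
  out
}

#' Side-view site container
#'
#' @param ch1,ch2 n x 2 matrices of localization coordinates (nm) of the
#'   base marker (e.g. Las17) and the tracked channel (e.g. Abp1), in the
#'   raw (unrotated) side-view frame where y is the optical axis.
#' @param rotation_angle supplied rotation (radians) that makes endocytosis
#'   point upward (+y).
#' @return a `sideview_site` list.
#' @export
sideview_site <- function(ch1, ch2, rotation_angle = 0) {
  ch1 <- as.matrix(ch1); ch2 <- as.matrix(ch2)
  if (ncol(ch1) != 2L || ncol(ch2) != 2L) stopf("channels must be n x 2")
  structure(list(ch1 = ch1, ch2 = ch2, rotation_angle = rotation_angle),
            class = "sideview_site")
}

rotate_pts <- function(p, theta) {
  R <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  p %*% t(R)
}

#' Temporal reconstruction of side-view images
#'
#' Rotates each site by its supplied angle, aligns all sites at the bottom
#' by the 5th percentile of the channel-1 (base marker) axial positions,
#' sorts sites by increasing channel-2 centroid along the growth axis
#' (pseudo-time), renders dual-channel images, and emits running-window
#' average images (stride 1).
#'
#' @param sites list of [sideview_site()] objects (length >= `window`).
#' @param window running window size (default 7).
#' @param pixel_size render pixel size, nm.
#' @param xlim,ylim common field bounds after alignment, nm.
#' @param min_sigma rendered Gaussian sigma, nm.
#' @return list: `order` (site indices sorted by pseudo-time), `centroids`
#'   (sorted ch2 centroid heights), `averages` (list of length
#'   `n - window + 1`, each an H x W x 2 array).
#' @export
sideview_reconstruct <- function(sites, window = 7L, pixel_size = 5,
                                 xlim = c(-250, 250), ylim = c(-100, 400),
                                 min_sigma = 10) {
  n <- length(sites)
  if (n < window) stopf("need at least %d sites for window %d", window, window)
  aligned <- lapply(sites, function(s) {
    c1 <- rotate_pts(s$ch1, s$rotation_angle)
    c2 <- rotate_pts(s$ch2, s$rotation_angle)
    base <- stats::quantile(c1[, 2], 0.05, type = 7, names = FALSE)
    c1[, 2] <- c1[, 2] - base
    c2[, 2] <- c2[, 2] - base
    ## lateral alignment on the ch1 centroid
    mx <- mean(c1[, 1])
    c1[, 1] <- c1[, 1] - mx; c2[, 1] <- c2[, 1] - mx
    list(ch1 = c1, ch2 = c2, centroid2 = mean(c2[, 2]))
  })
  cen <- vapply(aligned, `[[`, 1, "centroid2")
  ord <- order(cen, seq_len(n))
  st <- render_settings(pixel_size = pixel_size, min_sigma = min_sigma)
  rend <- function(p) {
    tb <- localization_table(frame = rep(1L, nrow(p)), x_nm = p[, 1],
                             y_nm = p[, 2], photons = 1, bg = 0,
                             sigma_nm = 0, precision_nm = 0)
    render_image(tb, st, xlim, ylim)
  }
  imgs <- lapply(aligned[ord], function(s) {
    H <- rend(s$ch1); A <- rend(s$ch2)
    ar <- array(0, dim = c(dim(H), 2))
    ar[, , 1] <- H; ar[, , 2] <- A
    ar
  })
  n_avg <- n - window + 1L
  averages <- vector("list", n_avg)
  for (k in seq_len(n_avg)) {
    acc <- imgs[[k]]
    for (j in seq_len(window - 1L)) acc <- acc + imgs[[k + j]]
    averages[[k]] <- acc / window
  }
  list(order = ord, centroids = cen[ord], averages = averages)
}
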