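## localizer: detect and fit single emitters in raw camera frames.
## Detection = smoothing + a-trous wavelet background subtraction + threshold
## + non-maximum suppression; fitting = pixelated-Gaussian MLE under Poisson
## noise by damped Fisher scoring, with CRLB-based precision estimates.

B3_KERNEL <- c(1, 4, 6, 4, 1) / 16

## separable 1D convolution with mirror boundary, kernel dilated by `step`
conv_sep <- function(img, kernel, step = 1L) {
  nk <- length(kernel)
  half <- (nk - 1L) %/% 2L
  offs <- (seq_len(nk) - 1L - half) * step
  ## full reflective boundary (period 2n), valid for any offset size
  mirror <- function(idx, n) {
    j <- (idx - 1L) %% (2L * n)
    j[j < 0L] <- j[j < 0L] + 2L * n
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  conv_dim <- function(m, margin) {
    n <- dim(m)[margin]
    out <- m * 0
    for (k in seq_len(nk)) {
      idx <- mirror(seq_len(n) + offs[k], n)
      out <- out + kernel[k] * (if (margin == 1L) m[idx, , drop = FALSE]
                                else m[, idx, drop = FALSE])
    }
    out
  }
  conv_dim(conv_dim(img, 1L), 2L)
}

#' A-trous wavelet background estimate
#'
#' Computes the smooth approximation of an image at the given level of the
#' undecimated (a-trous) B3-spline wavelet decomposition: the image is
#' convolved successively with the separable kernel (1,4,6,4,1)/16 dilated
#' by 2^(j-1) at level j, with mirror boundary handling. The result is the
#' standard wavelet background used for spot detection and for
#' diffraction-limited marker images.
#'
#' @param image numeric matrix.
#' @param level decomposition level (>= 1), default 3.
#' @return background matrix of the same size.
#' @export
wavelet_background <- function(image, level = 3L) {
  if (!is.matrix(image)) stopf("'image' must be a matrix")
  check_number(level, "level", 1)
  if (min(dim(image)) < length(B3_KERNEL)) {
    stopf("image (%d x %d) smaller than the wavelet kernel support",
          nrow(image), ncol(image))
  }
  a <- image
  for (j in seq_len(level)) a <- conv_sep(a, B3_KERNEL, step = 2L^(j - 1L))
  a
}

#' Detection parameters
#'
#' @param wavelet_level background wavelet level (>= 1).
#' @param nms_radius non-maximum suppression radius, pixels.
#' @param threshold_factor detection threshold in multiples of the robust
#'   noise SD (1.4826 * MAD) of the filtered image.
#' @param roi_size fitting ROI side length, pixels (odd, >= 5).
#' @return a `detection_params` list.
#' @export
detection_params <- function(wavelet_level = 3L, nms_radius = 3L,
                             threshold_factor = 5, roi_size = 13L) {
  check_number(wavelet_level, "wavelet_level", 1)
  check_number(roi_size, "roi_size", 5)
  if (roi_size %% 2 == 0) stopf("'roi_size' must be odd")
  structure(list(wavelet_level = as.integer(wavelet_level),
                 nms_radius = as.integer(nms_radius),
                 threshold_factor = threshold_factor,
                 roi_size = as.integer(roi_size)),
            class = "detection_params")
}

#' Detect candidate emitters in one frame
#'
#' Smooths the frame (level-1 B3 approximation), subtracts the wavelet
#' background, thresholds at `threshold_factor` times the robust noise SD of
#' the filtered image, and applies non-maximum suppression within
#' `nms_radius`. Ties are broken by higher intensity, then row-major order.
#'
#' @param image numeric matrix (photon counts).
#' @param params a [detection_params()].
#' @return data.frame with columns `row`, `col`, `value` (filtered
#'   intensity), sorted by decreasing value.
#' @export
detect_peaks <- function(image, params = detection_params()) {
  if (!inherits(params, "detection_params")) {
    stopf("'params' must be a detection_params object")
  }
  smoothed <- conv_sep(image, B3_KERNEL)
  filt <- smoothed - wavelet_background(image, params$wavelet_level)
  noise <- 1.4826 * stats::mad(filt, center = stats::median(filt),
                               constant = 1)
  thr <- params$threshold_factor * noise
  H <- nrow(filt); W <- ncol(filt)
  ## candidates: 3x3 local maxima of the filtered image that are also local
  ## maxima of the smoothed image (rejects background-subtraction ringing)
  ## tolerant test: not clearly below any neighbour (near-ties at pixel
  ## edges survive and are resolved by the NMS pass below)
  is_locmax <- function(m, tol = 5e-3) {
    pad <- matrix(-Inf, H + 2L, W + 2L)
    pad[2:(H + 1L), 2:(W + 1L)] <- m
    out <- matrix(TRUE, H, W)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nb <- pad[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc]
      out <- out & (m >= nb - tol * pmax(abs(nb), abs(m)))
    }
    out
  }
  cand <- which(filt > thr & filt > 0 & is_locmax(filt) & is_locmax(smoothed))
  if (!length(cand)) {
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  }
  rows <- (cand - 1L) %% H + 1L
  cols <- (cand - 1L) %/% H + 1L
  vals <- filt[cand]
  ## NMS: accept in decreasing intensity, suppress within nms_radius
  ord <- order(-vals, rows, cols)
  rows <- rows[ord]; cols <- cols[ord]; vals <- vals[ord]
  keep <- logical(length(vals))
  r2 <- params$nms_radius^2
  for (i in seq_along(vals)) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    sel <- which(keep)
    if (all((rows[sel] - rows[i])^2 + (cols[sel] - cols[i])^2 > r2)) {
      keep[i] <- TRUE
    }
  }
  data.frame(row = rows[keep], col = cols[keep], value = vals[keep])
}

## pixel-integration weights and derivatives for one axis
## pixel k (1-based) covers [k-1, k) in pixel units; x is the center coord
axis_weights <- function(n, x, sigma) {
  e <- 0:n
  u <- (e - x) / sigma
  P <- stats::pnorm(u); phi <- stats::dnorm(u)
  list(E = diff(P),
       dx = (phi[-(n + 1L)] - phi[-1L]) / sigma,
       ds = (u[-(n + 1L)] * phi[-(n + 1L)] - u[-1L] * phi[-1L]) / sigma)
}

#' Fit a pixelated Gaussian to an ROI by Poisson MLE
#'
#' Maximizes the Poisson log-likelihood of the pixel-integrated Gaussian
#' model `mu = b + N * Ex * Ey` over (x, y, N, b) and optionally sigma,
#' using damped Fisher scoring (modified Newton, expected information),
#' at most `max_iter` iterations, converged when every parameter step is
#' below 1e-3 of its unit (pixels / photons). Precision estimates are the
#' square roots of the CRLB diagonal (inverse expected information at the
#' optimum).
#'
#' @param roi square numeric matrix of non-negative counts.
#' @param sigma_init initial PSF sigma, pixels.
#' @param fit_sigma logical: fit sigma (default) or keep it fixed.
#' @param init optional named list overriding initial `x`, `y`, `N`, `b`
#'   (x, y in pixel units, origin at the ROI corner).
#' @param max_iter iteration cap.
#' @return a `fit_result` list: `x`, `y` (pixels from ROI corner), `photons`,
#'   `bg`, `sigma` (pixels), `crlb` (named vector of parameter SDs),
#'   `log_likelihood`, `converged`, `n_iter`.
#' @export
fit_mle_gaussian <- function(roi, sigma_init = 1.3, fit_sigma = TRUE,
                             init = NULL, max_iter = 50L) {
  if (!is.matrix(roi) || nrow(roi) != ncol(roi)) {
    stopf("'roi' must be a square matrix")
  }
  if (any(roi < 0)) stopf("'roi' must contain non-negative counts")
  n <- nrow(roi)
  k <- as.vector(roi)                    # column-major: index = row + (col-1)*n
  tot <- sum(k)
  if (tot == 0) {
    return(structure(list(x = n / 2, y = n / 2, photons = 0, bg = 0,
                          sigma = sigma_init, crlb = c(x = Inf, y = Inf),
                          log_likelihood = 0, converged = TRUE, n_iter = 0L),
                     class = "fit_result"))
  }
  ## init: background from border median, position from centre of mass
  border <- c(roi[1, ], roi[n, ], roi[, 1], roi[, n])
  b0 <- max(stats::median(border), 0.01)
  resid <- pmax(roi - b0, 0)
  w <- sum(resid)
  cx <- if (w > 0) sum(t(resid) * (seq_len(n) - 0.5)) / w else n / 2
  cy <- if (w > 0) sum(resid * (seq_len(n) - 0.5)) / w else n / 2
  theta <- c(x = cx, y = cy, N = max(w, 1), b = b0, s = sigma_init)
  if (!is.null(init)) {
    for (nm in intersect(names(init), c("x", "y", "N", "b", "s"))) {
      theta[nm] <- init[[nm]]
    }
  }
  use <- if (fit_sigma) 1:5 else 1:4
  loglik <- function(mu) sum(k * log(mu) - mu)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ax <- axis_weights(n, theta["x"], theta["s"])
    ay <- axis_weights(n, theta["y"], theta["s"])
    Ex <- ax$E; Ey <- ay$E
    mu <- pmax(theta["b"] + theta["N"] * outer(Ey, Ex), 1e-12)
    J <- cbind(x = as.vector(theta["N"] * outer(Ey, ax$dx)),
               y = as.vector(theta["N"] * outer(ay$dx, Ex)),
               N = as.vector(outer(Ey, Ex)),
               b = rep(1, n * n),
               s = as.vector(theta["N"] * (outer(Ey, ax$ds) +
                                             outer(ay$ds, Ex))))
    J <- J[, use, drop = FALSE]
    muv <- as.vector(mu)
    g <- crossprod(J, (k - muv) / muv)
    FI <- crossprod(J, J / muv)
    step <- tryCatch(
      solve(FI + lambda * diag(diag(FI), length(use)), g),
      error = function(e) NULL)
    if (is.null(step)) break
    theta_new <- theta
    theta_new[use] <- theta[use] + step
    theta_new["N"] <- max(theta_new["N"], 1e-6)
    theta_new["b"] <- max(theta_new["b"], 1e-9)
    if (fit_sigma) theta_new["s"] <- min(max(theta_new["s"], 0.3), n)
    theta_new["x"] <- min(max(theta_new["x"], -1), n + 1)
    theta_new["y"] <- min(max(theta_new["y"], -1), n + 1)
    axn <- axis_weights(n, theta_new["x"], theta_new["s"])
    ayn <- axis_weights(n, theta_new["y"], theta_new["s"])
    mun <- pmax(theta_new["b"] + theta_new["N"] * outer(ayn$E, axn$E), 1e-12)
    if (loglik(mun) >= loglik(mu)) {
      moved <- max(abs(theta_new[use] - theta[use]))
      theta <- theta_new
      lambda <- max(lambda / 3, 1e-7)
      if (moved < 1e-3) { converged <- TRUE; break }
    } else {
      lambda <- lambda * 10
      if (lambda > 1e6) break
    }
    if (iter >= max_iter) break
  }
  ## CRLB at the final estimate
  ax <- axis_weights(n, theta["x"], theta["s"])
  ay <- axis_weights(n, theta["y"], theta["s"])
  mu <- pmax(theta["b"] + theta["N"] * outer(ay$E, ax$E), 1e-12)
  J <- cbind(x = as.vector(theta["N"] * outer(ay$E, ax$dx)),
             y = as.vector(theta["N"] * outer(ay$dx, ax$E)),
             N = as.vector(outer(ay$E, ax$E)),
             b = rep(1, n * n),
             s = as.vector(theta["N"] * (outer(ay$E, ax$ds) +
                                           outer(ay$ds, ax$E))))
  J <- J[, use, drop = FALSE]
  FI <- crossprod(J, J / as.vector(mu))
  crlb <- tryCatch(sqrt(pmax(diag(solve(FI)), 0)),
                   error = function(e) rep(NA_real_, length(use)))
  names(crlb) <- c("x", "y", "N", "b", "s")[use]
  structure(list(x = unname(theta["x"]), y = unname(theta["y"]),
                 photons = unname(theta["N"]), bg = unname(theta["b"]),
                 sigma = unname(theta["s"]), crlb = crlb,
                 log_likelihood = loglik(mu), converged = converged,
                 n_iter = iter),
            class = "fit_result")
}

#' Localize emitters in a stack of raw frames
#'
#' Runs peak detection and MLE fitting on every frame and assembles the
#' results into a localization table in nm.
#'
#' @param stack `H x W x n_frames` numeric array of photon counts (or a
#'   single matrix).
#' @param pixelsize_nm camera pixel size, nm.
#' @param params a [detection_params()].
#' @param psf_sigma_nm initial PSF sigma, nm.
#' @param fit_sigma fit the PSF width per spot (default) or keep it fixed.
#' @return a localization table (`precision_nm` is the CRLB of x/y averaged,
#'   in nm; non-converged fits are dropped).
#' @export
localize_frames <- function(stack, pixelsize_nm, params = detection_params(),
                            psf_sigma_nm = 130, fit_sigma = TRUE) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  half <- (params$roi_size - 1L) %/% 2L
  res <- vector("list", dim(stack)[3])
  for (f in seq_len(dim(stack)[3])) {
    img <- stack[, , f]
    peaks <- detect_peaks(img, params)
    if (!nrow(peaks)) next
    rows <- vector("list", nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      r0 <- peaks$row[i]; c0 <- peaks$col[i]
      if (r0 - half < 1 || r0 + half > nrow(img) ||
          c0 - half < 1 || c0 + half > ncol(img)) next
      roi <- img[(r0 - half):(r0 + half), (c0 - half):(c0 + half)]
      fit <- fit_mle_gaussian(roi, sigma_init = psf_sigma_nm / pixelsize_nm,
                              fit_sigma = fit_sigma)
      if (!fit$converged) next
      prec <- mean(fit$crlb[c("x", "y")]) * pixelsize_nm
      rows[[i]] <- data.frame(
        frame = f,
        x_nm = (c0 - 1L - half + fit$x) * pixelsize_nm,
        y_nm = (r0 - 1L - half + fit$y) * pixelsize_nm,
        photons = fit$photons, bg = fit$bg,
        sigma_nm = fit$sigma * pixelsize_nm,
        precision_nm = prec, channel = 1L)
    }
    res[[f]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(localization_table())
  as_locs(out)
}
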