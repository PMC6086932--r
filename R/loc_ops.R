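## loc_ops: post-processing of localization tables — grouping of blink
## chains, quality filtering, Gaussian rendering, drift correction by
## redundant image cross-correlation, and projective channel registration.

#' Rendering settings
#'
#' @param pixel_size render pixel size, nm.
#' @param min_sigma minimum rendered Gaussian SD, nm (display floor for very
#'   precise localizations).
#' @param saturation_quantile fraction of brightest pixels saturated on
#'   display export only; the numeric array is never clipped.
#' @return a `render_settings` list.
#' @export
render_settings <- function(pixel_size = 10, min_sigma = 6,
                            saturation_quantile = 0.001) {
  check_number(pixel_size, "pixel_size", 0, strict = TRUE)
  check_number(min_sigma, "min_sigma", 0)
  structure(list(pixel_size = pixel_size, min_sigma = min_sigma,
                 saturation_quantile = saturation_quantile),
            class = "render_settings")
}

#' Group localizations from consecutive frames
#'
#' Localizations found in consecutive frames (gaps up to `max_gap` frames
#' allowed) within a circular range of `radius` are considered repeated
#' detections of one blinking event and merged into a single record:
#' photon-weighted mean position, summed photons, first frame of the chain,
#' and precision recombined as the inverse-variance combination
#' `(sum 1/sigma_i^2)^(-1/2)`. Linking is greedy nearest-neighbour per
#' frame; ties are broken by distance, then record order.
#'
#' @param table a localization table.
#' @param radius linking radius, nm (default 75).
#' @param max_gap maximum number of skipped frames inside a chain (default 1).
#' @return the grouped localization table; attribute `"n_merged"` gives the
#'   number of records each output row absorbed.
#' @export
group_localizations <- function(table, radius = 75, max_gap = 1L) {
  check_loc_columns(table)
  n <- nrow(table)
  if (n < 2L) return(table)
  ord <- order(table$frame, seq_len(n))
  tb <- table[ord, ]
  chain <- integer(n)            # chain id per record
  ## active chains: last position, last frame, id
  act_x <- numeric(0); act_y <- numeric(0); act_f <- integer(0)
  act_id <- integer(0)
  next_id <- 0L
  frames <- unique(tb$frame)
  for (f in frames) {
    live <- act_f >= f - 1L - max_gap
    act_x <- act_x[live]; act_y <- act_y[live]
    act_f <- act_f[live]; act_id <- act_id[live]
    idx <- which(tb$frame == f)
    ## greedy nearest-neighbour matching between records and active chains
    if (length(act_id) && length(idx)) {
      d <- outer(tb$x_nm[idx], act_x, "-")^2 + outer(tb$y_nm[idx], act_y, "-")^2
      cand <- which(d <= radius^2, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(d[cand], cand[, 1L]), , drop = FALSE]
        used_r <- logical(length(idx)); used_c <- logical(length(act_id))
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1L]; j <- cand[k, 2L]
          if (used_r[i] || used_c[j]) next
          used_r[i] <- TRUE; used_c[j] <- TRUE
          chain[idx[i]] <- act_id[j]
          act_x[j] <- tb$x_nm[idx[i]]; act_y[j] <- tb$y_nm[idx[i]]
          act_f[j] <- f
        }
        idx_new <- idx[!used_r]
      } else idx_new <- idx
    } else idx_new <- idx
    if (length(idx_new)) {
      ids <- next_id + seq_along(idx_new)
      next_id <- next_id + length(idx_new)
      chain[idx_new] <- ids
      act_x <- c(act_x, tb$x_nm[idx_new]); act_y <- c(act_y, tb$y_nm[idx_new])
      act_f <- c(act_f, rep(f, length(idx_new))); act_id <- c(act_id, ids)
    }
  }
  ## merge chains
  sp <- split(seq_len(n), chain)
  first <- vapply(sp, `[`, 1L, 1L)
  out <- tb[first, , drop = FALSE]      # template rows, keeps channel etc.
  merge_one <- function(ii) {
    w <- tb$photons[ii]
    if (!all(is.finite(w)) || sum(w) <= 0) w <- rep(1, length(ii))
    c(x = sum(w * tb$x_nm[ii]) / sum(w),
      y = sum(w * tb$y_nm[ii]) / sum(w),
      ph = sum(tb$photons[ii]),
      bg = mean(tb$bg[ii]),
      sg = sum(w * tb$sigma_nm[ii]) / sum(w),
      pr = 1 / sqrt(sum(1 / tb$precision_nm[ii]^2)),
      fr = min(tb$frame[ii]),
      nm = length(ii))
  }
  m <- vapply(sp, merge_one, numeric(8))
  out$x_nm <- m["x", ]; out$y_nm <- m["y", ]
  out$photons <- m["ph", ]; out$bg <- m["bg", ]
  out$sigma_nm <- m["sg", ]; out$precision_nm <- m["pr", ]
  out$frame <- as.integer(m["fr", ])
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  res <- as_locs(out)
  attr(res, "n_merged") <- as.integer(m["nm", order(m["fr", ])])
  res
}

#' Filter localizations by precision and PSF width
#'
#' Discards records with localization precision worse than `max_precision`
#' or fitted PSF standard deviation larger than `max_sigma`; boundary values
#' are kept. These loose cutoffs remove dim background and out-of-focus
#' events while retaining the majority of localizations.
#'
#' @param table a localization table.
#' @param max_precision precision cutoff, nm (default 30).
#' @param max_sigma PSF sigma cutoff, nm (default 175).
#' @return the filtered table.
#' @export
filter_localizations <- function(table, max_precision = 30, max_sigma = 175) {
  check_loc_columns(table, c("precision_nm", "sigma_nm"))
  keep <- table$precision_nm <= max_precision & table$sigma_nm <= max_sigma
  keep[is.na(keep)] <- FALSE
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a superresolution image from localizations
#'
#' Every record adds a unit-integral pixel-integrated Gaussian at its
#' coordinates with standard deviation `max(precision_nm, min_sigma)`, so
#' that the image integral equals the number of (interior) records.
#'
#' @param table a localization table.
#' @param settings a [render_settings()].
#' @param xlim,ylim field bounds, nm (default: tight bounds padded by 3
#'   maximal sigmas).
#' @return numeric matrix (rows = y); attributes `"xlim"`, `"ylim"`,
#'   `"pixel_size"` record the geometry.
#' @export
render_image <- function(table, settings = render_settings(),
                         xlim = NULL, ylim = NULL) {
  check_loc_columns(table, c("x_nm", "y_nm", "precision_nm"))
  p <- settings$pixel_size
  sig <- pmax(table$precision_nm, settings$min_sigma)
  if (nrow(table) && any(!is.finite(sig))) {
    sig[!is.finite(sig)] <- settings$min_sigma
  }
  pad <- if (nrow(table)) 3 * max(sig, p) else p
  if (is.null(xlim)) {
    xlim <- if (nrow(table)) c(min(table$x_nm) - pad, max(table$x_nm) + pad)
            else c(0, p)
  }
  if (is.null(ylim)) {
    ylim <- if (nrow(table)) c(min(table$y_nm) - pad, max(table$y_nm) + pad)
            else c(0, p)
  }
  W <- max(1L, ceiling((xlim[2] - xlim[1]) / p))
  H <- max(1L, ceiling((ylim[2] - ylim[1]) / p))
  img <- matrix(0, H, W)
  xe <- xlim[1] + (0:W) * p; ye <- ylim[1] + (0:H) * p
  for (k in seq_len(nrow(table))) {
    s <- sig[k]
    ## restrict to +- 6 sigma for speed; truncation error < 1e-8 of mass
    c1 <- max(1L, pixel_index(table$x_nm[k] - 6 * s - xlim[1], p))
    c2 <- min(W, pixel_index(table$x_nm[k] + 6 * s - xlim[1], p))
    r1 <- max(1L, pixel_index(table$y_nm[k] - 6 * s - ylim[1], p))
    r2 <- min(H, pixel_index(table$y_nm[k] + 6 * s - ylim[1], p))
    if (c1 > c2 || r1 > r2) next
    wx <- diff(stats::pnorm(xe[c1:(c2 + 1L)], table$x_nm[k], s))
    wy <- diff(stats::pnorm(ye[r1:(r2 + 1L)], table$y_nm[k], s))
    img[r1:r2, c1:c2] <- img[r1:r2, c1:c2] + outer(wy, wx)
  }
  attr(img, "xlim") <- xlim; attr(img, "ylim") <- ylim
  attr(img, "pixel_size") <- p
  img
}

## sub-pixel peak of a cross-correlation matrix: integer argmax plus
## 3-point quadratic interpolation per axis
subpixel_peak <- function(cc) {
  ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  H <- nrow(cc); W <- ncol(cc)
  interp <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (vm - vp) / den))
  }
  r <- ij[1]; c <- ij[2]
  dr <- interp(cc[if (r > 1) r - 1 else H, c], cc[r, c],
               cc[if (r < H) r + 1 else 1, c])
  dc <- interp(cc[r, if (c > 1) c - 1 else W], cc[r, c],
               cc[r, if (c < W) c + 1 else 1])
  c(row = r + dr, col = c + dc)
}

## shift of image b relative to image a (in pixels), by FFT cross-correlation
xcorr_shift <- function(a, b) {
  A <- stats::fft(a); B <- stats::fft(b)
  cc <- Re(stats::fft(A * Conj(B), inverse = TRUE))
  pk <- subpixel_peak(cc)
  H <- nrow(a); W <- ncol(a)
  sh <- pk - 1
  if (sh[1] > H / 2) sh[1] <- sh[1] - H
  if (sh[2] > W / 2) sh[2] <- sh[2] - W
  c(dy = -unname(sh[1]), dx = -unname(sh[2]))
}

#' Drift correction by redundant image cross-correlation
#'
#' Bins the movie into `n_windows` time windows, renders a superresolution
#' image per window, estimates all pairwise window shifts by FFT
#' cross-correlation with sub-pixel (3-point quadratic) peak interpolation,
#' solves the redundant shift system by least squares with window 1 as the
#' reference, interpolates a per-frame trajectory with a cubic spline, and
#' subtracts it. Correction is skipped (input returned unchanged, flag set)
#' for movies shorter than `min_frames` frames or when the estimated maximal
#' drift is below `min_drift`.
#'
#' @param table a localization table (>= 2 frames).
#' @param n_windows number of time windows (default 10).
#' @param min_frames minimum movie length in frames (default 5000).
#' @param min_drift minimum maximal drift amplitude to correct, nm
#'   (default 10).
#' @param render_pixel pixel size of the intermediate images, nm.
#' @return list with `table` (corrected), `drift` (n_frames x 2 matrix of
#'   subtracted drift, nm), `skipped` (logical), `reason`.
#' @export
drift_correct <- function(table, n_windows = 10L, min_frames = 5000L,
                          min_drift = 10, render_pixel = 10) {
  check_loc_columns(table)
  n_frames <- max(table$frame)
  if (length(unique(table$frame)) < 2L) stopf("need localizations in >= 2 frames")
  if (n_frames < min_frames) {
    return(list(table = table, drift = matrix(0, n_frames, 2),
                skipped = TRUE, reason = "short_movie"))
  }
  breaks <- round(seq(0L, n_frames, length.out = n_windows + 1L))
  win <- findInterval(table$frame, breaks[-1], left.open = FALSE) + 1L
  win <- pmin(win, n_windows)
  if (any(tabulate(win, n_windows) == 0L)) {
    stopf("degenerate windowing: at least one time window has no localizations")
  }
  st <- render_settings(pixel_size = render_pixel, min_sigma = render_pixel)
  pad <- 3 * render_pixel
  xlim <- c(min(table$x_nm) - pad, max(table$x_nm) + pad)
  ylim <- c(min(table$y_nm) - pad, max(table$y_nm) + pad)
  imgs <- lapply(seq_len(n_windows), function(w) {
    render_image(table[win == w, , drop = FALSE], st, xlim, ylim)
  })
  ## redundant pairwise shifts -> least squares for per-window positions
  pairs <- utils::combn(n_windows, 2)
  n_pairs <- ncol(pairs)
  A <- matrix(0, 2 * n_pairs, n_windows)
  bx <- numeric(n_pairs); by <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    sh <- xcorr_shift(imgs[[i]], imgs[[j]])
    bx[k] <- sh["dx"] * render_pixel
    by[k] <- sh["dy"] * render_pixel
  }
  ## s_j - s_i = shift(i, j); gauge: s_1 = 0 (drop column 1)
  M <- matrix(0, n_pairs, n_windows)
  for (k in seq_len(n_pairs)) {
    M[k, pairs[1, k]] <- -1; M[k, pairs[2, k]] <- 1
  }
  Mr <- M[, -1, drop = FALSE]
  sx <- c(0, stats::lsfit(Mr, bx, intercept = FALSE)$coefficients)
  sy <- c(0, stats::lsfit(Mr, by, intercept = FALSE)$coefficients)
  centers <- (breaks[-1] + breaks[-(n_windows + 1L)] + 1) / 2
  fx <- stats::splinefun(centers, sx, method = "natural")
  fy <- stats::splinefun(centers, sy, method = "natural")
  drift <- cbind(x = fx(seq_len(n_frames)), y = fy(seq_len(n_frames)))
  if (max(abs(drift)) < min_drift) {
    return(list(table = table, drift = matrix(0, n_frames, 2),
                skipped = TRUE, reason = "small_drift"))
  }
  out <- table
  out$x_nm <- out$x_nm - drift[out$frame, 1]
  out$y_nm <- out$y_nm - drift[out$frame, 2]
  list(table = out, drift = drift, skipped = FALSE, reason = "corrected")
}

#' Estimate a projective transform between two channels
#'
#' Least-squares homography (normalized DLT) mapping `moving_points` onto
#' `ref_points`, as used for dual-channel registration from bead
#' calibration images.
#'
#' @param ref_points,moving_points n x 2 matrices of matched positions (nm),
#'   n >= 5, not collinear.
#' @return a `projective_transform`: list with the 3 x 3 `matrix`
#'   (moving -> reference), `rms_error` (nm) and `n_control_points`.
#' @export
estimate_channel_transform <- function(ref_points, moving_points) {
  ref <- as.matrix(ref_points); mov <- as.matrix(moving_points)
  if (nrow(ref) != nrow(mov)) stopf("point sets must have equal size")
  if (nrow(ref) < 5L) stopf("at least 5 point pairs are required")
  ## collinearity check via rank of centred coordinates
  if (any(svd(scale(ref, scale = FALSE))$d < 1e-9 * max(abs(ref), 1)) ||
      any(svd(scale(mov, scale = FALSE))$d < 1e-9 * max(abs(mov), 1))) {
    stopf("control points are collinear; homography is degenerate")
  }
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, ctr)^2)))
    Tm <- rbind(c(sc, 0, -sc * ctr[1]), c(0, sc, -sc * ctr[2]), c(0, 0, 1))
    list(p = cbind(sc * (p[, 1] - ctr[1]), sc * (p[, 2] - ctr[2])), T = Tm)
  }
  nr <- norm_pts(ref); nm <- norm_pts(mov)
  x <- nm$p[, 1]; y <- nm$p[, 2]; u <- nr$p[, 1]; v <- nr$p[, 2]
  n <- length(x)
  Z <- rep(0, n); O <- rep(1, n)
  A <- rbind(cbind(x, y, O, Z, Z, Z, -u * x, -u * y, -u),
             cbind(Z, Z, Z, x, y, O, -v * x, -v * y, -v))
  h <- svd(A, nu = 0)$v[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nr$T) %*% Hn %*% nm$T
  H <- H / H[3, 3]
  mapped <- apply_transform(H, mov)
  rms <- sqrt(mean(rowSums((mapped - ref)^2)))
  structure(list(matrix = H, rms_error = rms, n_control_points = nrow(ref)),
            class = "projective_transform")
}

#' Apply a projective transform to points
#'
#' @param transform a `projective_transform` or a 3 x 3 matrix.
#' @param points n x 2 matrix (nm).
#' @return transformed n x 2 matrix.
#' @export
apply_transform <- function(transform, points) {
  H <- if (inherits(transform, "projective_transform")) transform$matrix
       else transform
  p <- cbind(as.matrix(points), 1) %*% t(H)
  p[, 1:2, drop = FALSE] / p[, 3]
}
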