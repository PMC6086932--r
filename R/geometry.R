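## geometry: the analytical core. An endocytic site is modelled as an
## annulus (ring) or filled disk (patch) convolved with the localization
## precision:
##
##   f(X,Y) = A * [ erf((r_out - R)/(sqrt(2) sigma))
##                - erf((r_out - dr - R)/(sqrt(2) sigma)) ]
##   R(X,Y) = sqrt((X - x0)^2 + (Y - y0)^2)
##
## with sigma fixed at 15 nm (the expected localization spread). Rings have
## dr < r_out (central hole); patches have dr >= r_out. The model is fitted
## to a 3 nm rendering of each site by least squares over
## {x0, y0, r_out, dr}, the amplitude A being profiled out linearly.

#' Geometric ring/patch model
#'
#' @param x0,y0 center coordinates, nm.
#' @param r_out outer radius, nm (> 0).
#' @param dr rim thickness, nm (> 0).
#' @param A amplitude (>= 0).
#' @param sigma blur SD, nm (default 15, the expected localization spread).
#' @return a `geometric_model` list.
#' @export
geometric_model <- function(x0 = 0, y0 = 0, r_out, dr, A = 1, sigma = 15) {
  check_number(r_out, "r_out", 0, strict = TRUE)
  check_number(dr, "dr", 0, strict = TRUE)
  check_number(A, "A", 0)
  check_number(sigma, "sigma", 0, strict = TRUE)
  structure(list(x0 = x0, y0 = y0, r_out = r_out, dr = dr, A = A,
                 sigma = sigma),
            class = "geometric_model")
}

#' Evaluate the ring/patch model on a grid
#'
#' @param model a [geometric_model()].
#' @param X,Y congruent coordinate grids (nm), e.g. from `outer()`; vectors
#'   are also accepted and evaluated elementwise.
#' @return numeric array of model densities, same shape as `X`.
#' @export
model_density <- function(model, X, Y) {
  if (!identical(dim(X), dim(Y)) || length(X) != length(Y)) {
    stopf("'X' and 'Y' grids must be congruent")
  }
  R <- sqrt((X - model$x0)^2 + (Y - model$y0)^2)
  s2 <- sqrt(2) * model$sigma
  model$A * (erf((model$r_out - R) / s2) -
               erf((model$r_out - model$dr - R) / s2))
}

## model on the pixel-center grid of a rendered image (attributes from
## render_image); returns a matrix congruent with the image
model_on_image <- function(model, img) {
  p <- attr(img, "pixel_size")
  xs <- attr(img, "xlim")[1] + pixel_centers(ncol(img), p)
  ys <- attr(img, "ylim")[1] + pixel_centers(nrow(img), p)
  X <- matrix(xs, nrow(img), ncol(img), byrow = TRUE)
  Y <- matrix(ys, nrow(img), ncol(img))
  model_density(model, X, Y)
}

## profile out A for a fixed shape: least-squares amplitude, clamped >= 0
profile_amplitude <- function(f0, img) {
  den <- sum(f0 * f0)
  if (den <= 0) return(0)
  max(0, sum(f0 * img) / den)
}

#' Fit the ring/patch model to one site
#'
#' Renders the site's localizations at `render_pixel` nm (minimum rendered
#' sigma 6 nm) and minimizes the sum of squared residuals between the image
#' and the model over {x0, y0, r_out, dr}, the amplitude being solved
#' analytically at every step. A bounded Nelder-Mead search with perturbed
#' restarts is used; bounds are r_out in [5, 300] nm, dr in [5, 600] nm.
#' Initialization: localization centroid and RMS radius. Exclusion rules
#' are applied afterwards: the `"general"` policy excludes sites with fitted
#' r_out < 30 nm or fewer than 30 localizations; the `"coat_scission"`
#' policy (small coat/scission structures) excludes only on count.
#'
#' @param locs localization table of one site (>= 5 records).
#' @param render_pixel render pixel size, nm (default 3).
#' @param init optional [geometric_model()] initial guess.
#' @param sigma model blur SD, nm (default 15).
#' @param policy exclusion policy: `"general"` or `"coat_scission"`.
#' @param restarts number of perturbed restarts (default 3).
#' @param max_r half-size of the fitted field around the centroid, nm.
#' @return a `site_fit`: list with `model`, `n_localizations`,
#'   `residual_ss`, `excluded`, `reason` (`"none"`, `"small_radius"`,
#'   `"few_locs"`, `"optim_failure"`), and `image` (the rendering).
#' @export
fit_site <- function(locs, render_pixel = 3, init = NULL, sigma = 15,
                     policy = c("general", "coat_scission"), restarts = 3L,
                     max_r = 250) {
  policy <- match.arg(policy)
  check_loc_columns(locs, c("x_nm", "y_nm", "precision_nm"))
  n <- nrow(locs)
  if (n < 5L) stopf("at least 5 localizations are required to fit a site")
  ## fit in centroid-local coordinates: better conditioned than absolute
  ## field coordinates, and (with micro-nm quantization) the fitter sees
  ## bit-identical data under any translation of the input, making the fit
  ## exactly translation-equivariant
  cx <- round(mean(locs$x_nm), 6); cy <- round(mean(locs$y_nm), 6)
  flat <- locs
  flat$x_nm <- round(locs$x_nm - cx, 6)
  flat$y_nm <- round(locs$y_nm - cy, 6)
  ## render as a near-histogram (floor kernel only): the blur observed in
  ## the image is then the true localization scatter, which the model's
  ## fixed sigma represents -- rendering with per-record precision would
  ## count the localization error twice
  st <- render_settings(pixel_size = render_pixel, min_sigma = 6)
  flat$precision_nm <- 0
  img <- render_image(flat, st, xlim = c(-max_r, max_r),
                      ylim = c(-max_r, max_r))
  rms_r <- sqrt(mean(flat$x_nm^2 + flat$y_nm^2))
  if (is.null(init)) {
    init <- geometric_model(x0 = 0, y0 = 0,
                            r_out = min(max(rms_r * 1.2, 10), 290),
                            dr = min(max(rms_r, 10), 590), sigma = sigma)
  } else {
    init <- geometric_model(x0 = init$x0 - cx, y0 = init$y0 - cy,
                            r_out = init$r_out, dr = init$dr, A = init$A,
                            sigma = init$sigma)
  }
  ## looser simplex settings than the ideal-image fit: estimates from a
  ## few hundred localizations carry nm-scale statistical error, so
  ## sub-1e-3-nm objective resolution buys nothing
  fit <- fit_model_to_image(img, init, sigma = sigma, restarts = restarts,
                            maxit = 600, reltol = 1e-7, polish = FALSE)
  if (is.null(fit)) {
    init$x0 <- init$x0 + cx; init$y0 <- init$y0 + cy
    return(structure(list(model = init, n_localizations = n,
                          residual_ss = NA_real_, excluded = TRUE,
                          reason = "optim_failure", image = img),
                     class = "site_fit"))
  }
  model <- fit$model
  model$x0 <- model$x0 + cx; model$y0 <- model$y0 + cy
  reason <- "none"
  if (n < 30L) reason <- "few_locs"
  else if (policy == "general" && model$r_out < 30) reason <- "small_radius"
  structure(list(model = model, n_localizations = n,
                 residual_ss = fit$residual_ss, excluded = reason != "none",
                 reason = reason, image = img),
            class = "site_fit")
}

#' Least-squares fit of the ring/patch model to an image
#'
#' Core optimizer behind [fit_site()], usable directly on any rendered (or
#' ideal) image carrying the geometry attributes set by [render_image()].
#' Minimizes the pixelwise sum of squared residuals over
#' {x0, y0, r_out, dr} by bounded Nelder-Mead with perturbed restarts
#' (tie-break by residual sum of squares); A is profiled out linearly at
#' every step.
#'
#' @param img numeric matrix with attributes `xlim`, `ylim`, `pixel_size`.
#' @param init a [geometric_model()] start.
#' @param sigma blur SD of the model, nm.
#' @param restarts number of perturbed restarts.
#' @param maxit,reltol Nelder-Mead control settings; the defaults are tight
#'   enough for 1e-2 nm recovery on ideal images. Noisy single-site fits
#'   (whose estimates carry nm-scale statistical error anyway) may use
#'   looser values for speed.
#' @param polish run a second simplex from the located optimum (default
#'   TRUE; the restarted simplex recovers curvature lost to shrinkage).
#' @return list with `model` and `residual_ss`, or NULL on optimizer
#'   failure.
#' @export
fit_model_to_image <- function(img, init, sigma = 15, restarts = 3L,
                               maxit = 4000, reltol = 1e-12, polish = TRUE) {
  xlim <- attr(img, "xlim"); ylim <- attr(img, "ylim")
  p <- attr(img, "pixel_size")
  if (is.null(xlim) || is.null(p)) {
    stopf("'img' must carry xlim/ylim/pixel_size attributes")
  }
  xs <- xlim[1] + pixel_centers(ncol(img), p)
  ys <- ylim[1] + pixel_centers(nrow(img), p)
  X <- matrix(xs, nrow(img), ncol(img), byrow = TRUE)
  Y <- matrix(ys, nrow(img), ncol(img))
  s2 <- sqrt(2) * sigma
  lo <- c(xlim[1], ylim[1], 5, 5)
  hi <- c(xlim[2], ylim[2], 300, 600)
  obj <- function(th) {
    if (any(th < lo) || any(th > hi)) return(1e12)
    R <- sqrt((X - th[1])^2 + (Y - th[2])^2)
    f0 <- erf((th[3] - R) / s2) - erf((th[3] - th[4] - R) / s2)
    A <- profile_amplitude(f0, img)
    sum((img - A * f0)^2)
  }
  th0 <- c(init$x0, init$y0, init$r_out, init$dr)
  best <- NULL
  for (r in seq_len(max(1L, restarts))) {
    start <- th0
    if (r > 1L) {
      start <- th0 + c(stats::rnorm(2, 0, 10),
                       stats::rnorm(2, 0, 0.25 * pmax(th0[3:4], 10)))
      start <- pmin(pmax(start, lo + 1e-6), hi - 1e-6)
    }
    opt <- tryCatch(
      stats::optim(start, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (polish) {
      ## restart the simplex at the located optimum to recover curvature
      opt2 <- tryCatch(
        stats::optim(opt$par, obj, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = reltol)),
        error = function(e) opt)
      if (opt2$value <= opt$value) opt <- opt2
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) return(NULL)
  th <- best$par
  R <- sqrt((X - th[1])^2 + (Y - th[2])^2)
  f0 <- erf((th[3] - R) / s2) - erf((th[3] - th[4] - R) / s2)
  A <- profile_amplitude(f0, img)
  list(model = geometric_model(x0 = th[1], y0 = th[2], r_out = th[3],
                               dr = th[4], A = A, sigma = sigma),
       residual_ss = best$value)
}

#' Radial profile of localizations around a center
#'
#' Histogram of distances from `center` with half-open bins
#' `[k*w, (k+1)*w)`; density is counts divided by the annulus area of each
#' bin (per nm^2).
#'
#' @param locs localization table (or matrix with x, y columns).
#' @param center length-2 center, nm.
#' @param bin_width bin width, nm (default 5).
#' @param max_r maximum radius, nm (default 250).
#' @return a `radial_profile`: data.frame with `r_mid`, `counts`, `density`,
#'   plus attributes `bin_edges`, `n_localizations`.
#' @export
radial_profile <- function(locs, center, bin_width = 5, max_r = 250) {
  if (is.matrix(locs)) {
    x <- locs[, 1]; y <- locs[, 2]
  } else {
    check_loc_columns(locs, c("x_nm", "y_nm"))
    x <- locs$x_nm; y <- locs$y_nm
  }
  d <- sqrt((x - center[1])^2 + (y - center[2])^2)
  edges <- seq(0, max_r, by = bin_width)
  if (edges[length(edges)] < max_r) edges <- c(edges, max_r)
  nb <- length(edges) - 1L
  bin <- findInterval(d, edges, rightmost.closed = FALSE, left.open = FALSE)
  counts <- tabulate(bin[bin >= 1L & bin <= nb & d < edges[nb + 1L]], nb)
  area <- pi * diff(edges^2)
  out <- data.frame(r_mid = (edges[-1] + edges[-(nb + 1L)]) / 2,
                    counts = counts, density = counts / area)
  attr(out, "bin_edges") <- edges
  attr(out, "n_localizations") <- sum(counts)
  class(out) <- c("radial_profile", "data.frame")
  out
}

## half-width at half-maximum of a discrete radial profile, by linear
## interpolation on the first crossing below half of the profile maximum
profile_hwhm <- function(profile) {
  dens <- profile$density
  r <- profile$r_mid
  pk <- which.max(dens)
  half <- dens[pk] / 2
  for (i in seq(pk, length(dens) - 1L)) {
    if (dens[i + 1L] <= half && dens[i] > half) {
      return(r[i] + (dens[i] - half) / (dens[i] - dens[i + 1L]) *
               (r[i + 1L] - r[i]))
    }
  }
  NA_real_
}

#' Align sites by their fitted centers and average
#'
#' Translates each site's localizations by minus its fitted center, renders
#' all centered sites on a common grid, sums the renderings, and averages
#' the radial profiles. The summary reports mean, SD and SEM of the fitted
#' outer radii, the ring fraction (sites with `dr < r_out`), and the HWHM of
#' the average profile.
#'
#' @param fits list of `site_fit` objects.
#' @param locs_list list of localization tables, parallel to `fits`.
#' @param render_pixel pixel size of the average image, nm.
#' @param max_r field half-size and profile range, nm.
#' @param bin_width radial profile bin width, nm.
#' @return list with `image` (average image), `profile` (average radial
#'   profile), and `summary` (a `module_summary`).
#' @export
align_and_average <- function(fits, locs_list, render_pixel = 3,
                              max_r = 250, bin_width = 5) {
  keep <- !vapply(fits, `[[`, TRUE, "excluded")
  if (!any(keep)) stopf("all site fits are excluded; nothing to average")
  fits <- fits[keep]; locs_list <- locs_list[keep]
  st <- render_settings(pixel_size = render_pixel, min_sigma = 6)
  img <- NULL
  prof_dens <- NULL
  counts_tot <- NULL
  for (i in seq_along(fits)) {
    m <- fits[[i]]$model
    ctr <- localization_table(
      frame = locs_list[[i]]$frame,
      x_nm = locs_list[[i]]$x_nm - m$x0,
      y_nm = locs_list[[i]]$y_nm - m$y0,
      photons = locs_list[[i]]$photons, bg = locs_list[[i]]$bg,
      sigma_nm = locs_list[[i]]$sigma_nm,
      precision_nm = locs_list[[i]]$precision_nm,
      channel = locs_list[[i]]$channel)
    im <- render_image(ctr, st, xlim = c(-max_r, max_r),
                       ylim = c(-max_r, max_r))
    img <- if (is.null(img)) im else img + im
    pr <- radial_profile(ctr, c(0, 0), bin_width, max_r)
    prof_dens <- if (is.null(prof_dens)) pr$density else prof_dens + pr$density
    counts_tot <- if (is.null(counts_tot)) pr$counts else counts_tot + pr$counts
  }
  n_sites <- length(fits)
  prof <- data.frame(r_mid = radial_profile(matrix(0, 0, 2), c(0, 0),
                                            bin_width, max_r)$r_mid,
                     counts = counts_tot, density = prof_dens / n_sites)
  class(prof) <- c("radial_profile", "data.frame")
  r_out <- vapply(fits, function(f) f$model$r_out, 1)
  dr <- vapply(fits, function(f) f$model$dr, 1)
  stats <- summary_stats(r_out)
  summary <- structure(list(
    mean_r_out = stats[["mean"]], sd_r_out = stats[["sd"]],
    sem_r_out = stats[["sem"]], n_sites = n_sites,
    ring_fraction = mean(dr < r_out),
    mean_dr = mean(dr),
    hwhm = profile_hwhm(prof)), class = "module_summary")
  attr(img, "xlim") <- c(-max_r, max_r); attr(img, "ylim") <- c(-max_r, max_r)
  attr(img, "pixel_size") <- render_pixel
  list(image = img, profile = prof, summary = summary)
}

#' Classify the average shape of a protein's distribution
#'
#' Dome: mean outer radius above 80 nm and a central density above 80% of
#' the profile maximum (large structure with only a slight central minimum,
#' the projection of a hemispherical network). Otherwise ring if the average
#' fit has `dr < r_out` (central hole), else patch.
#'
#' @param summary a `module_summary` from [align_and_average()].
#' @param profile the average radial profile.
#' @return one of `"dome"`, `"ring"`, `"patch"`.
#' @export
classify_shape <- function(summary, profile) {
  center_density <- profile$density[1]
  if (summary$mean_r_out > 80 &&
      center_density > 0.8 * max(profile$density)) {
    return("dome")
  }
  if (summary$mean_dr < summary$mean_r_out) "ring" else "patch"
}

#' Mean, SD and SEM of a sample
#'
#' SD uses the n-1 denominator; SEM = SD / sqrt(n).
#'
#' @param values numeric vector.
#' @return named vector `c(mean, sd, sem, n)`.
#' @export
summary_stats <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  s <- stats::sd(values)
  c(mean = mean(values), sd = s, sem = s / sqrt(n), n = n)
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided test of the null hypothesis of equal distributions. For small
#' samples (`min(n) <= 8`) without ties the exact null distribution of the
#' U statistic is used; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b numeric samples (n >= 1 each).
#' @return list with `statistic` (U of sample `a`), `p_value`, `method`.
#' @export
rank_sum_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stopf("both samples must be non-empty")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (min(n1, n2) <= 8L && !has_ties) {
    ## exact null distribution of U
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n1 + n2 + 1 - tie_term))
    z <- (U - mu - sign(U - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  list(statistic = U, p_value = p, method = method)
}
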