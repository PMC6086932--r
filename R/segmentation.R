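## segmentation: find cells in the reconstructed image and candidate
## endocytic sites restricted to the flat cell-bottom region (center of the
## cell footprint, where invaginations are perpendicular to the focal
## plane and structures are not tilted).

## Gaussian blur of a matrix, sigma in pixels (separable, zero boundary:
## outside the field there are no localizations)
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-half:half, 0, sigma_px)
  k <- k / sum(k)
  pad <- matrix(0, nrow(img) + 2L * half, ncol(img) + 2L * half)
  pad[half + seq_len(nrow(img)), half + seq_len(ncol(img))] <- img
  out <- conv_sep(pad, k)
  out[half + seq_len(nrow(img)), half + seq_len(ncol(img))]
}

## local maxima above a threshold with a minimum separation (px);
## greedy by decreasing intensity
peaks_with_separation <- function(img, threshold, min_sep_px) {
  H0 <- nrow(img); W0 <- ncol(img)
  locmax <- matrix(TRUE, H0, W0)
  pad <- matrix(-Inf, H0 + 2L, W0 + 2L)
  pad[2:(H0 + 1L), 2:(W0 + 1L)] <- img
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    locmax <- locmax & (img >= pad[(2:(H0 + 1L)) + dr, (2:(W0 + 1L)) + dc])
  }
  cand <- which(img > threshold & locmax)
  if (!length(cand)) return(data.frame(row = integer(), col = integer(),
                                       value = numeric()))
  H <- nrow(img)
  rows <- (cand - 1L) %% H + 1L
  cols <- (cand - 1L) %/% H + 1L
  vals <- img[cand]
  ord <- order(-vals, rows, cols)
  rows <- rows[ord]; cols <- cols[ord]; vals <- vals[ord]
  keep <- logical(length(vals))
  for (i in seq_along(vals)) {
    sel <- which(keep)
    if (!length(sel) ||
        all((rows[sel] - rows[i])^2 + (cols[sel] - cols[i])^2 >
              min_sep_px^2)) {
      keep[i] <- TRUE
    }
  }
  data.frame(row = rows[keep], col = cols[keep], value = vals[keep])
}

#' Segment cells in a reconstructed image
#'
#' Renders the table, filters with a large Gaussian blur, and returns peaks
#' above the threshold as one seed per cell, with a minimum seed separation
#' of `2 * blur_sigma`.
#'
#' @param table localization table.
#' @param blur_sigma blur SD, nm (default 1000: much larger than any site,
#'   well below the cell diameter).
#' @param threshold peak threshold in blurred localization density
#'   (localizations per pixel after blur).
#' @param pixel_size render pixel size, nm (default 200).
#' @return data.frame with `x_nm`, `y_nm`, `value` (one row per seed).
#' @export
segment_cells <- function(table, blur_sigma = 1000, threshold = 0.05,
                          pixel_size = 200) {
  check_loc_columns(table, c("x_nm", "y_nm"))
  if (!nrow(table)) {
    return(data.frame(x_nm = numeric(), y_nm = numeric(), value = numeric()))
  }
  st <- render_settings(pixel_size = pixel_size, min_sigma = pixel_size / 2)
  img <- render_image(table, st)
  bl <- gaussian_blur(img, blur_sigma / pixel_size)
  pk <- peaks_with_separation(bl, threshold, 2 * blur_sigma / pixel_size)
  ## refine each seed to the intensity-weighted centroid of the blurred
  ## density within one blur sigma (the blurred peak of an extended cell
  ## is a plateau; its argmax alone is quantized to the render pixel)
  xs <- attr(img, "xlim")[1] + (pk$col - 0.5) * pixel_size
  ys <- attr(img, "ylim")[1] + (pk$row - 0.5) * pixel_size
  cgx <- attr(img, "xlim")[1] + pixel_centers(ncol(img), pixel_size)
  cgy <- attr(img, "ylim")[1] + pixel_centers(nrow(img), pixel_size)
  for (i in seq_len(nrow(pk))) {
    D2 <- outer((cgy - ys[i])^2, (cgx - xs[i])^2, "+")
    w <- bl * (D2 <= blur_sigma^2)
    xs[i] <- sum(w %*% cgx) / sum(w)
    ys[i] <- sum(t(w) %*% cgy) / sum(w)
  }
  data.frame(x_nm = xs, y_nm = ys, value = pk$value)
}

#' Flat cell-bottom region of one cell
#'
#' Masks a coarse (default 200 nm) rendering at `mask_threshold`
#' localizations per pixel, takes the convex hull of the in-mask
#' localizations, constricts it by iteratively removing the hull points
#' `hull_peel` times, and finally scales the polygon about its centroid so
#' that its area shrinks by at least `shrink_fraction`. Only sites inside
#' this shrunk polygon are analyzed (they sit on the flat membrane at the
#' cell bottom; peripheral structures are tilted).
#'
#' @param locs localizations of one cell (>= 10 records).
#' @param mask_pixel mask rendering pixel size, nm (default 200).
#' @param mask_threshold mask threshold, localizations per mask pixel.
#' @param hull_peel hull peeling iterations (default 3).
#' @param shrink_fraction minimum area shrink fraction (default 0.30).
#' @return a `cell_region`: list with `hull_vertices`, `shrunk_polygon`
#'   (matrices of x, y in nm) and `localization_indices` (rows of `locs`
#'   inside the shrunk polygon).
#' @export
cell_bottom_region <- function(locs, mask_pixel = 200, mask_threshold = 1,
                               hull_peel = 3L, shrink_fraction = 0.30) {
  check_loc_columns(locs, c("x_nm", "y_nm"))
  if (nrow(locs) < 10L) stopf("at least 10 localizations are required")
  ## mask on the coarse rendering: keep localizations in dense pixels
  ix <- pixel_index(locs$x_nm - min(locs$x_nm), mask_pixel)
  iy <- pixel_index(locs$y_nm - min(locs$y_nm), mask_pixel)
  key <- paste(ix, iy)
  dens <- table(key)
  inmask <- dens[key] >= mask_threshold
  pts <- cbind(locs$x_nm, locs$y_nm)[inmask, , drop = FALSE]
  ## convex hull, peeled hull_peel times
  work <- pts
  for (i in seq_len(hull_peel)) {
    if (nrow(work) < 4L) break
    h <- grDevices::chull(work)
    if (nrow(work) - length(h) < 3L) break
    work <- work[-h, , drop = FALSE]
  }
  if (nrow(work) < 3L) stopf("fewer than 3 points remain after hull peeling")
  h <- grDevices::chull(work)
  hull <- work[h, , drop = FALSE]
  if (length(unique(hull[, 1])) < 2L || length(unique(hull[, 2])) < 2L ||
      abs(polygon_area(hull)) < 1e-9) {
    stopf("degenerate (collinear) point set; cannot form a cell region")
  }
  ctr <- colMeans(hull)
  scale <- sqrt(1 - shrink_fraction)
  shrunk <- sweep(sweep(hull, 2, ctr) * scale, 2, ctr, "+")
  inside <- mgcv::in.out(rbind(shrunk, shrunk[1, ]),
                         cbind(locs$x_nm, locs$y_nm))
  structure(list(hull_vertices = hull, shrunk_polygon = shrunk,
                 localization_indices = which(inside)),
            class = "cell_region")
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y) / 2
}

## connected component of above-threshold pixels containing (row, col)
flood_component <- function(mask, row, col) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  stack_r <- row; stack_c <- col
  seen[row, col] <- TRUE
  out_r <- integer(0); out_c <- integer(0)
  while (length(stack_r)) {
    r <- stack_r[1]; c <- stack_c[1]
    stack_r <- stack_r[-1]; stack_c <- stack_c[-1]
    out_r <- c(out_r, r); out_c <- c(out_c, c)
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
          mask[rr, cc] && !seen[rr, cc]) {
        seen[rr, cc] <- TRUE
        stack_r <- c(stack_r, rr); stack_c <- c(stack_c, cc)
      }
    }
  }
  cbind(row = out_r, col = out_c)
}

#' Segment endocytic sites inside a cell-bottom region
#'
#' Renders the region's localizations at `site_pixel` nm, picks peaks above
#' the threshold inside the shrunk polygon, and measures the connected
#' component of above-threshold pixels around each peak. Components whose
#' maximal (Feret) diameter exceeds `max_extent` are flagged `too_large`:
#' they are typically closely juxtaposed double sites, which would bias the
#' geometric fit.
#'
#' @param locs the cell's localization table.
#' @param region a [cell_bottom_region()].
#' @param site_pixel render pixel size, nm (default 100).
#' @param threshold peak threshold, localization-equivalents per site pixel
#'   (default 5).
#' @param max_extent maximal allowed component diameter, nm (default 500).
#' @return data.frame of site picks: `x_nm`, `y_nm`, `peak_value`,
#'   `extent_nm`, `excluded_reason` (`"none"` or `"too_large"`).
#' @export
segment_sites <- function(locs, region, site_pixel = 100, threshold = 5,
                          max_extent = 500) {
  check_loc_columns(locs, c("x_nm", "y_nm"))
  empty <- data.frame(x_nm = numeric(), y_nm = numeric(),
                      peak_value = numeric(), extent_nm = numeric(),
                      excluded_reason = character())
  sel <- locs[region$localization_indices, , drop = FALSE]
  if (!nrow(sel)) return(empty)
  st <- render_settings(pixel_size = site_pixel, min_sigma = site_pixel / 3)
  img <- render_image(sel, st)
  pk <- peaks_with_separation(img, threshold, 2)
  if (!nrow(pk)) return(empty)
  x0 <- attr(img, "xlim")[1]; y0 <- attr(img, "ylim")[1]
  xs <- x0 + (pk$col - 0.5) * site_pixel
  ys <- y0 + (pk$row - 0.5) * site_pixel
  poly <- rbind(region$shrunk_polygon, region$shrunk_polygon[1, ])
  inside <- mgcv::in.out(poly, cbind(xs, ys))
  pk <- pk[inside, , drop = FALSE]
  xs <- xs[inside]; ys <- ys[inside]
  if (!nrow(pk)) return(empty)
  mask <- img > threshold
  extent <- numeric(nrow(pk))
  comp_key <- character(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    comp <- flood_component(mask, pk$row[i], pk$col[i])
    comp_key[i] <- paste(min((comp[, "col"] - 1L) * nrow(img) +
                               comp[, "row"]))
    cxy <- cbind(x0 + (comp[, "col"] - 0.5) * site_pixel,
                 y0 + (comp[, "row"] - 0.5) * site_pixel)
    w <- img[comp]
    ## center = intensity-weighted centroid of the component (the peak
    ## pixel of a ring sits on the rim, not at the site center)
    xs[i] <- sum(w * cxy[, 1]) / sum(w)
    ys[i] <- sum(w * cxy[, 2]) / sum(w)
    extent[i] <- if (nrow(comp) == 1L) site_pixel else
      max(stats::dist(cxy)) + site_pixel
  }
  ## one pick per connected component (strongest peak wins; pk is sorted
  ## by decreasing value)
  first <- !duplicated(comp_key)
  data.frame(x_nm = xs, y_nm = ys, peak_value = pk$value,
             extent_nm = extent,
             excluded_reason = ifelse(extent > max_extent,
                                      "too_large", "none"))[first, ]
}

#' Extract per-site localizations around picked centers
#'
#' Convenience cutter: returns, for every pick, the localizations within
#' `radius` of the pick center.
#'
#' @param locs localization table.
#' @param picks data.frame with `x_nm`, `y_nm`.
#' @param radius cut radius, nm (default 250).
#' @return list of localization tables, one per pick.
#' @export
cut_sites <- function(locs, picks, radius = 250) {
  lapply(seq_len(nrow(picks)), function(i) {
    d2 <- (locs$x_nm - picks$x_nm[i])^2 + (locs$y_nm - picks$y_nm[i])^2
    out <- locs[d2 <= radius^2, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Acquisition-statistics quality report
#'
#' The four per-experiment quality metrics monitored during automated
#' imaging: median localization precision, median fitted background, total
#' localization count, and frame count.
#'
#' @param table a localization table.
#' @return named list of the four metrics.
#' @export
acquisition_report <- function(table) {
  check_loc_columns(table)
  list(median_precision_nm = stats::median(table$precision_nm),
       median_background = stats::median(table$bg),
       n_localizations = nrow(table),
       n_frames = if (nrow(table)) max(table$frame) else 0L)
}
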