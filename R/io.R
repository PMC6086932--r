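## Plain-text file formats. Localization tables travel as CSV (tables.R);
## manifests and configuration as JSON; image stacks as a small text format
## (JSON header line + one whitespace-separated row of values per line),
## since no TIFF codec is available in the target R stack. All formats are
## self-describing and round-trip exactly at full double precision.

#' Write / read an image stack as plain text
#'
#' Line 1 is a JSON header with the array dimensions and optional metadata;
#' the remaining lines contain the values of each slice in row-major order,
#' one image row per line.
#'
#' @param stack numeric matrix or 3D array (`H x W x n`).
#' @param path file path.
#' @param meta optional named list stored in the header.
#' @return `write_stack_txt` returns `path` invisibly; `read_stack_txt`
#'   returns the array with the metadata in attribute `"meta"`.
#' @export
write_stack_txt <- function(stack, path, meta = list()) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  hdr <- jsonlite::toJSON(c(list(dim = dim(stack)), meta),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  for (k in seq_len(dim(stack)[3])) {
    utils::write.table(stack[, , k], con, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_stack_txt
#' @export
read_stack_txt <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  d <- as.integer(hdr$dim)
  vals <- scan(text = lines[-1], quiet = TRUE)
  if (length(vals) != prod(d)) stopf("stack data does not match header dims")
  ## rows were written as lines: values come row-major per slice
  arr <- array(NA_real_, d)
  per_slice <- d[1] * d[2]
  for (k in seq_len(d[3])) {
    sl <- vals[((k - 1L) * per_slice + 1L):(k * per_slice)]
    arr[, , k] <- matrix(sl, d[1], d[2], byrow = TRUE)
  }
  meta <- hdr[setdiff(names(hdr), "dim")]
  attr(arr, "meta") <- meta
  arr
}

#' Write / read a ground-truth manifest as JSON
#'
#' @param manifest a [ground_truth_manifest()].
#' @param path file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns a `gt_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  obj <- list(
    sites = lapply(manifest$sites, unclass),
    molecule_positions = lapply(manifest$molecule_positions, function(m) {
      list(x = m[, 1], y = m[, 2])
    }),
    drift_trajectory = list(x = manifest$drift_trajectory[, 1],
                            y = manifest$drift_trajectory[, 2]),
    gfp_true_amplitudes = manifest$gfp_true_amplitudes,
    n_frames = manifest$n_frames)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  sites <- lapply(obj$sites, function(s) {
    structure_spec(shape = s$shape, center = unlist(s$center),
                   r_out = s$r_out, dr = s$dr, n_molecules = s$n_molecules,
                   dome_height = s$dome_height)
  })
  pos <- lapply(obj$molecule_positions, function(m) cbind(m$x, m$y))
  drift <- cbind(obj$drift_trajectory$x, obj$drift_trajectory$y)
  structure(list(sites = sites, molecule_positions = pos,
                 drift_trajectory = drift,
                 gfp_true_amplitudes = obj$gfp_true_amplitudes,
                 n_frames = obj$n_frames),
            class = "gt_manifest")
}
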