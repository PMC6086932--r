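## LocalizationTable: the central tabular container of the pipeline.
## A plain data.frame with a fixed schema, one row per detected (or grouped)
## blink event. All coordinates are nm with the origin at the field corner.

LOC_COLUMNS <- c("frame", "x_nm", "y_nm", "photons", "bg",
                 "sigma_nm", "precision_nm", "channel")

#' Construct a localization table
#'
#' Builds the standard localization table used throughout the package, one
#' record per detected blink (or per grouped blink chain). Missing columns
#' are filled with defaults; extra columns are rejected.
#'
#' @param frame integer frame indices (1-based).
#' @param x_nm,y_nm coordinates in nm, origin at the field corner.
#' @param photons detected photon counts.
#' @param bg fitted background, photons per pixel.
#' @param sigma_nm fitted PSF standard deviation, nm.
#' @param precision_nm localization precision (CRLB-based), nm.
#' @param channel integer channel label.
#' @return a `data.frame` with class `locs` and columns
#'   `frame, x_nm, y_nm, photons, bg, sigma_nm, precision_nm, channel`.
#' @export
localization_table <- function(frame = integer(), x_nm = numeric(),
                               y_nm = numeric(), photons = NA_real_,
                               bg = NA_real_, sigma_nm = NA_real_,
                               precision_nm = NA_real_, channel = 1L) {
  n <- max(length(frame), length(x_nm), length(y_nm))
  rep_n <- function(v) if (n == 0L) v[0] else rep_len(v, n)
  out <- data.frame(frame = rep_n(as.integer(frame)),
                    x_nm = rep_n(as.numeric(x_nm)),
                    y_nm = rep_n(as.numeric(y_nm)),
                    photons = rep_n(as.numeric(photons)),
                    bg = rep_n(as.numeric(bg)),
                    sigma_nm = rep_n(as.numeric(sigma_nm)),
                    precision_nm = rep_n(as.numeric(precision_nm)),
                    channel = rep_n(as.integer(channel)))
  class(out) <- c("locs", "data.frame")
  out
}

## validate that a table carries the columns an operation needs
check_loc_columns <- function(table, cols = LOC_COLUMNS) {
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    stopf("localization table is missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  invisible(table)
}

as_locs <- function(df) {
  check_loc_columns(df)
  df <- df[LOC_COLUMNS]
  class(df) <- c("locs", "data.frame")
  df
}

#' Read / write localization tables as CSV
#'
#' The on-disk format is plain CSV with exactly the schema columns.
#'
#' @param path file path.
#' @return `read_localizations()` returns a localization table;
#'   `write_localizations()` returns `path` invisibly.
#' @export
read_localizations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_locs(df)
}

#' @rdname read_localizations
#' @param table a localization table.
#' @export
write_localizations <- function(table, path) {
  check_loc_columns(table)
  utils::write.csv(as.data.frame(table)[LOC_COLUMNS], path, row.names = FALSE)
  invisible(path)
}
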