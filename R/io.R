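# Text-based I/O: localisation tables (nm CSV and the Picasso camera-pixel
# convention with a YAML sidecar), event/site/condensate tables, labelled
# masks as TIFF with JSON metadata, and radial profiles as CSV or JSON.

#' Read / write localisation tables (nm units)
#'
#' Plain CSV with columns `frame` (0-based), `x`, `y` (nm) and `precision`
#' (nm). Values round-trip at full double precision.
#'
#' @param locs Localisation tibble.
#' @param path File path.
#' @return `read_locs_csv()` returns the tibble; writers return `path`
#'   invisibly.
#' @export
write_locs_csv <- function(locs, path) {
  readr::write_csv(locs[, intersect(c("frame", "x", "y", "precision"),
                                    names(locs))], path)
  invisible(path)
}

#' @rdname write_locs_csv
#' @export
read_locs_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("frame", "x", "y")
  if (!all(req %in% names(out))) {
    abort(sprintf("malformed localisation file %s: missing column(s) %s",
                  path, paste(setdiff(req, names(out)), collapse = ", ")))
  }
  out
}

#' Localisation tables in the Picasso camera-pixel convention
#'
#' Writes `frame`, `x`, `y` in camera-pixel units with per-axis precisions
#' `lpx`, `lpy`, plus a YAML sidecar (`<path>.yaml`) holding the
#' nm-per-pixel factor and field extent, mirroring the sidecar convention of
#' Picasso-processed localisation files. `read_locs_picasso()` converts back
#' to nm using the sidecar.
#'
#' @param locs Localisation tibble in nm.
#' @param path CSV path; the sidecar is written next to it.
#' @param pixel_size_nm Camera pixel size (default 86 nm).
#' @export
write_locs_picasso <- function(locs, path, pixel_size_nm = 86) {
  prec <- locs$precision %||% rep(NA_real_, nrow(locs))
  readr::write_csv(tibble(frame = locs$frame,
                          x = locs$x / pixel_size_nm,
                          y = locs$y / pixel_size_nm,
                          lpx = prec / pixel_size_nm,
                          lpy = prec / pixel_size_nm), path)
  yaml::write_yaml(list(pixel_size_nm = pixel_size_nm,
                        units = "camera pixels",
                        n_locs = nrow(locs)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_locs_picasso
#' @export
read_locs_picasso <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  px <- meta$pixel_size_nm
  raw <- readr::read_csv(path, show_col_types = FALSE)
  tibble(frame = as.integer(raw$frame), x = raw$x * px, y = raw$y * px,
         precision = raw$lpx * px)
}

#' Write / read a labelled mask as TIFF
#'
#' 16-bit single-page TIFF of region labels plus a JSON sidecar with the
#' pixel size and origin.
#'
#' @param mask A `condensate_mask`.
#' @param path TIFF path; metadata goes to `<path>.json`.
#' @export
write_mask_tiff <- function(mask, path) {
  lab <- mask$labels
  if (max(lab) > 65535) abort("more than 65535 regions")
  # tiff stores [row, col] top-down; transpose so x runs along image width
  tiff::writeTIFF(t(lab[, rev(seq_len(ncol(lab))), drop = FALSE]) / 65535,
                  path, bits.per.sample = 16)
  jsonlite::write_json(list(pixel_size_nm = mask$pixel_size_nm,
                            origin = mask$origin,
                            n_regions = nrow(mask$regions)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  img <- tiff::readTIFF(path)
  lab <- t(img) * 65535
  lab <- lab[, rev(seq_len(ncol(lab))), drop = FALSE]
  new_condensate_mask(matrix(as.integer(round(lab)), nrow(lab)),
                      meta$pixel_size_nm,
                      origin = unlist(meta$origin))
}

#' Write a radial profile
#'
#' CSV columns `r`, `value`, `dispersion`, `n_units`; JSON additionally
#' records the profile kind.
#'
#' @param profile A `radial_profile`.
#' @param path Output path, `.csv` or `.json`.
#' @export
write_profile <- function(profile, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(kind = attr(profile, "kind"),
                              r = profile$r, value = profile$value,
                              dispersion = profile$dispersion,
                              n_units = profile$n_units),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(as_tibble(profile), path)
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (grepl("\\.json$", path)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    new_radial_profile(j$kind, j$r, j$value, j$dispersion, j$n_units)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
    new_radial_profile(NA_character_, df$r, df$value, df$dispersion,
                       df$n_units)
  }
}
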