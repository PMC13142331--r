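# Shared geometry / raster helpers. Coordinates are continuous nm with the
# origin at the lower-left corner of the field of view; frames are 0-based.

#' Define a rectangular field of view
#'
#' @param width_nm,height_nm Extent of the field in nm. Must be positive.
#' @return A `paint_window` object (named list with `width_nm`, `height_nm`).
#' @export
sim_window <- function(width_nm, height_nm = width_nm) {
  stopifnot(is.numeric(width_nm), is.numeric(height_nm))
  if (width_nm <= 0 || height_nm <= 0) {
    abort("window dimensions must be strictly positive (zero-area window)")
  }
  structure(list(width_nm = width_nm, height_nm = height_nm),
            class = "paint_window")
}

window_area_um2 <- function(window) {
  window$width_nm * window$height_nm / 1e6
}

as_window <- function(window) {
  if (inherits(window, "paint_window")) return(window)
  if (is.numeric(window) && length(window) == 2L) {
    return(sim_window(window[[1]], window[[2]]))
  }
  abort("`window` must be a paint_window or a numeric length-2 vector (nm)")
}

# Deterministic sub-seed for a named stage, derived from the master seed.
# Kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483587)
}

#' Bin points into a 2-D count raster
#'
#' Builds a count image over the window with half-open pixels: pixel `i`
#' covers `[origin + (i-1)*px, origin + i*px)`. Points outside the window are
#' dropped (with a message when any are).
#'
#' @param points Data frame with `x`, `y` columns (nm).
#' @param pixel_size_nm Pixel size in nm (> 0).
#' @param window Field of view (see [sim_window()]).
#' @param origin Lower-left corner of the raster in nm.
#' @param quiet Suppress the dropped-points message.
#' @return A `density_image`: list with `counts` (matrix indexed
#'   `[ix, iy]`), `pixel_size_nm`, `origin`, `window`.
#' @export
render_density <- function(points, pixel_size_nm, window, origin = c(0, 0),
                           quiet = FALSE) {
  if (pixel_size_nm <= 0) abort("pixel_size_nm must be > 0")
  window <- as_window(window)
  nx <- ceiling(window$width_nm / pixel_size_nm)
  ny <- ceiling(window$height_nm / pixel_size_nm)
  counts <- matrix(0L, nx, ny)
  if (nrow(points)) {
    ix <- floor((points$x - origin[1]) / pixel_size_nm) + 1L
    iy <- floor((points$y - origin[2]) / pixel_size_nm) + 1L
    ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
    if (any(!ok) && !quiet) {
      inform(sprintf("render_density: dropped %d point(s) outside the window",
                     sum(!ok)))
    }
    if (any(ok)) {
      tab <- table(factor((iy[ok] - 1L) * nx + ix[ok], levels = seq_len(nx * ny)))
      counts <- matrix(as.integer(tab), nx, ny)
    }
  }
  structure(list(counts = counts, pixel_size_nm = pixel_size_nm,
                 origin = origin, window = window),
            class = "density_image")
}

# Pixel-centre coordinates (nm) of a raster.
pixel_centres <- function(img) {
  px <- img$pixel_size_nm
  list(x = img$origin[1] + (seq_len(nrow(img$counts)) - 0.5) * px,
       y = img$origin[2] + (seq_len(ncol(img$counts)) - 0.5) * px)
}

# Raster lookup: matrix of pixel indices for point coordinates; NA outside.
raster_index <- function(x, y, mat, pixel_size_nm, origin = c(0, 0)) {
  ix <- floor((x - origin[1]) / pixel_size_nm) + 1L
  iy <- floor((y - origin[2]) / pixel_size_nm) + 1L
  ok <- ix >= 1L & ix <= nrow(mat) & iy >= 1L & iy <= ncol(mat)
  idx <- rep(NA_integer_, length(x))
  idx[ok] <- (iy[ok] - 1L) * nrow(mat) + ix[ok]
  idx
}

new_radial_profile <- function(kind, r, value, dispersion = NA_real_,
                               n_units = 1L) {
  stopifnot(!is.unsorted(r, strictly = TRUE))
  out <- tibble(r = r, value = value,
                dispersion = rep_len(dispersion, length(r)),
                n_units = rep_len(as.integer(n_units), length(r)))
  class(out) <- c("radial_profile", class(out))
  attr(out, "kind") <- kind
  out
}

#' Locate the first peak or the minimum of a radial profile
#'
#' For `what = "first_max"` returns the radius of the first strict local
#' maximum, optionally excluding the zero-lag bin and requiring the value to
#' exceed `above` (for pair-correlation profiles the clustering peak must
#' exceed the CSR level of 1). For `what = "min"` returns the radius of the
#' global minimum.
#'
#' @param profile A `radial_profile`.
#' @param what `"first_max"` or `"min"`.
#' @param exclude_zero Drop the `r = 0` bin before searching.
#' @param above For `"first_max"`, minimum value a peak must exceed.
#' @return Radius (nm) of the located feature, `NA` if none.
#' @export
profile_peak <- function(profile, what = c("first_max", "min"),
                         exclude_zero = TRUE, above = -Inf) {
  what <- match.arg(what)
  r <- profile$r
  v <- profile$value
  if (exclude_zero) {
    keep <- r > 0
    r <- r[keep]; v <- v[keep]
  }
  if (what == "min") return(r[which.min(v)])
  n <- length(v)
  if (n < 3) return(NA_real_)
  for (i in 2:(n - 1)) {
    if (v[i] > v[i - 1] && v[i] >= v[i + 1] && v[i] > above) return(r[i])
  }
  NA_real_
}
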