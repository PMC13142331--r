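# Condensate segmentation from diffuse-probe binding density, inside/outside
# classification of binding sites, and per-condensate statistics.

new_condensate_mask <- function(labels, pixel_size_nm, origin = c(0, 0)) {
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0]))
  # relabel contiguous from 1
  if (length(ids) && !identical(ids, seq_along(ids))) {
    labels <- matrix(match(labels, ids, nomatch = 0L),
                     nrow(labels), ncol(labels))
    ids <- seq_along(ids)
  }
  px_um2 <- pixel_size_nm^2 / 1e6
  regions <- if (length(ids)) {
    n <- tabulate(labels[labels > 0], nbins = length(ids))
    ix <- (which(labels > 0) - 1L) %% nrow(labels)
    iy <- (which(labels > 0) - 1L) %/% nrow(labels)
    lab <- labels[labels > 0]
    tibble(condensate = ids,
           area_um2 = n * px_um2,
           centroid_x = origin[1] +
             (as.numeric(tapply(ix, lab, mean)) + 0.5) * pixel_size_nm,
           centroid_y = origin[2] +
             (as.numeric(tapply(iy, lab, mean)) + 0.5) * pixel_size_nm)
  } else {
    tibble(condensate = integer(), area_um2 = numeric(),
           centroid_x = numeric(), centroid_y = numeric())
  }
  structure(list(labels = labels, pixel_size_nm = pixel_size_nm,
                 origin = origin, regions = regions),
            class = "condensate_mask")
}

# Ground-truth labelled raster for disc domains (used by the simulator).
disc_mask <- function(domains, window, pixel_size_nm = 10) {
  window <- as_window(window)
  nx <- ceiling(window$width_nm / pixel_size_nm)
  ny <- ceiling(window$height_nm / pixel_size_nm)
  lab <- matrix(0L, nx, ny)
  cx <- (seq_len(nx) - 0.5) * pixel_size_nm
  cy <- (seq_len(ny) - 0.5) * pixel_size_nm
  for (d in seq_len(nrow(domains))) {
    r <- domains$radius[d]
    xr <- which(abs(cx - domains$cx[d]) <= r)
    yr <- which(abs(cy - domains$cy[d]) <= r)
    if (!length(xr) || !length(yr)) next
    sub <- outer(cx[xr] - domains$cx[d], cy[yr] - domains$cy[d],
                 function(a, b) a^2 + b^2) <= r^2
    lab[xr, yr][sub] <- domains$domain[d]
  }
  new_condensate_mask(lab, pixel_size_nm)
}

#' Segment condensates from diffuse binding events
#'
#' Renders the diffuse-event positions at `pixel_size_nm`, smooths with a
#' Gaussian filter, thresholds with Otsu's method computed from the smoothed
#' per-cell image, removes regions below `min_area_um2`, fills holes and
#' labels the remaining regions.
#'
#' @param diffuse_events Tibble with `x`, `y` (nm).
#' @param window Field of view.
#' @param pixel_size_nm Raster pixel (default 10 nm).
#' @param smooth_sigma_px Gaussian smoothing SD in pixels (default 1).
#' @param min_area_um2 Minimum retained region area (default 0.01 um^2).
#' @return A `condensate_mask` (empty, with a warning, when the rendered
#'   image has no dynamic range).
#' @export
segment_condensates <- function(diffuse_events, window, pixel_size_nm = 10,
                                smooth_sigma_px = 1, min_area_um2 = 0.01) {
  window <- as_window(window)
  img <- render_density(diffuse_events, pixel_size_nm, window, quiet = TRUE)
  counts <- img$counts
  if (max(counts) == min(counts)) {
    warn("segment_condensates: image has zero dynamic range; empty mask")
    return(new_condensate_mask(matrix(0L, nrow(counts), ncol(counts)),
                               pixel_size_nm))
  }
  sm <- EBImage::gblur(counts, sigma = smooth_sigma_px)
  smn <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- EBImage::otsu(EBImage::Image(smn), range = c(0, 1))
  bw <- smn > thr
  lab <- EBImage::bwlabel(bw)
  min_px <- ceiling(min_area_um2 * 1e6 / pixel_size_nm^2)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  drop_ids <- which(sizes < min_px)
  if (length(drop_ids)) bw[matrix(lab %in% drop_ids, nrow(bw))] <- FALSE
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  new_condensate_mask(matrix(as.integer(lab), nrow(lab)), pixel_size_nm)
}

#' Classify sites as inside or outside condensates
#'
#' A site is inside iff the pixel under its centroid is labelled; the
#' enclosing condensate id is recorded. Sites off the raster are treated as
#' outside with a warning.
#'
#' @param sites Tibble with `x`, `y` (nm).
#' @param mask A `condensate_mask`.
#' @return The sites tibble with `inside` (logical) and `condensate`
#'   (id, `NA` outside).
#' @export
classify_sites <- function(sites, mask) {
  stopifnot(inherits(mask, "condensate_mask"))
  idx <- raster_index(sites$x, sites$y, mask$labels, mask$pixel_size_nm,
                      mask$origin)
  if (any(is.na(idx)) && nrow(sites)) {
    warn(sprintf("classify_sites: %d site(s) outside the raster; treated as outside",
                 sum(is.na(idx))))
  }
  lab <- rep(0L, nrow(sites))
  lab[!is.na(idx)] <- mask$labels[idx[!is.na(idx)]]
  sites$inside <- lab > 0L
  sites$condensate <- ifelse(lab > 0L, lab, NA_integer_)
  sites
}

#' Cell footprint mask from all binding events
#'
#' Otsu threshold on a coarsely rendered (50 nm pixels), heavily smoothed
#' image of all events; the largest connected component with holes filled
#' defines the cell. Used as the window for whole-cell spatial statistics
#' and for relative radial positions.
#'
#' @param all_events Tibble with `x`, `y` (nm) pooling every channel.
#' @param window Field of view.
#' @param pixel_size_nm Render pixel (default 50 nm).
#' @param smooth_sigma_px Smoothing SD in pixels (default 10).
#' @return A `condensate_mask` with a single region (the cell).
#' @export
cell_mask <- function(all_events, window, pixel_size_nm = 50,
                      smooth_sigma_px = 10) {
  window <- as_window(window)
  img <- render_density(all_events, pixel_size_nm, window, quiet = TRUE)
  sm <- EBImage::gblur(img$counts, sigma = smooth_sigma_px)
  if (max(sm) == min(sm)) {
    warn("cell_mask: image has zero dynamic range; empty mask")
    return(new_condensate_mask(matrix(0L, nrow(sm), ncol(sm)), pixel_size_nm))
  }
  smn <- (sm - min(sm)) / (max(sm) - min(sm))
  bw <- smn > EBImage::otsu(EBImage::Image(smn), range = c(0, 1))
  lab <- EBImage::bwlabel(bw)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    bw <- lab == which.max(sizes)
  }
  bw <- EBImage::fillHull(bw)
  new_condensate_mask(matrix(as.integer(bw), nrow(bw)), pixel_size_nm)
}

# Relative radial position of a point within a cell mask: 1 at the cell
# centroid, 0 on the boundary along the centre-to-point ray.
relative_radial_position <- function(qx, qy, cell) {
  ctr <- c(cell$regions$centroid_x[1], cell$regions$centroid_y[1])
  px <- cell$pixel_size_nm
  inside <- function(x, y) {
    i <- raster_index(x, y, cell$labels, px, cell$origin)
    !is.na(i) && cell$labels[i] > 0
  }
  purrr::map2_dbl(qx, qy, function(x, y) {
    dq <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
    if (dq < px) return(1)
    u <- c(x - ctr[1], y - ctr[2]) / dq
    step <- px / 2
    d <- dq
    while (inside(ctr[1] + (d + step) * u[1], ctr[2] + (d + step) * u[2])) {
      d <- d + step
      if (d > 1e7) break
    }
    max(0, min(1, 1 - dq / d))
  })
}

#' Per-condensate statistics
#'
#' Site counts and densities per species, diffuse-event influx rates, and
#' (when a cell mask is supplied) the relative radial position of each
#' condensate from the cell edge (0) to the centre (1).
#'
#' @param mask A `condensate_mask` from [segment_condensates()] or ground
#'   truth.
#' @param sites Classified site tibble ([classify_sites()]) with a `species`
#'   column (a single species is assumed when absent).
#' @param diffuse_events Optional tibble of diffuse events (`x`, `y`).
#' @param acquisition_time_s Total acquisition time, required for influx.
#' @param cell Optional cell-footprint `condensate_mask`.
#' @return Tibble with one row per condensate: `condensate`, `area_um2`,
#'   `n_<species>` and `density_<species>` columns, `influx_rate` (events/s,
#'   `NA` without diffuse events) and `radial_position`.
#' @export
condensate_stats <- function(mask, sites, diffuse_events = NULL,
                             acquisition_time_s = NULL, cell = NULL) {
  stopifnot(inherits(mask, "condensate_mask"))
  out <- mask$regions
  if (!"species" %in% names(sites)) sites$species <- "A"
  cls <- sites[sites[["inside"]] %||% TRUE, , drop = FALSE]
  if (!"condensate" %in% names(cls)) cls <- classify_sites(cls, mask)
  for (sp in unique(sites$species)) {
    cnt <- table(factor(cls$condensate[cls$species == sp & cls$inside],
                        levels = out$condensate))
    out[[paste0("n_", sp)]] <- as.integer(cnt)
    out[[paste0("density_", sp)]] <- as.integer(cnt) / out$area_um2
  }
  out$influx_rate <- NA_real_
  if (!is.null(diffuse_events) && nrow(out)) {
    if (is.null(acquisition_time_s) || acquisition_time_s <= 0) {
      abort("influx rates need a positive acquisition_time_s")
    }
    idx <- raster_index(diffuse_events$x, diffuse_events$y, mask$labels,
                        mask$pixel_size_nm, mask$origin)
    lab <- mask$labels[idx[!is.na(idx)]]
    cnt <- table(factor(lab[lab > 0], levels = out$condensate))
    out$influx_rate <- as.integer(cnt) / acquisition_time_s
  }
  out$radial_position <- NA_real_
  if (!is.null(cell) && nrow(out)) {
    out$radial_position <- relative_radial_position(out$centroid_x,
                                                    out$centroid_y, cell)
  }
  out
}

#' Linear regression across condensates
#'
#' Ordinary least squares of one per-condensate quantity on another, e.g.
#' site count on area (slope = mean density) or counts of one species on
#' another (slope = stoichiometry).
#'
#' @param records Per-condensate tibble ([condensate_stats()]).
#' @param x_field,y_field Column names.
#' @return Tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
count_area_regression <- function(records, x_field, y_field) {
  if (nrow(records) < 3) abort("need at least 3 condensates")
  x <- records[[x_field]]; y <- records[[y_field]]
  if (sd(x) == 0) abort("degenerate regressor: zero variance")
  fit <- lm(y ~ x)
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared, n = length(x))
}
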