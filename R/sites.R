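# Binding-site identification: event density maps at 5 nm pixels, local
# maxima on a Gaussian-smoothed map, elliptical 2-D Gaussian refinement on
# the raw counts, and event-to-site assignment within a fixed radius.

# Elliptical Gaussian + flat background model for a count sub-window.
fit_gaussian2d <- function(sub, px, x0_nm, y0_nm, origin_nm, precision_nm) {
  nx <- nrow(sub); ny <- ncol(sub)
  gx <- origin_nm[1] + (seq_len(nx) - 0.5) * px
  gy <- origin_nm[2] + (seq_len(ny) - 0.5) * px
  df <- data.frame(z = as.vector(sub),
                   x = rep(gx, times = ny),
                   y = rep(gy, each = nx))
  # widths below precision/3 are not resolvable on the raster (and fail
  # acceptance anyway), so the optimiser is bounded there to avoid collapse
  start <- list(A = max(sub), x0 = x0_nm, y0 = y0_nm,
                sx = precision_nm, sy = precision_nm, bg = 0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ bg + A * exp(-((x - x0)^2 / (2 * sx^2) + (y - y0)^2 / (2 * sy^2))),
      data = df, start = start,
      lower = c(A = 0, x0 = min(gx), y0 = min(gy),
                sx = precision_nm / 3, sy = precision_nm / 3, bg = -1),
      upper = c(A = Inf, x0 = max(gx), y0 = max(gy),
                sx = 10 * precision_nm, sy = 10 * precision_nm, bg = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  as.list(coef(fit))
}

#' Detect binding sites on an event density map
#'
#' Smooths the raster with a Gaussian of SD equal to the localisation
#' precision, finds local maxima with non-maximum suppression over a radius
#' of twice the precision, refines each candidate by fitting an elliptical
#' two-dimensional Gaussian to the raw counts in a window of +/- 3 precisions,
#' and accepts candidates whose amplitude (event count within three
#' precisions of the fitted centroid) is at least `min_events` and whose
#' fitted widths lie in `[precision/3, 2 * precision]` (widths consistent
#' with single sites at the localisation precision).
#' Candidates whose fit does not converge are dropped with a warning.
#'
#' @param img A `density_image` of binding-event positions (see
#'   [render_density()]); the conventional pixel size is 5 nm.
#' @param precision_nm Localisation precision SD in nm.
#' @param min_events Minimum integrated event count to accept a site.
#' @return Tibble of accepted sites: `site`, `x`, `y` (sub-pixel centroid,
#'   nm), `sigma_x`, `sigma_y` (nm), `amplitude` (events), and placeholder
#'   columns `n_events` / `overlapping` filled in by [assign_events()].
#' @export
detect_sites <- function(img, precision_nm, min_events = 5) {
  stopifnot(inherits(img, "density_image"))
  px <- img$pixel_size_nm
  counts <- img$counts
  empty <- tibble(site = integer(), x = numeric(), y = numeric(),
                  sigma_x = numeric(), sigma_y = numeric(),
                  amplitude = numeric(), n_events = integer(),
                  overlapping = logical())
  if (sum(counts) == 0) return(empty)
  sm <- as.matrix(EBImage::gblur(counts, sigma = max(precision_nm / px, 0.5)))
  # candidate floor: a quarter of the expected smoothed peak of a site with
  # min_events events (Gaussian of SD sqrt(2) * precision after smoothing)
  floor_val <- 0.25 * min_events * px^2 / (2 * pi * 2 * precision_nm^2)
  # local maxima: at least as high as every pixel within the suppression
  # radius of 2 * precision (max-filter by shift-and-compare)
  rad <- max(1L, ceiling(2 * precision_nm / px))
  is_max <- sm > floor_val
  nx <- nrow(sm); ny <- ncol(sm)
  shift_ge <- function(dx, dy) {
    sh <- matrix(-1, nx, ny)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    sh[xs, ys] <- sm[xs - dx, ys - dy]
    sm >= sh
  }
  for (dx in -rad:rad) for (dy in -rad:rad) {
    if ((dx != 0 || dy != 0) && dx^2 + dy^2 <= rad^2) {
      if (!any(is_max)) break
      is_max <- is_max & shift_ge(dx, dy)
    }
  }
  cand <- which(is_max)
  if (!length(cand)) return(empty)
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  cx <- (cand - 1L) %% nx + 1L
  cy <- (cand - 1L) %/% nx + 1L
  # greedy suppression of plateau duplicates among equal-valued maxima
  sup2 <- (2 * precision_nm / px)^2
  keep_x <- numeric(0); keep_y <- numeric(0)
  for (i in seq_along(cand)) {
    if (!length(keep_x) ||
        min((keep_x - cx[i])^2 + (keep_y - cy[i])^2) > sup2) {
      keep_x <- c(keep_x, cx[i]); keep_y <- c(keep_y, cy[i])
    }
  }
  half <- ceiling(3 * precision_nm / px)
  n_fail <- 0L
  out <- vector("list", length(keep_x))
  for (i in seq_along(keep_x)) {
    x_lo <- max(1L, keep_x[i] - half); x_hi <- min(nrow(counts), keep_x[i] + half)
    y_lo <- max(1L, keep_y[i] - half); y_hi <- min(ncol(counts), keep_y[i] + half)
    sub <- counts[x_lo:x_hi, y_lo:y_hi, drop = FALSE]
    orig <- c(img$origin[1] + (x_lo - 1) * px, img$origin[2] + (y_lo - 1) * px)
    co <- fit_gaussian2d(sub, px,
                         img$origin[1] + (keep_x[i] - 0.5) * px,
                         img$origin[2] + (keep_y[i] - 0.5) * px,
                         orig, precision_nm)
    if (is.null(co)) { n_fail <- n_fail + 1L; next }
    # amplitude: events within three precisions of the fitted centroid
    # (robust when the event scatter is broader than the fitted core)
    pcx <- orig[1] + (seq_len(nrow(sub)) - 0.5) * px
    pcy <- orig[2] + (seq_len(ncol(sub)) - 0.5) * px
    in_disc <- outer((pcx - co$x0)^2, (pcy - co$y0)^2, "+") <=
      (3 * precision_nm)^2
    amp <- sum(sub[in_disc])
    if (amp >= min_events &&
        co$sx >= precision_nm / 3 && co$sx <= 2 * precision_nm &&
        co$sy >= precision_nm / 3 && co$sy <= 2 * precision_nm) {
      out[[i]] <- tibble(x = co$x0, y = co$y0, sigma_x = co$sx,
                         sigma_y = co$sy, amplitude = amp)
    }
  }
  if (n_fail > 0) {
    warn(sprintf("detect_sites: %d candidate fit(s) did not converge and were dropped",
                 n_fail))
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) return(empty)
  res$site <- seq_len(nrow(res))
  res$n_events <- NA_integer_
  res$overlapping <- NA
  dplyr::relocate(res, "site")
}

#' Assign binding events to sites
#'
#' Each event is assigned to the nearest site centroid within
#' `assign_radius_nm` (45 nm by default, about three localisation
#' precisions), or left unassigned. Sites whose assignment discs intersect
#' (centroid separation below twice the radius) are flagged `overlapping`,
#' since such sites share events and their apparent on-rates are inflated.
#'
#' @param sites Site tibble from [detect_sites()].
#' @param events Event tibble with `x`, `y` (nm), e.g. from [link_events()].
#' @param assign_radius_nm Assignment radius in nm.
#' @return List with `events` (input plus `site` column, `NA` when
#'   unassigned, and `dist_nm`) and `sites` (input with `n_events` and
#'   `overlapping` updated).
#' @export
assign_events <- function(sites, events, assign_radius_nm = 45) {
  if (!nrow(sites)) {
    events$site <- rep(NA_integer_, nrow(events))
    events$dist_nm <- rep(NA_real_, nrow(events))
    return(list(events = events, sites = sites))
  }
  n_ev <- nrow(events)
  site_id <- rep(NA_integer_, n_ev)
  dist_nm <- rep(NA_real_, n_ev)
  if (n_ev) {
    # chunked nearest-site search
    chunk <- max(1L, floor(4e6 / nrow(sites)))
    for (lo in seq(1L, n_ev, by = chunk)) {
      hi <- min(lo + chunk - 1L, n_ev)
      d2 <- outer(events$x[lo:hi], sites$x, "-")^2 +
        outer(events$y[lo:hi], sites$y, "-")^2
      j <- max.col(-d2, ties.method = "first")
      dmin <- sqrt(d2[cbind(seq_len(hi - lo + 1L), j)])
      ok <- dmin <= assign_radius_nm
      site_id[lo:hi][ok] <- sites$site[j[ok]]
      dist_nm[lo:hi] <- dmin
    }
  }
  events$site <- site_id
  events$dist_nm <- dist_nm
  cnt <- table(factor(site_id, levels = sites$site))
  sites$n_events <- as.integer(cnt)
  ov <- rep(FALSE, nrow(sites))
  if (nrow(sites) > 1) {
    d <- as.matrix(dist(cbind(sites$x, sites$y)))
    diag(d) <- Inf
    ov <- apply(d < 2 * assign_radius_nm, 1, any)
  }
  sites$overlapping <- ov
  list(events = events, sites = sites)
}
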