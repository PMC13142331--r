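# Nanoscale spatial statistics on binding-site point patterns:
# FFT pair-/cross-correlation with mask edge normalisation, Ripley's K / L
# with isotropic edge correction on arbitrary raster masks (whole-cell,
# per-condensate pooled, and cross-species), nearest-neighbour distance
# CDFs, and DBSCAN clustering.

# ---- observation windows ---------------------------------------------------

# A window is either a rectangle (paint_window) or a raster mask
# (condensate_mask, labels > 0). Both provide: a vectorised inside test,
# the area (um^2 -> here nm^2), and a bounding extent.
window_geometry <- function(window) {
  if (inherits(window, "paint_window")) {
    w <- window$width_nm; h <- window$height_nm
    list(inside = function(x, y) x >= 0 & x <= w & y >= 0 & y <= h,
         area_nm2 = w * h, extent = c(w, h))
  } else if (inherits(window, "condensate_mask")) {
    lab <- window$labels
    px <- window$pixel_size_nm
    org <- window$origin
    npix <- sum(lab > 0)
    if (npix == 0) abort("empty mask window")
    list(inside = function(x, y) {
      i <- raster_index(x, y, lab, px, org)
      out <- !is.na(i)
      out[out] <- lab[i[out]] > 0L
      out
    },
    area_nm2 = npix * px^2,
    extent = c(nrow(lab), ncol(lab)) * px)
  } else {
    window_geometry(as_window(window))
  }
}

# Isotropic edge-correction weights: fraction of the circle of radius d
# centred at (x, y) lying inside the window, sampled at `n_angles` equally
# spaced points, floored at `w_floor` to bound the variance of 1/w.
iso_weights <- function(x, y, d, inside, n_angles = 72, w_floor = 0.1) {
  frac <- numeric(length(d))
  th <- (seq_len(n_angles) - 0.5) * 2 * pi / n_angles
  for (k in seq_len(n_angles)) {
    frac <- frac + inside(x + d * cos(th[k]), y + d * sin(th[k]))
  }
  pmax(frac / n_angles, w_floor)
}

# Core edge-corrected K: ordered pairs (centre i from `from`, target j from
# `to`); `self` TRUE when from and to are the same pattern (i = j excluded).
ripley_k_core <- function(from, to, geom, r_grid, self, n_angles = 72,
                          w_floor = 0.1) {
  n1 <- nrow(from); n2 <- nrow(to)
  r_max <- max(r_grid)
  dx <- outer(from$x, to$x, "-")
  dy <- outer(from$y, to$y, "-")
  d <- sqrt(dx^2 + dy^2)
  if (self) diag(d) <- Inf
  sel <- which(d <= r_max)
  K <- numeric(length(r_grid))
  denom <- if (self) n1 * (n1 - 1) else n1 * n2
  if (length(sel)) {
    i <- (sel - 1L) %% n1 + 1L
    dd <- d[sel]
    w <- iso_weights(from$x[i], from$y[i], dd, geom$inside, n_angles, w_floor)
    ord <- order(dd)
    dd <- dd[ord]; invw <- 1 / w[ord]
    cum <- cumsum(invw)
    pos <- findInterval(r_grid, dd)
    K <- ifelse(pos > 0, cum[pmax(pos, 1L)], 0)
    K[pos == 0] <- 0
  }
  geom$area_nm2 * K / denom
}

check_r_grid <- function(r_grid, geom) {
  r_lim <- min(geom$extent) / 2
  if (max(r_grid) > r_lim) {
    warn(sprintf("r grid truncated at half the window extent (%.0f nm)", r_lim))
    r_grid <- r_grid[r_grid <= r_lim]
  }
  if (!length(r_grid)) abort("empty r grid after truncation")
  r_grid
}

#' Ripley's L function with isotropic edge correction
#'
#' Computes `K(r) = (A / (n (n - 1))) * sum over ordered pairs of
#' 1/w_ij * 1(d_ij <= r)` where `w_ij` is the fraction of the circle of
#' radius `d_ij` centred on point i lying inside the window, then the
#' variance-stabilised `L(r) = sqrt(K(r) / pi)`, returned as
#' `L(r) - r` (`L_CSR(r) = r`): positive values indicate clustering at
#' scale `r`, negative values dispersion.
#'
#' @param points Tibble with `x`, `y` (nm), at least 5 points.
#' @param window A [sim_window()] rectangle or a `condensate_mask` raster.
#' @param r_grid Radii (nm, ascending); truncated with a warning beyond half
#'   the window extent.
#' @param n_angles Circle sample points for the edge weights.
#' @param w_floor Lower bound on the edge weight.
#' @return A `radial_profile` (kind `L_minus_LCSR`).
#' @export
ripley_l <- function(points, window, r_grid = seq(10, 1000, by = 10),
                     n_angles = 72, w_floor = 0.1) {
  if (nrow(points) < 5) abort("need at least 5 points")
  geom <- window_geometry(window)
  r_grid <- check_r_grid(r_grid, geom)
  K <- ripley_k_core(points, points, geom, r_grid, self = TRUE,
                     n_angles = n_angles, w_floor = w_floor)
  new_radial_profile("L_minus_LCSR", r_grid, sqrt(K / pi) - r_grid)
}

# Crop a single region of a labelled mask to its bounding box.
region_mask <- function(mask, id) {
  sel <- mask$labels == id
  ix <- which(rowSums(sel) > 0)
  iy <- which(colSums(sel) > 0)
  lab <- matrix(0L, length(ix), length(iy))
  lab[sel[ix, iy, drop = FALSE]] <- 1L
  new_condensate_mask(lab, mask$pixel_size_nm,
                      origin = mask$origin +
                        c(ix[1] - 1, iy[1] - 1) * mask$pixel_size_nm)
}

pool_profiles <- function(kind, r_grid, curves) {
  m <- do.call(cbind, curves)
  n <- ncol(m)
  new_radial_profile(kind, r_grid, rowMeans(m),
                     dispersion = 1.96 * apply(m, 1, sd) / sqrt(n),
                     n_units = n)
}

#' Condensate-restricted pooled Ripley's L
#'
#' Computes [ripley_l()] separately inside each condensate region, with the
#' region's own raster as the window and its own point count and area in the
#' normalisation (so large-scale clustering of the condensates themselves
#' does not masquerade as nanoscale structure), and pools the curves as the
#' unweighted mean across regions with a 95% CI (1.96 SEM).
#'
#' @param points Tibble with `x`, `y` (nm).
#' @param mask A `condensate_mask` (segmented or ground truth).
#' @param r_grid Radii (nm).
#' @param min_points_per_region Regions with fewer points are skipped.
#' @param ... Passed to [ripley_l()].
#' @return A `radial_profile` pooled across condensates.
#' @export
ripley_l_masked <- function(points, mask, r_grid = seq(5, 300, by = 5),
                            min_points_per_region = 5, ...) {
  cls <- classify_sites(points, mask)
  ids <- mask$regions$condensate
  curves <- list()
  for (id in ids) {
    pts <- cls[!is.na(cls$condensate) & cls$condensate == id, ]
    if (nrow(pts) < min_points_per_region) next
    rm <- region_mask(mask, id)
    prof <- suppressWarnings(ripley_l(pts, rm, r_grid, ...))
    if (nrow(prof) == length(r_grid)) curves[[length(curves) + 1]] <- prof$value
  }
  if (!length(curves)) abort("no condensate with enough points")
  pool_profiles("L_minus_LCSR", r_grid, curves)
}

#' Cross-species Ripley's L
#'
#' `K_AB(r) = (A / (n_A n_B)) * sum_{i in A, j in B} 1/w_ij * 1(d_ij <= r)`
#' with circles centred on the A points, returned as `L_AB(r) - r`, the
#' deviation from independent processes with matched densities.
#'
#' @param points_a,points_b Tibbles with `x`, `y` (nm), each at least 5 rows.
#' @param window Rectangle or raster mask.
#' @param r_grid Radii (nm).
#' @inheritParams ripley_l
#' @return A `radial_profile` (kind `crossL_minus_LCSR`).
#' @export
cross_ripley <- function(points_a, points_b, window,
                         r_grid = seq(5, 300, by = 5),
                         n_angles = 72, w_floor = 0.1) {
  if (nrow(points_a) < 5 || nrow(points_b) < 5) {
    abort("need at least 5 points in each species")
  }
  geom <- window_geometry(window)
  r_grid <- check_r_grid(r_grid, geom)
  K <- ripley_k_core(points_a, points_b, geom, r_grid, self = FALSE,
                     n_angles = n_angles, w_floor = w_floor)
  new_radial_profile("crossL_minus_LCSR", r_grid, sqrt(K / pi) - r_grid)
}

#' Condensate-restricted pooled cross-species L
#'
#' Per-condensate [cross_ripley()] with each region's own raster, counts and
#' area, pooled as the unweighted mean across regions holding at least
#' `min_points_per_region` points of both species.
#'
#' @inheritParams cross_ripley
#' @param mask A `condensate_mask`.
#' @param min_points_per_region Minimum points of each species per region.
#' @return A pooled `radial_profile` (kind `crossL_minus_LCSR`).
#' @export
cross_ripley_masked <- function(points_a, points_b, mask,
                                r_grid = seq(5, 300, by = 5),
                                min_points_per_region = 5, ...) {
  ca <- classify_sites(points_a, mask)
  cb <- classify_sites(points_b, mask)
  curves <- list()
  for (id in mask$regions$condensate) {
    pa <- ca[!is.na(ca$condensate) & ca$condensate == id, ]
    pb <- cb[!is.na(cb$condensate) & cb$condensate == id, ]
    if (nrow(pa) < min_points_per_region ||
        nrow(pb) < min_points_per_region) next
    rm <- region_mask(mask, id)
    prof <- suppressWarnings(cross_ripley(pa, pb, rm, r_grid, ...))
    if (nrow(prof) == length(r_grid)) curves[[length(curves) + 1]] <- prof$value
  }
  if (!length(curves)) abort("no condensate with enough points of both species")
  pool_profiles("crossL_minus_LCSR", r_grid, curves)
}

# ---- FFT pair correlation --------------------------------------------------

fft_xcorr <- function(a, b) {
  p1 <- stats::nextn(2 * nrow(a), c(2, 3, 5))
  p2 <- stats::nextn(2 * ncol(a), c(2, 3, 5))
  pa <- matrix(0, p1, p2); pa[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  pb <- matrix(0, p1, p2); pb[seq_len(nrow(b)), seq_len(ncol(b))] <- b
  Re(fft(fft(pa) * Conj(fft(pb)), inverse = TRUE)) / (p1 * p2)
}

#' FFT pair-correlation of binding-site patterns
#'
#' Bins each species into a raster over the window, computes the
#' two-dimensional correlation by zero-padded FFT, divides by the FFT
#' autocorrelation of the window mask (finite-window edge normalisation),
#' normalises by the species densities so complete spatial randomness gives
#' 1, and radially averages into bins of one pixel width. For
#' autocorrelation the self-pair contribution is removed from the zero-lag
#' bin and the reported `r = 0` value is pinned to 1, the zero-shift
#' reference; peak searches should ignore that bin. For cross-correlation no
#' self term exists and the `r = 0` bin is the computed value.
#'
#' @param points_a Tibble with `x`, `y` (nm).
#' @param points_b Optional second species; `NULL` for autocorrelation.
#' @param window A [sim_window()] rectangle or a `condensate_mask` (the
#'   mask's own pixel size then applies).
#' @param pixel_size_nm Raster pixel (default 10 nm).
#' @param r_max Largest radius (nm) reported.
#' @return A `radial_profile` (kind `autocorr` or `crosscorr`).
#' @export
pair_correlation <- function(points_a, points_b = NULL, window,
                             pixel_size_nm = 10, r_max = 500) {
  auto <- is.null(points_b)
  if (nrow(points_a) < 10 || (!auto && nrow(points_b) < 10)) {
    abort("insufficient points (need >= 10 per species)")
  }
  if (inherits(window, "condensate_mask")) {
    W <- (window$labels > 0) * 1
    px <- window$pixel_size_nm
    org <- window$origin
    win <- sim_window(nrow(W) * px, ncol(W) * px)
  } else {
    win <- as_window(window)
    px <- pixel_size_nm
    org <- c(0, 0)
    W <- matrix(1, ceiling(win$width_nm / px), ceiling(win$height_nm / px))
  }
  bin <- function(p) {
    img <- render_density(tibble(x = p$x - org[1], y = p$y - org[2]),
                          px, win, quiet = TRUE)
    img$counts * (W > 0)
  }
  A <- bin(points_a)
  B <- if (auto) A else bin(points_b)
  nA <- sum(A); nB <- sum(B)
  npixW <- sum(W)
  S <- fft_xcorr(A, B)
  NW <- fft_xcorr(W, W)
  if (auto) S[1, 1] <- S[1, 1] - nA  # remove self pairs at zero lag
  p1 <- nrow(S); p2 <- ncol(S)
  dx <- c(0:(p1 %/% 2), -((p1 - p1 %/% 2 - 1):1))
  dy <- c(0:(p2 %/% 2), -((p2 - p2 %/% 2 - 1):1))
  rlag <- sqrt(outer(dx^2, dy^2, "+")) * px
  keep <- NW > 0.5 & rlag <= r_max + px / 2
  bin_id <- as.integer(round(rlag[keep] / px))
  s_sum <- tapply(S[keep], bin_id, sum)
  w_sum <- tapply(NW[keep], bin_id, sum)
  lam2 <- (nA / npixW) * (nB / npixW)
  r_bins <- as.numeric(names(s_sum)) * px
  val <- as.numeric(s_sum / w_sum) / lam2
  ord <- order(r_bins)
  r_bins <- r_bins[ord]; val <- val[ord]
  if (auto && length(r_bins) && r_bins[1] == 0) val[1] <- 1
  new_radial_profile(if (auto) "autocorr" else "crosscorr", r_bins, val)
}

# ---- nearest neighbours ----------------------------------------------------

# Nearest-neighbour distances from each point of `a` to `b`
# (self excluded when `self` is TRUE), computed in chunks.
nn_dist <- function(a, b, self) {
  n <- nrow(a)
  out <- numeric(n)
  chunk <- max(1L, floor(4e6 / max(nrow(b), 1L)))
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    d2 <- outer(a$x[lo:hi], b$x, "-")^2 + outer(a$y[lo:hi], b$y, "-")^2
    if (self) d2[cbind(seq_len(hi - lo + 1L), lo:hi)] <- Inf
    out[lo:hi] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Nearest-neighbour distance CDF
#'
#' Empirical cumulative distribution of the distance from each point of
#' species A to its nearest neighbour in species B (homotypic when
#' `points_b` is `NULL`; the self distance is then excluded).
#'
#' @param points_a Tibble with `x`, `y` (nm).
#' @param points_b Optional second species.
#' @param r_grid Radii (nm) at which the CDF is evaluated.
#' @return A `radial_profile` (kind `nn_cdf`), monotone within `[0, 1]`.
#' @export
nn_cdf <- function(points_a, points_b = NULL, r_grid = seq(0, 500, by = 5)) {
  self <- is.null(points_b)
  if (self && nrow(points_a) < 2) abort("homotypic CDF needs >= 2 points")
  if (!self && !nrow(points_b)) abort("empty target species")
  d <- nn_dist(points_a, if (self) points_a else points_b, self)
  new_radial_profile("nn_cdf", r_grid, ecdf(d)(r_grid),
                     n_units = nrow(points_a))
}

# ---- DBSCAN ----------------------------------------------------------------

#' DBSCAN clustering of binding sites
#'
#' Standard density-based clustering: a point is a core point when at least
#' `min_pts` points (itself included) lie within `eps_nm`; clusters grow
#' from core points, border points join the first reachable cluster, and
#' the rest are noise. Cluster areas are convex hulls of member points.
#'
#' @param points Tibble with `x`, `y` (nm).
#' @param eps_nm Search radius (default 200 nm).
#' @param min_pts Minimum points per cluster (default 3).
#' @return List with `points` (input plus `cluster`, `NA` = noise) and
#'   `clusters` (per cluster: `cluster`, `n_points`, `area_um2`,
#'   `centroid_x`, `centroid_y`).
#' @export
dbscan_clusters <- function(points, eps_nm = 200, min_pts = 3) {
  n <- nrow(points)
  if (n < 1) abort("need at least 1 point")
  d2 <- outer(points$x, points$x, "-")^2 + outer(points$y, points$y, "-")^2
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps_nm^2))
  core <- vapply(nb, length, 1L) >= min_pts
  lab <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(lab[i]) || !core[i]) next
    cl <- cl + 1L
    queue <- i
    lab[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (core[j]) {
        newly <- nb[[j]][is.na(lab[nb[[j]]])]
        lab[newly] <- cl
        queue <- c(queue, newly[core[newly]])
      }
    }
  }
  points$cluster <- lab
  hull_area <- function(px, py) {
    if (length(px) < 3) return(0)
    h <- grDevices::chull(px, py)
    xs <- px[h]; ys <- py[h]
    abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2 / 1e6
  }
  clusters <- if (cl > 0) {
    purrr::map_dfr(seq_len(cl), function(k) {
      m <- which(lab == k)
      tibble(cluster = k, n_points = length(m),
             area_um2 = hull_area(points$x[m], points$y[m]),
             centroid_x = mean(points$x[m]), centroid_y = mean(points$y[m]))
    })
  } else {
    tibble(cluster = integer(), n_points = integer(), area_um2 = numeric(),
           centroid_x = numeric(), centroid_y = numeric())
  }
  list(points = points, clusters = clusters)
}
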