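# Synthetic PAINT data generation: structured spatial point processes for
# binding-site positions, exponential on/off binding traces, and the forward
# measurement model that turns bound intervals into per-frame localisations.

#' Movie acquisition parameters
#'
#' @param exposure_s Frame exposure time in seconds (default 0.05, i.e. 50 ms).
#' @param n_frames Number of frames acquired.
#' @param probe_conc_uM Probe concentration in micromolar (cell imaging is
#'   typically 0.001, in-vitro up to 0.01).
#' @return A named list of class `movie_params`.
#' @export
movie_params <- function(exposure_s = 0.05, n_frames, probe_conc_uM) {
  stopifnot(exposure_s > 0, n_frames >= 1)
  if (probe_conc_uM <= 0) abort("probe concentration must be positive")
  structure(list(exposure_s = exposure_s, n_frames = as.integer(n_frames),
                 probe_conc_uM = probe_conc_uM),
            class = "movie_params")
}

#' Configuration for a synthetic PAINT experiment
#'
#' Bundles the spatial generator, per-site binding kinetics, movie and noise
#' parameters, and a master seed. The same configuration (including seed)
#' always produces bit-identical output; per-stage random streams are derived
#' deterministically from the master seed.
#'
#' @param window Field of view, see [sim_window()].
#' @param generator One of `"csr"`, `"hardcore"`, `"lattice"`,
#'   `"condensate_field"`, `"interleaved"`.
#' @param density_um2 Site density in sites per square micron. For
#'   `condensate_field` a (possibly named) vector gives one species per
#'   element; inside-domain density.
#' @param hardcore_nm Minimum pairwise distance (nm) for hard-core placement;
#'   vectorised alongside `density_um2`.
#' @param lattice_spacing_nm,lattice_jitter_nm Triangular lattice spacing and
#'   isotropic Gaussian jitter SD (nm).
#' @param n_condensates,condensate_radius_nm Number and disc radius of
#'   condensate domains; a length-2 radius is a uniform range sampled per
#'   domain.
#' @param background_density_um2 Site density outside domains
#'   (`condensate_field` only).
#' @param shell_radius_nm,shell_sd_nm,cross_exclusion_nm Interleaved
#'   generator: species B is placed at a radial distance ~
#'   Normal(`shell_radius_nm`, `shell_sd_nm`) from a species-A site, subject
#'   to a minimum distance `cross_exclusion_nm` from every A site.
#' @param b_per_a Mean number of B sites per A site (interleaved).
#' @param k_on Per-binding-site association rate, uM^-1 s^-1.
#' @param k_off Dissociation rate, s^-1. Optionally a second component via
#'   `koff2`/`koff_frac` (fraction of events drawn from `k_off`).
#' @param koff2,koff_frac Optional second dissociation component.
#' @param valence Number of co-located binding sites (ITAMs) per site;
#'   modelled as single occupancy with aggregate on-rate `valence * k_on * c`.
#' @param movie A [movie_params()] object.
#' @param precision_nm Localisation precision SD (nm), typically 10-15.
#' @param diffuse_rate_um2_s Rate of diffuse (single-frame, low-affinity)
#'   binding events inside condensate domains, per square micron per second.
#' @param mask_pixel_nm Pixel size of the ground-truth domain raster.
#' @param seed Master seed (integer).
#' @return A `sim_config` list.
#' @export
sim_config <- function(window, generator = c("csr", "hardcore", "lattice",
                                             "condensate_field", "interleaved"),
                       density_um2 = 100, hardcore_nm = 40,
                       lattice_spacing_nm = 70, lattice_jitter_nm = 10,
                       n_condensates = 50, condensate_radius_nm = 300,
                       background_density_um2 = 0,
                       shell_radius_nm = 100, shell_sd_nm = 5,
                       cross_exclusion_nm = 15, b_per_a = 4,
                       k_on = 1, k_off = 1, koff2 = NULL, koff_frac = 1,
                       valence = 1L,
                       movie = movie_params(n_frames = 2000,
                                            probe_conc_uM = 0.01),
                       precision_nm = 10, diffuse_rate_um2_s = 0,
                       mask_pixel_nm = 10, seed = 1L) {
  generator <- match.arg(generator)
  window <- as_window(window)
  chk_pos <- function(x, nm) {
    if (any(!is.finite(x)) || any(x <= 0)) {
      abort(sprintf("`%s` must be strictly positive", nm))
    }
  }
  chk_pos(k_on, "k_on"); chk_pos(k_off, "k_off")
  chk_pos(precision_nm, "precision_nm")
  if (any(density_um2 < 0)) abort("`density_um2` must be non-negative")
  if (any(valence < 1)) abort("`valence` must be >= 1")
  if (!inherits(movie, "movie_params")) abort("`movie` must be movie_params()")
  structure(list(window = window, generator = generator,
                 density_um2 = density_um2, hardcore_nm = hardcore_nm,
                 lattice_spacing_nm = lattice_spacing_nm,
                 lattice_jitter_nm = lattice_jitter_nm,
                 n_condensates = n_condensates,
                 condensate_radius_nm = condensate_radius_nm,
                 background_density_um2 = background_density_um2,
                 shell_radius_nm = shell_radius_nm, shell_sd_nm = shell_sd_nm,
                 cross_exclusion_nm = cross_exclusion_nm, b_per_a = b_per_a,
                 k_on = k_on, k_off = k_off, koff2 = koff2,
                 koff_frac = koff_frac, valence = as.integer(valence),
                 movie = movie, precision_nm = precision_nm,
                 diffuse_rate_um2_s = diffuse_rate_um2_s,
                 mask_pixel_nm = mask_pixel_nm, seed = as.integer(seed)),
            class = "sim_config")
}

# -- spatial generators ------------------------------------------------------

csr_points <- function(density_um2, window) {
  n <- rpois(1, density_um2 * window_area_um2(window))
  tibble(x = runif(n, 0, window$width_nm), y = runif(n, 0, window$height_nm))
}

# Dart-throwing hard core: candidates are accepted if at least `hc` nm from
# every previously accepted point. Approximate Matern II; a retry cap keeps
# the loop bounded, and densities above the triangular packing bound fail
# up front with the achievable maximum.
dart_hardcore <- function(n_target, hc, sampler, max_attempts = 1e6) {
  if (n_target == 0) return(tibble(x = numeric(), y = numeric()))
  acc <- matrix(NA_real_, n_target, 2)
  n_acc <- 0L
  attempts <- 0L
  batch <- max(64L, n_target)
  while (n_acc < n_target && attempts < max_attempts) {
    cand <- sampler(batch)
    attempts <- attempts + batch
    for (i in seq_len(nrow(cand))) {
      if (n_acc >= n_target) break
      if (n_acc == 0L ||
          min((acc[seq_len(n_acc), 1] - cand[i, 1])^2 +
              (acc[seq_len(n_acc), 2] - cand[i, 2])^2) >= hc^2) {
        n_acc <- n_acc + 1L
        acc[n_acc, ] <- cand[i, ]
      }
    }
  }
  if (n_acc < n_target) {
    abort(sprintf(paste0("hard-core placement failed: %d of %d points placed ",
                         "after %g attempts; the achievable bound for this ",
                         "window is about %d points"),
                  n_acc, n_target, max_attempts, n_acc))
  }
  tibble(x = acc[, 1], y = acc[, 2])
}

hardcore_points <- function(density_um2, hc, window) {
  area <- window_area_um2(window)
  n_target <- rpois(1, density_um2 * area)
  n_max <- floor(area * 1e6 / (sqrt(3) / 2 * hc^2))
  if (n_target > n_max) {
    abort(sprintf(paste0("requested hard-core density (%g / um^2) exceeds the ",
                         "packing bound for this window: at most %d points ",
                         "fit at a %g nm hard-core distance"),
                  density_um2, n_max, hc))
  }
  dart_hardcore(n_target, hc, function(k) {
    cbind(runif(k, 0, window$width_nm), runif(k, 0, window$height_nm))
  })
}

lattice_points <- function(spacing, jitter_sd, window) {
  dy <- spacing * sqrt(3) / 2
  rows <- seq(dy / 2, window$height_nm - 1e-9, by = dy)
  pts <- purrr::map_dfr(seq_along(rows), function(i) {
    off <- if (i %% 2 == 0) spacing / 2 else 0
    xs <- seq(spacing / 2 + off, window$width_nm - 1e-9, by = spacing)
    tibble(x = xs, y = rows[i])
  })
  pts$x <- pts$x + rnorm(nrow(pts), 0, jitter_sd)
  pts$y <- pts$y + rnorm(nrow(pts), 0, jitter_sd)
  dplyr::filter(pts, .data$x >= 0, .data$x < window$width_nm,
                .data$y >= 0, .data$y < window$height_nm)
}

# Non-overlapping disc domain centres; `radius` may be a scalar or a
# c(min, max) range sampled uniformly per domain.
place_domains <- function(n, radius, window, gap_nm = 100) {
  r_max <- max(radius)
  if (2 * r_max >= min(window$width_nm, window$height_nm)) {
    abort("condensate radius too large for the window")
  }
  radii <- if (length(radius) == 2) runif(n, radius[1], radius[2])
    else rep_len(radius, n)
  ctr <- dart_hardcore(n, 2 * r_max + gap_nm, function(k) {
    cbind(runif(k, r_max, window$width_nm - r_max),
          runif(k, r_max, window$height_nm - r_max))
  })
  tibble(domain = seq_len(n), cx = ctr$x, cy = ctr$y, radius = radii)
}

disc_sampler <- function(cx, cy, radius) {
  function(k) {
    r <- radius * sqrt(runif(k))
    th <- runif(k, 0, 2 * pi)
    cbind(cx + r * cos(th), cy + r * sin(th))
  }
}

hardcore_in_disc <- function(density_um2, hc, cx, cy, radius) {
  area_um2 <- pi * radius^2 / 1e6
  n_target <- rpois(1, density_um2 * area_um2)
  n_max <- floor(area_um2 * 1e6 / (sqrt(3) / 2 * hc^2))
  if (n_target > n_max) {
    abort(sprintf("hard-core density %g / um^2 exceeds the in-disc packing bound (%d points)",
                  density_um2, n_max))
  }
  dart_hardcore(n_target, hc, disc_sampler(cx, cy, radius))
}

condensate_field_points <- function(cfg, domains, species, density, hc) {
  pts <- purrr::map_dfr(seq_len(nrow(domains)), function(d) {
    p <- hardcore_in_disc(density, hc, domains$cx[d], domains$cy[d],
                          domains$radius[d])
    if (!nrow(p)) return(NULL)
    p$domain <- domains$domain[d]
    p
  })
  if (cfg$background_density_um2 > 0) {
    bg <- csr_points(cfg$background_density_um2, cfg$window)
    keep <- rep(TRUE, nrow(bg))
    for (d in seq_len(nrow(domains))) {
      keep <- keep & ((bg$x - domains$cx[d])^2 + (bg$y - domains$cy[d])^2 >
                        domains$radius[d]^2)
    }
    bg <- bg[keep, , drop = FALSE]
    bg$domain <- NA_integer_
    pts <- dplyr::bind_rows(pts, bg)
  }
  pts$species <- species
  pts
}

# Species B in a tight radial shell around species-A sites, with a hard
# minimum distance to every A site.
shell_points <- function(a_pts, cfg, domains) {
  out <- vector("list", nrow(a_pts))
  for (i in seq_len(nrow(a_pts))) {
    nb <- rpois(1, cfg$b_per_a)
    if (nb == 0) next
    got <- matrix(NA_real_, nb, 2)
    n_got <- 0L
    tries <- 0L
    dom <- a_pts$domain[i]
    while (n_got < nb && tries < 200L) {
      tries <- tries + 1L
      r <- rnorm(1, cfg$shell_radius_nm, cfg$shell_sd_nm)
      th <- runif(1, 0, 2 * pi)
      bx <- a_pts$x[i] + r * cos(th)
      by <- a_pts$y[i] + r * sin(th)
      if (!is.na(dom)) {
        d <- which(domains$domain == dom)
        if ((bx - domains$cx[d])^2 + (by - domains$cy[d])^2 >
            domains$radius[d]^2) next
      }
      if (min((a_pts$x - bx)^2 + (a_pts$y - by)^2) < cfg$cross_exclusion_nm^2) next
      n_got <- n_got + 1L
      got[n_got, ] <- c(bx, by)
    }
    if (n_got > 0) {
      out[[i]] <- tibble(x = got[seq_len(n_got), 1], y = got[seq_len(n_got), 2],
                         domain = dom)
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) res <- tibble(x = numeric(), y = numeric(),
                                domain = integer())
  res$species <- "B"
  res
}

#' Generate binding-site positions
#'
#' Draws site positions from the spatial process named in the configuration:
#' complete spatial randomness (`csr`), dart-throwing hard core (`hardcore`),
#' jittered triangular lattice (`lattice`), hard-core sites inside disc
#' condensate domains (`condensate_field`, one species per element of
#' `density_um2`), or a two-species interleaved pattern in which species B
#' sits in a tight shell around species-A sites (`interleaved`).
#'
#' @param config A [sim_config()].
#' @return List with `points` (tibble: `site_id`, `species`, `x`, `y`,
#'   `domain`), `domains` (disc table or `NULL`) and `mask` (ground-truth
#'   [condensate_mask] raster or `NULL`).
#' @export
gen_points <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, "points"), {
    domains <- NULL
    mask <- NULL
    if (config$generator == "csr") {
      pts <- csr_points(config$density_um2[[1]], config$window)
      pts$species <- "A"; pts$domain <- NA_integer_
    } else if (config$generator == "hardcore") {
      pts <- hardcore_points(config$density_um2[[1]], config$hardcore_nm[[1]],
                             config$window)
      pts$species <- "A"; pts$domain <- NA_integer_
    } else if (config$generator == "lattice") {
      pts <- lattice_points(config$lattice_spacing_nm,
                            config$lattice_jitter_nm, config$window)
      pts$species <- "A"; pts$domain <- NA_integer_
    } else if (config$generator == "condensate_field") {
      domains <- place_domains(config$n_condensates,
                               config$condensate_radius_nm, config$window)
      dens <- config$density_um2
      hc <- rep_len(config$hardcore_nm, length(dens))
      sp_names <- names(dens) %||% LETTERS[seq_along(dens)]
      pts <- purrr::map_dfr(seq_along(dens), function(k) {
        condensate_field_points(config, domains, sp_names[k], dens[[k]],
                                hc[[k]])
      })
    } else { # interleaved
      domains <- place_domains(config$n_condensates,
                               config$condensate_radius_nm, config$window)
      a <- condensate_field_points(config, domains, "A",
                                   config$density_um2[[1]],
                                   config$hardcore_nm[[1]])
      b <- shell_points(a, config, domains)
      pts <- dplyr::bind_rows(a, b)
    }
    if (!is.null(domains)) {
      mask <- disc_mask(domains, config$window, config$mask_pixel_nm)
    }
    pts <- dplyr::select(pts, "species", "x", "y", "domain")
    pts$site_id <- seq_len(nrow(pts))
    list(points = dplyr::relocate(pts, "site_id"), domains = domains,
         mask = mask)
  })
}

# -- kinetics ----------------------------------------------------------------

#' Simulate binding traces at sites
#'
#' Alternating-renewal simulation per site: dark intervals are
#' Exponential(valence * k_on * c) and bound intervals Exponential(k_off)
#' (optionally a two-component mixture), over the movie span. Events
#' extending past either movie boundary are clipped and flagged censored.
#'
#' @param sites Tibble with `site_id` and per-site kinetic columns `k_on`
#'   (uM^-1 s^-1), `k_off` (s^-1), `valence`; optional `koff2`, `koff_frac`.
#' @param movie A [movie_params()].
#' @param seed Integer seed.
#' @return Tibble: `site_id`, `start_s`, `duration_s`, `censored_start`,
#'   `censored_end`.
#' @export
simulate_traces <- function(sites, movie, seed = 1L) {
  stopifnot(inherits(movie, "movie_params"))
  c_uM <- movie$probe_conc_uM
  if (c_uM <= 0) abort("probe concentration must be positive (k_on undefined)")
  t_end <- movie$n_frames * movie$exposure_s
  if (!all(c("k_on", "k_off") %in% names(sites))) {
    abort("`sites` needs k_on and k_off columns")
  }
  valence <- sites[["valence"]] %||% rep(1L, nrow(sites))
  koff2 <- sites[["koff2"]] %||% rep(NA_real_, nrow(sites))
  koff_frac <- sites[["koff_frac"]] %||% rep(1, nrow(sites))
  rate_dark <- valence * sites$k_on * c_uM
  if (any(!is.finite(rate_dark) | rate_dark <= 0) ||
      any(!is.finite(sites$k_off) | sites$k_off <= 0)) {
    abort("all on/off rates must be finite and positive")
  }
  withr::with_seed(seed, {
    out <- vector("list", nrow(sites))
    for (i in seq_len(nrow(sites))) {
      # expected cycle length bounds the event count; draw in blocks
      n_exp <- ceiling(t_end / (1 / rate_dark[i] + 1 / sites$k_off[i])) + 10
      starts <- numeric(0); durs <- numeric(0)
      t <- 0
      repeat {
        gaps <- rexp(n_exp, rate_dark[i])
        bnds <- if (is.na(koff2[i])) {
          rexp(n_exp, sites$k_off[i])
        } else {
          pick <- runif(n_exp) < koff_frac[i]
          ifelse(pick, rexp(n_exp, sites$k_off[i]), rexp(n_exp, koff2[i]))
        }
        s <- t + cumsum(gaps + c(0, head(bnds, -1))) # start times of events
        starts <- c(starts, s); durs <- c(durs, bnds)
        t <- s[length(s)] + bnds[length(bnds)]
        if (t >= t_end) break
      }
      keep <- starts < t_end
      starts <- starts[keep]; durs <- durs[keep]
      ends <- starts + durs
      cs <- starts < 0
      ce <- ends > t_end
      starts[cs] <- 0
      ends[ce] <- t_end
      out[[i]] <- tibble(site_id = sites$site_id[i], start_s = starts,
                         duration_s = ends - starts,
                         censored_start = cs, censored_end = ce)
    }
    dplyr::bind_rows(out)
  })
}

#' Render localisations from binding traces
#'
#' Forward measurement model: an event contributes one localisation to every
#' frame whose exposure it covers for more than half of the frame; the
#' localisation is the site position plus isotropic Gaussian noise with SD
#' equal to the localisation precision.
#'
#' @param traces Output of [simulate_traces()].
#' @param sites Tibble with `site_id`, `x`, `y` (nm).
#' @param precision_nm Localisation precision SD (> 0).
#' @param movie A [movie_params()].
#' @param seed Integer seed.
#' @return Localisation tibble: `frame` (0-based), `x`, `y`, `precision`,
#'   plus ground-truth `site_id` and `event_id`.
#' @export
render_localisations <- function(traces, sites, precision_nm, movie,
                                 seed = 1L) {
  if (precision_nm <= 0) abort("precision must be > 0")
  e <- movie$exposure_s
  if (!nrow(traces)) {
    return(tibble(frame = integer(), x = numeric(), y = numeric(),
                  precision = numeric(), site_id = integer(),
                  event_id = integer()))
  }
  start <- traces$start_s
  end <- traces$start_s + traces$duration_s
  f0 <- floor(start / e + 1e-12)
  f1 <- ceiling(end / e - 1e-12) - 1
  f1 <- pmax(f1, f0)
  k <- as.integer(f1 - f0 + 1)
  ev <- rep(seq_len(nrow(traces)), k)
  frames <- rep(f0, k) + sequence(k) - 1
  ov <- pmin(end[ev], (frames + 1) * e) - pmax(start[ev], frames * e)
  keep <- ov > e / 2 & frames >= 0 & frames <= movie$n_frames - 1
  ev <- ev[keep]; frames <- frames[keep]
  sx <- sites$x[match(traces$site_id, sites$site_id)]
  sy <- sites$y[match(traces$site_id, sites$site_id)]
  withr::with_seed(seed, {
    tibble(frame = as.integer(frames),
           x = sx[ev] + rnorm(length(ev), 0, precision_nm),
           y = sy[ev] + rnorm(length(ev), 0, precision_nm),
           precision = precision_nm,
           site_id = traces$site_id[ev],
           event_id = ev) |>
      dplyr::arrange(.data$frame)
  })
}

#' Generate a diffuse low-affinity binding field
#'
#' Spatio-temporal Poisson events inside a condensate mask, each lasting one
#' frame, at fresh positions (no rebinding). Emulates cloud-like low-affinity
#' probe binding within condensates.
#'
#' @param mask A [condensate_mask] (ground truth or segmented).
#' @param rate_um2_s Events per square micron per second.
#' @param movie A [movie_params()].
#' @param seed Integer seed.
#' @return Tibble: `frame`, `x`, `y`.
#' @export
gen_diffuse_events <- function(mask, rate_um2_s, movie, seed = 1L) {
  if (rate_um2_s == 0) return(tibble(frame = integer(), x = numeric(),
                                     y = numeric()))
  inside <- which(mask$labels > 0)
  if (!length(inside)) abort("mask is empty but diffuse rate > 0")
  px <- mask$pixel_size_nm
  area_um2 <- length(inside) * px^2 / 1e6
  t_total <- movie$n_frames * movie$exposure_s
  withr::with_seed(seed, {
    n <- rpois(1, rate_um2_s * area_um2 * t_total)
    pix <- sample(inside, n, replace = TRUE)
    ix <- (pix - 1L) %% nrow(mask$labels)
    iy <- (pix - 1L) %/% nrow(mask$labels)
    tibble(frame = sample.int(movie$n_frames, n, replace = TRUE) - 1L,
           x = mask$origin[1] + (ix + runif(n)) * px,
           y = mask$origin[2] + (iy + runif(n)) * px) |>
      dplyr::arrange(.data$frame)
  })
}

#' Run the full synthetic experiment described by a configuration
#'
#' Generates site positions, binding traces, rendered localisations and,
#' when a diffuse rate is set, the diffuse low-affinity field. All random
#' streams derive from the configuration's master seed.
#'
#' @param config A [sim_config()].
#' @return List: `points`, `domains`, `mask`, `traces`, `locs` (one tibble,
#'   all species, with a `species` column), `diffuse`, `config`.
#' @export
simulate_paint <- function(config) {
  gp <- gen_points(config)
  pts <- gp$points
  sp <- unique(pts$species)
  kin <- tibble(species = sp,
                k_on = rep_len(config$k_on, length(sp)),
                k_off = rep_len(config$k_off, length(sp)),
                valence = rep_len(config$valence, length(sp)))
  locs <- vector("list", length(sp))
  traces <- vector("list", length(sp))
  for (i in seq_along(sp)) {
    ss <- dplyr::inner_join(pts, kin[i, ], by = "species")
    tr <- simulate_traces(ss, config$movie,
                          seed = derive_seed(config$seed, paste0("traces", sp[i])))
    lc <- render_localisations(tr, ss, config$precision_nm, config$movie,
                               seed = derive_seed(config$seed, paste0("locs", sp[i])))
    tr$species <- sp[i]; lc$species <- sp[i]
    traces[[i]] <- tr; locs[[i]] <- lc
  }
  diffuse <- NULL
  if (config$diffuse_rate_um2_s > 0) {
    if (is.null(gp$mask)) abort("diffuse field requires condensate domains")
    diffuse <- gen_diffuse_events(gp$mask, config$diffuse_rate_um2_s,
                                  config$movie,
                                  seed = derive_seed(config$seed, "diffuse"))
  }
  list(points = pts, domains = gp$domains, mask = gp$mask,
       traces = dplyr::bind_rows(traces), locs = dplyr::bind_rows(locs),
       diffuse = diffuse, config = config)
}
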