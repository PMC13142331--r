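test_that("generation is deterministic given the config seed", {
  cfg <- small_field(seed = 11, n_cond = 4)
  a <- gen_points(cfg)
  b <- gen_points(cfg)
  expect_identical(a$points, b$points)
  expect_identical(a$mask$labels, b$mask$labels)
  cfg2 <- sim_config(sim_window(1500), "csr", density_um2 = 20,
                     k_on = 5, k_off = 2,
                     movie = movie_params(n_frames = 500, probe_conc_uM = 0.01),
                     seed = 4)
  r1 <- simulate_paint(cfg2)
  r2 <- simulate_paint(cfg2)
  expect_identical(r1$locs, r2$locs)
  expect_identical(r1$traces, r2$traces)
})

test_that("CSR generator has Poisson counts and handles the zero case", {
  w <- sim_window(sqrt(10) * 1000) # 10 um^2
  empty <- gen_points(sim_config(w, "csr", density_um2 = 0, seed = 1))
  expect_equal(nrow(empty$points), 0)
  counts <- vapply(1:100, function(s) {
    nrow(gen_points(sim_config(w, "csr", density_um2 = 100, seed = s))$points)
  }, 1)
  # mean of 100 Poisson(1000) draws: 1000 +/- 3 * sqrt(1000)/sqrt(100)
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000) / sqrt(100))
  expect_gt(var(counts) / mean(counts), 0.5) # dispersion consistent with Poisson
})

test_that("hard-core generator respects the inhibition distance and packing bound", {
  pts <- gen_points(sim_config(sim_window(2000), "hardcore", density_um2 = 100,
                               hardcore_nm = 40, seed = 2))$points
  expect_gte(min(dist(cbind(pts$x, pts$y))), 40)
  expect_error(
    gen_points(sim_config(sim_window(1000), "hardcore", density_um2 = 2000,
                          hardcore_nm = 40, seed = 3)),
    "packing bound")
  expect_error(sim_window(0, 100), "positive")
})

test_that("lattice and condensate-field points stay in bounds", {
  cfg <- sim_config(sim_window(3000), "lattice", lattice_spacing_nm = 70,
                    lattice_jitter_nm = 10, seed = 5)
  pts <- gen_points(cfg)$points
  expect_true(all(pts$x >= 0 & pts$x < 3000 & pts$y >= 0 & pts$y < 3000))
  gp <- gen_points(small_field(seed = 6, n_cond = 5))
  dom <- gp$domains
  d2 <- outer(gp$points$x, dom$cx, "-")^2 + outer(gp$points$y, dom$cy, "-")^2
  expect_true(all(apply(d2, 1, min) <= dom$radius[1]^2))
  # every point lies inside its own domain disc
  own <- d2[cbind(seq_len(nrow(gp$points)), gp$points$domain)]
  expect_true(all(own <= dom$radius[1]^2))
})

test_that("trace intervals follow the generating exponentials", {
  mv <- movie_params(0.05, n_frames = 48e6, probe_conc_uM = 0.01)
  site <- tibble::tibble(site_id = 1L, x = 0, y = 0,
                         k_on = 0.86, k_off = 1, valence = 1L)
  tr <- simulate_traces(site, mv, seed = 7)
  gaps <- tr$start_s[-1] - (tr$start_s + tr$duration_s)[-nrow(tr)]
  expect_gt(length(gaps), 1e4)
  # mean dark interval = 1 / (0.86 * 0.01) = 116.28 s, within 2%
  expect_lt(abs(mean(gaps) - 1 / 0.0086) / (1 / 0.0086), 0.02)
  bt <- tr$duration_s[!(tr$censored_start | tr$censored_end)]
  expect_lt(abs(mean(bt) - 1), 0.03)
  # distributional shape at alpha = 0.01
  expect_gt(suppressWarnings(ks.test(gaps, "pexp", 0.0086))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(bt, "pexp", 1))$p.value, 0.01)
  # events at one site never overlap in time
  expect_true(all(gaps > 0))
})

test_that("multivalent sites have proportionally faster dark rates", {
  mv <- movie_params(0.05, n_frames = 6e6, probe_conc_uM = 0.01)
  dark_rate <- function(m, seed) {
    site <- tibble::tibble(site_id = 1L, x = 0, y = 0, k_on = 1, k_off = 2,
                           valence = m)
    tr <- simulate_traces(site, mv, seed = seed)
    gaps <- tr$start_s[-1] - (tr$start_s + tr$duration_s)[-nrow(tr)]
    1 / mean(gaps)
  }
  r1 <- dark_rate(1L, 8)
  expect_lt(abs(dark_rate(3L, 9) / r1 - 3), 0.15)
  expect_error(simulate_traces(
    tibble::tibble(site_id = 1L, x = 0, y = 0, k_on = 1, k_off = 1,
                   valence = 1L),
    movie_params(0.05, 10, probe_conc_uM = 1), seed = 1),
    NA)
  expect_error(movie_params(0.05, 10, probe_conc_uM = 0), "positive")
})

test_that("localisation rendering follows the half-frame detection rule", {
  mv <- movie_params(0.05, n_frames = 100, probe_conc_uM = 0.01)
  site <- tibble::tibble(site_id = 1L, x = 500, y = 500)
  # spans exactly frames 10..19
  tr <- tibble::tibble(site_id = 1L, start_s = 0.5, duration_s = 0.5,
                       censored_start = FALSE, censored_end = FALSE)
  lc <- render_localisations(tr, site, 15, mv, seed = 10)
  expect_equal(nrow(lc), 10)
  expect_equal(sort(lc$frame), 10:19)
  # too short to cover half a frame anywhere it falls
  tr2 <- tibble::tibble(site_id = 1L, start_s = 0.52, duration_s = 0.01,
                        censored_start = FALSE, censored_end = FALSE)
  expect_equal(nrow(render_localisations(tr2, site, 15, mv, seed = 1)), 0)
  # localisation noise has the configured SD
  tr3 <- tibble::tibble(site_id = 1L, start_s = 0, duration_s = 500,
                        censored_start = FALSE, censored_end = TRUE)
  mv3 <- movie_params(0.05, n_frames = 1e4, probe_conc_uM = 0.01)
  lc3 <- render_localisations(tr3, site, 15, mv3, seed = 11)
  expect_equal(nrow(lc3), 1e4)
  expect_lt(abs(sd(lc3$x - 500) - 15) / 15, 0.03)
})

test_that("diffuse field events are Poisson inside the mask", {
  dom <- tibble::tibble(domain = 1L, cx = 1000, cy = 1000,
                        radius = sqrt(1e6 / pi)) # 1 um^2 disc
  mask <- nanopaint:::disc_mask(dom, sim_window(2000), 10)
  mv <- movie_params(0.05, n_frames = 2000, probe_conc_uM = 0.01) # 100 s
  expect_equal(nrow(gen_diffuse_events(mask, 0, mv, seed = 1)), 0)
  area <- sum(mask$labels > 0) * 100 / 1e6
  ns <- vapply(1:20, function(s) nrow(gen_diffuse_events(mask, 10, mv, s)), 1)
  lambda <- 10 * area * 100
  expect_lt(abs(mean(ns) - lambda), 4 * sqrt(lambda / 20))
  ev <- gen_diffuse_events(mask, 10, mv, seed = 3)
  idx <- nanopaint:::raster_index(ev$x, ev$y, mask$labels, 10, c(0, 0))
  expect_true(all(mask$labels[idx] > 0))
})
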