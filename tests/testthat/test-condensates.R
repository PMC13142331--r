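test_that("segmentation handles empty input and recovers disc geometry", {
  expect_warning(
    m0 <- segment_condensates(tibble::tibble(x = numeric(), y = numeric()),
                              sim_window(1000)),
    "dynamic range")
  expect_equal(nrow(m0$regions), 0)
  # dense disc of diffuse events, radius 250 nm, on a sparse background
  dom <- tibble::tibble(domain = 1L, cx = 1500, cy = 1500, radius = 250)
  mask <- nanopaint:::disc_mask(dom, sim_window(3000), 10)
  mv <- movie_params(0.05, 4000, 0.01)
  de <- gen_diffuse_events(mask, 40, mv, seed = 61)
  bg <- csr_pts(300, 3000, seed = 62)
  seg <- segment_condensates(dplyr::bind_rows(de[, c("x", "y")], bg),
                             sim_window(3000))
  expect_equal(nrow(seg$regions), 1)
  expect_lt(abs(seg$regions$area_um2 - pi * 0.25^2) / (pi * 0.25^2), 0.1)
})

test_that("regions below the minimum area are removed, larger ones retained", {
  doms <- tibble::tibble(domain = 1:2, cx = c(700, 2300), cy = c(700, 2300),
                         radius = c(40, 70)) # 0.0050 and 0.0154 um^2
  mask <- nanopaint:::disc_mask(doms, sim_window(3000), 10)
  mv <- movie_params(0.05, 4000, 0.01)
  de <- gen_diffuse_events(mask, 400, mv, seed = 63)
  seg <- segment_condensates(de, sim_window(3000), min_area_um2 = 0.01)
  expect_equal(nrow(seg$regions), 1)
  # the surviving region is the large disc
  expect_lt(abs(seg$regions$centroid_x - 2300), 30)
  expect_gte(seg$regions$area_um2, 0.01)
})

test_that("site classification follows the pixel rule", {
  dom <- tibble::tibble(domain = 1L, cx = 500, cy = 500, radius = 200)
  mask <- nanopaint:::disc_mask(dom, sim_window(1000), 10)
  sites <- tibble::tibble(x = c(500, 500 + 195, 500 + 215, 1500),
                          y = c(500, 500, 500, 500))
  expect_warning(cls <- classify_sites(sites, mask), "outside the raster")
  expect_equal(cls$inside, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cls$condensate[1], 1L)
  # ground-truth field with no background: every site classifies inside
  gp <- gen_points(small_field(seed = 64, n_cond = 6))
  cls2 <- classify_sites(gp$points, gp$mask)
  expect_gt(mean(cls2$inside), 0.99)
})

test_that("per-condensate statistics are consistent sums and densities", {
  gp <- gen_points(small_field(seed = 65, n_cond = 10))
  cls <- classify_sites(gp$points, gp$mask)
  st <- condensate_stats(gp$mask, cls)
  expect_equal(sum(st$n_A), sum(cls$inside))
  expect_equal(st$density_A, st$n_A / st$area_um2)
  # influx counts diffuse events by position over acquisition time
  mv <- movie_params(0.05, 2000, 0.01)
  de <- gen_diffuse_events(gp$mask, 20, mv, seed = 66)
  st2 <- condensate_stats(gp$mask, cls, de, acquisition_time_s = 100)
  expect_equal(sum(st2$influx_rate) * 100, nrow(de))
  expect_error(condensate_stats(gp$mask, cls, de, acquisition_time_s = 0),
               "positive")
})

test_that("relative radial position runs from edge 0 to centre 1", {
  # circular cell of radius 1000 nm centred at (1500, 1500)
  cellm <- nanopaint:::disc_mask(
    tibble::tibble(domain = 1L, cx = 1500, cy = 1500, radius = 1000),
    sim_window(3000), 50)
  pos <- nanopaint:::relative_radial_position(c(1500, 1500 + 980, 1500 + 500),
                                              c(1500, 1500, 1500), cellm)
  expect_equal(pos[1], 1)
  expect_lt(pos[2], 0.1)
  expect_equal(pos[3], 0.5, tolerance = 0.1)
})

test_that("count-area regressions recover construction slopes", {
  # varying domain radii spread the regressor; slope estimates the density
  gp <- gen_points(sim_config(sim_window(8000), "condensate_field",
                              density_um2 = 80, hardcore_nm = 40,
                              n_condensates = 25,
                              condensate_radius_nm = c(200, 400), seed = 67))
  cls <- classify_sites(gp$points, gp$mask)
  st <- condensate_stats(gp$mask, cls)
  reg <- count_area_regression(st, "area_um2", "n_A")
  expect_lt(abs(reg$slope - 80) / 80, 0.15)
  expect_gt(reg$r_squared, 0.8)
  exact <- suppressWarnings(
    count_area_regression(tibble::tibble(a = 1:5, b = 1:5), "a", "b"))
  expect_equal(exact$slope, 1)
  expect_equal(exact$r_squared, 1)
  expect_error(count_area_regression(tibble::tibble(a = c(1, 1, 1), b = 1:3),
                                     "a", "b"), "degenerate")
  expect_error(count_area_regression(tibble::tibble(a = 1:2, b = 1:2),
                                     "a", "b"), "at least 3")
})

test_that("density recovery through detection is unbiased against realised truth", {
  cfg <- sim_config(sim_window(7000), "condensate_field", density_um2 = 80,
                    hardcore_nm = 40, n_condensates = 15,
                    condensate_radius_nm = 300, k_on = 10, k_off = 5,
                    movie = movie_params(n_frames = 3000, probe_conc_uM = 0.01),
                    precision_nm = 10, seed = 68)
  res <- simulate_paint(cfg)
  ev <- link_events(res$locs, n_frames = 3000)
  det <- suppressWarnings(
    detect_sites(render_density(ev, 5, cfg$window, quiet = TRUE), 10))
  st <- condensate_stats(res$mask, classify_sites(det, res$mask))
  truth <- condensate_stats(res$mask, classify_sites(res$points, res$mask))
  expect_lt(abs(mean(st$density_A) - mean(truth$density_A)) /
              mean(truth$density_A), 0.05)
})
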