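test_that("CSR autocorrelation is flat at 1 with a pinned zero-lag bin", {
  profs <- lapply(1:3, function(s) {
    pair_correlation(csr_pts(2000, 5000, seed = 70 + s), NULL,
                     sim_window(5000), 10, r_max = 520)
  })
  expect_equal(profs[[1]]$value[profs[[1]]$r == 0], 1)
  v <- rowMeans(vapply(profs, function(p) p$value, profs[[1]]$value))
  r <- profs[[1]]$r
  expect_true(all(abs(v[r >= 30 & r <= 500] - 1) < 0.1))
})

test_that("FFT pair correlation matches the pairwise-histogram estimator", {
  pts <- csr_pts(500, 5000, seed = 74)
  fftg <- pair_correlation(pts, NULL, sim_window(5000), 10, r_max = 310)
  br <- seq(25, 305, by = 10)
  oracle <- gr_histogram(pts, 5000, br)
  mids <- (head(br, -1) + tail(br, -1)) / 2
  fv <- fftg$value[match(mids, fftg$r)]
  # distance quantisation migrates pairs between adjacent 10 nm bins;
  # a 3-bin average removes the migration while preserving the profile
  dv <- abs(roll3(fv) - roll3(oracle))
  expect_lt(mean(dv, na.rm = TRUE), 0.05)
})

test_that("jittered lattices show their spacing as the first correlation peak", {
  cfg <- sim_config(sim_window(5000), "lattice", lattice_spacing_nm = 70,
                    lattice_jitter_nm = 10, seed = 75)
  pts <- gen_points(cfg)$points
  pc <- pair_correlation(pts, NULL, sim_window(5000), 10, r_max = 300)
  expect_equal(profile_peak(pc, above = 1), 70)
  expect_error(pair_correlation(pts[1:5, ], NULL, sim_window(5000)),
               "insufficient")
})

test_that("edge-corrected K equals the brute-force double loop", {
  pts <- csr_pts(50, 1000, seed = 76)
  rg <- seq(20, 300, by = 20)
  fast <- ripley_l(pts, sim_window(1000), rg)
  geom <- nanopaint:::window_geometry(sim_window(1000))
  th <- (seq_len(72) - 0.5) * 2 * pi / 72
  Kbf <- vapply(rg, function(r) {
    s <- 0
    for (i in 1:50) for (j in 1:50) {
      if (i == j) next
      d <- sqrt((pts$x[i] - pts$x[j])^2 + (pts$y[i] - pts$y[j])^2)
      if (d <= r) {
        w <- max(mean(geom$inside(pts$x[i] + d * cos(th),
                                  pts$y[i] + d * sin(th))), 0.1)
        s <- s + 1 / w
      }
    }
    1e6 * s / (50 * 49)
  }, 1)
  expect_lt(max(abs(sqrt(Kbf / pi) - rg - fast$value)), 1e-9)
})

test_that("CSR L(r) - r averages to zero", {
  vals <- vapply(1:40, function(s) {
    ripley_l(csr_pts(500, 5000, seed = 200 + s), sim_window(5000),
             seq(20, 200, by = 20))$value
  }, numeric(10))
  expect_true(all(abs(rowMeans(vals)) < 2))
})

test_that("hard-core patterns are dispersed up to the inhibition distance", {
  cfg <- sim_config(sim_window(4000), "hardcore", density_um2 = 100,
                    hardcore_nm = 40, seed = 77)
  pts <- gen_points(cfg)$points
  rl <- ripley_l(pts, sim_window(4000), seq(5, 150, by = 5))
  expect_true(all(rl$value[rl$r <= 40] < 0))
  expect_lt(abs(profile_peak(rl, "min") - 40), 10 + 1e-9)
})

test_that("mask restriction removes condensate-scale clustering from L", {
  gp <- gen_points(sim_config(sim_window(8000), "condensate_field",
                              density_um2 = 80, hardcore_nm = 1e-3,
                              n_condensates = 20, condensate_radius_nm = 300,
                              seed = 78))
  rg <- seq(10, 150, by = 10)
  pooled <- ripley_l_masked(gp$points, gp$mask, rg)
  expect_equal(pooled$n_units[1], 20L)
  # CSR inside each domain: pooled curve near zero despite micro clustering
  expect_true(all(abs(pooled$value) < 8))
  # whole-window analysis of the same points is dominated by the domains
  whole <- ripley_l(gp$points, sim_window(8000), seq(50, 400, by = 50))
  expect_gt(max(whole$value), 100)
  # hard-core inside domains: pooled minimum at the inhibition distance
  gp2 <- gen_points(small_field(seed = 79, n_cond = 15, hc = 40))
  pooled2 <- ripley_l_masked(gp2$points, gp2$mask, seq(5, 150, by = 5))
  expect_lt(abs(profile_peak(pooled2, "min") - 40), 10 + 1e-9)
  expect_error(ripley_l_masked(gp$points[1:3, ], gp$mask), "enough points")
})

test_that("cross-L is null for independent species and symmetric", {
  a <- csr_pts(400, 4000, seed = 80)
  b <- csr_pts(400, 4000, seed = 81)
  rg <- seq(20, 200, by = 20)
  ab <- cross_ripley(a, b, sim_window(4000), rg)
  expect_true(all(abs(ab$value) < 12))
  ba <- cross_ripley(b, a, sim_window(4000), rg)
  interior <- rg <= 100
  expect_lt(max(abs(ab$value - ba$value)[interior]) /
              max(abs(ab$value[interior]) + 100), 0.01)
})

test_that("cross-L with identical patterns equals auto-K plus the self term", {
  a <- csr_pts(60, 1000, seed = 82)
  rg <- seq(50, 300, by = 50)
  cr <- cross_ripley(a, a, sim_window(1000), rg)
  au <- ripley_l(a, sim_window(1000), rg)
  n <- nrow(a)
  K_auto <- (au$value + rg)^2 * pi
  K_cross <- (cr$value + rg)^2 * pi
  # K_AA(cross) = (n-1)/n K_auto + A/n  (self pairs at distance zero)
  expect_equal(K_cross, (n - 1) / n * K_auto + 1e6 / n, tolerance = 1e-9)
})

test_that("shell-interleaved species cluster at the shell radius", {
  cfg <- sim_config(sim_window(8000), "interleaved", density_um2 = 20,
                    hardcore_nm = 25, n_condensates = 20,
                    condensate_radius_nm = 300, shell_radius_nm = 100,
                    shell_sd_nm = 5, cross_exclusion_nm = 15, b_per_a = 4,
                    seed = 83)
  gp <- gen_points(cfg)
  a <- gp$points[gp$points$species == "A", ]
  b <- gp$points[gp$points$species == "B", ]
  cr <- cross_ripley_masked(a, b, gp$mask, seq(5, 200, by = 5))
  expect_true(all(cr$value[cr$r <= 15] < 0))
  peak_r <- cr$r[which.max(cr$value)]
  expect_lt(abs(peak_r - 100), 15 + 1e-9)
})

test_that("nearest-neighbour CDF follows the CSR law and detects interleaving", {
  pts <- csr_pts(1000, 5000, seed = 84)
  nc <- nn_cdf(pts, NULL, seq(0, 300, by = 5))
  expect_equal(nc$value[nc$r == 0], 0)
  expect_true(all(diff(nc$value) >= 0))
  rho <- 1000 / 25 # per um^2
  theo <- 1 - exp(-rho * pi * (nc$r / 1000)^2)
  expect_lt(max(abs(nc$value - theo)), 1.63 / sqrt(1000)) # KS alpha = 0.01
  # heterotypic neighbours dominate at short range in interleaved patterns
  cfg <- sim_config(sim_window(8000), "interleaved", density_um2 = 20,
                    hardcore_nm = 25, n_condensates = 15,
                    condensate_radius_nm = 300, shell_radius_nm = 100,
                    shell_sd_nm = 5, cross_exclusion_nm = 15, b_per_a = 4,
                    seed = 85)
  gp <- gen_points(cfg)
  a <- gp$points[gp$points$species == "A", ]
  b <- gp$points[gp$points$species == "B", ]
  rg <- seq(0, 200, by = 10)
  het <- nn_cdf(a, b, rg)
  hom_a <- nn_cdf(a, NULL, rg)
  expect_gt(mean(het$value[rg < 150]), mean(hom_a$value[rg < 150]))
  expect_error(nn_cdf(a, a[0, ], rg), "empty")
})

test_that("profiles are invariant under rigid motions of the pattern", {
  pts <- csr_pts(300, 2000, seed = 86)
  rg <- seq(20, 200, by = 20)
  base <- ripley_l(pts, sim_window(2000), rg)$value
  shifted <- dplyr::mutate(pts, x = x + 5000, y = y + 3000)
  # same pattern in a translated window: rebase coordinates
  expect_equal(ripley_l(dplyr::mutate(shifted, x = x - 5000, y = y - 3000),
                        sim_window(2000), rg)$value, base)
  rotated <- tibble::tibble(x = 2000 - pts$y, y = pts$x) # 90 degrees in square
  expect_equal(ripley_l(rotated, sim_window(2000), rg)$value, base,
               tolerance = 1e-9)
})

test_that("DBSCAN follows the min-points and radius rules", {
  tri <- tibble::tibble(x = c(0, 100, 50), y = c(0, 0, 80))
  res <- dbscan_clusters(tri, 200, 3)
  expect_equal(res$points$cluster, c(1L, 1L, 1L))
  expect_equal(res$clusters$n_points, 3L)
  expect_equal(res$clusters$area_um2, 0.5 * 100 * 80 / 1e6)
  iso <- dbscan_clusters(tibble::tibble(x = c(0, 50), y = c(0, 0)), 200, 3)
  expect_true(all(is.na(iso$points$cluster)))
  two <- dbscan_clusters(dplyr::bind_rows(tri,
                                          dplyr::mutate(tri, x = x + 5000)),
                         200, 3)
  expect_equal(nrow(two$clusters), 2)
})

test_that("CSR replicates stay inside a simulated null envelope", {
  rg <- seq(30, 150, by = 30)
  sim_l <- function(seeds) {
    vapply(seeds, function(s) {
      ripley_l(csr_pts(100, 2000, seed = s), sim_window(2000), rg)$value
    }, numeric(length(rg)))
  }
  ref <- sim_l(1000 + 1:100)
  lo <- apply(ref, 1, quantile, 0.025)
  hi <- apply(ref, 1, quantile, 0.975)
  test <- sim_l(3000 + 1:40)
  inside <- colMeans(test >= lo - 1e-9 & test <= hi + 1e-9)
  expect_gt(mean(inside), 0.85)
})
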