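# Shared fixture builders; everything is generated in code at test time.

csr_pts <- function(n, w_nm, seed) {
  withr::with_seed(seed, tibble::tibble(x = runif(n, 0, w_nm),
                                        y = runif(n, 0, w_nm)))
}

# Events scattered as a Gaussian cloud around a site centre.
site_cloud <- function(n, cx, cy, sd_nm, seed) {
  withr::with_seed(seed, tibble::tibble(x = rnorm(n, cx, sd_nm),
                                        y = rnorm(n, cy, sd_nm)))
}

# Pairwise-distance histogram estimator of g(r) in a square window, using
# the closed-form isotropised set covariance of the rectangle as the CSR
# normalisation; independent of the FFT implementation.
gr_histogram <- function(pts, side_nm, r_breaks) {
  d <- as.vector(dist(cbind(pts$x, pts$y)))
  d <- d[d >= min(r_breaks) & d <= max(r_breaks)]
  cnt <- hist(d, breaks = r_breaks, plot = FALSE)$counts
  n <- nrow(pts)
  a <- side_nm; A <- a^2
  exp_per_r <- function(r) {
    # density of inter-point distance under CSR in an a x a square
    2 * pi * r / A * (1 - 4 * r / (pi * a) + r^2 / (pi * A))
  }
  mids <- (head(r_breaks, -1) + tail(r_breaks, -1)) / 2
  widths <- diff(r_breaks)
  expected <- n * (n - 1) / 2 * exp_per_r(mids) * widths
  cnt / expected
}

roll3 <- function(x) stats::filter(x, rep(1 / 3, 3), sides = 2)

# One-condensate-field simulation reused across tests.
small_field <- function(seed = 301, n_cond = 12, density = 80, hc = 40) {
  sim_config(sim_window(6000), "condensate_field", density_um2 = density,
             hardcore_nm = hc, n_condensates = n_cond,
             condensate_radius_nm = 300, seed = seed)
}
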