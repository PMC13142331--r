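test_that("exponential dissociation MLE is exact arithmetic on degenerate data", {
  f <- fit_koff(rep(2, 10))
  expect_equal(f$k_off, 0.5)
  expect_equal(f$mean_bound_time_s, 2)
})

test_that("dissociation MLE is unbiased on exponential dwell samples", {
  ks <- vapply(1:50, function(s) {
    withr::with_seed(s, fit_koff(rexp(1e4, 0.5))$k_off)
  }, 1)
  expect_lt(abs(mean(ks) - 0.5) / 0.5, 0.02)
  expect_true(all(abs(ks - 0.5) / 0.5 < 0.05))
})

test_that("right-censoring is handled as in a survival model", {
  skip_if_not_installed("survival")
  withr::with_seed(51, {
    t_true <- rexp(2000, 0.8)
    cens <- runif(2000, 0, 4)
    obs <- pmin(t_true, cens)
    is_cens <- t_true > cens
  })
  f <- fit_koff(obs, is_cens)
  sr <- survival::survreg(survival::Surv(obs, !is_cens) ~ 1,
                          dist = "exponential")
  expect_equal(f$k_off, exp(-unname(coef(sr))), tolerance = 1e-6)
  expect_lt(abs(f$k_off - 0.8) / 0.8, 0.1)
})

test_that("two-component dissociation mixtures are recovered", {
  withr::with_seed(52, x <- c(rexp(5000, 0.2), rexp(5000, 5)))
  f <- fit_koff(x, model = "exp2")
  expect_equal(f$model, "exp2")
  expect_lt(abs(f$k_off[1] - 0.2) / 0.2, 0.1)
  expect_lt(abs(f$k_off[2] - 5) / 5, 0.1)
  expect_lt(abs(f$frac[1] - 0.5), 0.05)
  expect_equal(sum(f$frac), 1)
  # BIC model selection picks the mixture here, exp1 on clean data
  expect_equal(fit_koff(x, model = "auto")$model, "exp2")
  withr::with_seed(53, y <- rexp(2000, 1))
  expect_equal(fit_koff(y, model = "auto")$model, "exp1")
  expect_error(fit_koff(rep(1, 5), model = "exp2"), "at least 20")
  expect_error(fit_koff(c(1, 2), censored = c(TRUE, TRUE)), "no uncensored")
})

test_that("association fits are exact on degenerate gaps and scale with concentration", {
  f <- fit_kon(rep(100, 10), 0.01)
  expect_equal(f$dark_rate, 0.01)
  expect_equal(f$k_on, 1)
  f2 <- fit_kon(rep(100, 10), 0.02)
  expect_equal(f2$k_on, 0.5)
  expect_error(fit_kon(rep(100, 10), 0), "positive")
  expect_error(fit_kon(c(1, 2), 0.01), "at least 3")
})

test_that("truncated association MLE recovers the single-ITAM regime", {
  withr::with_seed(54, {
    g <- rexp(4000, 0.0086)
    g <- g[g >= 0.3][1:2000]
  })
  f <- fit_kon(g, 0.01, truncation_s = 0.3)
  expect_lt(abs(f$k_on - 0.86) / 0.86, 0.05)
  expect_true(f$ci[1, "low"] < f$k_on && f$k_on < f$ci[1, "high"])
})

test_that("CDF and MLE association methods agree on clean samples", {
  withr::with_seed(55, g <- rexp(2000, 0.05))
  m <- fit_kon(g, 0.01, method = "mle")
  c_ <- fit_kon(g, 0.01, method = "cdf")
  expect_lt(abs(m$k_on - c_$k_on) / m$k_on, 0.05)
})

test_that("fitted aggregate rate is linear in site multiplicity", {
  mv <- movie_params(0.05, n_frames = 6e6, probe_conc_uM = 0.01)
  ms <- c(1, 2, 3, 5, 10)
  rates <- vapply(seq_along(ms), function(i) {
    site <- tibble::tibble(site_id = 1L, x = 0, y = 0, k_on = 1, k_off = 2,
                           valence = ms[i])
    tr <- simulate_traces(site, mv, seed = 60 + i)
    gaps <- tr$start_s[-1] - (tr$start_s + tr$duration_s)[-nrow(tr)]
    fit_kon(head(gaps, 2000), 0.01)$dark_rate
  }, 1)
  fit <- lm(rates ~ ms)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_lt(abs(coef(fit)[2] / (1 * 0.01) - 1), 0.1) # slope = k_on * c
})

test_that("site kinetics derives bound times and interior gaps from frames", {
  mv <- movie_params(0.05, n_frames = 1000, probe_conc_uM = 0.01)
  ev <- tibble::tibble(start_frame = c(10L, 110L, 210L, 310L),
                       end_frame = c(19L, 119L, 219L, 319L),
                       duration_s = 0.5,
                       censored_start = FALSE, censored_end = FALSE)
  sk <- site_kinetics(ev, mv, max_gap_frames = 5, overlapping = TRUE)
  expect_equal(sk$koff$mean_bound_time_s, 0.5)
  # three 90-frame gaps of 4.5 s, truncated at 0.3 s
  expect_equal(sk$kon$dark_rate, 3 / (3 * (4.5 - 0.3)))
  expect_true(sk$overlapping)
  expect_equal(glance(sk)$n_events, 4L)
  # single event: dissociation only, association undefined but no failure
  one <- site_kinetics(ev[1, ], mv)
  expect_null(one$kon)
  expect_false(glance(one)$k_on_defined)
  expect_equal(one$koff$k_off, 1 / (0.5 - 0.025))
})

test_that("tidiers expose estimates with confidence intervals", {
  withr::with_seed(56, f <- fit_koff(rexp(500, 2)))
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "fraction", "conf.low", "conf.high"))
  expect_true(td$conf.low < td$estimate & td$estimate < td$conf.high)
  withr::with_seed(57, k <- fit_kon(rexp(500, 0.1), 0.01))
  expect_equal(tidy(k)$term, "k_on")
  expect_equal(glance(k)$n_gaps, 500L)
})
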