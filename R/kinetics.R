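# Per-site binding kinetics: dissociation rates from bound-time
# distributions (censored exponential / two-component mixture MLE) and
# association rates from dark-gap distributions (left-truncated exponential
# MLE or a CDF least-squares fit), normalised by probe concentration.

# Exact gamma-based CI for an exponential rate with n events and total
# exposure `total`.
rate_ci <- function(n, total, level = 0.95) {
  a <- (1 - level) / 2
  c(qgamma(a, shape = n, rate = total), qgamma(1 - a, shape = n, rate = total))
}

#' Fit the dissociation rate from bound times
#'
#' Maximum likelihood under right-censoring: censored dwell times contribute
#' survival terms. Durations measured in whole frames are corrected for
#' discreteness by a half-frame offset (`duration - exposure_s/2`) on
#' uncensored events; pass `exposure_s = 0` for continuous durations. The
#' two-component model (`exp2`) is a mixture of exponentials fitted by
#' direct likelihood maximisation; `auto` selects between them by BIC.
#'
#' @param bound_times_s Dwell times in seconds.
#' @param censored Logical vector; `TRUE` marks right-censored events
#'   (touching a movie boundary). Default all uncensored.
#' @param exposure_s Frame exposure used for the discreteness correction
#'   (0 = continuous data).
#' @param model `"exp1"`, `"exp2"` or `"auto"`.
#' @return A `koff_fit`: dissociation rate component(s) `k_off` (s^-1,
#'   ascending), mixture fractions `frac`, `mean_bound_time_s` (arithmetic
#'   mean of uncensored durations), event counts, 95% CIs, log-likelihood
#'   and BIC.
#' @export
fit_koff <- function(bound_times_s, censored = NULL, exposure_s = 0,
                     model = c("exp1", "exp2", "auto")) {
  model <- match.arg(model)
  censored <- censored %||% rep(FALSE, length(bound_times_s))
  stopifnot(length(censored) == length(bound_times_s))
  t_unc <- bound_times_s[!censored]
  t_cen <- bound_times_s[censored]
  n_unc <- length(t_unc)
  if (n_unc == 0) abort("no uncensored dwell times")
  if (model == "exp2" && n_unc < 20) {
    abort("exp2 requires at least 20 uncensored dwell times")
  }
  adj_unc <- pmax(t_unc - exposure_s / 2, exposure_s / 2 + 1e-12)
  if (exposure_s == 0) adj_unc <- t_unc

  fit1 <- {
    total <- sum(adj_unc) + sum(t_cen)
    k <- n_unc / total
    ll <- n_unc * log(k) - k * total
    list(k_off = k, frac = 1, loglik = ll, bic = -2 * ll + log(n_unc),
         ci = matrix(rate_ci(n_unc, total), 1,
                     dimnames = list("k_off", c("low", "high"))))
  }
  fit2 <- NULL
  if (model %in% c("exp2", "auto") && n_unc >= 20) {
    nll <- function(th) {
      k1 <- exp(th[1]); k2 <- exp(th[2]); f <- stats::plogis(th[3])
      d <- f * k1 * exp(-k1 * adj_unc) + (1 - f) * k2 * exp(-k2 * adj_unc)
      s <- if (length(t_cen)) f * exp(-k1 * t_cen) + (1 - f) * exp(-k2 * t_cen)
        else numeric(0)
      -(sum(log(pmax(d, 1e-300))) + sum(log(pmax(s, 1e-300))))
    }
    med <- stats::median(adj_unc)
    th0 <- c(log(1 / max(mean(adj_unc[adj_unc >= med]), 1e-9)),
             log(1 / max(mean(adj_unc[adj_unc < med]), 1e-9)), 0)
    op <- tryCatch(optim(th0, nll, method = "BFGS", hessian = TRUE),
                   error = function(e) NULL)
    if (!is.null(op) && is.finite(op$value)) {
      ks <- exp(op$par[1:2]); f <- stats::plogis(op$par[3])
      o <- order(ks)
      fr <- c(f, 1 - f)[o]
      se <- tryCatch(suppressWarnings(sqrt(diag(solve(op$hessian)))[1:2]),
                     error = function(e) rep(NA_real_, 2))
      ci <- cbind(low = exp(op$par[1:2] - 1.96 * se),
                  high = exp(op$par[1:2] + 1.96 * se))[o, , drop = FALSE]
      rownames(ci) <- c("k_off1", "k_off2")
      ll <- -op$value
      fit2 <- list(k_off = ks[o], frac = fr, loglik = ll,
                   bic = -2 * ll + 3 * log(n_unc), ci = ci)
    }
  }
  chosen <- switch(model,
                   exp1 = fit1,
                   exp2 = fit2 %||% abort("exp2 mixture fit failed"),
                   auto = if (!is.null(fit2) && fit2$bic < fit1$bic) fit2
                          else fit1)
  structure(list(model = if (length(chosen$k_off) == 1) "exp1" else "exp2",
                 k_off = chosen$k_off, frac = chosen$frac,
                 mean_bound_time_s = mean(t_unc),
                 n_events = length(bound_times_s), n_censored = length(t_cen),
                 ci = chosen$ci, loglik = chosen$loglik, bic = chosen$bic,
                 exposure_s = exposure_s),
            class = c("koff_fit", "kinetic_fit"))
}

#' Fit the association rate from dark gaps
#'
#' The aggregate dark rate is estimated from the gaps between consecutive
#' binding events at a site and normalised by the probe concentration:
#' `k_on = dark_rate / concentration_uM`. Gaps shorter than
#' `truncation_s` are unobservable when the event linker bridges them, so
#' the exponential likelihood is left-truncated at that value (the MLE is
#' `n / sum(gap - truncation)`). `method = "cdf"` instead least-squares fits
#' the empirical cumulative gap distribution to `1 - exp(-rate * (t - t0))`.
#'
#' @param off_gaps_s Dark gaps in seconds (at least 3).
#' @param concentration_uM Probe concentration in uM (> 0).
#' @param method `"mle"` or `"cdf"`.
#' @param truncation_s Minimum resolvable gap, typically
#'   `(max_gap_frames + 1) * exposure_s` after linking; 0 for continuous data.
#' @return A `kon_fit` with `dark_rate` (s^-1), `k_on` (uM^-1 s^-1), 95% CI,
#'   and bookkeeping fields.
#' @export
fit_kon <- function(off_gaps_s, concentration_uM,
                    method = c("mle", "cdf"), truncation_s = 0) {
  method <- match.arg(method)
  if (concentration_uM <= 0) abort("probe concentration must be positive")
  if (any(!is.finite(off_gaps_s))) abort("off gaps must be finite")
  n <- length(off_gaps_s)
  if (n < 3) abort("need at least 3 off gaps")
  if (any(off_gaps_s < truncation_s - 1e-9)) {
    warn("gaps shorter than the truncation bound present; flooring at 0 excess")
  }
  excess <- pmax(off_gaps_s - truncation_s, 0)
  rate <- n / sum(excess)
  if (method == "cdf") {
    ts <- sort(off_gaps_s)
    emp <- seq_len(n) / n
    ss <- function(lr) {
      sum((emp - (1 - exp(-exp(lr) * pmax(ts - truncation_s, 0))))^2)
    }
    rate <- exp(stats::optimize(ss, log(rate) + c(-4, 4))$minimum)
  }
  ci <- rate_ci(n, sum(excess))
  structure(list(dark_rate = rate, k_on = rate / concentration_uM,
                 concentration_uM = concentration_uM, n_gaps = n,
                 method = method, truncation_s = truncation_s,
                 ci = matrix(ci / concentration_uM, 1,
                             dimnames = list("k_on", c("low", "high")))),
            class = c("kon_fit", "kinetic_fit"))
}

#' Per-site kinetics from assigned binding events
#'
#' Orders a site's events in time, derives bound times (with boundary
#' censoring) and inter-event dark gaps, and applies [fit_koff()] and
#' [fit_kon()]. Gaps truncated by the movie boundaries (before the first or
#' after the last event) are never formed; linker-bridged short gaps are
#' handled by left truncation at `(max_gap_frames + 1) * exposure_s`. With a
#' single event only the dissociation side is fitted and `k_on` is flagged
#' undefined.
#'
#' @param events Event tibble for one site (columns `start_frame`,
#'   `end_frame`, `duration_s`, `censored_start`, `censored_end`).
#' @param movie A [movie_params()].
#' @param max_gap_frames Gap-joining length used during linking.
#' @param koff_model Passed to [fit_koff()].
#' @param overlapping Overlap flag of the site, carried into the record.
#' @return A `site_kinetics` object with elements `koff` (a `koff_fit`),
#'   `kon` (a `kon_fit` or `NULL`), `n_events`, `overlapping`.
#' @export
site_kinetics <- function(events, movie, max_gap_frames = 5,
                          koff_model = "exp1", overlapping = FALSE) {
  stopifnot(inherits(movie, "movie_params"))
  ev <- dplyr::arrange(events, .data$start_frame)
  cen <- ev$censored_start | ev$censored_end
  koff <- fit_koff(ev$duration_s, cen, exposure_s = movie$exposure_s,
                   model = koff_model)
  kon <- NULL
  if (nrow(ev) >= 2) {
    gap_f <- ev$start_frame[-1] - ev$end_frame[-nrow(ev)] - 1L
    gaps <- gap_f * movie$exposure_s
    if (length(gaps) >= 3) {
      kon <- fit_kon(gaps, movie$probe_conc_uM,
                     truncation_s = (max_gap_frames + 1) * movie$exposure_s)
    }
  }
  structure(list(koff = koff, kon = kon, n_events = nrow(ev),
                 overlapping = overlapping),
            class = c("site_kinetics", "kinetic_fit"))
}

#' Kinetics table for all sites
#'
#' Applies [site_kinetics()] to every assigned site and returns one row per
#' site with rates, confidence intervals and the overlap flag, ready for
#' joining with condensate classification.
#'
#' @param assigned Result of [assign_events()].
#' @param movie A [movie_params()].
#' @param max_gap_frames,koff_model Passed to [site_kinetics()].
#' @param min_events Skip sites with fewer assigned events.
#' @return Tibble: `site`, `n_events`, `k_on`, `k_on_low`, `k_on_high`,
#'   `k_off`, `k_off2`, `frac1`, `mean_bound_time_s`, `overlapping`.
#' @export
kinetics_table <- function(assigned, movie, max_gap_frames = 5,
                           koff_model = "exp1", min_events = 3) {
  ev <- dplyr::filter(assigned$events, !is.na(.data$site))
  purrr::map_dfr(split(ev, ev$site), function(e) {
    s <- e$site[1]
    if (nrow(e) < min_events) return(NULL)
    fit <- tryCatch(
      site_kinetics(e, movie, max_gap_frames, koff_model,
                    overlapping = assigned$sites$overlapping[
                      match(s, assigned$sites$site)]),
      error = function(err) NULL)
    if (is.null(fit)) return(NULL)
    tibble(site = s, n_events = fit$n_events,
           k_on = if (is.null(fit$kon)) NA_real_ else fit$kon$k_on,
           k_on_low = if (is.null(fit$kon)) NA_real_ else fit$kon$ci[1, "low"],
           k_on_high = if (is.null(fit$kon)) NA_real_ else fit$kon$ci[1, "high"],
           k_off = fit$koff$k_off[1],
           k_off2 = if (length(fit$koff$k_off) > 1) fit$koff$k_off[2] else NA_real_,
           frac1 = fit$koff$frac[1],
           mean_bound_time_s = fit$koff$mean_bound_time_s,
           overlapping = fit$overlapping)
  })
}

#' @method tidy koff_fit
#' @export
tidy.koff_fit <- function(x, ...) {
  tibble(term = rownames(x$ci) %||% paste0("k_off", seq_along(x$k_off)),
         estimate = x$k_off, fraction = x$frac,
         conf.low = x$ci[, "low"], conf.high = x$ci[, "high"])
}

#' @method tidy kon_fit
#' @export
tidy.kon_fit <- function(x, ...) {
  tibble(term = "k_on", estimate = x$k_on, fraction = 1,
         conf.low = x$ci[, "low"], conf.high = x$ci[, "high"])
}

#' @method tidy site_kinetics
#' @export
tidy.site_kinetics <- function(x, ...) {
  out <- tidy(x$koff)
  if (!is.null(x$kon)) out <- dplyr::bind_rows(out, tidy(x$kon))
  out
}

#' @method glance koff_fit
#' @export
glance.koff_fit <- function(x, ...) {
  tibble(model = x$model, n_events = x$n_events, n_censored = x$n_censored,
         mean_bound_time_s = x$mean_bound_time_s, logLik = x$loglik,
         BIC = x$bic)
}

#' @method glance kon_fit
#' @export
glance.kon_fit <- function(x, ...) {
  tibble(method = x$method, n_gaps = x$n_gaps, dark_rate = x$dark_rate,
         concentration_uM = x$concentration_uM,
         truncation_s = x$truncation_s)
}

#' @method glance site_kinetics
#' @export
glance.site_kinetics <- function(x, ...) {
  tibble(n_events = x$n_events, overlapping = x$overlapping,
         k_on_defined = !is.null(x$kon))
}

#' @export
print.koff_fit <- function(x, ...) {
  cat("Dissociation fit (", x$model, "), n =", x$n_events,
      "events,", x$n_censored, "censored\n")
  for (i in seq_along(x$k_off)) {
    cat(sprintf("  k_off%s = %.4g /s (%.0f%%) [%.4g, %.4g]\n",
                if (length(x$k_off) > 1) i else "", x$k_off[i],
                100 * x$frac[i], x$ci[i, "low"], x$ci[i, "high"]))
  }
  invisible(x)
}

#' @export
print.kon_fit <- function(x, ...) {
  cat(sprintf("Association fit: k_on = %.4g /uM/s [%.4g, %.4g] (dark rate %.4g /s, n = %d gaps)\n",
              x$k_on, x$ci[1, "low"], x$ci[1, "high"], x$dark_rate, x$n_gaps))
  invisible(x)
}
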