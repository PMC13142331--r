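# Linking of per-frame localisations into binding events: greedy chaining
# within a spatial radius, bridging up to a fixed number of dark frames.

#' Link localisations into binding events
#'
#' Greedy chaining in frame order: a localisation in frame `f` joins the
#' nearest open chain whose last position is within `link_radius_nm` and
#' whose last frame is at least `f - (max_gap_frames + 1)`, i.e. up to
#' `max_gap_frames` consecutive dark frames are bridged and one more splits
#' the event. Ties between equally near chains are broken towards the chain
#' with the lower start frame; a chain accepts at most one localisation per
#' frame. Event positions are precision-weighted means of the member
#' localisations. Events touching frame 0 are flagged `censored_start`,
#' events touching the final frame `censored_end`.
#'
#' @param locs Localisation tibble with `frame` (0-based integer), `x`, `y`
#'   (nm) and optionally `precision` (nm; equal weights when absent).
#' @param link_radius_nm Linking radius (default 80 nm).
#' @param max_gap_frames Maximum number of bridgeable dark frames (default 5).
#' @param exposure_s Frame exposure in seconds, used for `duration_s`.
#' @param n_frames Total frames in the movie; inferred from the data when
#'   `NULL` (used only for the end-censoring flag).
#' @param return_locs Also return the localisation table with an `event_id`
#'   column (as attribute `"locs"`).
#' @return Tibble of events: `event_id`, `start_frame`, `end_frame`, `x`,
#'   `y`, `n_locs`, `duration_s`, `censored_start`, `censored_end`.
#' @export
link_events <- function(locs, link_radius_nm = 80, max_gap_frames = 5,
                        exposure_s = 0.05, n_frames = NULL,
                        return_locs = FALSE) {
  if (link_radius_nm < 0 || max_gap_frames < 0) {
    abort("link radius and gap length must be non-negative")
  }
  empty <- tibble(event_id = integer(), start_frame = integer(),
                  end_frame = integer(), x = numeric(), y = numeric(),
                  n_locs = integer(), duration_s = numeric(),
                  censored_start = logical(), censored_end = logical())
  if (!nrow(locs)) return(empty)
  ord <- order(locs$frame)
  frame <- as.integer(locs$frame[ord])
  x <- locs$x[ord]; y <- locs$y[ord]
  w <- if ("precision" %in% names(locs)) 1 / locs$precision[ord]^2 else
    rep(1, length(ord))
  n <- length(frame)
  if (is.null(n_frames)) n_frames <- max(frame) + 1L

  # chain state, preallocated and grown as needed
  cap <- max(256L, n %/% 4L)
  c_lastx <- c_lasty <- c_swx <- c_swy <- c_sw <- numeric(cap)
  c_lastf <- c_startf <- c_n <- integer(cap)
  n_chain <- 0L
  active <- integer(0)          # indices of open chains
  ev_id <- integer(n)           # event id per localisation (sorted order)
  r2 <- link_radius_nm^2

  # frame-grouped processing
  starts <- c(1L, which(diff(frame) > 0L) + 1L)
  ends <- c(starts[-1L] - 1L, n)
  for (g in seq_along(starts)) {
    f <- frame[starts[g]]
    if (length(active)) {
      active <- active[c_lastf[active] >= f - (max_gap_frames + 1L)]
    }
    claimed <- rep(FALSE, length(active))
    for (i in starts[g]:ends[g]) {
      joined <- 0L
      if (length(active)) {
        el <- !claimed & c_lastf[active] < f
        if (any(el)) {
          cand <- active[el]
          d2 <- (c_lastx[cand] - x[i])^2 + (c_lasty[cand] - y[i])^2
          ok <- d2 <= r2
          if (any(ok)) {
            cand <- cand[ok]; d2 <- d2[ok]
            best <- cand[order(d2, c_startf[cand])][1L]
            joined <- best
          }
        }
      }
      if (joined == 0L) {
        n_chain <- n_chain + 1L
        if (n_chain > cap) {
          grow <- function(v, fill) c(v, rep(fill, cap))
          c_lastx <- grow(c_lastx, 0); c_lasty <- grow(c_lasty, 0)
          c_swx <- grow(c_swx, 0); c_swy <- grow(c_swy, 0)
          c_sw <- grow(c_sw, 0)
          c_lastf <- grow(c_lastf, 0L); c_startf <- grow(c_startf, 0L)
          c_n <- grow(c_n, 0L)
          cap <- 2L * cap
        }
        joined <- n_chain
        c_startf[joined] <- f
        c_swx[joined] <- 0; c_swy[joined] <- 0; c_sw[joined] <- 0
        c_n[joined] <- 0L
        active <- c(active, joined)
        claimed <- c(claimed, TRUE)
      } else {
        claimed[match(joined, active)] <- TRUE
      }
      c_lastx[joined] <- x[i]; c_lasty[joined] <- y[i]
      c_lastf[joined] <- f
      c_swx[joined] <- c_swx[joined] + w[i] * x[i]
      c_swy[joined] <- c_swy[joined] + w[i] * y[i]
      c_sw[joined] <- c_sw[joined] + w[i]
      c_n[joined] <- c_n[joined] + 1L
      ev_id[i] <- joined
    }
  }
  idx <- seq_len(n_chain)
  events <- tibble(
    event_id = idx,
    start_frame = c_startf[idx],
    end_frame = c_lastf[idx],
    x = c_swx[idx] / c_sw[idx],
    y = c_swy[idx] / c_sw[idx],
    n_locs = c_n[idx]) |>
    dplyr::mutate(
      duration_s = (.data$end_frame - .data$start_frame + 1) * exposure_s,
      censored_start = .data$start_frame == 0L,
      censored_end = .data$end_frame == n_frames - 1L) |>
    dplyr::arrange(.data$start_frame, .data$event_id)
  events$event_id <- seq_len(nrow(events))
  if (return_locs) {
    remap <- match(ev_id, idx[order(c_startf[idx], idx)])
    out_locs <- locs[ord, ]
    out_locs$event_id <- remap
    attr(events, "locs") <- out_locs
  }
  events
}
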