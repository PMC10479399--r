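# Speckle-track analysis: motion classification, nanometer flow-onset
# detection, censored survival-rate estimation with photobleaching
# correction, the four-state flux-balance clutch model, and whole-cell force
# bookkeeping.

.AVOGADRO <- 6.02214076e23

.project_flow <- function(track, flow_axis) {
  ax <- flow_axis / sqrt(sum(flow_axis^2))
  track$x_nm * ax[1] + track$y_nm * ax[2]
}

# Per-step motion label from the centered two-frame displacement: step k
# (frames k -> k+1) is labelled by (p[k+1] - p[k-1]) / 2 (one-sided at the
# first step), which halves the localization-noise variance relative to the
# raw single-step difference at the cost of blurring boundaries by <= 1
# frame.
.step_labels <- function(p, threshold) {
  n <- length(p)
  k <- seq_len(n - 1)
  d <- c(p[2] - p[1],
         if (n > 2) (p[pmin(k[-1] + 1, n)] - p[k[-1] - 1]) / 2)
  ifelse(d > threshold, "flow", ifelse(d < -threshold, "counter", "stat"))
}

# Tile the steps of one track into segments: non-qualifying runs inherit the
# label of the preceding qualifying run (the following one for a leading
# stretch), then adjacent equal labels merge. `min_run` may be a single
# length or a named vector of per-label run lengths.
.track_segments <- function(labels, min_run) {
  r <- rle(labels)
  need <- if (length(min_run) == 1) rep(min_run, length(r$values))
  else {
    mr <- min_run[r$values]
    mr[is.na(mr)] <- max(min_run)
    mr
  }
  qual <- r$lengths >= need
  lab <- r$values
  if (any(qual)) {
    last <- NA_character_
    for (i in seq_along(lab)) {
      if (qual[i]) last <- lab[i] else if (!is.na(last)) lab[i] <- last
    }
    # leading non-qualifying runs take the first qualifying label
    first_q <- which(qual)[1]
    if (first_q > 1) lab[seq_len(first_q - 1)] <- lab[first_q]
  }
  r$values <- lab
  x <- inverse.rle(r)
  r2 <- rle(x)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1
  # steps k..k' span frames k..k'+1
  data.frame(label = r2$values, start_frame = starts, end_frame = ends + 1,
             n_steps = r2$lengths)
}

#' Classify speckle tracks by their motion behaviour
#'
#' Implements the run-length classification of speckle trajectories relative
#' to the retrograde-flow axis. In coarse mode (2-s frames, 120-s window) a
#' track is `flowing`/`stationary` when it shows a run of more than 2
#' sequential images of with-flow/stationary motion and `switching` when it
#' shows both; in fast mode (100-ms frames, 10-s window) the run threshold is
#' more than 10 images, and an additional `back_and_forth` category captures
#' a with-flow excursion of more than 8 images followed by counter-flow and
#' stationary motion of more than 3 images. Tracks matching no rule are
#' `unclassified`; tracks below the minimum lifetime (4 s coarse, 2 s fast)
#' are `excluded`.
#'
#' @param tracks A data.frame with columns `track_id`, `frame`, `t_s`,
#'   `x_nm`, `y_nm` (one row per frame).
#' @param mode `"coarse_2s"` or `"fast_100ms"`.
#' @param motion_threshold Per-frame with-flow displacement, nm, above which
#'   a step counts as directional motion; defaults to twice the localization
#'   SD.
#' @param flow_axis Unit vector of the retrograde flow direction.
#' @param localization_sd Localization noise SD, nm.
#' @return A data.frame with one row per track: `track_id`, `category`,
#'   `n_frames`, `reason` (for exclusions), and a list-column `segments`
#'   tiling each classified track into labelled segments.
#' @export
classify_tracks <- function(tracks, mode = c("coarse_2s", "fast_100ms"),
                            motion_threshold = NULL, flow_axis = c(1, 0),
                            localization_sd = 18.6) {
  mode <- match.arg(mode)
  stopifnot(all(c("track_id", "t_s", "x_nm", "y_nm") %in% names(tracks)))
  expected_dt <- if (mode == "coarse_2s") 2 else 0.1
  min_life <- if (mode == "coarse_2s") 4 else 2
  min_run <- if (mode == "coarse_2s") 2L else 10L
  if (is.null(motion_threshold)) motion_threshold <- 2 * localization_sd
  ids <- unique(tracks$track_id)
  res <- vector("list", length(ids))
  for (ii in seq_along(ids)) {
    tr <- tracks[tracks$track_id == ids[ii], , drop = FALSE]
    tr <- tr[order(tr$t_s), , drop = FALSE]
    n <- nrow(tr)
    dtv <- diff(tr$t_s)
    if (n >= 2 && any(abs(dtv - expected_dt) > 1e-6))
      stop("track ", ids[ii], ": frame interval does not match mode ", mode)
    if (n < 2 || (n - 1) * expected_dt < min_life) {
      res[[ii]] <- list(track_id = ids[ii], category = "excluded",
                        n_frames = n, reason = "below minimum lifetime",
                        segments = list(NULL))
      next
    }
    p <- .project_flow(tr, flow_axis)
    labs <- .step_labels(p, motion_threshold)
    r <- rle(labs)
    flow_runs <- r$lengths[r$values == "flow"]
    stat_runs <- r$lengths[r$values == "stat"]
    category <- "unclassified"
    if (mode == "fast_100ms") {
      # with-flow run of > 8 images then counter-flow + stationary > 3 images
      bf <- FALSE
      for (q in which(r$values == "flow" & r$lengths >= 8L)) {
        if (q < length(r$values)) {
          after <- seq(q + 1, length(r$values))
          nonflow <- cumsum(r$values[after] != "flow") == seq_along(after)
          span <- after[nonflow]
          if (length(span) && sum(r$lengths[span]) >= 3L &&
              any(r$values[span] == "counter")) { bf <- TRUE; break }
        }
      }
      if (bf) category <- "back_and_forth"
    }
    if (category == "unclassified") {
      has_flow <- any(flow_runs >= min_run)
      has_stat <- any(stat_runs >= min_run)
      if (has_flow && has_stat) category <- "switching"
      else if (has_flow) category <- "flowing"
      else if (has_stat) category <- "stationary"
    }
    segs <- .track_segments(labs, min_run)
    segs$t_start <- tr$t_s[segs$start_frame]
    segs$t_end <- tr$t_s[segs$end_frame]
    res[[ii]] <- list(track_id = ids[ii], category = category, n_frames = n,
                      reason = NA_character_, segments = list(segs))
  }
  out <- data.frame(
    track_id = vapply(res, `[[`, ids[1], "track_id"),
    category = vapply(res, `[[`, "", "category"),
    n_frames = vapply(res, `[[`, 0L, "n_frames"),
    reason = vapply(res, `[[`, "", "reason"),
    stringsAsFactors = FALSE)
  out$segments <- lapply(res, function(z) z$segments[[1]])
  out
}

#' Detect the onset of flowing motion in a fast-mode track
#'
#' The mean position over the initial stationary stretch (at least
#' `stationary_window` frames) defines the origin; flow is detected at the
#' first frame of the first run of three consecutive frames whose along-flow
#' distance from the origin exceeds the stationary SD. The jump distance
#' delta_x is the flowing-segment linear fit evaluated at the detection time,
#' minus the origin.
#'
#' @param track Data.frame of one track (`t_s`, `x_nm`, `y_nm`), time-sorted.
#' @param stationary_window Minimum initial stationary stretch, frames.
#' @param flow_axis Unit vector of the retrograde flow direction.
#' @return A list: `origin` (nm, along flow), `sd_stationary`, `t_detect`
#'   (s, NA if no detection), `delta_x` (nm, NA if no detection),
#'   `flow_speed` (nm/s, fit slope), `applicable` and `reason`.
#' @export
detect_flow_onset <- function(track, stationary_window = 8,
                              flow_axis = c(1, 0)) {
  track <- track[order(track$t_s), , drop = FALSE]
  n <- nrow(track)
  W <- stationary_window
  na_out <- function(reason, origin = NA_real_, sdv = NA_real_)
    list(origin = origin, sd_stationary = sdv, t_detect = NA_real_,
         delta_x = NA_real_, flow_speed = NA_real_, applicable = FALSE,
         reason = reason)
  if (n < W + 3) return(na_out("track too short for onset analysis"))
  p <- .project_flow(track, flow_axis)
  # two passes: refine origin/SD over the full pre-detection stretch
  k_end <- W
  det <- NA_integer_
  for (pass in 1:3) {
    origin <- mean(p[1:k_end])
    sdv <- stats::sd(p[1:k_end])
    exceed <- (p - origin) > sdv
    runs <- exceed & c(exceed[-1], FALSE) & c(exceed[-(1:2)], FALSE, FALSE)
    cand <- which(runs)
    det_new <- if (length(cand)) cand[1] else NA_integer_
    if (!is.na(det_new) && det_new > W + 1) {
      if (!is.na(det) && det_new == det) break
      det <- det_new
      k_end <- det - 1
    } else {
      det <- det_new
      break
    }
  }
  if (is.na(det))
    return(list(origin = origin, sd_stationary = sdv, t_detect = NA_real_,
                delta_x = NA_real_, flow_speed = NA_real_, applicable = TRUE,
                reason = "no flow detected"))
  if (det <= W)
    return(na_out("initial stationary segment shorter than required window",
                  origin, sdv))
  flow_idx <- det:n
  fit <- lm(p[flow_idx] ~ track$t_s[flow_idx])
  t_det <- track$t_s[det]
  dx <- unname(coef(fit)[1] + coef(fit)[2] * t_det) - origin
  list(origin = origin, sd_stationary = sdv, t_detect = t_det,
       delta_x = dx, flow_speed = unname(coef(fit)[2]), applicable = TRUE,
       reason = NA_character_)
}

#' Exponential rate from a censored Kaplan-Meier survival curve
#'
#' Builds the Kaplan-Meier survival estimate with right-censoring, fits a
#' single exponential to it (weighted least squares of log-survival through
#' the origin, weights the number at risk), and optionally subtracts the
#' photobleaching rate from the fitted disappearance rate. The closed-form
#' censored MLE (events / total time at risk) is reported alongside.
#'
#' @param durations Observed state durations, s.
#' @param censored Logical; TRUE where the duration is right-censored.
#' @param bleach_per_frame Photobleaching probability per frame (e.g. 0.0071
#'   for 2-s coarse imaging), or NULL for no correction.
#' @param frame_interval Frame interval, s, used to convert the per-frame
#'   bleach rate to 1/s.
#' @return A list of class `talin_rate_estimate`: `rate` (1/s, corrected if
#'   requested), `rate_observed`, `rate_mle`, `n_events`, `n_censored`,
#'   `ci` (95%, on `rate`), `bleach_corrected`.
#' @export
km_exponential_rate <- function(durations, censored = rep(FALSE, length(durations)),
                                bleach_per_frame = NULL, frame_interval = 2) {
  stopifnot(length(durations) == length(censored), all(durations >= 0))
  events <- !censored
  if (!any(events)) stop("all observations censored: rate undefined")
  fit <- survival::survfit(survival::Surv(durations, events) ~ 1)
  use <- fit$n.event > 0 & fit$surv > 0 & fit$time > 0
  if (sum(use) >= 2) {
    tt <- fit$time[use]; ls <- log(fit$surv[use]); w <- fit$n.risk[use]
    rate_obs <- -sum(w * tt * ls) / sum(w * tt^2)
  } else {
    rate_obs <- sum(events) / sum(durations)
  }
  rate_mle <- sum(events) / sum(durations)
  corrected <- !is.null(bleach_per_frame)
  rate <- rate_obs - if (corrected) bleach_per_frame / frame_interval else 0
  rel <- exp(1.96 / sqrt(sum(events)))
  structure(list(rate = rate, rate_observed = rate_obs, rate_mle = rate_mle,
                 n_events = sum(events), n_censored = sum(censored),
                 ci = c(rate / rel, rate * rel),
                 bleach_corrected = corrected),
            class = "talin_rate_estimate")
}

#' Steady-state proportions of the four-state clutch model
#'
#' Solves the flux balance of the stationary (S), clutch (C) and flowing (F)
#' speckle states with net recycling flux X through the diffusing pool:
#' \deqn{-k_a S + k_b C + X = 0}
#' \deqn{k_a S + k_d F - (k_b + k_c) C = 0}
#' \deqn{k_c C - k_d F - X = 0}
#' \deqn{X = k_2 S - k_4 F}
#' The three state equations are linearly dependent; given S and the six
#' rate constants the system is solved for C, F and X, and the residuals of
#' all three are verified below 1e-9.
#'
#' @param S Stationary proportion, percent.
#' @param rates Named list or vector with `k_a`, `k_b`, `k_c`, `k_d`,
#'   `k_2`, `k_4` (1/s).
#' @return A list of class `clutch_state_solution`: `S`, `C`, `F` (percent)
#'   and `X` (percent/s).
#' @export
#' @examples
#' clutch_flux_balance(57, list(k_a = 0.0548, k_b = 0.374, k_c = 0.680,
#'                              k_d = 0.0315, k_2 = 0.0324, k_4 = 0.00694))
clutch_flux_balance <- function(S, rates) {
  stopifnot(S > 0)
  need <- c("k_a", "k_b", "k_c", "k_d", "k_2", "k_4")
  if (!all(need %in% names(rates)))
    stop("rates must contain: ", paste(need, collapse = ", "))
  r <- lapply(need, function(nm) rates[[nm]])
  names(r) <- need
  if (any(unlist(r) < 0)) stop("rates must be non-negative")
  # substitute X = k2 S - k4 F into eq 1 and pair with eq 2
  A <- matrix(c(r$k_b, -r$k_4,
                r$k_b + r$k_c, -r$k_d), 2, 2, byrow = TRUE)
  b <- c((r$k_a - r$k_2) * S, r$k_a * S)
  if (abs(det(A)) >= 1e-14) {
    sol <- solve(A, b)
    C <- sol[1]; F <- sol[2]
  } else if (r$k_d == 0 && r$k_4 == 0 && r$k_b + r$k_c > 0) {
    # no return path into the flowing pool: F drains to zero at steady state
    C <- r$k_a * S / (r$k_b + r$k_c)
    F <- 0
  } else {
    stop("singular flux-balance system for these rate constants")
  }
  X <- r$k_2 * S - r$k_4 * F
  resid <- c(-r$k_a * S + r$k_b * C + X,
             r$k_a * S + r$k_d * F - (r$k_b + r$k_c) * C,
             r$k_c * C - r$k_d * F - X)
  if (max(abs(resid)) > 1e-9)
    stop("flux-balance residuals exceed tolerance: ",
         signif(max(abs(resid)), 3))
  structure(list(S = S, C = unname(C), F = unname(F), X = unname(X),
                 residuals = resid),
            class = "clutch_state_solution")
}

#' Clutch rate constants from displacement statistics
#'
#' k_c is the reciprocal of the mean clutch duration (first-order
#' disengagement toward flowing); k_b scales k_c by the ratio of observed
#' back-and-forth events (clutch returning to stationary) to
#' stationary-to-flowing switching events.
#'
#' @param mean_clutch_duration Mean clutch duration, s.
#' @param n_back_and_forth Number of back-and-forth events observed.
#' @param n_switch_to_flow Number of stationary-to-flowing switches observed.
#' @return A list with `k_c` and `k_b` (1/s; `k_b` NA when no switching
#'   events are supplied).
#' @export
derive_rate_constants <- function(mean_clutch_duration, n_back_and_forth = NA,
                                  n_switch_to_flow = NA) {
  stopifnot(mean_clutch_duration > 0)
  k_c <- 1 / mean_clutch_duration
  k_b <- if (is.na(n_back_and_forth) || is.na(n_switch_to_flow)) NA_real_
  else {
    if (n_switch_to_flow == 0) stop("k_b undefined: no switch-to-flow events")
    k_c * n_back_and_forth / n_switch_to_flow
  }
  list(k_c = k_c, k_b = k_b)
}

.as_range <- function(x) if (length(x) == 1) c(x, x) else sort(x[1:2])

#' Whole-cell force bookkeeping of the Talin clutch
#'
#' Propagates the arithmetic from cellular Talin concentration to the force
#' borne by a single clutch-engaged molecule: total molecules from
#' concentration x cytosol volume, the speckle-state and clutch-state
#' subpopulations, the total flow-resisting force from the per-filament force
#' and filament count at the lamellipodium edge, and the per-speckle and
#' per-clutch shares. Scalar inputs may be length-2 ranges; ranges are
#' propagated by interval arithmetic.
#'
#' @param concentration_uM Talin concentration, micromolar.
#' @param cytosol_volume_pL Cytosol volume, picolitres.
#' @param speckle_fraction Fraction of molecules in a speckle (bound) state.
#' @param clutch_fraction Fraction of speckle-state molecules in a clutch
#'   state.
#' @param per_filament_force_pN Flow-resisting force per actin filament, pN.
#' @param n_filaments Filaments in contact with the lamellipodium edge
#'   region.
#' @param region_fraction Fraction of the cell edge occupied by that region.
#' @return A list of ranges (lo, hi): `molecules_per_cell`, `speckle_count`,
#'   `clutch_count`, `region_speckle_count`, `total_force_pN`,
#'   `force_per_speckle_pN`, `force_per_clutch_pN`.
#' @export
#' @examples
#' force_bookkeeping(concentration_uM = c(3, 5))
force_bookkeeping <- function(concentration_uM = c(3, 5),
                              cytosol_volume_pL = 0.68,
                              speckle_fraction = 0.064,
                              clutch_fraction = 0.041,
                              per_filament_force_pN = 1.8,
                              n_filaments = 2500,
                              region_fraction = 1 / 16) {
  args <- list(concentration_uM, cytosol_volume_pL, speckle_fraction,
               clutch_fraction, per_filament_force_pN, n_filaments,
               region_fraction)
  if (any(unlist(args) <= 0)) stop("all inputs must be positive")
  conc <- .as_range(concentration_uM)
  vol <- .as_range(cytosol_volume_pL)
  spf <- .as_range(speckle_fraction)
  clf <- .as_range(clutch_fraction)
  ff <- .as_range(per_filament_force_pN)
  nf <- .as_range(n_filaments)
  rf <- .as_range(region_fraction)
  molecules <- conc * 1e-6 * vol * 1e-12 * .AVOGADRO
  speckles <- molecules * spf
  clutches <- speckles * clf
  region_speckles <- speckles * rf
  total_force <- ff * nf
  per_speckle <- sort(c(total_force[1] / region_speckles[2],
                        total_force[2] / region_speckles[1]))
  per_clutch <- sort(c(per_speckle[1] / clf[2], per_speckle[2] / clf[1]))
  list(molecules_per_cell = molecules,
       speckle_count = speckles,
       clutch_count = clutches,
       region_speckle_count = region_speckles,
       total_force_pN = total_force,
       force_per_speckle_pN = per_speckle,
       force_per_clutch_pN = per_clutch)
}
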