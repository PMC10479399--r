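# Synthetic SiMS track generation: a three-state continuous-time Markov
# chain (stationary <-> clutch <-> flowing) with exits to a diffusing state
# (track end), tag-geometry kinematics along the flow axis, Gaussian
# localization noise and per-frame photobleaching. The generator defines the
# ground truth against which the analysis pipeline is validated.

#' Kinetic ground truth of the synthetic speckle ensemble
#'
#' Defaults are the measured single-molecule rate constants: the
#' coarse-grained set k1-k4 (stationary/flowing dissociation and switching)
#' and the clutch-resolved set k_a-k_d. The initial-state split between
#' stationary and flowing appearance is chosen so that ensemble state
#' occupancy reproduces the measured proportions (57% stationary, 4.1%
#' clutch, 39% flowing); pass `appearance_split` to override.
#'
#' @param k1,k2,k3,k4 Coarse-grained rates, 1/s.
#' @param k_a,k_b,k_c,k_d Clutch engagement/disengagement rates, 1/s.
#' @param S_percent Stationary proportion used to anchor the appearance
#'   split.
#' @param appearance_split Probability that a new speckle appears stationary
#'   (NULL: derived from the rates).
#' @return An object of class `talin_kinetic_truth`.
#' @export
kinetic_ground_truth <- function(k1 = 0.170, k2 = 0.0324, k3 = 0.104,
                                 k4 = 0.00694, k_a = 0.0548, k_b = 0.374,
                                 k_c = 0.680, k_d = 0.0315,
                                 S_percent = 57, appearance_split = NULL) {
  rates <- c(k1, k2, k3, k4, k_a, k_b, k_c, k_d)
  stopifnot(all(rates >= 0))
  if (is.null(appearance_split)) {
    fb <- clutch_flux_balance(S_percent,
                              list(k_a = k_a, k_b = k_b, k_c = k_c,
                                   k_d = k_d, k_2 = k2, k_4 = k4))
    alpha_S <- (k1 + k_a) * fb$S - k_b * fb$C
    alpha_F <- (k3 + k_d) * fb$F - k_c * fb$C
    appearance_split <- alpha_S / (alpha_S + alpha_F)
  }
  stopifnot(appearance_split >= 0, appearance_split <= 1)
  structure(list(k1 = k1, k2 = k2, k3 = k3, k4 = k4,
                 k_a = k_a, k_b = k_b, k_c = k_c, k_d = k_d,
                 appearance_split = appearance_split),
            class = "talin_kinetic_truth")
}

#' Imaging model of a synthetic SiMS acquisition
#'
#' @param mode `"coarse_2s"` (2-s frames, 120-s window, bleach 0.0071/frame)
#'   or `"fast_100ms"` (100-ms frames, 10-s window, window-limited only).
#' @param localization_sd Localization noise SD per coordinate, nm.
#' @param v_retro Retrograde flow speed, nm/s.
#' @param tag `"N_tag"` (integrin-end fluorophore) or `"C_tag"` (actin-end).
#' @param bleach_per_frame Override the per-frame bleaching probability.
#' @return An object of class `talin_imaging_model`.
#' @export
imaging_model <- function(mode = c("coarse_2s", "fast_100ms"),
                          localization_sd = 18.6, v_retro = 30,
                          tag = c("N_tag", "C_tag"),
                          bleach_per_frame = NULL) {
  mode <- match.arg(mode)
  tag <- match.arg(tag)
  fi <- if (mode == "coarse_2s") 2 else 0.1
  win <- if (mode == "coarse_2s") 120 else 10
  if (is.null(bleach_per_frame))
    bleach_per_frame <- if (mode == "coarse_2s") 0.0071 else 0
  stopifnot(localization_sd >= 0, v_retro >= 0,
            bleach_per_frame >= 0, bleach_per_frame < 1)
  structure(list(mode = mode, frame_interval = fi, window = win,
                 localization_sd = localization_sd,
                 bleach_per_frame = bleach_per_frame,
                 v_retro = v_retro, tag = tag),
            class = "talin_imaging_model")
}

# One CTMC path: data.frame(state, t_start, t_end) ending with exit or t_max.
.sim_clutch_path <- function(truth, init_state, t_max) {
  t <- 0
  state <- init_state
  st <- character(0); t0 <- numeric(0); t1 <- numeric(0)
  exited <- FALSE
  while (t < t_max) {
    rates <- switch(state,
      stationary = c(exit = truth$k1, clutch = truth$k_a),
      clutch = c(stationary = truth$k_b, flowing = truth$k_c),
      flowing = c(exit = truth$k3, clutch = truth$k_d))
    tot <- sum(rates)
    dwell <- if (tot > 0) rexp(1, tot) else Inf
    t_end <- min(t + dwell, t_max)
    st <- c(st, state); t0 <- c(t0, t); t1 <- c(t1, t_end)
    if (t + dwell >= t_max) break
    nxt <- names(rates)[sample.int(length(rates), 1, prob = rates)]
    t <- t_end
    if (nxt == "exit") { exited <- TRUE; break }
    state <- nxt
  }
  list(path = data.frame(state = st, t_start = t0, t_end = t1), exited = exited)
}

# Along-flow tag position at the frame times, from the state path.
.tag_positions <- function(path, tag, v, t_frames) {
  x <- numeric(length(t_frames))
  x_cur <- 0
  for (r in seq_len(nrow(path))) {
    s <- path$state[r]; a <- path$t_start[r]; b <- path$t_end[r]
    slope <- switch(s, stationary = 0,
                    clutch = if (tag == "C_tag") v else 0,
                    flowing = v)
    # final sojourn owns its right endpoint so the last frame is rendered
    inwin <- if (r < nrow(path)) t_frames >= a & t_frames < b
    else t_frames >= a & t_frames <= b
    x[inwin] <- x_cur + slope * (t_frames[inwin] - a)
    x_end <- x_cur + slope * (b - a)
    nxt <- if (r < nrow(path)) path$state[r + 1] else NA
    if (s == "clutch" && !is.na(nxt)) {
      if (tag == "C_tag" && nxt == "stationary") x_end <- x_cur  # snap back
      if (tag == "N_tag" && nxt == "flowing") x_end <- x_cur + v * (b - a)
    }
    x_cur <- x_end
  }
  x
}

#' Generate a synthetic SiMS track ensemble
#'
#' Simulates n speckles through the clutch kinetic model, renders the
#' fluorophore position according to the tag geometry (C-terminal/actin-end
#' tags advance with the flow during clutch engagement and snap back on
#' disengagement; N-terminal/integrin-end tags stay put during clutch and
#' jump forward by the stretch distance when the clutch releases to flowing),
#' samples at the frame interval, adds isotropic Gaussian localization noise
#' and truncates at photobleaching or the imaging window.
#'
#' @param truth A [kinetic_ground_truth()] object.
#' @param imaging An [imaging_model()] object.
#' @param n Number of tracks.
#' @param seed Integer seed; the ensemble is reproducible given the seed.
#' @param init_state Optional fixed initial state (`"stationary"` or
#'   `"flowing"`); default draws from `truth$appearance_split`.
#' @return A list: `tracks` (data.frame `track_id`, `frame`, `t_s`, `x_nm`,
#'   `y_nm`; flow along +x), `labels` (per-track ground truth: initial and
#'   final state, exit cause, number of clutch episodes, total clutch time),
#'   `paths` (list of state paths), `truth`, `imaging`, `seed`.
#' @export
generate_tracks <- function(truth = kinetic_ground_truth(),
                            imaging = imaging_model(), n, seed = 1L,
                            init_state = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  fi <- imaging$frame_interval
  frames_max <- floor(imaging$window / fi) + 1
  tracks <- vector("list", n)
  labels <- vector("list", n)
  paths <- vector("list", n)
  for (i in seq_len(n)) {
    s0 <- if (!is.null(init_state)) init_state
    else if (runif(1) < truth$appearance_split) "stationary" else "flowing"
    sim <- .sim_clutch_path(truth, s0, imaging$window)
    path <- sim$path
    t_exit <- path$t_end[nrow(path)]
    # visible frames: before exit, before bleach, within window
    tf_all <- seq(0, by = fi, length.out = frames_max)
    n_vis <- if (sim$exited) sum(tf_all < t_exit) else sum(tf_all <= t_exit)
    n_vis <- min(n_vis, frames_max)
    if (imaging$bleach_per_frame > 0) {
      bleach_at <- which(runif(frames_max) < imaging$bleach_per_frame)
      if (length(bleach_at)) n_vis <- min(n_vis, bleach_at[1])
    }
    n_vis <- max(n_vis, 1)
    t_frames <- seq(0, by = fi, length.out = n_vis)
    x <- .tag_positions(path, imaging$tag, imaging$v_retro, t_frames)
    noise_sd <- imaging$localization_sd
    tracks[[i]] <- data.frame(
      track_id = i, frame = seq_len(n_vis), t_s = t_frames,
      x_nm = x + rnorm(n_vis, 0, noise_sd),
      y_nm = rnorm(n_vis, 0, noise_sd))
    labels[[i]] <- data.frame(
      track_id = i, init_state = s0,
      final_state = path$state[nrow(path)],
      exited = sim$exited,
      n_clutch = sum(path$state == "clutch"),
      clutch_time = sum((path$t_end - path$t_start)[path$state == "clutch"]),
      t_end_true = t_exit)
    paths[[i]] <- path
  }
  list(tracks = do.call(rbind, tracks), labels = do.call(rbind, labels),
       paths = paths, truth = truth, imaging = imaging, seed = seed)
}

#' Immobile-speckle fixture
#'
#' Pure Gaussian localization scatter about a fixed point, emulating
#' surface-immobilized single molecules used to measure the localization
#' precision.
#'
#' @param n_frames Number of frames (>= 8).
#' @param sd Localization SD, nm.
#' @param seed Integer seed.
#' @param frame_interval Frame interval, s.
#' @return A track data.frame (`track_id`, `frame`, `t_s`, `x_nm`, `y_nm`).
#' @export
generate_immobile_fixture <- function(n_frames, sd = 18.6, seed = 1L,
                                      frame_interval = 0.1) {
  stopifnot(n_frames >= 8)
  set.seed(seed)
  data.frame(track_id = 1L, frame = seq_len(n_frames),
             t_s = (seq_len(n_frames) - 1) * frame_interval,
             x_nm = rnorm(n_frames, 0, sd),
             y_nm = rnorm(n_frames, 0, sd))
}

#' Apparent coarse-grained rates implied by the clutch kinetic model
#'
#' At a 2-s frame interval the sub-resolution clutch state is invisible for
#' an integrin-end tag, so a stationary-appearing sojourn alternates between
#' true stationary and clutch phases until the molecule either dissociates or
#' the clutch releases toward flowing. First-passage analysis of that
#' phase-type sojourn gives the apparent exponential rates that a
#' coarse-grained measurement recovers.
#'
#' @param truth A [kinetic_ground_truth()] object.
#' @return Named vector `k1`, `k2`, `k3`, `k4` (apparent rates, 1/s).
#' @export
effective_coarse_rates <- function(truth = kinetic_ground_truth()) {
  pa <- truth$k_a / (truth$k1 + truth$k_a)
  pc <- truth$k_c / (truth$k_b + truth$k_c)
  pbs <- truth$k_b / (truth$k_b + truth$k_c)
  pd <- truth$k_d / (truth$k3 + truth$k_d)
  q_S <- pa * pc / (1 - pa * pbs)
  E_TS <- (1 / (truth$k1 + truth$k_a) + pa / (truth$k_b + truth$k_c)) /
    (1 - pa * pbs)
  q_F <- pd * pbs / (1 - pd * pc)
  E_TF <- (1 / (truth$k3 + truth$k_d) + pd / (truth$k_b + truth$k_c)) /
    (1 - pd * pc)
  c(k1 = (1 - q_S) / E_TS, k2 = q_S / E_TS,
    k3 = (1 - q_F) / E_TF, k4 = q_F / E_TF)
}

# Expected fraction of ensemble observation time per state (oracle for the
# occupancy property test): integrate the sub-generator from the appearance
# split.
.expected_occupancy <- function(truth) {
  Q <- matrix(c(-(truth$k1 + truth$k_a), truth$k_a, 0,
                truth$k_b, -(truth$k_b + truth$k_c), truth$k_c,
                0, truth$k_d, -(truth$k3 + truth$k_d)),
              3, 3, byrow = TRUE,
              dimnames = list(c("stationary", "clutch", "flowing"), NULL))
  pi0 <- c(truth$appearance_split, 0, 1 - truth$appearance_split)
  tt <- solve(t(Q), -pi0)
  setNames(tt / sum(tt), rownames(Q))
}

#' End-to-end parameter-recovery experiment
#'
#' Closes the loop between the generator and the analysis pipeline:
#' coarse-mode tracks are generated, classified and segmented; the apparent
#' rates k1-k4 are re-estimated by censored Kaplan-Meier survival analysis
#' with photobleaching correction; a fast-mode integrin-end-tag ensemble is
#' run through the nanometer flow-onset detector to recover the clutch
#' duration, k_c and the jump-distance (delta x) distribution; and the clutch
#' fraction is recomputed by flux balance from the recovered stationary
#' proportion. Recovered values are compared against the generator's own
#' effective rates (see [effective_coarse_rates()]).
#'
#' @param truth A [kinetic_ground_truth()] object.
#' @param imaging Coarse-mode [imaging_model()].
#' @param n Number of coarse-mode tracks.
#' @param seed Integer seed.
#' @param n_fast Number of fast-mode tracks for the delta-x analysis.
#' @param imaging_fast Fast-mode [imaging_model()] (integrin-end tag).
#' @return A list: `rates` (data.frame parameter/true/recovered/rel_error),
#'   `occupancy` (recovered stationary/flowing percent of observations),
#'   `clutch_fraction_percent` (flux-balance C from the recovered S),
#'   `delta_x` (detected jump distances, nm), `modal_bin` (20-nm bin with
#'   most counts), `mean_clutch_duration`, `k_c_recovered`, `seed`.
#' @export
recovery_experiment <- function(truth = kinetic_ground_truth(),
                                imaging = imaging_model("coarse_2s",
                                                        tag = "N_tag"),
                                n = 1000, seed = 1L, n_fast = 1000,
                                imaging_fast = imaging_model("fast_100ms",
                                                             tag = "N_tag")) {
  gen <- generate_tracks(truth, imaging, n, seed = seed)
  fi <- imaging$frame_interval
  frames_max <- floor(imaging$window / fi) + 1
  thr <- 2 * imaging$localization_sd

  # Kinetics use every track with at least one step: restricting to the
  # classification-eligible tracks (lifetime >= 4 s) would left-truncate the
  # sojourn times and inflate them by E[T | T > 4] - E[T]. Appearance-side
  # truncation (a track must survive one frame to be seen at all) is handled
  # by subtracting one frame interval from first-segment durations
  # (memorylessness of the exponential sojourns); the half-frame midpoint
  # correction accounts for the unobserved tail of each segment.
  s_dur <- numeric(0); s_event_k1 <- logical(0); s_event_k2 <- logical(0)
  f_dur <- numeric(0); f_event_k3 <- logical(0); f_event_k4 <- logical(0)
  occ <- c(stat = 0, flow = 0)
  for (id in unique(gen$tracks$track_id)) {
    tr <- gen$tracks[gen$tracks$track_id == id, , drop = FALSE]
    nfr <- nrow(tr)
    if (nfr < 2) next
    p <- .project_flow(tr, c(1, 0))
    labs <- .step_labels(p, thr)
    labs[labs == "counter"] <- "stat"
    segs <- .track_segments(labs, min_run = 2L)
    # segment-level validation: a genuinely stationary segment has a small
    # net along-flow displacement, whereas a spurious "stationary" run
    # inside a flowing stretch (localization noise cancelling the centered
    # step labels) still drifts at the flow speed; relabel such segments
    if (nrow(segs) > 1) {
      net <- p[segs$end_frame] - p[segs$start_frame]
      bad <- segs$label == "stat" & net > thr * segs$n_steps
      if (any(bad)) {
        segs$label[bad] <- "flow"
        keep <- c(TRUE, segs$label[-1] != segs$label[-nrow(segs)])
        grp <- cumsum(keep)
        segs <- data.frame(
          label = segs$label[keep],
          start_frame = as.vector(tapply(segs$start_frame, grp, min)),
          end_frame = as.vector(tapply(segs$end_frame, grp, max)))
        segs$n_steps <- segs$end_frame - segs$start_frame
      }
    }
    # a genuine stationary-to-flowing switch just before the track ends
    # shows fewer than 2 flow steps and would otherwise be absorbed into the
    # stationary segment, deflating k2; keep a short trailing flow run as
    # its own segment (mid-track single-step "flow" labels remain treated as
    # noise)
    rl <- rle(labs)
    nr <- length(rl$values)
    if (nr >= 2 && rl$values[nr] == "flow" && rl$lengths[nr] < 2 &&
        segs$label[nrow(segs)] == "stat") {
      cut <- length(labs) - rl$lengths[nr]
      segs$end_frame[nrow(segs)] <- cut + 1
      segs <- rbind(segs, data.frame(label = "flow", start_frame = cut + 1,
                                     end_frame = length(labs) + 1,
                                     n_steps = rl$lengths[nr]))
    }
    segs$t_start <- tr$t_s[segs$start_frame]
    segs$t_end <- tr$t_s[segs$end_frame]
    at_window_end <- nfr >= frames_max
    for (sgi in seq_len(nrow(segs))) {
      lab <- segs$label[sgi]
      dur <- segs$t_end[sgi] - segs$t_start[sgi] + fi / 2 -
        (if (sgi == 1) fi else 0)
      if (dur <= 0) dur <- fi / 4
      is_last <- sgi == nrow(segs)
      to_flow <- !is_last && segs$label[sgi + 1] == "flow"
      to_stat <- !is_last && segs$label[sgi + 1] == "stat"
      disappeared <- is_last && !at_window_end
      occ[if (lab == "flow") "flow" else "stat"] <-
        occ[if (lab == "flow") "flow" else "stat"] +
        (segs$t_end[sgi] - segs$t_start[sgi])
      if (lab == "stat") {
        s_dur <- c(s_dur, dur)
        s_event_k1 <- c(s_event_k1, disappeared)
        s_event_k2 <- c(s_event_k2, to_flow)
      } else if (lab == "flow") {
        f_dur <- c(f_dur, dur)
        f_event_k3 <- c(f_event_k3, disappeared)
        f_event_k4 <- c(f_event_k4, to_stat)
      }
    }
  }
  bl <- if (imaging$bleach_per_frame > 0) imaging$bleach_per_frame else NULL
  k1_est <- km_exponential_rate(s_dur, censored = !s_event_k1,
                                bleach_per_frame = bl, frame_interval = fi)
  k2_est <- km_exponential_rate(s_dur, censored = !s_event_k2)
  k3_est <- km_exponential_rate(f_dur, censored = !f_event_k3,
                                bleach_per_frame = bl, frame_interval = fi)
  k4_est <- km_exponential_rate(f_dur, censored = !f_event_k4)
  eff <- effective_coarse_rates(truth)
  recovered <- c(k1_est$rate, k2_est$rate, k3_est$rate, k4_est$rate)
  rates <- data.frame(parameter = c("k1", "k2", "k3", "k4"),
                      true = as.numeric(eff), recovered = recovered,
                      rel_error = (recovered - as.numeric(eff)) /
                        as.numeric(eff))

  S_occ <- 100 * occ["stat"] / sum(occ)
  C_flux <- clutch_flux_balance(
    as.numeric(S_occ),
    list(k_a = truth$k_a, k_b = truth$k_b, k_c = truth$k_c, k_d = truth$k_d,
         k_2 = truth$k2, k_4 = truth$k4))$C

  # fast-mode delta-x analysis on stationary-appearing integrin-end tags
  # Delta-x ensemble: the switching events quantified by the onset detector
  # are the clutch episodes that release toward flowing; their measured
  # duration distribution defines k_c as a first-order rate, so the emulated
  # durations are drawn as Exp(k_c) (k_b = 0 in the generator for this
  # ensemble only).
  truth_dx <- kinetic_ground_truth(k1 = truth$k1, k2 = truth$k2,
                                   k3 = truth$k3, k4 = truth$k4,
                                   k_a = truth$k_a, k_b = 0,
                                   k_c = truth$k_c, k_d = truth$k_d,
                                   appearance_split = 1)
  genf <- generate_tracks(truth_dx, imaging_fast, n_fast,
                          seed = seed + 1L, init_state = "stationary")
  dx <- numeric(0); cdur <- numeric(0)
  for (i in unique(genf$tracks$track_id)) {
    tr <- genf$tracks[genf$tracks$track_id == i, , drop = FALSE]
    ons <- detect_flow_onset(tr, flow_axis = c(1, 0))
    if (!ons$applicable || is.na(ons$t_detect)) next
    # accept only detections whose flowing segment sustains a significantly
    # positive along-flow drift (>= 5 post-detection frames, slope more than
    # twice its standard error): isolated noise excursions over the 1-SD
    # onset threshold are otherwise counted as switching events
    flow_idx <- which(tr$t_s >= ons$t_detect)
    if (length(flow_idx) < 5) next
    p <- .project_flow(tr, c(1, 0))[flow_idx]
    fit <- summary(lm(p ~ tr$t_s[flow_idx]))$coefficients
    if (fit[2, 1] <= 0 || fit[2, 1] < 2 * fit[2, 2]) next
    if (ons$delta_x > 0) {
      dx <- c(dx, ons$delta_x)
      cdur <- c(cdur, ons$delta_x / ons$flow_speed)
    }
  }
  modal_bin <- c(NA_real_, NA_real_)
  if (length(dx)) {
    breaks <- seq(0, 20 * ceiling(max(dx) / 20), by = 20)
    h <- findInterval(dx, breaks, rightmost.closed = TRUE)
    mb <- as.integer(names(which.max(table(h))))
    modal_bin <- c(breaks[mb], breaks[mb + 1])
  }
  mean_cd <- if (length(cdur)) mean(cdur) else NA_real_
  list(rates = rates,
       occupancy = c(S_percent = as.numeric(S_occ),
                     F_percent = 100 - as.numeric(S_occ)),
       clutch_fraction_percent = C_flux,
       delta_x = dx, modal_bin = modal_bin,
       mean_clutch_duration = mean_cd,
       k_c_recovered = if (is.na(mean_cd)) NA_real_ else 1 / mean_cd,
       n_detected = length(dx), seed = seed)
}
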