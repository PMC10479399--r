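# Shared helpers: fast simulation parameter sets and programmatic track
# fixtures used across the unit tests.

# Coarse-timestep overdamped parameters for ensemble tests: the bead
# relaxation time zeta/k = 1e-4 s stays far below every kinetic timescale,
# so the quasi-static tension is preserved while 10x fewer steps are needed.
fast_sim <- function(dt_sim = 1e-5, ...) {
  sim_params(zeta = 1e-3, dt_sim = dt_sim, rate_update_every = 10L, ...)
}

# Noiseless single-mode track: along-flow step sizes given per frame.
make_track <- function(steps_nm, frame_interval, id = 1L) {
  x <- cumsum(c(0, steps_nm))
  data.frame(track_id = id, frame = seq_along(x),
             t_s = (seq_along(x) - 1) * frame_interval,
             x_nm = x, y_nm = 0)
}

# One noiseless fixture with a known classification category.
# Step sizes: 60 nm/frame coarse flow (v = 30 nm/s at 2 s), 6 nm fast flow.
make_category_fixture <- function(category, mode, id = 1L) {
  if (mode == "coarse_2s") {
    fi <- 2; fl <- 60
    switch(category,
      flowing = make_track(rep(fl, 8), fi, id),
      stationary = make_track(rep(0, 8), fi, id),
      switching = make_track(c(rep(0, 6), rep(fl, 6)), fi, id),
      stop("bad category"))
  } else {
    fi <- 0.1; fl <- 6   # minimum lifetime 2 s = 21 frames at 100 ms
    switch(category,
      flowing = make_track(rep(fl, 25), fi, id),
      stationary = make_track(rep(0, 25), fi, id),
      switching = make_track(c(rep(0, 12), rep(fl, 12)), fi, id),
      back_and_forth = make_track(c(rep(fl, 9), rep(-fl, 2), rep(0, 10)),
                                  fi, id),
      stop("bad category"))
  }
}
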