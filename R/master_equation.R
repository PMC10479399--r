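# Discrete-time master equation over the number (or identity) of unfolded
# rod subdomains of a single integrin-bound Talin chain under retrograde
# loading, with unbinding as an absorbing exit.
#
# Scheme (explicit, start-of-step tension):
#   P_j(t) = sum_i A_ij(t, dt) P_i(t - dt) - p_j^unbind(t, dt) P_j(t - dt)
# where A is the binomial redistribution of additional unfolds and
# P_unbound = 1 - sum_j P_j, so probability is conserved by construction.

#' Per-step transition probability of a Poisson event
#'
#' p = 1 - exp(-k dt), elementwise over rates.
#'
#' @param rates Non-negative rates, 1/s.
#' @param dt Time step, s.
#' @return Probabilities in \[0, 1).
#' @export
step_probabilities <- function(rates, dt) {
  stopifnot(dt > 0, all(rates >= 0))
  1 - exp(-rates * dt)
}

#' One row of the unfolding redistribution matrix
#'
#' A_ij is the probability that j - i of the M - i still-folded subdomains
#' unfold within one step, i.e. the binomial pmf with M - i trials and
#' per-domain probability `p_unfold`; entries with j < i are zero.
#'
#' @param M Number of unfoldable subdomains.
#' @param i Number already unfolded at the start of the step.
#' @param p_unfold Per-domain unfolding probability for this step.
#' @return Numeric vector of length M + 1 (states j = 0..M) summing to 1.
#' @export
unfold_transition_row <- function(M, i, p_unfold) {
  stopifnot(i >= 0, i <= M, p_unfold >= 0, p_unfold <= 1)
  row <- numeric(M + 1)
  row[(i + 1):(M + 1)] <- dbinom(0:(M - i), M - i, p_unfold)
  row
}

#' Solve the homogeneous master equation of the Talin clutch
#'
#' Evolves the probabilities P_j(t) of remaining integrin-bound with j of M
#' identical unfoldable subdomains unfolded, under uniform tension recomputed
#' every step from the force balance at the current total chain length.
#' Terminates when the unbound probability exceeds `p_terminate` or at
#' `t_max`.
#'
#' @param config A [chain_config()] object.
#' @param mech A [mechanical_params()] object.
#' @param unfold A [bell_params()] object: Bell-law unfolding parameters
#'   shared by all unfoldable subdomains.
#' @param unbind A [bell_params()] or [catch_slip_params()] object for the
#'   integrin-Talin bond.
#' @param dt Time step, s.
#' @param t_max Maximum simulated time, s.
#' @param p_terminate Stop once P_unbound exceeds this.
#' @return An object of class `talin_me_result`: `time` (step-end grid),
#'   `P` (matrix (M+1) x (nt+1), column 1 the initial condition), `P_unbound`,
#'   `tension` (per state and step start), `unbind_mass` (per state and step),
#'   `converged`, and `observables` (see [me_observables()]).
#' @export
master_equation <- function(config = chain_config(), mech = mechanical_params(),
                            unfold = unfolding_defaults(),
                            unbind = unbinding_defaults(),
                            dt = 1e-3, t_max = 120, p_terminate = 0.999) {
  stopifnot(dt > 0, t_max > dt, p_terminate > 0, p_terminate <= 1)
  M <- config$n_unfoldable
  kT <- mech$kT
  unbind_rate <- .unbind_rate_fun(unbind, kT)
  n_max <- ceiling(t_max / dt)
  js <- 0:M

  P <- matrix(0, M + 1, n_max + 1)
  P[1, 1] <- 1
  tension <- matrix(0, M + 1, n_max)
  unbind_mass <- matrix(0, M + 1, n_max)
  P_unb <- numeric(n_max)
  tau <- rep(0, M + 1)
  A <- matrix(0, M + 1, M + 1)
  p_cur <- P[, 1]
  cum_unb <- 0
  n_used <- n_max
  warned <- FALSE

  for (n in seq_len(n_max)) {
    t0 <- (n - 1) * dt
    L <- total_length(t0, config, mech)
    tau <- .solve_tension_vec(rep(L, M + 1), js, config, mech, tau_init = tau)
    tension[, n] <- tau
    p_unf <- step_probabilities(bell_rate(tau, unfold, kT), dt)
    p_unb <- step_probabilities(unbind_rate(tau), dt)
    if (any(p_unb[p_cur > 1e-8] > 0.2) && !warned) {
      warning("per-step unbinding probability exceeds 0.2 at t = ",
              signif(t0, 4), "; decrease dt", call. = FALSE)
      warned <- TRUE
    }
    for (i in 0:M)
      A[i + 1, ] <- unfold_transition_row(M, i, p_unf[i + 1])
    m <- p_unb * p_cur
    new_p <- drop(p_cur %*% A) - m
    if (any(new_p < -1e-12))
      stop("probability out of [0,1]: decrease dt")
    unbind_mass[, n] <- m
    cum_unb <- cum_unb + sum(m)
    p_cur <- new_p
    P[, n + 1] <- p_cur
    P_unb[n] <- cum_unb
    if (cum_unb > p_terminate) { n_used <- n; break }
  }

  res <- structure(list(
    time = dt * seq_len(n_used), dt = dt,
    P = P[, 1:(n_used + 1), drop = FALSE],
    P_unbound = P_unb[1:n_used],
    tension = tension[, 1:n_used, drop = FALSE],
    unbind_mass = unbind_mass[, 1:n_used, drop = FALSE],
    config = config, mech = mech,
    converged = P_unb[n_used] > p_terminate
  ), class = "talin_me_result")
  res$observables <- me_observables(res)
  res
}

#' Observables of a master-equation solution
#'
#' Mean clutch duration, mean work done on actin, the unbinding-time and
#' unbinding-displacement densities (x = v_retro t), and the maximum-force
#' (force-at-unbinding) histogram. The work accumulates the flow-axis
#' component of the ensemble tension times the flow displacement per step.
#'
#' @param result A `talin_me_result` from [master_equation()].
#' @param fmax_bin Bin width of the maximum-force histogram, pN.
#' @return A list with `mean_clutch_duration` (s), `mean_work` (pN nm),
#'   `mean_unbind_displacement` (nm), `work_t` (cumulative work over time),
#'   `unbind_time_density` (1/s), `unbind_displacement_density` (1/nm),
#'   `fmax_hist` (data.frame of force-bin edges and probability mass),
#'   `terminal_P_unbound`, and `converged`.
#' @export
me_observables <- function(result, fmax_bin = 0.5) {
  stopifnot(inherits(result, "talin_me_result"))
  dt <- result$dt
  tt <- result$time
  cfg <- result$config
  v <- cfg$v_retro
  nt <- length(tt)
  if (!result$converged)
    warning("master equation run not converged; observables are partial",
            call. = FALSE)
  dP <- colSums(result$unbind_mass)                    # mass unbinding per step
  p_end <- result$P_unbound[nt]
  mean_t <- sum(tt * dP) / p_end
  cosphi <- flow_direction_cosine(tt - dt, cfg, result$mech)
  # ensemble tension (bound states only) at each step start
  Fens <- colSums(result$tension * result$P[, 1:nt, drop = FALSE])
  work_t <- cumsum(Fens * cosphi * v * dt)
  # maximum-force histogram: unbind mass binned by tension at unbinding
  fvals <- as.vector(result$tension)
  w <- as.vector(result$unbind_mass)
  keep <- w > 0
  if (any(keep)) {
    breaks <- seq(0, max(fvals[keep]) + fmax_bin, by = fmax_bin)
    bin <- findInterval(fvals[keep], breaks, rightmost.closed = TRUE)
    mass <- vapply(seq_len(length(breaks) - 1),
                   function(b) sum(w[keep][bin == b]), numeric(1))
    fmax_hist <- data.frame(f_lo = breaks[-length(breaks)],
                            f_hi = breaks[-1], mass = mass)
  } else {
    fmax_hist <- data.frame(f_lo = numeric(0), f_hi = numeric(0),
                            mass = numeric(0))
  }
  list(mean_clutch_duration = mean_t,
       mean_work = work_t[nt],
       mean_unbind_displacement = v * mean_t,
       work_t = work_t,
       unbind_time_density = dP / dt,
       unbind_displacement_density = if (v > 0) dP / (v * dt) else rep(NA_real_, nt),
       fmax_hist = fmax_hist,
       terminal_P_unbound = p_end,
       converged = result$converged)
}

#' Parameter sweep of master-equation observables
#'
#' Runs [master_equation()] over a grid of chain parameters and tabulates the
#' mean clutch duration, mean work and mean unbinding displacement.
#'
#' @param vary Named list of parameter grids; names among `n_unfoldable`,
#'   `n_total`, `theta0`, `v_retro`, `dx_unbind`. The full factorial grid is
#'   explored.
#' @param config,mech,unfold,unbind,dt,t_max,p_terminate As in
#'   [master_equation()]; `config` supplies the non-varied values.
#' @return A data.frame with one row per grid point.
#' @export
me_sweep <- function(vary, config = chain_config(), mech = mechanical_params(),
                     unfold = unfolding_defaults(),
                     unbind = unbinding_defaults(),
                     dt = 1e-3, t_max = 120, p_terminate = 0.999) {
  allowed <- c("n_unfoldable", "n_total", "theta0", "v_retro", "dx_unbind")
  if (!length(vary) || is.null(names(vary)) || !all(names(vary) %in% allowed))
    stop("vary must be a named list over: ", paste(allowed, collapse = ", "))
  grid <- expand.grid(vary, KEEP.OUT.ATTRS = FALSE)
  out <- grid
  out$mean_clutch_duration <- NA_real_
  out$mean_work <- NA_real_
  out$mean_unbind_displacement <- NA_real_
  for (r in seq_len(nrow(grid))) {
    cfg <- config
    ub <- unbind
    for (nm in names(grid)) {
      if (nm == "dx_unbind") ub <- bell_params(ub$k0, grid[r, nm])
      else cfg[[nm]] <- grid[r, nm]
    }
    if (cfg$n_unfoldable > cfg$n_total)
      stop("n_unfoldable exceeds n_total in sweep grid")
    cfg <- chain_config(cfg$n_total, cfg$n_unfoldable, cfg$theta0, cfg$v_retro)
    res <- master_equation(cfg, mech, unfold, ub, dt = dt, t_max = t_max,
                           p_terminate = p_terminate)
    obs <- res$observables
    out$mean_clutch_duration[r] <- obs$mean_clutch_duration
    out$mean_work[r] <- obs$mean_work
    out$mean_unbind_displacement[r] <- obs$mean_unbind_displacement
  }
  out
}

#' Calibrate the unbinding barrier distance against a displacement histogram
#'
#' Scans a grid of candidate barrier distances, solves the master equation at
#' each, and scores the model's unbinding-displacement distribution against
#' the target histogram by a chi-square discrepancy on the target's bins.
#'
#' @param target A list with `breaks` (bin edges, nm, increasing) and
#'   `counts` (observed counts per bin, length `length(breaks) - 1`).
#' @param grid Candidate barrier distances, nm, in (0, 5].
#' @param k_unbind0 Zero-force unbinding rate held fixed during calibration.
#' @param config,mech,unfold,dt,t_max As in [master_equation()].
#' @return The grid value minimising the discrepancy, with attributes
#'   `objective` (the full scan) and a warning listing ties if the objective
#'   is flat at its minimum.
#' @export
calibrate_dx_unbind <- function(target, grid, k_unbind0 = 0.17,
                                config = chain_config(),
                                mech = mechanical_params(),
                                unfold = unfolding_defaults(),
                                dt = 1e-3, t_max = 120) {
  stopifnot(is.list(target), length(target$counts) >= 1,
            length(target$breaks) == length(target$counts) + 1,
            all(diff(target$breaks) > 0), sum(target$counts) > 0,
            all(grid > 0), all(grid <= 5))
  total <- sum(target$counts)
  obj <- vapply(grid, function(dx) {
    res <- master_equation(config, mech, unfold, bell_params(k_unbind0, dx),
                           dt = dt, t_max = t_max)
    x <- res$config$v_retro * res$time
    dP <- colSums(res$unbind_mass)
    bin <- findInterval(x, target$breaks, rightmost.closed = TRUE)
    inb <- bin >= 1 & bin <= length(target$counts)
    mass <- vapply(seq_along(target$counts),
                   function(b) sum(dP[inb][bin[inb] == b]), numeric(1))
    if (sum(mass) <= 0) return(Inf)
    expected <- total * mass / sum(mass)
    sum((target$counts - expected)^2 / pmax(expected, 1e-12))
  }, numeric(1))
  best <- which(obj == min(obj))
  if (length(best) > 1)
    warning("flat calibration objective; ties at dx = ",
            paste(signif(grid[best], 4), collapse = ", "), call. = FALSE)
  structure(grid[best[1]], objective = data.frame(dx = grid, chisq = obj))
}
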