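# R surface of the stochastic bead-spring pulling simulation.

#' Initial bead positions of a Talin pulling simulation
#'
#' All springs start at their rest lengths along a straight line at angle
#' `theta0` to the substrate: N + 3 beads (integrin anchor, N + 1 chain
#' beads, actin bead). The finite-compliance variant appends a substrate bead
#' and an actin-network bead co-located with the chain ends (zero-rest-length
#' anchoring springs).
#'
#' @param config A [chain_config()] object.
#' @param mech A [mechanical_params()] object.
#' @param sim A [sim_params()] object (only `compliance_k3` matters here).
#' @return A data.frame with columns `x`, `y` (nm) and `role` (one of
#'   `"anchor"`, `"chain"`, `"actin"`, `"substrate"`, `"network"`).
#' @export
init_chain <- function(config = chain_config(), mech = mechanical_params(),
                       sim = sim_params()) {
  th <- config$theta0 * pi / 180
  nb <- config$n_total + 3
  d <- (seq_len(nb) - 1) * mech$l_folded0
  out <- data.frame(x = d * cos(th), y = d * sin(th),
                    role = c("anchor", rep("chain", config$n_total + 1),
                             "actin"))
  if (!is.null(sim$compliance_k3)) {
    out <- rbind(out,
                 data.frame(x = out$x[c(1, nb)], y = out$y[c(1, nb)],
                            role = c("substrate", "network")))
  }
  out
}

.kinetics_args <- function(config, unfold, unbind) {
  N <- config$n_total
  if (inherits(unfold, "bell_params")) {
    sd_spec <- subdomain_spec(rep(unfold$k0, N), rep(unfold$dx, N),
                              unfoldable = seq_len(N) <= config$n_unfoldable)
  } else if (inherits(unfold, "subdomain_spec")) {
    sd_spec <- unfold
    if (length(sd_spec$k0) != N)
      stop("subdomain_spec length must equal n_total")
    if (sum(sd_spec$unfoldable) != config$n_unfoldable)
      stop("number of unfoldable subdomains must equal config$n_unfoldable")
  } else stop("unfold must be bell_params or subdomain_spec")
  if (inherits(unbind, "bell_params")) {
    list(sd = sd_spec, model = 0L, par = c(unbind$k0, unbind$dx))
  } else if (inherits(unbind, "catch_slip_params")) {
    list(sd = sd_spec, model = 1L,
         par = c(unbind$k10_0, unbind$k12_0, unbind$k21_0, unbind$k20_0,
                 unbind$x10, unbind$x20, unbind$x12, unbind$x21))
  } else stop("unbind must be bell_params or catch_slip_params")
}

#' Run one stochastic Talin pulling trace
#'
#' Forward-Euler overdamped dynamics of the bead-spring chain with Monte
#' Carlo unfolding and unbinding events drawn from accumulated Bell-law
#' hazards of the local segment tensions. The trace terminates at unbinding
#' (or is censored at `sim$max_time`).
#'
#' @param config A [chain_config()] object.
#' @param mech A [mechanical_params()] object.
#' @param unfold A [bell_params()] (uniform subdomains) or
#'   [subdomain_spec()].
#' @param unbind A [bell_params()] or [catch_slip_params()] object.
#' @param sim A [sim_params()] object.
#' @param seed Integer seed; identical seeds give identical traces.
#' @return A list of class `talin_pulling_trace`: `unbind_time` (s, NA if
#'   censored), `work` (pN nm), `n_unfolds`, `censored`, `events`
#'   (data.frame time/type/tension; type 0 is the unbind event, 1..N the rod
#'   segment that unfolded), `final_positions`, `seed`.
#' @export
run_pulling <- function(config = chain_config(), mech = mechanical_params(),
                        unfold = unfolding_defaults(),
                        unbind = unbinding_defaults(),
                        sim = sim_params(), seed = sim$seed) {
  .check_sim_stability(sim, mech)
  ka <- .kinetics_args(config, unfold, unbind)
  set.seed(seed)
  out <- run_pulling_cpp(config$n_total, config$theta0, config$v_retro,
                         mech$k_f, mech$l_folded0, mech$kuhn_b, mech$n_res,
                         mech$kT,
                         ka$sd$k0, ka$sd$dx, ka$sd$unfoldable,
                         ka$model, ka$par,
                         sim$zeta, sim$dt_sim, sim$rate_update_every,
                         sim$max_time,
                         if (is.null(sim$compliance_k3)) 0 else sim$compliance_k3,
                         !is.null(sim$compliance_k3))
  out$seed <- seed
  class(out) <- "talin_pulling_trace"
  out
}

#' Run an ensemble of pulling simulations
#'
#' @inheritParams run_pulling
#' @param n Ensemble size (overrides `sim$n_realizations` when given).
#' @param base_seed Seed of the ensemble RNG stream.
#' @return A list of class `talin_pulling_ensemble`: `traces` (data.frame
#'   with per-trace `trace`, `t_unbind_s`, `work_pN_nm`, `n_unfolds`,
#'   `censored`), `mean_unbind_time`, `se_unbind_time`, `mean_work`,
#'   `se_work`, `base_seed`.
#' @export
run_pulling_ensemble <- function(config = chain_config(),
                                 mech = mechanical_params(),
                                 unfold = unfolding_defaults(),
                                 unbind = unbinding_defaults(),
                                 sim = sim_params(),
                                 n = sim$n_realizations,
                                 base_seed = sim$seed) {
  stopifnot(n >= 1)
  .check_sim_stability(sim, mech)
  ka <- .kinetics_args(config, unfold, unbind)
  set.seed(base_seed)
  tu <- numeric(n); wk <- numeric(n); nu <- integer(n); cs <- logical(n)
  for (r in seq_len(n)) {
    out <- run_pulling_cpp(config$n_total, config$theta0, config$v_retro,
                           mech$k_f, mech$l_folded0, mech$kuhn_b, mech$n_res,
                           mech$kT,
                           ka$sd$k0, ka$sd$dx, ka$sd$unfoldable,
                           ka$model, ka$par,
                           sim$zeta, sim$dt_sim, sim$rate_update_every,
                           sim$max_time,
                           if (is.null(sim$compliance_k3)) 0 else sim$compliance_k3,
                           !is.null(sim$compliance_k3))
    tu[r] <- out$unbind_time; wk[r] <- out$work
    nu[r] <- out$n_unfolds; cs[r] <- out$censored
  }
  ok <- !cs
  structure(list(
    traces = data.frame(trace = seq_len(n), t_unbind_s = tu,
                        work_pN_nm = wk, n_unfolds = nu, censored = cs),
    mean_unbind_time = mean(tu[ok]),
    se_unbind_time = stats::sd(tu[ok]) / sqrt(sum(ok)),
    mean_work = mean(wk[ok]),
    se_work = stats::sd(wk[ok]) / sqrt(sum(ok)),
    n = n, n_censored = sum(cs), base_seed = base_seed
  ), class = "talin_pulling_ensemble")
}
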