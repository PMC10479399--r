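# Heterogeneous-subdomain master equation: the state is the identity (not
# just the number) of unfolded subdomains, a binary array over the M
# unfoldable rod subdomains. Mechanics depend only on the unfolded count, so
# the tension solve is shared across states of equal count.

#' Solve the heterogeneous-subdomain master equation
#'
#' Each unfoldable rod subdomain j carries its own Bell parameters
#' (k_unfold0_j, dx_unfold_j); the chain state sigma is the set of unfolded
#' subdomains (2^M states). Within one step the additional unfolds are drawn
#' independently per still-folded domain, the exact multi-event analogue of
#' the binomial redistribution of the homogeneous scheme.
#'
#' @param config A [chain_config()] object; `config$n_unfoldable` must equal
#'   the number of unfoldable entries of `subdomains`.
#' @param mech A [mechanical_params()] object.
#' @param subdomains A [subdomain_spec()] of length `config$n_total`.
#' @param unbind A [bell_params()] or [catch_slip_params()] object.
#' @param dt,t_max,p_terminate As in [master_equation()].
#' @param max_M Guard on the 2^M state space.
#' @return An object of class `talin_me_het_result` with `time`,
#'   `P_state` (2^M x (nt+1); states indexed by bitmask + 1), `P_count`
#'   (count-aggregated probabilities, (M+1) x (nt+1)), `P_unbound`,
#'   `tension` (per count), `unbind_mass` (per count) and `observables`.
#' @export
master_equation_het <- function(config, mech = mechanical_params(),
                                subdomains, unbind = unbinding_defaults(),
                                dt = 1e-3, t_max = 120, p_terminate = 0.999,
                                max_M = 20) {
  stopifnot(inherits(subdomains, "subdomain_spec"),
            length(subdomains$k0) == config$n_total)
  uf <- which(subdomains$unfoldable)
  M <- length(uf)
  if (M != config$n_unfoldable)
    stop("config$n_unfoldable must match the number of unfoldable subdomains")
  if (M > max_M) stop("state space 2^M too large (M = ", M, ")")
  kT <- mech$kT
  unbind_rate <- .unbind_rate_fun(unbind, kT)
  k0u <- subdomains$k0[uf]
  dxu <- subdomains$dx[uf]

  n_states <- 2^M
  masks <- 0:(n_states - 1)
  count_of <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(M - 1))) > 0L),
                     numeric(1))
  folded_of <- lapply(masks, function(m) which(bitwAnd(m, 2^(0:(M - 1))) == 0L))
  # transition table: every (sigma, D subset of folded(sigma)) pair
  from <- integer(0); to <- integer(0); Dlist <- list(); Rlist <- list()
  for (s in seq_len(n_states)) {
    f <- folded_of[[s]]
    # enumerate subsets D of the still-folded set f
    Ds <- list(integer(0))
    for (j in f) Ds <- c(Ds, lapply(Ds, function(d) c(d, j)))
    for (d in Ds) {
      from <- c(from, s)
      to <- c(to, s + sum(2^(d - 1)))
      Dlist[[length(Dlist) + 1L]] <- d
      Rlist[[length(Rlist) + 1L]] <- setdiff(f, d)  # stay folded
    }
  }
  n_pairs <- length(from)

  n_max <- ceiling(t_max / dt)
  Ps <- matrix(0, n_states, n_max + 1)
  Ps[1, 1] <- 1
  tension <- matrix(0, M + 1, n_max)
  unbind_mass <- matrix(0, M + 1, n_max)
  P_unb <- numeric(n_max)
  tau <- rep(0, M + 1)
  p_cur <- Ps[, 1]
  cum_unb <- 0
  n_used <- n_max
  counts1 <- count_of + 1          # 1-based count index per state

  for (n in seq_len(n_max)) {
    t0 <- (n - 1) * dt
    L <- total_length(t0, config, mech)
    tau <- .solve_tension_vec(rep(L, M + 1), 0:M, config, mech, tau_init = tau)
    tension[, n] <- tau
    # q[j, i+1]: per-step unfold probability of subdomain j at count i
    q <- matrix(0, M, M + 1)
    for (i in 0:M)
      q[, i + 1] <- step_probabilities(
        k0u * exp(pmin(tau[i + 1] * dxu / kT, 700)), dt)
    p_unb <- step_probabilities(unbind_rate(tau), dt)
    w <- numeric(n_pairs)
    for (p in seq_len(n_pairs)) {
      s <- from[p]; d <- Dlist[[p]]; rest <- Rlist[[p]]
      w[p] <- prod(q[d, counts1[s]]) * prod(1 - q[rest, counts1[s]])
    }
    flow <- w * p_cur[from]
    new_p <- numeric(n_states)
    agg <- rowsum(flow, group = to)
    new_p[as.integer(rownames(agg))] <- agg[, 1]
    m_state <- p_unb[counts1] * p_cur
    new_p <- new_p - m_state
    um <- numeric(M + 1)
    agg2 <- rowsum(m_state, group = counts1)
    um[as.integer(rownames(agg2))] <- agg2[, 1]
    unbind_mass[, n] <- um
    cum_unb <- cum_unb + sum(m_state)
    p_cur <- new_p
    Ps[, n + 1] <- p_cur
    P_unb[n] <- cum_unb
    if (cum_unb > p_terminate) { n_used <- n; break }
  }

  P_count <- matrix(0, M + 1, n_used + 1)
  for (cidx in 1:(M + 1))
    P_count[cidx, ] <- colSums(Ps[counts1 == cidx, 1:(n_used + 1), drop = FALSE])

  res <- structure(list(
    time = dt * seq_len(n_used), dt = dt,
    P = P_count,                       # count-aggregated, same shape contract
    P_state = Ps[, 1:(n_used + 1), drop = FALSE],
    P_unbound = P_unb[1:n_used],
    tension = tension[, 1:n_used, drop = FALSE],
    unbind_mass = unbind_mass[, 1:n_used, drop = FALSE],
    config = config, mech = mech,
    converged = P_unb[n_used] > p_terminate
  ), class = c("talin_me_het_result", "talin_me_result"))
  res$observables <- me_observables(res)
  res
}
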