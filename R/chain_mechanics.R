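# Force laws and geometry of the bead-spring Talin chain.
#
# Folded rod subdomains (and the two end linkers) are Hookean, tensile only;
# unfolded subdomains follow freely-jointed-chain (FJC) entropic elasticity.
# All internal units: pN, nm, s.

# Langevin function L(y) = coth(y) - 1/y, stable near 0 via its series.
.langevin <- function(y) {
  out <- y
  small <- abs(y) < 1e-4
  out[small] <- y[small] / 3 - y[small]^3 / 45
  ys <- y[!small]
  out[!small] <- 1 / tanh(ys) - 1 / ys
  out
}

# dL/dy = 1 - coth(y)^2 + 1/y^2, -> 1/3 as y -> 0
.langevin_prime <- function(y) {
  out <- y
  small <- abs(y) < 1e-4
  out[small] <- 1 / 3 - y[small]^2 / 15
  ys <- y[!small]
  cth <- 1 / tanh(ys)
  out[!small] <- 1 - cth^2 + 1 / ys^2
  out
}

#' Inverse Langevin function
#'
#' Solves coth(y) - 1/y = x for y >= 0, by Newton iteration seeded with the
#' Pade approximant y0 = x (3 - x^2) / (1 - x^2). Used for the FJC
#' force-extension law of unfolded subdomains.
#'
#' @param x Fractional extension(s), in \[0, 1).
#' @param tol Relative tolerance of the Newton iteration.
#' @return y >= 0 such that the Langevin function of y equals x.
#' @export
#' @examples
#' inverse_langevin(0.5)
inverse_langevin <- function(x, tol = 1e-10) {
  if (any(!is.finite(x)) || any(x < 0) || any(x >= 1))
    stop("inverse_langevin: x must lie in [0, 1)")
  y <- x * (3 - x^2) / (1 - x^2)
  for (i in 1:50) {
    f <- .langevin(y) - x
    step <- f / .langevin_prime(y)
    y <- pmax(y - step, 0)
    if (max(abs(step) / pmax(y, 1)) < tol) break
  }
  y
}

#' Force of a folded (Hookean) segment
#'
#' Tensile-only spring: zero force below the rest length (the loading
#' protocol only lengthens the chain, so compressed springs carry no force).
#'
#' @param l Segment end-to-end length(s), nm.
#' @param params A [mechanical_params()] object.
#' @return Force, pN.
#' @export
folded_force <- function(l, params = mechanical_params()) {
  stopifnot(all(l >= 0))
  pmax(params$k_f * (l - params$l_folded0), 0)
}

#' Force of an unfolded segment (freely jointed chain)
#'
#' F = (kT / b) Linv(l / (b n)), diverging as l approaches the contour
#' length b n.
#'
#' @param l Segment end-to-end length(s), nm; must be below the contour length.
#' @param params A [mechanical_params()] object.
#' @return Force, pN.
#' @export
unfolded_force <- function(l, params = mechanical_params()) {
  if (any(l < 0) || any(l >= params$l_contour))
    stop("unfolded_force: length must lie in [0, contour length)")
  (params$kT / params$kuhn_b) * inverse_langevin(l / params$l_contour)
}

# FJC end-to-end extension at tension tau (inverse of unfolded_force)
.fjc_extension <- function(tau, params) {
  params$l_contour * .langevin(tau * params$kuhn_b / params$kT)
}

#' Total anchor-to-actin chain length under retrograde loading
#'
#' The integrin anchor is fixed and the actin end advances at `v_retro` along
#' the flow; with initial straight-chain length L0 = (N + 2) l_folded0 at
#' angle theta0, the end-to-end distance is
#' sqrt(L0^2 + 2 L0 v t cos(theta0) + v^2 t^2).
#'
#' @param t Time(s) since linkage formation, s.
#' @param config A [chain_config()] object.
#' @param params A [mechanical_params()] object.
#' @return Length, nm.
#' @export
total_length <- function(t, config = chain_config(),
                         params = mechanical_params()) {
  stopifnot(all(t >= 0))
  L0 <- (config$n_total + 2) * params$l_folded0
  v <- config$v_retro
  ct <- cos(config$theta0 * pi / 180)
  sqrt(L0^2 + 2 * L0 * v * t * ct + (v * t)^2)
}

#' Cosine of the angle between the chain axis and the flow direction
#'
#' Geometry helper for projecting the uniform tension onto the retrograde
#' flow axis (the chain is a straight line between anchors in the
#' master-equation picture): (L0 cos(theta0) + v t) / L_tot(t).
#'
#' @inheritParams total_length
#' @return Dimensionless value in (0, 1\]; tends to 1 as the chain aligns
#'   with the flow.
#' @export
flow_direction_cosine <- function(t, config = chain_config(),
                                  params = mechanical_params()) {
  stopifnot(all(t >= 0))
  L0 <- (config$n_total + 2) * params$l_folded0
  ct <- cos(config$theta0 * pi / 180)
  (L0 * ct + config$v_retro * t) / total_length(t, config, params)
}

# Vectorised uniform-tension solve for several unfolded counts at once.
# For each pair (L_tot[m], i[m]) finds tau >= 0 with
#   i * l_u(tau) + (N + 2 - i) * l_f(tau) = L_tot,
# where l_f = l_folded0 + tau/k_f and l_u is the FJC extension. The left side
# is strictly increasing in tau, so a safeguarded warm-started Newton
# iteration converges; tau = 0 whenever the chain is slack.
.solve_tension_vec <- function(L_tot, i, config, params, tau_init = NULL,
                               tol = 1e-9, max_iter = 200) {
  nseg <- config$n_total + 2
  nf <- nseg - i
  rest <- nf * params$l_folded0
  slack <- L_tot <= rest
  tau <- if (is.null(tau_init)) rep(1, length(L_tot)) else pmax(tau_init, 1e-8)
  act <- which(!slack)
  if (length(act)) {
    taua <- tau[act]
    for (iter in 1:max_iter) {
      lu <- .fjc_extension(taua, params)
      g <- i[act] * lu + nf[act] * (params$l_folded0 + taua / params$k_f) -
        L_tot[act]
      dlu <- params$l_contour * params$kuhn_b / params$kT *
        .langevin_prime(taua * params$kuhn_b / params$kT)
      dg <- i[act] * dlu + nf[act] / params$k_f
      step <- g / dg
      taua <- taua - step
      bad <- taua <= 0
      taua[bad] <- (taua[bad] + step[bad]) / 2  # bisect toward 0
      if (max(abs(step)) < tol) break
    }
    if (iter == max_iter && max(abs(step)) > 1e-6)
      stop("tension solve failed to converge: residual ",
           signif(max(abs(step)), 3), " pN")
    tau[act] <- taua
  }
  tau[slack] <- 0
  tau
}

#' Solve the uniform-tension force balance of a partially unfolded chain
#'
#' With `n_unfolded` = i unfolded subdomains, the folded length l_f and
#' unfolded length l_u satisfy length conservation
#' `i l_u + (N + 2 - i) l_f = L_tot` and uniform tension
#' `F_folded(l_f) = F_unfolded(l_u)`. When the chain is slack (total length
#' at or below the taut rest length) the tension is zero and segments are
#' reported at their forceless lengths.
#'
#' @param L_tot Total chain length, nm.
#' @param n_unfolded Number of unfolded rod subdomains, 0..M.
#' @param config A [chain_config()] object.
#' @param params A [mechanical_params()] object.
#' @return A list of class `talin_chain_state` with elements `n_unfolded`,
#'   `tension` (pN), `l_folded`, `l_unfolded`, `L_tot` (nm).
#' @export
#' @examples
#' solve_tension(150, 5)
solve_tension <- function(L_tot, n_unfolded, config = chain_config(),
                          params = mechanical_params()) {
  stopifnot(length(L_tot) == 1, L_tot > 0,
            n_unfolded >= 0, n_unfolded <= config$n_unfoldable)
  i <- as.integer(n_unfolded)
  tau <- .solve_tension_vec(L_tot, i, config, params)
  nseg <- config$n_total + 2
  if (tau > 0) {
    l_f <- params$l_folded0 + tau / params$k_f
    l_u <- if (i > 0) .fjc_extension(tau, params) else 0
  } else {
    # slack: forceless lengths that still sum to L_tot
    l_f <- min(params$l_folded0, L_tot / (nseg - i))
    l_u <- if (i > 0) max(0, (L_tot - (nseg - i) * params$l_folded0) / i) else 0
  }
  structure(list(n_unfolded = i, tension = tau, l_folded = l_f,
                 l_unfolded = l_u, L_tot = L_tot),
            class = "talin_chain_state")
}
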