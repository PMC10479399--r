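#' @useDynLib talinclutch, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dbinom rnorm runif rexp lm coef setNames uniroot integrate
#' @importFrom utils read.csv write.csv modifyList packageVersion
"_PACKAGE"

# Boltzmann constant in pN nm / K
.KB <- 0.0138065

#' Mechanical parameters of the Talin chain
#'
#' Elastic constants of the coarse-grained chain: folded rod subdomains (and
#' the two end linkers to integrin and F-actin) are Hookean springs; unfolded
#' subdomains are freely jointed chains (FJC) of one Kuhn segment per residue.
#'
#' @param k_folded Spring constant of a folded subdomain, pN/um.
#' @param l_folded0 Rest length of a folded subdomain, nm.
#' @param kuhn_b Kuhn length of the unfolded polypeptide, nm.
#' @param n_res Number of amino acids per rod subdomain.
#' @param temperature Absolute temperature, K.
#'
#' @return An object of class `talin_mech_params` with the inputs plus derived
#'   quantities: `k_f` (pN/nm), `kT` (pN nm) and `l_contour` (FJC contour
#'   length per unfolded subdomain, nm).
#' @export
#' @examples
#' mp <- mechanical_params()
#' mp$kT # ~4.14 pN nm at 300 K
mechanical_params <- function(k_folded = 1e4, l_folded0 = 2, kuhn_b = 0.38,
                              n_res = 145, temperature = 300) {
  stopifnot(k_folded > 0, l_folded0 > 0, kuhn_b > 0, n_res > 0, temperature > 0)
  l_contour <- kuhn_b * n_res
  if (l_contour <= l_folded0)
    stop("contour length per unfolded subdomain must exceed the folded rest length")
  structure(list(
    k_folded = k_folded, l_folded0 = l_folded0, kuhn_b = kuhn_b,
    n_res = n_res, temperature = temperature,
    k_f = k_folded / 1e3,            # pN/nm
    kT = .KB * temperature,          # pN nm
    l_contour = l_contour            # nm
  ), class = "talin_mech_params")
}

#' Geometry and composition of one Talin linkage
#'
#' @param n_total Total number of rod subdomains N. The chain carries N + 2
#'   spring segments: the two extra segments are the integrin-bond and
#'   actin-bond linkers, modelled with folded-subdomain parameters and never
#'   unfoldable.
#' @param n_unfoldable Number M (<= N) of rod subdomains that can unfold.
#' @param theta0 Initial angle of the chain with respect to the substrate,
#'   degrees, in (0, 90].
#' @param v_retro Retrograde flow speed, nm/s.
#'
#' @return An object of class `talin_chain_config`.
#' @export
chain_config <- function(n_total = 12, n_unfoldable = n_total, theta0 = 45,
                         v_retro = 20) {
  stopifnot(n_total >= 0, n_unfoldable >= 0, n_unfoldable <= n_total,
            theta0 > 0, theta0 <= 90, v_retro >= 0)
  structure(list(n_total = as.integer(n_total),
                 n_unfoldable = as.integer(n_unfoldable),
                 theta0 = theta0, v_retro = v_retro),
            class = "talin_chain_config")
}

#' Bell-law rate parameters
#'
#' @param k0 Zero-force rate, 1/s.
#' @param dx Distance to the transition barrier, nm (>= 0 for slip behaviour).
#' @return An object of class `bell_params`.
#' @export
bell_params <- function(k0, dx) {
  stopifnot(is.numeric(k0), k0 > 0, is.numeric(dx), is.finite(dx))
  structure(list(k0 = k0, dx = dx), class = "bell_params")
}

#' Default slip-bond unbinding parameters of the integrin-Talin bond
#'
#' Zero-force rate 0.17 1/s (the measured dissociation rate of stationary
#' speckles) and barrier distance 0.51 nm (calibrated against the measured
#' unbinding-displacement distribution).
#' @return A [bell_params()] object.
#' @export
unbinding_defaults <- function() bell_params(k0 = 0.17, dx = 0.51)

#' Illustrative Bell-law unfolding parameters for a rod subdomain
#'
#' The unfolding parameters of individual Talin rod subdomains vary between
#' subdomains and experiments; these defaults are an illustrative uniform set
#' (not a measured ground truth) and should be overridden per use case.
#' @return A [bell_params()] object with k0 = 1e-4 1/s and dx = 4 nm.
#' @export
unfolding_defaults <- function() bell_params(k0 = 1e-4, dx = 4)

#' Per-subdomain unfolding specification
#'
#' Heterogeneous Bell parameters for the N rod subdomains of a chain.
#'
#' @param k0 Numeric vector of zero-force unfolding rates, 1/s, length N.
#' @param dx Numeric vector of unfolding barrier distances, nm, length N.
#' @param unfoldable Logical vector, length N; which subdomains can unfold.
#' @return An object of class `subdomain_spec`.
#' @export
subdomain_spec <- function(k0, dx, unfoldable = rep(TRUE, length(k0))) {
  n <- length(k0)
  stopifnot(length(dx) == n, length(unfoldable) == n, all(k0 > 0))
  structure(list(k0 = as.numeric(k0), dx = as.numeric(dx),
                 unfoldable = as.logical(unfoldable)),
            class = "subdomain_spec")
}

#' Two-state catch-slip bond parameters for the integrin-Talin linkage
#'
#' State 0 is unbound, state 1 a fast-dissociating and state 2 a
#' slow-dissociating bound state in rapid equilibrium. Each transition rate
#' obeys Bell's law, k_ij(F) = k_ij0 exp(F x_ij / kT). Only the ratio
#' k12_0/k21_0 is constrained by the model (0.142); k21_0 = 1 is a convention.
#'
#' @param k10_0,k12_0,k21_0,k20_0 Zero-force rates, 1/s.
#' @param x10,x20,x12,x21 Barrier distances, nm (signs allowed).
#' @return An object of class `catch_slip_params`.
#' @export
catch_slip_params <- function(k10_0 = 0.194, k12_0 = 0.142, k21_0 = 1,
                              k20_0 = 5.5e-6, x10 = 0, x20 = 2.5,
                              x12 = 0.4, x21 = -1.6) {
  stopifnot(k10_0 > 0, k12_0 > 0, k21_0 > 0, k20_0 > 0)
  structure(list(k10_0 = k10_0, k12_0 = k12_0, k21_0 = k21_0, k20_0 = k20_0,
                 x10 = x10, x20 = x20, x12 = x12, x21 = x21),
            class = "catch_slip_params")
}

#' Stochastic pulling-simulation parameters
#'
#' @param zeta Bead friction coefficient, pN s/nm.
#' @param dt_sim Integration timestep, s. Must satisfy
#'   `dt_sim * k_max / zeta < 0.5` for stability of the explicit update.
#' @param seed Integer RNG seed recorded with the outputs.
#' @param n_realizations Ensemble size.
#' @param compliance_k3 Spring constant, pN/um, of the two extra springs of
#'   the finite-compliance variant (substrate and actin-network anchoring),
#'   or `NULL` for rigid anchoring.
#' @param rate_update_every Recompute Bell rates every this many steps; the
#'   tension changes on the slow loading timescale so a modest stride loses
#'   no accuracy.
#' @param max_time Guard, s; traces still bound at `max_time` are censored.
#' @return An object of class `talin_sim_params`.
#' @export
sim_params <- function(zeta = 1e-4, dt_sim = 1e-6, seed = 1L,
                       n_realizations = 1L, compliance_k3 = NULL,
                       rate_update_every = 10L, max_time = 600) {
  stopifnot(zeta > 0, dt_sim > 0, n_realizations >= 1, max_time > 0,
            rate_update_every >= 1)
  structure(list(zeta = zeta, dt_sim = dt_sim, seed = as.integer(seed),
                 n_realizations = as.integer(n_realizations),
                 compliance_k3 = compliance_k3,
                 rate_update_every = as.integer(rate_update_every),
                 max_time = max_time, dimensionality = 2L),
            class = "talin_sim_params")
}

.check_sim_stability <- function(sim, mech) {
  kmax <- mech$k_f
  if (!is.null(sim$compliance_k3)) kmax <- max(kmax, sim$compliance_k3 / 1e3)
  if (sim$dt_sim * kmax / sim$zeta >= 0.5)
    stop("unstable timestep: dt_sim * k_max / zeta must be < 0.5 ",
         "(got ", signif(sim$dt_sim * kmax / sim$zeta, 3), ")")
  invisible(TRUE)
}
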