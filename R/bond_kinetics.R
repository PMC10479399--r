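# Force-dependent rate laws: Bell slip bonds and the two-state catch-slip
# integrin-Talin bond.

# Exponent cap: beyond this the rate is astronomically fast anyway and the
# exponential would overflow; the capped rate is still reported as a number.
.EXP_CAP <- 700

#' Bell-law transition rate
#'
#' k(F) = k0 exp(F dx / kT). Monotone increasing in force for dx > 0
#' (slip bond); the exponent is capped at 700 to avoid numeric overflow.
#'
#' @param F Applied force(s), pN (>= 0).
#' @param params A [bell_params()] object.
#' @param kT Thermal energy, pN nm.
#' @return Rate(s), 1/s.
#' @export
#' @examples
#' bell_rate(10, bell_params(0.17, 0.51))
bell_rate <- function(F, params, kT = mechanical_params()$kT) {
  stopifnot(inherits(params, "bell_params"), all(F >= 0))
  params$k0 * exp(pmin(F * params$dx / kT, .EXP_CAP))
}

#' Overall unbinding rate of the two-state catch-slip bond
#'
#' With bound states 1 (fast-dissociating) and 2 (slow-dissociating) in rapid
#' equilibrium, each transition rate Bell-like, the overall dissociation rate
#' is
#' \deqn{k_{unbind}(F) = \frac{k_{21} k_{10} + k_{12} k_{20}}{k_{12} + k_{21}}}
#' with every k_ij evaluated at force F. For the default parameters the rate
#' has an interior minimum (catch regime) before rising at high force.
#'
#' @param F Applied force(s), pN (>= 0).
#' @param params A [catch_slip_params()] object.
#' @param kT Thermal energy, pN nm.
#' @return Rate(s), 1/s.
#' @export
#' @examples
#' catch_slip_unbind_rate(0, catch_slip_params()) # ~0.17 1/s
catch_slip_unbind_rate <- function(F, params = catch_slip_params(),
                                   kT = mechanical_params()$kT) {
  stopifnot(inherits(params, "catch_slip_params"), all(F >= 0))
  ex <- function(k0, x) k0 * exp(pmin(F * x / kT, .EXP_CAP))
  k10 <- ex(params$k10_0, params$x10)
  k20 <- ex(params$k20_0, params$x20)
  k12 <- ex(params$k12_0, params$x12)
  k21 <- ex(params$k21_0, params$x21)
  (k21 * k10 + k12 * k20) / (k12 + k21)
}

# Uniform rate-law dispatcher: returns a function F -> rate for either a
# slip (bell_params) or catch-slip unbinding model.
.unbind_rate_fun <- function(unbind, kT) {
  if (inherits(unbind, "bell_params")) {
    function(F) bell_rate(F, unbind, kT)
  } else if (inherits(unbind, "catch_slip_params")) {
    function(F) catch_slip_unbind_rate(F, unbind, kT)
  } else stop("unbind must be bell_params or catch_slip_params")
}
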