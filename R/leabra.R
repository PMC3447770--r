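#' Ionic channel parameters
#'
#' Defines the three conductance channels of the point-neuron model:
#' excitatory, inhibitory and leak. Each channel has a maximum conductance
#' `gbar` and a reversal (driving) potential `E` in normalized potential
#' units. The membrane potential always stays inside the span of the
#' reversal potentials.
#'
#' @param E_excit,E_leak,E_inhib Reversal potentials; must satisfy
#'   `E_inhib <= E_leak < E_excit`.
#' @param gbar_excit,gbar_leak,gbar_inhib Maximum (scaling) conductances,
#'   all non-negative.
#' @return An object of class `leabra_channels`.
#' @examples
#' ch <- leabra_channels()
#' ch$E[["excit"]]
#' @export
leabra_channels <- function(E_excit = 1.00, E_leak = 0.30, E_inhib = 0.15,
                            gbar_excit = 1.0, gbar_leak = 0.1,
                            gbar_inhib = 2.0) {
  gbar <- c(excit = gbar_excit, leak = gbar_leak, inhib = gbar_inhib)
  E <- c(excit = E_excit, leak = E_leak, inhib = E_inhib)
  if (any(gbar < 0)) stop("channel conductances gbar must be non-negative")
  if (!(E_inhib <= E_leak && E_leak < E_excit)) {
    stop("reversal potentials must be ordered E_inhib <= E_leak < E_excit")
  }
  structure(list(E = E, gbar = gbar), class = "leabra_channels")
}

#' Neuron dynamics and learning-schedule parameters
#'
#' @param tau Integration time constant of the membrane update (per cycle),
#'   `> 0`.
#' @param cycles Settling cycles per phase, `>= 1`.
#' @param gain Activation gain applied to `V_m - threshold`.
#' @param threshold Firing threshold on the membrane potential; activation is
#'   exactly zero at or below it.
#' @param aggregation `"per_epoch"` (weight deltas averaged over the epoch and
#'   applied once) or `"per_pattern"` (applied after every pattern).
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(tau = 0.2, cycles = 60, gain = 1000,
                            threshold = 0.60,
                            aggregation = c("per_epoch", "per_pattern")) {
  aggregation <- match.arg(aggregation)
  stopifnot(tau > 0, cycles >= 1, gain > 0)
  structure(
    list(tau = tau, cycles = as.integer(cycles), gain = gain,
         threshold = threshold, aggregation = aggregation),
    class = "dynamics_params"
  )
}

#' One membrane-potential update step
#'
#' Moves the membrane potential one Euler step toward the conductance-weighted
#' mixture of reversal potentials:
#' `V_m <- V_m + tau * sum_c g_c * gbar_c * (E_c - V_m)`.
#' The step factor `tau * G` (total conductance `G`) is capped at 1, so very
#' strong drive — e.g. the climbing-fiber projection, four orders of
#' magnitude stronger than the rest — moves the potential directly to its
#' conductance-weighted equilibrium rather than overshooting; the result is
#' additionally clamped to the span of the reversal potentials.
#'
#' @param unit A list with elements `v_m` (membrane potential) and `g`
#'   (named numeric vector of time-varying conductances `excit`, `inhib`,
#'   `leak`; missing entries are 0). May carry `lesioned = TRUE`, in which
#'   case the unit is not updated.
#' @param channels A [leabra_channels()] object.
#' @param params A [dynamics_params()] object.
#' @return The updated unit.
#' @examples
#' u <- list(v_m = 0.3, g = c(excit = 1, leak = 1))
#' step_membrane(u, leabra_channels(), dynamics_params())$v_m
#' @export
step_membrane <- function(unit, channels, params) {
  if (isTRUE(unit$lesioned)) stop("step_membrane: unit is lesioned")
  g <- c(excit = 0, inhib = 0, leak = 0)
  g[names(unit$g)] <- unit$g
  if (any(!is.finite(g)) || any(g < 0) || !is.finite(unit$v_m)) {
    stop("step_membrane: non-finite or negative conductance / potential in unit")
  }
  gg <- g * channels$gbar[names(g)]
  G <- sum(gg)
  if (G > 0) {
    # step toward the conductance-weighted equilibrium; step factor capped at
    # 1 so very strong total conductance cannot overshoot (equivalent to the
    # plain Euler update whenever tau * G < 1)
    e_star <- sum(gg * channels$E[names(g)]) / G
    alpha <- min(params$tau * G, 1)
    v <- unit$v_m + alpha * (e_star - unit$v_m)
  } else {
    v <- unit$v_m
  }
  unit$v_m <- min(max(v, min(channels$E)), max(channels$E))
  unit
}

#' Rate-code activation function
#'
#' A saturating, monotone non-decreasing function of `gain * (V_m -
#' threshold)`: exactly 0 at or below threshold, then a rescaled logistic
#' `2 / (1 + exp(-gain * d)) - 1` that approaches 1. With the default gain
#' the function reaches 1 to double precision for strongly driven units, so a
#' trained network can express an exactly correct binary response.
#'
#' @param v_m Membrane potential(s); numeric vector or matrix.
#' @param params A [dynamics_params()] object.
#' @return Activation(s) in `[0, 1]`, same shape as `v_m`.
#' @export
rate_activation <- function(v_m, params) {
  if (any(!is.finite(v_m))) stop("rate_activation: non-finite membrane potential")
  d <- v_m - params$threshold
  y <- 2 / (1 + exp(-params$gain * pmax(d, 0))) - 1
  y[d <= 0] <- 0
  y
}

# Inhibitory conductance that would put a unit exactly at threshold, given its
# excitatory/leak/synaptic-inhibitory conductances. Used by the fast kWTA rule.
kwta_gi_theta <- function(ge, gi_syn, channels, params) {
  th <- params$threshold
  E <- channels$E
  gb <- channels$gbar
  (ge * gb[["excit"]] * (E[["excit"]] - th) +
     1 * gb[["leak"]] * (E[["leak"]] - th) +
     gi_syn * gb[["inhib"]] * (E[["inhib"]] - th)) /
    ((th - E[["inhib"]]) * gb[["inhib"]])
}

# Layer-level kWTA inhibitory conductance for a vector of threshold
# conductances. `alive` is a logical vector of non-lesioned units.
kwta_layer_gi <- function(gith, k, alive = NULL) {
  if (!is.null(alive)) gith[!alive] <- -Inf
  n_alive <- if (is.null(alive)) length(gith) else sum(alive)
  k <- min(k, n_alive)
  if (n_alive == 0L) return(0)
  if (k <= 0L) return(max(gith[is.finite(gith)], 0) + 1)
  if (k >= n_alive) return(0)
  s <- sort(-gith, partial = c(k, k + 1L))
  gi <- -(s[k] + s[k + 1L]) / 2
  max(gi, 0)
}

#' Apply k-winners-take-all inhibition to a layer
#'
#' Implements the fast average-based kWTA approximation: for each unit the
#' inhibitory conductance `g_i_theta` that would hold it exactly at threshold
#' is computed, and the layer-wide inhibitory conductance is placed midway
#' between the k-th and (k+1)-th largest values, so that at settling
#' equilibrium at most `k` units exceed threshold while the ordering of unit
#' drives is preserved. `k = 0` silences the layer; `k >= n` leaves the
#' no-inhibition baseline. Exactly tied boundary drives leave both units at
#' threshold (hence silent).
#'
#' @param layer A list with `g_e` (numeric vector of excitatory conductances),
#'   `k` (winners), optional `g_i_syn` (synaptic inhibitory conductance,
#'   scalar or vector) and optional `lesioned` (logical vector; lesioned units
#'   never win).
#' @param channels A [leabra_channels()] object.
#' @param params A [dynamics_params()] object.
#' @return The layer with `g_i` (scalar layer inhibition) set.
#' @export
apply_kwta <- function(layer, channels = leabra_channels(),
                       params = dynamics_params()) {
  n <- length(layer$g_e)
  gi_syn <- layer$g_i_syn %||% 0
  alive <- if (is.null(layer$lesioned)) rep(TRUE, n) else !layer$lesioned
  gith <- kwta_gi_theta(layer$g_e, gi_syn, channels, params)
  layer$g_i <- kwta_layer_gi(gith, layer$k, alive)
  layer
}

#' Hebbian (CPCA) weight change
#'
#' Conditional principal-components-analysis rule: the weight moves toward the
#' presynaptic input conditioned on postsynaptic activity,
#' `delta = eps * y_j * (x_i - w_ij)`, optionally scaled by a sparse-activity
#' correction factor (default 1, i.e. off). Applying the delta keeps the
#' weight inside `[0, 1]`.
#'
#' @param x_i Presynaptic input in `[0, 1]`.
#' @param y_j Postsynaptic output in `[0, 1]`.
#' @param w_ij Current weight in `[0, 1]`.
#' @param eps Learning rate (non-negative).
#' @param correction Multiplicative sparse-activity correction factor.
#' @return The weight change (not yet applied).
#' @examples
#' cpca_delta(1, 1, 0.25, 0.1) # 0.075
#' @export
cpca_delta <- function(x_i, y_j, w_ij, eps, correction = 1) {
  eps * correction * y_j * (x_i - w_ij)
}

#' Error-driven (GeneRec) weight change
#'
#' Contrastive two-phase rule: the difference of pre/post activation products
#' between the outcome (plus) phase, where the output layer is clamped to the
#' target, and the expectation (minus) phase, where the output runs free:
#' `delta = eps * (x_plus * y_plus - x_minus * y_minus)`.
#'
#' @param x_minus,y_minus Pre-/postsynaptic activations in the minus phase.
#' @param x_plus,y_plus Pre-/postsynaptic activations in the plus phase.
#' @param eps Learning rate.
#' @return The weight change (not yet applied).
#' @examples
#' generec_delta(0.2, 0.5, 0.8, 0.5, 0.1) # 0.03
#' @export
generec_delta <- function(x_minus, y_minus, x_plus, y_plus, eps) {
  eps * (x_plus * y_plus - x_minus * y_minus)
}
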