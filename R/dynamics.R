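#' Centred firing-rate sigmoid
#'
#' Maps mean membrane depolarisation (mV) to population firing rate (1/s):
#' `S(v) = 2 e0 / (1 + exp(r (v0 - v))) - 2 e0 / (1 + exp(r v0))`.
#' The subtraction centres the curve so `S(0) = 0` and the resting state of
#' the network is an exact fixed point. Strictly increasing and bounded.
#'
#' @param v depolarisation (mV), any finite numeric.
#' @param const a [jr_constants()] object (only `e0`, `r`, `v0` are used).
#' @return firing rate(s), same shape as `v`.
#' @export
jr_sigmoid <- function(v, const) {
  2 * const$e0 / (1 + exp(const$r * (const$v0 - v))) -
    2 * const$e0 / (1 + exp(const$r * const$v0))
}

#' Jansen-Rit network right-hand side
#'
#' The canonical three-population Jansen-Rit unit per source: each synaptic
#' kernel is a critically damped second-order system, so each output `y`
#' obeys `y'' = (H/tau) * input - (2/tau) y' - y / tau^2`. `y0` is the
#' pyramidal output feeding both interneuron populations, `y1` the
#' excitatory and `y2` the inhibitory postsynaptic potential at the
#' pyramidal population; the pyramidal potential is `vP = y1 - y2`.
#' Forward and lateral afferents (weighted pyramidal firing of presynaptic
#' sources) drive the excitatory equation alongside the stimulus; backward
#' afferents enter the inhibitory sigmoid argument.
#'
#' This is the reference R implementation used for testing; simulation goes
#' through the compiled integrator in [simulate_sources()].
#'
#' @param state n x 6 matrix (columns y0, y1, y2, dy0, dy1, dy2).
#' @param eff effective model from the internal builder: matrices `CfL`,
#'   `Cb` and vectors `He`, `Hi`, `tau_e`, `tau_i`, `gamma`.
#' @param const a [jr_constants()] object (sigmoid constants).
#' @param u stimulus value at this instant.
#' @param u_weight per-source input weight (1 at the input site, else 0).
#' @return n x 6 matrix of state derivatives.
#' @export
jr_rhs <- function(state, eff, const, u = 0, u_weight = NULL) {
  if (!all(is.finite(state))) stop("non-finite state")
  n <- nrow(state)
  if (is.null(u_weight)) u_weight <- c(1, numeric(n - 1))
  S <- function(v) jr_sigmoid(v, const)
  y0 <- state[, 1]; y1 <- state[, 2]; y2 <- state[, 3]
  d0 <- state[, 4]; d1 <- state[, 5]; d2 <- state[, 6]
  sp <- S(y1 - y2)
  rs <- const$rate_scale
  ke <- eff$He / eff$tau_e
  ki <- eff$Hi / eff$tau_i
  g <- eff$gamma
  cbind(d0, d1, d2,
        ke * rs * S(y1 - y2) - 2 / eff$tau_e * d0 - y0 / eff$tau_e^2,
        ke * rs * (u_weight * u + g[2] * S(g[1] * y0) + drop(eff$CfL %*% sp)) -
          2 / eff$tau_e * d1 - y1 / eff$tau_e^2,
        ki * rs * g[4] * S(g[3] * y0 + drop(eff$Cb %*% sp)) -
          2 / eff$tau_i * d2 - y2 / eff$tau_i^2,
        deparse.level = 0)
}

#' Gaussian stimulus bump
#'
#' @param t times (ms).
#' @param const a [jr_constants()] (uses `u_amp`, `u_peak`, `u_sd`).
#' @export
stimulus_bump <- function(t, const) {
  const$u_amp * exp(-(t - const$u_peak)^2 / (2 * const$u_sd^2))
}

#' Simulate the source network for one condition
#'
#' Integrates the Jansen-Rit network from rest over `[0, duration]` with a
#' fixed-step 4th-order Runge-Kutta scheme (compiled). Condition-dependent
#' effective connectivity follows [effective_strength()] semantics: `A`
#' log-scalings apply always, `B` (and intrinsic gain modulations) only in
#' the interference condition.
#'
#' @param network a [network_spec()].
#' @param const a [jr_constants()] for the network.
#' @param theta full parameter vector from [param_template()] (log-scalings).
#' @param condition `"control"` or `"interference"`.
#' @param duration epoch length (ms). @param dt integration step (ms).
#' @param intrinsic optional named per-site intrinsic log-modulation
#'   (interference only).
#' @param b_mask optional logical mask over B entries declared modulated by
#'   the active model variant; unmasked B entries are ignored.
#' @param stimulus function of time (ms) giving the input; default the
#'   Gaussian bump in `const`.
#' @param keep_states return the full state trajectory too.
#' @return list of class `source_states`: `time` (ms), `vp` (sources x
#'   samples pyramidal potentials, mV), optionally `states`.
#' @export
simulate_sources <- function(network, const, theta = param_template(network),
                             condition = c("control", "interference"),
                             duration = 350, dt = 1,
                             intrinsic = NULL, b_mask = NULL,
                             stimulus = NULL, keep_states = FALSE) {
  condition <- match.arg(condition)
  nt <- duration / dt
  if (abs(nt - round(nt)) > 1e-9) stop("dt must divide duration")
  nt <- as.integer(round(nt))
  eff <- effective_model(network, const, theta, condition, intrinsic, b_mask)
  if (is.null(stimulus)) stimulus <- function(t) stimulus_bump(t, const)
  u <- stimulus(seq(0, duration, by = dt / 2))
  uw <- as.numeric(network$sources == network$input_site)
  n <- network$n_sources
  out <- jr_integrate_cpp(matrix(0, n, 6), eff$He, eff$Hi, eff$tau_e, eff$tau_i,
                          eff$gamma, const$e0, const$r, const$v0, const$rate_scale,
                          eff$CfL, eff$Cb, u, uw, dt, keep_states)
  res <- list(time = seq(0, duration, by = dt),
              vp = structure(out$vp, dimnames = list(network$sources, NULL)),
              condition = condition, dt = dt)
  if (keep_states) res$states <- out$states
  structure(res, class = "source_states")
}
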