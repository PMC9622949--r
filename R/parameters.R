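#' Jansen-Rit population constants
#'
#' Baseline (prior-mean) constants of the three-population Jansen-Rit unit:
#' synaptic gains `He`/`Hi` (mV), time constants `tau_e`/`tau_i` (ms), the
#' four intrinsic coupling constants `gamma` (dimensionless), and the firing
#' sigmoid constants `e0` (half of max rate, 1/s), `r` (slope, 1/mV), `v0`
#' (threshold, mV). The sigmoid is centred so that S(0) = 0 and rest is a
#' fixed point of the dynamics.
#'
#' `tau_e`/`tau_i` may be vectors over sources: the default MSIT profile
#' slows synaptic kinetics up the hierarchy so the frontal response falls in
#' the late (Positive Potential) window.
#'
#' @param n_sources number of sources the constants are replicated over.
#' @param He,Hi,tau_e,tau_i scalar or per-source values.
#' @param gamma length-4 intrinsic coupling constants.
#' @param e0,r,v0 sigmoid constants.
#' @param rate_scale conversion from sigmoid firing (1/s) to synaptic drive
#'   in the millisecond-unit kernels; sets the operating-point loop gains
#'   (defaults keep every intrinsic and extrinsic loop below unit gain, so
#'   the evoked response is stable and near-linear).
#' @param base_fwd,base_bwd,base_lat baseline extrinsic strengths applied to
#'   forward, backward and lateral edges before any log-scaling.
#' @param u_amp,u_peak,u_sd exogenous stimulus: Gaussian bump amplitude,
#'   peak time (ms) and width (ms), delivered to the input site only.
#' @return list of class `jr_constants`.
#' @export
jr_constants <- function(n_sources,
                         He = 3.25, Hi = 22,
                         tau_e = 10, tau_i = 20,
                         gamma = c(50, 40, 12, 4),
                         e0 = 2.5, r = 0.56, v0 = 6, rate_scale = 0.006,
                         base_fwd = 32, base_bwd = 1, base_lat = 2,
                         u_amp = 2, u_peak = 160, u_sd = 40) {
  stopifnot(length(gamma) == 4, all(gamma > 0),
            all(He > 0), all(Hi > 0), all(tau_e > 0), all(tau_i > 0))
  structure(list(
    n_sources = n_sources,
    He = rep_len(He, n_sources), Hi = rep_len(Hi, n_sources),
    tau_e = rep_len(tau_e, n_sources), tau_i = rep_len(tau_i, n_sources),
    gamma = gamma, e0 = e0, r = r, v0 = v0, rate_scale = rate_scale,
    base_fwd = base_fwd, base_bwd = base_bwd, base_lat = base_lat,
    u_amp = u_amp, u_peak = u_peak, u_sd = u_sd), class = "jr_constants")
}

#' Default constants for a network
#'
#' [jr_constants()] for the network's source count. The default stimulus is
#' a slow conflict-related input wave (peak 160 ms, SD 40 ms) whose
#' propagation through the four-level hierarchy places the frontal evoked
#' component inside the 250-350 ms Positive Potential window while keeping
#' every synaptic loop below unit gain (flat 10/20 ms time constants).
#'
#' @param network a [network_spec()].
#' @param ... overrides forwarded to [jr_constants()].
#' @export
default_constants <- function(network, ...) {
  jr_constants(n_sources = network$n_sources, ...)
}

#' Canonical biophysical parameter template for a network
#'
#' Returns the zero log-scaling parameter vector in the fixed category order
#' A (forward then backward extrinsic), B (condition modulation, same edge
#' order), G (He then Hi scaling per source), H (the four intrinsic coupling
#' constants, global), T (tau_e then tau_i scaling per source). For the
#' 10-source MSIT network this is 12+12 + 12+12 + 10+10 + 4 + 10+10 = 92
#' parameters. All parameters act multiplicatively through `exp()` on their
#' baseline values, so the zero vector is the baseline model.
#'
#' @param network a [network_spec()].
#' @return named numeric vector of zeros.
#' @export
param_template <- function(network) {
  fk <- gsub("->", ".", edge_keys(network$forward), fixed = TRUE)
  bk <- gsub("->", ".", edge_keys(network$backward), fixed = TRUE)
  nm <- c(paste0("A_f_", fk), paste0("A_b_", bk),
          paste0("B_f_", fk), paste0("B_b_", bk),
          paste0("G_He_", network$sources), paste0("G_Hi_", network$sources),
          paste0("H_g", 1:4),
          paste0("T_te_", network$sources), paste0("T_ti_", network$sources))
  stats::setNames(numeric(length(nm)), nm)
}

#' @rdname param_template
#' @export
param_categories <- function(network) {
  nm <- names(param_template(network))
  sub("_.*", "", nm)
}

#' Condition-dependent effective connection strength
#'
#' The baseline strength of an edge is scaled by `exp(A)` in both task
#' conditions; in the interference condition a modulated edge is
#' additionally scaled by `exp(B)`. Supplying a modulation for an edge the
#' active model variant does not declare modulated is an error; the control
#' condition never reads `B`.
#'
#' @param base baseline strength (> 0).
#' @param A log-scaling applied in both conditions.
#' @param B condition (interference) log-scaling; only allowed when
#'   `modulated` is TRUE.
#' @param condition `"control"` or `"interference"`.
#' @param modulated does the active model variant modulate this edge?
#' @return effective strength (numeric).
#' @export
effective_strength <- function(base, A = 0, B = NULL, condition = c("control", "interference"),
                               modulated = FALSE) {
  condition <- match.arg(condition)
  if (!modulated && !is.null(B)) stop("B supplied for an edge the model variant does not modulate")
  s <- base * exp(A)
  if (condition == "interference" && modulated) {
    if (is.null(B)) B <- 0
    s <- s * exp(B)
  }
  s
}

# Effective source-level quantities for one condition.
# theta: full template vector; intrinsic: named vector of per-site intrinsic
# log-modulations (applied to He in interference only); b_mask: logical over
# the B entries actually free in the active variant (generation uses all).
# Returns the n x n forward+lateral and backward matrices (row = target) and
# per-source He/Hi/tau vectors and gamma.
effective_model <- function(network, const, theta, condition,
                            intrinsic = NULL, b_mask = NULL) {
  n <- network$n_sources
  src <- network$sources
  nm <- names(theta)
  interference <- identical(condition, "interference")

  edge_mat <- function(edges, base, a_pref, b_pref) {
    M <- matrix(0, n, n, dimnames = list(src, src))
    if (!nrow(edges)) return(M)
    keys <- gsub("->", ".", edge_keys(edges), fixed = TRUE)
    A <- theta[paste0(a_pref, keys)]
    B <- theta[paste0(b_pref, keys)]
    if (!is.null(b_mask)) B[!b_mask[paste0(b_pref, keys)]] <- 0
    s <- base * exp(A + if (interference) B else 0)
    M[cbind(match(edges$to, src), match(edges$from, src))] <- s
    M
  }
  Cf <- edge_mat(network$forward, const$base_fwd, "A_f_", "B_f_")
  Cb <- edge_mat(network$backward, const$base_bwd, "A_b_", "B_b_")
  Cl <- matrix(0, n, n, dimnames = list(src, src))
  if (nrow(network$lateral_pairs)) {
    ia <- match(network$lateral_pairs$a, src); ib <- match(network$lateral_pairs$b, src)
    Cl[cbind(ia, ib)] <- const$base_lat
    Cl[cbind(ib, ia)] <- const$base_lat
  }

  He <- const$He * exp(theta[paste0("G_He_", src)])
  Hi <- const$Hi * exp(theta[paste0("G_Hi_", src)])
  if (interference && length(intrinsic)) {
    idx <- match(names(intrinsic), src)
    if (anyNA(idx)) stop("intrinsic modulation for unknown site")
    He[idx] <- He[idx] * exp(intrinsic)
  }
  list(CfL = Cf + Cl, Cb = Cb,
       He = unname(He), Hi = unname(Hi),
       tau_e = unname(const$tau_e * exp(theta[paste0("T_te_", src)])),
       tau_i = unname(const$tau_i * exp(theta[paste0("T_ti_", src)])),
       gamma = const$gamma * exp(theta[paste0("H_g", 1:4)]))
}
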