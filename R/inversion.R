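#' Prior specification for model inversion
#'
#' Zero-mean Gaussian priors on the log-scaling parameters, with variances
#' set per category: 1/2 for extrinsic baseline (A), condition modulation
#' (B) and intrinsic modulation (I), 1/16 for synaptic gains (G), intrinsic
#' coupling (H) and time constants (T). The free set is the union of the
#' requested categories, with B restricted to the variant's modulated edges
#' and I to its intrinsic sites.
#'
#' @param network a [network_spec()].
#' @param variant a [model_variant()].
#' @param free categories to free: subset of A, B, G, H, T, I.
#' @param var named per-category prior variances (overrides defaults).
#' @return list of class `prior_spec`: `names`, `mean`, `var` (vectors over
#'   the free set).
#' @export
prior_spec <- function(network, variant, free = c("A", "B"),
                       var = c(A = 1/2, B = 1/2, I = 1/2, G = 1/16, H = 1/16, T = 1/16)) {
  v0 <- c(A = 1/2, B = 1/2, I = 1/2, G = 1/16, H = 1/16, T = 1/16)
  v0[names(var)] <- var
  tmpl <- param_template(network)
  cat_of <- param_categories(network)
  nm <- character()
  for (cc in intersect(c("A", "G", "H", "T"), free))
    nm <- c(nm, names(tmpl)[cat_of == cc])
  if ("B" %in% free && length(variant$b_edges)) {
    fwd <- edge_keys(network$forward)
    keys <- gsub("->", ".", variant$b_edges, fixed = TRUE)
    nm <- c(nm, ifelse(variant$b_edges %in% fwd,
                       paste0("B_f_", keys), paste0("B_b_", keys)))
  }
  if ("I" %in% free && length(variant$sites_expanded))
    nm <- c(nm, paste0("I_", variant$sites_expanded))
  stopifnot(!anyDuplicated(nm))
  structure(list(names = nm,
                 mean = stats::setNames(numeric(length(nm)), nm),
                 var = stats::setNames(unname(v0[substr(nm, 1, 1)]), nm)),
            class = "prior_spec")
}

# split a free-parameter vector into the full template vector plus the
# per-site intrinsic modulations
expand_free <- function(theta_free, network) {
  tmpl <- param_template(network)
  is_int <- startsWith(names(theta_free), "I_")
  th <- theta_free[!is_int]
  bad <- setdiff(names(th), names(tmpl))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  tmpl[names(th)] <- th
  intr <- theta_free[is_int]
  names(intr) <- sub("^I_", "", names(intr))
  list(theta = tmpl, intrinsic = intr)
}

#' Predict mode-space evoked responses from parameters
#'
#' Runs the neural-mass forward model for both task conditions with the
#' given free parameters (noiselessly), projects pyramidal activity through
#' the gain matrix and the spatial-mode projector, and returns the
#' concatenated mode-space prediction. This is the generative mapping the
#' variational optimizer inverts.
#'
#' @param theta_free named free-parameter vector (template names plus
#'   optional `I_<site>` intrinsic modulations).
#' @param network,const network and constants.
#' @param variant the active [model_variant()]; its B structure masks which
#'   modulations the interference condition reads.
#' @param gain a [gain_matrix()].
#' @param projection channels x n_modes orthonormal projector (or NULL for
#'   channel space).
#' @param duration,dt integration settings (ms).
#' @return array `modes x samples x 2` (conditions control, interference).
#' @export
predict_erp <- function(theta_free, network, const, variant, gain,
                        projection = NULL, duration = 350, dt = 1) {
  ex <- expand_free(theta_free, network)
  b_mask <- b_mask_for(variant, network)
  out <- lapply(c("control", "interference"), function(cond) {
    st <- simulate_sources(network, const, ex$theta, cond, duration, dt,
                           intrinsic = ex$intrinsic, b_mask = b_mask)
    Y <- unclass(gain) %*% st$vp
    if (!is.null(projection)) Y <- crossprod(projection, Y) else Y
  })
  array(c(out[[1]], out[[2]]),
        dim = c(nrow(out[[1]]), ncol(out[[1]]), 2),
        dimnames = list(NULL, NULL, c("control", "interference")))
}

# logical mask over the template's B entries: TRUE where the variant frees them
b_mask_for <- function(variant, network) {
  tmpl <- param_template(network)
  mask <- startsWith(names(tmpl), "B_") & FALSE
  names(mask) <- names(tmpl)
  if (length(variant$b_edges)) {
    fwd <- edge_keys(network$forward)
    keys <- gsub("->", ".", variant$b_edges, fixed = TRUE)
    nm <- ifelse(variant$b_edges %in% fwd, paste0("B_f_", keys), paste0("B_b_", keys))
    mask[nm] <- TRUE
  }
  mask
}

#' Variational free energy under the Laplace approximation
#'
#' `F = E_q[log p(y | theta)] - KL(q || prior)` for a Gaussian observation
#' model with precision `tau` and Gaussian posterior `q`. The expected
#' log-likelihood is `N/2 log(tau / 2 pi) - tau/2 (r'r + tr(J Sigma J'))`;
#' the trace term (the posterior-uncertainty correction through the local
#' Jacobian `J`) is omitted when `J` is NULL. On linear-Gaussian models
#' evaluated at the exact posterior this equals the exact log model
#' evidence.
#'
#' @param residuals data-minus-prediction vector at the posterior mean.
#' @param posterior list with `mean` and `cov` (symmetric positive
#'   definite).
#' @param prior list with `mean` and `var` (vector of prior variances).
#' @param tau observation noise precision.
#' @param J optional N x p Jacobian of the prediction at the posterior
#'   mean.
#' @return free energy in nats.
#' @export
free_energy <- function(residuals, posterior, prior, tau, J = NULL) {
  Sigma <- posterior$cov
  ch <- tryCatch(chol(Sigma), error = function(e) stop("posterior covariance not positive definite"))
  p <- length(posterior$mean)
  N <- length(residuals)
  rss <- sum(residuals^2)
  if (!is.null(J)) rss <- rss + sum((J %*% Sigma) * J)
  dm <- posterior$mean - prior$mean
  tr_term <- sum(diag(Sigma) / prior$var)
  logdet_Sigma <- 2 * sum(log(diag(ch)))
  logdet_prior <- sum(log(prior$var))
  kl <- 0.5 * (tr_term + sum(dm^2 / prior$var) - p + logdet_prior - logdet_Sigma)
  0.5 * N * log(tau / (2 * pi)) - 0.5 * tau * rss - kl
}

#' Gauss-Newton / Levenberg-Marquardt ascent on the free energy
#'
#' Generic variational-Laplace fitter for `y = f(theta) + e` with Gaussian
#' noise of unknown precision and a Gaussian prior. Sensitivities come from
#' central finite differences; the noise precision has a closed-form update
#' each outer iteration; steps are accepted only when they increase F, so
#' the accepted-F trace is non-decreasing by construction.
#'
#' @param y data vector.
#' @param f prediction function: named theta vector -> vector like `y`.
#' @param prior a [prior_spec()] (or list with `names`, `mean`, `var`).
#' @param control list: `max_iter` (64), `tol` (0.01 nats), `tol_count`
#'   (4 consecutive small improvements), `fd_step` (1e-3), `max_tries`
#'   (inner damping trials, 6), `restarts` (extra random starts, 0).
#' @param seed seed used only when `restarts > 0`.
#' @return list of class `dcm_posterior`: `mean`, `cov`, `F`, `F_trace`,
#'   `tau`, `converged`, `n_iter`.
#' @export
laplace_fit <- function(y, f, prior, control = list(), seed = 1L) {
  ctl <- utils::modifyList(list(max_iter = 64, tol = 0.01, tol_count = 4,
                                fd_step = 1e-3, max_tries = 10, restarts = 0), control)
  starts <- list(prior$mean)
  if (ctl$restarts > 0) {
    extra <- withr_seed(seed, lapply(seq_len(ctl$restarts), function(i)
      prior$mean + stats::rnorm(length(prior$mean), sd = sqrt(prior$var) / 2)))
    starts <- c(starts, extra)
  }
  fits <- lapply(starts, function(s) laplace_fit_one(y, f, prior, s, ctl))
  fits[[which.max(vapply(fits, `[[`, 0, "F"))]]
}

laplace_fit_one <- function(y, f, prior, start, ctl) {
  p <- length(prior$mean)
  N <- length(y)
  Pi <- diag(1 / prior$var, p)
  theta <- start
  g <- f(theta)
  r <- y - g
  tau <- N / max(sum(r^2), 1e-12)
  Sigma <- diag(prior$var, p)
  J <- NULL
  F_trace <- numeric()
  small <- 0
  converged <- FALSE
  nu <- 1e-2   # LM damping, persistent across iterations

  for (iter in seq_len(ctl$max_iter)) {
    J <- fd_jacobian(f, theta, g, ctl$fd_step)
    JtJ <- crossprod(J)
    # closed-form noise precision update given current posterior spread
    tau <- N / max(sum(r^2) + sum((J %*% Sigma) * J), 1e-12)
    H <- tau * JtJ + Pi
    Sigma <- chol2inv(chol(H))
    F_cur <- free_energy(r, list(mean = theta, cov = Sigma), prior, tau, J)
    if (!length(F_trace)) F_trace <- F_cur
    grad <- tau * crossprod(J, r) - Pi %*% (theta - prior$mean)

    accepted <- FALSE
    for (try in seq_len(ctl$max_tries)) {
      Hd <- H + nu * diag(diag(H), p)
      step <- drop(solve(Hd, grad))
      th_new <- theta + stats::setNames(step, names(theta))
      g_new <- tryCatch(f(th_new), error = function(e) NULL)
      if (!is.null(g_new)) {
        r_new <- y - g_new
        tau_new <- N / max(sum(r_new^2) + sum((J %*% Sigma) * J), 1e-12)
        Sig_new <- chol2inv(chol(tau_new * JtJ + Pi))
        F_new <- free_energy(r_new, list(mean = th_new, cov = Sig_new), prior, tau_new, J)
        if (is.finite(F_new) && F_new > F_cur) {
          dF <- F_new - F_cur
          theta <- th_new; g <- g_new; r <- r_new
          tau <- tau_new; Sigma <- Sig_new
          F_trace <- c(F_trace, F_new)
          small <- if (dF < ctl$tol) small + 1 else 0
          accepted <- TRUE
          nu <- max(nu / 5, 1e-6)
          break
        }
      }
      nu <- nu * 10
    }
    if (!accepted) small <- small + 1
    if (small >= ctl$tol_count) { converged <- TRUE; break }
  }
  # final consistent posterior at the accepted mean
  J <- fd_jacobian(f, theta, g, ctl$fd_step)
  H <- tau * crossprod(J) + Pi
  Sigma <- chol2inv(chol(H))
  F_fin <- free_energy(r, list(mean = theta, cov = Sigma), prior, tau, J)
  F_trace <- c(F_trace, max(F_fin, F_trace[length(F_trace)]))
  structure(list(mean = theta, cov = Sigma, F = F_fin, F_trace = F_trace,
                 tau = tau, converged = converged, n_iter = length(F_trace)),
            class = "dcm_posterior")
}

fd_jacobian <- function(f, theta, g0, h) {
  p <- length(theta)
  J <- matrix(0, length(g0), p)
  for (j in seq_len(p)) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h
    tm[j] <- tm[j] - h
    J[, j] <- (f(tp) - f(tm)) / (2 * h)
  }
  J
}

#' Fit one subject's two-condition ERP pair
#'
#' Reduces the subject's channel data to spatial modes, then maximises the
#' variational free energy over the variant's free parameters starting from
#' the prior mean.
#'
#' @param erps list of two [subject_erp()] (control and interference).
#' @param network,const,variant,gain forward-model ingredients.
#' @param priors a [prior_spec()]; default frees A and the variant's B.
#' @param n_modes spatial modes used for inversion.
#' @param projection optional fixed channels x n_modes orthonormal
#'   projector shared across subjects (e.g. modes of the noiseless
#'   baseline template); default: the subject's own data modes.
#' @param control optimizer control, see [laplace_fit()].
#' @return a `dcm_posterior` with fields `subject`, `variant_id`,
#'   `full_mean` (posterior means embedded in the full [param_template()])
#'   added.
#' @export
fit_subject <- function(erps, network, const, variant, gain,
                        priors = prior_spec(network, variant),
                        n_modes = 4, projection = NULL, control = list()) {
  conds <- vapply(erps, `[[`, "", "condition")
  if (!setequal(conds, c("control", "interference"))) stop("need both conditions")
  erps <- erps[order(match(conds, c("control", "interference")))]
  if (is.null(projection)) {
    red <- reduce_spatial_modes(erps, n_modes)
  } else {
    red <- list(projection = projection,
                modes = lapply(erps, function(e) crossprod(projection, e$data)))
  }
  y <- c(red$modes[[1]], red$modes[[2]])
  dt <- 1000 / erps[[1]]$rate
  duration <- (ncol(erps[[1]]$data) - 1) * dt
  fn <- function(th) as.vector(predict_erp(th, network, const, variant, gain,
                                           projection = red$projection,
                                           duration = duration, dt = dt))
  fit <- laplace_fit(y, fn, priors, control)
  fit$subject <- erps[[1]]$subject
  fit$variant_id <- variant$id
  ex <- expand_free(fit$mean, network)
  fit$full_mean <- ex$theta
  if (length(ex$intrinsic)) fit$intrinsic_mean <- ex$intrinsic
  fit
}
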