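test_that("free energy equals exact log evidence on conjugate linear-Gaussian models", {
  set.seed(42)
  errs <- replicate(20, {
    N <- sample(20:60, 1); p <- sample(2:6, 1)
    X <- matrix(rnorm(N * p), N, p)
    pv <- runif(p, 0.1, 2)
    tau <- runif(1, 0.5, 4)
    theta <- rnorm(p, 0, sqrt(pv))
    y <- drop(X %*% theta) + rnorm(N, 0, 1 / sqrt(tau))
    # exact Gaussian posterior
    H <- tau * crossprod(X) + diag(1 / pv, p)
    Sigma <- chol2inv(chol(H))
    mu <- drop(tau * Sigma %*% crossprod(X, y))
    Fv <- free_energy(y - drop(X %*% mu),
                      list(mean = mu, cov = Sigma),
                      list(mean = numeric(p), var = pv), tau, J = X)
    abs(Fv - exact_log_evidence(y, X, pv, tau))
  })
  expect_lt(max(errs), 1e-6)
})

test_that("free energy degenerate and monotonicity properties hold", {
  p <- 3
  prior <- list(mean = numeric(p), var = rep(2, p))
  post <- list(mean = numeric(p), cov = diag(2, p))
  # posterior = prior, zero residuals: F is the Gaussian log-normaliser only
  N <- 10; tau <- 1.5
  expect_equal(free_energy(numeric(N), post, prior, tau),
               0.5 * N * log(tau / (2 * pi)))
  # inflating posterior variance above the prior strictly decreases F
  r <- rnorm(N)
  f1 <- free_energy(r, list(mean = numeric(p), cov = diag(2, p)), prior, tau)
  f2 <- free_energy(r, list(mean = numeric(p), cov = diag(4, p)), prior, tau)
  expect_lt(f2, f1)
  expect_error(free_energy(r, list(mean = numeric(p), cov = diag(c(1, -1, 1))),
                           prior, tau), "positive definite")
})

test_that("the Laplace optimizer reaches the exact posterior on a linear model", {
  set.seed(7)
  N <- 40; p <- 3
  X <- matrix(rnorm(N * p), N, p)
  pv <- rep(0.5, p)
  theta <- c(0.7, -0.3, 0.2)
  y <- drop(X %*% theta) + rnorm(N, 0, 0.1)
  prior <- list(names = paste0("b", 1:p),
                mean = stats::setNames(numeric(p), paste0("b", 1:p)),
                var = stats::setNames(pv, paste0("b", 1:p)))
  fit <- laplace_fit(y, function(th) drop(X %*% th), prior)
  # exact posterior at the fitted noise precision
  H <- fit$tau * crossprod(X) + diag(1 / pv, p)
  mu <- drop(fit$tau * chol2inv(chol(H)) %*% crossprod(X, y))
  expect_equal(unname(fit$mean), mu, tolerance = 1e-3)
  expect_true(all(diff(fit$F_trace) >= -1e-8))
  expect_true(fit$converged)
})

test_that("predicting at the prior mean reproduces the baseline template", {
  net <- chain_network()
  cst <- default_constants(net)
  v <- chain_variants(net)$gen
  g <- bench_gain(net)
  pr <- prior_spec(net, v, free = "B")
  pred <- predict_erp(pr$mean, net, cst, v, g)
  expect_equal(dim(pred), c(12, 351, 2))
  # identical to a direct baseline simulation
  st <- simulate_sources(net, cst, condition = "control")
  expect_equal(pred[, , 1], unclass(g) %*% st$vp, ignore_attr = TRUE)
  # B = 0: both conditions coincide
  expect_equal(pred[, , 1], pred[, , 2])
  # smoothness: a tiny perturbation moves the prediction only slightly
  th <- pr$mean; th[1] <- 1e-6
  pred2 <- predict_erp(th, net, cst, v, g)
  expect_lt(max(abs(pred2 - pred)), 1e-3)
})

test_that("fitting noiseless baseline data returns the prior mean", {
  net <- chain_network()
  cst <- default_constants(net)
  v <- chain_variants(net)$gen
  g <- bench_gain(net)
  theta <- param_template(net)
  erps <- lapply(c("control", "interference"), function(cond) {
    st <- simulate_sources(net, cst, theta, cond)
    project_to_channels(st, g, Inf, subject = "s0", condition = cond)
  })
  fit <- fit_subject(erps, net, cst, v, g, prior_spec(net, v, free = "B"))
  expect_lt(max(abs(fit$mean)), 0.05)
})

test_that("posterior spread shrinks as SNR increases", {
  sds <- vapply(c(0, 10), function(snr) {
    rb <- recovery_benchmark(n_seeds = 3, snr_db = snr, seed = 5)
    rb$posterior_sd
  }, 0)
  expect_gt(sds[1], sds[2])
})

test_that("fitting null data yields smaller estimates than fitting planted data", {
  net <- chain_network()
  cst <- default_constants(net)
  v <- chain_variants(net)$gen
  g <- bench_gain(net)
  pr <- prior_spec(net, v, free = "B")
  norm_fit <- function(b, seed) {
    theta <- param_template(net)
    theta["B_f_ITG.SPL"] <- b
    erps <- dcmerp:::withr_seed(seed, dcmerp:::bench_erp_pair(theta, net, cst, g, 10))
    sqrt(sum(fit_subject(erps, net, cst, v, g, pr)$mean^2))
  }
  null_norms <- vapply(1:5, function(i) norm_fit(0, 100 + i), 0)
  alt_norms <- vapply(1:5, function(i) norm_fit(0.7, 100 + i), 0)
  expect_true(all(alt_norms > null_norms))
})
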