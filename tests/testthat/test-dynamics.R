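test_that("the centred sigmoid is zero at rest, bounded, and has the closed-form limit", {
  cst <- jr_constants(1)
  expect_identical(jr_sigmoid(0, cst), 0)
  lim <- 2 * cst$e0 - 2 * cst$e0 / (1 + exp(cst$r * cst$v0))
  expect_equal(jr_sigmoid(1e6, cst), lim, tolerance = 1e-12)
  expect_equal(lim, 4.829, tolerance = 1e-3)
  v <- seq(-50, 50, by = 0.5)
  s <- jr_sigmoid(v, cst)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > -2 * cst$e0 / (1 + exp(cst$r * cst$v0))) && all(s < lim))
  # numerical derivative at 0 matches the analytic slope
  h <- 1e-5
  slope_num <- (jr_sigmoid(h, cst) - jr_sigmoid(-h, cst)) / (2 * h)
  slope_an <- 2 * cst$e0 * cst$r * exp(cst$r * cst$v0) / (1 + exp(cst$r * cst$v0))^2
  expect_equal(slope_num, slope_an, tolerance = 1e-6)
})

test_that("rest is a fixed point of the network right-hand side and of simulation", {
  net <- chain_network()
  cst <- default_constants(net)
  eff <- dcmerp:::effective_model(net, cst, param_template(net), "control")
  d <- jr_rhs(matrix(0, 4, 6), eff, cst, u = 0)
  expect_equal(max(abs(d)), 0)
  st <- simulate_sources(net, cst, condition = "control",
                         stimulus = function(t) 0 * t)
  expect_equal(max(abs(st$vp)), 0)
})

test_that("the compiled integrator matches an R-level RK4 on the reference RHS", {
  net <- chain_network()
  cst <- default_constants(net)
  theta <- param_template(net)
  theta["B_f_ITG.SPL"] <- 0.4
  eff <- dcmerp:::effective_model(net, cst, theta, "interference")
  uw <- as.numeric(net$sources == net$input_site)
  dt <- 1; nt <- 60
  u <- stimulus_bump(seq(0, nt * dt, by = dt / 2), cst)
  s <- matrix(0, 4, 6)
  for (k in seq_len(nt)) {
    u0 <- u[2 * k - 1]; uh <- u[2 * k]; u1 <- u[2 * k + 1]
    k1 <- jr_rhs(s, eff, cst, u0, uw)
    k2 <- jr_rhs(s + dt / 2 * k1, eff, cst, uh, uw)
    k3 <- jr_rhs(s + dt / 2 * k2, eff, cst, uh, uw)
    k4 <- jr_rhs(s + dt * k3, eff, cst, u1, uw)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  st <- simulate_sources(net, cst, theta, "interference", duration = nt * dt, dt = dt)
  expect_equal(unname(st$vp[, nt + 1]), unname(s[, 2] - s[, 3]), tolerance = 1e-10)
})

test_that("an isolated linear source reproduces the alpha-kernel impulse response", {
  # impulse into the excitatory equation: y1(t) = (He/tau) t exp(-t/tau),
  # peak He/e at t = tau
  He <- 4; tau <- 10
  cst <- jr_constants(1, He = He, tau_e = tau, gamma = c(1e-9, 1e-9, 1e-9, 1e-9))
  dt <- 0.01
  u <- numeric(2 * (30 / dt) + 1)
  out <- dcmerp:::jr_integrate_cpp(
    matrix(c(0, 0, 0, 0, He / tau, 0), 1, 6), cst$He, cst$Hi,
    cst$tau_e, cst$tau_i, cst$gamma, cst$e0, cst$r, cst$v0, cst$rate_scale,
    matrix(0, 1, 1), matrix(0, 1, 1), u, 1, dt, FALSE)
  y <- drop(out$vp)
  t <- seq(0, 30, by = dt)
  expect_equal(max(y), He / exp(1), tolerance = 1e-4)
  expect_equal(t[which.max(y)], tau, tolerance = 0.05)
  expect_equal(y, (He / tau) * t * exp(-t / tau), tolerance = 1e-3)
})

test_that("disconnected sources stay at rest when only V1 is stimulated", {
  net <- chain_network()
  cst <- default_constants(net, base_fwd = 0, base_bwd = 0, base_lat = 0)
  st <- simulate_sources(net, cst, condition = "control")
  expect_gt(max(abs(st$vp["V1", ])), 0)
  expect_equal(max(abs(st$vp[-1, ])), 0)
})

test_that("halving the integration step changes traces by less than 1e-3 relative", {
  net <- chain_network()
  cst <- default_constants(net)
  s1 <- simulate_sources(net, cst, condition = "control", dt = 1)
  s2 <- simulate_sources(net, cst, condition = "control", dt = 0.5)
  v2 <- s2$vp[, seq(1, ncol(s2$vp), by = 2)]
  expect_lt(max(abs(s1$vp - v2)) / max(abs(v2)), 1e-3)
})

test_that("responses propagate causally down the forward chain", {
  net <- chain_network()
  cst <- default_constants(net)
  st <- simulate_sources(net, cst, condition = "control")
  onset <- function(v) which(abs(v) > 0.05 * max(abs(v)))[1]
  expect_lt(onset(st$vp["V1", ]), onset(st$vp["ITG", ]))
  expect_lt(onset(st$vp["ITG", ]), onset(st$vp["SPL", ]))
})

test_that("the response is linear in the small-signal limit", {
  net <- chain_network()
  cst1 <- default_constants(net, u_amp = 0.02)
  cst2 <- default_constants(net, u_amp = 0.01)
  p1 <- max(abs(simulate_sources(net, cst1, condition = "control")$vp))
  p2 <- max(abs(simulate_sources(net, cst2, condition = "control")$vp))
  expect_lt(p1, 0.1)
  expect_equal(p1 / p2, 2, tolerance = 0.02)
})

test_that("condition modulation semantics follow the A/B contract", {
  expect_equal(effective_strength(1, A = log(0.5), B = log(2),
                                  condition = "control", modulated = TRUE), 0.5)
  expect_equal(effective_strength(1, A = log(0.5), B = log(2),
                                  condition = "interference", modulated = TRUE), 1.0)
  expect_error(effective_strength(1, B = 0.3, condition = "interference",
                                  modulated = FALSE), "does not modulate")
  # B = 0 everywhere: both conditions produce identical effective models
  net <- chain_network()
  cst <- default_constants(net)
  e1 <- dcmerp:::effective_model(net, cst, param_template(net), "control")
  e2 <- dcmerp:::effective_model(net, cst, param_template(net), "interference")
  expect_identical(e1, e2)
})

test_that("swapping condition labels while negating B mirrors the traces", {
  net <- chain_network()
  cst <- default_constants(net)
  th <- param_template(net)
  th["B_f_ITG.SPL"] <- 0.5
  a <- simulate_sources(net, cst, th, "interference")
  th2 <- th
  th2["A_f_ITG.SPL"] <- 0.5   # baseline now at the modulated level
  th2["B_f_ITG.SPL"] <- -0.5
  b <- simulate_sources(net, cst, th2, "control")
  expect_equal(a$vp, b$vp, tolerance = 1e-12)
})
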