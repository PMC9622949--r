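test_that("channel projection is exact at infinite SNR and respects dimensions", {
  net <- single_source_network()
  cst <- default_constants(net)
  st <- simulate_sources(net, cst, condition = "control")
  g <- structure(matrix(1, 1, 1, dimnames = list("Cz", "A")),
                 class = c("gain_matrix", "matrix"))
  erp <- project_to_channels(st, g, snr_db = Inf)
  expect_equal(unname(erp$data[1, ]), unname(st$vp[1, ]))
  gw <- gain_matrix(chain_network())
  expect_error(project_to_channels(st, gw, Inf), "mismatch")
})

test_that("the realised channel SNR matches the requested level", {
  net <- chain_network()
  cst <- default_constants(net)
  st <- simulate_sources(net, cst, condition = "control")
  g <- bench_gain(net)
  signal <- unclass(g) %*% st$vp
  p_sig <- mean(signal^2)
  set.seed(11)
  snr_hat <- replicate(100, {
    e <- project_to_channels(st, g, snr_db = 10)
    10 * log10(p_sig / mean((e$data - signal)^2))
  })
  expect_lt(abs(mean(snr_hat) - 10), 1)
})

test_that("zero sources yield pure noise at the configured floor", {
  net <- chain_network()
  cst <- default_constants(net)
  st <- simulate_sources(net, cst, condition = "control",
                         stimulus = function(t) 0 * t)
  set.seed(2)
  erp <- project_to_channels(st, bench_gain(net), snr_db = 10, noise_floor = 0.05)
  expect_equal(sd(erp$data), 0.05, tolerance = 0.01)
})

test_that("spatial mode reduction is lossless at full rank and idempotent", {
  coh <- quick_cohort()
  erps <- coh$erps[1:4]
  full <- reduce_spatial_modes(erps, n_modes = nrow(erps[[1]]$data))
  rec <- full$back_project(full$modes[[1]])
  expect_lt(max(abs(rec - erps[[1]]$data)), 1e-10)
  red <- reduce_spatial_modes(erps, n_modes = 3)
  # projection then back-projection then projection changes nothing
  m <- red$modes[[2]]
  expect_equal(crossprod(red$projection, red$back_project(m)), m, tolerance = 1e-12)
  # captured variance is non-decreasing in the number of modes
  v <- vapply(1:6, function(k) reduce_spatial_modes(erps, k)$variance_captured, 0)
  expect_true(all(diff(v) >= -1e-12))
  expect_error(reduce_spatial_modes(erps, 0), "n_modes")
})

test_that("Positive Potential features take the windowed peak with earliest-tie rule", {
  tri <- pmax(0, 5 - abs(seq(0, 350) - 300) / 10)     # triangular, peak 5 at 300 ms
  zero <- numeric(351)
  two <- numeric(351); two[c(261, 341)] <- 3          # equal maxima at 260 and 340 ms
  dat <- rbind(tri, zero, two)
  rownames(dat) <- c("Cz", "Pz", "Fz")
  erp <- subject_erp("s1", "control", dat, rate = 1000)
  pp <- extract_pp_features(erp)
  expect_equal(pp$amplitude[pp$channel == "Cz"], 5)
  expect_equal(pp$latency[pp$channel == "Cz"], 300)
  expect_equal(pp$amplitude[pp$channel == "Pz"], 0)
  expect_equal(pp$latency[pp$channel == "Pz"], 250)   # earliest tie on a flat trace
  expect_equal(pp$latency[pp$channel == "Fz"], 260)   # earliest of two equal maxima
  expect_error(extract_pp_features(erp, window = c(400, 500)), "window")
})

test_that("feature extraction is invariant to channel order", {
  coh <- quick_cohort()
  e <- coh$erps[[1]]
  perm <- sample(nrow(e$data))
  ep <- subject_erp(e$subject, e$condition, e$data[perm, ], e$rate)
  a <- extract_pp_features(e); b <- extract_pp_features(ep)
  expect_equal(a[order(a$channel), -1], b[order(b$channel), -1],
               ignore_attr = TRUE)
})

test_that("peak amplitude is non-decreasing under amplitude scaling >= 1", {
  coh <- quick_cohort()
  e <- coh$erps[[1]]
  a <- extract_pp_features(e)
  e2 <- subject_erp(e$subject, e$condition, e$data * 1.7, e$rate)
  b <- extract_pp_features(e2)
  expect_true(all(b$amplitude >= a$amplitude))
})

test_that("the paired Wilcoxon test matches exact sign-assignment enumeration at n = 6", {
  # toy: 6 paired differences, exact two-sided p by enumerating all 2^6
  # sign assignments of the ranked |differences|
  d <- c(1.3, -0.4, 2.2, 0.8, -1.9, 0.6)
  rk <- rank(abs(d))
  Wobs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  Wall <- as.matrix(signs) %*% rk
  mu <- sum(rk) / 2
  p_exact <- mean(abs(Wall - mu) >= abs(Wobs - mu) - 1e-12)
  pp <- data.frame(subject = rep(paste0("s", 1:6), 2),
                   condition = rep(c("control", "interference"), each = 6),
                   channel = "Cz",
                   amplitude = c(numeric(6), d),
                   latency = 1)
  res <- wilcoxon_condition_test(pp)
  expect_equal(res$p_value[res$feature == "amplitude"], p_exact, tolerance = 1e-12)
  # identical conditions: degenerate p = 1, no exception
  expect_equal(res$p_value[res$feature == "latency"], 1)
  # antisymmetry: negating all differences leaves the two-sided p unchanged
  pp2 <- pp; pp2$amplitude <- c(numeric(6), -d)
  res2 <- wilcoxon_condition_test(pp2)
  expect_equal(res2$p_value[res2$feature == "amplitude"],
               res$p_value[res$feature == "amplitude"])
})

test_that("ERP CSV export round-trips", {
  coh <- quick_cohort(n_control = 2, n_patient = 0)
  path <- tempfile(fileext = ".csv")
  write_erp_csv(coh$erps[1:2], path)
  back <- read_erp_csv(path)
  expect_equal(back[[1]]$data, coh$erps[[1]]$data, tolerance = 1e-9)
  expect_identical(back[[2]]$condition, coh$erps[[2]]$condition)
})
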